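test_that("annotation files read under default and permuted column mappings", {
  p <- tempfile()
  writeLines(c("track name=x", "chr1\t100\t200\tgeneA",
               "# note", "chr2\t5\t9\tgeneB"), p)
  r <- read_annotation_file(p)
  expect_equal(nrow(r), 2L)
  expect_equal(r$name, c("geneA", "geneB"))
  expect_equal(r$start, c(100L, 5L))

  p2 <- tempfile()
  writeLines(c("geneA\tchr1\t100\t200"), p2)
  r2 <- read_annotation_file(p2, column_mapping(2, 3, 4, name = 1))
  expect_equal(r2$chrom, "chr1")
  expect_equal(r2$start, 100L)
  expect_equal(r2$name, "geneA")

  p3 <- tempfile()
  writeLines("chr1 100 200 + geneA", p3)
  r3 <- read_annotation_file(p3, column_mapping(1, 2, 3, name = 5, strand = 4))
  expect_equal(r3$strand, "+")
  expect_equal(r3$name, "geneA")
})

test_that("annotation file errors carry line numbers", {
  p <- tempfile()
  writeLines(c("chr1\t1\t2\ta", "chr1\t5"), p)
  expect_error(read_annotation_file(p), "line 2")
  writeLines(c("chr1\t1\t2\ta", "chr1\tx\t9\tb"), p)
  expect_error(read_annotation_file(p), "line 2.*non-numeric")
  writeLines(c("chr1\t1\t2\t?\ta"), p)
  expect_error(read_annotation_file(p, column_mapping(1, 2, 3, name = 5,
                                                      strand = 4)),
               "line 1.*strand")
  writeLines(c("chr1\t1\t2\ta//b"), p)
  expect_error(read_annotation_file(p), "reserved separator")
  writeLines(c("chr1\t1\t2\t.\t0\t+", "chr1\t4\t9\t.\t0\t."), p)
  expect_error(read_annotation_file(p, require_strand = TRUE),
               "line 2.*strand")
  expect_error(read_annotation_file(tempfile()), "not found")
})

test_that("column mappings validate their indices", {
  expect_error(column_mapping(0, 2, 3), "positive")
  expect_error(column_mapping(1, 2, 2), "distinct")
  m <- column_mapping(1, 2, 3, name = NA)
  expect_true(is.na(m$name))
})

test_that("output table joins hits with // and preserves duplicates", {
  q <- gr(rep("chr1", 3), c(0, 0, 50), c(20, 20, 60))
  a <- gr(c("chr1", "chr1"), c(5, 10), c(15, 30), c("TP53", "WRAP53"))
  tbl <- annotate_table(q, build_index(a, "genes"), assembly = "hg19")
  expect_equal(nrow(tbl), 3L)
  expect_equal(tbl$genes, c("TP53//WRAP53", "TP53//WRAP53", ""))
  expect_identical(unlist(tbl[1, ], use.names = FALSE),
                   unlist(tbl[2, ], use.names = FALSE))
  expect_match(tbl$link[1], "db=hg19", fixed = TRUE)

  out <- tempfile()
  write_output_table(tbl, out)
  lines <- readLines(out)
  expect_equal(length(lines), 4L)
  back <- read.table(out, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                     na.strings = NULL, colClasses = "character")
  expect_equal(strsplit(back$genes, "//", fixed = TRUE)[[1]],
               c("TP53", "WRAP53"))
  expect_equal(back$genes[3], "")
})

test_that("single-hit mode reports the first hit in sort order", {
  q <- gr("chr1", 0, 20)
  a <- gr(c("chr1", "chr1"), c(10, 5), c(30, 15), c("late", "early"))
  tbl <- annotate_table(q, build_index(a, "src"), multiple_hits = FALSE)
  expect_equal(tbl$src, "early")
})

test_that("ucsc links use display coordinates", {
  expect_equal(ucsc_link(gr("chr1", 7577505, 7577606), "hg19"),
               "https://genome.ucsc.edu/cgi-bin/hgTracks?db=hg19&position=chr1:7577506-7577606")
  expect_match(ucsc_link(gr("chr2", 5, 5), "mm10"),
               "db=mm10&position=chr2:5-5", fixed = TRUE)
})

test_that("promoters span halfwidth around the TSS with 0-clamp", {
  tr <- gr(rep("chr1", 3), c(10000, 10000, 400), c(15000, 15000, 5000),
           c("nm_x", "nm_y", "nm_z"), c("+", "-", "+"))
  pr <- make_promoters(tr)
  expect_equal(pr$start, c(9000L, 14000L, 0L))
  expect_equal(pr$end, c(11000L, 16000L, 1400L))
  expect_equal(pr$name, c("nm_x", "nm_y", "nm_z"))
  expect_error(make_promoters(gr("chr1", 0, 10, "x")), "strand")
  # width property on a random stranded fixture
  r <- generate_regions(300, seed = 71, zero_fraction = 0, stranded = TRUE,
                        chrom_length = 100000)
  w <- make_promoters(r, 250)
  expect_true(all(w$end - w$start == 500L | w$start == 0L))
})

test_that("sort_annotation_file orders by (chrom, start, end) and is idempotent", {
  p <- tempfile(); s1 <- tempfile(); s2 <- tempfile()
  writeLines(c("track x", "chr2\t5\t9\tb", "chr1\t30\t40\tc",
               "chr1\t30\t35\ta"), p)
  sort_annotation_file(p, s1)
  expect_equal(readLines(s1),
               c("track x", "chr1\t30\t35\ta", "chr1\t30\t40\tc",
                 "chr2\t5\t9\tb"))
  sort_annotation_file(s1, s2)
  expect_identical(readLines(s2), readLines(s1))
  # large fixture against an independent sort
  r <- generate_regions(5000, seed = 72, zero_fraction = 0.05)
  big <- tempfile(); sorted <- tempfile()
  write_bed(r, big)
  sort_annotation_file(big, sorted)
  got <- read.table(sorted, sep = "\t", stringsAsFactors = FALSE)
  d <- as.data.frame(r)
  o <- order(d$chrom, d$start, d$end, method = "radix")
  expect_equal(got$V2, d$start[o])
  expect_equal(got$V3, d$end[o])
})
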