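test_that("build_index partitions by chromosome and sorts by (start, end, name)", {
  a <- gr(c("chr2", "chr1", "chr1"), c(5, 30, 0), c(9, 40, 10))
  idx <- build_index(a, "s")
  r <- index_regions(idx)
  expect_equal(r$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(r$start, c(0L, 30L, 5L))
  # duplicates retained
  dup <- build_index(rbind(a, a[1, ]))
  expect_equal(nrow(index_regions(dup)), 4L)
  # empty input yields a valid empty index
  e <- build_index(genomic_regions())
  expect_equal(nrow(index_regions(e)), 0L)
  expect_equal(find_overlaps(e, a), rep(list(integer(0)), 3L))
})

test_that("index sort matches an independent full sort on a large fixture", {
  a <- generate_regions(10000, seed = 41, zero_fraction = 0.1)
  r <- index_regions(build_index(a))
  d <- as.data.frame(a)
  o <- order(d$chrom, d$start, d$end, d$name, method = "radix")
  expect_equal(r$start, d$start[o])
  expect_equal(r$end, d$end[o])
  expect_equal(r$name, d$name[o])
})

test_that("overlap queries handle gaps, containment and absent chromosomes", {
  idx <- build_index(gr(c("chr1", "chr1"), c(0, 30), c(10, 40),
                        c("a", "b")))
  expect_equal(find_overlaps(idx, gr("chr1", 15, 20))[[1]], integer(0))
  expect_equal(find_overlaps(idx, gr("chr9", 0, 50))[[1]], integer(0))
  nest <- build_index(gr(c("chr1", "chr1"), c(0, 5), c(10, 50)))
  expect_equal(find_overlaps(nest, gr("chr1", 8, 9))[[1]], c(1L, 2L))
})

test_that("query order is preserved regardless of internal sorting", {
  q <- generate_regions(300, seed = 42, zero_fraction = 0.1)
  a <- generate_regions(200, seed = 43, zero_fraction = 0.1)
  idx <- build_index(a)
  base_ov <- find_overlaps(idx, q)
  base_nb <- find_neighbors(idx, q)
  set.seed(99)
  perm <- sample(nrow(q))
  expect_identical(find_overlaps(idx, q[perm, ]), base_ov[perm])
  expect_identical(find_neighbors(idx, q[perm, ]),
                   `rownames<-`(base_nb[perm, ], NULL))
})

test_that("repeated batches give identical results (cursors reset)", {
  q <- generate_regions(200, seed = 44)
  a <- generate_regions(150, seed = 45)
  idx <- build_index(a)
  first <- find_overlaps(idx, q)
  expect_identical(find_overlaps(idx, q), first)
  nb <- find_neighbors(idx, q)
  expect_identical(find_neighbors(idx, q), nb)
})

test_that("neighbors follow the max-end / min-start definition with distances", {
  idx <- build_index(gr(c("chr1", "chr1"), c(0, 30), c(10, 40)))
  nb <- find_neighbors(idx, gr("chr1", 15, 20))
  expect_equal(nb$left, 1L)
  expect_equal(nb$left_dist, 5L)
  expect_equal(nb$right, 2L)
  expect_equal(nb$right_dist, 10L)
  # the only annotation overlaps: no neighbor on either side
  solo <- find_neighbors(build_index(gr("chr1", 0, 10)), gr("chr1", 5, 8))
  expect_true(is.na(solo$left) && is.na(solo$right))
})

test_that("nested annotations: left neighbor is the max-end, not last-by-start", {
  idx <- build_index(gr(c("chr1", "chr1"), c(0, 40), c(100, 45)))
  nb <- find_neighbors(idx, gr("chr1", 200, 210))
  expect_equal(nb$left, 1L)
  expect_equal(nb$left_dist, 100L)
  expect_true(is.na(nb$right))
})

test_that("abutting proper annotations are zero-distance neighbors; boundary points are not", {
  idx <- build_index(gr(c("chr1", "chr1"), c(0, 20), c(10, 30)))
  nb <- find_neighbors(idx, gr("chr1", 10, 20))
  expect_equal(nb$left_dist, 0L)
  expect_equal(nb$right_dist, 0L)
  # a zero-length annotation on the boundary overlaps, so it is skipped
  # and the next-best becomes the neighbor
  idx2 <- build_index(gr(c("chr1", "chr1"), c(10, 2), c(10, 7)))
  nb2 <- find_neighbors(idx2, gr("chr1", 10, 20))
  expect_equal(nb2$left, 2L)
  expect_equal(nb2$left_dist, 3L)
  expect_true(region_overlaps(gr("chr1", 10, 10), gr("chr1", 10, 20)))
})

test_that("neighbor ties break deterministically by (end, start, name)", {
  a <- gr(rep("chr1", 3), c(0, 5, 5), c(10, 10, 10), c("zeta", "beta", "alpha"))
  nb <- find_neighbors(build_index(a), gr("chr1", 50, 60))
  # same end 10: prefer maximal start 5, then smallest name "alpha"
  expect_equal(nb$left, 3L)
  b <- gr(rep("chr1", 3), c(80, 80, 80), c(99, 90, 90), c("c", "b", "a"))
  nb2 <- find_neighbors(build_index(b), gr("chr1", 50, 60))
  # same start 80: prefer minimal end 90, then name "a"
  expect_equal(nb2$right, 3L)
})

test_that("no annotation is reported both as overlap and neighbor", {
  q <- generate_regions(500, seed = 46, zero_fraction = 0.15,
                        n_chromosomes = 2, chrom_length = 5000,
                        max_length = 200)
  a <- generate_regions(300, seed = 47, zero_fraction = 0.15,
                        n_chromosomes = 2, chrom_length = 5000,
                        max_length = 200)
  idx <- build_index(a)
  ov <- find_overlaps(idx, q)
  nb <- find_neighbors(idx, q)
  for (i in seq_len(nrow(q))) {
    expect_false(nb$left[i] %in% ov[[i]])
    expect_false(nb$right[i] %in% ov[[i]])
  }
})

test_that("engine equals the brute-force oracle on dense mixed fixtures", {
  for (s in c(51, 52, 53)) {
    q <- generate_regions(800, seed = s, zero_fraction = 0.2,
                          n_chromosomes = 3, chrom_length = 4000,
                          max_length = 150)
    a <- generate_regions(600, seed = s + 10, zero_fraction = 0.2,
                          n_chromosomes = 3, chrom_length = 4000,
                          max_length = 150)
    a <- rbind(a, a[1:25, ])  # duplicated annotations
    idx <- build_index(a)
    expect_identical(find_overlaps(idx, q), oracle_overlaps(q, a))
    expect_identical(find_neighbors(idx, q), oracle_neighbors(q, a))
  }
})
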