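# Readers and writers: BED / custom-column annotation files, the
# tab-delimited output table with "//"-joined hits and UCSC links, and
# annotation-preparation helpers (promoter construction, file sorting).

#' Column mapping for annotation files
#'
#' Describes which 1-based column of a delimited annotation file holds each
#' field. The default is standard BED (`chrom`, `start`, `end`, `name` in
#' columns 1-4, strand in column 6 when present); the 5-column stranded
#' distance format "chromosome start end strand annotation" corresponds to
#' `column_mapping(1, 2, 3, name = 5, strand = 4)`.
#'
#' @param chrom,start,end,name 1-based column indices; `name` may be `NA`
#'   (no name column).
#' @param strand Optional 1-based strand column index (`NULL` for none).
#' @return An object of class `column_mapping`.
#' @export
column_mapping <- function(chrom = 1L, start = 2L, end = 3L, name = 4L,
                           strand = NULL) {
  idx <- c(chrom = chrom, start = start, end = end,
           name = if (is.na(name)) NULL else name,
           strand = strand)
  idx <- as.integer(idx)
  if (any(is.na(idx)) || any(idx < 1L))
    stop("column indices must be positive integers", call. = FALSE)
  if (anyDuplicated(idx))
    stop("column indices must be pairwise distinct", call. = FALSE)
  structure(list(chrom = as.integer(chrom), start = as.integer(start),
                 end = as.integer(end),
                 name = if (is.na(name)) NA_integer_ else as.integer(name),
                 strand = if (is.null(strand)) NA_integer_
                          else as.integer(strand)),
            class = "column_mapping")
}

# standard BED mapping but tolerant of 3-column files (name column optional)
.bed_mapping <- function() column_mapping(1L, 2L, 3L, name = 4L, strand = 6L)

#' Read an annotation file
#'
#' Reads a whitespace/tab-delimited annotation file using a
#' [column_mapping()]. Coordinates are taken as 0-based half-open (BED
#' convention). Lines starting with `track`, `browser` or `#` and empty
#' lines are skipped; errors report the offending line number. Strand
#' column values must be `+`, `-` or `.` (unstranded); name and strand
#' columns beyond a line's field count yield `NA`. Names containing the
#' reserved output separator `"//"` are rejected at ingest.
#'
#' @param path File path.
#' @param mapping A [column_mapping()]; default standard BED.
#' @param require_strand If `TRUE`, every record must carry `+` or `-`
#'   strand (used by distance annotation).
#' @return A [genomic_regions] object in file order.
#' @export
read_annotation_file <- function(path, mapping = .bed_mapping(),
                                 require_strand = FALSE) {
  if (!file.exists(path))
    stop(sprintf("annotation file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) &
                  !grepl("^[ \t]*(track|browser)\\b", lines) &
                  !grepl("^[ \t]*#", lines))
  if (!length(keep)) return(genomic_regions())
  parts <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(parts)
  need <- max(mapping$chrom, mapping$start, mapping$end,
              if (require_strand && !is.na(mapping$strand)) mapping$strand
              else 0L)
  short <- which(nf < need)
  if (length(short))
    .err_line(keep[short[1L]],
              sprintf("expected at least %d fields, found %d", need,
                      nf[short[1L]]))
  col <- function(i, default = NA_character_) {
    out <- rep(default, length(parts))
    ok <- nf >= i
    out[ok] <- vapply(parts[ok], `[[`, "", i)
    out
  }
  chrom <- col(mapping$chrom)
  start <- mapply(.parse_coord, col(mapping$start), keep)
  end <- mapply(.parse_coord, col(mapping$end), keep)
  bad <- which(end < start)
  if (length(bad))
    .err_line(keep[bad[1L]], "end before start")
  name <- if (is.na(mapping$name)) rep(NA_character_, length(parts))
          else col(mapping$name)
  badnm <- which(grepl("//", name, fixed = TRUE))
  if (length(badnm))
    .err_line(keep[badnm[1L]],
              sprintf("annotation name '%s' contains the reserved separator '//'",
                      name[badnm[1L]]))
  strand <- rep(NA_character_, length(parts))
  if (!is.na(mapping$strand)) {
    sv <- col(mapping$strand)
    badst <- which(!is.na(sv) & !sv %in% c("+", "-", "."))
    if (length(badst))
      .err_line(keep[badst[1L]],
                sprintf("unknown strand symbol '%s'", sv[badst[1L]]))
    strand <- ifelse(sv %in% c("+", "-"), sv, NA_character_)
  }
  if (require_strand) {
    badst <- which(is.na(strand))
    if (length(badst))
      .err_line(keep[badst[1L]], "record lacks strand information")
  }
  genomic_regions(chrom, start, end, name = name, strand = strand)
}

#' Write the tab-delimited annotation table
#'
#' One header line (unless suppressed) followed by one row per query region
#' in input order, duplicates included. Multiple hits within a cell are
#' joined by the literal separator `"//"`; a query with no hits gets an
#' empty cell.
#'
#' @param tbl A data frame of character columns (first column the formatted
#'   query region).
#' @param path Destination file.
#' @param header Write the column-name header line?
#' @return Invisibly, `path`.
#' @export
write_output_table <- function(tbl, path, header = TRUE) {
  tbl <- as.data.frame(tbl, check.names = FALSE, stringsAsFactors = FALSE)
  for (j in seq_along(tbl)) {
    v <- as.character(tbl[[j]])
    v[is.na(v)] <- ""
    tbl[[j]] <- v
  }
  utils::write.table(tbl, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = header)
  invisible(path)
}

#' UCSC genome browser link for a region
#'
#' Builds an hgTracks URL displaying the region in the chosen assembly,
#' using the 1-based inclusive position string.
#'
#' @param r A [genomic_regions] object.
#' @param assembly Genome assembly label (e.g. `"hg19"`, `"mm9"`).
#' @return Character vector of URLs.
#' @examples
#' ucsc_link(genomic_regions("chr1", 7577505, 7577606), "hg19")
#' @export
ucsc_link <- function(r, assembly) {
  if (length(assembly) != 1L || is.na(assembly) || !nzchar(assembly))
    stop("assembly label required", call. = FALSE)
  sprintf("https://genome.ucsc.edu/cgi-bin/hgTracks?db=%s&position=%s",
          assembly, format_region(r, "positions"))
}

#' Build promoter regions around transcription start sites
#'
#' The TSS of a transcript is its start on the plus strand and its end on
#' the minus strand. The promoter is the window of `halfwidth` bases
#' upstream and downstream of the TSS (default 1 kb each side), clamped at
#' coordinate 0; the transcript's name and strand are inherited.
#'
#' @param transcripts Stranded [genomic_regions].
#' @param halfwidth Bases on each side of the TSS (default 1000).
#' @return A [genomic_regions] object of promoters.
#' @examples
#' make_promoters(genomic_regions("chr1", 10000, 15000, "nm_x", "+"))
#' @export
make_promoters <- function(transcripts, halfwidth = 1000L) {
  tr <- as_genomic_regions(transcripts)
  halfwidth <- as.integer(halfwidth)
  bad <- which(is.na(tr$strand))
  if (length(bad))
    stop(sprintf("unstranded transcript %s: promoter construction requires strand",
                 format_region(tr[bad[1L], , drop = FALSE], "positions")),
         call. = FALSE)
  tss <- ifelse(tr$strand == "+", tr$start, tr$end)
  genomic_regions(tr$chrom, pmax(0L, tss - halfwidth), tss + halfwidth,
                  name = tr$name, strand = tr$strand)
}

#' Sort an annotation file by chromosome, start and end
#'
#' Reorders the data lines of a delimited annotation file by
#' `(chromosome, start, end)` (chromosome compared case-insensitively,
#' lexicographically) without altering line content. Comment/track lines
#' are kept at the top in their original order. Sorting is stable, so an
#' already-sorted file is rewritten unchanged.
#'
#' @param in_path,out_path Input and output file paths.
#' @param mapping A [column_mapping()] locating the coordinate columns.
#' @return Invisibly, `out_path`.
#' @export
sort_annotation_file <- function(in_path, out_path,
                                 mapping = column_mapping()) {
  if (!file.exists(in_path))
    stop(sprintf("annotation file not found: %s", in_path), call. = FALSE)
  lines <- readLines(in_path, warn = FALSE)
  is_data <- nzchar(trimws(lines)) &
    !grepl("^[ \t]*(track|browser)\\b", lines) &
    !grepl("^[ \t]*#", lines)
  data_idx <- which(is_data)
  if (!length(data_idx)) {
    writeLines(lines, out_path)
    return(invisible(out_path))
  }
  parts <- strsplit(trimws(lines[data_idx]), "[ \t]+")
  nf <- lengths(parts)
  need <- max(mapping$chrom, mapping$start, mapping$end)
  short <- which(nf < need)
  if (length(short))
    .err_line(data_idx[short[1L]],
              sprintf("expected at least %d fields, found %d", need,
                      nf[short[1L]]))
  chrom <- tolower(vapply(parts, `[[`, "", mapping$chrom))
  start <- mapply(.parse_coord, vapply(parts, `[[`, "", mapping$start),
                  data_idx)
  end <- mapply(.parse_coord, vapply(parts, `[[`, "", mapping$end),
                data_idx)
  o <- order(chrom, start, end, method = "radix")
  writeLines(c(lines[!is_data], lines[data_idx][o]), out_path)
  invisible(out_path)
}
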