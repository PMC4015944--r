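#' Construct a set of genomic regions
#'
#' The basic container used throughout the package for both query regions and
#' annotations. A region is a chromosome-addressed interval in the 0-based
#' half-open convention native to BED: `[start, end)` covers offsets
#' `start ... end - 1` and `start == end` denotes a zero-length element (an
#' insertion point, as found e.g. in genome-variation data). Chromosome labels
#' are matched case-insensitively and stored lower-cased; `"1"` and `"chr1"`
#' remain distinct labels.
#'
#' @param chrom Character vector of chromosome labels.
#' @param start,end Integer base offsets, `0 <= start <= end`. `end` is the
#'   exclusive bound.
#' @param name Optional character vector of region/annotation identifiers
#'   (`NA` for unnamed). Names may not contain the output cell separator
#'   `"//"`.
#' @param strand Optional strand, `"+"`, `"-"` or `NA` (unstranded).
#'
#' @return A data frame of class `genomic_regions` with columns `chrom`,
#'   `start`, `end`, `name`, `strand`; one row per region.
#'
#' @examples
#' genomic_regions("Chr1", 7577505, 7577606, name = "TP53")
#' genomic_regions("chr1", 5, 5)   # zero-length insertion point
#' @export
genomic_regions <- function(chrom = character(), start = integer(),
                            end = integer(), name = NA_character_,
                            strand = NA_character_) {
  n <- max(length(chrom), length(start), length(end))
  if (length(chrom) == 0L || length(start) == 0L || length(end) == 0L) n <- 0L
  chrom <- rep_len(tolower(as.character(chrom)), n)
  start <- rep_len(.as_coord(start), n)
  end <- rep_len(.as_coord(end), n)
  name <- rep_len(as.character(name), n)
  strand <- rep_len(as.character(strand), n)
  if (n > 0L) {
    if (anyNA(chrom) || any(!nzchar(chrom)))
      stop("missing or empty chromosome label", call. = FALSE)
    if (anyNA(start) || anyNA(end))
      stop("missing start/end coordinate", call. = FALSE)
    if (any(start < 0L))
      stop("negative start coordinate", call. = FALSE)
    bad <- which(end < start)
    if (length(bad))
      stop(sprintf("end before start (%s:%d-%d)",
                   chrom[bad[1L]], start[bad[1L]], end[bad[1L]]),
           call. = FALSE)
    if (!all(strand %in% c("+", "-", NA_character_)))
      stop("strand must be '+', '-' or NA", call. = FALSE)
    if (any(grepl("//", name, fixed = TRUE), na.rm = TRUE))
      stop("region names may not contain the reserved separator '//'",
           call. = FALSE)
  }
  df <- data.frame(chrom = chrom, start = start, end = end, name = name,
                   strand = strand, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  class(df) <- c("genomic_regions", "data.frame")
  df
}

.as_coord <- function(x) {
  x <- as.numeric(x)
  bad <- !is.na(x) & (x != trunc(x) | abs(x) >= .Machine$integer.max)
  if (any(bad)) stop("coordinate not a representable integer", call. = FALSE)
  as.integer(x)
}

#' Coerce to genomic_regions
#'
#' Accepts a `genomic_regions` object (returned unchanged) or any data frame
#' with at least `chrom`, `start`, `end` columns (optional `name`, `strand`).
#'
#' @param x Object to coerce.
#' @return A `genomic_regions` object.
#' @export
as_genomic_regions <- function(x) {
  if (inherits(x, "genomic_regions")) return(x)
  if (is.data.frame(x)) {
    need <- c("chrom", "start", "end")
    if (!all(need %in% names(x)))
      stop("data frame needs columns chrom, start, end", call. = FALSE)
    return(genomic_regions(
      x$chrom, x$start, x$end,
      name = if ("name" %in% names(x)) x$name else NA_character_,
      strand = if ("strand" %in% names(x)) x$strand else NA_character_))
  }
  stop("cannot coerce to genomic_regions", call. = FALSE)
}

#' @export
print.genomic_regions <- function(x, ...) {
  cat(sprintf("genomic_regions with %d region%s\n", nrow(x),
              if (nrow(x) == 1L) "" else "s"))
  if (nrow(x) > 0L) {
    show <- utils::head(as.data.frame(x), 10L)
    print(show, ...)
    if (nrow(x) > 10L) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  }
  invisible(x)
}

.err_line <- function(line, msg) {
  if (is.na(line)) stop(msg, call. = FALSE)
  stop(sprintf("line %d: %s", line, msg), call. = FALSE)
}

.parse_coord <- function(tok, line = NA_integer_) {
  stripped <- gsub(",", "", tok, fixed = TRUE)
  if (!grepl("^[0-9]+$", stripped))
    .err_line(line, sprintf("non-numeric coordinate '%s'", tok))
  .as_coord(as.numeric(stripped))
}

#' Parse one query-region line
#'
#' Tolerant parser for the position-coordinate and column dialects accepted
#' for query input. All of the following parse to the same coordinates:
#' `"chr1:7577506-7577606"`, `"Chr1:7,577,506-7,577,606"`,
#' `"CHR1 7577506 7,577,606"` (space- or tab-separated). Chromosome case is
#' folded to lower case and thousands separators are stripped. Colon (between
#' chromosome and start) and minus (between start and end) are
#' interchangeable with runs of spaces/tabs. Lines with three or more
#' whitespace-separated fields are treated as columns (BED-style:
#' chrom, start, end, optional name in column 4 and strand in column 6).
#'
#' Coordinates are returned exactly as printed in the input; conversion
#' between the 1-based inclusive display convention and the package's
#' internal 0-based half-open convention is [normalize_region()]'s job.
#'
#' @param text A single non-empty line.
#' @param line Optional input line number, used in error messages.
#' @return A one-row [genomic_regions] object (coordinates as printed).
#' @seealso [normalize_region()], [format_region()], [read_queries()]
#' @examples
#' parse_region_string("Chr2:7,577,506-7,577,606")
#' @export
parse_region_string <- function(text, line = NA_integer_) {
  raw <- trimws(text)
  if (length(raw) != 1L || is.na(raw) || !nzchar(raw))
    .err_line(line, "empty query line")
  toks <- strsplit(raw, "[ \t]+")[[1L]]
  if (length(toks) < 3L) {
    # position-coordinate dialect: break on colon, and on minus between digits
    expanded <- gsub(":", " ", raw, fixed = TRUE)
    expanded <- gsub("(?<=[0-9,])-(?=[0-9,])", " ", expanded, perl = TRUE)
    toks <- strsplit(trimws(expanded), "[ \t]+")[[1L]]
  }
  if (length(toks) < 3L)
    .err_line(line, sprintf("cannot find chromosome, start and end in '%s'", raw))
  chrom <- toks[1L]
  start <- .parse_coord(toks[2L], line)
  end <- .parse_coord(toks[3L], line)
  if (end < start)
    .err_line(line, sprintf("end before start in '%s'", raw))
  name <- if (length(toks) >= 4L) toks[4L] else NA_character_
  strand <- if (length(toks) >= 6L && toks[6L] %in% c("+", "-"))
    toks[6L] else NA_character_
  genomic_regions(chrom, start, end, name = name, strand = strand)
}

#' Convert parsed coordinates to the internal convention
#'
#' Internally all regions are 0-based half-open (BED native). Input parsed
#' from BED (`convention = "bed"`) passes through unchanged. Input parsed
#' from position coordinates (`convention = "positions"`, the 1-based
#' inclusive convention used by genome browsers) has its start shifted down
#' by one. Rows with `start == end` are taken to be zero-length insertion
#' points already expressed on the half-open scale and pass through
#' unchanged under either convention (see the package vignette for the
#' display convention of zero-length elements).
#'
#' @param r A [genomic_regions] object with coordinates as printed.
#' @param convention `"bed"` or `"positions"`.
#' @return A [genomic_regions] object in the internal convention.
#' @examples
#' r <- parse_region_string("chr1:7577506-7577606")
#' normalize_region(r, "positions")
#' @export
normalize_region <- function(r, convention = c("bed", "positions")) {
  convention <- match.arg(convention)
  r <- as_genomic_regions(r)
  if (convention == "positions") {
    shift <- r$start < r$end
    if (any(shift & r$start == 0L))
      stop("coordinate 0 is not valid in 1-based positions input", call. = FALSE)
    r$start[shift] <- r$start[shift] - 1L
  }
  r
}

#' Compare two base positions
#'
#' The three-valued position-relation primitive from which all overlap
#' configurations are derived: any two positions are related by exactly one
#' of less-than, equality, or greater-than.
#'
#' @param a,b Integer base offsets (vectorized, recycled).
#' @return Character vector over `"less"`, `"equal"`, `"greater"`.
#' @examples
#' compare_positions(5, 9)
#' @export
compare_positions <- function(a, b) {
  c("less", "equal", "greater")[sign(as.numeric(a) - as.numeric(b)) + 2]
}

#' Format regions as text
#'
#' `"positions"` renders the 1-based inclusive display form
#' `"chrN:start-end"` (the inverse of [normalize_region()]); zero-length
#' regions render on their raw half-open bounds as `"chrN:p-p"`. `"bed"`
#' renders tab-separated `chrom`, `start`, `end` on the internal 0-based
#' half-open scale.
#'
#' @param r A [genomic_regions] object (internal convention).
#' @param convention `"positions"` or `"bed"`.
#' @return Character vector, one string per region.
#' @examples
#' format_region(genomic_regions("chr1", 7577505, 7577606), "positions")
#' @export
format_region <- function(r, convention = c("positions", "bed")) {
  convention <- match.arg(convention)
  r <- as_genomic_regions(r)
  if (convention == "bed")
    return(paste(r$chrom, r$start, r$end, sep = "\t"))
  disp_start <- ifelse(r$start == r$end, r$start, r$start + 1L)
  sprintf("%s:%d-%d", r$chrom, disp_start, r$end)
}

#' Read query regions from a file
#'
#' Reads one query region per line, skipping empty lines and `track`,
#' `browser` and `#` comment lines, and returns regions in the internal
#' 0-based half-open convention. Duplicated query lines are preserved and
#' annotated independently (duplicates typically represent alternatively
#' spliced transcripts sharing coordinates).
#'
#' @param path Path to the query file, or `NULL` when `text` is given.
#' @param format `"auto"` (default), `"bed"` or `"positions"`. Under
#'   `"auto"`, a line containing a colon or thousands separators is read as
#'   1-based position coordinates; plain column lines are read as BED.
#' @param text Optional character vector of lines, used instead of `path`.
#' @return A [genomic_regions] object, one row per query line, in input
#'   order.
#' @export
read_queries <- function(path = NULL, format = c("auto", "bed", "positions"),
                         text = NULL) {
  format <- match.arg(format)
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  keep <- which(nzchar(trimws(lines)) &
                  !grepl("^[ \t]*(track|browser)\\b", lines) &
                  !grepl("^[ \t]*#", lines))
  if (length(keep) == 0L)
    return(genomic_regions())
  parts <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    r <- parse_region_string(lines[ln], line = ln)
    conv <- switch(format,
                   bed = "bed",
                   positions = "positions",
                   auto = if (grepl("[:,]", lines[ln])) "positions" else "bed")
    parts[[i]] <- normalize_region(r, conv)
  }
  out <- do.call(rbind, lapply(parts, as.data.frame))
  rownames(out) <- NULL
  class(out) <- c("genomic_regions", "data.frame")
  out
}
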