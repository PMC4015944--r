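# Start-sorted per-chromosome annotation index with memoized sweep cursors.
#
# The engine mirrors the sorted-sweep idea: annotations are kept per
# chromosome sorted by (start, end, name); queries are processed in start
# order while a per-chromosome cursor advances monotonically past the front
# of the list. The cursor only moves past an annotation when its end precedes
# the current (and hence every future) query start, so a long annotation that
# spans many queries is never skipped; candidates between the cursor and the
# start-bound break are scanned but reported only if they truly overlap.

#' Build a per-chromosome annotation index
#'
#' Partitions annotations by chromosome and sorts each partition by
#' `(start, end, name)`. Duplicate annotations are retained. The index keeps
#' a memoized sweep cursor per chromosome (reset at the start of each query
#' batch) and a secondary end-sorted view used by neighbor queries.
#'
#' @param annotations A [genomic_regions] object (any order).
#' @param source_name Label for this annotation source; used as the output
#'   column name.
#' @return An object of class `annotation_index`.
#' @seealso [find_overlaps()], [find_neighbors()], [index_regions()]
#' @export
build_index <- function(annotations, source_name = "annotation") {
  a <- as_genomic_regions(annotations)
  nm <- ifelse(is.na(a$name), "", a$name)
  o <- order(a$chrom, a$start, a$end, nm, method = "radix")
  regions <- as.data.frame(a)[o, , drop = FALSE]
  regions$.row <- o  # original input position of each sorted row
  rownames(regions) <- NULL
  if (nrow(regions) > 0L) {
    runs <- rle(regions$chrom)
    to <- cumsum(runs$lengths)
    from <- to - runs$lengths + 1L
    names(from) <- names(to) <- runs$values
  } else {
    from <- to <- integer(0)
  }
  # end-sorted view per chromosome: (end asc, start asc, name desc), so that
  # walking it backwards visits left-neighbor candidates in preference order;
  # the final reversed-input-order key makes full duplicates resolve to the
  # earliest input record, matching the forward (right-neighbor) direction
  end_view <- lapply(seq_along(from), function(i) {
    rows <- from[i]:to[i]
    nm_i <- ifelse(is.na(regions$name[rows]), "", regions$name[rows])
    rows[order(regions$end[rows], regions$start[rows], nm_i, seq_along(rows),
               method = "radix", decreasing = c(FALSE, FALSE, TRUE, TRUE))]
  })
  names(end_view) <- names(from)
  structure(list(source_name = source_name, regions = regions,
                 chrom_from = from, chrom_to = to, end_view = end_view,
                 cursors = new.env(parent = emptyenv())),
            class = "annotation_index")
}

#' Regions stored in an index
#'
#' @param index An [build_index()] result.
#' @return The indexed regions as a [genomic_regions] object, sorted by
#'   `(chrom, start, end, name)`.
#' @export
index_regions <- function(index) {
  r <- index$regions
  r$.row <- NULL
  class(r) <- c("genomic_regions", "data.frame")
  r
}

#' @export
print.annotation_index <- function(x, ...) {
  cat(sprintf("annotation_index '%s': %d regions on %d chromosome%s\n",
              x$source_name, nrow(x$regions), length(x$chrom_from),
              if (length(x$chrom_from) == 1L) "" else "s"))
  invisible(x)
}

#' Batch overlap query against an index
#'
#' For every query region, finds all indexed annotations on the same
#' chromosome that overlap it (see [region_overlaps()] for the convention).
#' Queries need not be sorted: the engine sorts them by start internally,
#' sweeps each chromosome once with a memoized cursor, and restores input
#' order in the result.
#'
#' @param index An [annotation_index][build_index()].
#' @param queries A [genomic_regions] object.
#' @return A list with one element per query (input order): an integer
#'   vector of positions into the annotation set the index was built from,
#'   ordered by `(start, end, name)`. Empty vector when nothing overlaps.
#' @export
find_overlaps <- function(index, queries) {
  q <- as_genomic_regions(queries)
  res <- rep(list(integer(0)), nrow(q))
  for (ch in intersect(unique(q$chrom), names(index$chrom_from))) {
    rows <- index$chrom_from[[ch]]:index$chrom_to[[ch]]
    astart <- index$regions$start[rows]
    aend <- index$regions$end[rows]
    aorig <- index$regions$.row[rows]
    qi <- which(q$chrom == ch)
    qs <- q$start[qi]
    qe <- q$end[qi]
    hi <- findInterval(qe, astart)  # number of annotation starts <= query end
    cur <- 1L
    na <- length(astart)
    for (k in order(qs, method = "radix")) {
      s <- qs[k]
      while (cur <= na && aend[cur] < s) cur <- cur + 1L
      h <- hi[k]
      if (h >= cur) {
        cand <- cur:h
        m <- .ov(s, qe[k], astart[cand], aend[cand])
        if (any(m)) res[[qi[k]]] <- aorig[cand[m]]
      }
    }
    assign(ch, cur, envir = index$cursors)  # memoized sweep position
  }
  res
}

#' Batch neighbor query against an index
#'
#' For every query region, finds the nearest non-overlapping annotation on
#' each side. The left neighbor is the annotation with maximal end position
#' `<=` the query start (ties: maximal start, then lexicographically
#' smallest name); the right neighbor has minimal start `>=` the query end
#' (ties: minimal end, then name). An annotation that overlaps the query is
#' never a neighbor; in particular a zero-length annotation sitting exactly
#' on a query boundary overlaps and is skipped, while an abutting proper
#' annotation is a neighbor at distance 0. Distances follow the convention:
#' left distance = query start - annotation end; right distance =
#' annotation start - query end (both non-negative).
#'
#' @param index An [annotation_index][build_index()].
#' @param queries A [genomic_regions] object.
#' @return A data frame, one row per query (input order), with columns
#'   `left`, `left_dist`, `right`, `right_dist`; `left`/`right` are
#'   positions into the annotation set the index was built from (`NA` when
#'   that side has no neighbor).
#' @export
find_neighbors <- function(index, queries) {
  q <- as_genomic_regions(queries)
  n <- nrow(q)
  left <- right <- rep(NA_integer_, n)
  left_dist <- right_dist <- rep(NA_integer_, n)
  for (ch in intersect(unique(q$chrom), names(index$chrom_from))) {
    rows <- index$chrom_from[[ch]]:index$chrom_to[[ch]]
    astart <- index$regions$start[rows]
    aend <- index$regions$end[rows]
    aorig <- index$regions$.row[rows]
    ev <- index$end_view[[ch]] - index$chrom_from[[ch]] + 1L  # local indices
    e_end <- aend[ev]
    qi <- which(q$chrom == ch)
    qs <- q$start[qi]
    qe <- q$end[qi]
    na <- length(astart)

    # left: last end-view position with end <= query start, stepping back
    # over boundary cases that actually overlap (zero-length elements)
    k <- findInterval(qs, e_end)
    sel <- which(k > 0L)
    if (length(sel)) {
      cand <- ev[k[sel]]
      ovl <- .ov(qs[sel], qe[sel], astart[cand], aend[cand])
      for (i in sel[ovl]) {
        kk <- k[i]
        while (kk > 0L) {
          cc <- ev[kk]
          if (!.ov(qs[i], qe[i], astart[cc], aend[cc])) break
          kk <- kk - 1L
        }
        k[i] <- kk
      }
      sel <- which(k > 0L)
      cand <- ev[k[sel]]
      left[qi[sel]] <- aorig[cand]
      left_dist[qi[sel]] <- qs[sel] - aend[cand]
    }

    # right: first start-order position with start >= query end, stepping
    # forward over boundary cases that overlap
    j <- findInterval(qe - 1L, astart) + 1L
    sel <- which(j <= na)
    if (length(sel)) {
      ovl <- .ov(qs[sel], qe[sel], astart[j[sel]], aend[j[sel]])
      for (i in sel[ovl]) {
        jj <- j[i]
        while (jj <= na && .ov(qs[i], qe[i], astart[jj], aend[jj]))
          jj <- jj + 1L
        j[i] <- jj
      }
      sel <- which(j <= na)
      right[qi[sel]] <- aorig[j[sel]]
      right_dist[qi[sel]] <- astart[j[sel]] - qe[sel]
    }
  }
  data.frame(left = left, left_dist = left_dist,
             right = right, right_dist = right_dist)
}
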