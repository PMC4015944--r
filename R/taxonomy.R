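# Overlap predicate and the 16-class configuration taxonomy.
#
# Convention (the unique natural one under which exhaustive enumeration yields
# exactly 16 classes): two proper intervals overlap iff their half-open
# intersection is non-empty (abutting intervals do NOT overlap); a zero-length
# element at p overlaps a proper interval [s, e) iff s <= p <= e (touching
# either boundary counts -- an insertion point at a boundary lies "in" the
# interval); two zero-length elements overlap iff they coincide.

# relation codes used internally: 1 = less, 2 = equal, 3 = greater
.rel <- function(a, b) sign(as.numeric(a) - as.numeric(b)) + 2

# core predicate on raw coordinates, same chromosome assumed; vectorized
.ov <- function(qs, qe, as_, ae) {
  n <- max(length(qs), length(qe), length(as_), length(ae))
  qs <- rep_len(qs, n); qe <- rep_len(qe, n)
  as_ <- rep_len(as_, n); ae <- rep_len(ae, n)
  qp <- qs == qe
  ap <- as_ == ae
  out <- qs < ae & as_ < qe
  i <- qp & !ap
  if (any(i)) out[i] <- as_[i] <= qs[i] & qs[i] <= ae[i]
  i <- !qp & ap
  if (any(i)) out[i] <- qs[i] <= as_[i] & as_[i] <= qe[i]
  i <- qp & ap
  if (any(i)) out[i] <- qs[i] == as_[i]
  out
}

#' Do a query region and an annotation region overlap?
#'
#' Pairwise (vectorized) overlap test. Proper intervals overlap when their
#' half-open intersection is non-empty, so abutting intervals do not overlap.
#' A zero-length element overlaps a proper interval when it lies inside it or
#' on either boundary, and two zero-length elements overlap only when they
#' coincide. Regions on different chromosomes never overlap.
#'
#' @param q,a [genomic_regions] objects; rows are paired (length-1 arguments
#'   are recycled).
#' @return Logical vector.
#' @examples
#' region_overlaps(genomic_regions("chr1", 10, 20), genomic_regions("chr1", 20, 30))
#' region_overlaps(genomic_regions("chr1", 5, 5), genomic_regions("chr1", 0, 5))
#' @export
region_overlaps <- function(q, a) {
  q <- as_genomic_regions(q)
  a <- as_genomic_regions(a)
  if (nrow(q) == 0L || nrow(a) == 0L) return(logical(0))
  n <- max(nrow(q), nrow(a))
  qi <- rep_len(seq_len(nrow(q)), n)
  ai <- rep_len(seq_len(nrow(a)), n)
  q$chrom[qi] == a$chrom[ai] &
    .ov(q$start[qi], q$end[qi], a$start[ai], a$end[ai])
}

.class_label <- function(r1, r4, qp, ap, r2) {
  if (qp && ap) return("coincident points")
  if (qp) {
    if (r1 == 2) return("query point at annotation start")
    if (r2 == 2) return("query point at annotation end")
    return("query point inside annotation")
  }
  if (ap) {
    if (r1 == 2) return("annotation point at query start")
    if (r4 == 2) return("annotation point at query end")  # r4 here: qe vs ae
    return("annotation point inside query")
  }
  key <- paste0(c("L", "E", "G")[r1], c("L", "E", "G")[r4])
  switch(key,
         LL = "overlaps (query extends left)",
         LE = "finished-by (query extends left, co-end)",
         LG = "contains",
         EL = "starts (co-start, query ends inside)",
         EE = "equals",
         EG = "started-by (co-start, query extends right)",
         GL = "during (query contained)",
         GE = "finishes (query starts inside, co-end)",
         GG = "overlapped-by (query extends right)")
}

.class_diagram <- function(qs, qe, as_, ae) {
  width <- max(qe, ae) + 1L
  lane <- function(s, e) {
    ch <- rep(".", width)
    if (s < e) ch[(s + 1L):e] <- "#" else ch[s + 1L] <- "|"
    paste(ch, collapse = "")
  }
  paste0("q: ", lane(qs, qe), "\na: ", lane(as_, ae))
}

# Build the canonical class table by exhaustive enumeration on a 5-position
# grid. Numbering: proper-proper classes 1-9, query-point 10-12,
# annotation-point 13-15, both-point 16; within each group, patterns are
# ordered lexicographically with less < equal < greater.
.build_class_table <- function() {
  g <- 0:4
  iv <- expand.grid(s = g, e = g)
  iv <- iv[iv$s <= iv$e, , drop = FALSE]
  pr <- expand.grid(q = seq_len(nrow(iv)), a = seq_len(nrow(iv)))
  qs <- iv$s[pr$q]; qe <- iv$e[pr$q]
  as_ <- iv$s[pr$a]; ae <- iv$e[pr$a]
  keep <- .ov(qs, qe, as_, ae)
  qs <- qs[keep]; qe <- qe[keep]; as_ <- as_[keep]; ae <- ae[keep]
  r1 <- .rel(qs, as_); r2 <- .rel(qs, ae)
  r3 <- .rel(qe, as_); r4 <- .rel(qe, ae)
  qp <- qs == qe; ap <- as_ == ae
  key <- paste(r1, r2, r3, r4, qp, ap)
  first <- !duplicated(key)
  tab <- data.frame(r1 = r1[first], r2 = r2[first], r3 = r3[first],
                    r4 = r4[first], q_is_point = qp[first],
                    a_is_point = ap[first],
                    qs = qs[first], qe = qe[first],
                    as_ = as_[first], ae = ae[first],
                    key = key[first], stringsAsFactors = FALSE)
  group <- ifelse(!tab$q_is_point & !tab$a_is_point, 1L,
                  ifelse(tab$q_is_point & !tab$a_is_point, 2L,
                         ifelse(!tab$q_is_point, 3L, 4L)))
  tab <- tab[order(group, tab$r1, tab$r2, tab$r3, tab$r4), , drop = FALSE]
  lett <- c("L", "E", "G")
  out <- data.frame(
    class_id = seq_len(nrow(tab)),
    pattern = paste(lett[tab$r1], lett[tab$r2], lett[tab$r3], lett[tab$r4],
                    sep = ","),
    q_is_point = tab$q_is_point,
    a_is_point = tab$a_is_point,
    label = vapply(seq_len(nrow(tab)), function(i)
      .class_label(tab$r1[i], tab$r4[i], tab$q_is_point[i],
                   tab$a_is_point[i], tab$r2[i]), ""),
    diagram = vapply(seq_len(nrow(tab)), function(i)
      .class_diagram(tab$qs[i], tab$qe[i], tab$as_[i], tab$ae[i]), ""),
    key = tab$key,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.overlap_class_table <- .build_class_table()

#' The 16 overlap configuration classes
#'
#' Machine-readable table of every realizable overlap configuration between a
#' query region and an annotation region, including zero-length elements.
#' Each class is identified by the four position relations
#' (query start vs annotation start, query start vs annotation end,
#' query end vs annotation start, query end vs annotation end; encoded
#' `L`/`E`/`G` for less/equal/greater) together with the two zero-length
#' flags. Classes 1-9 are the proper-proper configurations (the Allen
#' relations that share at least one position under the half-open
#' convention), 10-12 involve a zero-length query, 13-15 a zero-length
#' annotation, and 16 two coincident points.
#'
#' @return A data frame with columns `class_id`, `pattern`, `q_is_point`,
#'   `a_is_point`, `label` and `diagram` (an ASCII sketch; `#` marks covered
#'   bases, `|` a zero-length insertion point).
#' @examples
#' overlap_classes()[, c("class_id", "pattern", "label")]
#' @export
overlap_classes <- function() {
  .overlap_class_table[, c("class_id", "pattern", "q_is_point", "a_is_point",
                           "label", "diagram")]
}

#' Classify an overlapping query/annotation pair
#'
#' Computes the four cross-comparisons between the start and end positions of
#' the two regions and looks up the unique configuration class they realize.
#' The pair must overlap (see [region_overlaps()]).
#'
#' @param q,a [genomic_regions] objects; rows paired, length-1 recycled.
#' @return A data frame (one row per pair) with columns `class_id`,
#'   `pattern`, `q_is_point`, `a_is_point`, `label`.
#' @examples
#' classify_overlap(genomic_regions("chr1", 10, 20), genomic_regions("chr1", 10, 20))
#' @export
classify_overlap <- function(q, a) {
  q <- as_genomic_regions(q)
  a <- as_genomic_regions(a)
  if (nrow(q) == 0L || nrow(a) == 0L)
    return(.overlap_class_table[integer(0), c("class_id", "pattern",
                                              "q_is_point", "a_is_point",
                                              "label")])
  n <- max(nrow(q), nrow(a))
  qi <- rep_len(seq_len(nrow(q)), n)
  ai <- rep_len(seq_len(nrow(a)), n)
  if (!all(region_overlaps(q[qi, , drop = FALSE], a[ai, , drop = FALSE])))
    stop("classify_overlap called on a non-overlapping pair", call. = FALSE)
  qs <- q$start[qi]; qe <- q$end[qi]
  as_ <- a$start[ai]; ae <- a$end[ai]
  key <- paste(.rel(qs, as_), .rel(qs, ae), .rel(qe, as_), .rel(qe, ae),
               qs == qe, as_ == ae)
  m <- match(key, .overlap_class_table$key)
  out <- .overlap_class_table[m, c("class_id", "pattern", "q_is_point",
                                   "a_is_point", "label")]
  rownames(out) <- NULL
  out
}

#' Enumerate overlap classes by brute force
#'
#' Places query and annotation start/end positions on every quadruple
#' `(qs <= qe, as <= ae)` over the offsets `0 .. grid_size - 1`, keeps the
#' overlapping pairs, classifies each, and returns the distinct classes
#' found. For any `grid_size >= 5` the result is the full set of 16 classes;
#' restricted to proper (positive-length) intervals it is the 9
#' proper-proper classes.
#'
#' @param grid_size Number of grid positions (>= 2; >= 5 realizes every
#'   class).
#' @param proper_only If `TRUE`, only positive-length intervals are placed.
#' @return The subset of [overlap_classes()] realized, ordered by
#'   `class_id`.
#' @examples
#' nrow(enumerate_overlap_classes(5))
#' nrow(enumerate_overlap_classes(5, proper_only = TRUE))
#' @export
enumerate_overlap_classes <- function(grid_size = 5L, proper_only = FALSE) {
  grid_size <- as.integer(grid_size)
  if (grid_size < 2L) stop("grid_size must be >= 2", call. = FALSE)
  g <- 0:(grid_size - 1L)
  iv <- expand.grid(s = g, e = g)
  iv <- iv[if (proper_only) iv$s < iv$e else iv$s <= iv$e, , drop = FALSE]
  pr <- expand.grid(q = seq_len(nrow(iv)), a = seq_len(nrow(iv)))
  q <- genomic_regions(rep("chr1", nrow(pr)), iv$s[pr$q], iv$e[pr$q])
  a <- genomic_regions(rep("chr1", nrow(pr)), iv$s[pr$a], iv$e[pr$a])
  keep <- region_overlaps(q, a)
  cls <- classify_overlap(q[keep, , drop = FALSE], a[keep, , drop = FALSE])
  ids <- sort(unique(cls$class_id))
  out <- overlap_classes()[ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}
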