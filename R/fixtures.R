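# Seeded synthetic fixtures and the brute-force oracles that anchor the
# engine tests. The oracles re-state the overlap predicate and the neighbor
# definition independently of the engine and taxonomy code, so a predicate
# bug cannot validate itself.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a reproducible synthetic region set
#'
#' Draws `n` regions with uniform start positions on `n_chromosomes`
#' chromosomes of length `chrom_length`, lengths uniform in
#' `[min_length, max_length]`, and an exact fraction `zero_fraction` of
#' zero-length (insertion-point) regions — `round(n * zero_fraction)` by
#' construction. Identical arguments and seed yield identical regions.
#'
#' @param n Number of regions.
#' @param seed Random seed (the caller's RNG state is left untouched).
#' @param n_chromosomes Number of chromosomes (`chr1 ...`).
#' @param chrom_length Chromosome length in bases.
#' @param min_length,max_length Length range for proper regions (bases). The
#'   default floor is 2 bp: the 1-based positions display of a single base
#'   (`"chrN:p-p"`) is indistinguishable from the zero-length insertion-point
#'   form, so fixtures avoid 1 bp regions to keep the display invertible.
#' @param zero_fraction Fraction of regions that are zero-length.
#' @param stranded Assign random `+`/`-` strands?
#' @param named Assign names `r000001 ...`?
#' @return A [genomic_regions] object with `n` rows.
#' @export
generate_regions <- function(n, seed = 1L, n_chromosomes = 5L,
                             chrom_length = 1000000L, min_length = 2L,
                             max_length = 1000L, zero_fraction = 0.05,
                             stranded = FALSE, named = TRUE) {
  n <- as.integer(n)
  if (n == 0L) return(genomic_regions())
  .with_seed(seed, {
    len <- sample.int(max_length - min_length + 1L, n, replace = TRUE) +
      min_length - 1L
    n_zero <- round(n * zero_fraction)
    if (n_zero > 0L) len[sample.int(n, n_zero)] <- 0L
    chrom <- paste0("chr", sample.int(n_chromosomes, n, replace = TRUE))
    start <- as.integer(floor(stats::runif(n) * (chrom_length - len)))
    genomic_regions(
      chrom, start, start + len,
      name = if (named) sprintf("r%06d", seq_len(n)) else NA_character_,
      strand = if (stranded) sample(c("+", "-"), n, replace = TRUE)
               else NA_character_)
  })
}

# predicate re-stated from the convention, independent of .ov: half-open
# intersection for proper intervals, boundary-inclusive containment for
# zero-length elements, coincidence for two points
.oracle_ov <- function(qs, qe, as_, ae) {
  (qs < qe & as_ < ae & qs < ae & as_ < qe) |
    (qs == qe & as_ < ae & as_ <= qs & qs <= ae) |
    (qs < qe & as_ == ae & qs <= as_ & as_ <= qe) |
    (qs == qe & as_ == ae & qs == as_)
}

#' Brute-force overlap oracle
#'
#' All-pairs evaluation of the overlap convention with no index: every
#' annotation is tested against every query. Results are ordered like the
#' engine's, by annotation `(start, end, name)`.
#'
#' @param queries,annotations [genomic_regions] objects.
#' @return Per-query list of integer positions into `annotations` (same
#'   shape as [find_overlaps()]).
#' @export
oracle_overlaps <- function(queries, annotations) {
  q <- as_genomic_regions(queries)
  a <- as_genomic_regions(annotations)
  res <- rep(list(integer(0)), nrow(q))
  if (nrow(a) == 0L) return(res)
  nm <- ifelse(is.na(a$name), "", a$name)
  ao <- order(a$start, a$end, nm, method = "radix")
  for (i in seq_len(nrow(q))) {
    hit <- a$chrom[ao] == q$chrom[i] &
      .oracle_ov(q$start[i], q$end[i], a$start[ao], a$end[ao])
    if (any(hit)) res[[i]] <- ao[hit]
  }
  res
}

#' Brute-force neighbor oracle
#'
#' Scans all annotations per query: the left neighbor maximizes
#' `(end, start)` with lexicographically smallest name among non-overlapping
#' annotations with `end <= query start`; the right neighbor minimizes
#' `(start, end, name)` among those with `start >= query end`.
#'
#' @param queries,annotations [genomic_regions] objects.
#' @return Data frame shaped like the [find_neighbors()] result.
#' @export
oracle_neighbors <- function(queries, annotations) {
  q <- as_genomic_regions(queries)
  a <- as_genomic_regions(annotations)
  n <- nrow(q)
  left <- right <- rep(NA_integer_, n)
  left_dist <- right_dist <- rep(NA_integer_, n)
  if (nrow(a) > 0L) {
    nm <- ifelse(is.na(a$name), "", a$name)
    for (i in seq_len(n)) {
      same <- a$chrom == q$chrom[i]
      ov <- same & .oracle_ov(q$start[i], q$end[i], a$start, a$end)
      lc <- which(same & !ov & a$end <= q$start[i])
      if (length(lc)) {
        best <- lc[order(a$end[lc], a$start[lc], nm[lc], method = "radix",
                         decreasing = c(TRUE, TRUE, FALSE))[1L]]
        left[i] <- best
        left_dist[i] <- q$start[i] - a$end[best]
      }
      rc <- which(same & !ov & a$start >= q$end[i])
      if (length(rc)) {
        best <- rc[order(a$start[rc], a$end[rc], nm[rc],
                         method = "radix")[1L]]
        right[i] <- best
        right_dist[i] <- a$start[best] - q$end[i]
      }
    }
  }
  data.frame(left = left, left_dist = left_dist,
             right = right, right_dist = right_dist)
}

#' Engine-vs-oracle benchmark sweep
#'
#' Runs the sweep engine and the brute-force oracle on identical seeded
#' fixtures across a sweep of query-set sizes, asserts that the results are
#' identical, and reports wall-clock timings (for documentation only;
#' absolute timings are hardware-dependent).
#'
#' @param sizes Query-set sizes to sweep.
#' @param n_sources Number of annotation sources (1 or 10).
#' @param seed Base random seed.
#' @param n_annotations Annotations per source.
#' @param oracle Also run the brute-force oracle (and check equality)?
#'   Disable for engine-only timing at large sizes.
#' @return Data frame with columns `size`, `n_sources`, `engine_time`,
#'   `oracle_time` (`NA` when the oracle is skipped) and `equal`.
#' @export
benchmark_protocol <- function(sizes = c(10L, 1000L, 100000L),
                               n_sources = 1L, seed = 1L,
                               n_annotations = 1000L, oracle = TRUE) {
  out <- data.frame(size = as.integer(sizes), n_sources = n_sources,
                    engine_time = NA_real_, oracle_time = NA_real_,
                    equal = NA)
  for (r in seq_along(sizes)) {
    queries <- generate_regions(sizes[r], seed = seed + 1000L * r)
    anns <- lapply(seq_len(n_sources), function(s)
      generate_regions(n_annotations, seed = seed + 1000L * r + s))
    t0 <- proc.time()[["elapsed"]]
    eng_ov <- lapply(anns, function(a) find_overlaps(build_index(a), queries))
    eng_nb <- lapply(anns, function(a) find_neighbors(build_index(a), queries))
    out$engine_time[r] <- proc.time()[["elapsed"]] - t0
    if (oracle) {
      t0 <- proc.time()[["elapsed"]]
      ora_ov <- lapply(anns, function(a) oracle_overlaps(queries, a))
      ora_nb <- lapply(anns, function(a) oracle_neighbors(queries, a))
      out$oracle_time[r] <- proc.time()[["elapsed"]] - t0
      out$equal[r] <- identical(eng_ov, ora_ov) && identical(eng_nb, ora_nb)
      if (!out$equal[r])
        stop(sprintf("engine/oracle mismatch at size %d", sizes[r]),
             call. = FALSE)
    }
  }
  out
}
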