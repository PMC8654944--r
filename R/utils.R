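# Internal helpers shared across modules.

#' @import data.table
#' @importFrom stats cor dist hclust quantile rnorm runif rlnorm rpois
#'   rnbinom qnbinom rbinom rgamma ppois p.adjust fisher.test sd pnorm
#' @importFrom utils packageVersion
NULL

# GRanges view of a 0-based half-open table (chrom/start/end columns).
# BED [start, end) maps to the 1-based closed interval [start+1, end].
.as_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges   = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

# C-locale (radix) order on the BED sort key; stable, so already-sorted
# inputs map to the identity permutation.
.bed_order <- function(x, with_barcode = FALSE) {
  if (with_barcode) {
    order(x$chrom, x$start, x$end, x$barcode, method = "radix")
  } else {
    order(x$chrom, x$start, x$end, method = "radix")
  }
}

# findOverlaps/overlapsAny wrappers; disjoint chromosome sets between query
# and subject are legitimate here, so the seqlevel warning is silenced.
.find_overlaps <- function(query, subject, ...) {
  suppressWarnings(GenomicRanges::findOverlaps(query, subject, ...))
}

.overlaps_any <- function(query, subject, ...) {
  suppressWarnings(IRanges::overlapsAny(query, subject, ...))
}

.count_overlaps <- function(query, subject, ...) {
  suppressWarnings(GenomicRanges::countOverlaps(query, subject, ...))
}

.assert_disjoint <- function(regions, what = "regions") {
  gr <- .as_gr(regions)
  hits <- GenomicRanges::findOverlaps(gr, gr, minoverlap = 1L)
  hits <- hits[S4Vectors::queryHits(hits) < S4Vectors::subjectHits(hits)]
  if (length(hits) > 0L) {
    i <- S4Vectors::queryHits(hits)[1L]
    j <- S4Vectors::subjectHits(hits)[1L]
    stop(sprintf(
      "%s must be pairwise disjoint; %s:%d-%d overlaps %s:%d-%d",
      what, regions$chrom[i], regions$start[i], regions$end[i],
      regions$chrom[j], regions$start[j], regions$end[j]
    ), call. = FALSE)
  }
  invisible(TRUE)
}

.check_scalar_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  as.integer(seed)
}

# Stage-specific seed derived from a run seed; kept within 32-bit range.
.stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 131L + offset) %% 2147483647)
}

#' Adjusted Rand index between two partitions
#'
#' Pair-counting agreement between two labelings of the same items, corrected
#' for chance. Used to score cluster recovery against simulator truth labels.
#'
#' @param a,b Vectors of cluster labels (any atomic type), equal length.
#' @return A single number; 1 for identical partitions, ~0 for random ones.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Euclidean cross-distance matrix between rows of x and rows of y.
.cross_dist <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  sqrt(pmax(d2, 0))
}
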