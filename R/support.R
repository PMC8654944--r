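# Cell-to-cell G4 variability: per-peak supporting-cell counts per cluster,
# common/specific peak partitioning, support distributions and top-quartile
# extraction. A supporting cell is a barcode with at least one deduplicated
# fragment overlapping the peak by >= 1 bp; multiple fragments from one
# barcode count once.

#' Count supporting cells per peak and cluster
#'
#' @param cluster_fragments Named list: cluster label -> deduplicated
#'   fragment `data.table` for that cluster's cells.
#' @param peaks_per_cluster Named list: cluster label -> disjoint peak
#'   `data.table` (must cover the same labels).
#' @param peak_classes Optional named list: cluster label -> character vector
#'   of peak classes (`"common"` / `"specific_to_<cluster>"`), parallel to
#'   that cluster's peaks.
#' @return A `data.table` with one row per (cluster, peak): `cluster`,
#'   `chrom`, `start`, `end`, `name`, `class`, `n_supporting_cells`,
#'   `n_cells_in_cluster`, `support_fraction`. Empty clusters yield
#'   `n_cells_in_cluster = 0` and `NA` fractions, flagged with a warning.
#' @export
count_supporting_cells <- function(cluster_fragments, peaks_per_cluster,
                                   peak_classes = NULL) {
  stopifnot(identical(sort(names(cluster_fragments)),
                      sort(names(peaks_per_cluster))))
  out <- vector("list", length(cluster_fragments))
  for (i in seq_along(cluster_fragments)) {
    lab <- names(cluster_fragments)[i]
    frags <- cluster_fragments[[lab]]
    peaks <- as.data.table(peaks_per_cluster[[lab]])
    .assert_disjoint(peaks, what = sprintf("peaks of cluster '%s'", lab))
    n_cells <- length(unique(frags$barcode))
    if (n_cells == 0L) {
      warning("cluster '", lab, "' has no cells; support rows flagged invalid")
    }
    nsupp <- integer(nrow(peaks))
    if (nrow(frags) > 0L && nrow(peaks) > 0L) {
      hits <- .find_overlaps(.as_gr(peaks), .as_gr(frags),
                                          minoverlap = 1L)
      pairs <- unique(data.table(
        peak = S4Vectors::queryHits(hits),
        barcode = frags$barcode[S4Vectors::subjectHits(hits)]))
      tab <- pairs[, .N, by = "peak"]
      nsupp[tab$peak] <- tab$N
    }
    cls <- if (!is.null(peak_classes)) peak_classes[[lab]] else NA_character_
    out[[i]] <- data.table(
      cluster = lab, chrom = peaks$chrom, start = peaks$start,
      end = peaks$end,
      name = if ("name" %in% names(peaks)) peaks$name else NA_character_,
      class = cls,
      n_supporting_cells = nsupp,
      n_cells_in_cluster = n_cells,
      support_fraction = if (n_cells > 0L) nsupp / n_cells else NA_real_)
  }
  rbindlist(out)[]
}

#' Partition two peak sets into common and specific peaks
#'
#' A peak is common if it overlaps at least one peak of the other set by
#' >= 1 bp; common pairs record both partners (a peak overlapping several
#' partners yields one row per partner). The specific sets are the
#' non-overlapping remainders, so every input peak lands in exactly one
#' category.
#'
#' @param peaks_a,peaks_b Internally disjoint peak `data.table`s.
#' @return A list: `common_pairs` (`data.table` with `a_*` and `b_*`
#'   coordinate columns), `specific_a`, `specific_b`, plus `common_a` /
#'   `common_b` (the common peaks of each input, one row per peak).
#' @export
partition_peaks <- function(peaks_a, peaks_b) {
  peaks_a <- as.data.table(peaks_a)
  peaks_b <- as.data.table(peaks_b)
  .assert_disjoint(peaks_a, "peaks_a")
  .assert_disjoint(peaks_b, "peaks_b")
  hits <- .find_overlaps(.as_gr(peaks_a), .as_gr(peaks_b),
                                      minoverlap = 1L)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  common_pairs <- data.table(
    a_chrom = peaks_a$chrom[qi], a_start = peaks_a$start[qi],
    a_end = peaks_a$end[qi],
    b_chrom = peaks_b$chrom[si], b_start = peaks_b$start[si],
    b_end = peaks_b$end[si])
  in_a <- sort(unique(qi))
  in_b <- sort(unique(si))
  list(common_pairs = common_pairs,
       common_a = peaks_a[in_a],
       common_b = peaks_b[in_b],
       specific_a = peaks_a[setdiff(seq_len(nrow(peaks_a)), in_a)],
       specific_b = peaks_b[setdiff(seq_len(nrow(peaks_b)), in_b)])
}

#' Support distribution summaries and top-supported loci
#'
#' Summarizes supporting-cell counts per cluster and class and extracts, per
#' cluster, the loci whose support reaches the `(1 - top_quantile)`
#' percentile (linear interpolation), ties included.
#'
#' @param table Output of [count_supporting_cells()].
#' @param top_quantile Upper tail to extract (default 0.25, i.e. the top 25%
#'   supported loci).
#' @return A list: `summary` (per cluster x class median/mean/quartiles) and
#'   `top_loci` (rows of `table` at or above the threshold, with the
#'   threshold recorded).
#' @export
support_distribution <- function(table, top_quantile = 0.25) {
  table <- as.data.table(table)
  if (nrow(table) == 0L) stop("empty support table", call. = FALSE)
  summ <- table[, list(
    n_peaks = .N,
    median_support = as.numeric(stats::median(n_supporting_cells)),
    mean_support = mean(n_supporting_cells),
    q25 = quantile(n_supporting_cells, 0.25, names = FALSE),
    q75 = quantile(n_supporting_cells, 0.75, names = FALSE)),
    by = c("cluster", "class")]
  top <- table[, {
    thr <- quantile(n_supporting_cells, 1 - top_quantile, type = 7,
                    names = FALSE)
    cbind(.SD[n_supporting_cells >= thr], support_threshold = thr)
  }, by = "cluster"]
  list(summary = summ[], top_loci = top[])
}

#' Compare support of common versus specific peaks
#'
#' For each cluster with both classes present, reports the median support of
#' common and specific peaks, the direction of the difference, and a
#' Mann-Whitney rank-sum statistic (average ranks for ties, normal
#' approximation with tie correction, two-sided p). The rank-sum test is an
#' addition of this package to make the qualitative common-versus-specific
#' claim quantitative.
#'
#' @param table Output of [count_supporting_cells()] with a `class` column
#'   coded `"common"` or `"specific*"`.
#' @return A `data.table` per cluster: medians, `direction`, `U` (for the
#'   common class), and `p_value`. Clusters missing a class are skipped with
#'   a warning.
#' @export
support_class_comparison <- function(table) {
  table <- as.data.table(table)
  out <- list()
  for (lab in unique(table$cluster)) {
    sub <- table[cluster == lab]
    common <- sub[class == "common", n_supporting_cells]
    specific <- sub[startsWith(class, "specific"), n_supporting_cells]
    if (length(common) == 0L || length(specific) == 0L) {
      warning("cluster '", lab, "': a class is empty; comparison skipped")
      next
    }
    n1 <- length(common); n2 <- length(specific)
    r <- rank(c(common, specific))
    u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    p <- if (sigma2 == 0) 1 else {
      z <- (u - mu) / sqrt(sigma2)
      2 * pnorm(-abs(z))
    }
    out[[lab]] <- data.table(
      cluster = lab,
      median_common = as.numeric(stats::median(common)),
      median_specific = as.numeric(stats::median(specific)),
      direction = if (stats::median(common) > stats::median(specific)) {
        "common > specific"
      } else if (stats::median(common) < stats::median(specific)) {
        "common < specific"
      } else "tied",
      U = u, p_value = min(1, p))
  }
  rbindlist(out)[]
}
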