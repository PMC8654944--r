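# Interval algebra, a Poisson sliding-window peak caller, promoter windows,
# promoter differential enrichment between clusters, and copy-number
# annotation of differential promoters.

#' Merge one or more peak sets into a disjoint sorted set
#'
#' Overlapping or book-ended intervals (`end == start`) are merged, matching
#' the bedtools-merge default. Idempotent.
#'
#' @param ... One or more peak `data.table`s (`chrom`, `start`, `end`).
#' @return A sorted, pairwise-disjoint `data.table` (`chrom`, `start`,
#'   `end`).
#' @export
merge_intervals <- function(...) {
  pool <- rbindlist(lapply(list(...), function(x) {
    as.data.table(x)[, list(chrom, start, end)]
  }))
  if (nrow(pool) == 0L) {
    return(data.table(chrom = character(), start = integer(),
                      end = integer()))
  }
  pool <- pool[.bed_order(pool)]
  # book-ended merge: an interval starting at or before the running max end
  # continues the current run
  new_run <- c(TRUE, pool$chrom[-1L] != pool$chrom[-nrow(pool)] |
                       pool$start[-1L] > cummax_by_chrom(pool))
  pool[, run := cumsum(new_run)]
  pool[, list(chrom = chrom[1L], start = start[1L], end = max(end)),
       by = "run"][, run := NULL][]
}

# running max of `end` within chromosome, lagged by one row
cummax_by_chrom <- function(pool) {
  if (nrow(pool) < 2L) return(integer(0))
  out <- integer(nrow(pool) - 1L)
  last_chr <- pool$chrom[1L]
  running <- pool$end[1L]
  for (i in seq.int(2L, nrow(pool))) {
    if (pool$chrom[i] != last_chr) {
      last_chr <- pool$chrom[i]
      running <- pool$end[i]
      out[i - 1L] <- -1L  # never triggers a continuation across chromosomes
    } else {
      out[i - 1L] <- running
      running <- max(running, pool$end[i])
    }
  }
  out
}

#' Fraction of query peaks overlapping a reference set
#'
#' @param query_peaks Non-empty peak `data.table`.
#' @param reference_peaks Peak `data.table`.
#' @return Fraction of query peaks overlapping >= 1 reference peak by
#'   >= 1 bp.
#' @export
overlap_fraction <- function(query_peaks, reference_peaks) {
  if (nrow(query_peaks) == 0L) stop("empty query peak set", call. = FALSE)
  mean(.overlaps_any(.as_gr(query_peaks), .as_gr(reference_peaks),
                            minoverlap = 1L))
}

#' Peak-caller configuration
#'
#' A Poisson sliding-window caller: fragment counts in fixed windows are
#' tested against a uniform-genome background rate, with Benjamini-Hochberg
#' correction over all windows. The 147 bp default window mirrors the
#' nucleosomal fragment extension used in bulk analyses of this assay; the
#' `min_qscore` filter is configurable because useful values scale with
#' sequencing depth (deeply sequenced bulk libraries support far more
#' stringent cutoffs than simulated or shallow data).
#'
#' @param window Window size in bp (default 147).
#' @param step Window step in bp (default `window %/% 3`).
#' @param p_threshold Raw Poisson p-value cutoff (default 1e-5).
#' @param min_qscore Minimum `-log10(q)` a window must reach (default 2).
#' @param merge_gap Kept windows closer than this are merged (default
#'   `window`).
#' @return A validated list of class `peak_call_config`.
#' @export
peak_call_config <- function(window = 147L, step = NULL, p_threshold = 1e-5,
                             min_qscore = 2, merge_gap = NULL) {
  if (is.null(step)) step <- max(1L, window %/% 3L)
  if (is.null(merge_gap)) merge_gap <- window
  cfg <- list(window = as.integer(window), step = as.integer(step),
              p_threshold = p_threshold, min_qscore = min_qscore,
              merge_gap = as.integer(merge_gap))
  if (cfg$step < 1L || cfg$window < cfg$step) {
    stop("need window >= step >= 1", call. = FALSE)
  }
  if (cfg$p_threshold <= 0 || cfg$min_qscore < 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  class(cfg) <- "peak_call_config"
  cfg
}

#' Call peaks with a Poisson sliding window
#'
#' Slides a window over each chromosome, counts overlapping fragments, and
#' computes the upper-tail Poisson p-value against the genome-wide uniform
#' background rate `lambda = n_fragments * window / genome_length`.
#' the background rate is
#' `lambda = sum(window + fragment_length - 1) / genome_length`, the
#' expected overlap count under uniform fragment placement.
#' Benjamini-Hochberg q-values are computed over all windows; windows
#' passing both `p <= p_threshold` and `-log10(q) >= min_qscore` are merged
#' within `merge_gap`, and each merged peak is scored with the maximum
#' `-log10(q)` among its windows.
#'
#' @param fragments Fragment `data.table` (e.g. a cluster pseudobulk).
#' @param chrom_sizes Named vector of chromosome lengths; chromosomes
#'   shorter than the window are skipped with a warning.
#' @param config A [peak_call_config()].
#' @return A peak `data.table` (`chrom`, `start`, `end`, `name`, `score`),
#'   `score` being `-log10(q)`.
#' @export
call_peaks <- function(fragments, chrom_sizes, config = peak_call_config()) {
  stopifnot(inherits(config, "peak_call_config"))
  if (nrow(fragments) == 0L) stop("no fragments to call peaks on",
                                  call. = FALSE)
  if (!all(fragments$chrom %in% names(chrom_sizes))) {
    stop("chrom_sizes must cover all fragment chromosomes", call. = FALSE)
  }
  genome_len <- sum(as.numeric(chrom_sizes))
  # expected number of fragments OVERLAPPING a window under uniform
  # placement: a fragment of length L overlaps a width-w window from
  # w + L - 1 distinct start positions
  lambda <- sum(config$window + (fragments$end - fragments$start) - 1) /
    genome_len
  wins <- list()
  for (chrom in names(chrom_sizes)) {
    len <- as.integer(chrom_sizes[[chrom]])
    if (len < config$window) {
      warning("chromosome ", chrom, " shorter than the window; skipped")
      next
    }
    starts <- seq.int(0L, len - config$window, by = config$step)
    wins[[chrom]] <- data.table(chrom = chrom, start = starts,
                                end = starts + config$window)
  }
  wins <- rbindlist(wins)
  frag_gr <- .as_gr(fragments)
  wins[, count := .count_overlaps(.as_gr(wins), frag_gr,
                                               minoverlap = 1L)]
  wins[, p := ppois(count - 1L, lambda, lower.tail = FALSE)]
  wins[, q := p.adjust(p, method = "BH")]
  keep <- wins[p <= config$p_threshold & -log10(q) >= config$min_qscore]
  if (nrow(keep) == 0L) {
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      score = numeric()))
  }
  # merge kept windows within merge_gap, carrying the best q-score
  keep <- keep[.bed_order(keep)]
  gap <- config$merge_gap
  new_run <- c(TRUE, keep$chrom[-1L] != keep$chrom[-nrow(keep)] |
                       keep$start[-1L] > keep$end[-nrow(keep)] + gap)
  keep[, run := cumsum(new_run)]
  peaks <- keep[, list(chrom = chrom[1L], start = start[1L], end = max(end),
                       score = max(-log10(q))), by = "run"][, run := NULL]
  peaks[, name := sprintf("peak%04d", .I)]
  peaks[, list(chrom, start, end, name, score)][]
}

#' Promoter windows from a TSS table
#'
#' A promoter spans 1,000 bases upstream to 100 bases downstream of the TSS:
#' strand `+` gives `[tss - 1000, tss + 100)`, strand `-` mirrors to
#' `[tss - 100, tss + 1000)`; windows are clipped to the chromosome.
#'
#' @param tss_table TSS `data.table` (`gene_id`, `chrom`, `tss`, `strand`).
#' @param chrom_sizes Optional named vector of chromosome lengths used for
#'   clipping the downstream edge.
#' @param upstream,downstream Window extents in bp.
#' @return A `data.table` (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @export
define_promoters <- function(tss_table, chrom_sizes = NULL,
                             upstream = 1000L, downstream = 100L) {
  tss_table <- as.data.table(tss_table)
  if (any(!tss_table$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  plus <- tss_table$strand == "+"
  start <- ifelse(plus, tss_table$tss - upstream, tss_table$tss - downstream)
  end <- ifelse(plus, tss_table$tss + downstream, tss_table$tss + upstream)
  start <- pmax(as.integer(start), 0L)
  end <- as.integer(end)
  if (!is.null(chrom_sizes)) {
    end <- pmin(end, as.integer(chrom_sizes[tss_table$chrom]))
  }
  data.table(gene_id = tss_table$gene_id, chrom = tss_table$chrom,
             start = start, end = end, strand = tss_table$strand)
}

#' Differential promoter enrichment between two clusters
#'
#' For each promoter peak, compares cut-site counts between clusters A and B
#' with `log2fc = log2(((count_A + 1)/total_A) / ((count_B + 1)/total_B))`
#' and a two-sided Fisher's exact test on the 2x2 table
#' `[count_A, total_A - count_A; count_B, total_B - count_B]`;
#' Benjamini-Hochberg q-values are reported alongside. Records passing
#' `|log2fc| > fc_min` and `p < p_max` are ranked by p ascending (ties by
#' `|log2fc|` descending) and truncated to `top_n`.
#'
#' @param counts_a,counts_b Named integer vectors of per-promoter-peak
#'   cut-site counts for the two clusters (same names/order).
#' @param total_a,total_b Cluster-wide cut-site totals (> 0).
#' @param peaks Optional `data.table` parallel to the counts carrying
#'   `gene_id`, `chrom`, `start`, `end` for the output.
#' @param top_n Maximum records returned after filtering (default 50).
#' @param fc_min Absolute log2 fold-change filter (default 0.6).
#' @param p_max Raw p-value filter (default 0.05).
#' @return A list: `records` (filtered, ranked `data.table`) and
#'   `all_tests` (every promoter peak with log2fc, p and q).
#' @export
differential_promoter_enrichment <- function(counts_a, counts_b, total_a,
                                             total_b, peaks = NULL,
                                             top_n = 50L, fc_min = 0.6,
                                             p_max = 0.05) {
  stopifnot(length(counts_a) == length(counts_b))
  if (total_a <= 0 || total_b <= 0) {
    stop("cluster cut-site totals must be positive", call. = FALSE)
  }
  if (any(counts_a > total_a) || any(counts_b > total_b)) {
    stop("counts exceed totals", call. = FALSE)
  }
  n <- length(counts_a)
  log2fc <- log2(((counts_a + 1) / total_a) / ((counts_b + 1) / total_b))
  p <- vapply(seq_len(n), function(i) {
    fisher.test(matrix(c(counts_a[i], total_a - counts_a[i],
                         counts_b[i], total_b - counts_b[i]),
                       nrow = 2L, byrow = TRUE))$p.value
  }, numeric(1))
  all_tests <- data.table(
    count_A = as.integer(counts_a), count_B = as.integer(counts_b),
    total_A = as.integer(total_a), total_B = as.integer(total_b),
    log2fc = log2fc, p_value = p, q_value = p.adjust(p, method = "BH"))
  if (!is.null(peaks)) {
    all_tests <- cbind(as.data.table(peaks), all_tests)
  } else if (!is.null(names(counts_a))) {
    all_tests <- cbind(data.table(gene_id = names(counts_a)), all_tests)
  }
  rec <- all_tests[abs(log2fc) > fc_min & p_value < p_max]
  rec <- rec[order(p_value, -abs(log2fc))]
  if (nrow(rec) > top_n) rec <- rec[seq_len(top_n)]
  list(records = rec[], all_tests = all_tests[])
}

#' Annotate differential records with gene copy number
#'
#' Joins records to a copy-number table on `gene_id` (scale
#' `log2(relative to ploidy + 1)`); a record is `cn_high` when its value
#' exceeds `cn_threshold`. The summary fraction is computed among records
#' with known copy number and is `NA` when none is known.
#'
#' @param records A `data.table` with a `gene_id` column (e.g. the
#'   `records` of [differential_promoter_enrichment()]).
#' @param cn_table Copy-number `data.table` (`gene_id`, `cn_value`).
#' @param cn_threshold High-copy-number cutoff (default 1.5).
#' @return A list: `records` (with `cn_value`, `cn_high` columns),
#'   `fraction_cn_high`, `n_missing_cn`.
#' @export
annotate_copy_number <- function(records, cn_table, cn_threshold = 1.5) {
  records <- as.data.table(records)
  cn_table <- as.data.table(cn_table)
  records[, cn_value := cn_table$cn_value[match(gene_id, cn_table$gene_id)]]
  records[, cn_high := cn_value > cn_threshold]
  known <- !is.na(records$cn_value)
  frac <- if (any(known)) mean(records$cn_high[known]) else NA_real_
  list(records = records[], fraction_cn_high = frac,
       n_missing_cn = sum(!known))
}
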