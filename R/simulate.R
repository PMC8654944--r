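# Synthetic barcoded-fragment simulator. Emulates the statistical structure
# of a two-cell-type single-nuclei G4-CUT&Tag experiment: a peak repertoire
# partly shared between the two types, overdispersed per-cell fragment
# depths, a fixed fraction of fragments landing in peaks (FRiP), pooled bulk
# replicate libraries, and TSS/copy-number annotation with known
# differentially enriched promoters. Full ground truth is returned so every
# downstream stage can be scored.

#' Simulation configuration
#'
#' Defaults describe the regime the package targets: two cell types with a
#' few hundred nuclei each, a median of ~800 unique fragments per cell,
#' ~45% of fragments in peaks, and a peak repertoire half shared between
#' the types.
#'
#' @param chrom_sizes Named integer vector of chromosome lengths (bp).
#' @param n_peaks Number of peaks in the combined repertoire.
#' @param peak_width_mean Mean peak width (bp).
#' @param shared_fraction Fraction of peaks present in both cell types; the
#'   remainder is split evenly into A-specific and B-specific peaks.
#' @param n_cells_A,n_cells_B Number of cells per type.
#' @param median_frags_per_cell Target median unique fragments per cell.
#' @param frag_count_dispersion Negative-binomial dispersion of per-cell
#'   depth (variance = mu + dispersion * mu^2).
#' @param frip Probability that a fragment is a peak fragment.
#' @param fragment_length_log_mean,fragment_length_log_sd Lognormal fragment
#'   length parameters; lengths are clipped to [30, 1000] bp.
#' @param n_bulk_replicates Bulk replicate libraries per cell type.
#' @param bulk_depth Fragments per bulk replicate library.
#' @param n_genes Number of annotated genes.
#' @param n_diff_promoters Genes whose promoter contains a truth-differential
#'   peak (enriched in type A).
#' @param diff_rate_ratio Sampling-rate ratio (A over B) at truth-differential
#'   promoter peaks.
#' @param cn_high_fraction Fraction of differential genes assigned a high
#'   copy-number value (> 1.5 on the log2(relative to ploidy + 1) scale).
#' @param seed Default seed used by [simulate_dataset()].
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(chrom_sizes = c(chr1 = 2000000L, chr2 = 2000000L,
                                       chr3 = 2000000L),
                       n_peaks = 600L,
                       peak_width_mean = 300L,
                       shared_fraction = 0.5,
                       n_cells_A = 300L,
                       n_cells_B = 300L,
                       median_frags_per_cell = 800L,
                       frag_count_dispersion = 0.35,
                       frip = 0.45,
                       fragment_length_log_mean = log(170),
                       fragment_length_log_sd = 0.4,
                       n_bulk_replicates = 2L,
                       bulk_depth = 100000L,
                       n_genes = 200L,
                       n_diff_promoters = 20L,
                       diff_rate_ratio = 4,
                       cn_high_fraction = 0.3,
                       seed = 1L) {
  cfg <- list(
    chrom_sizes = chrom_sizes, n_peaks = as.integer(n_peaks),
    peak_width_mean = as.integer(peak_width_mean),
    shared_fraction = shared_fraction,
    n_cells_A = as.integer(n_cells_A), n_cells_B = as.integer(n_cells_B),
    median_frags_per_cell = as.integer(median_frags_per_cell),
    frag_count_dispersion = frag_count_dispersion, frip = frip,
    fragment_length_log_mean = fragment_length_log_mean,
    fragment_length_log_sd = fragment_length_log_sd,
    n_bulk_replicates = as.integer(n_bulk_replicates),
    bulk_depth = as.integer(bulk_depth),
    n_genes = as.integer(n_genes),
    n_diff_promoters = as.integer(n_diff_promoters),
    diff_rate_ratio = diff_rate_ratio,
    cn_high_fraction = cn_high_fraction,
    seed = .check_scalar_seed(seed)
  )
  if (is.null(names(cfg$chrom_sizes)) || any(!nzchar(names(cfg$chrom_sizes)))) {
    stop("chrom_sizes must be a named vector", call. = FALSE)
  }
  if (any(cfg$chrom_sizes < 10000)) stop("chromosomes too short", call. = FALSE)
  for (f in c("shared_fraction", "frip", "cn_high_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop(sprintf("%s must lie in [0, 1]", f), call. = FALSE)
    }
  }
  for (f in c("n_peaks", "n_cells_A", "n_cells_B", "median_frags_per_cell",
              "n_bulk_replicates", "n_genes")) {
    if (cfg[[f]] < 1L) stop(sprintf("%s must be positive", f), call. = FALSE)
  }
  if (cfg$diff_rate_ratio <= 0) stop("diff_rate_ratio must be > 0", call. = FALSE)
  if (cfg$frag_count_dispersion <= 0) {
    stop("frag_count_dispersion must be > 0", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate the peak repertoire
#'
#' Places non-overlapping peaks uniformly over the genome and assigns each a
#' class (shared, A_specific or B_specific, by `shared_fraction` with the
#' remainder split evenly) and a gamma-distributed sampling strength
#' (shape 2, scale 1).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; same seed and config give identical output.
#' @return A `data.table` with columns `chrom`, `start`, `end`, `name`,
#'   `class`, `strength`, sorted by genomic position.
#' @export
simulate_peak_repertoire <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.check_scalar_seed(seed))
  n <- config$n_peaks
  sizes <- config$chrom_sizes
  widths <- pmin(1000L, pmax(100L,
    as.integer(round(rnorm(n, config$peak_width_mean, config$peak_width_mean / 6)))))
  if (sum(as.numeric(widths)) > 0.5 * sum(as.numeric(sizes))) {
    stop("peak repertoire would cover more than half the genome", call. = FALSE)
  }
  placed <- data.table(chrom = character(), start = integer(), end = integer())
  need <- seq_len(n)
  widths_left <- widths
  for (attempt in seq_len(50L)) {
    m <- length(need)
    if (m == 0L) break
    chrom <- sample(names(sizes), m, replace = TRUE,
                    prob = as.numeric(sizes) / sum(as.numeric(sizes)))
    start <- as.integer(floor(runif(m) * (sizes[chrom] - widths_left)))
    cand <- data.table(chrom = chrom, start = start,
                       end = start + widths_left)
    pool <- rbind(placed, cand)
    pool <- pool[.bed_order(pool)]
    # greedy scan: drop any interval starting before the running max end
    keep <- rep(TRUE, nrow(pool))
    last_end <- -1L
    last_chr <- ""
    for (i in seq_len(nrow(pool))) {
      if (pool$chrom[i] != last_chr) { last_chr <- pool$chrom[i]; last_end <- -1L }
      if (pool$start[i] < last_end) keep[i] <- FALSE
      else last_end <- pool$end[i]
    }
    placed <- pool[keep]
    short <- n - nrow(placed)
    if (short == 0L) break
    need <- seq_len(short)
    widths_left <- widths_left[seq_len(short)]
  }
  if (nrow(placed) < n) {
    stop("could not place non-overlapping peaks; genome too crowded",
         call. = FALSE)
  }
  placed <- placed[.bed_order(placed)]
  placed[, name := sprintf("pk%04d", seq_len(n))]
  n_shared <- round(n * config$shared_fraction)
  n_a <- ceiling((n - n_shared) / 2)
  n_b <- n - n_shared - n_a
  cls <- sample(rep(c("shared", "A_specific", "B_specific"),
                    times = c(n_shared, n_a, n_b)))
  placed[, class := cls]
  placed[, strength := rgamma(n, shape = 2, scale = 1)]
  placed[]
}

#' Simulate TSS and copy-number annotation
#'
#' Places gene TSSs so that exactly `n_diff_promoters` promoters contain a
#' truth-differential peak: a shared peak whose sampling strength in type A
#' is boosted by `diff_rate_ratio` relative to type B. The remaining genes
#' are placed uniformly, avoiding differential peaks. Copy-number values are
#' high (> 1.5) for `cn_high_fraction` of the differential genes and drawn
#' from Normal(1.0, 0.1) otherwise.
#'
#' @param config A [sim_config()].
#' @param repertoire Output of [simulate_peak_repertoire()].
#' @param seed Integer seed.
#' @return A list with `tss` (TSS table), `cn_table`, `diff_genes`
#'   (character vector), and `repertoire` amended with per-type strengths
#'   (`strength_A`, `strength_B`), a `diff` flag and `gene_id` for
#'   differential peaks.
#' @export
simulate_annotation <- function(config, repertoire, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.check_scalar_seed(seed))
  rep2 <- copy(as.data.table(repertoire))
  n_diff <- config$n_diff_promoters
  shared_idx <- which(rep2$class == "shared")
  if (n_diff > length(shared_idx)) {
    stop("n_diff_promoters exceeds the number of shared peaks", call. = FALSE)
  }
  diff_idx <- sort(sample(shared_idx, n_diff))
  rep2[, diff := FALSE]
  rep2[diff_idx, diff := TRUE]
  rep2[, strength_A := ifelse(class == "B_specific", 0, strength)]
  rep2[, strength_B := ifelse(class == "A_specific", 0, strength)]
  rep2[diff_idx, strength_A := strength * config$diff_rate_ratio]
  rep2[, gene_id := NA_character_]

  sizes <- config$chrom_sizes
  gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
  diff_genes <- gene_ids[seq_len(n_diff)]
  tss_list <- vector("list", config$n_genes)
  # differential genes: TSS chosen so the diff peak sits wholly inside the
  # promoter window ('+': [tss-1000, tss+100); '-': [tss-100, tss+1000))
  for (i in seq_len(n_diff)) {
    pk <- rep2[diff_idx[i]]
    strand <- sample(c("+", "-"), 1L)
    if (strand == "+") {
      lo <- pk$end - 100L; hi <- pk$start + 1000L
    } else {
      lo <- pk$end - 1000L; hi <- pk$start + 100L
    }
    lo <- max(lo, 0L)
    hi <- min(hi, sizes[[pk$chrom]] - 1L)
    if (hi < lo) stop("differential peak too wide for a promoter window",
                      call. = FALSE)
    tss_list[[i]] <- data.table(
      gene_id = gene_ids[i], chrom = pk$chrom,
      tss = as.integer(lo + floor(runif(1) * (hi - lo + 1L))), strand = strand)
    rep2[diff_idx[i], gene_id := gene_ids[i]]
  }
  # remaining genes: uniform placement, redrawing any whose promoter window
  # would overlap a truth-differential peak
  diff_gr <- .as_gr(rep2[diff_idx])
  n_rest <- config$n_genes - n_diff
  if (n_rest > 0L) {
    rest <- data.table(gene_id = gene_ids[seq.int(n_diff + 1L, config$n_genes)],
                       chrom = NA_character_, tss = NA_integer_,
                       strand = NA_character_)
    redo <- seq_len(n_rest)
    for (try in seq_len(100L)) {
      m <- length(redo)
      if (m == 0L) break
      chrom <- sample(names(sizes), m, replace = TRUE,
                      prob = as.numeric(sizes) / sum(as.numeric(sizes)))
      tss <- as.integer(1000L + floor(runif(m) * (sizes[chrom] - 2000L)))
      strand <- sample(c("+", "-"), m, replace = TRUE)
      ws <- ifelse(strand == "+", tss - 1000L, tss - 100L)
      we <- ifelse(strand == "+", tss + 100L, tss + 1000L)
      win_gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(ws + 1L, we))
      bad <- .overlaps_any(win_gr, diff_gr)
      ok <- redo[!bad]
      data.table::set(rest, i = ok, j = "chrom", value = chrom[!bad])
      data.table::set(rest, i = ok, j = "tss", value = tss[!bad])
      data.table::set(rest, i = ok, j = "strand", value = strand[!bad])
      redo <- redo[bad]
    }
    if (length(redo) > 0L) {
      stop("could not place non-differential gene promoters clear of differential peaks",
           call. = FALSE)
    }
    tss_list[seq.int(n_diff + 1L, config$n_genes)] <-
      split(rest, seq_len(n_rest))
  }
  tss <- rbindlist(tss_list)

  n_high <- round(config$cn_high_fraction * n_diff)
  high_genes <- if (n_high > 0L) sample(diff_genes, n_high) else character()
  cn_value <- rnorm(config$n_genes, 1.0, 0.1)
  hi_i <- match(high_genes, gene_ids)
  cn_value[hi_i] <- 1.6 + abs(rnorm(n_high, 0.5, 0.2))
  cn_table <- data.table(gene_id = gene_ids, cn_value = cn_value)

  list(tss = tss, cn_table = cn_table, diff_genes = diff_genes,
       repertoire = rep2[])
}

# Shared fragment-drawing core: n fragments for one cell type.
# Peak fragments are anchored at a uniform point inside the chosen peak so
# they may spill over the peak edges; background fragments are uniform.
.draw_fragments <- function(config, repertoire, type, n) {
  if (n == 0L) {
    return(data.table(chrom = character(), start = integer(), end = integer()))
  }
  sizes <- config$chrom_sizes
  strength_col <- if (type == "A") "strength_A" else "strength_B"
  if (!strength_col %in% names(repertoire)) {
    repertoire <- copy(as.data.table(repertoire))
    repertoire[, strength_A := ifelse(class == "B_specific", 0, strength)]
    repertoire[, strength_B := ifelse(class == "A_specific", 0, strength)]
  }
  w <- repertoire[[strength_col]]
  in_rep <- which(w > 0)
  len <- as.integer(pmin(1000, pmax(30, round(
    rlnorm(n, config$fragment_length_log_mean, config$fragment_length_log_sd)))))
  is_peak <- runif(n) < config$frip
  n_pk <- sum(is_peak)
  chrom <- character(n)
  start <- integer(n)
  if (n_pk > 0L) {
    pk_i <- in_rep[sample.int(length(in_rep), n_pk, replace = TRUE,
                              prob = w[in_rep])]
    pw <- repertoire$end[pk_i] - repertoire$start[pk_i]
    mid <- repertoire$start[pk_i] + as.integer(floor(runif(n_pk) * pw))
    s <- mid - len[is_peak] %/% 2L
    e <- s + len[is_peak]
    lim <- as.integer(sizes[repertoire$chrom[pk_i]])
    s <- pmax(s, 0L)
    e <- pmin(e, lim)
    chrom[is_peak] <- repertoire$chrom[pk_i]
    start[is_peak] <- s
    len[is_peak] <- e - s
  }
  n_bg <- n - n_pk
  if (n_bg > 0L) {
    bg_chr <- sample(names(sizes), n_bg, replace = TRUE,
                     prob = as.numeric(sizes) / sum(as.numeric(sizes)))
    lim <- as.integer(sizes[bg_chr])
    chrom[!is_peak] <- bg_chr
    start[!is_peak] <- as.integer(floor(runif(n_bg) * (lim - len[!is_peak])))
  }
  data.table(chrom = chrom, start = start, end = start + len)
}

# Negative-binomial mu calibrated so the distribution's median hits target.
.nb_mu_for_median <- function(target, size) {
  mu <- as.numeric(target)
  for (i in seq_len(30L)) {
    med <- qnbinom(0.5, size = size, mu = mu)
    if (med == target) break
    mu <- mu * target / max(med, 1)
  }
  mu
}

#' Simulate single-cell fragments for a two-type mixed population
#'
#' Per-cell depths are negative-binomial with median calibrated to
#' `median_frags_per_cell`; each fragment is a peak fragment with probability
#' `frip` (peak drawn from the cell type's repertoire proportionally to its
#' per-type strength) and uniform background otherwise. Output fragments are
#' deduplicated on `(chrom, start, end, barcode)` and carry read supports
#' drawn as 1 + Poisson(0.3).
#'
#' @param config A [sim_config()].
#' @param repertoire Peak repertoire, ideally amended by
#'   [simulate_annotation()] (falls back to symmetric strengths otherwise).
#' @param seed Integer seed.
#' @return A list with `fragments` (sorted fragment `data.table`) and
#'   `cell_labels` (named character vector barcode -> "A"/"B").
#' @export
simulate_cells <- function(config, repertoire, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.check_scalar_seed(seed))
  size <- 1 / config$frag_count_dispersion
  mu <- .nb_mu_for_median(config$median_frags_per_cell, size)
  barcodes <- c(sprintf("BCA%04d-1", seq_len(config$n_cells_A)),
                sprintf("BCB%04d-1", seq_len(config$n_cells_B)))
  labels <- c(rep("A", config$n_cells_A), rep("B", config$n_cells_B))
  depth <- pmax(50L, rnbinom(length(barcodes), size = size, mu = mu))
  frag_list <- vector("list", 2L)
  for (t in c("A", "B")) {
    sel <- labels == t
    n_t <- sum(depth[sel])
    fr <- .draw_fragments(config, repertoire, t, n_t)
    fr[, barcode := rep(barcodes[sel], depth[sel])]
    frag_list[[match(t, c("A", "B"))]] <- fr
  }
  frags <- rbindlist(frag_list)
  frags <- unique(frags, by = c("chrom", "start", "end", "barcode"))
  frags[, read_support := 1L + rpois(.N, 0.3)]
  frags <- frags[.bed_order(frags, with_barcode = TRUE)]
  names(labels) <- barcodes
  list(fragments = frags[], cell_labels = labels)
}

#' Simulate bulk replicate libraries
#'
#' For each cell type, draws `n_bulk_replicates` libraries of `bulk_depth`
#' fragments from the same per-type fragment model used for cells, each with
#' a single pooled barcode, so replicates of a type differ only by sampling
#' noise.
#'
#' @inheritParams simulate_cells
#' @return A named list of fragment `data.table`s, names like `bulkA_rep1`.
#' @export
simulate_bulk_replicates <- function(config, repertoire, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.check_scalar_seed(seed))
  if (config$bulk_depth == 0L) {
    warning("bulk_depth is 0; bulk libraries are empty and RPM is undefined")
  }
  out <- list()
  for (t in c("A", "B")) {
    for (r in seq_len(config$n_bulk_replicates)) {
      nm <- sprintf("bulk%s_rep%d", t, r)
      fr <- .draw_fragments(config, repertoire, t, config$bulk_depth)
      if (nrow(fr) > 0L) fr[, barcode := nm]
      else fr[, barcode := character(0)]
      fr <- unique(fr, by = c("chrom", "start", "end", "barcode"))
      if (nrow(fr) > 0L) fr[, read_support := 1L + rpois(.N, 0.3)]
      else fr[, read_support := integer(0)]
      out[[nm]] <- fr[.bed_order(fr, with_barcode = TRUE)][]
    }
  }
  out
}

#' Simulate a complete dataset with ground truth
#'
#' Runs repertoire, annotation, single-cell and bulk simulation with
#' stage-derived seeds, and optionally writes every artifact to `outdir`
#' (`fragments_sc.tsv`, `fragments_bulk_*.tsv`, `peaks_truth.bed`,
#' `cell_labels.tsv`, `tss.tsv`, `copy_number.tsv`, `truth.json`).
#'
#' @param config A [sim_config()].
#' @param outdir Optional output directory.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A list: `fragments`, `bulk` (named list), `repertoire`, `tss`,
#'   `cn_table`, and `truth` (cell labels, peak classes/strengths,
#'   differential genes, copy-number table).
#' @export
simulate_dataset <- function(config = sim_config(), outdir = NULL,
                             seed = config$seed) {
  seed <- .check_scalar_seed(seed)
  repertoire <- simulate_peak_repertoire(config, seed = .stage_seed(seed, 1L))
  ann <- simulate_annotation(config, repertoire, seed = .stage_seed(seed, 2L))
  sc <- simulate_cells(config, ann$repertoire, seed = .stage_seed(seed, 3L))
  bulk <- simulate_bulk_replicates(config, ann$repertoire,
                                   seed = .stage_seed(seed, 4L))
  truth <- list(
    cell_labels = sc$cell_labels,
    peak_classes = stats::setNames(ann$repertoire$class, ann$repertoire$name),
    peak_strengths = stats::setNames(ann$repertoire$strength,
                                     ann$repertoire$name),
    diff_promoter_genes = ann$diff_genes,
    cn_table = ann$cn_table
  )
  out <- list(fragments = sc$fragments, bulk = bulk,
              repertoire = ann$repertoire, tss = ann$tss,
              cn_table = ann$cn_table, truth = truth)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fragment_file(out$fragments, file.path(outdir, "fragments_sc.tsv"))
    for (nm in names(bulk)) {
      write_fragment_file(bulk[[nm]],
                          file.path(outdir, sprintf("fragments_%s.tsv", nm)))
    }
    write_bed(out$repertoire[, list(chrom, start, end, name,
                                    score = strength)],
              file.path(outdir, "peaks_truth.bed"))
    data.table::fwrite(
      data.table(barcode = names(truth$cell_labels),
                 label = unname(truth$cell_labels)),
      file.path(outdir, "cell_labels.tsv"), sep = "\t", eol = "\n")
    write_tss_table(out$tss, file.path(outdir, "tss.tsv"))
    write_copy_number_table(out$cn_table, file.path(outdir, "copy_number.tsv"))
    jsonlite::write_json(
      list(cell_labels = as.list(truth$cell_labels),
           peak_classes = as.list(truth$peak_classes),
           diff_promoter_genes = truth$diff_promoter_genes),
      file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
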