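# The identity-imputation stack: Spearman correlation across libraries, the
# z-score / upper-quartile-cap / unit-rescale signal transform, k-medoids
# clustering (PAM, and its subsampling extension CLARA) implemented from
# first principles, average-linkage hierarchical clustering of library
# correlations, and an LSI + k-medoids cell-clustering stage.

.signal_matrix <- function(x) {
  if (inherits(x, "library_signal_matrix")) x$rpm else as.matrix(x)
}

#' Pairwise Spearman correlation across libraries
#'
#' Ranks each library's signal (average ranks for ties) and computes the
#' Pearson correlation of the ranks. A constant library has no rank
#' variation; its correlations are recorded as 0 and the affected libraries
#' are listed in the `"constant_columns"` attribute.
#'
#' @param signal A `library_signal_matrix` or a numeric matrix
#'   (regions x libraries, >= 3 regions, >= 2 libraries).
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(signal) {
  m <- .signal_matrix(signal)
  if (ncol(m) < 2L) stop("need at least 2 libraries", call. = FALSE)
  if (nrow(m) < 3L) stop("need at least 3 regions", call. = FALSE)
  ranks <- apply(m, 2L, rank)
  const <- apply(ranks, 2L, function(x) sd(x) == 0)
  rho <- suppressWarnings(cor(ranks))
  if (any(const)) {
    warning("constant library signal; correlations set to 0 for: ",
            paste(colnames(m)[const], collapse = ", "))
    rho[const, ] <- 0
    rho[, const] <- 0
  }
  diag(rho) <- 1
  dimnames(rho) <- list(colnames(m), colnames(m))
  attr(rho, "constant_columns") <- colnames(m)[const]
  rho
}

#' Z-score, upper-quartile cap and unit rescale of a signal matrix
#'
#' Three matrix-level steps: (1) z-score each region row across libraries
#' (rows with zero spread map to all zeros); (2) compute the 75th percentile
#' (linear interpolation) over all matrix entries and cap every entry above
#' it at that value; (3) min-max rescale the whole matrix to `[0, 1]`, where
#' 0 indicates low and 1 high signal (an all-constant matrix maps to all
#' zeros).
#'
#' @param signal A `library_signal_matrix` or numeric matrix (regions x
#'   libraries, >= 2 libraries).
#' @return A numeric matrix of the same shape with entries in `[0, 1]`.
#' @export
transform_signal_matrix <- function(signal) {
  m <- .signal_matrix(signal)
  if (ncol(m) < 2L) {
    stop("z-score across libraries undefined for a single library",
         call. = FALSE)
  }
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, sd)
  z <- (m - mu) / ifelse(sdv == 0, 1, sdv)
  z[sdv == 0, ] <- 0
  q <- quantile(z, 0.75, type = 7, names = FALSE)
  z[z > q] <- q
  lo <- min(z); hi <- max(z)
  out <- if (hi == lo) array(0, dim(z)) else (z - lo) / (hi - lo)
  dimnames(out) <- dimnames(m)
  out
}

# Assign items to nearest medoid (tie -> lowest medoid index) given the
# n x k item-to-medoid distance matrix.
.assign_to_medoids <- function(dmed, medoids) {
  cl <- max.col(-dmed, ties.method = "first")
  cost <- sum(dmed[cbind(seq_len(nrow(dmed)), cl)])
  list(labels = cl, total_dissimilarity = cost)
}

.new_cluster_assignment <- function(d_to_medoids, medoids, item_names = NULL) {
  a <- .assign_to_medoids(d_to_medoids, medoids)
  labels <- a$labels
  if (!is.null(item_names)) names(labels) <- item_names
  structure(list(labels = labels, medoids = medoids,
                 total_dissimilarity = a$total_dissimilarity,
                 k = length(medoids)),
            class = "cluster_assignment")
}

# Best-improvement SWAP descent from a given medoid set: repeatedly apply
# the single best strictly improving (medoid, non-medoid) exchange until no
# exchange improves; ties broken by lowest item index.
.pam_swap_descend <- function(d, medoids) {
  n <- nrow(d)
  repeat {
    dm <- d[, medoids, drop = FALSE]
    ord1 <- max.col(-dm, ties.method = "first")
    nd <- dm[cbind(seq_len(n), ord1)]
    dm2 <- dm
    dm2[cbind(seq_len(n), ord1)] <- Inf
    sd2 <- dm2[cbind(seq_len(n), max.col(-dm2, ties.method = "first"))]
    cost <- sum(nd)
    best <- list(delta = 0, mi = NA_integer_, h = NA_integer_)
    non_medoids <- setdiff(seq_len(n), medoids)
    for (mi in seq_along(medoids)) {
      affected <- ord1 == mi
      base <- ifelse(affected, sd2, nd)
      for (h in non_medoids) {
        newcost <- sum(pmin(base, d[, h]))
        delta <- newcost - cost
        if (delta < best$delta - 1e-12) best <- list(delta = delta, mi = mi, h = h)
      }
    }
    if (is.na(best$mi)) return(list(medoids = medoids, cost = cost))
    medoids[best$mi] <- best$h
  }
}

#' Partitioning Around Medoids (PAM)
#'
#' Two-phase PAM on a precomputed dissimilarity matrix, with multiple
#' starts. The first start is the classic greedy BUILD (k medoids chosen to
#' minimize total dissimilarity); the remaining starts are seeded random
#' medoid sets. Each start is refined by best-improvement SWAP (repeatedly
#' apply the single best strictly improving (medoid, non-medoid) exchange,
#' ties broken by lowest item index, until none improves) and the best final
#' solution is returned. Single-swap descent can stall on plateau
#' configurations where two medoid exchanges are needed; the extra starts
#' make the returned solution reliably optimal on small instances while
#' keeping the result deterministic for a given input and seed.
#'
#' @param d Square symmetric dissimilarity matrix with zero diagonal.
#' @param k Number of clusters, `1 <= k < n`.
#' @param n_starts Total number of starts (BUILD plus `n_starts - 1` random
#'   initializations; default 10).
#' @param seed Seed for the random initializations; the caller's RNG state
#'   is left untouched.
#' @return A `cluster_assignment`: `labels` (cluster index per item, named if
#'   `d` has dimnames), `medoids` (item indices), `total_dissimilarity`.
#' @export
pam_kmedoids <- function(d, k, n_starts = 10L, seed = 1L) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n != ncol(d)) stop("dissimilarity matrix must be square", call. = FALSE)
  if (k < 1L || k >= n) stop("k must satisfy 1 <= k < n", call. = FALSE)
  if (any(d < 0)) stop("dissimilarities must be non-negative", call. = FALSE)

  # BUILD
  medoids <- which.min(colSums(d))
  nd <- d[, medoids]
  while (length(medoids) < k) {
    gains <- colSums(pmax(nd - d, 0))
    gains[medoids] <- -Inf
    cand <- which.max(gains)
    medoids <- c(medoids, cand)
    nd <- pmin(nd, d[, cand])
  }
  best <- .pam_swap_descend(d, medoids)

  if (n_starts > 1L) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(.stage_seed(.check_scalar_seed(seed), 97L))
    for (s in seq_len(n_starts - 1L)) {
      init <- sort(sample.int(n, k))
      cand <- .pam_swap_descend(d, init)
      if (cand$cost < best$cost - 1e-12) best <- cand
    }
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }
  medoids <- sort(unname(best$medoids))
  .new_cluster_assignment(d[, medoids, drop = FALSE], medoids, rownames(d))
}

#' CLARA: k-medoids by repeated subsampling
#'
#' Runs PAM on `n_samples` random subsamples of size
#' `min(sample_size, n)` (each subsample after the first also contains the
#' best medoids found so far), scores every candidate medoid set by total
#' dissimilarity over all items, and keeps the best. When the subsample size
#' reaches `n` the whole set is used once and the result is exactly PAM on
#' the full set.
#'
#' @param x Numeric matrix of item features (items as rows) or a vector
#'   (treated as one feature).
#' @param k Number of clusters.
#' @param n_samples Number of subsamples (default 5).
#' @param sample_size Subsample size (default `40 + 2 * k`).
#' @param seed Integer seed for subsampling.
#' @param dist_fn Function `(a, b)` returning the cross-distance matrix
#'   between rows of `a` and rows of `b`; Euclidean by default.
#' @return A `cluster_assignment` over all items; medoids are row indices of
#'   `x`.
#' @export
clara <- function(x, k, n_samples = 5L, sample_size = NULL, seed = 1L,
                  dist_fn = NULL) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(sample_size)) sample_size <- 40L + 2L * k
  if (sample_size < k) stop("sample_size must be >= k", call. = FALSE)
  if (k < 1L || k >= n) stop("k must satisfy 1 <= k < n", call. = FALSE)
  if (is.null(dist_fn)) dist_fn <- .cross_dist
  set.seed(.check_scalar_seed(seed))
  ssize <- min(sample_size, n)
  full <- ssize == n
  best <- NULL
  n_draws <- if (full) 1L else n_samples
  for (s in seq_len(n_draws)) {
    if (full) {
      idx <- seq_len(n)
    } else if (is.null(best)) {
      idx <- sort(sample.int(n, ssize))
    } else {
      extra <- sample(setdiff(seq_len(n), best$medoids),
                      ssize - length(best$medoids))
      idx <- sort(c(best$medoids, extra))
    }
    sub_d <- dist_fn(x[idx, , drop = FALSE], x[idx, , drop = FALSE])
    fit <- pam_kmedoids(sub_d, k)
    medoids <- sort(idx[fit$medoids])
    dmed <- dist_fn(x, x[medoids, , drop = FALSE])
    cand <- .assign_to_medoids(dmed, medoids)
    if (is.null(best) || cand$total_dissimilarity < best$cost - 1e-12) {
      best <- list(medoids = medoids, cost = cand$total_dissimilarity)
    }
  }
  dmed <- dist_fn(x, x[best$medoids, , drop = FALSE])
  .new_cluster_assignment(dmed, best$medoids, rownames(x))
}

#' Average-linkage hierarchical clustering of a correlation matrix
#'
#' Agglomerates libraries on the distance `1 - r_s` with average linkage.
#'
#' @param corr Correlation matrix (e.g. from [spearman_matrix()]).
#' @param linkage Linkage method (default `"average"`).
#' @return An `hclust` object.
#' @export
hierarchical_cluster <- function(corr, linkage = "average") {
  d <- stats::as.dist(1 - as.matrix(corr))
  hclust(d, method = linkage)
}

#' Impute the cell identity of single-cell clusters
#'
#' Each single-cell cluster's aggregate profile is assigned the reference
#' label whose libraries correlate best with it (Spearman); the margin is
#' the gap between the best and second-best label. For concordance, the
#' joint signal matrix is also passed through [transform_signal_matrix()]
#' and its region rows clustered with [clara()] (K = 4 signal archetypes),
#' and the library correlation matrix is hierarchically clustered.
#'
#' @param signal A `library_signal_matrix` or numeric matrix over a shared
#'   region set whose columns include both cluster aggregates and reference
#'   libraries.
#' @param cluster_cols Column names of the single-cell cluster aggregates.
#' @param reference_labels Named character vector: reference column name ->
#'   candidate label.
#' @param min_margin Margin below which a call is flagged low-confidence.
#' @param archetype_k Number of CLARA region archetypes (default 4).
#' @param seed Seed for the CLARA subsampling step.
#' @return A list: `calls` (`data.table` with cluster, label, r_s, margin,
#'   low_confidence), `correlations`, `hclust`, `region_archetypes`.
#' @export
impute_cluster_identity <- function(signal, cluster_cols, reference_labels,
                                    min_margin = 0.05, archetype_k = 4L,
                                    seed = 1L) {
  m <- .signal_matrix(signal)
  stopifnot(all(cluster_cols %in% colnames(m)),
            all(names(reference_labels) %in% colnames(m)),
            length(unique(reference_labels)) >= 1L)
  rho <- spearman_matrix(m)
  calls <- rbindlist(lapply(cluster_cols, function(cc) {
    r_by_label <- vapply(split(names(reference_labels),
                               as.character(reference_labels)),
                         function(cols) max(rho[cc, cols]), numeric(1))
    o <- order(-r_by_label, names(r_by_label))
    best <- r_by_label[o[1L]]
    second <- if (length(r_by_label) > 1L) r_by_label[o[2L]] else -1
    data.table(cluster = cc, label = names(r_by_label)[o[1L]],
               r_s = unname(best), margin = unname(best - second))
  }))
  calls[, low_confidence := margin < min_margin]
  trans <- transform_signal_matrix(m)
  arch <- clara(trans, k = archetype_k, seed = seed)
  list(calls = calls[], correlations = rho,
       hclust = hierarchical_cluster(rho),
       region_archetypes = arch)
}

#' Latent semantic indexing embedding of a cell-region matrix
#'
#' Binarizes the counts, applies TF-IDF weighting (term frequency times
#' `log(1 + n_cells / n_cells_with_region)`), L2-normalizes cells and
#' projects onto the top singular directions, with a fixed sign convention
#' (the largest-magnitude region loading of each component is positive).
#' Component 1, typically depth-correlated, is dropped by default.
#'
#' @param x A `cell_region_matrix` or a cells x regions count matrix.
#' @param n_dims Number of singular directions to compute.
#' @param drop_first Drop the first component (default `TRUE`).
#' @return A cells x dims embedding matrix; cells and regions with all-zero
#'   counts are dropped and listed in the `"dropped_cells"` /
#'   `"dropped_regions"` attributes.
#' @export
lsi_embed <- function(x, n_dims = 10L, drop_first = TRUE) {
  counts <- if (inherits(x, "cell_region_matrix")) x$counts else as.matrix(x)
  bin <- (counts > 0) * 1
  zero_cells <- rowSums(bin) == 0
  zero_regions <- colSums(bin) == 0
  bin <- bin[!zero_cells, !zero_regions, drop = FALSE]
  if (nrow(bin) < n_dims + 1L) {
    stop("need more than n_dims cells with signal", call. = FALSE)
  }
  tf <- bin / rowSums(bin)
  idf <- log(1 + nrow(bin) / colSums(bin))
  w <- sweep(tf, 2L, idf, "*")
  w <- w / sqrt(rowSums(w^2))
  ncomp <- min(n_dims, dim(w) - 1L)
  s <- svd(w, nu = ncomp, nv = ncomp)
  flip <- vapply(seq_len(ncomp), function(j) {
    v <- s$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  emb <- sweep(s$u, 2L, s$d[seq_len(ncomp)] * flip, "*")
  rownames(emb) <- rownames(bin)
  colnames(emb) <- sprintf("LSI%d", seq_len(ncomp))
  if (drop_first && ncomp > 1L) emb <- emb[, -1L, drop = FALSE]
  attr(emb, "dropped_cells") <- rownames(counts)[zero_cells]
  attr(emb, "dropped_regions") <- colnames(counts)[zero_regions]
  emb
}

#' Cluster cells in an embedding with k-medoids
#'
#' Uses [pam_kmedoids()] on Euclidean distances; above `clara_threshold`
#' cells it switches to [clara()] for tractability.
#'
#' @param embedding Cells x dims matrix (e.g. from [lsi_embed()]).
#' @param k Number of clusters (default 2).
#' @param seed Seed (used by the CLARA path).
#' @param clara_threshold Cell count above which CLARA replaces full PAM.
#' @return A `cluster_assignment` with labels named by cell barcode.
#' @export
cluster_cells <- function(embedding, k = 2L, seed = 1L,
                          clara_threshold = 2000L) {
  emb <- as.matrix(embedding)
  if (k > nrow(emb)) stop("k exceeds the number of cells", call. = FALSE)
  if (nrow(emb) > clara_threshold) {
    clara(emb, k = k, seed = seed)
  } else {
    pam_kmedoids(.cross_dist(emb, emb), k)
  }
}
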