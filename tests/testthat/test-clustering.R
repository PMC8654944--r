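test_that("Spearman matrix matches rank-then-Pearson and flags constant libraries", {
  m <- cbind(a = c(1, 2, 3), b = c(10, 20, 30), c = c(3, 2, 1))
  rho <- spearman_matrix(m)
  expect_equal(rho["a", "b"], 1)
  expect_equal(rho["a", "c"], -1)
  expect_equal(diag(rho), c(a = 1, b = 1, c = 1))

  # tie handling equals the standard Spearman estimator
  m2 <- cbind(x = c(1, 2, 2, 4), y = c(2, 1, 3, 4))
  rho2 <- spearman_matrix(m2)
  expect_equal(rho2["x", "y"],
               cor(c(1, 2, 2, 4), c(2, 1, 3, 4), method = "spearman"))

  m3 <- cbind(x = c(1, 2, 3), k = c(5, 5, 5))
  expect_warning(rho3 <- spearman_matrix(m3), "constant")
  expect_equal(rho3["x", "k"], 0)
  expect_equal(rho3["k", "k"], 1)

  expect_error(spearman_matrix(m[1:2, ]), "3 regions")
  expect_error(spearman_matrix(m[, 1, drop = FALSE]), "2 libraries")
})

test_that("signal transform matches an independent step-by-step computation", {
  set.seed(19)
  m <- matrix(rnorm(32, mean = 5, sd = 2), nrow = 8, ncol = 4)

  # independent oracle: explicit loops and a sort-based linear-interpolation
  # percentile
  z <- m
  for (i in 1:8) {
    mu <- mean(m[i, ]); s <- sqrt(sum((m[i, ] - mu)^2) / 3)
    z[i, ] <- if (s == 0) 0 else (m[i, ] - mu) / s
  }
  v <- sort(as.vector(z))
  h <- (length(v) - 1) * 0.75 + 1
  q <- v[floor(h)] + (h - floor(h)) * (v[floor(h) + 1] - v[floor(h)])
  z[z > q] <- q
  expected <- (z - min(z)) / (max(z) - min(z))

  expect_equal(transform_signal_matrix(m), expected, tolerance = 1e-12)
})

test_that("transform output is bounded with exactly the top quartile saturated", {
  set.seed(23)
  for (i in 1:100) {
    m <- matrix(rnorm(8 * sample(4:12, 1)), nrow = 8)
    out <- transform_signal_matrix(m)
    expect_true(all(out >= 0 & out <= 1))
  }

  # all-distinct entries after z-scoring: exactly 25% of entries hit 1
  m <- matrix(rnorm(40), nrow = 10, ncol = 4)
  out <- transform_signal_matrix(m)
  expect_equal(mean(out == 1), 0.25)

  # constant rows z-score to zero and share a single image value
  m2 <- rbind(m, c(7, 7, 7, 7), c(2, 2, 2, 2))
  out2 <- transform_signal_matrix(m2)
  expect_equal(out2[11L, ], out2[12L, ])
  expect_equal(length(unique(as.vector(out2[11:12, ]))), 1L)

  # an all-constant matrix collapses to the minimum image, all zeros
  expect_true(all(transform_signal_matrix(matrix(3, 4, 3)) == 0))

  expect_error(transform_signal_matrix(matrix(1:4, ncol = 1)), "single library")
})

test_that("PAM recovers hand-enumerable medoid configurations", {
  x <- c(0, 1, 10, 11)
  d <- abs(outer(x, x, "-"))
  fit <- pam_kmedoids(d, 2)
  expect_equal(fit$total_dissimilarity, 2)
  expect_equal(fit$labels[1:2], rep(fit$labels[1L], 2L))
  expect_equal(fit$labels[3:4], rep(fit$labels[3L], 2L))
  expect_false(fit$labels[1L] == fit$labels[3L])

  # k = 1: the medoid minimizes summed dissimilarity by definition
  set.seed(5)
  y <- runif(9)
  dy <- abs(outer(y, y, "-"))
  expect_equal(pam_kmedoids(dy, 1)$medoids, which.min(colSums(dy)))

  # k = n - 1: all singletons except the closest pair
  expect_equal(pam_kmedoids(dy, 8)$total_dissimilarity,
               min(dy[upper.tri(dy)]))

  expect_error(pam_kmedoids(dy, 9), "k must satisfy")
  expect_error(pam_kmedoids(dy, 0), "k must satisfy")
})

test_that("PAM and full-sample CLARA attain the exhaustive-search optimum", {
  set.seed(101)
  for (rep_i in 1:25) {
    n <- sample(6:10, 1)
    k <- sample(2:3, 1)
    pts <- matrix(runif(n * 2), ncol = 2)
    d <- as.matrix(dist(pts))
    cost <- function(med) sum(apply(d[, med, drop = FALSE], 1L, min))
    best <- min(apply(utils::combn(n, k), 2L, cost))
    fit <- pam_kmedoids(d, k)
    expect_equal(fit$total_dissimilarity, best, tolerance = 1e-12)
    # evaluate CLARA's medoid choice with the same cost arithmetic as the
    # exhaustive oracle (its internal cross-distances differ only in float
    # rounding)
    cfit <- clara(pts, k, sample_size = n, seed = rep_i)
    expect_equal(cost(cfit$medoids), best, tolerance = 1e-12)
  }
})

test_that("CLARA reduces exactly to PAM when the subsample is the full set", {
  set.seed(55)
  pts <- matrix(rnorm(60), ncol = 2)
  d <- as.matrix(dist(pts))
  ref <- pam_kmedoids(d, 3)
  for (s in 1:20) {
    cfit <- clara(pts, 3, sample_size = nrow(pts), seed = s)
    expect_identical(cfit$medoids, ref$medoids)
    expect_equal(cfit$total_dissimilarity, ref$total_dissimilarity)
    expect_equal(unname(cfit$labels), unname(ref$labels))
  }
})

test_that("CLARA recovers well-separated blobs and beats random medoids", {
  set.seed(77)
  centers <- matrix(c(0, 0, 10, 0, 0, 10, 10, 10), ncol = 2, byrow = TRUE)
  truth <- rep(1:4, each = 100)
  pts <- centers[truth, ] + matrix(rnorm(800, sd = 0.5), ncol = 2)
  fit <- clara(pts, 4, seed = 3)
  expect_gte(adjusted_rand_index(fit$labels, truth), 0.99)

  for (i in 1:20) {
    set.seed(i)
    n <- 40
    x <- matrix(runif(n * 3), ncol = 3)
    fit <- clara(x, 3, seed = i)
    rand_med <- sample.int(n, 3)
    rand_cost <- sum(apply(sng4kit:::.cross_dist(x, x[rand_med, ]), 1, min))
    expect_lte(fit$total_dissimilarity, rand_cost + 1e-12)
  }
})

test_that("average-linkage hierarchy matches hand computation and merges duplicates first", {
  corr <- matrix(c(1, 0.9, 0.5,
                   0.9, 1, 0.7,
                   0.5, 0.7, 1), nrow = 3,
                 dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  hc <- hierarchical_cluster(corr)
  # distances: d(a,b)=0.1, d(a,c)=0.5, d(b,c)=0.3; {a,b} merge at 0.1,
  # then c joins at mean(0.5, 0.3) = 0.4
  expect_equal(hc$height, c(0.1, 0.4))

  m <- cbind(x = c(1, 5, 2, 7), y = c(1, 5, 2, 7), z = c(4, 1, 9, 2))
  hc2 <- hierarchical_cluster(spearman_matrix(m))
  expect_equal(hc2$height[1L], 0)
  expect_setequal(abs(hc2$merge[1L, ]), c(1L, 2L))
})

test_that("identity imputation labels clusters correctly and is order-invariant", {
  set.seed(12)
  base_a <- rgamma(200, 2); base_b <- rgamma(200, 2)
  mk <- function(base) pmax(base + rnorm(200, sd = 0.05), 0)
  m <- cbind(cl1 = mk(base_a), cl2 = mk(base_b),
             refA1 = mk(base_a), refA2 = mk(base_a),
             refB1 = mk(base_b), refB2 = mk(base_b))
  refs <- c(refA1 = "A", refA2 = "A", refB1 = "B", refB2 = "B")
  res <- impute_cluster_identity(m, c("cl1", "cl2"), refs)
  expect_equal(res$calls$label, c("A", "B"))
  expect_true(all(res$calls$margin > 0))
  expect_false(any(res$calls$low_confidence))
  expect_s3_class(res$hclust, "hclust")
  expect_equal(res$region_archetypes$k, 4L)

  # permuting the library columns must not change the calls
  perm <- m[, c("refB2", "cl2", "refA1", "cl1", "refB1", "refA2")]
  res_p <- impute_cluster_identity(perm, c("cl1", "cl2"), refs)
  expect_equal(res_p$calls[order(cluster)]$label,
               res$calls[order(cluster)]$label)
  # rescaling one library (RPM scale change) leaves Spearman calls alone
  m_scaled <- m; m_scaled[, "refA1"] <- m_scaled[, "refA1"] * 7
  res_s <- impute_cluster_identity(m_scaled, c("cl1", "cl2"), refs)
  expect_equal(res_s$calls$label, res$calls$label)

  # aggregate identical to one reference: margin = 1 - r_s(other label)
  m2 <- cbind(cl1 = base_a, refA = base_a, refB = base_b)
  res2 <- impute_cluster_identity(m2, "cl1", c(refA = "A", refB = "B"))
  expect_equal(res2$calls$r_s, 1)
  expect_equal(res2$calls$margin,
               1 - cor(base_a, base_b, method = "spearman"))
})

test_that("LSI embedding deduplicates profiles and separates simulated types", {
  counts <- matrix(rpois(20 * 30, 1), nrow = 20)
  counts[1L, ] <- counts[2L, ]
  emb <- lsi_embed(counts, n_dims = 5)
  expect_equal(emb[1L, ], emb[2L, ])
  expect_equal(ncol(emb), 4L)  # first component dropped

  cfg <- small_sim_config()
  rep <- simulate_peak_repertoire(cfg, seed = 41L)
  sc <- simulate_cells(cfg, rep, seed = 41L)
  crm <- build_cell_region_matrix(sc$fragments, rep[, list(chrom, start, end, name)],
                                  "fragments")
  emb2 <- lsi_embed(crm, n_dims = 10)
  labels <- sc$cell_labels[rownames(emb2)]
  fit <- cluster_cells(emb2, k = 2)
  expect_gte(adjusted_rand_index(fit$labels, labels), 0.95)

  # all-zero cells are dropped and reported
  counts0 <- counts; counts0[3L, ] <- 0L
  rownames(counts0) <- sprintf("c%02d", 1:20)
  emb3 <- lsi_embed(counts0, n_dims = 5)
  expect_equal(attr(emb3, "dropped_cells"), "c03")
})

test_that("cell clustering splits far-apart blobs perfectly and deterministically", {
  set.seed(9)
  pts <- rbind(matrix(rnorm(40, 0, 0.1), ncol = 2),
               matrix(rnorm(40, 5, 0.1), ncol = 2))
  rownames(pts) <- sprintf("cell%02d", 1:40)
  f1 <- cluster_cells(pts, k = 2, seed = 1)
  f2 <- cluster_cells(pts, k = 2, seed = 1)
  expect_identical(f1$labels, f2$labels)
  expect_equal(length(unique(f1$labels[1:20])), 1L)
  expect_equal(length(unique(f1$labels[21:40])), 1L)
  expect_false(f1$labels[1L] == f1$labels[40L])
})
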