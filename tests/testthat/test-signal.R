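test_that("fragment and cut-site counting respect half-open boundaries", {
  regions <- data.table(chrom = "chr1", start = 150L, end = 400L)
  # overlaps by [150,200); only the end-1 = 199 insertion is inside
  fr <- frag_row("chr1", 100, 200, "BC-1")
  m_frag <- build_cell_region_matrix(fr, regions, "fragments")
  m_cut <- build_cell_region_matrix(fr, regions, "cut_sites")
  expect_equal(unname(m_frag$counts[1L, 1L]), 1L)
  expect_equal(unname(m_cut$counts[1L, 1L]), 1L)

  inside <- frag_row("chr1", 200, 300, "BC-1")
  expect_equal(unname(build_cell_region_matrix(inside, regions,
                                               "cut_sites")$counts[1L, 1L]), 2L)

  # end == region start: no overlap under half-open coordinates
  touching <- frag_row("chr1", 100, 150, "BC-1")
  expect_equal(unname(build_cell_region_matrix(touching, regions,
                                               "fragments")$counts[1L, 1L]), 0L)
})

test_that("overlapping regions are rejected with the offending pair named", {
  regions <- data.table(chrom = "chr1", start = c(0L, 50L), end = c(100L, 80L))
  expect_error(build_cell_region_matrix(frag_row("chr1", 0, 10, "b"),
                                        regions, "fragments"),
               "chr1:0-100.*chr1:50-80")
})

test_that("cell-region counts equal a brute-force fragment-by-region scan", {
  set.seed(42)
  regions <- random_peaks(50)
  n <- 1000L
  frags <- data.table(
    chrom = "chr1",
    start = sample.int(99000L, n, replace = TRUE))
  frags[, end := start + sample(30:400, n, replace = TRUE)]
  frags[, barcode := sample(sprintf("BC%02d", 1:20), n, replace = TRUE)]
  frags[, read_support := 1L]
  frags <- unique(frags, by = c("chrom", "start", "end", "barcode"))

  got <- build_cell_region_matrix(frags, regions, "fragments")
  brute <- matrix(0L, nrow = length(got$barcodes), ncol = nrow(regions),
                  dimnames = dimnames(got$counts))
  for (i in seq_len(nrow(frags))) {
    bi <- match(frags$barcode[i], got$barcodes)
    for (j in seq_len(nrow(regions))) {
      if (intervals_overlap(frags$start[i], frags$end[i],
                            regions$start[j], regions$end[j])) {
        brute[bi, j] <- brute[bi, j] + 1L
      }
    }
  }
  expect_identical(got$counts, brute)

  got_cut <- build_cell_region_matrix(frags, regions, "cut_sites")
  brute_cut <- 0L * brute
  for (i in seq_len(nrow(frags))) {
    bi <- match(frags$barcode[i], got$barcodes)
    for (pos in c(frags$start[i], frags$end[i] - 1L)) {
      inside <- pos >= regions$start & pos < regions$end
      brute_cut[bi, inside] <- brute_cut[bi, inside] + 1L
    }
  }
  expect_identical(got_cut$counts, brute_cut)

  # row sums never exceed per-cell fragment (or 2x) totals
  per_cell <- table(frags$barcode)[got$barcodes]
  expect_true(all(rowSums(got$counts) <= as.integer(per_cell)))
  expect_true(all(rowSums(got_cut$counts) <= 2L * as.integer(per_cell)))
})

test_that("RPM normalization is exact arithmetic and rank-preserving", {
  regions <- data.table(chrom = "chr1", start = c(0L, 1000L),
                        end = c(500L, 1500L))
  lib <- rbind(
    do.call(rbind, lapply(1:50, function(i) frag_row("chr1", 10 + i, 490, "b"))),
    do.call(rbind, lapply(1:950, function(i) frag_row("chr1", 5000 + i, 5600 + i, "b")))
  )
  rpmm <- compute_rpm_matrix(list(L = lib), regions)
  expect_equal(unname(rpmm$rpm[1L, "L"]), 50 * 1e6 / 1000)
  expect_equal(unname(rpmm$rpm[2L, "L"]), 0)
  expect_equal(unname(rpmm$library_totals["L"]), 1000L)
  expect_error(compute_rpm_matrix(list(L = lib[0L]), regions), "empty")

  # duplicating a library (new barcode) doubles counts and totals alike,
  # leaving RPM and hence Spearman against any library unchanged
  set.seed(7)
  regions2 <- random_peaks(30)
  mk_lib <- function() {
    n <- 2000L
    fr <- data.table(chrom = "chr1",
                     start = sample.int(99000L, n, replace = TRUE))
    fr[, end := start + sample(30:300, n, replace = TRUE)]
    fr[, barcode := "pool"]
    fr[, read_support := 1L]
    unique(fr, by = c("chrom", "start", "end", "barcode"))
  }
  a <- mk_lib(); b <- mk_lib()
  a2 <- copy(a)[, barcode := "pool2"]
  r1 <- compute_rpm_matrix(list(A = a, B = b), regions2)
  r2 <- compute_rpm_matrix(list(A = rbind(a, a2), B = b), regions2)
  expect_equal(r2$rpm[, "A"], r1$rpm[, "A"])
  expect_equal(spearman_matrix(r1)["A", "B"], spearman_matrix(r2)["A", "B"])
})

test_that("FRiP is the exact overlap fraction with edge cases handled", {
  peaks <- data.table(chrom = "chr1", start = 0L, end = 1000L)
  fr <- rbind(
    do.call(rbind, lapply(1:8, function(i) frag_row("chr1", i * 10, i * 10 + 50, sprintf("b%d", i)))),
    do.call(rbind, lapply(1:12, function(i) frag_row("chr1", 5000 + i * 10, 5100 + i * 10, sprintf("c%d", i))))
  )
  expect_equal(compute_frip(fr, peaks), 0.4)
  genome_wide <- data.table(chrom = "chr1", start = 0L, end = 10000L)
  expect_equal(compute_frip(fr, genome_wide), 1)
  expect_error(compute_frip(fr[0L], peaks), "zero fragments")
})

test_that("pseudobulk aggregation partitions fragments and tallies the unassigned", {
  fr <- rbind(frag_row("chr1", 0, 10, "b1"), frag_row("chr1", 5, 15, "b1"),
              frag_row("chr1", 20, 30, "b2"), frag_row("chr1", 40, 50, "b3"),
              frag_row("chr1", 60, 70, "zz"))
  res <- aggregate_pseudobulk(fr, c(b1 = "X", b2 = "X", b3 = "Y"))
  expect_equal(nrow(res$clusters$X), 3L)
  expect_equal(nrow(res$clusters$Y), 1L)
  expect_equal(res$unassigned, 1L)
  # conservation: union of outputs plus unassigned equals the input
  expect_equal(sum(vapply(res$clusters, nrow, integer(1))) + res$unassigned,
               nrow(fr))
  recombined <- rbindlist(res$clusters)
  expect_setequal(paste(recombined$start, recombined$barcode),
                  paste(fr$start, fr$barcode)[fr$barcode != "zz"])
})

test_that("coverage tracks cover exactly the fragment bins and conserve base coverage", {
  sizes <- c(chr1 = 1000L)
  fr <- frag_row("chr1", 105, 134, "b")
  tr <- make_coverage_track(fr, sizes, bin_size = 10L, scale = "raw")
  expect_equal(tr$start[1L], 100L)
  expect_equal(tr$end[nrow(tr)], 140L)
  expect_true(all(tr$value == 1))

  # rpm scaling is invariant to exact depth duplication
  fr2 <- rbind(fr, copy(fr)[, barcode := "b2"])
  t1 <- make_coverage_track(fr, sizes, 10L, "rpm")
  t2 <- make_coverage_track(fr2, sizes, 10L, "rpm")
  expect_equal(t1$value, t2$value)

  # at bin_size = 1 the track sums to total fragment-base coverage
  set.seed(3)
  frs <- data.table(chrom = "chr1", start = sample.int(800L, 40L))
  frs[, end := start + sample(10:60, 40L, replace = TRUE)]
  frs[, barcode := "b"]; frs[, read_support := 1L]
  frs <- unique(frs, by = c("chrom", "start", "end", "barcode"))
  tr1 <- make_coverage_track(frs, sizes, 1L, "raw")
  expect_equal(sum(tr1$value * (tr1$end - tr1$start)),
               sum(frs$end - frs$start))
})
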