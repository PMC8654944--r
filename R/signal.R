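# Signal quantification over region sets: cell x region count matrices,
# library RPM matrices, FRiP, pseudobulk aggregation and bedGraph tracks.
# Overlap is always >= 1 bp on 0-based half-open intervals, so a fragment
# ending exactly at a region start does not count.

#' Build a cells-by-regions count matrix
#'
#' In `fragments` mode an entry is the number of distinct fragments of that
#' barcode overlapping the region by at least 1 bp. In `cut_sites` mode it is
#' the number of Tn5 insertion positions falling inside the region; the two
#' insertions of a fragment are its start and end-1 positions (no base
#' shift), counted separately.
#'
#' @param fragments Deduplicated fragment `data.table`.
#' @param regions Peak `data.table`; must be pairwise disjoint.
#' @param count_mode `"fragments"` or `"cut_sites"`.
#' @return A list of class `cell_region_matrix`: `counts` (integer matrix,
#'   cells x regions), `barcodes`, `regions`, `count_mode`.
#' @export
build_cell_region_matrix <- function(fragments, regions,
                                     count_mode = c("fragments", "cut_sites")) {
  count_mode <- match.arg(count_mode)
  regions <- as.data.table(regions)
  .assert_disjoint(regions)
  barcodes <- sort(unique(fragments$barcode), method = "radix")
  region_ids <- if ("name" %in% names(regions) && !anyNA(regions$name)) {
    regions$name
  } else {
    sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end)
  }
  counts <- matrix(0L, nrow = length(barcodes), ncol = nrow(regions),
                   dimnames = list(barcodes, region_ids))
  if (nrow(fragments) > 0L && nrow(regions) > 0L) {
    reg_gr <- .as_gr(regions)
    if (count_mode == "fragments") {
      hits <- .find_overlaps(.as_gr(fragments), reg_gr,
                                          minoverlap = 1L)
      pairs <- data.table(
        cell = match(fragments$barcode[S4Vectors::queryHits(hits)], barcodes),
        region = S4Vectors::subjectHits(hits))
    } else {
      # insertion positions: 0-based start and end-1, i.e. 1-based start+1, end
      pos <- c(fragments$start + 1L, fragments$end)
      site_gr <- GenomicRanges::GRanges(
        rep(fragments$chrom, 2L), IRanges::IRanges(pos, width = 1L))
      hits <- .find_overlaps(site_gr, reg_gr)
      bc2 <- rep(fragments$barcode, 2L)
      pairs <- data.table(
        cell = match(bc2[S4Vectors::queryHits(hits)], barcodes),
        region = S4Vectors::subjectHits(hits))
    }
    agg <- pairs[, .N, by = c("cell", "region")]
    counts[cbind(agg$cell, agg$region)] <- agg$N
  }
  structure(list(counts = counts, barcodes = barcodes,
                 regions = regions, count_mode = count_mode),
            class = "cell_region_matrix")
}

#' Build a regions-by-libraries RPM matrix
#'
#' Raw counts are fragments overlapping each region by >= 1 bp;
#' `rpm = count * 1e6 / library_total`, where the library total is the
#' number of deduplicated fragments genome-wide (not only those in regions).
#'
#' @param libraries Named list of fragment `data.table`s, one per library.
#' @param regions Disjoint reference regions (`data.table`).
#' @return A list of class `library_signal_matrix`: `rpm` (regions x
#'   libraries), `counts`, `library_totals`, `regions`.
#' @export
compute_rpm_matrix <- function(libraries, regions) {
  stopifnot(is.list(libraries), length(libraries) >= 1L,
            !is.null(names(libraries)))
  regions <- as.data.table(regions)
  .assert_disjoint(regions)
  totals <- vapply(libraries, nrow, integer(1))
  if (any(totals == 0L)) {
    stop("library '", names(libraries)[which(totals == 0L)[1L]],
         "' is empty; RPM normalization undefined", call. = FALSE)
  }
  reg_gr <- .as_gr(regions)
  counts <- vapply(libraries, function(fr) {
    .count_overlaps(reg_gr, .as_gr(fr), minoverlap = 1L)
  }, integer(nrow(regions)))
  counts <- matrix(counts, nrow = nrow(regions),
                   dimnames = list(NULL, names(libraries)))
  rpm <- sweep(counts, 2L, totals, function(x, t) x * 1e6 / t)
  structure(list(rpm = rpm, counts = counts, library_totals = totals,
                 regions = regions),
            class = "library_signal_matrix")
}

#' Fraction of fragments in peaks (FRiP)
#'
#' Peaks are merged to a disjoint set first; the result is the fraction of
#' distinct fragments overlapping at least one peak by >= 1 bp.
#'
#' @param fragments Deduplicated fragment `data.table` (non-empty).
#' @param peaks Peak `data.table`.
#' @return A number in `[0, 1]`.
#' @export
compute_frip <- function(fragments, peaks) {
  if (nrow(fragments) == 0L) {
    stop("FRiP undefined for zero fragments", call. = FALSE)
  }
  merged <- merge_intervals(peaks)
  hits <- .overlaps_any(.as_gr(fragments), .as_gr(merged),
                               minoverlap = 1L)
  mean(hits)
}

#' Partition fragments into cluster pseudobulks
#'
#' @param fragments Fragment `data.table`.
#' @param cluster_map Named vector barcode -> cluster label; barcodes absent
#'   from the map are dropped and tallied.
#' @return A list: `clusters` (named list of fragment tables, one per
#'   cluster label including empty clusters) and `unassigned` (dropped
#'   fragment count).
#' @export
aggregate_pseudobulk <- function(fragments, cluster_map) {
  stopifnot(!is.null(names(cluster_map)))
  cl <- cluster_map[fragments$barcode]
  unassigned <- sum(is.na(cl))
  labels <- sort(unique(as.character(cluster_map)), method = "radix")
  clusters <- lapply(labels, function(lab) {
    fragments[!is.na(cl) & cl == lab]
  })
  names(clusters) <- labels
  list(clusters = clusters, unassigned = unassigned)
}

#' Binned coverage track (bedGraph records)
#'
#' Tiles each chromosome with fixed-width bins; the value of a bin is the
#' number of fragments overlapping it (multiplied by `1e6 / n_fragments`
#' under `scale = "rpm"`). Zero bins are dropped and runs of adjacent
#' equal-value bins are merged.
#'
#' @param fragments Fragment `data.table`.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param bin_size Bin width in bp (>= 1).
#' @param scale `"raw"` or `"rpm"`.
#' @return A `data.table` of bedGraph records (`chrom`, `start`, `end`,
#'   `value`), sorted.
#' @export
make_coverage_track <- function(fragments, chrom_sizes, bin_size = 100L,
                                scale = c("raw", "rpm")) {
  scale <- match.arg(scale)
  stopifnot(bin_size >= 1L)
  total <- nrow(fragments)
  out <- vector("list", length(chrom_sizes))
  for (ci in seq_along(chrom_sizes)) {
    chrom <- names(chrom_sizes)[ci]
    len <- as.integer(chrom_sizes[[ci]])
    starts <- seq.int(0L, len - 1L, by = bin_size)
    ends <- pmin(starts + as.integer(bin_size), len)
    fr <- fragments[fragments$chrom == chrom]
    if (nrow(fr) == 0L) next
    bins_gr <- GenomicRanges::GRanges(chrom,
                                      IRanges::IRanges(starts + 1L, ends))
    val <- .count_overlaps(bins_gr, .as_gr(fr), minoverlap = 1L)
    if (scale == "rpm") val <- val * 1e6 / total
    nz <- val != 0
    if (!any(nz)) next
    dt <- data.table(chrom = chrom, start = starts[nz], end = ends[nz],
                     value = val[nz])
    # merge adjacent equal-value bins
    new_run <- c(TRUE, dt$start[-1L] != dt$end[-nrow(dt)] |
                         dt$value[-1L] != dt$value[-nrow(dt)])
    run <- cumsum(new_run)
    dt <- dt[, list(chrom = chrom[1L], start = start[1L], end = end[.N],
                    value = value[1L]), by = run][, run := NULL]
    out[[ci]] <- dt
  }
  res <- rbindlist(out)
  if (nrow(res) == 0L) {
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), value = numeric()))
  }
  res[.bed_order(res)][]
}

#' Write bedGraph records
#'
#' @param track Output of [make_coverage_track()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  data.table::fwrite(as.data.table(track)[, list(chrom, start, end, value)],
                     path, sep = "\t", col.names = FALSE, eol = "\n",
                     quote = FALSE)
  invisible(path)
}
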