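# Shared fixtures: all built in code at test time.

library(data.table)

frag_row <- function(chrom, start, end, barcode, read_support = 1L) {
  data.table(chrom = chrom, start = as.integer(start), end = as.integer(end),
             barcode = barcode, read_support = as.integer(read_support))
}

# a small, scaled-down simulation used by unit tests where the property
# under test does not depend on the full study-sized defaults
small_sim_config <- function(seed = 11L, ...) {
  defaults <- list(n_cells_A = 60L, n_cells_B = 60L,
                   median_frags_per_cell = 300L, n_peaks = 200L,
                   bulk_depth = 20000L, n_genes = 80L,
                   n_diff_promoters = 10L, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# random disjoint peak set on one or more chromosomes
random_peaks <- function(n, chrom = "chr1", chrom_len = 100000L,
                         width_range = c(50L, 400L)) {
  starts <- sort(sample.int(chrom_len - width_range[2L] - 1L, n))
  widths <- sample(seq(width_range[1L], width_range[2L]), n, replace = TRUE)
  ends <- pmin(starts + widths, c(starts[-1L], chrom_len))
  keep <- ends > starts
  data.table(chrom = chrom, start = starts[keep], end = ends[keep])
}

# brute-force >=1 bp overlap of two half-open intervals
intervals_overlap <- function(a_start, a_end, b_start, b_end) {
  max(a_start, b_start) < min(a_end, b_end)
}
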