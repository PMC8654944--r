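# Readers and writers for the plain-text formats the pipeline consumes:
# 10X-style fragment files, BED peak sets, TSS tables and gene-level
# copy-number tables. All genomic coordinates are 0-based half-open
# (BED convention) throughout the package; chromosome order is plain
# lexicographic (C locale), with no karyotype ordering.

.read_text_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con)
}

.parse_int_column <- function(x, lines, colname) {
  out <- suppressWarnings(as.integer(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0L) {
    stop(sprintf("line %d: non-integer %s field '%s'",
                 lines[bad[1L]], colname, x[bad[1L]]), call. = FALSE)
  }
  out
}

#' Read a barcoded fragment file
#'
#' Parses a 10X-style fragment file: tab-separated columns chrom, start, end,
#' barcode, read_support, with 0-based half-open coordinates. Lines starting
#' with `#` are comments. Extra columns beyond the fifth are ignored.
#' Gzip-compressed files (`.gz`) are read transparently.
#'
#' Each row is one deduplicated fragment; `(chrom, start, end, barcode)` is
#' the deduplication key. Duplicate keys are rejected by default because the
#' analysis counts unique fragments per cell; with `dedup = TRUE` duplicates
#' are collapsed and their read supports summed.
#'
#' @param path Path to the fragment file.
#' @param require_sorted Verify (chrom, start, end) lexicographic order and
#'   fail if violated.
#' @param dedup Collapse duplicate `(chrom, start, end, barcode)` rows,
#'   summing `read_support`, instead of treating them as an error.
#' @return A `data.table` with columns `chrom`, `start`, `end`, `barcode`,
#'   `read_support`.
#' @export
read_fragment_file <- function(path, require_sorted = FALSE, dedup = FALSE) {
  raw <- .read_text_lines(path)
  keep <- !startsWith(raw, "#") & nzchar(raw)
  line_no <- which(keep)
  body <- raw[keep]
  if (length(body) == 0L) {
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      barcode = character(), read_support = integer()))
  }
  parts <- data.table::tstrsplit(body, "\t", fixed = TRUE)
  if (length(parts) < 5L) {
    stop(sprintf("line %d: expected >= 5 tab-separated fields", line_no[1L]),
         call. = FALSE)
  }
  short <- which(is.na(parts[[5L]]))
  if (length(short) > 0L) {
    stop(sprintf("line %d: expected >= 5 tab-separated fields",
                 line_no[short[1L]]), call. = FALSE)
  }
  frags <- data.table(
    chrom   = parts[[1L]],
    start   = .parse_int_column(parts[[2L]], line_no, "start"),
    end     = .parse_int_column(parts[[3L]], line_no, "end"),
    barcode = parts[[4L]],
    read_support = .parse_int_column(parts[[5L]], line_no, "read_support")
  )
  bad <- which(frags$start < 0L | frags$end <= frags$start)
  if (length(bad) > 0L) {
    stop(sprintf("line %d: invalid interval [%d, %d)", line_no[bad[1L]],
                 frags$start[bad[1L]], frags$end[bad[1L]]), call. = FALSE)
  }
  bad <- which(!nzchar(frags$chrom) | !nzchar(frags$barcode))
  if (length(bad) > 0L) {
    stop(sprintf("line %d: empty chrom or barcode", line_no[bad[1L]]),
         call. = FALSE)
  }
  bad <- which(frags$read_support < 1L)
  if (length(bad) > 0L) {
    stop(sprintf("line %d: read_support must be >= 1", line_no[bad[1L]]),
         call. = FALSE)
  }
  if (require_sorted) {
    o <- .bed_order(frags)
    if (!identical(o, seq_len(nrow(frags)))) {
      first <- which(o != seq_len(nrow(frags)))[1L]
      stop(sprintf("fragment file not sorted by (chrom, start, end) near line %d",
                   line_no[first]), call. = FALSE)
    }
  }
  dup <- duplicated(frags, by = c("chrom", "start", "end", "barcode"))
  if (any(dup)) {
    if (!dedup) {
      stop(sprintf(
        "line %d: duplicate (chrom, start, end, barcode) key; use dedup = TRUE to collapse",
        line_no[which(dup)[1L]]), call. = FALSE)
    }
    frags <- frags[, list(read_support = sum(read_support)),
                   by = c("chrom", "start", "end", "barcode")]
  }
  frags[]
}

#' Write a barcoded fragment file
#'
#' Emits fragments as tab-separated chrom/start/end/barcode/read_support,
#' sorted by (chrom, start, end, barcode) in C-locale order, newline
#' terminated. Output is byte-deterministic for identical input.
#'
#' @param fragments A fragment `data.table` as returned by
#'   [read_fragment_file()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fragment_file <- function(fragments, path) {
  stopifnot(all(c("chrom", "start", "end", "barcode", "read_support")
                %in% names(fragments)))
  out <- as.data.table(fragments)[
    , list(chrom, start, end, barcode, read_support)]
  out <- out[.bed_order(out, with_barcode = TRUE)]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, eol = "\n",
                     quote = FALSE)
  invisible(path)
}

#' Read a BED3/BED4/BED5 peak file
#'
#' Coordinates are kept 0-based half-open exactly as stored. A fourth column
#' maps to `name` and a fifth to `score`; missing columns become `NA`.
#'
#' @param path Path to a BED file (optionally gzipped).
#' @return A `data.table` with columns `chrom`, `start`, `end`, `name`,
#'   `score`.
#' @export
read_bed <- function(path) {
  raw <- .read_text_lines(path)
  keep <- !startsWith(raw, "#") & !startsWith(raw, "track") & nzchar(raw)
  line_no <- which(keep)
  body <- raw[keep]
  if (length(body) == 0L) {
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric()))
  }
  parts <- data.table::tstrsplit(body, "\t", fixed = TRUE)
  if (length(parts) < 3L || any(is.na(parts[[3L]]))) {
    bad <- if (length(parts) < 3L) 1L else which(is.na(parts[[3L]]))[1L]
    stop(sprintf("line %d: expected >= 3 tab-separated fields", line_no[bad]),
         call. = FALSE)
  }
  peaks <- data.table(
    chrom = parts[[1L]],
    start = .parse_int_column(parts[[2L]], line_no, "start"),
    end   = .parse_int_column(parts[[3L]], line_no, "end"),
    name  = if (length(parts) >= 4L) parts[[4L]] else NA_character_,
    score = if (length(parts) >= 5L) {
      sc <- suppressWarnings(as.numeric(parts[[5L]]))
      bad <- which(is.na(sc) & !is.na(parts[[5L]]) & parts[[5L]] != ".")
      if (length(bad) > 0L) {
        stop(sprintf("line %d: non-numeric score '%s'",
                     line_no[bad[1L]], parts[[5L]][bad[1L]]), call. = FALSE)
      }
      sc
    } else NA_real_
  )
  bad <- which(peaks$start < 0L | peaks$end <= peaks$start)
  if (length(bad) > 0L) {
    stop(sprintf("line %d: invalid interval [%d, %d)", line_no[bad[1L]],
                 peaks$start[bad[1L]], peaks$end[bad[1L]]), call. = FALSE)
  }
  peaks[]
}

#' Write a BED peak file
#'
#' Writes BED3 when neither names nor scores are present, BED4 with names
#' only, and BED5 otherwise (missing names become `.`). Output is sorted by
#' (chrom, start, end) and byte-deterministic.
#'
#' @param peaks A peak `data.table` (`chrom`, `start`, `end`, optional
#'   `name`, `score`).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bed <- function(peaks, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(peaks)))
  out <- as.data.table(peaks)
  if (!"name" %in% names(out)) out[, name := NA_character_]
  if (!"score" %in% names(out)) out[, score := NA_real_]
  out <- out[, list(chrom, start, end, name, score)]
  out <- out[.bed_order(out)]
  has_name <- nrow(out) > 0L && any(!is.na(out$name))
  has_score <- nrow(out) > 0L && any(!is.na(out$score))
  if (has_score) {
    out[is.na(name), name := "."]
    data.table::fwrite(out, path, sep = "\t", col.names = FALSE, eol = "\n",
                       quote = FALSE)
  } else if (has_name) {
    data.table::fwrite(out[, list(chrom, start, end, name)], path, sep = "\t",
                       col.names = FALSE, eol = "\n", quote = FALSE)
  } else {
    data.table::fwrite(out[, list(chrom, start, end)], path, sep = "\t",
                       col.names = FALSE, eol = "\n", quote = FALSE)
  }
  invisible(path)
}

#' Read a TSS annotation table
#'
#' Tab-separated with header columns `gene_id`, `chrom`, `tss`, `strand`;
#' `tss` is a 0-based position and `strand` must be `+` or `-`.
#'
#' @param path Path to the TSV file.
#' @return A `data.table` with one row per gene.
#' @export
read_tss_table <- function(path) {
  tss <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = list(character = c("gene_id", "chrom", "strand"),
                                             integer = "tss"))
  stopifnot(all(c("gene_id", "chrom", "tss", "strand") %in% names(tss)))
  if (any(!tss$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  if (any(tss$tss < 0L)) stop("tss positions must be >= 0", call. = FALSE)
  tss[]
}

#' @rdname read_tss_table
#' @param tss A TSS `data.table`.
#' @export
write_tss_table <- function(tss, path) {
  data.table::fwrite(
    as.data.table(tss)[, list(gene_id, chrom, tss, strand)],
    path, sep = "\t", eol = "\n", quote = FALSE)
  invisible(path)
}

#' Read a gene-level copy-number table
#'
#' Tab-separated with header columns `gene_id` and `cn_value`, where
#' `cn_value` is on the log2(relative to ploidy + 1) scale.
#'
#' @param path Path to the TSV file.
#' @return A `data.table` with columns `gene_id`, `cn_value`.
#' @export
read_copy_number_table <- function(path) {
  cn <- data.table::fread(path, sep = "\t", header = TRUE)
  stopifnot(all(c("gene_id", "cn_value") %in% names(cn)))
  if (any(!is.finite(cn$cn_value))) {
    stop("cn_value must be finite", call. = FALSE)
  }
  cn[, list(gene_id = as.character(gene_id), cn_value = as.numeric(cn_value))]
}

#' @rdname read_copy_number_table
#' @param cn A copy-number `data.table`.
#' @export
write_copy_number_table <- function(cn, path) {
  data.table::fwrite(as.data.table(cn)[, list(gene_id, cn_value)],
                     path, sep = "\t", eol = "\n", quote = FALSE)
  invisible(path)
}
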