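#' Extract UMIs from read sequences
#'
#' Splits each read into its leading UMI (first `umi_len` bases) and the
#' remaining sequence to be aligned. Reads of length `<= umi_len` carry no
#' alignable sequence and are skipped; the number skipped is recorded in
#' the `n_skipped` attribute.
#'
#' @param seqs Character vector of read sequences.
#' @param umi_len UMI length (default 8).
#' @return Tibble with columns `umi` and `seq`, attribute `n_skipped`.
#' @examples
#' extract_umi(c("ACGTACGTTTTTGGG", "ACGTACG"))
#' @export
extract_umi <- function(seqs, umi_len = 8L) {
  umi_len <- as.integer(umi_len)
  stopifnot(umi_len >= 0L)
  keep <- nchar(seqs) > umi_len
  out <- tibble::tibble(
    umi = substr(seqs[keep], 1L, umi_len),
    seq = substr(seqs[keep], umi_len + 1L, nchar(seqs[keep]))
  )
  attr(out, "n_skipped") <- sum(!keep)
  out
}

#' Extract UMIs from a FASTQ file
#'
#' Reads a FASTQ file and applies [extract_umi()] to its sequences.
#'
#' @param path FASTQ file.
#' @inheritParams extract_umi
#' @return As [extract_umi()], with an extra `read_id` column.
#' @export
read_fastq_umis <- function(path, umi_len = 8L) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required to read FASTQ", call. = FALSE)
  }
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- extract_umi(unname(as.character(ss)), umi_len)
  ids <- sub(" .*", "", names(ss))
  out$read_id <- ids[nchar(as.character(ss)) > umi_len]
  out
}

#' Collapse PCR duplicates
#'
#' Reads with identical 5' mapping position and UMI within a gene are PCR
#' copies of one molecule and are collapsed to a single record. The
#' operation is idempotent and never increases the library size.
#'
#' @param reads Read tibble (`gene_id`, `pos`, `umi`).
#' @return Deduplicated read tibble, attribute `deduplicated = TRUE`.
#' @export
dedup_reads <- function(reads) {
  out <- dplyr::distinct(reads, .data$gene_id, .data$pos, .data$umi,
                         .keep_all = TRUE)
  attr(out, "deduplicated") <- TRUE
  out
}

new_coverage <- function(df, scale, library_size, n_dropped = 0L) {
  out <- tibble::as_tibble(df)
  attr(out, "scale") <- scale
  attr(out, "library_size") <- library_size
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("fivep_coverage", class(tibble::tibble()))
  out
}

#' Coverage table metadata
#'
#' Accessors for the scale (`"raw"` or `"rpm"`), the deduplicated library
#' size, and the number of reads dropped (unknown gene or out-of-range
#' position) of a coverage table built by [fivep_counts()].
#'
#' @param cov A coverage tibble.
#' @return A scalar.
#' @export
cov_scale <- function(cov) attr(cov, "scale") %||% "raw"

#' @rdname cov_scale
#' @export
cov_library_size <- function(cov) attr(cov, "library_size")

#' @rdname cov_scale
#' @export
cov_dropped <- function(cov) attr(cov, "n_dropped") %||% 0L

#' Per-transcript 5'P coverage
#'
#' Counts deduplicated 5'P ends per (gene, transcript position). Reads on
#' genes absent from the transcript set, or at positions outside the
#' transcript, are dropped and counted in the `n_dropped` attribute. The
#' library size is the number of retained reads.
#'
#' @param reads Read tibble (`gene_id`, `pos`; a `umi` column is ignored
#'   here). Should be deduplicated first — a warning is raised otherwise.
#' @param transcripts A `fivep_transcripts` tibble.
#' @return Coverage tibble (`gene_id`, `pos`, `count`) with scale `"raw"`.
#' @export
fivep_counts <- function(reads, transcripts) {
  if (!isTRUE(attr(reads, "deduplicated"))) {
    warning("reads do not appear to be deduplicated; run dedup_reads() first")
  }
  n_in <- nrow(reads)
  if (n_in == 0L) {
    return(new_coverage(
      tibble::tibble(gene_id = character(), pos = integer(), count = integer()),
      "raw", 0L
    ))
  }
  geom <- transcripts[, c("gene_id", "tx_length")]
  kept <- reads |>
    dplyr::inner_join(geom, by = "gene_id") |>
    dplyr::filter(.data$pos >= 0L, .data$pos < .data$tx_length)
  cov <- kept |>
    dplyr::count(.data$gene_id, .data$pos, name = "count") |>
    dplyr::arrange(.data$gene_id, .data$pos)
  new_coverage(cov, "raw", nrow(kept), n_in - nrow(kept))
}

#' Scale a coverage table to reads per million
#'
#' Multiplies every count by `1e6 / library_size`, where the library size
#' is the number of deduplicated mapped reads the table was built from.
#'
#' @param cov Raw-scale coverage tibble from [fivep_counts()].
#' @return Coverage tibble with scale `"rpm"`.
#' @export
rpm_normalize <- function(cov) {
  if (cov_scale(cov) != "raw") {
    stop("coverage is already scaled (", cov_scale(cov), ")", call. = FALSE)
  }
  n <- cov_library_size(cov)
  if (is.null(n) || n == 0L) {
    stop("library size is zero; cannot scale to rpm", call. = FALSE)
  }
  out <- dplyr::mutate(cov, count = .data$count * 1e6 / n)
  new_coverage(out, "rpm", n, cov_dropped(cov))
}

#' Write a coverage table as TSV
#'
#' One row per covered position with both anchor offsets:
#' `gene_id, offset_from_start, offset_from_stop, count`.
#'
#' @param cov Coverage tibble.
#' @param transcripts Matching `fivep_transcripts` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_tsv <- function(cov, transcripts, path) {
  out <- cov |>
    dplyr::inner_join(
      transcripts[, c("gene_id", "utr5_len", "cds_len")], by = "gene_id"
    ) |>
    dplyr::transmute(
      .data$gene_id,
      offset_from_start = .data$pos - .data$utr5_len,
      offset_from_stop = .data$pos - (.data$utr5_len + .data$cds_len - 3L),
      count = .data$count
    )
  readr::write_tsv(out, path)
  invisible(path)
}
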