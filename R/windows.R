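#' Window scheme around the start and stop codons
#'
#' Defines the fixed windows over which 5'P reads are counted per gene:
#' three 45-nt windows around the start codon — `uS` upstream of the
#' start, `dS` spanning the initiation-paused ribosome, `ddS` further
#' within the ORF — and two windows around the stop codon (`uE` upstream,
#' including the termination-paused ribosome, `dE` downstream). All
#' intervals are half-open `[lo, hi)` in anchor offsets (offset 0 = first
#' nucleotide of the start or stop codon).
#'
#' The `"default"` preset uses half-open intervals on the published left
#' bounds, giving exactly 45 nt per start window: `uS = [-60, -15)`,
#' `dS = [-14, 31)`, `ddS = [32, 77)`, `uE = [-62, -17)`, `dE = [-17, 46)`.
#' (The single-nucleotide gap at -15 between `uS` and `dS` is a property
#' of the published bounds.) The `"literal"` preset exposes the
#' published inclusive bounds verbatim (`uS` 46 nt, `dE = [-18, 46)`
#' overlapping `uE`), for comparison only.
#'
#' @param preset `"default"` or `"literal"`.
#' @param uS,dS,ddS Start-anchored half-open intervals, `c(lo, hi)`.
#' @param uE,dE Stop-anchored half-open intervals.
#' @param min_reads Per-ratio read filter: a gene's loading ratio `XvsY`
#'   is reported only when `X + Y >= min_reads` (default 20).
#' @return A list of class `fivep_window_scheme`.
#' @export
window_scheme <- function(preset = c("default", "literal"),
                          uS = NULL, dS = NULL, ddS = NULL,
                          uE = NULL, dE = NULL, min_reads = 20L) {
  preset <- match.arg(preset)
  base <- if (preset == "default") {
    list(uS = c(-60L, -15L), dS = c(-14L, 31L), ddS = c(32L, 77L),
         uE = c(-62L, -17L), dE = c(-17L, 46L))
  } else {
    list(uS = c(-60L, -14L), dS = c(-14L, 32L), ddS = c(32L, 78L),
         uE = c(-62L, -16L), dE = c(-18L, 46L))
  }
  sch <- list(
    uS = as.integer(uS %||% base$uS), dS = as.integer(dS %||% base$dS),
    ddS = as.integer(ddS %||% base$ddS),
    uE = as.integer(uE %||% base$uE), dE = as.integer(dE %||% base$dE),
    min_reads = as.integer(min_reads)
  )
  for (w in c("uS", "dS", "ddS", "uE", "dE")) {
    iv <- sch[[w]]
    if (length(iv) != 2L || iv[1] >= iv[2]) {
      stop("window ", w, " must be a half-open interval c(lo, hi) with lo < hi",
           call. = FALSE)
    }
  }
  class(sch) <- "fivep_window_scheme"
  sch
}

window_width <- function(iv) iv[2] - iv[1]

#' Per-gene window read counts
#'
#' Sums raw 5'P coverage over each window of a [window_scheme()] for
#' every gene in the transcript set. Genes whose 5'UTR is shorter than
#' the upstream extent of `uS` cannot host the full upstream window and
#' are flagged (`utr5_ok = FALSE`); they are excluded from uS-based
#' ratios downstream.
#'
#' @param cov Raw-scale coverage tibble.
#' @param transcripts Matching `fivep_transcripts` tibble.
#' @param scheme A [window_scheme()].
#' @return Tibble: `gene_id`, `uS`, `dS`, `ddS`, `uE`, `dE`, `total`,
#'   `utr5_ok`.
#' @export
window_counts <- function(cov, transcripts, scheme = window_scheme()) {
  if (cov_scale(cov) != "raw") {
    stop("window counts require raw-scale coverage", call. = FALSE)
  }
  dat <- dplyr::inner_join(
    cov, transcripts[, c("gene_id", "utr5_len", "cds_len")], by = "gene_id"
  ) |>
    dplyr::mutate(
      so = .data$pos - .data$utr5_len,
      eo = .data$pos - (.data$utr5_len + .data$cds_len - 3L)
    )
  in_iv <- function(x, iv) x >= iv[1] & x < iv[2]
  sums <- dat |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      uS = sum(.data$count[in_iv(.data$so, scheme$uS)]),
      dS = sum(.data$count[in_iv(.data$so, scheme$dS)]),
      ddS = sum(.data$count[in_iv(.data$so, scheme$ddS)]),
      uE = sum(.data$count[in_iv(.data$eo, scheme$uE)]),
      dE = sum(.data$count[in_iv(.data$eo, scheme$dE)]),
      .groups = "drop"
    )
  out <- transcripts[, c("gene_id", "utr5_len")] |>
    dplyr::left_join(sums, by = "gene_id") |>
    dplyr::mutate(
      dplyr::across(c("uS", "dS", "ddS", "uE", "dE"),
                    ~ dplyr::coalesce(.x, 0L)),
      total = .data$uS + .data$dS + .data$ddS + .data$uE + .data$dE,
      utr5_ok = .data$utr5_len >= -scheme$uS[1]
    ) |>
    dplyr::select(-"utr5_len")
  attr(out, "scheme") <- scheme
  out
}

log2_ratio <- function(x, y) {
  c0 <- ifelse(x == 0 | y == 0, 0.5, 0)   # pseudocount only at zeros
  log2((x + c0) / (y + c0))
}

#' Per-gene loading ratios
#'
#' Computes the log2 loading ratios `uSvsdS`, `uSvsddS` (5' region) and
#' `uEvsdE` (3' region) from window counts. A positive ratio means more
#' ribosome footprints towards the 5' side of the compared pair
#' (ribosomes accumulating upstream). A ratio `XvsY` is reported only for
#' genes with `X + Y >= min_reads` (and, for uS-based ratios, a 5'UTR
#' long enough to host `uS`); filtered genes carry `NA` with their
#' `*_pass` flag `FALSE`. When one count is zero a pseudocount of 0.5 is
#' added to both.
#'
#' @param wct Window count table from [window_counts()].
#' @param scheme The [window_scheme()] (defaults to the one recorded in
#'   `wct`).
#' @return Tibble: `gene_id`, `uSvsdS`, `uSvsddS`, `uEvsdE` and the
#'   matching `*_pass` flags.
#' @export
loading_ratios <- function(wct, scheme = NULL) {
  scheme <- scheme %||% attr(wct, "scheme") %||% window_scheme()
  m <- scheme$min_reads
  ratio_if <- function(x, y, pass) ifelse(pass, log2_ratio(x, y), NA_real_)
  out <- wct |>
    dplyr::mutate(
      uSvsdS_pass = .data$utr5_ok & (.data$uS + .data$dS >= m),
      uSvsddS_pass = .data$utr5_ok & (.data$uS + .data$ddS >= m),
      uEvsdE_pass = .data$uE + .data$dE >= m,
      uSvsdS = ratio_if(.data$uS, .data$dS, .data$uSvsdS_pass),
      uSvsddS = ratio_if(.data$uS, .data$ddS, .data$uSvsddS_pass),
      uEvsdE = ratio_if(.data$uE, .data$dE, .data$uEvsdE_pass)
    ) |>
    dplyr::select("gene_id", "uSvsdS", "uSvsddS", "uEvsdE",
                  dplyr::ends_with("_pass"))
  attr(out, "scheme") <- scheme
  out
}
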