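#' Anchor-aligned metagene 5'P profile
#'
#' Aggregates 5'P coverage across genes after aligning every transcript
#' on a common anchor: offset 0 is the first nucleotide of the start
#' codon (`anchor = "start"`) or of the stop codon (`anchor = "stop"`).
#' The profile value at offset `o` is the sum over genes of the coverage
#' at that offset (pooled signal); with `per_gene = TRUE` each gene's
#' coverage is first divided by that gene's total, giving an
#' equal-weight-per-gene variant for sensitivity analysis. Genes too
#' short to reach a given offset simply contribute nothing there.
#'
#' In a co-translational-decay library the start-anchored profile peaks
#' at offset -14 (5'P ends of molecules whose last protecting ribosome is
#' paused with its P-site on the start codon) and the stop-anchored
#' profile at -17 (termination pause).
#'
#' @param cov Coverage tibble ([fivep_counts()], usually rpm-scaled via
#'   [rpm_normalize()]).
#' @param transcripts Matching `fivep_transcripts` tibble.
#' @param anchor `"start"` or `"stop"`.
#' @param window Length-2 integer vector, inclusive offset range.
#' @param per_gene Normalize each gene to its total before summing.
#' @return Tibble (`anchor`, `offset`, `value`) covering every offset in
#'   `window`, classed `fivep_metagene`, with attributes `n_genes` and
#'   `scale`.
#' @export
metagene_profile <- function(cov, transcripts, anchor = c("start", "stop"),
                             window = c(-100L, 100L), per_gene = FALSE) {
  anchor <- match.arg(anchor)
  stopifnot(length(window) == 2L, window[1] <= window[2])
  offs <- tibble::tibble(offset = seq.int(window[1], window[2]))

  dat <- dplyr::inner_join(
    cov, transcripts[, c("gene_id", "utr5_len", "cds_len")], by = "gene_id"
  )
  dat$offset <- if (anchor == "start") {
    dat$pos - dat$utr5_len
  } else {
    dat$pos - (dat$utr5_len + dat$cds_len - 3L)
  }
  if (per_gene && nrow(dat) > 0L) {
    dat <- dat |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::mutate(count = .data$count / sum(.data$count)) |>
      dplyr::ungroup()
  }
  prof <- dat |>
    dplyr::filter(.data$offset >= window[1], .data$offset <= window[2]) |>
    dplyr::group_by(.data$offset) |>
    dplyr::summarise(value = sum(.data$count), .groups = "drop")
  out <- offs |>
    dplyr::left_join(prof, by = "offset") |>
    dplyr::mutate(anchor = anchor,
                  value = dplyr::coalesce(.data$value, 0)) |>
    dplyr::select("anchor", "offset", "value")
  attr(out, "n_genes") <- dplyr::n_distinct(cov$gene_id)
  attr(out, "scale") <- cov_scale(cov)
  class(out) <- c("fivep_metagene", class(out))
  out
}

#' Peak offset of a metagene profile
#'
#' Argmax offset of the profile within a search range (ties resolved to
#' the most upstream offset).
#'
#' @param profile A `fivep_metagene` tibble.
#' @param search Inclusive offset range to search, e.g. `c(-60, -1)`.
#' @return Integer offset of the maximum.
#' @export
metagene_peak <- function(profile, search = c(-60L, -1L)) {
  p <- profile[profile$offset >= search[1] & profile$offset <= search[2], ]
  if (nrow(p) == 0L) stop("search range outside profile window", call. = FALSE)
  p$offset[which.max(p$value)]
}

#' Reading-frame histogram of 5'P ends
#'
#' Counts 5'P ends in each reading frame relative to the start codon,
#' either in the 5'UTR (start offsets `[-width, -1]`) or in the coding
#' region (start offsets `[0, width - 1]`). Frame is
#' `offset mod 3` (always in 0..2), one consistent rule for both regions.
#' Elongating ribosomes leave 5'P ends with 3-nt periodicity, so a
#' translated region concentrates reads in a single frame while the
#' 5'UTR does not.
#'
#' @param cov Coverage tibble (raw counts).
#' @param transcripts Matching `fivep_transcripts` tibble.
#' @param region `"utr5"` or `"cds"`.
#' @param width Window width in nt (default 80).
#' @return Tibble (`region`, `frame`, `count`) with frames 0, 1, 2.
#' @export
frame_histogram <- function(cov, transcripts, region = c("utr5", "cds"),
                            width = 80L) {
  region <- match.arg(region)
  rng <- if (region == "utr5") c(-width, -1L) else c(0L, width - 1L)
  dat <- dplyr::inner_join(
    cov, transcripts[, c("gene_id", "utr5_len")], by = "gene_id"
  ) |>
    dplyr::mutate(offset = .data$pos - .data$utr5_len) |>
    dplyr::filter(.data$offset >= rng[1], .data$offset <= rng[2]) |>
    dplyr::mutate(frame = .data$offset %% 3L) |>
    dplyr::count(.data$frame, wt = .data$count, name = "count")
  tibble::tibble(frame = 0:2) |>
    dplyr::left_join(dat, by = "frame") |>
    dplyr::mutate(region = region,
                  count = dplyr::coalesce(.data$count, 0)) |>
    dplyr::select("region", "frame", "count")
}

#' Plot a metagene profile
#'
#' @param object A `fivep_metagene` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fivep_metagene <- function(object, ...) {
  ylab <- if (identical(attr(object, "scale"), "rpm")) {
    "5'P intermediates (rpm)"
  } else "5'P intermediates (reads)"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset, y = .data$value)) +
    ggplot2::geom_col(width = 1, fill = "grey30") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "red") +
    ggplot2::labs(
      x = sprintf("offset from %s codon (nt)", object$anchor[1]),
      y = ylab
    ) +
    ggplot2::theme_classic()
}
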