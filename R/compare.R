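#' Pool window counts across replicate libraries
#'
#' Sums per-gene window counts over replicate libraries before ratios are
#' taken (the default replicate handling; apply [loading_ratios()] to
#' each table instead for a per-replicate analysis).
#'
#' @param ... Window count tables from [window_counts()] built on the
#'   same transcript set and scheme.
#' @return A pooled window count table.
#' @export
pool_window_counts <- function(...) {
  tabs <- list(...)
  stopifnot(length(tabs) >= 1L)
  out <- dplyr::bind_rows(tabs) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      dplyr::across(c("uS", "dS", "ddS", "uE", "dE", "total"), sum),
      utr5_ok = all(.data$utr5_ok),
      .groups = "drop"
    )
  attr(out, "scheme") <- attr(tabs[[1]], "scheme")
  out
}

#' Per-gene genotype score
#'
#' The mutant-vs-wild-type 5'UTR ribosome accumulation score: the
#' difference of log2 loading ratios, `score = ratio(mut) - ratio(wt)`,
#' which equals the log2 fold change of the raw window ratios. Only genes
#' passing the read filter in *both* strains are scored.
#'
#' @param lt_mut,lt_wt Loading tables from [loading_ratios()] computed
#'   under the same window scheme.
#' @param ratio_name One of `"uSvsdS"`, `"uSvsddS"`, `"uEvsdE"`.
#' @return Tibble (`gene_id`, `mut`, `wt`, `score`), classed
#'   `fivep_scores`.
#' @export
genotype_score <- function(lt_mut, lt_wt, ratio_name = "uSvsdS") {
  stopifnot(ratio_name %in% c("uSvsdS", "uSvsddS", "uEvsdE"))
  pass <- paste0(ratio_name, "_pass")
  m <- lt_mut[lt_mut[[pass]], c("gene_id", ratio_name)]
  w <- lt_wt[lt_wt[[pass]], c("gene_id", ratio_name)]
  names(m)[2] <- "mut"
  names(w)[2] <- "wt"
  out <- dplyr::inner_join(m, w, by = "gene_id") |>
    dplyr::mutate(score = .data$mut - .data$wt)
  if (nrow(out) == 0L) {
    stop("no genes pass the filter in both strains", call. = FALSE)
  }
  attr(out, "ratio_name") <- ratio_name
  class(out) <- c("fivep_scores", class(out))
  out
}

#' Cumulative distribution summary
#'
#' Right-continuous ECDF and median of a set of values (typically
#' per-gene loading ratios or genotype scores). The median follows the
#' sample-median convention: the middle order statistic for odd n, the
#' midpoint of the two middle order statistics for even n
#' (`stats::median()`).
#'
#' @param values Non-empty numeric vector (NAs dropped).
#' @return List of class `fivep_ecdf`: `ecdf` (a `stats::ecdf` function),
#'   `support` (sorted values), `median`, `n`.
#' @export
cumulative_summary <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no values to summarise", call. = FALSE)
  structure(
    list(ecdf = stats::ecdf(values), support = sort(values),
         median = stats::median(values), n = length(values)),
    class = "fivep_ecdf"
  )
}

#' @export
print.fivep_ecdf <- function(x, ...) {
  cat(sprintf("ECDF of %d values; median %.4f; range [%.4f, %.4f]\n",
              x$n, x$median, min(x$support), max(x$support)))
  invisible(x)
}

#' Median increment between two loading distributions
#'
#' Difference of the cumulative-distribution medians of a loading ratio
#' between two strains, over the genes passing the filter in both:
#' `median(ratio mut) - median(ratio wt)`. This is the distribution-level
#' shift; it equals the median per-gene score only for symmetric paired
#' differences and is reported separately.
#'
#' @inheritParams genotype_score
#' @return Numeric scalar.
#' @export
median_increment <- function(lt_mut, lt_wt, ratio_name = "uSvsdS") {
  sc <- genotype_score(lt_mut, lt_wt, ratio_name)
  stats::median(sc$mut) - stats::median(sc$wt)
}

#' Mann-Whitney shift test of a gene subset
#'
#' Tests whether per-gene scores in a subset (e.g. osmotic-stress-induced
#' transcripts) are shifted relative to the remaining genes, with the
#' Mann-Whitney U (Wilcoxon rank-sum) test. The exact null distribution
#' is used when the smaller group has at most `exact_max` observations
#' and there are no ties; otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param scores A `fivep_scores` table from [genotype_score()], or any
#'   tibble with `gene_id` and `score`.
#' @param subset Character vector of gene ids defining the subset.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (subset vs rest).
#' @param exact_max Largest min-group size for which the exact
#'   distribution is used (default 8).
#' @return List of class `fivep_mwu`: `U`, `n1`, `n2`, `p_value`,
#'   `method`, `alternative`.
#' @export
subset_shift_test <- function(scores, subset,
                              alternative = c("two.sided", "greater", "less"),
                              exact_max = 8L) {
  alternative <- match.arg(alternative)
  in_set <- scores$gene_id %in% subset
  x <- scores$score[in_set]
  y <- scores$score[!in_set]
  if (length(x) == 0L || length(y) == 0L) {
    stop("subset and complement must both be non-empty within the score table",
         call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && min(length(x), length(y)) <= exact_max
  if (length(unique(c(x, y))) == 1L) {
    # fully tied data: no evidence of a shift in either direction
    return(structure(
      list(U = length(x) * length(y) / 2, n1 = length(x), n2 = length(y),
           p_value = 1, method = "normal-approx", alternative = alternative),
      class = "fivep_mwu"
    ))
  }
  ht <- stats::wilcox.test(x, y, alternative = alternative,
                           exact = exact, correct = TRUE)
  structure(
    list(U = unname(ht$statistic), n1 = length(x), n2 = length(y),
         p_value = ht$p.value,
         method = if (exact) "exact" else "normal-approx",
         alternative = alternative),
    class = "fivep_mwu"
  )
}

#' @export
print.fivep_mwu <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), %s, p = %.4g [%s]\n",
              x$U, x$n1, x$n2, x$alternative, x$p_value, x$method))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.fivep_mwu <- function(x, ...) {
  tibble::tibble(statistic = x$U, p.value = x$p_value, n1 = x$n1, n2 = x$n2,
                 method = x$method, alternative = x$alternative)
}

#' Rank genes for external GO enrichment
#'
#' Orders genes by descending score (ties broken by gene id) and
#' optionally writes a two-column TSV consumable by generic GO
#' enrichment tools.
#'
#' @param scores A `fivep_scores` table.
#' @param path Optional output TSV path.
#' @return Tibble (`gene_id`, `score`) in rank order.
#' @export
rank_for_go <- function(scores, path = NULL) {
  out <- scores |>
    dplyr::arrange(dplyr::desc(.data$score), .data$gene_id) |>
    dplyr::select("gene_id", "score")
  if (!is.null(path)) readr::write_tsv(out, path)
  out
}

#' Plot cumulative score distributions
#'
#' ECDF curves for one or more named score vectors, the visual used to
#' compare mutant and wild-type loading-ratio distributions.
#'
#' @param ... Named numeric vectors.
#' @return A ggplot object.
#' @export
plot_ecdf <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1L, !is.null(names(sets)))
  df <- purrr::imap(sets, function(v, nm) {
    tibble::tibble(set = nm, value = v[!is.na(v)])
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, colour = .data$set)) +
    ggplot2::stat_ecdf(linewidth = 0.7) +
    ggplot2::labs(x = "log2 loading ratio", y = "cumulative fraction",
                  colour = NULL) +
    ggplot2::theme_classic()
}
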