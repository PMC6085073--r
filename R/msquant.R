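#' Label-free protein quantification from peptide tables
#'
#' `top3_quant()` estimates per-sample protein abundance as the mean
#' chromatographic intensity of the protein's three most intense
#' confident peptides (fewer than three available: the mean of those
#' present, flagged in `n_used`), log2-transformed. `count_mw_quant()`
#' uses the number of confident peptides divided by the protein's
#' molecular weight (an emPAI-like estimate), log2-transformed. Proteins
#' with no confident peptide in a sample are absent from that sample
#' (not zero).
#'
#' @param tbl Peptide tibble with columns `protein_id`, `strain`,
#'   `replicate`, `gel_set`, `intensity`, `confident`, `mw` (kDa).
#' @param top_n Number of top peptides (default 3).
#' @param aggregate `"mean"` (default) or `"sum"` of the top intensities.
#' @return Abundance tibble: `protein_id`, `strain`, `replicate`,
#'   `gel_set`, `method`, `abundance` (log2), `n_used`; attribute
#'   `normalized = FALSE`.
#' @export
top3_quant <- function(tbl, top_n = 3L, aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "mean") mean else sum
  out <- tbl |>
    dplyr::filter(.data$confident, .data$intensity > 0) |>
    dplyr::group_by(.data$protein_id, .data$strain, .data$replicate,
                    .data$gel_set) |>
    dplyr::summarise(
      abundance = log2(agg(sort(.data$intensity, decreasing = TRUE)[
        seq_len(min(top_n, dplyr::n()))])),
      n_used = min(top_n, dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::mutate(method = "top3", .before = "abundance")
  attr(out, "normalized") <- FALSE
  out
}

#' @rdname top3_quant
#' @export
count_mw_quant <- function(tbl) {
  out <- tbl |>
    dplyr::filter(.data$confident) |>
    dplyr::group_by(.data$protein_id, .data$strain, .data$replicate,
                    .data$gel_set) |>
    dplyr::summarise(
      abundance = log2(dplyr::n() / .data$mw[1]),
      n_used = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(method = "count_mw", .before = "abundance")
  attr(out, "normalized") <- FALSE
  out
}

#' Median-normalize abundance sets
#'
#' Within each quantitative set — one (strain, replicate, gel_set,
#' method) combination — subtracts the set's median log2 abundance, so
#' every normalized set has median exactly 0. Absorbs global per-sample
#' intensity scaling.
#'
#' @param aset Abundance tibble from [top3_quant()] or [count_mw_quant()].
#' @return The normalized abundance tibble (`normalized = TRUE`).
#' @export
median_normalize <- function(aset) {
  if (isTRUE(attr(aset, "normalized"))) {
    stop("abundance set is already normalized", call. = FALSE)
  }
  if (nrow(aset) == 0L) stop("empty abundance set", call. = FALSE)
  out <- aset |>
    dplyr::group_by(.data$strain, .data$replicate, .data$gel_set,
                    .data$method) |>
    dplyr::mutate(abundance = .data$abundance - stats::median(.data$abundance)) |>
    dplyr::ungroup()
  attr(out, "normalized") <- TRUE
  out
}

#' Combine the two peptide-count gel sets
#'
#' The count-based quantitative sets from the bait band and the remainder
#' of the gel lane are combined into one set per sample: the mean of the
#' normalized values present (one or two per protein). Intensity-based
#' (top3) sets are treated individually and must not be combined.
#'
#' @param bait,remainder Normalized `count_mw` abundance tibbles (either
#'   argument may already contain both gel sets; rows are pooled).
#' @return Combined abundance tibble with `gel_set = "combined"`.
#' @export
combine_count_sets <- function(bait, remainder) {
  both <- dplyr::bind_rows(bait, remainder)
  if (!all(both$method == "count_mw")) {
    stop("only count_mw sets can be combined", call. = FALSE)
  }
  if (!isTRUE(attr(bait, "normalized")) || !isTRUE(attr(remainder, "normalized"))) {
    stop("normalize both sets before combining", call. = FALSE)
  }
  out <- both |>
    dplyr::group_by(.data$protein_id, .data$strain, .data$replicate,
                    .data$method) |>
    dplyr::summarise(abundance = mean(.data$abundance),
                     n_used = sum(.data$n_used), .groups = "drop") |>
    dplyr::mutate(gel_set = "combined", .after = "replicate")
  attr(out, "normalized") <- TRUE
  out
}

# Student's t on two numeric vectors, tolerating degenerate (constant)
# input the way the funnel needs: identical constant groups -> t 0, p 1;
# constant groups with different means -> p 0.
safe_t_test <- function(x, y, var_equal = TRUE) {
  if (stats::sd(c(x, y)) == 0) {
    return(list(t = 0, p = 1))
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0))
  }
  ht <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Enrichment test against the untagged strain
#'
#' For each protein and quantification unit (method x gel set), compares
#' normalized log2 abundances in a tagged strain against the untagged
#' control with a two-sample Student's t-test (equal variances by
#' default; `var_equal = FALSE` for Welch). Only proteins with values in
#' at least `min_reps` replicates of the tagged strain are tested; no
#' multiple-testing correction is applied (candidates are meant to be
#' validated independently). Proteins present in the tagged strain but
#' missing (or below `min_reps`) in the untagged control are tested
#' against a detection floor imputed at the `impute_quantile` quantile of
#' all untagged abundances in the unit, and flagged `imputed`.
#'
#' @param aset Normalized abundance tibble (possibly several methods/gel
#'   sets; each is tested separately).
#' @param tagged_strain,untagged_strain Strain labels.
#' @param min_reps Minimum tagged-strain replicates (default 2).
#' @param var_equal Equal-variance Student's t (default) or Welch.
#' @param impute_quantile Quantile of the untagged distribution used as
#'   the missing-value floor (default 0.05).
#' @return Tibble: `protein_id`, `strain`, `method`, `gel_set`, `n_tag`,
#'   `n_untag`, `mean_ratio` (mean log2 tagged - untagged), `t`,
#'   `p_value`, `imputed`.
#' @export
enrichment_test <- function(aset, tagged_strain, untagged_strain,
                            min_reps = 2L, var_equal = TRUE,
                            impute_quantile = 0.05) {
  if (!isTRUE(attr(aset, "normalized"))) {
    warning("abundance set is not median-normalized")
  }
  units <- dplyr::distinct(aset, .data$method, .data$gel_set)
  res <- purrr::pmap(units, function(method, gel_set) {
    u <- aset[aset$method == method & aset$gel_set == gel_set, ]
    untag_all <- u$abundance[u$strain == untagged_strain]
    floor_val <- if (length(untag_all)) {
      stats::quantile(untag_all, impute_quantile, names = FALSE)
    } else NA_real_
    tag <- u[u$strain == tagged_strain, ]
    prots <- tag |>
      dplyr::count(.data$protein_id, name = "n_tag") |>
      dplyr::filter(.data$n_tag >= min_reps)
    purrr::map(prots$protein_id, function(p) {
      x <- tag$abundance[tag$protein_id == p]
      y <- u$abundance[u$strain == untagged_strain & u$protein_id == p]
      n_untag <- length(y)
      imputed <- n_untag < min_reps
      if (imputed) {
        if (is.na(floor_val)) {
          stop("no untagged values available for imputation", call. = FALSE)
        }
        y <- c(y, rep(floor_val, max(length(x), min_reps) - n_untag))
      }
      tt <- safe_t_test(x, y, var_equal)
      tibble::tibble(
        protein_id = p, strain = tagged_strain,
        method = method, gel_set = gel_set,
        n_tag = length(x), n_untag = n_untag,
        mean_ratio = mean(x) - mean(y),
        t = tt$t, p_value = tt$p, imputed = imputed
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  res
}

#' Preferential-enrichment funnel filter
#'
#' Applies the final selection criteria of the pull-down funnel to the
#' [enrichment_test()] results of several tagged strains:
#'
#' * `reproducibly_enriched` (per strain): mean log2 ratio vs untagged
#'   `> enrich_lfc` (default 1, i.e. 2-fold) with `p < p_cutoff`;
#' * `preferential`: significant (`p < p_cutoff`) in *both* bait strains,
#'   log2 ratio `> pref_lfc` (default 1.5, i.e. 3-fold) vs the untagged
#'   strain in both bait strains, and log2 ratio `> pref_lfc` of each
#'   bait strain over each control strain.
#'
#' A protein qualifies in a quantification unit (method x gel set); units
#' are aggregated with `method_mode = "either"` (any unit; default) or
#' `"both"` (at least one intensity-based and the count-based unit).
#'
#' @param enr Row-bound [enrichment_test()] results for all tagged
#'   strains against the same untagged control.
#' @param aset The normalized abundance tibble the tests were computed
#'   from (used for bait-vs-control strain ratios).
#' @param bait_strains Two strains carrying the mRNAs of interest.
#' @param control_strains Control-mRNA strains.
#' @param p_cutoff,enrich_lfc,pref_lfc Thresholds (see above).
#' @param method_mode `"either"` or `"both"`.
#' @param impute_quantile Floor quantile for strains where a protein is
#'   absent (as in [enrichment_test()]).
#' @return Tibble: `protein_id`, `preferential` plus per-unit detail in
#'   `units` (list-column of qualifying unit names).
#' @export
preferential_filter <- function(enr, aset,
                                bait_strains = c("GPD1", "STL1"),
                                control_strains = c("ASH1", "HYP2"),
                                p_cutoff = 0.05, enrich_lfc = 1,
                                pref_lfc = 1.5,
                                method_mode = c("either", "both"),
                                impute_quantile = 0.05) {
  method_mode <- match.arg(method_mode)
  missing_strains <- setdiff(bait_strains, enr$strain)
  if (length(missing_strains)) {
    stop("no enrichment results for strain(s): ",
         paste(missing_strains, collapse = ", "), call. = FALSE)
  }

  # mean normalized abundance per protein/strain/unit, floored when absent
  unit_means <- aset |>
    dplyr::group_by(.data$method, .data$gel_set, .data$strain) |>
    dplyr::mutate(.floor = stats::quantile(.data$abundance, impute_quantile)) |>
    dplyr::group_by(.data$protein_id, .data$method, .data$gel_set,
                    .data$strain) |>
    dplyr::summarise(mean_ab = mean(.data$abundance),
                     .floor = .data$.floor[1], .groups = "drop")
  floor_of <- unit_means |>
    dplyr::distinct(.data$method, .data$gel_set, .data$strain, .data$.floor)

  mean_ab <- function(p, strain, method, gel_set) {
    hit <- unit_means$mean_ab[
      unit_means$protein_id == p & unit_means$strain == strain &
        unit_means$method == method & unit_means$gel_set == gel_set]
    if (length(hit)) return(hit)
    floor_of$.floor[
      floor_of$strain == strain & floor_of$method == method &
        floor_of$gel_set == gel_set][1]
  }

  units <- dplyr::distinct(enr, .data$method, .data$gel_set)
  cand <- enr |>
    dplyr::filter(.data$strain %in% bait_strains) |>
    dplyr::group_by(.data$protein_id, .data$method, .data$gel_set) |>
    dplyr::summarise(
      both_sig = sum(.data$p_value < p_cutoff &
                       .data$strain %in% bait_strains) == length(bait_strains),
      both_lfc = sum(.data$mean_ratio > pref_lfc &
                       .data$strain %in% bait_strains) == length(bait_strains),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$both_sig, .data$both_lfc)

  pass_unit <- purrr::pmap_lgl(cand, function(protein_id, method, gel_set, ...) {
    all(purrr::map_lgl(bait_strains, function(b) {
      mb <- mean_ab(protein_id, b, method, gel_set)
      all(purrr::map_lgl(control_strains, function(ctl) {
        mb - mean_ab(protein_id, ctl, method, gel_set) > pref_lfc
      }))
    }))
  })
  cand <- cand[pass_unit, , drop = FALSE]

  per_prot <- cand |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      units = list(paste(.data$method, .data$gel_set, sep = "/")),
      .groups = "drop"
    )
  if (method_mode == "both") {
    keep <- purrr::map_lgl(per_prot$units, function(u) {
      any(grepl("^top3/", u)) && any(grepl("^count_mw/", u))
    })
    per_prot <- per_prot[keep, , drop = FALSE]
  }
  dplyr::mutate(per_prot, preferential = TRUE)
}

#' Run the full MS enrichment funnel
#'
#' Convenience pipeline from a raw peptide table to the preferential
#' protein list: top-3 and count/MW quantification per gel set, median
#' normalization, combination of the count sets, enrichment tests of
#' every tagged strain against the untagged control, and the
#' preferential filter.
#'
#' @inheritParams top3_quant
#' @inheritParams preferential_filter
#' @param untagged_strain Untagged control strain label.
#' @param min_reps Replicate rule for [enrichment_test()].
#' @param ... Passed to [preferential_filter()].
#' @return List: `abundance` (normalized combined abundance tibble),
#'   `enrichment` (all strains), `preferential` (final protein list).
#' @export
ms_funnel <- function(tbl, bait_strains = c("GPD1", "STL1"),
                      control_strains = c("ASH1", "HYP2"),
                      untagged_strain = "untagged", min_reps = 2L, ...) {
  t3 <- median_normalize(top3_quant(tbl))
  cm <- median_normalize(count_mw_quant(tbl))
  cm_b <- cm[cm$gel_set == "bait", ]
  cm_r <- cm[cm$gel_set == "remainder", ]
  attr(cm_b, "normalized") <- TRUE
  attr(cm_r, "normalized") <- TRUE
  combined <- combine_count_sets(cm_b, cm_r)
  aset <- dplyr::bind_rows(t3, combined)
  attr(aset, "normalized") <- TRUE
  tagged <- setdiff(unique(tbl$strain), untagged_strain)
  enr <- purrr::map(tagged, function(s) {
    enrichment_test(aset, s, untagged_strain, min_reps = min_reps)
  }) |> dplyr::bind_rows()
  pref <- preferential_filter(enr, aset, bait_strains = bait_strains,
                              control_strains = control_strains, ...)
  list(abundance = aset, enrichment = enr, preferential = pref)
}
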