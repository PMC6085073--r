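#' Pull-down qPCR enrichment ratio
#'
#' Fold enrichment of an aptamer-tagged mRNA in the pull-down relative to
#' the untagged control:
#' `(PD_tagged / Input_tagged) / (PD_untagged / Input_untagged)`.
#' Vectorized; usable inside `dplyr::mutate()`.
#'
#' @param pd_tagged,input_tagged,pd_untagged,input_untagged Relative
#'   quantities (> 0).
#' @return Numeric ratio(s).
#' @examples
#' pulldown_enrichment(4, 1, 1, 2)   # 8
#' @export
pulldown_enrichment <- function(pd_tagged, input_tagged,
                                pd_untagged, input_untagged) {
  check_positive(pd_tagged, input_tagged, pd_untagged, input_untagged)
  (pd_tagged / input_tagged) / (pd_untagged / input_untagged)
}

#' Pull-down ratio between two mRNAs
#'
#' Relative recovery of one mRNA over another in the same pull-down:
#' `(PD1 / Input1) / (PD2 / Input2)`.
#'
#' @param pd1,in1,pd2,in2 Relative quantities (> 0).
#' @return Numeric ratio(s).
#' @export
mrna_pair_ratio <- function(pd1, in1, pd2, in2) {
  check_positive(pd1, in1, pd2, in2)
  (pd1 / in1) / (pd2 / in2)
}

check_positive <- function(...) {
  vals <- c(...)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all quantities must be positive and finite", call. = FALSE)
  }
  invisible(TRUE)
}

#' Relative expression from qPCR Ct values
#'
#' Efficiency-corrected ddCt fold change:
#' `E^-((ct_target - ct_ref) - (ct_target0 - ct_ref0))`, where the `0`
#' pair is the calibrator condition and `E` the amplification efficiency
#' from a standard curve (2 = perfect doubling).
#'
#' @param ct_target,ct_ref Ct values in the condition of interest.
#' @param ct_target0,ct_ref0 Ct values in the calibrator condition.
#' @param E Amplification efficiency, in (1, 2.2].
#' @return Fold change(s).
#' @export
relative_expression <- function(ct_target, ct_ref, ct_target0, ct_ref0,
                                E = 2.0) {
  if (any(E <= 1 | E > 2.2)) {
    stop("E must be in (1, 2.2]", call. = FALSE)
  }
  ddct <- (ct_target - ct_ref) - (ct_target0 - ct_ref0)
  E^(-ddct)
}

#' mRNA half-life after transcription shut-off
#'
#' Fits first-order decay by least squares on `ln(abundance) ~ time` and
#' reports `t1/2 = ln(2) / (-slope)` with a standard error propagated
#' from the slope SE (`SE(t1/2) = ln(2) * SE(slope) / slope^2`). A
#' non-negative slope (no measurable decay) yields an infinite half-life,
#' flagged `stable`.
#'
#' @param course Data frame with columns `time` (minutes, increasing from
#'   0) and `abundance` (normalized, > 0), at least 3 points.
#' @return Object of class `fivep_halflife`: `half_life`, `se`, `slope`,
#'   `stable`, `fit` (the `lm`).
#' @examples
#' hl <- half_life(data.frame(time = c(0, 10, 20), abundance = c(1, .5, .25)))
#' hl$half_life   # 10
#' @export
half_life <- function(course) {
  stopifnot(all(c("time", "abundance") %in% names(course)))
  if (nrow(course) < 3L) stop("need at least 3 time points", call. = FALSE)
  if (any(course$abundance <= 0)) {
    stop("abundances must be positive for log-linear decay fitting",
         call. = FALSE)
  }
  fit <- stats::lm(log(abundance) ~ time, data = course)
  slope <- unname(stats::coef(fit)["time"])
  # suppress the "essentially perfect fit" note on exact input
  se_slope <- suppressWarnings(summary(fit)$coefficients["time", "Std. Error"])
  stable <- slope >= 0
  hl <- if (stable) Inf else log(2) / (-slope)
  se <- if (stable) NA_real_ else log(2) * se_slope / slope^2
  structure(
    list(half_life = hl, se = se, slope = slope, stable = stable, fit = fit),
    class = "fivep_halflife"
  )
}

#' @export
print.fivep_halflife <- function(x, ...) {
  if (x$stable) {
    cat("half-life: stable (non-decaying fit)\n")
  } else {
    cat(sprintf("half-life: %.2f min (SE %.2f)\n", x$half_life, x$se))
  }
  invisible(x)
}

#' @export
tidy.fivep_halflife <- function(x, ...) {
  tibble::tibble(estimate = x$half_life, std.error = x$se,
                 slope = x$slope, stable = x$stable)
}

#' @export
glance.fivep_halflife <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))
  tibble::tibble(r.squared = s$r.squared, sigma = s$sigma,
                 nobs = stats::nobs(x$fit))
}

trapz_auc <- function(df, to = NULL) {
  stopifnot(all(c("time", "value") %in% names(df)))
  t <- df$time
  v <- df$value
  if (!is.null(to)) {
    if (to > max(t)) stop("AUC horizon beyond the data range", call. = FALSE)
    if (!to %in% t) {   # linear interpolation at the horizon
      vi <- stats::approx(t, v, xout = to)$y
      keep <- t < to
      t <- c(t[keep], to)
      v <- c(v[keep], vi)
    } else {
      keep <- t <= to
      t <- t[keep]
      v <- v[keep]
    }
  }
  pracma::trapz(t, v)
}

#' Plateau time of an induction curve
#'
#' The first time point from which the curve stays within `band`
#' (relative) of its running maximum at that point — i.e. the earliest
#' time after which no later value deviates by more than `band * max` so
#' far. Falls back to the last time point when no plateau is reached.
#'
#' @param df Data frame with `time` and `value`.
#' @param band Relative tolerance (default 0.05).
#' @return The plateau time.
#' @export
plateau_time <- function(df, band = 0.05) {
  t <- df$time
  v <- df$value
  for (i in seq_along(t)) {
    m <- max(v[seq_len(i)])
    if (all(abs(v[i:length(v)] - m) <= band * m)) return(t[i])
  }
  t[length(t)]
}

#' Translation-efficiency ratio from induction time-courses
#'
#' Translation efficiency of a strain is the trapezoid area under its
#' protein induction curve (integrated to the detected plateau) divided
#' by the area under its mRNA induction curve (integrated to a fixed
#' horizon, default 60 min). The returned value is `TE(mut) / TE(wt)`:
#' how much more protein per unit mRNA the mutant produces. A protein
#' curve that is flat from its first time point plateaus immediately;
#' its AUC is then taken over the full curve range rather than a
#' zero-width interval.
#'
#' @param mut,wt Each a list with `protein` and `mrna` data frames of
#'   `time` and `value`.
#' @param mrna_horizon mRNA AUC horizon in minutes (default 60).
#' @param band Plateau detection band (see [plateau_time()]).
#' @return List of class `fivep_te`: `ratio`, `te_mut`, `te_wt`,
#'   `plateau_mut`, `plateau_wt`.
#' @export
translation_efficiency_ratio <- function(mut, wt, mrna_horizon = 60,
                                         band = 0.05) {
  te_one <- function(pair) {
    pl <- plateau_time(pair$protein, band)
    # a curve flat from the first time point "plateaus" immediately and
    # would integrate to zero; fall back to the full curve range
    if (pl <= pair$protein$time[1]) pl <- max(pair$protein$time)
    auc_p <- trapz_auc(pair$protein, to = pl)
    auc_m <- trapz_auc(pair$mrna, to = mrna_horizon)
    if (auc_m <= 0) stop("mRNA AUC is zero", call. = FALSE)
    list(te = auc_p / auc_m, plateau = pl)
  }
  m <- te_one(mut)
  w <- te_one(wt)
  structure(
    list(ratio = m$te / w$te, te_mut = m$te, te_wt = w$te,
         plateau_mut = m$plateau, plateau_wt = w$plateau),
    class = "fivep_te"
  )
}

#' @export
print.fivep_te <- function(x, ...) {
  cat(sprintf(
    "TE ratio (mut/wt): %.3f  [TE mut %.3f @ plateau %g min; TE wt %.3f @ %g min]\n",
    x$ratio, x$te_mut, x$plateau_mut, x$te_wt, x$plateau_wt))
  invisible(x)
}

#' Polysome-to-subpolysome (P/FM) ratio
#'
#' Ratio of summed polysomal signal to summed sub-polysomal (free +
#' monosomal) signal across sucrose-gradient fractions. Default fraction
#' convention: sub-polysomal fractions 1-2, polysomal fractions 3-8.
#'
#' @param quantities Numeric vector of per-fraction quantities (indexed
#'   from 1).
#' @param polysomal,subpolysomal Disjoint index sets into `quantities`.
#' @return Numeric ratio.
#' @examples
#' pfm_ratio(c(1, 1, 2, 2, 2, 0, 0, 0))   # 3
#' @export
pfm_ratio <- function(quantities, polysomal = 3:8, subpolysomal = 1:2) {
  if (length(intersect(polysomal, subpolysomal))) {
    stop("fraction index sets must be disjoint", call. = FALSE)
  }
  if (any(quantities < 0)) stop("quantities must be >= 0", call. = FALSE)
  denom <- sum(quantities[subpolysomal])
  if (denom <= 0) stop("sub-polysomal signal is zero", call. = FALSE)
  sum(quantities[polysomal]) / denom
}
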