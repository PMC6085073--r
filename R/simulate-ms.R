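#' Simulate a peptide-level MS quantification table
#'
#' Emulates the input of the RNP pull-down enrichment funnel: per protein,
#' strain and replicate, a Poisson number of confidently identified
#' peptides (rate proportional to molecular weight) with log-normal
#' intensities, split between two gel-fraction sets per sample (the bait
#' band and the remainder of the lane). A chosen set of "enriched"
#' proteins gets a `+effect_log2` mean log2-intensity shift (and the same
#' fold change on expected peptide count) in the bait strains only.
#' Per-sample global intensity scaling noise is included; median
#' normalization downstream absorbs it.
#'
#' @param n_proteins Number of proteins.
#' @param n_enriched Number of truly enriched proteins.
#' @param n_replicates Biological replicates per strain (default 3).
#' @param strains Strain labels; the first is the untagged control.
#' @param enriched_strains Strains in which the enrichment applies.
#' @param effect_log2 Log2 enrichment effect size (>= 0; 0 gives a null
#'   dataset).
#' @param seed Integer seed.
#' @return List: `peptides` (tibble `protein_id`, `strain`, `replicate`,
#'   `gel_set`, `peptide_id`, `intensity`, `confident`, `mw`) and `truth`
#'   (tibble `protein_id`, `enriched`).
#' @export
simulate_ms_dataset <- function(n_proteins = 500L, n_enriched = 10L,
                                n_replicates = 3L,
                                strains = c("untagged", "GPD1", "STL1",
                                            "ASH1", "HYP2"),
                                enriched_strains = c("GPD1", "STL1"),
                                effect_log2 = 3, seed = 1L) {
  stopifnot(n_enriched <= n_proteins, effect_log2 >= 0, n_replicates >= 1L)
  with_seed(seed, {
    prot <- sprintf("P%04d", seq_len(n_proteins))
    mw <- round(stats::runif(n_proteins, 20, 150), 1)
    base <- stats::rnorm(n_proteins, mean = 20, sd = 1.5)
    enriched <- rep(FALSE, n_proteins)
    if (n_enriched > 0L) enriched[sample.int(n_proteins, n_enriched)] <- TRUE

    grid <- tidyr::expand_grid(
      p = seq_len(n_proteins), strain = strains,
      replicate = seq_len(n_replicates)
    )
    shift <- ifelse(enriched[grid$p] & grid$strain %in% enriched_strains,
                    effect_log2, 0)
    lambda <- pmax(mw[grid$p] / 12, 0.5) * 2^shift
    n_pep <- stats::rpois(nrow(grid), lambda)

    samp_scale <- stats::rnorm(length(strains) * n_replicates, 0, 0.5)
    names(samp_scale) <- paste(rep(strains, each = n_replicates),
                               seq_len(n_replicates), sep = "/")

    keep <- n_pep > 0L
    idx <- rep.int(which(keep), n_pep[keep])
    g <- grid[idx, ]
    pep_noise <- stats::rnorm(length(idx), 0, 0.8)
    log2_int <- base[g$p] + shift[idx] + pep_noise +
      samp_scale[paste(g$strain, g$replicate, sep = "/")]
    peptides <- tibble::tibble(
      protein_id = prot[g$p],
      strain = g$strain,
      replicate = g$replicate,
      gel_set = ifelse(stats::runif(length(idx)) < 0.2, "bait", "remainder"),
      peptide_id = paste0(prot[g$p], "_pep", stats::ave(idx, idx, FUN = seq_along)),
      intensity = 2^log2_int,
      confident = stats::runif(length(idx)) < 0.95,
      mw = mw[g$p]
    )
    list(
      peptides = peptides,
      truth = tibble::tibble(protein_id = prot, enriched = enriched)
    )
  })
}

#' Simulate assay time-courses with known ground truth
#'
#' Generates (i) an exponential mRNA decay course after transcription
#' shut-off with the given half-life, and (ii) a matched pair of
#' protein/mRNA induction curves for a "mutant" and a "wild type" whose
#' true translation-efficiency ratio (protein AUC to plateau over mRNA
#' AUC to 60 min, mutant vs wt) equals `te_ratio`. Noise is multiplicative
#' log-normal with standard deviation `noise_sd` on the natural-log scale.
#'
#' @param half_life_min True mRNA half-life (minutes, > 0).
#' @param te_ratio True mutant/wt translation-efficiency ratio.
#' @param noise_sd Log-scale noise SD (0 = exact curves).
#' @param seed Integer seed.
#' @param decay_times,course_times Sampling times (minutes).
#' @return List: `decay` (tibble `time`, `abundance`), `mut` and `wt`
#'   (each a list with `protein` and `mrna` tibbles of `time`, `value`),
#'   `truth` (list `half_life`, `te_ratio`).
#' @export
simulate_timecourse <- function(half_life_min = 10, te_ratio = 1,
                                noise_sd = 0, seed = 1L,
                                decay_times = c(0, 5, 10, 15, 25, 35, 45),
                                course_times = seq(0, 60, by = 5)) {
  stopifnot(half_life_min > 0, te_ratio > 0, noise_sd >= 0)
  with_seed(seed, {
    noisy <- function(v) v * exp(stats::rnorm(length(v), 0, noise_sd))
    k <- log(2) / half_life_min
    decay <- tibble::tibble(
      time = decay_times,
      abundance = noisy(exp(-k * decay_times))
    )
    mrna <- function() tibble::tibble(
      time = course_times, value = noisy(1 - exp(-course_times / 15))
    )
    protein <- function(scale) tibble::tibble(
      time = course_times,
      value = noisy(scale * (1 - exp(-course_times / 12)))
    )
    list(
      decay = decay,
      mut = list(protein = protein(te_ratio), mrna = mrna()),
      wt = list(protein = protein(1), mrna = mrna()),
      truth = list(half_life = half_life_min, te_ratio = te_ratio)
    )
  })
}
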