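pep_row <- function(protein, strain, rep, intensity, gel = "remainder",
                    conf = TRUE, mw = 50) {
  tibble::tibble(protein_id = protein, strain = strain, replicate = rep,
                 gel_set = gel,
                 peptide_id = paste0(protein, "_", seq_along(intensity)),
                 intensity = intensity, confident = conf, mw = mw)
}

test_that("top3 takes the mean of the three most intense confident peptides", {
  tbl <- pep_row("P1", "S", 1, c(8, 4, 2, 1))
  expect_equal(top3_quant(tbl)$abundance, log2(mean(c(8, 4, 2))))

  # exactly three -> their mean; fewer -> mean of available, flagged
  expect_equal(top3_quant(pep_row("P1", "S", 1, c(8, 4, 2)))$abundance,
               log2(mean(c(8, 4, 2))))
  two <- top3_quant(pep_row("P1", "S", 1, c(8, 4)))
  expect_equal(two$abundance, log2(6))
  expect_equal(two$n_used, 2L)

  # non-confident peptides are ignored; a protein with none is absent
  tbl2 <- dplyr::bind_rows(pep_row("P1", "S", 1, c(8, 4, 2)),
                           pep_row("P2", "S", 1, 100, conf = FALSE))
  expect_equal(top3_quant(tbl2)$protein_id, "P1")

  # global intensity scaling shifts all log2 abundances by log2 k
  a0 <- top3_quant(tbl)$abundance
  a3 <- top3_quant(dplyr::mutate(tbl, intensity = intensity * 8))$abundance
  expect_equal(a3 - a0, 3)

  # sum mode
  expect_equal(top3_quant(tbl, aggregate = "sum")$abundance, log2(14))
})

test_that("count/MW abundance is log2(peptide count / molecular weight)", {
  tbl <- pep_row("P1", "S", 1, rep(1, 10), mw = 50)
  expect_equal(count_mw_quant(tbl)$abundance, log2(10 / 50))

  # equal counts, MW ratio 2 -> abundance difference exactly 1
  tbl2 <- dplyr::bind_rows(pep_row("P1", "S", 1, rep(1, 6), mw = 40),
                           pep_row("P2", "S", 1, rep(1, 6), mw = 80))
  ab <- count_mw_quant(tbl2)
  expect_equal(ab$abundance[ab$protein_id == "P1"] -
                 ab$abundance[ab$protein_id == "P2"], 1)

  # zero confident peptides -> absent, not zero
  tbl3 <- pep_row("P1", "S", 1, 5, conf = FALSE)
  expect_equal(nrow(count_mw_quant(tbl3)), 0L)
})

test_that("median normalization zeroes each set median and absorbs shifts", {
  tbl <- dplyr::bind_rows(
    pep_row("P1", "S", 1, 2), pep_row("P2", "S", 1, 4), pep_row("P3", "S", 1, 8)
  )
  aset <- top3_quant(tbl)
  norm <- median_normalize(aset)
  expect_equal(sort(norm$abundance), c(-1, 0, 1))
  expect_equal(median(norm$abundance), 0)

  # adding a constant (global scaling) leaves normalized values unchanged
  shifted <- dplyr::mutate(aset, abundance = abundance + 5)
  attr(shifted, "normalized") <- FALSE
  expect_equal(median_normalize(shifted)$abundance, norm$abundance)

  expect_error(median_normalize(norm), "already normalized")

  # random set: median is 0 exactly
  set.seed(1)
  r <- dplyr::mutate(aset, abundance = rnorm(3))
  attr(r, "normalized") <- FALSE
  expect_equal(median(median_normalize(r)$abundance), 0)
})

test_that("combining count sets averages the values present", {
  mk <- function(gel, prots, vals) {
    a <- tibble::tibble(protein_id = prots, strain = "S", replicate = 1L,
                        gel_set = gel, method = "count_mw",
                        abundance = vals, n_used = 1L)
    attr(a, "normalized") <- TRUE
    a
  }
  bait <- mk("bait", c("P1", "P2"), c(1, 5))
  rem <- mk("remainder", c("P1", "P3"), c(3, 7))
  comb <- combine_count_sets(bait, rem)
  expect_equal(comb$abundance[comb$protein_id == "P1"], 2)  # mean(1, 3)
  expect_equal(comb$abundance[comb$protein_id == "P2"], 5)  # bait only
  expect_equal(comb$abundance[comb$protein_id == "P3"], 7)  # remainder only

  # combining a set with itself is the identity on values
  self <- combine_count_sets(bait, bait)
  expect_equal(self$abundance, bait$abundance)

  t3 <- dplyr::mutate(bait, method = "top3")
  attr(t3, "normalized") <- TRUE
  expect_error(combine_count_sets(t3, rem), "count_mw")
})

test_that("enrichment t-test matches the textbook formula to 1e-12", {
  mk_aset <- function(vals_tag, vals_untag) {
    a <- tibble::tibble(
      protein_id = "P1",
      strain = rep(c("TAG", "UNT"), c(length(vals_tag), length(vals_untag))),
      replicate = c(seq_along(vals_tag), seq_along(vals_untag)),
      gel_set = "combined", method = "count_mw",
      abundance = c(vals_tag, vals_untag), n_used = 1L
    )
    attr(a, "normalized") <- TRUE
    a
  }
  set.seed(42)
  for (i in 1:10) {
    x <- rnorm(3)
    y <- rnorm(3)
    res <- enrichment_test(mk_aset(x, y), "TAG", "UNT")
    expect_equal(res$t, textbook_t(x, y), tolerance = 1e-12)
    expect_equal(res$mean_ratio, mean(x) - mean(y), tolerance = 1e-12)
    df <- length(x) + length(y) - 2
    expect_equal(res$p_value, 2 * pt(-abs(textbook_t(x, y)), df),
                 tolerance = 1e-12)
  }

  # identical constant groups: t 0, p 1
  res <- enrichment_test(mk_aset(c(2, 2, 2), c(2, 2, 2)), "TAG", "UNT")
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)

  # the worked example: tagged {2,2,2} vs untagged {0,0,0}
  res <- enrichment_test(mk_aset(c(2, 2, 2), c(0, 0, 0)), "TAG", "UNT")
  expect_equal(res$mean_ratio, 2)
  expect_equal(res$p_value, 0)   # zero variance, nonzero difference

  # replicate rule: one tagged replicate only -> excluded
  res <- enrichment_test(mk_aset(2, c(0, 0, 0)), "TAG", "UNT")
  expect_equal(nrow(res), 0L)

  # missing untagged values are imputed at the floor and flagged
  a <- mk_aset(c(2, 2.5, 3), numeric(0))
  extra <- tibble::tibble(protein_id = c("P2", "P3"), strain = "UNT",
                          replicate = 1L, gel_set = "combined",
                          method = "count_mw", abundance = c(-1, 0), n_used = 1L)
  a2 <- dplyr::bind_rows(a, extra)
  attr(a2, "normalized") <- TRUE
  res <- enrichment_test(a2, "TAG", "UNT")
  expect_true(res$imputed[res$protein_id == "P1"])
  expect_equal(res$n_untag[res$protein_id == "P1"], 0L)
})

test_that("the funnel recovers spiked proteins and respects its thresholds", {
  ms <- simulate_ms_dataset(n_proteins = 150, n_enriched = 5,
                            effect_log2 = 3, seed = 5L)
  out <- ms_funnel(ms$peptides)
  truth <- ms$truth$protein_id[ms$truth$enriched]
  expect_gte(length(intersect(out$preferential$protein_id, truth)), 4L)
  expect_lte(length(setdiff(out$preferential$protein_id, truth)), 1L)

  # monotonicity: boosting a recovered protein's tagged intensities never
  # removes it from the list
  hit <- intersect(out$preferential$protein_id, truth)[1]
  boosted <- dplyr::mutate(ms$peptides, intensity = ifelse(
    protein_id == hit & strain %in% c("GPD1", "STL1"), intensity * 4, intensity))
  out2 <- ms_funnel(boosted)
  expect_true(hit %in% out2$preferential$protein_id)
})

test_that("a log2 ratio of 1.4 against a control strain is not preferential", {
  # constructed abundances: clearly enriched vs untagged in both bait
  # strains, but only 1.4 log2 above control strain ASH1
  strains <- c("untagged", "GPD1", "STL1", "ASH1", "HYP2")
  base <- tidyr::expand_grid(
    protein_id = sprintf("BG%02d", 1:11), strain = strains, replicate = 1:3
  ) |>
    dplyr::mutate(abundance = rep(seq(-0.5, 0.5, length.out = 11),
                                  each = length(strains) * 3))
  target <- tidyr::expand_grid(protein_id = "PX", strain = strains,
                               replicate = 1:3) |>
    dplyr::mutate(abundance = dplyr::case_when(
      strain %in% c("GPD1", "STL1") ~ 4,
      strain == "ASH1" ~ 4 - 1.4,
      strain == "HYP2" ~ 0,
      TRUE ~ 0
    ) + 0.01 * replicate)
  aset <- dplyr::bind_rows(base, target) |>
    dplyr::mutate(gel_set = "combined", method = "count_mw", n_used = 1L)
  attr(aset, "normalized") <- TRUE
  enr <- dplyr::bind_rows(lapply(setdiff(strains, "untagged"), function(s) {
    enrichment_test(aset, s, "untagged")
  }))
  pref <- preferential_filter(enr, aset)
  expect_false("PX" %in% pref$protein_id)

  # raising the ASH1 margin above 1.5 admits it
  aset2 <- dplyr::mutate(aset, abundance = ifelse(
    protein_id == "PX" & strain == "ASH1", abundance - 0.3, abundance))
  attr(aset2, "normalized") <- TRUE
  enr2 <- dplyr::bind_rows(lapply(setdiff(strains, "untagged"), function(s) {
    enrichment_test(aset2, s, "untagged")
  }))
  pref2 <- preferential_filter(enr2, aset2)
  expect_true("PX" %in% pref2$protein_id)

  expect_error(preferential_filter(enr[enr$strain != "GPD1", ], aset),
               "GPD1")
})
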