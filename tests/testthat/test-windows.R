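test_that("window scheme presets have the documented widths", {
  sch <- window_scheme()
  expect_equal(sch$uS, c(-60L, -15L))
  expect_equal(sch$dS, c(-14L, 31L))
  expect_equal(sch$ddS, c(32L, 77L))
  for (w in c("uS", "dS", "ddS")) {
    expect_equal(sch[[w]][2] - sch[[w]][1], 45L)
  }
  expect_equal(sch$uE, c(-62L, -17L))
  expect_equal(sch$dE, c(-17L, 46L))
  expect_equal(sch$min_reads, 20L)

  lit <- window_scheme("literal")
  expect_equal(lit$dE, c(-18L, 46L))     # printed bounds, overlapping uE
  expect_error(window_scheme(uS = c(5, 5)), "half-open")
})

test_that("one read per uS position counts to exactly 45", {
  tx <- tiny_tx()
  # start offsets -60..-16 on G1 (utr5 100): tx positions 40..84
  cov <- fivep_counts(reads_at(rep("G1", 45), 40:84), tx)
  wct <- window_counts(cov, tx)
  g1 <- wct[wct$gene_id == "G1", ]
  expect_equal(g1$uS, 45)
  expect_equal(g1$dS + g1$ddS + g1$uE + g1$dE, 0)
  # offset -15 is in neither uS nor dS under the default scheme
  cov2 <- fivep_counts(reads_at("G1", 85), tx)
  wct2 <- window_counts(cov2, tx)
  expect_equal(sum(wct2[wct2$gene_id == "G1", c("uS", "dS")]), 0)
})

test_that("window counts equal a brute-force per-position scan", {
  tx <- tiny_tx()
  sch <- window_scheme()
  for (seed in 1:10) {
    cov <- random_coverage(tx, n_reads = 400L, seed = seed)
    wct <- window_counts(cov, tx, sch)
    for (i in seq_len(nrow(tx))) {
      g <- tx$gene_id[i]
      cg <- cov[cov$gene_id == g, ]
      so <- cg$pos - tx$utr5_len[i]
      eo <- cg$pos - (tx$utr5_len[i] + tx$cds_len[i] - 3L)
      brute <- c(
        uS = sum(cg$count[so >= -60 & so < -15]),
        dS = sum(cg$count[so >= -14 & so < 31]),
        ddS = sum(cg$count[so >= 32 & so < 77]),
        uE = sum(cg$count[eo >= -62 & eo < -17]),
        dE = sum(cg$count[eo >= -17 & eo < 46])
      )
      row <- wct[wct$gene_id == g, ]
      expect_equal(unlist(row[, names(brute)]), brute,
                   ignore_attr = TRUE)
    }
  }
})

test_that("window counts are additive over libraries", {
  tx <- tiny_tx()
  c1 <- random_coverage(tx, n_reads = 300L, seed = 51L)
  c2 <- random_coverage(tx, n_reads = 300L, seed = 52L)
  w1 <- window_counts(c1, tx)
  w2 <- window_counts(c2, tx)
  pooled <- pool_window_counts(w1, w2)
  cols <- c("uS", "dS", "ddS", "uE", "dE")
  expect_equal(as.data.frame(pooled[, cols]),
               as.data.frame(w1[, cols] + w2[, cols]), ignore_attr = TRUE)
})

test_that("loading ratios: arithmetic, pseudocount, antisymmetry", {
  wct <- tibble::tibble(
    gene_id = c("A", "B", "C", "D"),
    uS = c(20, 40, 0, 30), dS = c(20, 10, 40, 0),
    ddS = 0, uE = 0, dE = 0,
    total = NA_real_, utr5_ok = TRUE
  )
  lt <- loading_ratios(wct, window_scheme())
  expect_equal(lt$uSvsdS[1], 0)                       # symmetry
  expect_equal(lt$uSvsdS[2], 2)                       # log2(40/10)
  expect_equal(lt$uSvsdS[3], log2(0.5 / 40.5))        # pseudocount at zero
  expect_equal(lt$uSvsdS[4], log2(30.5 / 0.5))

  # swapping the windows negates the ratio exactly when both nonzero
  swapped <- dplyr::mutate(wct, tmp = uS, uS = dS, dS = tmp)
  ls <- loading_ratios(swapped, window_scheme())
  expect_equal(ls$uSvsdS[1:2], -lt$uSvsdS[1:2])
})

test_that("the 20-read filter boundary excludes 19 and admits 20", {
  wct <- tibble::tibble(
    gene_id = c("A", "B"),
    uS = c(9, 10), dS = c(10, 10), ddS = 0, uE = 0, dE = 0,
    total = NA_real_, utr5_ok = TRUE
  )
  lt <- loading_ratios(wct, window_scheme())
  expect_false(lt$uSvsdS_pass[1])   # 19 reads: filtered
  expect_true(is.na(lt$uSvsdS[1]))
  expect_true(lt$uSvsdS_pass[2])    # 20 reads: kept
  expect_equal(lt$uSvsdS[2], 0)

  # the filter is per ratio: a gene may pass uSvsdS and fail uEvsdE
  wct2 <- tibble::tibble(gene_id = "A", uS = 15, dS = 15, ddS = 0,
                         uE = 3, dE = 4, total = NA_real_, utr5_ok = TRUE)
  lt2 <- loading_ratios(wct2, window_scheme())
  expect_true(lt2$uSvsdS_pass)
  expect_false(lt2$uEvsdE_pass)

  # short 5'UTR genes are excluded from uS-based ratios only
  wct3 <- tibble::tibble(gene_id = "A", uS = 50, dS = 50, ddS = 50,
                         uE = 50, dE = 50, total = NA_real_, utr5_ok = FALSE)
  lt3 <- loading_ratios(wct3, window_scheme())
  expect_false(lt3$uSvsdS_pass)
  expect_false(lt3$uSvsddS_pass)
  expect_true(lt3$uEvsdE_pass)
})

test_that("median uSvsdS is near zero on uniform coverage", {
  cfg <- degradome_config(n_genes = 100L, n_reads = 100000L,
                          w_init = 0, w_elong = 0, w_term = 0, w_bg = 1,
                          pcr_dup_mean = 0, seed = 61L)
  sim <- simulate_degradome(cfg)
  cov <- fivep_counts(dedup_reads(sim$reads), sim$transcripts)
  lt <- loading_ratios(window_counts(cov, sim$transcripts))
  expect_lt(abs(median(lt$uSvsdS, na.rm = TRUE)), 0.15)
})
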