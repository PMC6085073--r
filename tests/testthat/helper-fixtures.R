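# Shared fixtures, all built in code.

# A tiny transcript set with simple geometry for coordinate tests.
tiny_tx <- function() {
  transcript_models(
    gene_id = c("G1", "G2", "G3"),
    utr5_len = c(100L, 80L, 62L),
    cds_len = c(300L, 450L, 600L),
    utr3_len = c(80L, 60L, 120L)
  )
}

# Deduplicated read tibble at explicit positions.
reads_at <- function(gene_id, pos, umi = NULL) {
  r <- tibble::tibble(
    gene_id = gene_id, pos = as.integer(pos),
    umi = umi %||% sprintf("U%03d", seq_along(pos))
  )
  attr(r, "deduplicated") <- TRUE
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random raw coverage over a transcript set (deterministic given seed).
random_coverage <- function(tx, n_reads = 500L, seed = 1L) {
  set.seed(seed)
  i <- sample.int(nrow(tx), n_reads, replace = TRUE)
  pos <- floor(runif(n_reads) * tx$tx_length[i])
  fivep_counts(reads_at(tx$gene_id[i], pos), tx)
}

# A small fast degradome config for tests that do not need full depth.
small_cfg <- function(n_genes = 40L, n_reads = 20000L, ...) {
  degradome_config(n_genes = n_genes, n_reads = n_reads, ...)
}

# Exact Mann-Whitney p by enumeration over all group assignments.
enumerate_mwu <- function(x, y, alternative = "two.sided") {
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  obs <- u_stat(x, y)
  pooled <- c(x, y)
  n1 <- length(x)
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  mu <- n1 * length(y) / 2
  switch(alternative,
    two.sided = mean(abs(us - mu) >= abs(obs - mu)),
    greater = mean(us >= obs),
    less = mean(us <= obs)
  )
}

# Textbook equal-variance two-sample t statistic.
textbook_t <- function(x, y) {
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
}
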