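#' Degradome simulation configuration
#'
#' Parameters of the synthetic 5'P degradome. The positional model places
#' 5'P decay-intermediate ends where co-translational 5'-3' degradation
#' leaves them: a ribosome paused with its P-site on codon `k` protects
#' `p_offset` nt of upstream mRNA, so the 5'P end sits at start-anchor
#' offset `3k - p_offset`. Per transcript the intensity at each position
#' is:
#'
#' * `w_init` at start offset `-p_offset` (initiation pause, default -14);
#' * `w_elong` at offsets `-p_offset + 3k`, `k = 1 .. cds_len/3 - 1`
#'   (elongating ribosomes, the source of 3-nt periodicity);
#' * `w_term` at stop offset `-term_offset` (termination pause, default -17);
#' * `w_bg` per nucleotide of uniform background over the whole transcript.
#'
#' All intensity strictly upstream of the initiation-pause position
#' (start offsets `< -p_offset`) is multiplied by `f_utr5`, and
#' additionally by `f_utr5_osr` for genes in the osmotic-stress-response
#' (OSR) subset. Sampling probabilities are the normalized intensities
#' over all genes and positions; `n_reads` unique molecules are drawn
#' multinomially, each receives a UMI of `umi_len` random bases and
#' `1 + Geometric(pcr_dup_mean)` emitted PCR copies.
#'
#' @param n_genes Number of transcripts.
#' @param utr5_len_range,utr3_len_range Integer ranges (nt) for UTR lengths.
#'   The 5'UTR minimum must be >= 62 so the upstream windows fit.
#' @param cds_codon_range Integer range of CDS length in codons
#'   (stop included); minimum 48 codons so the downstream and stop
#'   windows fit.
#' @param n_reads Unique molecules to sample.
#' @param w_init,w_elong,w_term,w_bg Nonnegative intensity weights (see
#'   above); at least one must be positive.
#' @param p_offset Ribosome protection length: distance (nt) from the 5'P
#'   end to the first nucleotide of the paused P-site codon.
#' @param term_offset Distance (nt) upstream of the stop codon of the
#'   termination-pause 5'P end.
#' @param f_utr5 Genotype multiplier on 5'UTR intensity (wild type 1).
#' @param osr_fraction Fraction of genes flagged OSR.
#' @param f_utr5_osr Extra 5'UTR multiplier applied to OSR genes only.
#' @param umi_len UMI length in bases.
#' @param pcr_dup_mean Mean number of extra PCR copies per molecule.
#' @param distinct_umis If `TRUE`, molecules get globally distinct UMIs
#'   (collision-free; UMI length grows if needed) so deduplication can be
#'   checked against truth exactly.
#' @param seed Integer seed; every sampled quantity derives from it.
#' @return A validated config list of class `fivep_degradome_config`.
#' @export
degradome_config <- function(n_genes = 200L,
                             utr5_len_range = c(62L, 150L),
                             cds_codon_range = c(150L, 500L),
                             utr3_len_range = c(50L, 200L),
                             n_reads = 100000L,
                             w_init = 5, w_elong = 1, w_term = 5, w_bg = 0.5,
                             p_offset = 14L, term_offset = 17L,
                             f_utr5 = 1, osr_fraction = 0.1, f_utr5_osr = 1,
                             umi_len = 8L, pcr_dup_mean = 1,
                             distinct_umis = FALSE, seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    utr5_len_range = as.integer(utr5_len_range),
    cds_codon_range = as.integer(cds_codon_range),
    utr3_len_range = as.integer(utr3_len_range),
    n_reads = as.integer(n_reads),
    w_init = w_init, w_elong = w_elong, w_term = w_term, w_bg = w_bg,
    p_offset = as.integer(p_offset), term_offset = as.integer(term_offset),
    f_utr5 = f_utr5, osr_fraction = osr_fraction, f_utr5_osr = f_utr5_osr,
    umi_len = as.integer(umi_len), pcr_dup_mean = pcr_dup_mean,
    distinct_umis = isTRUE(distinct_umis), seed = as.integer(seed)
  )
  w <- c(cfg$w_init, cfg$w_elong, cfg$w_term, cfg$w_bg)
  if (any(w < 0) || all(w == 0)) {
    stop("weights must be >= 0 with at least one > 0", call. = FALSE)
  }
  if (cfg$p_offset < 0L || cfg$term_offset < 0L) {
    stop("offsets must be >= 0", call. = FALSE)
  }
  if (cfg$utr5_len_range[1] < 62L) {
    stop("5'UTR minimum must be >= 62 nt so the upstream windows fit",
         call. = FALSE)
  }
  if (cfg$cds_codon_range[1] < 48L) {
    stop("CDS minimum must be >= 48 codons so the ORF and stop windows fit",
         call. = FALSE)
  }
  if (cfg$n_genes < 1L || cfg$n_reads < 1L) {
    stop("n_genes and n_reads must be positive", call. = FALSE)
  }
  if (cfg$pcr_dup_mean < 0) stop("pcr_dup_mean must be >= 0", call. = FALSE)
  class(cfg) <- "fivep_degradome_config"
  cfg
}

#' Simulate a transcript set for degradome simulations
#'
#' Draws transcript geometries from the ranges in `cfg` and flags an OSR
#' subset. Two libraries to be compared (e.g. mutant vs wild type) must
#' share one transcript set: generate it once and pass it to both
#' [simulate_degradome()] calls.
#'
#' @param cfg A [degradome_config()].
#' @param seed Seed; defaults to `cfg$seed`.
#' @return A `fivep_transcripts` tibble with an extra logical `osr` column.
#' @export
simulate_transcripts <- function(cfg, seed = cfg$seed) {
  with_seed(seed, {
    r_int <- function(rng, n) {
      if (rng[1] == rng[2]) rep(rng[1], n) else sample(rng[1]:rng[2], n, replace = TRUE)
    }
    utr5 <- r_int(cfg$utr5_len_range, cfg$n_genes)
    cds <- 3L * r_int(cfg$cds_codon_range, cfg$n_genes)
    utr3 <- r_int(cfg$utr3_len_range, cfg$n_genes)
    tx <- transcript_models(
      sprintf("G%04d", seq_len(cfg$n_genes)), utr5, cds, utr3
    )
    n_osr <- round(cfg$osr_fraction * cfg$n_genes)
    tx$osr <- FALSE
    if (n_osr > 0) tx$osr[sample.int(cfg$n_genes, n_osr)] <- TRUE
    tx
  })
}

# Per-gene 5'P intensity vector over transcript positions 0..L-1.
degradome_intensity <- function(tx_row, cfg, osr) {
  L <- tx_row$tx_length
  utr5 <- tx_row$utr5_len
  cds <- tx_row$cds_len
  v <- rep(cfg$w_bg, L)
  init_pos <- utr5 - cfg$p_offset            # start offset -p_offset
  if (init_pos >= 0L) v[init_pos + 1L] <- v[init_pos + 1L] + cfg$w_init
  n_codons <- cds %/% 3L
  if (n_codons >= 2L && cfg$w_elong > 0) {
    k <- seq_len(n_codons - 1L)
    ep <- utr5 - cfg$p_offset + 3L * k
    ep <- ep[ep >= 0L & ep < L]
    v[ep + 1L] <- v[ep + 1L] + cfg$w_elong
  }
  term_pos <- utr5 + cds - 3L - cfg$term_offset   # stop offset -term_offset
  if (term_pos >= 0L && term_pos < L) v[term_pos + 1L] <- v[term_pos + 1L] + cfg$w_term
  f <- cfg$f_utr5 * if (osr) cfg$f_utr5_osr else 1
  if (f != 1 && init_pos > 0L) {
    v[seq_len(init_pos)] <- v[seq_len(init_pos)] * f   # start offsets < -p_offset
  }
  v
}

#' Simulate a 5'P degradome read library
#'
#' Produces a raw (pre-deduplication) read library with known per-position
#' ground truth under the intensity model described in
#' [degradome_config()]. Deterministic given `cfg$seed`.
#'
#' @param cfg A [degradome_config()].
#' @param transcripts Optional shared transcript set from
#'   [simulate_transcripts()]; generated from `cfg` when `NULL`.
#' @return A list with elements
#' \describe{
#'   \item{transcripts}{the `fivep_transcripts` tibble (with `osr`),}
#'   \item{reads}{raw read library: tibble `gene_id`, `pos` (0-based
#'     transcript position of the 5'P end), `umi` — one row per emitted
#'     PCR copy,}
#'   \item{truth}{list: `intensity` (gene, pos, intensity, prob),
#'     `molecules` (gene, pos, n unique pre-PCR molecules),
#'     `genes` (gene, osr flag, applied 5'UTR multiplier),
#'     `n_molecules` (total unique molecules).}
#' }
#' @examples
#' sim <- simulate_degradome(degradome_config(n_genes = 5, n_reads = 500))
#' head(sim$reads)
#' @export
simulate_degradome <- function(cfg, transcripts = NULL) {
  stopifnot(inherits(cfg, "fivep_degradome_config"))
  tx <- transcripts %||% simulate_transcripts(cfg)
  if (is.null(tx$osr)) tx$osr <- FALSE

  with_seed(cfg$seed + 1L, {
    ints <- lapply(seq_len(nrow(tx)), function(i) {
      degradome_intensity(tx[i, ], cfg, tx$osr[i])
    })
    lens <- vapply(ints, length, integer(1))
    allv <- unlist(ints, use.names = FALSE)
    prob <- allv / sum(allv)
    gene_of <- rep.int(tx$gene_id, lens)
    pos_of <- unlist(lapply(lens, function(L) 0:(L - 1L)), use.names = FALSE)

    counts <- as.integer(stats::rmultinom(1L, cfg$n_reads, prob))
    nz <- which(counts > 0L)
    mol_gene <- rep.int(gene_of[nz], counts[nz])
    mol_pos <- rep.int(pos_of[nz], counts[nz])
    n_mol <- length(mol_gene)

    if (cfg$distinct_umis) {
      len <- max(cfg$umi_len, ceiling(log(n_mol + 1) / log(4)))
      umi <- umi_strings(sample.int(n_mol) - 1L, len)
    } else {
      umi <- umi_strings(sample.int(4^cfg$umi_len, n_mol, replace = TRUE) - 1L,
                         cfg$umi_len)
    }
    copies <- if (cfg$pcr_dup_mean > 0) {
      1L + stats::rgeom(n_mol, prob = 1 / (1 + cfg$pcr_dup_mean))
    } else rep(1L, n_mol)

    idx <- rep.int(seq_len(n_mol), copies)
    reads <- tibble::tibble(
      gene_id = mol_gene[idx], pos = mol_pos[idx], umi = umi[idx]
    )
    # shuffle so downstream code cannot rely on molecule grouping
    reads <- reads[sample.int(nrow(reads)), ]

    truth <- list(
      intensity = tibble::tibble(gene_id = gene_of, pos = pos_of,
                                 intensity = allv, prob = prob),
      molecules = tibble::tibble(gene_id = mol_gene, pos = mol_pos) |>
        dplyr::count(.data$gene_id, .data$pos, name = "n"),
      genes = tibble::tibble(
        gene_id = tx$gene_id, osr = tx$osr,
        utr5_multiplier = cfg$f_utr5 * ifelse(tx$osr, cfg$f_utr5_osr, 1)
      ),
      n_molecules = n_mol
    )
    list(transcripts = tx, reads = reads, truth = truth)
  })
}

#' Write a simulated read library to disk
#'
#' `write_degradome_bed()` writes one BED6 record per read (chrom = gene,
#' 0-based 5'P position as a 1-nt interval, name = UMI).
#' `write_degradome_fastq()` writes reads as UMI-prefixed sequences with
#' random downstream bases (no sequence-level realism) plus a sidecar
#' truth TSV (`<path>.truth.tsv`: gene_id, pos per read, same order).
#'
#' @param reads Read tibble (`gene_id`, `pos`, `umi`).
#' @param path Output path.
#' @param read_len Total read length for FASTQ output (UMI included).
#' @param seed Seed for the random read bodies.
#' @return `path`, invisibly.
#' @export
write_degradome_bed <- function(reads, path) {
  readr::write_tsv(
    tibble::tibble(chrom = reads$gene_id, start = reads$pos,
                   end = reads$pos + 1L, name = reads$umi,
                   score = 0L, strand = "+"),
    path, col_names = FALSE
  )
  invisible(path)
}

#' @rdname write_degradome_bed
#' @export
write_degradome_fastq <- function(reads, path, read_len = 43L, seed = 1L) {
  n <- nrow(reads)
  umi_len <- nchar(reads$umi[1] %||% "")
  body_len <- read_len - umi_len
  if (body_len < 1L) stop("read_len must exceed the UMI length", call. = FALSE)
  body <- with_seed(seed, {
    umi_strings(sample.int(4^15, n * ceiling(body_len / 15), replace = TRUE) - 1L, 15L)
  })
  body <- substr(
    apply(matrix(body, nrow = n), 1L, paste0, collapse = ""), 1L, body_len
  )
  qual <- strrep("I", read_len)
  lines <- as.vector(rbind(
    sprintf("@read%d %s:%d", seq_len(n), reads$gene_id, reads$pos),
    paste0(reads$umi, body), "+", qual
  ))
  writeLines(lines, path)
  readr::write_tsv(reads[, c("gene_id", "pos")], paste0(path, ".truth.tsv"))
  invisible(path)
}

#' Read 5'P end intervals from a BED6 file
#'
#' Each record is one read: `chrom` is the gene/transcript, the interval
#' start (0-based) the 5'P end position, `name` the UMI.
#'
#' @param path BED6 file.
#' @return Read tibble (`gene_id`, `pos`, `umi`).
#' @export
read_fivep_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required to read BED", call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "BED")
  tibble::tibble(
    gene_id = as.character(GenomicRanges::seqnames(gr)),
    pos = GenomicRanges::start(gr) - 1L,   # back to 0-based
    umi = S4Vectors::mcols(gr)$name %||% NA_character_
  )
}

#' Read 5'P ends from transcriptome-space alignments (BAM)
#'
#' Takes primary alignments with mapping quality >= `min_mapq` from a BAM
#' file whose reference sequences are transcripts, and reports the
#' biological 5' end of each read (leftmost base on `+`, rightmost on
#' `-`). The UMI is parsed from the read name after the last `_` or `:`.
#'
#' @param path BAM file (indexed not required).
#' @param min_mapq Minimum mapping quality (default 1; multimappers with
#'   MAPQ 0 are excluded).
#' @return Read tibble (`gene_id`, `pos`, `umi`).
#' @export
read_fivep_bam <- function(path, min_mapq = 1L) {
  if (!requireNamespace("GenomicAlignments", quietly = TRUE)) {
    stop("GenomicAlignments is required to read BAM", call. = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE),
    mapqFilter = min_mapq, what = "qname"
  )
  ga <- GenomicAlignments::readGAlignments(path, param = param)
  gr <- GenomicRanges::resize(GenomicRanges::granges(ga), width = 1L, fix = "start")
  qn <- S4Vectors::mcols(ga)$qname
  umi <- sub(".*[_:]", "", qn)
  tibble::tibble(
    gene_id = as.character(GenomicRanges::seqnames(gr)),
    pos = GenomicRanges::start(gr) - 1L,
    umi = umi
  )
}
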