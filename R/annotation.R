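#' Build a transcript model table
#'
#' Constructs the per-gene coordinate frame used by every downstream
#' operation: 5'UTR / CDS / 3'UTR segment lengths on the spliced
#' transcript. Positions are 0-based transcript coordinates; offset 0 on
#' the start anchor is the first nucleotide of the start codon and offset
#' 0 on the stop anchor is the first nucleotide of the stop codon. The
#' CDS length is stop-codon inclusive, so it must be a multiple of 3 and
#' at least 6 nt (one codon plus the stop).
#'
#' @param gene_id Character vector of unique gene/transcript identifiers.
#' @param utr5_len,cds_len,utr3_len Integer vectors of segment lengths in
#'   nucleotides.
#' @return A `tbl_df` with columns `gene_id`, `utr5_len`, `cds_len`,
#'   `utr3_len`, `tx_length`, classed `fivep_transcripts`.
#' @examples
#' transcript_models("G1", 100, 300, 80)
#' @export
transcript_models <- function(gene_id, utr5_len, cds_len, utr3_len) {
  tx <- tibble::tibble(
    gene_id  = as.character(gene_id),
    utr5_len = as.integer(utr5_len),
    cds_len  = as.integer(cds_len),
    utr3_len = as.integer(utr3_len)
  )
  if (nrow(tx) == 0L) {
    stop("empty transcript set", call. = FALSE)
  }
  if (anyDuplicated(tx$gene_id)) {
    stop("gene_id values must be unique", call. = FALSE)
  }
  bad <- !transcript_valid(tx)
  if (any(bad)) {
    stop(
      "invalid transcript geometry for: ",
      paste(utils::head(tx$gene_id[bad], 5L), collapse = ", "),
      call. = FALSE
    )
  }
  tx$tx_length <- tx$utr5_len + tx$cds_len + tx$utr3_len
  class(tx) <- c("fivep_transcripts", class(tx))
  tx
}

transcript_valid <- function(tx) {
  !is.na(tx$utr5_len) & !is.na(tx$cds_len) & !is.na(tx$utr3_len) &
    tx$utr5_len >= 0L & tx$utr3_len >= 0L &
    tx$cds_len >= 6L & tx$cds_len %% 3L == 0L
}

#' Load transcript models from an annotation file
#'
#' Reads a transcript annotation and reduces it to the 5'UTR/CDS/3'UTR
#' coordinate frame. Three dialects are supported:
#'
#' * `"tsv"`: a 4-column table `gene_id, utr5_len, cds_len, utr3_len`
#'   (header required), where `cds_len` includes the stop codon;
#' * `"gtf"` / `"gff3"`: ensembl-style annotation (1-based inclusive
#'   genomic coordinates) with `exon` and `CDS` features per transcript.
#'   Exons are concatenated in transcript orientation (5' to 3', so
#'   descending genomic coordinates on the minus strand). When
#'   `stop_codon` features are present the CDS is taken as stop-exclusive
#'   (ensembl convention) and 3 nt are added; otherwise the CDS is
#'   assumed stop-inclusive.
#'
#' Transcripts violating the geometry invariants (CDS not a multiple of
#' 3, shorter than 6 nt, or not contained in the exons) are skipped with
#' a warning listing the reason.
#'
#' @param path Path to the annotation file.
#' @param dialect One of `"gtf"`, `"gff3"`, `"tsv"`. Defaults from the
#'   file extension.
#' @return A `fivep_transcripts` tibble (see [transcript_models()]).
#' @export
load_transcript_models <- function(path, dialect = c("auto", "gtf", "gff3", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("annotation file not found: ", path, call. = FALSE)
  }
  if (dialect == "auto") {
    dialect <- switch(tolower(tools::file_ext(path)),
      gtf = "gtf", gff = "gff3", gff3 = "gff3", tsv = "tsv", txt = "tsv",
      stop("cannot infer annotation dialect from extension: ", path, call. = FALSE)
    )
  }
  if (dialect == "tsv") {
    tx <- readr::read_tsv(path, show_col_types = FALSE)
    need <- c("gene_id", "utr5_len", "cds_len", "utr3_len")
    if (!all(need %in% names(tx))) {
      stop("TSV annotation must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    ok <- transcript_valid(tx)
    if (any(!ok)) {
      warning(sum(!ok), " transcript(s) skipped (invalid geometry): ",
              paste(utils::head(tx$gene_id[!ok], 5L), collapse = ", "))
      tx <- tx[ok, , drop = FALSE]
    }
    if (nrow(tx) == 0L) stop("no valid transcripts in ", path, call. = FALSE)
    return(transcript_models(tx$gene_id, tx$utr5_len, tx$cds_len, tx$utr3_len))
  }
  load_transcripts_gxf(path, dialect)
}

# GTF/GFF3 reduction via rtracklayer; exon concatenation in transcript
# orientation, CDS located on the concatenated frame.
load_transcripts_gxf <- function(path, dialect) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required to read GTF/GFF3", call. = FALSE)
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (dialect == "gtf") "gtf" else "gff3"),
    error = function(e) stop("unparseable annotation: ", conditionMessage(e), call. = FALSE)
  )
  mc <- S4Vectors::mcols(gr)
  id_col <- if (!is.null(mc$transcript_id)) "transcript_id" else "gene_id"
  if (is.null(mc[[id_col]])) {
    stop("annotation lacks transcript_id/gene_id attributes", call. = FALSE)
  }
  df <- tibble::tibble(
    id     = as.character(mc[[id_col]]),
    type   = as.character(mc$type),
    start  = GenomicRanges::start(gr),
    end    = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  df <- df[df$type %in% c("exon", "CDS", "stop_codon") & !is.na(df$id), , drop = FALSE]
  if (nrow(df) == 0L) stop("no exon/CDS features in ", path, call. = FALSE)

  res <- df |>
    dplyr::group_by(.data$id) |>
    dplyr::group_map(function(d, key) {
      reduce_tx_features(d, key$id)
    }) |>
    dplyr::bind_rows()

  bad <- is.na(res$utr5_len)
  if (any(bad)) {
    warning(sum(bad), " transcript(s) skipped: ",
            paste(utils::head(paste0(res$gene_id[bad], " (", res$reason[bad], ")"), 5L),
                  collapse = "; "))
  }
  res <- res[!bad, , drop = FALSE]
  if (nrow(res) == 0L) stop("no valid transcripts in ", path, call. = FALSE)
  transcript_models(res$gene_id, res$utr5_len, res$cds_len, res$utr3_len)
}

reduce_tx_features <- function(d, id) {
  skip <- function(reason) {
    tibble::tibble(gene_id = id, utr5_len = NA_integer_, cds_len = NA_integer_,
                   utr3_len = NA_integer_, reason = reason)
  }
  exons <- d[d$type == "exon", , drop = FALSE]
  cds <- d[d$type == "CDS", , drop = FALSE]
  if (nrow(exons) == 0L || nrow(cds) == 0L) return(skip("missing exon or CDS"))
  minus <- exons$strand[1] == "-"
  exons <- exons[order(exons$start, decreasing = minus), , drop = FALSE]
  widths <- exons$end - exons$start + 1L
  tx_len <- sum(widths)
  # transcript coordinate of a genomic position (0-based)
  to_tx <- function(gpos) {
    off <- 0L
    for (i in seq_len(nrow(exons))) {
      if (gpos >= exons$start[i] && gpos <= exons$end[i]) {
        within <- if (minus) exons$end[i] - gpos else gpos - exons$start[i]
        return(off + within)
      }
      off <- off + widths[i]
    }
    NA_integer_
  }
  cds_width <- sum(cds$end - cds$start + 1L)
  stop_width <- sum(d$end[d$type == "stop_codon"] - d$start[d$type == "stop_codon"] + 1L)
  cds_len <- cds_width + if (stop_width > 0L) 3L else 0L
  # 5'-most CDS base in transcript orientation
  cds_first <- if (minus) max(cds$end) else min(cds$start)
  utr5 <- to_tx(cds_first)
  if (is.na(utr5)) return(skip("CDS outside exons"))
  utr3 <- tx_len - utr5 - cds_len
  if (cds_len < 6L || cds_len %% 3L != 0L) return(skip("CDS length invalid"))
  if (utr3 < 0L) return(skip("CDS exceeds transcript"))
  tibble::tibble(gene_id = id, utr5_len = as.integer(utr5),
                 cds_len = as.integer(cds_len), utr3_len = as.integer(utr3),
                 reason = NA_character_)
}

#' Start- and stop-codon anchored offsets
#'
#' Convert 0-based transcript positions to offsets relative to the first
#' nucleotide of the start codon (`start_offset`) or of the stop codon
#' (`stop_offset`). Offset 0 is the anchor nucleotide itself; negative
#' offsets lie upstream. The canonical initiation-pause 5'P position sits
#' at start offset -14 (a ribosome with its P-site on the start codon
#' protects 14 nt of upstream mRNA from 5'-3' degradation) and the
#' termination pause at stop offset -17.
#'
#' @param tx A single row of a `fivep_transcripts` table, or the table
#'   itself with `gene_id` to select a row.
#' @param tx_pos 0-based transcript position(s), in `[0, tx_length)`.
#' @param gene_id Optional gene to select when `tx` has several rows.
#' @return Integer offset(s).
#' @examples
#' tx <- transcript_models("G1", 100, 300, 80)
#' start_offset(tx, 86)   # -14, the initiation-pause 5'P position
#' stop_offset(tx, 380)   # -17, the termination-pause 5'P position
#' @export
start_offset <- function(tx, tx_pos, gene_id = NULL) {
  tx <- pick_tx(tx, gene_id)
  check_tx_pos(tx, tx_pos)
  as.integer(tx_pos) - tx$utr5_len
}

#' @rdname start_offset
#' @export
stop_offset <- function(tx, tx_pos, gene_id = NULL) {
  tx <- pick_tx(tx, gene_id)
  check_tx_pos(tx, tx_pos)
  as.integer(tx_pos) - (tx$utr5_len + tx$cds_len - 3L)
}

pick_tx <- function(tx, gene_id = NULL) {
  if (!is.null(gene_id)) {
    tx <- tx[tx$gene_id == gene_id, , drop = FALSE]
  }
  if (nrow(tx) != 1L) {
    stop("expected exactly one transcript; use gene_id to select", call. = FALSE)
  }
  tx
}

check_tx_pos <- function(tx, tx_pos) {
  if (any(tx_pos < 0L | tx_pos >= tx$tx_length)) {
    stop("tx_pos out of range [0, ", tx$tx_length, ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Write transcript models to annotation files
#'
#' `write_transcripts_tsv()` writes the internal 4-column dialect.
#' `write_transcripts_gtf()` writes a single-exon ensembl-dialect GTF
#' (one reference sequence per gene, plus strand unless `strand` is
#' given), with stop-exclusive CDS and a `stop_codon` feature, so that
#' [load_transcript_models()] round-trips the table exactly.
#'
#' @param tx A `fivep_transcripts` tibble.
#' @param path Output file path.
#' @param strand Character vector of strands (`"+"`/`"-"`), recycled.
#' @return `path`, invisibly.
#' @export
write_transcripts_tsv <- function(tx, path) {
  readr::write_tsv(tx[, c("gene_id", "utr5_len", "cds_len", "utr3_len")], path)
  invisible(path)
}

#' @rdname write_transcripts_tsv
#' @export
write_transcripts_gtf <- function(tx, path, strand = "+") {
  strand <- rep_len(strand, nrow(tx))
  lines <- character(0)
  for (i in seq_len(nrow(tx))) {
    g <- tx$gene_id[i]
    L <- tx$tx_length[i]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', g, g)
    # 1-based inclusive genomic coordinates; transcript occupies 1..L on
    # its own reference sequence
    if (strand[i] == "+") {
      cds_start <- tx$utr5_len[i] + 1L
      cds_end <- tx$utr5_len[i] + tx$cds_len[i] - 3L
      stop_start <- cds_end + 1L
      stop_end <- stop_start + 2L
    } else {
      # minus strand: transcript 5' end at genomic coordinate L
      cds_end <- L - tx$utr5_len[i]
      cds_start <- cds_end - (tx$cds_len[i] - 3L) + 1L
      stop_end <- cds_start - 1L
      stop_start <- stop_end - 2L
    }
    row <- function(type, s, e) {
      paste(g, "fivep", type, s, e, ".", strand[i], ".", attrs, sep = "\t")
    }
    lines <- c(lines,
               row("exon", 1L, L),
               row("CDS", cds_start, cds_end),
               row("stop_codon", stop_start, stop_end))
  }
  writeLines(lines, path)
  invisible(path)
}
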