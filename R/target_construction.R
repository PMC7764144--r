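# Build the two per-promoter target sequence sets the pipeline compares:
# co-transcriptional = the first 1 kb of the nascent transcript (promoter-
# downstream genomic sequence, introns included), post-transcriptional = the
# longest mature isoform expressed from that promoter.

find_promoter <- function(genes, promoter_id) {
  for (g in genes) {
    if (promoter_id %in% g$promoters$promoter_id) return(g)
  }
  stop("unknown promoter_id: ", promoter_id, call. = FALSE)
}

extract_genomic <- function(genome, chrom, start, end) {
  seq <- genome[[chrom]]
  if (is.null(seq)) stop("unknown chromosome: ", chrom, call. = FALSE)
  substr(seq, start + 1L, end)
}

#' Co-transcriptional target: 5' window of the nascent transcript
#'
#' Returns the transcribed-sense sequence of the genomic window starting at
#' the promoter TSS and extending `window_len` bp in the direction of
#' transcription (reverse-complemented for minus-strand genes), truncated at
#' the chromosome edge and at the 3' end of the promoter's pre-mRNA (the
#' nascent transcript ends where its longest transcript ends, so genes
#' shorter than the window give shorter targets). Introns within the window
#' are included by construction: this is the 5' end of the pre-mRNA as it
#' emerges from the polymerase, the substrate for co-transcriptional lncRNA
#' base-pairing.
#'
#' @param gene A `gene_model`.
#' @param promoter_id Promoter within `gene`.
#' @param genome Named character vector of chromosome sequences.
#' @param window_len Window length in bp (default 1000).
#' @return A `target_sequence` list with fields promoter_id, mode,
#'   sequence, source_intervals (genomic, 0-based half-open), length.
#' @export
build_cotx_target <- function(gene, promoter_id, genome, window_len = 1000L) {
  idx <- match(promoter_id, gene$promoters$promoter_id)
  if (is.na(idx)) stop("unknown promoter_id: ", promoter_id, call. = FALSE)
  tss <- gene$promoters$tss[idx]
  clen <- nchar(genome[[gene$chrom]])
  if (is.null(genome[[gene$chrom]]) || tss < 0 || tss >= clen)
    stop("TSS of ", promoter_id, " outside chromosome bounds", call. = FALSE)
  txs <- Filter(function(tx) tx$promoter_id == promoter_id, gene$transcripts)
  pre_len <- max(vapply(txs, function(tx) {
    if (gene$strand == "+") max(tx$exons[, 2]) - tss
    else tss + 1L - min(tx$exons[, 1])
  }, 0L))
  wl <- min(window_len, pre_len)
  if (gene$strand == "+") {
    s <- tss; e <- min(tss + wl, clen)
    seq <- extract_genomic(genome, gene$chrom, s, e)
  } else {
    s <- max(tss + 1L - wl, 0L); e <- tss + 1L
    seq <- revcomp(extract_genomic(genome, gene$chrom, s, e))
  }
  structure(list(promoter_id = promoter_id, mode = "co", sequence = seq,
                 source_intervals = cbind(start = as.integer(s), end = as.integer(e)),
                 chrom = gene$chrom, strand = gene$strand,
                 length = nchar(seq)),
            class = "target_sequence")
}

# Mature (spliced) length of a transcript.
mature_length <- function(tx) sum(tx$exons[, 2] - tx$exons[, 1])

# Spliced sense-strand sequence of a transcript.
spliced_sequence <- function(tx, gene, genome) {
  parts <- vapply(seq_len(nrow(tx$exons)), function(i)
    extract_genomic(genome, gene$chrom, tx$exons[i, 1], tx$exons[i, 2]), "")
  seq <- paste(parts, collapse = "")
  if (gene$strand == "-") seq <- revcomp(seq)
  seq
}

#' Post-transcriptional target: longest mature isoform of a promoter
#'
#' Concatenates the exon sequences (5' to 3', strand-aware) of the transcript
#' with the maximal mature (spliced) length among the promoter's transcripts;
#' ties are broken by the lexicographically smallest transcript_id.
#'
#' @inheritParams build_cotx_target
#' @return A `target_sequence` with mode "post".
#' @export
build_posttx_target <- function(gene, promoter_id, genome) {
  idx <- match(promoter_id, gene$promoters$promoter_id)
  if (is.na(idx)) stop("unknown promoter_id: ", promoter_id, call. = FALSE)
  txs <- Filter(function(tx) tx$promoter_id == promoter_id, gene$transcripts)
  if (length(txs) == 0) stop("promoter ", promoter_id, " has no transcripts",
                             call. = FALSE)
  lens <- vapply(txs, mature_length, 0L)
  ids <- vapply(txs, function(tx) tx$transcript_id, "")
  best <- txs[[order(-lens, ids)[1]]]
  seq <- spliced_sequence(best, gene, genome)
  iv <- best$exons
  colnames(iv) <- c("start", "end")
  structure(list(promoter_id = promoter_id, mode = "post", sequence = seq,
                 source_intervals = iv, chrom = gene$chrom,
                 strand = gene$strand, transcript_id = best$transcript_id,
                 length = nchar(seq)),
            class = "target_sequence")
}

#' @export
print.target_sequence <- function(x, ...) {
  cat(sprintf("<target_sequence> %s [%s] %d nt (%s%s)\n", x$promoter_id,
              x$mode, x$length, x$chrom, x$strand))
  invisible(x)
}

#' Build a target set for a whole knockdown background
#'
#' One target per promoter in `promoter_ids`, in the requested mode.
#'
#' @param genes Named list of `gene_model`s.
#' @param promoter_ids Character vector of promoters.
#' @param genome Genome assembly.
#' @param mode "co" or "post".
#' @param window_len Co-mode window length.
#' @return Named character vector of sequences keyed by promoter_id.
#' @export
build_target_set <- function(genes, promoter_ids, genome,
                             mode = c("co", "post"), window_len = 1000L) {
  mode <- match.arg(mode)
  out <- vapply(promoter_ids, function(pid) {
    g <- find_promoter(genes, pid)
    t <- if (mode == "co") build_cotx_target(g, pid, genome, window_len)
         else build_posttx_target(g, pid, genome)
    t$sequence
  }, "")
  setNames(out, promoter_ids)
}

#' Promoter-centered intervals for co-localization
#'
#' One interval `[TSS - flank, TSS + flank)` per promoter, clipped to
#' chromosome bounds. These are the query intervals tested for co-localization
#' with RNA-chromatin contact peaks.
#'
#' @param genes Named list of `gene_model`s.
#' @param flank Flank in bp on each side of the TSS (> 0).
#' @param genome Optional genome for bound clipping (named character or
#'   named sizes); if NULL no upper clipping is applied.
#' @param promoter_ids Optional subset of promoters.
#' @return A `peak_set` with one row per promoter and a `promoter_id` column.
#' @export
promoter_intervals <- function(genes, flank = 500L, genome = NULL,
                               promoter_ids = NULL) {
  stopifnot(flank >= 1L)
  sizes <- if (is.null(genome)) NULL
           else if (is.character(genome)) chrom_sizes(genome) else genome
  rows <- do.call(rbind, lapply(genes, function(g) {
    data.frame(chrom = g$chrom, tss = g$promoters$tss,
               promoter_id = g$promoters$promoter_id, stringsAsFactors = FALSE)
  }))
  if (!is.null(promoter_ids))
    rows <- rows[rows$promoter_id %in% promoter_ids, , drop = FALSE]
  start <- pmax(rows$tss - flank, 0L)
  end <- rows$tss + flank
  if (!is.null(sizes)) end <- pmin(end, sizes[rows$chrom])
  ps <- peak_set(rows$chrom, start, end)
  ps$promoter_id <- rows$promoter_id
  ps
}
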