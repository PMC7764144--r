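# I/O for the standard formats touched by the pipeline, plus the shared
# coordinate conventions. Everything internal is 0-based half-open; GTF is
# the only 1-based closed dialect and is converted at this boundary. RNA
# inputs (U) are normalized to the DNA alphabet (T) on read.

#' Read a FASTA file into a named vector of normalized DNA sequences
#'
#' Sequences are uppercased and U is mapped to T, so all downstream pairing
#' logic is defined on A, C, G, T (N is tolerated in genomes). Duplicate
#' record ids are rejected. The id is the first whitespace-delimited token of
#' the header.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per record, in file order.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("FASTA parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- chartr("u", "t", toupper(as.character(set)))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    chars <- unique(unlist(strsplit(gsub("[ACGTN]", "", seqs[bad]), "")))
    stop("illegal sequence character(s) ", paste(chars, collapse = ","),
         " in record(s): ", paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  setNames(seqs, ids)
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = width)
  invisible(path)
}

#' Chromosome sizes of a genome assembly
#'
#' @param genome Named character vector as returned by [read_fasta()].
#' @return Named integer vector of sequence lengths in bp.
#' @export
chrom_sizes <- function(genome) setNames(nchar(genome), names(genome))

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## ---- gene models -----------------------------------------------------------

new_gene_model <- function(gene_id, chrom, strand, promoters, transcripts) {
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 promoters = promoters, transcripts = transcripts),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s(%s): %d promoter(s), %d transcript(s)\n",
              x$gene_id, x$chrom, x$strand, nrow(x$promoters),
              length(x$transcripts)))
  invisible(x)
}

validate_gene_model <- function(g) {
  stopifnot(inherits(g, "gene_model"), g$strand %in% c("+", "-"))
  for (tx in g$transcripts) {
    ex <- tx$exons
    stopifnot(is.matrix(ex), ncol(ex) == 2, all(ex[, 1] < ex[, 2]))
    if (nrow(ex) > 1) {
      stopifnot(all(diff(ex[, 1]) > 0), all(ex[-nrow(ex), 2] <= ex[-1, 1]))
    }
    tss <- if (g$strand == "+") ex[1, 1] else ex[nrow(ex), 2] - 1L
    ptss <- g$promoters$tss[match(tx$promoter_id, g$promoters$promoter_id)]
    if (is.na(ptss) || ptss != tss)
      stop("transcript ", tx$transcript_id, " 5' end (", tss,
           ") does not match its promoter TSS (", ptss, ")", call. = FALSE)
  }
  invisible(g)
}

# Strand-aware TSS of an exon matrix (0-based half-open rows, sorted).
exon_tss <- function(exons, strand) {
  if (strand == "+") exons[1, 1] else exons[nrow(exons), 2] - 1L
}

#' Read gene models from a GTF file
#'
#' GTF 1-based closed coordinates are converted to the internal 0-based
#' half-open convention. Transcripts sharing a strand-aware TSS (the exact
#' coordinate of the transcript 5' end) are grouped under one promoter;
#' promoter ids are `<gene_id>_p<k>` with k assigned in ascending TSS order.
#'
#' @param path Path to a GTF file with `gene_id` and `transcript_id`
#'   attributes and `exon` features.
#' @return Named list of `gene_model` objects (keyed by gene_id).
#' @export
read_gtf <- function(path) {
  stopifnot(file.exists(path))
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("GTF parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  md <- S4Vectors::mcols(gr)
  is_exon <- !is.na(md$type) & md$type == "exon"
  tx_all <- unique(stats::na.omit(md$transcript_id))
  tx_exon <- unique(md$transcript_id[is_exon])
  orphans <- setdiff(tx_all, tx_exon)
  if (length(orphans) > 0)
    stop("transcript(s) without exons: ", paste(orphans, collapse = ", "),
         call. = FALSE)
  ex <- gr[is_exon]
  exd <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex) - 1L,   # to 0-based half-open
    end   = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    gene_id = S4Vectors::mcols(ex)$gene_id,
    transcript_id = S4Vectors::mcols(ex)$transcript_id,
    stringsAsFactors = FALSE)
  if (any(exd$strand == "*"))
    stop("exon without strand in ", path, call. = FALSE)

  models <- list()
  for (gid in unique(exd$gene_id)) {
    gd <- exd[exd$gene_id == gid, , drop = FALSE]
    txs <- list()
    tss_of_tx <- c()
    for (tid in unique(gd$transcript_id)) {
      td <- gd[gd$transcript_id == tid, , drop = FALSE]
      if (length(unique(td$strand)) > 1)
        stop("mixed strands within transcript ", tid, call. = FALSE)
      if (length(unique(td$chrom)) > 1)
        stop("multiple chromosomes within transcript ", tid, call. = FALSE)
      em <- as.matrix(td[order(td$start), c("start", "end")])
      dimnames(em) <- NULL
      storage.mode(em) <- "integer"
      txs[[tid]] <- list(transcript_id = tid, promoter_id = NA_character_,
                         exons = em)
      tss_of_tx[tid] <- exon_tss(em, td$strand[1])
    }
    strand <- gd$strand[1]
    if (length(unique(gd$strand)) > 1)
      stop("mixed strands within gene ", gid, call. = FALSE)
    utss <- sort(unique(tss_of_tx))
    pid <- setNames(sprintf("%s_p%d", gid, seq_along(utss)), as.character(utss))
    for (tid in names(txs))
      txs[[tid]]$promoter_id <- pid[[as.character(tss_of_tx[tid])]]
    promoters <- data.frame(promoter_id = unname(pid), tss = utss,
                            stringsAsFactors = FALSE)
    models[[gid]] <- validate_gene_model(
      new_gene_model(gid, gd$chrom[1], strand, promoters, txs))
  }
  models
}

#' Write gene models to GTF
#'
#' Emits `transcript` and `exon` features with `gene_id` and `transcript_id`
#' attributes, converting internal 0-based half-open coordinates back to GTF
#' 1-based closed. Deterministic row order (gene, transcript, exon start).
#'
#' @param models List of `gene_model` objects.
#' @param path Output path.
#' @export
write_gtf <- function(models, path) {
  lines <- character(0)
  for (g in models[order(names(models))]) {
    for (tid in sort(names(g$transcripts))) {
      tx <- g$transcripts[[tid]]
      attrs <- sprintf('gene_id "%s"; transcript_id "%s";', g$gene_id, tid)
      span <- c(min(tx$exons[, 1]), max(tx$exons[, 2]))
      lines <- c(lines,
        sprintf("%s\tlncmode\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                g$chrom, span[1] + 1L, span[2], g$strand, attrs),
        sprintf("%s\tlncmode\texon\t%d\t%d\t.\t%s\t.\t%s",
                g$chrom, tx$exons[, 1] + 1L, tx$exons[, 2], g$strand, attrs))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

## ---- peak sets (BED) -------------------------------------------------------

#' Construct a peak set
#'
#' @param chrom,start,end Vectors defining 0-based half-open intervals.
#' @param score Optional numeric score.
#' @return A `peak_set` data.frame.
#' @export
peak_set <- function(chrom, start, end, score = NULL) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (length(start) > 0 && any(start >= end))
    stop("peak intervals must satisfy start < end", call. = FALSE)
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), stringsAsFactors = FALSE)
  if (!is.null(score)) df$score <- as.numeric(score)
  class(df) <- c("peak_set", "data.frame")
  df
}

#' Read a BED3+ file into a peak set
#'
#' BED is 0-based half-open, matching the internal convention, so no
#' coordinate shift occurs. Intervals with start >= end are rejected.
#'
#' @param path Path to a BED file.
#' @return A `peak_set` data.frame with columns chrom, start, end (and score
#'   if present in the file).
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  gr <- tryCatch(
    rtracklayer::import(path, format = "bed"),
    error = function(e) stop("BED parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (any(GenomicRanges::width(gr) < 1))
    stop("BED interval with start >= end in ", path, call. = FALSE)
  sc <- S4Vectors::mcols(gr)$score
  peak_set(as.character(GenomicRanges::seqnames(gr)),
           GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
           score = if (!is.null(sc) && !all(is.na(sc))) sc else NULL)
}

#' Write a peak set to BED
#'
#' @param peaks A `peak_set`.
#' @param path Output path.
#' @export
write_bed <- function(peaks, path) {
  gr <- peaks_to_granges(peaks)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

# peak_set (0-based half-open) -> GRanges (1-based closed)
peaks_to_granges <- function(peaks) {
  gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start + 1L, peaks$end))
  if (!is.null(peaks$score)) S4Vectors::mcols(gr)$score <- peaks$score
  gr
}

## ---- knockdown tables ------------------------------------------------------

#' Construct a knockdown table
#'
#' One ASO knockdown experiment: per-promoter log2 fold-change and DEG flag.
#' All rows form the tested background; DEG rows are the flagged subset.
#'
#' @param promoter_id,log2fc,deg_flag Parallel vectors.
#' @param aso_id,lncrna_id Experiment identifiers (attributes).
#' @return A `knockdown_table` data.frame.
#' @export
knockdown_table <- function(promoter_id, log2fc, deg_flag,
                            aso_id = NA_character_, lncrna_id = NA_character_) {
  stopifnot(length(promoter_id) == length(log2fc),
            length(log2fc) == length(deg_flag), !anyDuplicated(promoter_id))
  df <- data.frame(promoter_id = as.character(promoter_id),
                   log2fc = as.numeric(log2fc),
                   deg_flag = as.logical(deg_flag), stringsAsFactors = FALSE)
  attr(df, "aso_id") <- aso_id
  attr(df, "lncrna_id") <- lncrna_id
  class(df) <- c("knockdown_table", "data.frame")
  df
}

#' Read a knockdown table from TSV
#'
#' Requires header columns `promoter_id`, `log2fc`, `deg_flag`; `deg_flag`
#' is parsed strictly from {0, 1, true, false} (case-insensitive).
#'
#' @param path Path to a TSV file.
#' @param aso_id,lncrna_id Experiment identifiers; if NULL, taken from
#'   optional `aso_id` / `lncrna_id` columns when present.
#' @return A `knockdown_table`.
#' @export
read_knockdown_tsv <- function(path, aso_id = NULL, lncrna_id = NULL) {
  stopifnot(file.exists(path))
  df <- read.delim(path, colClasses = "character", check.names = FALSE)
  for (col in c("promoter_id", "log2fc", "deg_flag"))
    if (!col %in% names(df))
      stop("missing column '", col, "' in ", path, call. = FALSE)
  lfc <- suppressWarnings(as.numeric(df$log2fc))
  if (any(is.na(lfc)))
    stop("unparseable log2fc at row(s): ",
         paste(which(is.na(lfc)), collapse = ", "), call. = FALSE)
  flag_raw <- tolower(df$deg_flag)
  ok <- flag_raw %in% c("0", "1", "true", "false")
  if (!all(ok))
    stop("unparseable deg_flag at row(s): ",
         paste(which(!ok), collapse = ", "), call. = FALSE)
  flag <- flag_raw %in% c("1", "true")
  if (is.null(aso_id)) aso_id <- if ("aso_id" %in% names(df)) df$aso_id[1] else NA_character_
  if (is.null(lncrna_id)) lncrna_id <- if ("lncrna_id" %in% names(df)) df$lncrna_id[1] else NA_character_
  knockdown_table(df$promoter_id, lfc, flag, aso_id, lncrna_id)
}

#' Write a knockdown table to TSV
#'
#' @param kd A `knockdown_table`.
#' @param path Output path.
#' @export
write_knockdown_tsv <- function(kd, path) {
  out <- as.data.frame(kd)[order(kd$promoter_id), , drop = FALSE]
  out$deg_flag <- as.integer(out$deg_flag)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a duplex hit table to TSV
#'
#' Header row, deterministic row order (sorted by target then query id).
#'
#' @param hits Data.frame of duplex hits (see [predict_interactions()]).
#' @param path Output path.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- as.data.frame(hits)
  if (nrow(out) > 0) out <- out[order(out$target_id, out$query_id), , drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a generic result table to TSV
#'
#' @param df Data.frame of results; sorted by its first column for
#'   deterministic output.
#' @param path Output path.
#' @export
write_results_tsv <- function(df, path) {
  out <- as.data.frame(df)
  if (nrow(out) > 0) out <- out[order(out[[1]]), , drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
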