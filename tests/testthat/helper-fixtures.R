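# Shared fixtures: tiny hand-built genomes and gene models with known
# coordinates, plus independent R-side oracles used against the compiled
# search paths.

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# One gene, one promoter; exons given as a 0-based half-open matrix.
toy_gene <- function(gene_id = "gX", chrom = "chr1", strand = "+", exons,
                     extra_tx = NULL) {
  em <- matrix(as.integer(exons), ncol = 2, byrow = TRUE)
  tss <- if (strand == "+") em[1, 1] else em[nrow(em), 2] - 1L
  txs <- list()
  t1 <- paste0(gene_id, "_t1")
  txs[[t1]] <- list(transcript_id = t1, promoter_id = paste0(gene_id, "_p1"),
                    exons = em)
  if (!is.null(extra_tx)) {
    em2 <- matrix(as.integer(extra_tx), ncol = 2, byrow = TRUE)
    t2 <- paste0(gene_id, "_t2")
    txs[[t2]] <- list(transcript_id = t2, promoter_id = paste0(gene_id, "_p1"),
                      exons = em2)
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 promoters = data.frame(promoter_id = paste0(gene_id, "_p1"),
                                        tss = tss, stringsAsFactors = FALSE),
                 transcripts = txs),
            class = "gene_model")
}

# Independent oracle: best ungapped antiparallel segment over all diagonals,
# Kadane in plain R. Returns score plus the achieving intervals.
oracle_best_segment <- function(q, t, match = 2, wobble = 1, mismatch = -3) {
  qv <- strsplit(q, "")[[1]]
  tv <- strsplit(t, "")[[1]]
  m <- length(qv); n <- length(tv)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ps <- function(a, b) {
    if (comp[[a]] == b) match
    else if ((a == "G" && b == "T") || (a == "T" && b == "G")) wobble
    else mismatch
  }
  best <- 0; best_iv <- NULL
  for (d in 0:(m + n - 2)) {
    ilo <- max(0, d - (n - 1)); ihi <- min(m - 1, d)
    run <- 0; run_start <- ilo
    for (i in ilo:ihi) {
      s <- ps(qv[i + 1], tv[d - i + 1])
      if (run <= 0) { run <- s; run_start <- i } else run <- run + s
      if (run > best) {
        best <- run
        best_iv <- c(q_start = run_start, q_end = i + 1,
                     t_start = d - i, t_end = d - run_start + 1)
      }
    }
  }
  list(score = best, interval = best_iv)
}

# Score of a specific antiparallel alignment interval under the extension
# scoring, recomputed independently of the C++ code.
oracle_interval_score <- function(q, t, q_start, q_end, t_start, t_end,
                                  match = 2, wobble = 1, mismatch = -3) {
  qs <- strsplit(substr(q, q_start + 1, q_end), "")[[1]]
  ts <- rev(strsplit(substr(t, t_start + 1, t_end), "")[[1]])
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  sum(mapply(function(a, b) {
    if (comp[[a]] == b) match
    else if ((a == "G" && b == "T") || (a == "T" && b == "G")) wobble
    else mismatch
  }, qs, ts))
}

# Longest exact reverse-complement run between two sequences, by exhaustive
# word scan (independent of the seed machinery).
longest_rc_run <- function(a, b) {
  brc <- rc(b)
  na <- nchar(a); nb <- nchar(brc)
  has_run <- function(len) {
    words <- unique(substring(brc, 1:(nb - len + 1), len:nb))
    any(vapply(words, function(w) grepl(w, a, fixed = TRUE), TRUE))
  }
  # existence of a shared word is monotone in length: binary search
  lo <- 0; hi <- min(na, nb)
  while (lo < hi) {
    mid <- ceiling((lo + hi) / 2)
    if (has_run(mid)) lo <- mid else hi <- mid - 1
  }
  lo
}

dinuc_counts <- function(x) {
  v <- strsplit(x, "")[[1]]
  table(paste0(v[-length(v)], v[-1]))
}
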