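# Synthetic study generator: genomes, gene models, a lncRNA with planted
# mode-specific antisense signal, knockdown DEG tables and contact-peak sets
# with known ground truth. The mode contrast is structural: co-mode signal
# is planted inside an intron of the 5' 1 kb of the nascent transcript
# (absent from the mature mRNA); post-mode signal spans an exon-exon
# junction of the mature transcript (not contiguous in the genomic 5'
# window). Each generator draws from its own RNG stream derived from the
# master seed by a fixed offset, so regenerating one artifact does not
# perturb the others.

#' Simulation configuration
#'
#' Defaults define the study conditions used throughout the package's tests:
#' a small two-chromosome genome of 50 multi-exon genes, 10 true targets
#' carrying planted antisense signal, knockdown effects of -1.5 +/- 0.5
#' log2 units against a N(0, 0.3) null with a 5% DEG false-positive rate,
#' and contact peaks at 80% of true-target promoters over 50 background
#' peaks.
#'
#' @param n_genes Number of genes.
#' @param n_chroms Number of chromosomes.
#' @param gene_length_range Genomic gene span range, bp.
#' @param exon_count_range Range of exons per gene.
#' @param gc_content GC fraction of all generated sequence.
#' @param planted_mode "co", "post" or "none".
#' @param n_true_targets Number of genes carrying planted signal.
#' @param planted_match_len Length of each planted antisense segment, bp.
#' @param planted_mutation_rate Per-base substitution rate applied to
#'   planted segments.
#' @param effect_log2fc_mean,effect_log2fc_sd Knockdown effect on true
#'   targets (negative mean = down-regulation on knockdown).
#' @param null_log2fc_sd Null log2FC spread of unaffected genes.
#' @param deg_alpha Two-sided null tail rate at which unaffected genes are
#'   flagged DEG (false-positive contamination).
#' @param peak_true_frac Fraction of true targets receiving a contact peak.
#' @param peak_window Peak centers fall within +/- this many bp of the TSS.
#' @param peak_width Width of each contact peak, bp.
#' @param n_background_peaks Peaks placed uniformly on the genome.
#' @param lncrna_length Background length of the generated lncRNA, nt.
#' @param chrom_length Optional fixed chromosome length; auto-sized when
#'   NULL, error if genes cannot be placed without overlap.
#' @param seed Master seed; generator streams are seed + 0..3.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 50L, n_chroms = 2L,
                       gene_length_range = c(2200L, 5200L),
                       exon_count_range = c(3L, 4L), gc_content = 0.5,
                       planted_mode = c("co", "post", "none"),
                       n_true_targets = 10L, planted_match_len = 40L,
                       planted_mutation_rate = 0.05,
                       effect_log2fc_mean = -1.5, effect_log2fc_sd = 0.5,
                       null_log2fc_sd = 0.3, deg_alpha = 0.05,
                       peak_true_frac = 0.8, peak_window = 500L,
                       peak_width = 400L, n_background_peaks = 50L,
                       lncrna_length = 2000L, chrom_length = NULL,
                       seed = 1L) {
  planted_mode <- match.arg(planted_mode)
  stopifnot(gc_content >= 0, gc_content <= 1,
            planted_mutation_rate >= 0, planted_mutation_rate <= 1,
            deg_alpha > 0, deg_alpha < 1,
            peak_true_frac >= 0, peak_true_frac <= 1,
            n_true_targets <= n_genes, planted_match_len >= 8L,
            length(gene_length_range) == 2, length(exon_count_range) == 2,
            exon_count_range[1] >= 1)
  structure(as.list(environment()), class = "sim_config")
}

random_seq <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Draw one gene's exon/intron lengths (transcript order). Multi-exon genes
# use exons U(200,400) and introns U(800,1200), rescaled (introns floored at
# 600) if the span falls outside gene_length_range; this keeps intron 1
# inside the 5' 1 kb and pushes the last junction's upstream exon end beyond
# it, the structure the planted-mode contrast relies on.
draw_structure <- function(n_exons, config) {
  if (n_exons == 1) {
    len <- as.integer(round(runif(1, config$gene_length_range[1],
                                  config$gene_length_range[2])))
    return(list(exons = len, introns = integer(0)))
  }
  ex <- round(runif(n_exons, 200, 400))
  intr <- round(runif(n_exons - 1, 800, 1200))
  total <- sum(ex) + sum(intr)
  lo <- config$gene_length_range[1]; hi <- config$gene_length_range[2]
  if (total < lo || total > hi) {
    target <- max(lo, min(hi, total))
    scale <- (target - sum(ex)) / sum(intr)
    intr <- pmax(600L, round(intr * scale))
  }
  list(exons = as.integer(ex), introns = as.integer(intr))
}

#' Simulate a genome and gene models
#'
#' I.i.d. bases at the configured GC content; genes placed without overlap
#' on random strands, each with one promoter; 30% of multi-exon genes get a
#' second, shorter isoform (one internal exon skipped) sharing the same TSS.
#'
#' @param config A [sim_config()].
#' @return List with elements `genome` (named character) and `genes` (named
#'   list of `gene_model`s).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 0L, {
    n_exons <- sample(seq(config$exon_count_range[1],
                          config$exon_count_range[2]),
                      config$n_genes, replace = TRUE)
    if (config$exon_count_range[2] > 1 && all(n_exons == 1))
      n_exons[1] <- 2L
    structures <- lapply(n_exons, draw_structure, config = config)
    spans <- vapply(structures, function(s) as.integer(sum(s$exons) + sum(s$introns)), 0L)
    chrom_of <- rep(seq_len(config$n_chroms), length.out = config$n_genes)
    gap <- 1000L
    needed <- vapply(seq_len(config$n_chroms), function(ci) {
      idx <- which(chrom_of == ci)
      sum(spans[idx]) + gap * (length(idx) + 1L)
    }, 0L)
    clen <- if (is.null(config$chrom_length)) needed + 500L
            else rep(as.integer(config$chrom_length), config$n_chroms)
    if (any(clen < needed))
      stop("genes cannot be placed without overlap; increase chrom_length ",
           "(need >= ", max(needed), " bp)", call. = FALSE)
    chroms <- setNames(vapply(clen, random_seq, "", gc = config$gc_content),
                       sprintf("chr%d", seq_len(config$n_chroms)))
    genes <- list()
    offset <- rep(gap, config$n_chroms)
    for (i in seq_len(config$n_genes)) {
      gid <- sprintf("g%03d", i)
      ci <- chrom_of[i]
      st <- structures[[i]]
      strand <- sample(c("+", "-"), 1)
      gstart <- offset[ci]
      offset[ci] <- offset[ci] + spans[i] + gap
      # genomic exon intervals; transcript order = genomic order on '+',
      # reversed on '-': draw structure in transcript order then lay out
      ex_t <- st$exons; in_t <- st$introns
      lens_genomic <- if (strand == "+") {
        list(ex = ex_t, intr = in_t)
      } else {
        list(ex = rev(ex_t), intr = rev(in_t))
      }
      pos <- gstart
      exm <- matrix(0L, nrow = length(lens_genomic$ex), ncol = 2)
      for (k in seq_along(lens_genomic$ex)) {
        exm[k, ] <- c(pos, pos + lens_genomic$ex[k])
        pos <- pos + lens_genomic$ex[k]
        if (k <= length(lens_genomic$intr)) pos <- pos + lens_genomic$intr[k]
      }
      tss <- exon_tss(exm, strand)
      pid <- paste0(gid, "_p1")
      txs <- list()
      t1 <- paste0(gid, "_t1")
      txs[[t1]] <- list(transcript_id = t1, promoter_id = pid, exons = exm)
      if (nrow(exm) >= 3 && runif(1) < 0.3) {
        skip <- sample(2:(nrow(exm) - 1), 1)
        t2 <- paste0(gid, "_t2")
        txs[[t2]] <- list(transcript_id = t2, promoter_id = pid,
                          exons = exm[-skip, , drop = FALSE])
      }
      genes[[gid]] <- new_gene_model(
        gid, names(chroms)[ci], strand,
        data.frame(promoter_id = pid, tss = tss, stringsAsFactors = FALSE),
        txs)
    }
    list(genome = chroms, genes = genes)
  })
}

# Exon/intron lengths of the main transcript in transcript (5'->3') order.
tx_order_lengths <- function(gene, tx) {
  ex <- tx$exons[, 2] - tx$exons[, 1]
  n <- length(ex)
  intr <- if (n > 1) tx$exons[-1, 1] - tx$exons[-n, 2] else integer(0)
  if (gene$strand == "-") { ex <- rev(ex); intr <- rev(intr) }
  list(ex = ex, intr = intr)
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "")[[1]]
  hit <- runif(length(v)) < rate
  if (any(hit)) {
    v[hit] <- vapply(v[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  }
  paste(v, collapse = "")
}

#' Plant mode-specific antisense signal into a synthetic lncRNA
#'
#' The lncRNA is a random background sequence carrying, for each true
#' target, a planted segment that is the (optionally mutated) reverse
#' complement of a mode-specific source window: in co mode a fully intronic
#' window inside the first 1 kb of the nascent transcript (sequence absent
#' from the mature mRNA); in post mode a window of the mature transcript
#' centered on the 3'-most exon-exon junction (sequence not contiguous in
#' the genomic 5' window). Mode "none" plants nothing.
#'
#' @param genome,genes Output of [simulate_genome()].
#' @param config A [sim_config()].
#' @return List with `lncrna` (sequence) and `truth` (a `sim_truth`:
#'   true_target_ids, planted_mode, coords data.frame with the planted
#'   intervals on query and target, 0-based half-open, target coordinates in
#'   the mode's transcript space).
#' @export
plant_lncrna <- function(genome, genes, config) {
  stopifnot(inherits(config, "sim_config"))
  mode <- config$planted_mode
  plen <- config$planted_match_len
  with_seed(config$seed + 1L, {
    lnc <- random_seq(config$lncrna_length, config$gc_content)
    if (mode == "none") {
      return(list(lncrna = lnc,
                  truth = structure(list(true_target_ids = character(0),
                                         planted_mode = "none",
                                         coords = NULL), class = "sim_truth")))
    }
    eligible <- character(0)
    windows <- list()
    for (g in genes) {
      pid <- g$promoters$promoter_id[1]
      tx <- g$transcripts[[1]]
      tl <- tx_order_lengths(g, tx)
      if (mode == "co") {
        if (length(tl$intr) == 0) next
        lo <- tl$ex[1]
        hi <- min(tl$ex[1] + tl$intr[1], 1000L) - plen
        if (hi <= lo) next
        eligible <- c(eligible, pid)
        windows[[pid]] <- list(gene = g, lo = lo, hi = hi)
      } else {
        post <- build_posttx_target(g, pid, genome)
        txb <- g$transcripts[[post$transcript_id]]
        tlb <- tx_order_lengths(g, txb)
        if (length(tlb$ex) < 2) next
        juncs <- cumsum(tlb$ex)[-length(tlb$ex)]
        fit <- juncs[juncs - floor(plen / 2) >= 0 &
                     juncs + ceiling(plen / 2) <= sum(tlb$ex)]
        if (length(fit) == 0) next
        eligible <- c(eligible, pid)
        windows[[pid]] <- list(gene = g, junction = fit[length(fit)],
                               mature = post$sequence)
      }
    }
    if (length(eligible) < config$n_true_targets)
      stop("only ", length(eligible), " genes satisfy the '", mode,
           "' structural requirement; need ", config$n_true_targets,
           call. = FALSE)
    targets <- sort(sample(eligible, config$n_true_targets))
    slots <- round(config$lncrna_length *
                     seq_along(targets) / (length(targets) + 1))
    if (config$lncrna_length < (config$n_true_targets + 1) * plen)
      stop("lncrna_length too short for the requested planted segments",
           call. = FALSE)
    coords <- list()
    for (i in seq_along(targets)) {
      pid <- targets[i]
      wi <- windows[[pid]]
      if (mode == "co") {
        nascent <- build_cotx_target(wi$gene, pid, genome, 1000L)$sequence
        t_start <- sample(seq(wi$lo, wi$hi), 1)
        src <- substr(nascent, t_start + 1L, t_start + plen)
      } else {
        t_start <- wi$junction - floor(plen / 2)
        src <- substr(wi$mature, t_start + 1L, t_start + plen)
      }
      seg <- mutate_seq(revcomp(src), config$planted_mutation_rate)
      q_start <- slots[i] - floor(plen / 2)
      substr(lnc, q_start + 1L, q_start + plen) <- seg
      coords[[pid]] <- data.frame(
        promoter_id = pid, mode = mode, q_start = q_start,
        q_end = q_start + plen, t_start = t_start, t_end = t_start + plen,
        stringsAsFactors = FALSE)
    }
    list(lncrna = lnc,
         truth = structure(list(true_target_ids = targets,
                                planted_mode = mode,
                                coords = do.call(rbind, coords)),
                           class = "sim_truth"))
  })
}

#' Simulate a knockdown DEG table
#'
#' True targets draw log2FC ~ N(effect_mean, effect_sd) (down-regulation on
#' knockdown by default); all other promoters ~ N(0, null_sd). The DEG flag
#' applies the same rule to every row: |log2fc| above the two-sided
#' (1 - deg_alpha) null quantile, so true targets are almost always flagged
#' while null promoters contaminate the DEG list at rate ~ deg_alpha.
#'
#' @param genes Named list of `gene_model`s.
#' @param truth A `sim_truth`.
#' @param config A [sim_config()].
#' @return A `knockdown_table` over all promoters.
#' @export
simulate_knockdown <- function(genes, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 2L, {
    pids <- unlist(lapply(genes, function(g) g$promoters$promoter_id),
                   use.names = FALSE)
    pids <- sort(pids)
    is_true <- pids %in% truth$true_target_ids
    lfc <- numeric(length(pids))
    lfc[is_true] <- rnorm(sum(is_true), config$effect_log2fc_mean,
                          config$effect_log2fc_sd)
    lfc[!is_true] <- rnorm(sum(!is_true), 0, config$null_log2fc_sd)
    thr <- config$null_log2fc_sd * qnorm(1 - config$deg_alpha / 2)
    knockdown_table(pids, lfc, abs(lfc) > thr,
                    aso_id = sprintf("ASO_sim_%d", config$seed),
                    lncrna_id = "lnc_sim")
  })
}

#' Simulate RNA-chromatin contact peaks
#'
#' A fraction `peak_true_frac` of true targets receives one peak whose
#' center is uniform within +/- `peak_window` of the TSS; plus
#' `n_background_peaks` peaks placed uniformly on the genome (chromosome
#' chosen proportional to length). Peaks are `peak_width` bp, clipped to
#' chromosome bounds.
#'
#' @param genes Named list of `gene_model`s.
#' @param truth A `sim_truth`.
#' @param config A [sim_config()].
#' @param genome Genome assembly (for chromosome sizes).
#' @return A `peak_set`, sorted by chromosome and start.
#' @export
simulate_contacts <- function(genes, truth, config, genome) {
  stopifnot(inherits(config, "sim_config"))
  sizes <- chrom_sizes(genome)
  half <- floor(config$peak_width / 2)
  with_seed(config$seed + 3L, {
    rows <- list()
    for (pid in truth$true_target_ids) {
      if (runif(1) > config$peak_true_frac) next
      g <- find_promoter(genes, pid)
      tss <- g$promoters$tss[match(pid, g$promoters$promoter_id)]
      center <- tss + round(runif(1, -config$peak_window, config$peak_window))
      s <- max(0L, center - half)
      e <- min(sizes[[g$chrom]], center + half)
      rows[[length(rows) + 1L]] <- data.frame(chrom = g$chrom, start = s,
                                              end = e)
    }
    if (config$n_background_peaks > 0) {
      ch <- sample(names(sizes), config$n_background_peaks, replace = TRUE,
                   prob = sizes / sum(sizes))
      s <- floor(runif(config$n_background_peaks) *
                   (sizes[ch] - config$peak_width))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = s, end = s + config$peak_width)
    }
    df <- do.call(rbind, rows)
    if (is.null(df) || nrow(df) == 0) return(peak_set(character(0), integer(0), integer(0)))
    df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
    peak_set(df$chrom, df$start, df$end)
  })
}

#' Generate a complete synthetic dataset
#'
#' Runs all four generators and optionally writes genome.fa, genes.gtf,
#' lncrna.fa, knockdown.tsv, peaks.bed and truth.json to a directory.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return List: genome, genes, lncrna, truth, kd, peaks, config.
#' @export
simulate_dataset <- function(config = sim_config(), out_dir = NULL) {
  ga <- simulate_genome(config)
  pl <- plant_lncrna(ga$genome, ga$genes, config)
  kd <- simulate_knockdown(ga$genes, pl$truth, config)
  peaks <- simulate_contacts(ga$genes, pl$truth, config, ga$genome)
  out <- list(genome = ga$genome, genes = ga$genes, lncrna = pl$lncrna,
              truth = pl$truth, kd = kd, peaks = peaks, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(ga$genome, file.path(out_dir, "genome.fa"))
    write_gtf(ga$genes, file.path(out_dir, "genes.gtf"))
    write_fasta(setNames(pl$lncrna, "lnc_sim"),
                file.path(out_dir, "lncrna.fa"))
    write_knockdown_tsv(kd, file.path(out_dir, "knockdown.tsv"))
    if (nrow(peaks) > 0) write_bed(peaks, file.path(out_dir, "peaks.bed"))
    truth_json <- list(
      true_target_ids = pl$truth$true_target_ids,
      planted_mode = pl$truth$planted_mode,
      coords = pl$truth$coords,
      seed = config$seed)
    jsonlite::write_json(truth_json, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
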