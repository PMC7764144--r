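# Antisense RNA:RNA duplex prediction: word seeding, ungapped x-drop
# extension, nearest-neighbor hybridization energies, and length/GC-aware
# Gumbel significance calibrated on dinucleotide-preserving shuffles.
#
# The engine is a documented reconstruction of the behavioral contract of
# antisense-search tools of this class (hits scored by duplex free energy,
# p-values corrected for the lengths and GC contents of both molecules);
# every constant lives in duplex_params().

#' Tunable constants of the duplex predictor
#'
#' @param word_len Seed word length (exact reverse-complement matches).
#' @param xdrop X-drop threshold for ungapped extension, in extension-score
#'   units.
#' @param match,wobble,mismatch Extension scores for Watson-Crick pairs,
#'   G:T (G:U) wobble pairs, and mismatches.
#' @param exact_limit Pairs with both sequences at or below this length are
#'   scanned exhaustively over every antiparallel diagonal instead of
#'   requiring a word seed, making the search exact for short sequences.
#' @param n_null Null pairs per GC bin for Gumbel calibration.
#' @param hit_alpha Adjusted-p threshold defining a "strong" hit downstream.
#' @param initiation Duplex initiation penalty, kcal/mol.
#' @param wobble_stack_penalty Destabilization added to a stack per wobble
#'   pair it contains, kcal/mol (stacks are clamped at <= 0).
#' @param mismatch_penalty Fixed destabilizing term per mismatched position,
#'   kcal/mol; mismatches also break stacking.
#' @return A list of parameters.
#' @export
duplex_params <- function(word_len = 8L, xdrop = 12, match = 2, wobble = 1,
                          mismatch = -3, exact_limit = 100L, n_null = 200L,
                          hit_alpha = 0.01, initiation = 4.09,
                          wobble_stack_penalty = 0.9, mismatch_penalty = 2.0) {
  stopifnot(word_len >= 4L, xdrop >= 0, n_null >= 50L)
  list(word_len = as.integer(word_len), xdrop = xdrop, match = match,
       wobble = wobble, mismatch = mismatch,
       exact_limit = as.integer(exact_limit), n_null = as.integer(n_null),
       hit_alpha = hit_alpha, initiation = initiation,
       wobble_stack_penalty = wobble_stack_penalty,
       mismatch_penalty = mismatch_penalty)
}

# RNA/RNA Watson-Crick nearest-neighbor stack free energies (dG37, kcal/mol),
# indexed by the query-strand dinucleotide 5'->3' (DNA alphabet; the paired
# strand is the reverse complement). Symmetric entries expanded so lookup is
# a single subscript.
WC_STACKS <- c(
  AA = -0.93, TT = -0.93, AT = -1.10, TA = -1.33,
  CT = -2.08, AG = -2.08, CA = -2.11, TG = -2.11,
  GT = -2.24, AC = -2.24, GA = -2.35, TC = -2.35,
  CG = -2.36, GG = -3.26, CC = -3.26, GC = -3.42)

COMP <- c(A = "T", C = "G", G = "C", T = "A")

# Per-position pairing classes for an antiparallel ungapped duplex.
# query_sub and target_sub are both 5'->3' on their own molecules, so
# query position k pairs with target position L-1-k.
pairing_classes <- function(query_sub, target_sub) {
  stopifnot(nchar(query_sub) == nchar(target_sub))
  qv <- strsplit(query_sub, "")[[1]]
  tv <- rev(strsplit(target_sub, "")[[1]])
  cls <- rep("mismatch", length(qv))
  cls[COMP[qv] == tv] <- "WC"
  cls[(qv == "G" & tv == "T") | (qv == "T" & tv == "G")] <- "wobble"
  cls
}

#' Hybridization free energy of an ungapped antisense duplex
#'
#' Nearest-neighbor model: duplex initiation penalty plus one stack term per
#' adjacent pair of non-mismatched positions. Watson-Crick stacks use a
#' bundled RNA/RNA dG37 table; stacks containing wobble pairs are penalized
#' by a fixed amount per wobble pair and clamped at <= 0. Mismatched
#' positions break stacking and each adds a fixed destabilizing term. More
#' negative = more stable.
#'
#' @param query_sub,target_sub Equal-length duplex substrings, each 5'->3'
#'   on its own molecule (pairing is antiparallel).
#' @param pairing Optional precomputed per-position classes
#'   ("WC"/"wobble"/"mismatch"); computed if NULL.
#' @param params See [duplex_params()].
#' @return Free energy in kcal/mol.
#' @export
duplex_energy <- function(query_sub, target_sub, pairing = NULL,
                          params = duplex_params()) {
  if (nchar(query_sub) != nchar(target_sub))
    stop("duplex substrings must have equal length", call. = FALSE)
  if (is.null(pairing)) pairing <- pairing_classes(query_sub, target_sub)
  n <- nchar(query_sub)
  e <- params$initiation + params$mismatch_penalty * sum(pairing == "mismatch")
  if (n >= 2) {
    qv <- strsplit(query_sub, "")[[1]]
    paired <- pairing != "mismatch"
    both <- paired[-n] & paired[-1]
    if (any(both)) {
      keys <- paste0(qv[-n], qv[-1])[both]
      nwob <- ((pairing == "wobble")[-n] + (pairing == "wobble")[-1])[both]
      stacks <- pmin(0, WC_STACKS[keys] + params$wobble_stack_penalty * nwob)
      e <- e + sum(stacks)
    }
  }
  unname(e)
}

#' Find exact antisense seed matches
#'
#' All positions where `query[q_pos, q_pos + word_len)` equals the reverse
#' complement of `target[t_pos, t_pos + word_len)`. Positions are 0-based;
#' output ordered by q_pos then t_pos. Sequences shorter than the word
#' length yield an empty result.
#'
#' @param query,target DNA sequences (A/C/G/T).
#' @param word_len Word length (>= 4).
#' @return Integer matrix with columns q_pos, t_pos.
#' @export
find_seed_matches <- function(query, target, word_len = 8L) {
  stopifnot(word_len >= 4L)
  .seed_matches(query, target, as.integer(word_len))
}

#' X-drop ungapped extension of a single seed
#'
#' Extends antiparallel in both directions (advancing on the query recedes
#' on the target), accumulating extension scores and stopping when the
#' running score drops `xdrop` below the running maximum; returns the
#' maximal-scoring segment containing the seed.
#'
#' @param query,target DNA sequences.
#' @param seed Length-2 vector `c(q_pos, t_pos)` (0-based) from
#'   [find_seed_matches()].
#' @param params See [duplex_params()]; uses word_len, match/wobble/mismatch
#'   scores and xdrop.
#' @return One-row data.frame: q_start, q_end, t_start, t_end (0-based
#'   half-open), ext_score.
#' @export
extend_seed <- function(query, target, seed, params = duplex_params()) {
  .extend_seed_cpp(query, target, as.integer(seed[1]), as.integer(seed[2]),
                   params$word_len, params$match, params$wobble,
                   params$mismatch, params$xdrop)
}

# Candidate duplex segments for one (query, target) pair. Short pairs are
# scanned exactly on every diagonal; long pairs via seeded x-drop extension.
scan_pair <- function(query, target, params = duplex_params()) {
  if (max(nchar(query), nchar(target)) <= params$exact_limit)
    .scan_exhaustive(query, target, params$match, params$wobble,
                     params$mismatch)
  else
    .scan_seeded(query, target, params$word_len, params$match, params$wobble,
                 params$mismatch, params$xdrop)
}

# Drop candidates that duplicate a better candidate at the same locus
# (overlapping in both query and target intervals).
merge_candidates <- function(cands) {
  if (nrow(cands) <= 1) return(cands)
  cands <- cands[order(-cands$ext_score, cands$q_start, cands$t_start), ,
                 drop = FALSE]
  keep <- rep(TRUE, nrow(cands))
  for (i in seq_len(nrow(cands))[-1]) {
    for (j in which(keep[seq_len(i - 1)])) {
      if (cands$q_start[i] < cands$q_end[j] && cands$q_start[j] < cands$q_end[i] &&
          cands$t_start[i] < cands$t_end[j] && cands$t_start[j] < cands$t_end[i]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  cands[keep, , drop = FALSE]
}

gc_content <- function(seq) {
  v <- strsplit(seq, "")[[1]]
  mean(v == "G" | v == "C")
}

gc_bin <- function(gc, edges = c(0.4, 0.6)) 1L + findInterval(gc, edges)

## ---- dinucleotide-preserving shuffle --------------------------------------

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson shuffle: produces a random sequence with exactly the
#' same dinucleotide (and hence mononucleotide) counts as the input, by
#' drawing a uniform random Eulerian path through the dinucleotide
#' transition multigraph. Preserves the local composition the null model of
#' the duplex predictor must respect.
#'
#' @param seq DNA sequence.
#' @return A shuffled sequence of the same length.
#' @export
dinuc_shuffle <- function(seq) .dinuc_shuffle_cpp(seq)

## ---- Gumbel calibration ----------------------------------------------------

# Fit P(S_max >= s) = 1 - exp(-K_pair * m * n * exp(-lambda * s)) to null
# maxima with per-pair search-space sizes mn, where K_pair = K *
# exp(lambda * b_t * (gc_t - gc_t_ref)) modulates K continuously with the
# target's GC within the bin (GC-richer pairs reach higher scores by
# chance). Moment initialization, then maximum likelihood in
# (log lambda, log K, b_t).
fit_gumbel_karlin <- function(scores, mn, gc_t = NULL) {
  stopifnot(length(scores) == length(mn), length(scores) >= 10)
  if (sd(scores) < .Machine$double.eps)
    stop("degenerate null fit: all null maxima equal; increase n_null ",
         "or sequence lengths", call. = FALSE)
  gc_t_ref <- 0
  dgc <- rep(0, length(scores))
  if (!is.null(gc_t) && sd(gc_t) > 1e-6) {
    gc_t_ref <- mean(gc_t)
    dgc <- gc_t - gc_t_ref
  }
  lambda <- pi / (sd(scores) * sqrt(6))
  for (it in 1:3) {
    tt <- scores - log(mn) / lambda
    beta <- sd(tt) * sqrt(6) / pi
    lambda <- 1 / beta
    mu <- mean(tt) - 0.5772156649 * beta
  }
  K <- exp(lambda * mu)
  nll <- function(par) {
    l <- exp(par[1]); k <- exp(par[2]); b <- par[3]
    s_adj <- scores - b * dgc
    z <- k * mn * exp(-l * s_adj)
    -sum(log(l) + log(k * mn) - l * s_adj - z)
  }
  fit <- tryCatch(
    stats::optim(c(log(lambda), log(K), 0), nll, method = "Nelder-Mead",
                 control = list(maxit = 500)),
    error = function(e) NULL)
  b_t <- 0
  if (!is.null(fit) && is.finite(fit$value)) {
    lambda <- exp(fit$par[1]); K <- exp(fit$par[2]); b_t <- fit$par[3]
  }
  if (all(dgc == 0)) b_t <- 0
  if (!is.finite(lambda) || !is.finite(K) || lambda <= 0 || K <= 0)
    stop("degenerate null fit (non-finite parameters); increase n_null",
         call. = FALSE)
  list(lambda = lambda, K = K, b_t = b_t, gc_t_ref = gc_t_ref)
}

#' Calibrate the null score distribution per GC bin
#'
#' Generates dinucleotide-preserving shuffles of (query, target) pairs,
#' records the maximum duplex score (= -energy of the best hit, 0 when no
#' hit) per pair, and fits Gumbel parameters (lambda, K) of the
#' Karlin-Altschul form P(S_max >= s) = 1 - exp(-K m n exp(-lambda s)) per
#' (query-GC, target-GC) bin, with m, n the sequence lengths. This is what
#' makes reported p-values account for the lengths and GC contents of both
#' molecules.
#'
#' @param query Query lncRNA sequence.
#' @param targets Named character vector of target sequences.
#' @param n_null Null pairs per target GC bin (>= 50).
#' @param seed RNG seed.
#' @param params See [duplex_params()].
#' @param gc_edges Bin edges on GC fraction for both molecules.
#' @return A `null_calibration` object.
#' @export
calibrate_null <- function(query, targets, n_null = 200L, seed = 1L,
                           params = duplex_params(), gc_edges = c(0.4, 0.6)) {
  stopifnot(n_null >= 50L, length(targets) >= 1)
  q_bin <- gc_bin(gc_content(query), gc_edges)
  t_gc <- vapply(targets, gc_content, 0.0)
  t_bins <- gc_bin(t_gc, gc_edges)
  bins <- list()
  with_seed(seed, {
    for (b in sort(unique(t_bins))) {
      tb <- targets[t_bins == b]
      ord <- sample.int(length(tb))
      scores <- numeric(n_null)
      mn <- numeric(n_null)
      gct <- numeric(n_null)
      for (k in seq_len(n_null)) {
        tgt <- tb[[ord[((k - 1) %% length(tb)) + 1]]]
        qs <- dinuc_shuffle(query)
        ts <- dinuc_shuffle(tgt)         # preserves the target's GC exactly
        scores[k] <- best_pair_score(qs, ts, params)
        mn[k] <- nchar(qs) * nchar(ts)
        gct[k] <- gc_content(ts)
      }
      fit <- fit_gumbel_karlin(scores, mn, gct)
      bins[[bin_key(q_bin, b)]] <- list(
        lambda = fit$lambda, K = fit$K, b_t = fit$b_t,
        gc_t_ref = fit$gc_t_ref, gc_q_bin = q_bin, gc_t_bin = b,
        n_null = n_null, mean_null = mean(scores))
    }
  })
  structure(list(gc_edges = gc_edges, bins = bins, n_null = n_null,
                 seed = seed, query_gc_bin = q_bin),
            class = "null_calibration")
}

bin_key <- function(qb, tb) paste0(qb, ":", tb)

# Best duplex score (= -energy over merged candidates; 0 if none positive).
best_pair_score <- function(query, target, params = duplex_params()) {
  cands <- scan_pair(query, target, params)
  if (nrow(cands) == 0) return(0)
  cands <- merge_candidates(cands)
  best <- 0
  for (i in seq_len(nrow(cands))) {
    qs <- substr(query, cands$q_start[i] + 1L, cands$q_end[i])
    ts <- substr(target, cands$t_start[i] + 1L, cands$t_end[i])
    s <- -duplex_energy(qs, ts, params = params)
    if (s > best) best <- s
  }
  best
}

#' P-value of a duplex score under the Gumbel null
#'
#' p = 1 - exp(-K_pair * len_q * len_t * exp(-lambda * score)) with
#' (lambda, K) from the calibration bin matching the pair's GC contents and
#' K_pair = K * exp(lambda * b_t * (gc_t - gc_t_ref)) modulating K
#' continuously with the target's GC inside the bin; monotone decreasing in
#' score and increasing in len_q * len_t. Scores <= 0 map to p = 1. A pair
#' whose GC bin was not trained uses the nearest trained bin with a warning.
#'
#' @param score Duplex score (= -energy, kcal/mol).
#' @param len_q,len_t Full lengths of the query and target molecules.
#' @param calibration A `null_calibration`.
#' @param gc_q,gc_t GC fractions of the pair; defaults to the calibration's
#'   query bin and the middle target bin when omitted.
#' @return p in (0, 1].
#' @export
hit_pvalue <- function(score, len_q, len_t, calibration,
                       gc_q = NULL, gc_t = NULL) {
  if (score <= 0) return(1)
  qb <- if (is.null(gc_q)) calibration$query_gc_bin
        else gc_bin(gc_q, calibration$gc_edges)
  tb <- if (is.null(gc_t)) 2L else gc_bin(gc_t, calibration$gc_edges)
  key <- bin_key(qb, tb)
  if (is.null(calibration$bins[[key]])) {
    have <- names(calibration$bins)
    parts <- do.call(rbind, strsplit(have, ":"))
    d <- abs(as.integer(parts[, 1]) - qb) + abs(as.integer(parts[, 2]) - tb)
    key2 <- have[which.min(d)]
    warning("GC bin ", key, " not trained; using nearest bin ", key2)
    key <- key2
  }
  b <- calibration$bins[[key]]
  s_adj <- score
  if (!is.null(gc_t) && !is.null(b$b_t) && b$b_t != 0)
    s_adj <- score - b$b_t * (gc_t - b$gc_t_ref)
  p <- -expm1(-b$K * len_q * len_t * exp(-b$lambda * s_adj))
  min(max(p, 1e-300), 1)
}

#' Predict antisense interactions between a query lncRNA and a target set
#'
#' Per target: seed search, x-drop extension (exact diagonal scan for short
#' pairs), merging of duplicate candidates keeping the best, hybridization
#' energy, and the best hit per pair as the pair's summary with a raw Gumbel
#' p-value. p_adj is Benjamini-Hochberg across all targets in the run
#' (targets without a positive-score hit enter the correction with p = 1).
#' Output is sorted by p_adj then target_id.
#'
#' @param query Query sequence.
#' @param targets Named character vector of target sequences.
#' @param params See [duplex_params()].
#' @param calibration Optional prebuilt `null_calibration`; built from
#'   `query`/`targets` when NULL.
#' @param seed RNG seed used for calibration when it is built here.
#' @param query_id Id recorded in the hit table.
#' @return A `duplex_hits` data.frame: query_id, target_id, q_start, q_end,
#'   t_start, t_end (0-based half-open), ext_score, energy (kcal/mol),
#'   score (= -energy), p_raw, p_adj. The calibration is attached as an
#'   attribute.
#' @export
predict_interactions <- function(query, targets, params = duplex_params(),
                                 calibration = NULL, seed = 1L,
                                 query_id = "query") {
  empty <- data.frame(query_id = character(), target_id = character(),
                      q_start = integer(), q_end = integer(),
                      t_start = integer(), t_end = integer(),
                      ext_score = numeric(), energy = numeric(),
                      score = numeric(), p_raw = numeric(),
                      p_adj = numeric(), stringsAsFactors = FALSE)
  if (length(targets) == 0) return(structure(empty, class = c("duplex_hits", "data.frame")))
  if (is.null(calibration))
    calibration <- calibrate_null(query, targets, n_null = params$n_null,
                                  seed = seed, params = params)
  gc_q <- gc_content(query)
  rows <- list()
  p_all <- setNames(rep(1, length(targets)), names(targets))
  for (tid in names(targets)) {
    tgt <- targets[[tid]]
    cands <- scan_pair(query, tgt, params)
    if (nrow(cands) == 0) next
    cands <- merge_candidates(cands)
    energies <- numeric(nrow(cands))
    for (i in seq_len(nrow(cands))) {
      qs <- substr(query, cands$q_start[i] + 1L, cands$q_end[i])
      ts <- substr(tgt, cands$t_start[i] + 1L, cands$t_end[i])
      energies[i] <- duplex_energy(qs, ts, params = params)
    }
    scores <- -energies
    best <- which.max(scores)
    if (scores[best] <= 0) next
    p <- hit_pvalue(scores[best], nchar(query), nchar(tgt), calibration,
                    gc_q = gc_q, gc_t = gc_content(tgt))
    p_all[tid] <- p
    rows[[tid]] <- data.frame(
      query_id = query_id, target_id = tid,
      q_start = cands$q_start[best], q_end = cands$q_end[best],
      t_start = cands$t_start[best], t_end = cands$t_end[best],
      ext_score = cands$ext_score[best], energy = energies[best],
      score = scores[best], p_raw = p, p_adj = NA_real_,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    out <- empty
  } else {
    out <- do.call(rbind, rows)
    p_adj_all <- p.adjust(p_all, method = "BH")
    out$p_adj <- unname(p_adj_all[out$target_id])
    out <- out[order(out$p_adj, out$target_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "calibration") <- calibration
  attr(out, "n_targets") <- length(targets)
  class(out) <- c("duplex_hits", "data.frame")
  out
}
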