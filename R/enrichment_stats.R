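# Per-knockdown, per-mode enrichment of strong duplex hits among the
# differentially expressed promoters: exact hypergeometric over-
# representation plus a preranked weighted-KS (GSEA-style) permutation test.
# A knockdown/mode is significant when either test clears alpha.

#' Hypergeometric over-representation p-value
#'
#' Upper tail P(X >= k) for X ~ Hypergeometric(N, K, n): the chance of
#' drawing at least `k` hit promoters among `n` DEGs when `K` of the `N`
#' background promoters carry hits. Exact (no normal approximation).
#'
#' @param k Hits among DEGs.
#' @param n Number of DEGs drawn.
#' @param K Hit promoters in the background.
#' @param N Background size.
#' @return p in (0, 1].
#' @export
hgd_enrichment <- function(k, n, K, N) {
  stopifnot(length(k) == 1, length(n) == 1, length(K) == 1, length(N) == 1)
  if (k > min(n, K) || K > N || n > N || k < 0)
    stop("inconsistent hypergeometric counts: k=", k, " n=", n, " K=", K,
         " N=", N, call. = FALSE)
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Preranked GSEA enrichment of a promoter set
#'
#' Promoters are ranked by score (descending, ties broken by promoter id);
#' the enrichment score ES is the maximal positive deviation of the weighted
#' Kolmogorov-Smirnov running sum, with hit increments proportional to
#' |score|^weight and uniform miss decrements. The p-value permutes the set
#' labels: p = (1 + #\{permuted ES >= observed\}) / (1 + n_perm).
#'
#' @param scores Named numeric vector (promoter_id -> score).
#' @param deg_set Character vector of promoter ids forming the set; must be
#'   a subset of `names(scores)` and non-empty.
#' @param n_perm Number of label permutations (>= 100).
#' @param weight Exponent on |score| for hit increments; 0 gives uniform
#'   increments (rank-only test).
#' @param seed RNG seed.
#' @return List with elements `es` and `p`.
#' @export
gsea_enrichment <- function(scores, deg_set, n_perm = 1000L, weight = 1,
                            seed = 1L) {
  stopifnot(n_perm >= 100L)
  if (length(deg_set) == 0) stop("empty deg_set", call. = FALSE)
  if (!all(deg_set %in% names(scores)))
    stop("deg_set contains promoters without scores", call. = FALSE)
  ord <- order(-scores, names(scores))
  s_ranked <- abs(scores[ord])
  ids_ranked <- names(scores)[ord]
  N <- length(scores)
  nh <- length(deg_set)
  if (nh >= N) stop("deg_set must be a strict subset of scored promoters",
                    call. = FALSE)
  if (max(s_ranked) - min(s_ranked) < .Machine$double.eps && weight > 0)
    warning("all scores equal; ES computed with uniform increments")
  hit_idx <- which(ids_ranked %in% deg_set)
  es_obs <- running_es(s_ranked, hit_idx, N, nh, weight)
  perm <- numeric(n_perm)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      idx <- sample.int(N, nh)
      perm[b] <- running_es(s_ranked, idx, N, nh, weight)
    }
  })
  p <- (1 + sum(perm >= es_obs)) / (1 + n_perm)
  list(es = es_obs, p = p)
}

# Maximal positive deviation of the weighted-KS running sum.
running_es <- function(s_ranked, hit_idx, N, nh, weight) {
  w <- if (weight == 0) rep(1, nh) else s_ranked[hit_idx]^weight
  tot <- sum(w)
  incr <- numeric(N)
  if (tot <= .Machine$double.eps) {
    incr[hit_idx] <- 1 / nh                       # uniform fallback
  } else {
    incr[hit_idx] <- w / tot
  }
  miss <- rep(-1 / (N - nh), N)
  miss[hit_idx] <- 0
  max(cumsum(incr + miss))
}

#' Evaluate one knockdown in one interaction mode
#'
#' Defines "hit promoters" as those whose best duplex hit has adjusted
#' p-value below `hit_alpha`, then tests whether hits are over-represented
#' among the DEGs of the knockdown table by (i) the exact hypergeometric
#' test over the tested background (all promoters in the table) and (ii)
#' preranked GSEA on score = -log10(p_adj) (promoters without hits score 0).
#' The knockdown/mode is flagged significant when either p < alpha.
#'
#' @param hits A `duplex_hits` table computed against this mode's targets.
#' @param kd A `knockdown_table` (the tested background).
#' @param mode "co" or "post" (recorded in the result).
#' @param alpha Significance threshold for either test.
#' @param hit_alpha Adjusted-p threshold defining hit promoters.
#' @param n_perm,weight,seed GSEA parameters.
#' @return An `enrichment_result` list: aso_id, mode, n_background, n_deg,
#'   n_hits_background, n_hits_in_deg, hgd_p, gsea_es, gsea_p, significant.
#' @export
evaluate_knockdown_mode <- function(hits, kd, mode = c("co", "post"),
                                    alpha = 0.01, hit_alpha = 0.01,
                                    n_perm = 1000L, weight = 1, seed = 1L) {
  mode <- match.arg(mode)
  background <- kd$promoter_id
  if (nrow(hits) > 0 && !all(hits$target_id %in% background))
    stop("hit target(s) absent from the knockdown background: ",
         paste(head(setdiff(hits$target_id, background), 5), collapse = ", "),
         call. = FALSE)
  deg <- kd$promoter_id[kd$deg_flag]
  hit_prom <- hits$target_id[hits$p_adj < hit_alpha]
  if (length(deg) == 0) {
    # nothing responded to the knockdown: no enrichment is testable
    warning("knockdown table has no DEGs; returning a non-significant result")
    return(structure(list(
      aso_id = attr(kd, "aso_id"), mode = mode,
      n_background = length(background), n_deg = 0L,
      n_hits_background = length(hit_prom), n_hits_in_deg = 0L,
      hgd_p = 1, gsea_es = NA_real_, gsea_p = 1, significant = FALSE,
      alpha = alpha), class = "enrichment_result"))
  }
  k <- length(intersect(hit_prom, deg))
  hgd_p <- hgd_enrichment(k, length(deg), length(hit_prom), length(background))
  scores <- setNames(rep(0, length(background)), background)
  if (nrow(hits) > 0)
    scores[hits$target_id] <- -log10(pmax(hits$p_adj, 1e-300))
  gs <- suppressWarnings(
    gsea_enrichment(scores, deg, n_perm = n_perm, weight = weight, seed = seed))
  structure(list(
    aso_id = attr(kd, "aso_id"), mode = mode,
    n_background = length(background), n_deg = length(deg),
    n_hits_background = length(hit_prom), n_hits_in_deg = k,
    hgd_p = hgd_p, gsea_es = gs$es, gsea_p = gs$p,
    significant = (hgd_p < alpha) || (gs$p < alpha), alpha = alpha),
    class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> %s [%s]: %d/%d hits in %d DEGs of %d; HGD p=%.3g, GSEA p=%.3g -> %s\n",
    if (is.na(x$aso_id)) "?" else x$aso_id, x$mode, x$n_hits_in_deg,
    x$n_hits_background, x$n_deg, x$n_background, x$hgd_p, x$gsea_p,
    if (x$significant) "significant" else "not significant"))
  invisible(x)
}
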