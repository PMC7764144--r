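# Independent oracle: upper-tail hypergeometric by explicit combinatorial
# enumeration (no phyper).
enum_hyper_upper <- function(k, n, K, N, strict = FALSE) {
  lo <- if (strict) k + 1 else k
  hi <- min(n, K)
  if (lo > hi) return(if (strict || k > 0) 0 else 1)
  sum(vapply(lo:hi, function(x)
    choose(K, x) * choose(N - K, n - x), 0.0)) / choose(N, n)
}

test_that("hypergeometric enrichment matches closed forms", {
  expect_equal(hgd_enrichment(5, 5, 5, 20), 1 / choose(20, 5))
  expect_equal(hgd_enrichment(0, 3, 4, 10), 1)
  expect_equal(hgd_enrichment(2, 3, 4, 10), 1 / 3)
  expect_error(hgd_enrichment(6, 5, 5, 20), "inconsistent")
  expect_error(hgd_enrichment(2, 3, 11, 10), "inconsistent")
})

test_that("hypergeometric routines equal full enumeration for small universes", {
  set.seed(71)
  for (i in 1:60) {
    N <- sample(5:30, 1)
    K <- sample.int(N, 1)
    n <- sample.int(N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hgd_enrichment(k, n, K, N), enum_hyper_upper(k, n, K, N),
                 tolerance = 1e-12)
    expect_equal(overlap_pvalue(k, K, n, universe = N, tail = "ge"),
                 enum_hyper_upper(k, n, K, N), tolerance = 1e-12)
    expect_equal(overlap_pvalue(k, K, n, universe = N, tail = "gt"),
                 enum_hyper_upper(k, n, K, N, strict = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("GSEA gives the minimal p when the set is exactly the top ranks", {
  scores <- setNames(seq(100, 1, length.out = 30), sprintf("p%02d", 1:30))
  deg <- names(scores)[1:5]
  res <- gsea_enrichment(scores, deg, n_perm = 500, seed = 1)
  expect_equal(res$es, 1, tolerance = 1e-9)   # running sum peaks at full mass
  expect_equal(res$p, 1 / 501)
})

test_that("GSEA Monte-Carlo p agrees with exhaustive label enumeration", {
  scores <- setNames(c(9, 7, 5, 3, 1), paste0("g", 1:5))
  deg <- c("g1", "g3")
  res <- gsea_enrichment(scores, deg, n_perm = 2000, seed = 7)
  # oracle: all C(5,2) = 10 label placements
  combos <- utils::combn(5, 2)
  es_all <- apply(combos, 2, function(idx)
    lncmode:::running_es(sort(abs(scores), decreasing = TRUE), idx, 5, 2, 1))
  obs <- lncmode:::running_es(sort(abs(scores), decreasing = TRUE),
                              c(1, 3), 5, 2, 1)
  p_exact <- mean(es_all >= obs - 1e-12)
  expect_lt(abs(res$p - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 2000) +
              1e-3)
})

test_that("weight 0 makes GSEA invariant to monotone score transforms", {
  set.seed(73)
  scores <- setNames(runif(40, 1, 10), sprintf("m%02d", 1:40))
  deg <- sample(names(scores), 8)
  a <- gsea_enrichment(scores, deg, n_perm = 300, weight = 0, seed = 9)
  b <- gsea_enrichment(scores^3 + 2, deg, n_perm = 300, weight = 0, seed = 9)
  expect_equal(a$es, b$es)
  expect_equal(a$p, b$p)
})

test_that("GSEA enrichment score matches the fgsea reference", {
  skip_if_not_installed("fgsea")
  set.seed(79)
  scores <- setNames(sort(runif(50, 0.1, 20), decreasing = TRUE),
                     sprintf("q%02d", 1:50))
  deg <- sample(names(scores), 10)
  ours <- gsea_enrichment(scores, deg, n_perm = 100, seed = 1)$es
  ref <- fgsea::calcGseaStat(unname(scores),
                             selectedStats = which(names(scores) %in% deg),
                             gseaParam = 1)
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("GSEA input contracts are enforced", {
  scores <- setNames(1:10 * 1.0, paste0("x", 1:10))
  expect_error(gsea_enrichment(scores, character(0)), "empty")
  expect_error(gsea_enrichment(scores, "nope"), "without scores")
  expect_warning(
    gsea_enrichment(setNames(rep(1, 10), paste0("x", 1:10)), c("x1", "x2"),
                    n_perm = 100, seed = 1),
    "uniform")
})

test_that("knockdown evaluation combines tests and flags significance", {
  set.seed(83)
  pids <- sprintf("p%03d", 1:60)
  # strong enrichment: hits and DEGs coincide on 10 promoters; the other
  # promoters carry weak hits so the ranking is informative throughout
  hits <- data.frame(target_id = pids,
                     p_adj = c(rep(1e-6, 10), runif(50, 0.2, 1)))
  kd <- knockdown_table(pids, c(rnorm(10, -2, 0.3), rnorm(50, 0, 0.2)),
                        c(rep(TRUE, 10), rep(FALSE, 50)), aso_id = "asoT")
  res <- evaluate_knockdown_mode(hits, kd, "co", seed = 3)
  expect_true(res$significant)
  expect_equal(res$n_hits_background, 10L)   # p_adj < 0.01 only
  expect_equal(res$n_hits_in_deg, 10L)
  expect_lt(res$hgd_p, 1e-9)
  expect_lt(res$gsea_p, 0.01)
  expect_equal(res$mode, "co")

  # hits outside the tested background are rejected
  bad <- data.frame(target_id = c("p001", "zzz"), p_adj = c(1e-6, 1e-6))
  expect_error(evaluate_knockdown_mode(bad, kd, "co"), "absent from")

  # invariant: n_hits_in_deg <= min(n_deg, n_hits_background)
  expect_lte(res$n_hits_in_deg, min(res$n_deg, res$n_hits_background))
})

test_that("permuted DEG labels give a null-calibrated significance rate", {
  # with random labels and no real hits the either-test rule fires at a
  # rate governed by alpha (checked tightly in the acceptance suite)
  set.seed(89)
  pids <- sprintf("p%03d", 1:50)
  hits <- data.frame(target_id = character(0), p_adj = numeric(0))
  n_sig <- 0
  for (b in 1:40) {
    kd <- knockdown_table(pids, rnorm(50, 0, 0.3),
                          sample(c(rep(TRUE, 3), rep(FALSE, 47))),
                          aso_id = "a")
    r <- suppressWarnings(
      evaluate_knockdown_mode(hits, kd, "co", n_perm = 200, seed = b))
    n_sig <- n_sig + r$significant
  }
  expect_lte(n_sig, 4)   # ~ Binomial(40, ~0.01); 5+ would be wildly off
})
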