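test_that("seed matches are exact reverse-complement words", {
  m <- find_seed_matches("AAAAAAAA", "TTTTTTTT", 8)
  expect_equal(nrow(m), 1L)
  expect_equal(unname(m[1, ]), c(0L, 0L))

  # planted 20-nt reverse complement of target[5:25) gives 13 consecutive
  # seed positions at w = 8
  set.seed(101)
  tgt <- rand_seq(60)
  q <- paste0(rand_seq(15), rc(substr(tgt, 6, 25)), rand_seq(15))
  m2 <- find_seed_matches(q, tgt, 8)
  # oracle: exhaustive window comparison
  exp <- 0L
  for (qp in 0:(nchar(q) - 8)) for (tp in 0:(nchar(tgt) - 8))
    if (substr(q, qp + 1, qp + 8) == rc(substr(tgt, tp + 1, tp + 8)))
      exp <- exp + 1L
  expect_equal(nrow(m2), exp)
  expect_gte(nrow(m2), 13L)

  # unrelated random 100-mers at w = 12: expected count ~ (89*89)/4^12 << 1
  set.seed(7)
  hits <- sum(replicate(20, nrow(find_seed_matches(rand_seq(100),
                                                   rand_seq(100), 12))))
  expect_lte(hits, 2L)

  expect_equal(nrow(find_seed_matches("ACG", "ACGTACGT", 8)), 0L)
  expect_error(find_seed_matches("ACGT", "ACGT", 3))
})

test_that("x-drop extension recovers planted complements and respects xdrop = 0", {
  set.seed(11)
  core <- rand_seq(30)
  q <- paste0(rand_seq(20), core, rand_seq(20))
  tgt <- paste0(rand_seq(25), rc(core), rand_seq(25))
  seeds <- find_seed_matches(q, tgt, 8)
  expect_gt(nrow(seeds), 0)
  hit <- extend_seed(q, tgt, seeds[1, ])
  # oracle: exhaustive best-scoring segment over all diagonals
  orc <- oracle_best_segment(q, tgt)
  expect_equal(hit$ext_score, orc$score)
  # the maximal segment covers the planted core (it may extend into the
  # flanks when chance pairs continue the duplex)
  expect_lte(hit$q_start, 20L)
  expect_gte(hit$q_end, 50L)
  expect_lte(hit$t_start, 25L)
  expect_gte(hit$t_end, 55L)
  expect_equal(oracle_interval_score(q, tgt, hit$q_start, hit$q_end,
                                     hit$t_start, hit$t_end), orc$score)

  # xdrop = 0: extension stops at the first score drop on each side
  p0 <- duplex_params(xdrop = 0)
  q2 <- paste0("GG", "AAAAAAAA", "GG")      # mismatches flank the 8-mer
  t2 <- paste0("CA", "TTTTTTTT", "AC")
  hit0 <- extend_seed(q2, t2, c(2L, 2L), p0)
  expect_equal(c(hit0$q_start, hit0$q_end), c(2L, 10L))
  expect_equal(hit0$ext_score, 16)
})

test_that("mismatch-flanked perfect word extends to exactly the word", {
  set.seed(13)
  for (i in 1:10) {
    core <- rand_seq(8)
    # embed core with guaranteed mismatches at both flanks
    flipbase <- function(b) c(A = "C", C = "A", G = "T", T = "G")[[b]]
    tgt_core <- rc(core)
    q <- paste0(rand_seq(10), core, rand_seq(10))
    # target aligned so flanking positions mismatch: build explicitly
    left <- substr(q, 10, 10)    # base pairing against position left of core
    right <- substr(q, 19, 19)
    tgt <- paste0(rand_seq(4), flipbase(rc(right)), tgt_core,
                  flipbase(rc(left)), rand_seq(4))
    seeds <- find_seed_matches(q, tgt, 8)
    on_core <- seeds[seeds[, 1] == 10 & seeds[, 2] == 5, , drop = FALSE]
    if (nrow(on_core) == 1) {
      hit <- extend_seed(q, tgt, on_core[1, ], duplex_params(xdrop = 0))
      expect_equal(c(hit$q_start, hit$q_end), c(10L, 18L))
    }
  }
})

test_that("nearest-neighbor energies are stable, additive and GC-sensitive", {
  p <- duplex_params()
  # single pair: initiation only
  expect_equal(duplex_energy("A", "T"), p$initiation)
  # GC duplex strictly more stable than AT duplex of the same length
  gc <- duplex_energy(strrep("G", 10), strrep("C", 10))
  at <- duplex_energy(strrep("A", 10), strrep("T", 10))
  expect_lt(gc, at)
  # oracle: sum over the bundled stack table
  expect_equal(gc, p$initiation + 9 * lncmode:::WC_STACKS[["GG"]])
  expect_equal(at, p$initiation + 9 * lncmode:::WC_STACKS[["AA"]])
  # perfect-duplex energy is non-increasing in k (all stacks <= 0)
  set.seed(3)
  for (i in 1:5) {
    s <- rand_seq(30)
    e <- vapply(2:30, function(k)
      duplex_energy(substr(s, 1, k), rc(substr(s, 1, k))), 0.0)
    expect_true(all(diff(e) <= 1e-9))
  }
  expect_true(all(lncmode:::WC_STACKS <= 0))
  expect_error(duplex_energy("AA", "T"), "equal length")
})

test_that("wobble pairs score between match and mismatch", {
  # antiparallel pairing: query position 1 pairs the target's last base
  cls <- lncmode:::pairing_classes("GG", "TC")   # G~C WC, then G~T wobble
  expect_equal(cls, c("WC", "wobble"))
  e_wob <- duplex_energy("GG", "TC")
  e_wc <- duplex_energy("GG", "CC")
  expect_gt(e_wob, e_wc)
  expect_lte(e_wob - duplex_params()$initiation, 0)
})

test_that("dinucleotide shuffle preserves dinucleotide counts", {
  set.seed(21)
  for (i in 1:10) {
    s <- rand_seq(sample(100:500, 1))
    sh <- dinuc_shuffle(s)
    expect_identical(dinuc_counts(sh), dinuc_counts(s))
    expect_identical(substr(sh, 1, 1), substr(s, 1, 1))
  }
  # and actually randomizes
  s <- rand_seq(300)
  expect_false(dinuc_shuffle(s) == dinuc_shuffle(s) &&
                 dinuc_shuffle(s) == s)
})

test_that("best hit equals the brute-force oracle on short pairs", {
  set.seed(31)
  p <- duplex_params()
  for (i in 1:60) {
    q <- rand_seq(sample(20:60, 1))
    tgt <- rand_seq(sample(20:60, 1))
    cands <- lncmode:::scan_pair(q, tgt, p)
    impl <- if (nrow(cands) == 0) 0 else max(cands$ext_score)
    orc <- oracle_best_segment(q, tgt)
    expect_equal(impl, orc$score)
    if (impl > 0) {
      b <- cands[which.max(cands$ext_score), ]
      expect_equal(oracle_interval_score(q, tgt, b$q_start, b$q_end,
                                         b$t_start, b$t_end), orc$score)
    }
  }
})

test_that("swapping query and target roles preserves the best score", {
  set.seed(37)
  for (i in 1:10) {
    q <- rand_seq(50); tgt <- rand_seq(50)
    a <- oracle_best_segment(q, tgt)$score
    ca <- lncmode:::scan_pair(q, tgt, duplex_params())
    cb <- lncmode:::scan_pair(tgt, q, duplex_params())
    sa <- if (nrow(ca) == 0) 0 else max(ca$ext_score)
    sb <- if (nrow(cb) == 0) 0 else max(cb$ext_score)
    expect_equal(sa, sb)
    expect_equal(sa, a)
  }
})

test_that("seeded long-pair scan agrees with single-seed extension", {
  set.seed(41)
  core <- rand_seq(40)
  q <- paste0(rand_seq(120), core, rand_seq(140))
  tgt <- paste0(rand_seq(60), rc(core), rand_seq(100))
  p <- duplex_params()
  cands <- lncmode:::scan_pair(q, tgt, p)    # length > exact_limit: seeded
  expect_gt(nrow(cands), 0)
  best <- cands[which.max(cands$ext_score), ]
  expect_lte(best$q_start, 120L)
  expect_gte(best$q_end, 160L)
  seeds <- find_seed_matches(q, tgt, p$word_len)
  inside <- seeds[seeds[, 1] >= 120 & seeds[, 1] + p$word_len <= 160, ,
                  drop = FALSE]
  ext <- extend_seed(q, tgt, inside[1, ], p)
  expect_equal(ext$ext_score, best$ext_score)
})

test_that("Gumbel calibration is deterministic and length-monotone", {
  set.seed(43)
  query <- rand_seq(400)
  targets <- setNames(replicate(8, rand_seq(300)), paste0("t", 1:8))
  c1 <- calibrate_null(query, targets, n_null = 60, seed = 5)
  c2 <- calibrate_null(query, targets, n_null = 60, seed = 5)
  expect_identical(c1$bins, c2$bins)
  b <- c1$bins[[1]]
  expect_gt(b$lambda, 0)
  expect_gt(b$K, 0)

  # monotonicity of the p-value formula
  p1 <- hit_pvalue(20, 400, 300, c1, gc_t = 0.5)
  expect_lt(hit_pvalue(25, 400, 300, c1, gc_t = 0.5), p1)
  expect_gt(hit_pvalue(20, 400, 600, c1, gc_t = 0.5), p1)
  expect_equal(hit_pvalue(-1, 400, 300, c1), 1)
  expect_equal(hit_pvalue(1e6, 400, 300, c1, gc_t = 0.5), 1e-300)
})

test_that("higher-GC pairs need higher scores for the same p-value", {
  set.seed(47)
  gc_seq <- function(n, gc) paste(sample(c("A", "C", "G", "T"), n, TRUE,
    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)), collapse = "")
  query <- gc_seq(400, 0.5)
  lo <- setNames(replicate(6, gc_seq(300, 0.30)), paste0("lo", 1:6))
  hi <- setNames(replicate(6, gc_seq(300, 0.70)), paste0("hi", 1:6))
  cal <- calibrate_null(query, c(lo, hi), n_null = 120, seed = 3)
  expect_setequal(names(cal$bins), c("2:1", "2:3"))
  # at a fixed score in the upper tail, the GC-rich bin gives a larger p
  # (random GC-rich duplexes reach higher scores by chance)
  p_lo <- hit_pvalue(30, 400, 300, cal, gc_t = 0.30)
  p_hi <- hit_pvalue(30, 400, 300, cal, gc_t = 0.70)
  expect_gt(p_hi, p_lo)
})

test_that("predict_interactions ranks a planted target first with small p_adj", {
  set.seed(53)
  targets <- setNames(replicate(20, rand_seq(500)), sprintf("t%02d", 1:20))
  core <- substr(targets[["t07"]], 101, 140)          # 40 nt of the target
  seg <- rc(core)
  # ~5% mutation
  seg <- local({
    v <- strsplit(seg, "")[[1]]
    idx <- c(10, 30)
    v[idx] <- vapply(v[idx], function(b)
      setdiff(c("A", "C", "G", "T"), b)[1], "")
    paste(v, collapse = "")
  })
  query <- paste0(rand_seq(300), seg, rand_seq(300))
  hits <- predict_interactions(query, targets, seed = 2)
  expect_s3_class(hits, "duplex_hits")
  expect_equal(hits$target_id[1], "t07")
  expect_lt(hits$p_adj[1], 0.01)
  expect_true(all(hits$p_adj >= hits$p_raw - 1e-12))
  expect_true(all(hits$score > 0))
  expect_true(all(hits$q_end - hits$q_start == hits$t_end - hits$t_start))

  # whole-target reverse complement: best hit covers >= 90% of the target
  tgt_full <- rand_seq(500)
  targets2 <- c(targets[1:5], full = tgt_full)
  hits2 <- predict_interactions(rc(tgt_full), targets2, seed = 2)
  expect_equal(hits2$target_id[1], "full")
  cover <- (hits2$t_end[1] - hits2$t_start[1]) / 500
  expect_gte(cover, 0.9)
  expect_equal(hits2$p_adj[1], min(hits2$p_adj))

  expect_equal(nrow(predict_interactions(rand_seq(100), character(0))), 0L)
})

test_that("hit tables are byte-identical given identical inputs and seed", {
  set.seed(59)
  targets <- setNames(replicate(6, rand_seq(300)), paste0("t", 1:6))
  query <- rand_seq(400)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_hits_tsv(predict_interactions(query, targets, seed = 4), f1)
  write_hits_tsv(predict_interactions(query, targets, seed = 4), f2)
  expect_identical(readLines(f1), readLines(f2))
})
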