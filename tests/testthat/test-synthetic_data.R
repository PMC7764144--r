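test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(n_genes = 10L, n_true_targets = 4L, seed = 42L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  for (f in c("genome.fa", "genes.gtf", "lncrna.fa", "knockdown.tsv",
              "peaks.bed", "truth.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
})

test_that("simulated genome matches the configured GC content", {
  cfg <- sim_config(n_genes = 20L, n_true_targets = 5L, gc_content = 0.5,
                    seed = 8L)
  sim <- simulate_genome(cfg)
  seq <- paste(sim$genome, collapse = "")
  v <- strsplit(seq, "")[[1]]
  gc <- mean(v %in% c("G", "C"))
  # n > 100 kb of i.i.d. bases: binomial 99% bound is well inside +/- 0.02
  expect_gt(gc, 0.48)
  expect_lt(gc, 0.52)
})

test_that("exon_count_range (1,1) yields only single-exon transcripts", {
  cfg <- sim_config(n_genes = 6L, n_true_targets = 1L,
                    exon_count_range = c(1L, 1L), seed = 5L)
  sim <- simulate_genome(cfg)
  for (g in sim$genes)
    for (tx in g$transcripts) expect_equal(nrow(tx$exons), 1L)
  # and co-mode planting is structurally impossible there
  expect_error(plant_lncrna(sim$genome, sim$genes,
                            within.list(cfg, planted_mode <- "co")),
               "structural requirement")
})

test_that("unmutated planted segments are exact reverse complements", {
  for (mode in c("co", "post")) {
    cfg <- sim_config(n_genes = 12L, n_true_targets = 4L,
                      planted_mutation_rate = 0, planted_mode = mode,
                      seed = 9L)
    sim <- simulate_genome(cfg)
    pl <- plant_lncrna(sim$genome, sim$genes, cfg)
    for (i in seq_len(nrow(pl$truth$coords))) {
      cc <- pl$truth$coords[i, ]
      g <- sim$genes[[sub("_p1$", "", cc$promoter_id)]]
      tgt <- if (mode == "co")
        build_cotx_target(g, cc$promoter_id, sim$genome)$sequence
      else build_posttx_target(g, cc$promoter_id, sim$genome)$sequence
      src <- substr(tgt, cc$t_start + 1, cc$t_end)
      seg <- substr(pl$lncrna, cc$q_start + 1, cc$q_end)
      expect_identical(seg, rc(src))
    }
  }
})

test_that("mode 'none' plants no long reverse-complement match", {
  cfg <- sim_config(n_genes = 10L, n_true_targets = 3L,
                    planted_mode = "none", seed = 13L)
  sim <- simulate_genome(cfg)
  pl <- plant_lncrna(sim$genome, sim$genes, cfg)
  expect_length(pl$truth$true_target_ids, 0L)
  # exhaustive word scan: longest rc run vs co targets stays near chance
  # (expected max for 2 kb x 1 kb ~ log4(mn) ~ 10-11)
  for (g in sim$genes[1:5]) {
    co <- build_cotx_target(g, g$promoters$promoter_id[1], sim$genome)
    expect_lt(longest_rc_run(pl$lncrna, co$sequence), 16L)
  }
})

test_that("post-mode planting is broken by the junction in the co target", {
  cfg <- sim_config(n_genes = 12L, n_true_targets = 4L, planted_mode = "post",
                    planted_mutation_rate = 0, seed = 17L)
  sim <- simulate_genome(cfg)
  pl <- plant_lncrna(sim$genome, sim$genes, cfg)
  for (pid in pl$truth$true_target_ids) {
    g <- sim$genes[[sub("_p1$", "", pid)]]
    co <- build_cotx_target(g, pid, sim$genome)
    cc <- pl$truth$coords[pl$truth$coords$promoter_id == pid, ]
    seg <- substr(pl$lncrna, cc$q_start + 1, cc$q_end)
    # exhaustive scan, independent of the predictor: the exact complementary
    # run shared with the nascent 5' window is shorter than the plant
    expect_lt(longest_rc_run(seg, co$sequence), cfg$planted_match_len)
  }
})

test_that("co-mode planting is absent from the mature transcript", {
  cfg <- sim_config(n_genes = 12L, n_true_targets = 4L, planted_mode = "co",
                    planted_mutation_rate = 0, seed = 19L)
  sim <- simulate_genome(cfg)
  pl <- plant_lncrna(sim$genome, sim$genes, cfg)
  for (pid in pl$truth$true_target_ids) {
    g <- sim$genes[[sub("_p1$", "", pid)]]
    post <- build_posttx_target(g, pid, sim$genome)
    cc <- pl$truth$coords[pl$truth$coords$promoter_id == pid, ]
    seg <- substr(pl$lncrna, cc$q_start + 1, cc$q_end)
    expect_lt(longest_rc_run(seg, post$sequence), cfg$planted_match_len)
  }
})

test_that("DEG flag rates follow the null and effect distributions", {
  # pure-null effect distribution: flag rate ~ deg_alpha
  cfg <- sim_config(n_genes = 400L, n_true_targets = 40L,
                    effect_log2fc_mean = 0, effect_log2fc_sd = 0.3,
                    null_log2fc_sd = 0.3, deg_alpha = 0.05,
                    planted_mode = "none", seed = 23L)
  sim <- simulate_genome(cfg)
  truth <- structure(list(true_target_ids = character(0),
                          planted_mode = "none", coords = NULL),
                     class = "sim_truth")
  kd <- simulate_knockdown(sim$genes, truth, cfg)
  rate <- mean(kd$deg_flag)
  # binomial 99.9% CI around 0.05 at n = 400
  expect_gt(rate, 0.05 - 3.3 * sqrt(0.05 * 0.95 / 400))
  expect_lt(rate, 0.05 + 3.3 * sqrt(0.05 * 0.95 / 400))

  # strong effects: nearly all true targets flagged (normal tail bound)
  cfg2 <- sim_config(n_genes = 100L, n_true_targets = 40L, lncrna_length = 4000L,
                     effect_log2fc_mean = -2, effect_log2fc_sd = 0.5,
                     null_log2fc_sd = 0.2, planted_mode = "co", seed = 29L)
  sim2 <- simulate_genome(cfg2)
  pl2 <- plant_lncrna(sim2$genome, sim2$genes, cfg2)
  kd2 <- simulate_knockdown(sim2$genes, pl2$truth, cfg2)
  flagged <- kd2$deg_flag[kd2$promoter_id %in% pl2$truth$true_target_ids]
  expect_gte(mean(flagged), 0.95)
})

test_that("contact peaks honor peak_true_frac and placement windows", {
  cfg <- sim_config(n_genes = 15L, n_true_targets = 6L, peak_true_frac = 1,
                    n_background_peaks = 0L, seed = 31L)
  sim <- simulate_genome(cfg)
  pl <- plant_lncrna(sim$genome, sim$genes, cfg)
  peaks <- simulate_contacts(sim$genes, pl$truth, cfg, sim$genome)
  expect_equal(nrow(peaks), 6L)
  tss <- vapply(pl$truth$true_target_ids, function(pid) {
    g <- sim$genes[[sub("_p1$", "", pid)]]
    g$promoters$tss[1]
  }, 0L)
  mids <- (peaks$start + peaks$end) / 2
  for (i in seq_len(nrow(peaks))) {
    g_chr <- vapply(pl$truth$true_target_ids, function(pid)
      sim$genes[[sub("_p1$", "", pid)]]$chrom, "")
    same <- which(g_chr == peaks$chrom[i])
    expect_lte(min(abs(mids[i] - tss[same])), cfg$peak_window + 1)
  }

  cfg0 <- sim_config(n_genes = 15L, n_true_targets = 6L, peak_true_frac = 0,
                     n_background_peaks = 20L, seed = 31L)
  peaks0 <- simulate_contacts(sim$genes, pl$truth, cfg0, sim$genome)
  expect_equal(nrow(peaks0), 20L)
})
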