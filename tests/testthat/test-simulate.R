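test_that("generators are deterministic for a fixed seed", {
  cfg <- sim_config(seed = 21, n_zf_transcripts = 3,
                    n_control_transcripts = 3)
  a <- make_transcriptome(cfg)
  b <- make_transcriptome(cfg)
  expect_identical(a, b)
  fa <- simulate_footprints(a, cfg)
  fb <- simulate_footprints(b, cfg)
  expect_identical(fa$tracks, fb$tracks)
  ba <- simulate_bric(20, cfg)
  bb <- simulate_bric(20, cfg)
  expect_identical(ba, bb)
  expect_error(sim_config(), "seed")
})

test_that("scanner recovers every planted domain and nothing on controls", {
  cfg <- sim_config(seed = 8, n_zf_transcripts = 10,
                    n_control_transcripts = 10)
  tx <- make_transcriptome(cfg)
  hits <- scan_proteins(tx$proteins)
  # full recall with exact frames
  got <- hits[hits$is_canonical_28,
              c("protein_id", "frame_start", "frame_end")]
  want <- tx$truth[tx$truth$is_canonical_28,
                   c("protein_id", "frame_start", "frame_end")]
  rownames(got) <- rownames(want) <- NULL
  expect_identical(got, want)
  # zero false positives on domain-free controls
  expect_false(any(grepl("^ctrl", hits$protein_id)))
  # per-transcript domain counts within the configured range
  counts <- table(hits$protein_id)
  expect_true(all(counts >= 3 & counts <= 30))
})

test_that("an all-control transcriptome has no domains", {
  cfg <- sim_config(seed = 2, n_zf_transcripts = 0,
                    n_control_transcripts = 5)
  tx <- make_transcriptome(cfg)
  expect_equal(nrow(tx$truth), 0L)
  expect_equal(nrow(scan_proteins(tx$proteins)), 0L)
  expect_true(all(nchar(tx$proteins) >= cfg$orf_length_range[1]))
})

test_that("a planted length census is recovered by the scanner", {
  cfg <- sim_config(seed = 13, census = list(canonical = 100, total = 120))
  tx <- make_transcriptome(cfg)
  expect_equal(sum(tx$truth$is_canonical_28), 100L)
  expect_equal(nrow(tx$truth), 120L)
  hits <- scan_proteins(tx$proteins)
  expect_equal(nrow(hits), 120L)
  expect_equal(sum(hits$is_canonical_28), 100L)
})

test_that("unenriched footprints score at the domain codon fraction", {
  cfg <- sim_config(seed = 31, n_zf_transcripts = 200,
                    n_control_transcripts = 0,
                    domains_per_transcript = c(3L, 10L),
                    enrichment = 1, beta = 0)
  tx <- make_transcriptome(cfg)
  fp <- simulate_footprints(tx, cfg)
  scores <- do.call(rbind, lapply(names(fp$tracks), function(id)
    localization_score(fp$tracks[[id]], fp$masks[[id]])))
  scored <- scores$group == "scored"
  expect_gt(mean(scored), 0.95)
  dev <- scores$score[scored] -
    fp$truth$domain_codon_fraction[match(scores$transcript_id[scored],
                                         fp$truth$transcript_id)]
  expect_lt(abs(mean(dev)), 3 * sd(dev) / sqrt(sum(scored)))
})

test_that("in-domain enrichment raises localization scores", {
  base <- list(seed = 31, n_zf_transcripts = 50, n_control_transcripts = 0)
  scores_at <- function(enr) {
    cfg <- do.call(sim_config, c(base, list(enrichment = enr)))
    tx <- make_transcriptome(cfg)
    fp <- simulate_footprints(tx, cfg)
    vapply(names(fp$tracks), function(id)
      localization_score(fp$tracks[[id]], fp$masks[[id]])$score, numeric(1))
  }
  s10 <- scores_at(10)
  s1 <- scores_at(1)
  expect_gt(mean(s10), mean(s1))
  ht <- wilcox.test(s10, s1, alternative = "greater")
  expect_lt(ht$p.value, 0.01)
})

test_that("charge coupling shifts observed profiles above the null in the exit-tunnel band", {
  cfg <- sim_config(seed = 17, n_zf_transcripts = 20,
                    n_control_transcripts = 0,
                    domains_per_transcript = c(3L, 8L), beta = 0.5)
  tx <- make_transcriptome(cfg)
  fp <- simulate_footprints(tx, cfg)
  asites <- observed_domain_asites(fp$tracks, tx$truth)
  obs <- window_charge_profile(tx$proteins, asites, max_offset = 25)
  band <- 15:24  # offsets 14..23: windows 15-29 residues upstream
  obs_band <- mean(obs$mean_charge[band], na.rm = TRUE)
  null_band <- vapply(1:199, function(k) {
    r <- randomized_charge_profile(tx$truth, tx$proteins,
                                   n_positions = sum(asites$weight),
                                   seed = 1000 + k, max_offset = 25)
    mean(r$mean_charge[band], na.rm = TRUE)
  }, numeric(1))
  p <- (1 + sum(null_band >= obs_band)) / (1 + length(null_band))
  expect_lt(p, 0.01)
})

test_that("expression simulation embodies the stabilization ground truth", {
  groups <- setNames(rep(c("high", "middle", "low", "control"), each = 25),
                     sprintf("g%03d", 1:100))
  tc_genes <- sprintf("g%03d", 1:10)   # transcription-driven changes
  cfg <- sim_config(seed = 41)
  sim <- simulate_expression(groups, cfg, transcription_changed = tc_genes)
  expect_equal(dim(sim$transcript), c(100L, 4L))
  expect_true(all(sim$transcript >= sim$exon))
  expect_equal(sum(sim$truth$decay_stabilized), 15L)  # 25 high - 10 tc
  fc <- cpm_log2fc(sim$transcript, "wt_6hpf", "mz_6hpf")
  hi <- fc$lfc[sim$truth$decay_stabilized]
  lo <- fc$lfc[sim$truth$group == "low"]
  expect_gt(mean(hi), mean(lo))
  # transcription-changed genes shrink toward 0 after intron adjustment;
  # shown in the low-dispersion mode that isolates the count arithmetic
  # from sampling noise
  cfg_tight <- sim_config(seed = 41, base_mean = 10000, dispersion = 0.001)
  sim2 <- simulate_expression(groups, cfg_tight,
                              transcription_changed = tc_genes)
  adj <- intron_adjusted_lfc(sim2$transcript, sim2$exon,
                             "wt_6hpf", "mz_6hpf")
  tc <- adj[adj$gene %in% tc_genes, ]
  expect_true(all(abs(tc$adjusted_lfc) < abs(tc$lfc_mature)))
  expect_gt(min(tc$lfc_mature), 0.3)
})

test_that("spike-in renormalization removes the shared recovery drift", {
  cfg <- sim_config(seed = 19, sigma_log2 = 0, spikein_sigma = 0,
                    drift_log2_24h = 0.5)
  sim <- simulate_bric(30, cfg, halflives = 6)
  raw <- fit_halflives(sim$courses)
  renorm <- fit_halflives(spikein_renormalize(sim$courses))
  # unbiased (exact, since noiseless) after renormalization
  expect_true(all(abs(renorm$half_life - 6) < 1e-9))
  # biased without: drift flattens the apparent decay
  expect_true(all(raw$half_life > 6 + 0.1))
})

test_that("noisy decay courses are recovered within tolerance", {
  cfg <- sim_config(seed = 23, sigma_log2 = 0.2)
  sim <- simulate_bric(100, cfg, halflives = 6)
  fits <- fit_halflives(spikein_renormalize(sim$courses))
  rel_err <- abs(fits$half_life - 6) / 6
  expect_lt(median(rel_err, na.rm = TRUE), 0.15)
})
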