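make_track <- function(disome, mono = rep(0L, length(disome)), id = "tx") {
  codon_track(id, mono, disome)
}

test_that("A-site assignment applies fixed per-class offsets", {
  expect_equal(assign_asite(0, "monosome"), 5L)
  expect_equal(assign_asite(3, "disome"), 16L)
  expect_true(is.na(assign_asite(30, "monosome", n_codons = 15)))
  expect_error(assign_asite(-1, "monosome"), "negative")
})

test_that("disome occupancy self-normalizes to mean 1", {
  expect_equal(disome_occupancy(make_track(rep(3L, 8))), rep(1, 8))
  expect_equal(disome_occupancy(make_track(c(0L, 0L, 6L, 0L, 0L, 0L))),
               c(0, 0, 6, 0, 0, 0))
  tr <- make_track(c(1L, 2L, 3L, 4L))
  expect_equal(disome_occupancy(tr),
               disome_occupancy(make_track(c(2L, 4L, 6L, 8L))))
  expect_equal(mean(disome_occupancy(tr)), 1, tolerance = 1e-9)
  # domain-region normalization: mean over the mask is 1
  mask <- domain_mask("tx", 0, 2)
  occ <- disome_occupancy(tr, "domains", mask)
  expect_equal(mean(occ[1:2]), 1, tolerance = 1e-9)
  expect_message(
    expect_null(disome_occupancy(make_track(rep(0L, 4)))), "zero")
})

test_that("localization score honors the 10-read filter boundary", {
  mask <- domain_mask("tx", 2, 6)
  # 8 in-domain + 2 outside = exactly 10 reads: scored, 0.8
  tr <- make_track(c(1L, 0L, 2L, 2L, 2L, 2L, 0L, 1L))
  s <- localization_score(tr, mask)
  expect_equal(s$score, 0.8)
  expect_equal(s$group, "scored")
  # 9 reads: below the filter
  tr9 <- make_track(c(1L, 0L, 2L, 2L, 2L, 2L, 0L, 0L))
  expect_equal(localization_score(tr9, mask)$group, "unscored")
  # no domains: score 0, flagged
  s0 <- localization_score(tr, NULL)
  expect_equal(s0$score, 0)
  expect_true(s0$domain_free)
})

test_that("localization score equals the brute-force oracle and scales", {
  set.seed(33)
  for (i in 1:200) {
    n <- sample(20:120, 1)
    dis <- rpois(n, 0.8)
    if (sum(dis) == 0) dis[1] <- 1L
    ndom <- sample(1:3, 1)
    bounds <- sort(sample(0:n, 2 * ndom))
    starts <- bounds[seq(1, 2 * ndom, 2)]
    ends <- bounds[seq(2, 2 * ndom, 2)]
    keep <- ends > starts
    if (!any(keep)) next
    mask <- domain_mask("tx", starts[keep], ends[keep])
    tr <- make_track(as.integer(dis))
    s <- localization_score(tr, mask, min_reads = 1)
    expect_equal(s$score, oracle_loc_score(dis, starts[keep], ends[keep]))
    # invariant under count scaling
    k <- sample(2:9, 1)
    s2 <- localization_score(make_track(as.integer(dis * k)), mask,
                             min_reads = 1)
    expect_equal(s2$score, s$score)
  }
})

test_that("complementary masks partition the reads", {
  dis <- c(3L, 1L, 0L, 5L, 2L, 2L)
  tr <- make_track(dis)
  a <- localization_score(tr, domain_mask("tx", 0, 3), min_reads = 1)
  b <- localization_score(tr, domain_mask("tx", 3, 6), min_reads = 1)
  expect_equal(a$domain_reads + b$domain_reads, a$total_reads)
})

test_that("region read fraction reproduces interval arithmetic", {
  # 18 of 59 reads inside the region of interest -> 30.5%
  dis <- integer(59)
  dis[1:18] <- 1L   # region codons 0..17
  dis[19:59] <- 1L
  tr <- make_track(dis)
  expect_equal(round(100 * region_read_fraction(tr, 0, 18), 1), 30.5)
  expect_equal(region_read_fraction(tr, 0, 59), 1)
  expect_equal(region_read_fraction(tr, 5, 5), 0)
  expect_error(region_read_fraction(make_track(rep(0L, 4)), 0, 2),
               "undefined")
})

test_that("score grouping makes balanced, deterministic tertiles", {
  sc <- data.frame(transcript_id = c("a", "b", "c"),
                   domain_reads = 1L, total_reads = 10L,
                   score = c(0.9, 0.5, 0.1), group = "scored",
                   domain_free = FALSE)
  g <- group_by_score(sc)
  expect_equal(g$group, c("high", "middle", "low"))

  sc10 <- data.frame(transcript_id = sprintf("t%02d", 1:10),
                     domain_reads = 1L, total_reads = 10L,
                     score = seq(1, 0.1, by = -0.1), group = "scored",
                     domain_free = FALSE)
  g10 <- group_by_score(sc10)
  expect_equal(as.integer(table(g10$group)[c("high", "middle", "low")]),
               c(4L, 3L, 3L))
  # partition: every scored transcript in exactly one group
  expect_true(all(g10$group %in% c("high", "middle", "low")))

  # all-equal scores: tie-break by transcript id, still balanced
  sc10$score <- 0.5
  gt <- group_by_score(sc10)
  expect_equal(gt$group[order(gt$transcript_id)],
               rep(c("high", "middle", "low"), c(4, 3, 3)))
  expect_error(group_by_score(sc[1:2, ]), "fewer")
})

test_that("unscored transcripts pass through grouping unchanged", {
  sc <- data.frame(transcript_id = c("a", "b", "c", "d"),
                   domain_reads = 1L, total_reads = c(10L, 10L, 10L, 5L),
                   score = c(0.9, 0.5, 0.1, 0.7),
                   group = c("scored", "scored", "scored", "unscored"),
                   domain_free = FALSE)
  g <- group_by_score(sc)
  expect_equal(g$group, c("high", "middle", "low", "unscored"))
})

test_that("simple peak caller flags isolated spikes only", {
  expect_equal(call_peaks_simple(make_track(rep(4L, 30))), integer())
  dis <- integer(40); dis[21] <- 100L
  expect_equal(call_peaks_simple(make_track(dis)), 20L)
  # hand z-scores: mean 2, sd ~3.74 on this toy; only the 20 passes z >= 4
  toy <- c(rep(1L, 18), 20L, 1L)
  z <- (toy - mean(toy)) / sd(toy)
  expect_equal(call_peaks_simple(make_track(toy)),
               which(toy >= 5 & z >= 4) - 1L)
})

test_that("site occupancy tables correlate perfectly when regions coincide", {
  set.seed(9)
  n <- 60
  codons <- sample(setdiff(names(Biostrings::GENETIC_CODE),
                           c("TAA", "TAG", "TGA")), n, replace = TRUE)
  dis <- rpois(n, 2)
  tr <- codon_track("tx", rep(0L, n), as.integer(dis), codons = codons)
  res <- site_occupancy_pairs(list(tr),
                              list(tx = domain_mask("tx", 0, n)))
  expect_equal(unname(res$rho), rep(1, 3), tolerance = 1e-12)
  expect_true(all(c("A", "P", "E") %in% res$table$site))
})

test_that("site occupancy means match a hand aggregation on a toy track", {
  codons <- c("AAA", "AAA", "GGG", "AAA", "GGG", "CCC")
  dis <- c(0L, 0L, 2L, 4L, 6L, 0L)
  tr <- codon_track("tx", rep(0L, 6), dis, codons = codons)
  res <- site_occupancy_pairs(list(tr), list(tx = domain_mask("tx", 0, 6)))
  occ <- dis / mean(dis)
  a <- res$table[res$table$site == "A" & res$table$region == "orf", ]
  # A-site codons (index >= 2, 0-based): GGG at occ[3], AAA at occ[4], GGG occ[5]
  expect_equal(a$mean_occupancy[a$codon == "AAA"], occ[4])
  expect_equal(a$mean_occupancy[a$codon == "GGG"], mean(occ[c(3, 5)]))
})

test_that("count tracks round-trip through sparse TSV", {
  trs <- list(t1 = make_track(c(0L, 3L, 0L, 1L), id = "t1"),
              t2 = make_track(c(2L, 0L), c(1L, 1L), id = "t2"))
  f1 <- tempfile(); f2 <- tempfile()
  write_count_tracks(trs, f1, f2)
  back <- read_count_tracks(f1, f2)
  expect_equal(back$t1$disome, trs$t1$disome)
  expect_equal(back$t2$monosome, trs$t2$monosome)
  expect_equal(back$t2$n_codons, 2L)
})
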