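test_that("P-site assignment applies offset, length filter and ref checks", {
  m <- transcript_models("tx1", "g1",
                         paste0(strrep("A", 50), "ATGGCTGCTTAA",
                                strrep("C", 138)),
                         50, 62)
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "a.sam")
  write_hand_sam(sam, "tx1", 200L, list(
    list(qname = "r1", rname = "tx1", pos = 101L, len = 29L),
    list(qname = "r2", rname = "tx1", pos = 101L, len = 27L),  # too short
    list(qname = "r3", rname = "tx1", pos = 1L, len = 30L),
    list(qname = "r4", rname = "tx1", pos = 150L, len = 28L)))
  prof <- assign_psites(sam, m, length_range = c(28, 30), offset = 12)
  cnt <- prof$counts$tx1
  # 1-based pos 101 = 0-based 100; P-site at 100 + 12 = 112
  expect_equal(cnt[113], 1L)
  expect_equal(cnt[13], 1L)
  expect_equal(cnt[162], 1L)
  expect_equal(sum(cnt), 3L)
  expect_equal(prof$library_total, 3L)
  expect_error(assign_psites(sam, m, length_range = c(30, 28)),
               "length_range")

  sam2 <- file.path(dir, "b.sam")
  write_hand_sam(sam2, c("tx1", "other"), c(200L, 100L), list(
    list(qname = "r1", rname = "other", pos = 10L, len = 29L)))
  expect_warning(p2 <- assign_psites(sam2, m), "unknown reference")
  expect_equal(sum(p2$counts$tx1), 0L)

  sam3 <- file.path(dir, "c.sam")
  write_hand_sam(sam3, "tx1", 200L, list())
  p3 <- assign_psites(sam3, m)
  expect_equal(sum(p3$counts$tx1), 0L)
})

test_that("ORFscore matches hand arithmetic, sign rule and symmetry", {
  expect_equal(orfscore(10, 10, 10), 0)
  expect_equal(orfscore(30, 10, 10), log2(17), tolerance = 1e-12)
  expect_equal(orfscore(10, 30, 10), -log2(17), tolerance = 1e-12)
  expect_true(is.na(orfscore(0, 0, 0)))
  set.seed(5)
  for (i in 1:50) {
    f <- rpois(3, 20)
    expect_equal(orfscore(f[1], f[2], f[3]),
                 orfscore_oracle(f[1], f[2], f[3]), tolerance = 1e-12)
    # F1/F2 exchange leaves the score unchanged
    expect_equal(orfscore(f[1], f[2], f[3]), orfscore(f[1], f[3], f[2]))
    # uniform scaling strictly increases the magnitude of nonzero scores
    s1 <- orfscore(f[1], f[2], f[3])
    if (!is.na(s1) && s1 != 0)
      expect_gt(abs(orfscore(3 * f[1], 3 * f[2], 3 * f[3])), abs(s1))
  }
})

test_that("confidence tiers use strict per-species thresholds", {
  th_h <- species_thresholds("human")
  th_z <- species_thresholds("zebrafish")
  expect_equal(classify_confidence(6.2, th_h), "high")
  expect_equal(classify_confidence(4.6, th_z), "medium")
  expect_equal(classify_confidence(c(6, 4, 2), th_h),
               c("medium", "low", "none"))
  expect_equal(classify_confidence(c(5.5, 4.5, 3), th_z),
               c("medium", "low", "none"))
  expect_equal(classify_confidence(NA_real_, th_h), "none")
  expect_error(classify_confidence(1, list(high = 2, medium = 3, low = 1)))
})

test_that("ORF scoring excludes terminal codons and applies the count floor", {
  cds <- paste0("ATG", paste(rep("GCT", 18), collapse = ""), "TAA")
  m <- toy_model(strrep("C", 30), cds, strrep("C", 30))
  cnt <- integer(m$length)
  # frame-0 P-sites on interior codons, plus heavy terminal-codon signal
  interior <- m$cds_start + 3 * (1:18)
  cnt[interior + 1] <- 2L
  cnt[m$cds_start + 1] <- 50L            # start codon, excluded
  cnt[m$cds_end - 3 + 1] <- 50L          # stop codon, excluded
  prof <- make_profiles(list(tx1 = cnt))
  cat <- data.frame(transcript_id = "tx1", gene_id = "g1",
                    region_class = "CDS", start_codon = "ATG",
                    orf_start = m$cds_start, orf_end = m$cds_end,
                    n_codons = 19L, frame_rel_cds = 0L,
                    iutr_length = NA_integer_, stringsAsFactors = FALSE)
  sc <- score_orfs(cat, prof, min_psites = 10)
  expect_equal(sc$n_psites, 36)
  expect_equal(sc$f0, 36)
  expect_equal(sc$in_frame_proportion, 1)
  expect_equal(sc$orfscore, orfscore(36, 0, 0))

  sc_all <- score_orfs(cat, prof, exclude_terminal_codons = FALSE)
  expect_equal(sc_all$n_psites, 136)

  sc_floor <- score_orfs(cat, prof, min_psites = 37)
  expect_true(is.na(sc_floor$orfscore))
  expect_equal(sc_floor$confidence, "none")
})

test_that("greedy dORF pruning keeps the best of each overlap cluster", {
  mk <- function(start, end, score, tx = "t1")
    data.frame(transcript_id = tx, gene_id = "g", region_class = "dORF",
               start_codon = "ATG", orf_start = start, orf_end = end,
               n_codons = (end - start) / 3 - 1, frame_rel_cds = 0L,
               iutr_length = 0L, f0 = 0L, f1 = 0L, f2 = 0L, n_psites = 0L,
               orfscore = score, in_frame_proportion = NA_real_,
               confidence = "low", stringsAsFactors = FALSE)
  disjoint <- rbind(mk(0, 33, 5), mk(60, 93, 4))
  expect_equal(nrow(select_nonoverlapping_dorfs(disjoint)), 2L)

  mutual <- rbind(mk(0, 60, 7), mk(30, 90, 5), mk(45, 105, 3))
  kept <- select_nonoverlapping_dorfs(mutual)
  expect_equal(kept$orfscore, 7)

  # chain: A-B overlap, B-C overlap, A-C disjoint, scores A > B > C
  chain <- rbind(mk(0, 60, 7), mk(45, 120, 5), mk(100, 160, 3))
  kept <- select_nonoverlapping_dorfs(chain)
  expect_equal(sort(kept$orfscore), c(3, 7))

  # ties: 5'-most start, then start-codon priority
  tie <- rbind(mk(30, 63, 5), mk(0, 63, 5))
  expect_equal(select_nonoverlapping_dorfs(tie)$orf_start, 0)
})

test_that("metagene profile normalizes to 1 and handles degenerate inputs", {
  set.seed(9)
  mods <- transcript_models(
    paste0("t", 1:5), paste0("g", 1:5),
    vapply(1:5, function(i) random_seq(60 + 90 + 60), ""),
    rep(60, 5), rep(150, 5))
  uniform <- make_profiles(stats::setNames(
    lapply(1:5, function(i) rep(1L, 210)), paste0("t", 1:5)))
  mg <- metagene_profile(uniform, mods, window = 50, top_n = 5,
                         min_feature_len = 50)
  expect_equal(sum(mg$mean_value), 1, tolerance = 1e-9)
  expect_true(all(abs(mg$mean_value - 1 / 100) < 1e-12))

  delta <- stats::setNames(lapply(1:5, function(i) {
    v <- integer(210); v[61] <- 10L; v
  }), paste0("t", 1:5))
  mgd <- metagene_profile(make_profiles(delta), mods, window = 50,
                          top_n = 5, min_feature_len = 50)
  expect_equal(mgd$mean_value[mgd$anchor == "start" & mgd$rel_pos == 0], 1)
  expect_equal(sum(mgd$mean_value), 1)
  expect_error(metagene_profile(uniform, mods, window = 51),
               "window must be even")
  expect_error(metagene_profile(uniform, mods, min_feature_len = 100),
               "length filters")
})

test_that("RNA coverage bias is zero under uniformity and finite at zero", {
  cov <- rep(5, 400)
  b <- region_coverage_bias(cov, list(utr3 = c(300, 400)),
                            cds_start = 60, cds_end = 300)
  expect_equal(unname(b["utr3"]), 0)
  cov2 <- c(rep(5, 300), rep(10, 100))
  b2 <- region_coverage_bias(cov2, list(utr3 = c(300, 400)),
                             cds_start = 60, cds_end = 300)
  expect_equal(unname(b2["utr3"]), log2(10.05 / 5.05), tolerance = 1e-12)
  cov3 <- c(rep(5, 300), rep(0, 100))
  b3 <- region_coverage_bias(cov3, list(utr3 = c(300, 400)),
                             cds_start = 60, cds_end = 300)
  expect_true(is.finite(b3["utr3"]) && b3["utr3"] < -5)
  expect_error(region_coverage_bias(cov, list(bad = c(380, 420)),
                                    cds_start = 60, cds_end = 300),
               "outside")
})
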