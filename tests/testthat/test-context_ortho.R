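test_that("context extraction pads with N outside the transcript", {
  seqs <- paste0(strrep("C", 10), "ATG", strrep("G", 7))
  ctx <- extract_start_context(seqs, 10)
  expect_equal(nchar(ctx), 20L)
  expect_equal(ctx, paste0(strrep("C", 10), "ATG", strrep("G", 7)))
  expect_equal(substr(ctx, 11, 13), "ATG")

  short <- extract_start_context(paste0("CCCCC", "ATG", strrep("G", 12)), 5)
  expect_equal(substr(short, 1, 5), "NNNNN")
  expect_equal(substr(short, 6, 10), "CCCCC")
  expect_equal(substr(short, 11, 13), "ATG")

  m <- context_matrix(c(ctx, short))
  expect_equal(unname(colSums(m)), c(rep(1L, 5), rep(2L, 15)))
})

test_that("positional bias finds planted composition shifts and masks the codon", {
  set.seed(71)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  n <- 300
  ctx <- vapply(1:n, function(i)
    paste0(random_seq(3, rep(0.25, 4)), "A", random_seq(6, rep(0.25, 4)),
           "ATG", random_seq(7, rep(0.25, 4))), "")
  pb <- positional_bias(ctx, bg)
  expect_true(all(pb$masked[11:13]))
  expect_true(all(is.na(pb$p_value[pb$masked])))
  planted <- pb[pb$rel_pos == -7, ]
  expect_lt(planted$p_value, 1e-10)
  ratios <- attr(pb, "ratios")
  expect_equal(unname(ratios["A", 4]), 4, tolerance = 1e-9)
  # positions drawn from the background itself stay near the null
  null_p <- pb$p_value[!pb$masked & pb$rel_pos != -7]
  expect_gt(mean(null_p > 0.05), 0.5)

  expect_error(positional_bias(ctx, c(A = 0.5, C = 0.5, G = 0, T = 0)),
               "positive frequency")
  expect_error(positional_bias(ctx[1:5], bg), "at least 20")
})

test_that("4-mer enrichment is null for identical sets and complete over 256", {
  set.seed(72)
  ctx <- vapply(1:150, function(i)
    paste0(random_seq(10), "CTG", random_seq(7)), "")
  fe <- fourmer_enrichment(ctx, ctx)
  expect_equal(nrow(fe), 256L)
  expect_equal(sum(fe$count_translated), 150L)
  expect_true(all(abs(fe$log2_fc) < 1e-12))
  expect_true(all(fe$p_value[fe$count_translated > 0] > 1 - 1e-9))
  expect_equal(fe$fourmer[1:2], c("AAAA", "AAAC"))
})

test_that("4-mer binomial p-values equal the exact tail-sum oracle", {
  set.seed(73)
  tr <- vapply(1:180, function(i)
    paste0(random_seq(10), "ATG", random_seq(7)), "")
  un <- vapply(1:220, function(i)
    paste0(random_seq(10), "ATG", random_seq(7)), "")
  fe <- fourmer_enrichment(tr, un)
  n_t <- sum(fe$count_translated)
  n_c <- sum(fe$count_control)
  for (i in which(fe$count_control > 0)) {
    expect_equal(fe$p_value[i],
                 binom_p_oracle(fe$count_translated[i], n_t,
                                fe$count_control[i] / n_c),
                 tolerance = 1e-9)
  }
  expect_true(all(fe$control_zero == (fe$count_control == 0)))
})

test_that("context PCA is deterministic in sign and respects geometry", {
  set.seed(74)
  freqs <- lapply(1:4, function(i) runif(40))
  names(freqs) <- c("ATG", "CTG", "GTG", "TTG")
  freqs$CTG2 <- freqs$CTG
  pc <- context_pca(freqs)
  expect_equal(nrow(pc), 5L)
  ctg <- pc[pc$class %in% c("CTG", "CTG2"), ]
  expect_equal(ctg$PC1[1], ctg$PC1[2])
  expect_equal(ctg$PC2[1], ctg$PC2[2])

  # pairwise distances in PC space match an independent eigendecomposition
  x <- do.call(rbind, freqs[1:4])
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(xc))
  proj <- xc %*% ev$vectors[, 1:2]
  pc4 <- context_pca(freqs[1:4])
  expect_equal(as.numeric(dist(pc4[, c("PC1", "PC2")])),
               as.numeric(dist(proj)), tolerance = 1e-8)

  # one extra row per supplied reference profile
  with_ref <- context_pca(freqs[1:4], reference = list(kozak = runif(40)))
  expect_equal(nrow(with_ref), 5L)
  expect_true("kozak" %in% with_ref$class)

  const <- lapply(1:3, function(i) c(1, runif(5)))
  names(const) <- c("a", "b", "c")
  expect_warning(context_pca(const), "constant")
  expect_error(context_pca(freqs[1:2]), "at least 3")
})

test_that("ortholog bootstrap null matches the sampling expectation", {
  pairs <- data.frame(a = paste0("h", 1:100), b = paste0("z", 1:100))
  set_a <- paste0("h", 1:20)
  set_b <- paste0("z", 51:80)
  bt <- ortholog_bootstrap(pairs, set_a, set_b, n_iter = 1000, seed = 99)
  expect_equal(bt$observed, 0)
  # E[overlap] = m*n/N = 6; sample mean within 3 SE
  se <- stats::sd(bt$null_draws) / sqrt(bt$n_iter)
  expect_lt(abs(bt$null_mean - 6), 3 * se)
  expect_lt(bt$observed, bt$ci[1])
  expect_lt(bt$p_value, 1e-10)

  bt2 <- ortholog_bootstrap(pairs, set_a, set_b, n_iter = 1000, seed = 99)
  expect_identical(bt$null_draws, bt2$null_draws)

  expect_message(
    ortholog_bootstrap(pairs, c(set_a, "not_there"), set_b, n_iter = 10,
                       seed = 1),
    "outside the ortholog universe")
  # planted coincident sets: observed overlap sits far above the null
  bt3 <- ortholog_bootstrap(pairs, paste0("h", 1:30), paste0("z", 1:30),
                            n_iter = 500, seed = 3)
  expect_equal(bt3$observed, 30)
  expect_gt(bt3$observed, bt3$ci[2])
  expect_error(ortholog_bootstrap(data.frame(a = c("h1", "h1"),
                                             b = c("z1", "z2")),
                                  "h1", "z1"), "one-to-one")
})
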