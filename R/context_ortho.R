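BASES <- c("A", "C", "G", "T")

#' Extract the nucleotide context around a start codon
#'
#' Returns the window `[orf_start - up, orf_start + 3 + down)` (default 20 nt:
#' 10 upstream bases, the 3-base start codon, 7 downstream bases). Positions
#' falling outside the transcript are padded with `N`, which is excluded from
#' all downstream counting.
#'
#' @param sequence transcript sequence.
#' @param orf_start 0-based first base of the start codon.
#' @param up,down flanking lengths in nt.
#' @return character vector of fixed-width context strings.
#' @export
extract_start_context <- function(sequence, orf_start, up = 10L, down = 7L) {
  if (length(sequence) == 1L) sequence <- rep(sequence, length(orf_start))
  if (length(sequence) != length(orf_start))
    stop("sequence must have length 1 or length(orf_start)")
  width <- up + 3L + down
  vapply(seq_along(orf_start), function(i) {
    len <- nchar(sequence[i])
    from <- orf_start[i] - up
    pos <- from:(from + width - 1L)
    chars <- rep("N", width)
    inside <- pos >= 0L & pos < len
    if (any(inside))
      chars[inside] <- substring(sequence[i], pos[inside] + 1L,
                                 pos[inside] + 1L)
    paste(chars, collapse = "")
  }, character(1))
}

#' Per-position base-count matrix of a context set
#'
#' @param contexts equal-width context strings (see
#'   [extract_start_context()]).
#' @return 4 x width integer matrix (rows A/C/G/T); `N` is not counted. The
#'   context count is in `attr(, "n_contexts")`.
#' @export
context_matrix <- function(contexts) {
  width <- unique(nchar(contexts))
  if (length(width) != 1L) stop("contexts must have equal width")
  m <- sapply(seq_len(width), function(j) {
    b <- substring(contexts, j, j)
    tabulate(match(b, BASES), nbins = 4L)
  })
  rownames(m) <- BASES
  attr(m, "n_contexts") <- length(contexts)
  m
}

#' Positional nucleotide bias around start codons
#'
#' At every position of the context window outside the masked start codon,
#' the observed base counts are tested against the background composition
#' (chi-squared, 3 df), and observed/background frequency ratios reported.
#'
#' @param contexts context strings, all with the start codon at the same
#'   offset.
#' @param background length-4 probability vector (A/C/G/T), e.g. the pooled
#'   mononucleotide composition of all 3'UTRs of the species.
#' @param up number of upstream bases in the window (start codon occupies
#'   positions `up+1 .. up+3`).
#' @return data.frame with `rel_pos` (0 = first base of the start codon),
#'   `masked`, `statistic`, `p_value`; frequency ratios are in
#'   `attr(, "ratios")`.
#' @export
positional_bias <- function(contexts, background, up = 10L) {
  if (length(contexts) < 20L)
    stop("need at least 20 contexts for positional testing")
  background <- background[BASES]
  if (any(is.na(background)) || any(background <= 0))
    stop("background must give positive frequency to A, C, G and T")
  background <- background / sum(background)
  m <- context_matrix(contexts)
  width <- ncol(m)
  masked <- seq_len(width) %in% (up + 1L):(up + 3L)
  stat <- pval <- rep(NA_real_, width)
  ratios <- matrix(NA_real_, 4L, width, dimnames = list(BASES, NULL))
  for (j in seq_len(width)) {
    n <- sum(m[, j])
    if (n > 0) ratios[, j] <- (m[, j] / n) / background
    if (masked[j] || n == 0) next
    ct <- suppressWarnings(stats::chisq.test(m[, j], p = background))
    stat[j] <- unname(ct$statistic)
    pval[j] <- ct$p.value
  }
  out <- data.frame(rel_pos = seq_len(width) - (up + 1L), masked = masked,
                    statistic = stat, p_value = pval)
  attr(out, "ratios") <- ratios
  out
}

#' The initiation 4-mer of a context
#'
#' Three bases upstream of the start codon plus the base immediately
#' downstream of it.
#'
#' @param contexts context strings.
#' @param up upstream flank length (start codon at `up+1 .. up+3`).
#' @return character vector of 4-mers.
#' @export
context_fourmer <- function(contexts, up = 10L) {
  paste0(substr(contexts, up - 2L, up),
         substr(contexts, up + 4L, up + 4L))
}

#' 4-mer enrichment in translated vs untranslated dORF contexts
#'
#' For each of the 256 possible 4-mers, a two-sided binomial test of the
#' translated count against the 4-mer's frequency among untranslated controls
#' of the same start-codon class, plus a log2 fold change of frequencies
#' (pseudocount 0.5 on counts). 4-mers absent from the controls take a
#' pseudocount success probability and are flagged (`control_zero`).
#'
#' @param translated_contexts,untranslated_contexts context strings of the
#'   same start-codon class.
#' @param up upstream flank length.
#' @return data.frame per 4-mer: counts, frequencies, `log2_fc`, `p_value`,
#'   `p_adj_bh`, `control_zero`.
#' @export
fourmer_enrichment <- function(translated_contexts, untranslated_contexts,
                               up = 10L) {
  if (!length(translated_contexts) || !length(untranslated_contexts))
    stop("both context sets must be nonempty")
  universe <- apply(expand.grid(BASES, BASES, BASES, BASES)[, 4:1], 1,
                    paste, collapse = "")
  count_of <- function(ctx) {
    fm <- context_fourmer(ctx, up)
    fm <- fm[!grepl("N", fm)]
    table(factor(fm, levels = universe))
  }
  t_cnt <- count_of(translated_contexts)
  c_cnt <- count_of(untranslated_contexts)
  n_t <- sum(t_cnt); n_c <- sum(c_cnt)
  p0 <- ifelse(c_cnt > 0, c_cnt / n_c, 0.5 / n_c)
  pval <- vapply(seq_along(universe), function(i)
    stats::binom.test(t_cnt[i], n_t, p = min(p0[i], 1))$p.value, numeric(1))
  lfc <- log2(((t_cnt + 0.5) / n_t) / ((c_cnt + 0.5) / n_c))
  data.frame(fourmer = universe,
             count_translated = as.integer(t_cnt),
             count_control = as.integer(c_cnt),
             freq_translated = as.numeric(t_cnt / n_t),
             freq_control = as.numeric(c_cnt / n_c),
             log2_fc = as.numeric(lfc), p_value = pval,
             p_adj_bh = stats::p.adjust(pval, method = "BH"),
             control_zero = as.integer(c_cnt) == 0L,
             stringsAsFactors = FALSE)
}

#' PCA of context frequency profiles across start-codon classes
#'
#' Rows are classes (per species and start codon, optionally plus a Kozak
#' reference profile); columns are frequency features (positional or 4-mer).
#' Columns are centered, constant columns dropped with a warning, and rows
#' projected onto the top two principal axes with a deterministic sign
#' convention (the largest-magnitude loading of each axis is positive).
#'
#' @param frequency_tables named list of equal-length numeric feature
#'   vectors, one per class.
#' @param reference optional named list of reference profiles (e.g. Kozak)
#'   appended as extra rows.
#' @return data.frame `class`, `PC1`, `PC2`; loadings and variance explained
#'   as attributes.
#' @export
context_pca <- function(frequency_tables, reference = NULL) {
  rows <- c(frequency_tables, reference)
  if (length(rows) < 3L) stop("need at least 3 classes for a PCA")
  x <- do.call(rbind, rows)
  rownames(x) <- names(rows)
  const <- apply(x, 2, function(v) diff(range(v)) == 0)
  if (any(const)) {
    warning("dropping ", sum(const), " constant feature column(s)")
    x <- x[, !const, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$rotation))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  out <- data.frame(class = rownames(x),
                    PC1 = scores[, 1],
                    PC2 = if (k >= 2L) scores[, 2] else 0,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "loadings") <- load
  attr(out, "var_explained") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  out
}

#' Bootstrap test of shared dORF presence across orthologs
#'
#' Given a one-to-one ortholog table and the dORF-containing gene sets of the
#' two species, counts ortholog pairs with both members in their species' set
#' and compares this observed overlap to a null built by sampling, in each of
#' `n_iter` iterations, the same numbers of genes uniformly without
#' replacement from the ortholog universe. Reports the null mean, a
#' percentile 95% CI, and a one-sample t-test of the null draws against the
#' observed overlap.
#'
#' @param pairs data.frame with two columns of gene ids (species A, B); each
#'   gene in at most one pair.
#' @param set_a,set_b dORF gene sets; members outside the universe are
#'   dropped (with a message).
#' @param n_iter bootstrap iterations.
#' @param seed optional integer seed.
#' @return object of class `ortholog_bootstrap`.
#' @export
ortholog_bootstrap <- function(pairs, set_a, set_b, n_iter = 1000L,
                               seed = NULL) {
  ua <- pairs[[1]]; ub <- pairs[[2]]
  if (anyDuplicated(ua) || anyDuplicated(ub))
    stop("ortholog table is not one-to-one")
  drop_a <- sum(!set_a %in% ua); drop_b <- sum(!set_b %in% ub)
  if (drop_a + drop_b > 0)
    message("dropped ", drop_a, " / ", drop_b,
            " set members outside the ortholog universe")
  set_a <- intersect(set_a, ua); set_b <- intersect(set_b, ub)
  N <- nrow(pairs)
  m <- length(set_a); n <- length(set_b)
  if (m > N || n > N) stop("gene set larger than the ortholog universe")
  observed <- sum(ua %in% set_a & ub %in% set_b)
  if (!is.null(seed)) set.seed(seed)
  null_draws <- vapply(seq_len(n_iter), function(i)
    length(intersect(sample.int(N, m), sample.int(N, n))), integer(1))
  structure(list(
    observed = observed, n_universe = N, n_set_a = m, n_set_b = n,
    null_mean = mean(null_draws),
    ci = stats::quantile(null_draws, c(0.025, 0.975), names = FALSE),
    p_value = stats::t.test(null_draws, mu = observed)$p.value,
    n_iter = n_iter, null_draws = null_draws),
    class = "ortholog_bootstrap")
}

#' @export
print.ortholog_bootstrap <- function(x, ...) {
  cat(sprintf(paste0("Ortholog overlap: observed %d of %d pairs ",
                     "(sets %d / %d); null mean %.2f, 95%% CI [%.1f, %.1f], ",
                     "t-test p = %.3g (%d iterations)\n"),
              x$observed, x$n_universe, x$n_set_a, x$n_set_b, x$null_mean,
              x$ci[1], x$ci[2], x$p_value, x$n_iter))
  invisible(x)
}
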