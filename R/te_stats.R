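#' Reads per kilobase per million (RPKM)
#'
#' @param counts read (or P-site) counts in the region.
#' @param region_length region length in nt.
#' @param library_total total mapped reads in the library.
#' @return numeric vector of RPKM values.
#' @export
compute_rpkm <- function(counts, region_length, library_total) {
  if (any(region_length <= 0)) stop("region_length must be positive")
  if (any(library_total <= 0)) stop("library_total must be positive")
  counts / (region_length / 1e3) / (library_total / 1e6)
}

#' Translation efficiency
#'
#' `log2((rpf_rpkm + pseudo) / (rna_rpkm + pseudo))`; exactly 0 when the two
#' densities are equal (including the all-zero case).
#'
#' @param rpf_rpkm,rna_rpkm footprint and RNA RPKM over the CDS (first and
#'   last coding codons excluded upstream, see [build_te_table()]).
#' @param pseudo pseudocount added to both densities.
#' @return numeric vector of log2 TE values.
#' @export
compute_te <- function(rpf_rpkm, rna_rpkm, pseudo = 0.05) {
  log2((rpf_rpkm + pseudo) / (rna_rpkm + pseudo))
}

#' Per-gene TE table from P-site and RNA profiles
#'
#' CDS counts for both layers are taken over the coding codons excluding the
#' first and the last one (strong initiation/termination peaks would
#' otherwise couple TE to ORF length): positions
#' `[cds_start + 3, cds_end - 6)`.
#'
#' @param models `transcript_models` table (one representative per gene).
#' @param rpf_profiles,rna_profiles `psite_profiles`-shaped objects for the
#'   footprint and RNA libraries.
#' @param pseudo TE pseudocount.
#' @return data.frame with per-gene counts, RPKMs, `rna_level`
#'   (`log2(rna_rpkm + pseudo)`) and `te`.
#' @export
build_te_table <- function(models, rpf_profiles, rna_profiles,
                           pseudo = 0.05) {
  region_start <- models$cds_start + 3L
  region_end <- models$cds_end - 6L
  if (any(region_end <= region_start))
    stop("CDS too short to exclude terminal codons for: ",
         paste(utils::head(
           models$transcript_id[region_end <= region_start]), collapse = ", "))
  n <- nrow(models)
  rpf <- rna <- numeric(n)
  for (i in seq_len(n)) {
    idx <- (region_start[i] + 1L):region_end[i]
    rpf[i] <- sum(rpf_profiles$counts[[models$transcript_id[i]]][idx])
    rna[i] <- sum(rna_profiles$counts[[models$transcript_id[i]]][idx])
  }
  len <- region_end - region_start
  rpf_rpkm <- compute_rpkm(rpf, len, rpf_profiles$library_total)
  rna_rpkm <- compute_rpkm(rna, len, rna_profiles$library_total)
  data.frame(gene_id = models$gene_id, transcript_id = models$transcript_id,
             region_length = len, rpf_counts = rpf, rna_counts = rna,
             rpf_rpkm = rpf_rpkm, rna_rpkm = rna_rpkm,
             rna_level = log2(rna_rpkm + pseudo),
             te = compute_te(rpf_rpkm, rna_rpkm, pseudo),
             stringsAsFactors = FALSE)
}

#' Filter to expressed genes
#'
#' Keeps genes whose `log2(rna_rpkm)` reaches `min_log2_rna` in at least one
#' sample; with a single sample the rule reduces to that sample.
#'
#' @param te_table a TE table, optionally with a `sample` column.
#' @param min_log2_rna expression floor on `log2(rna_rpkm)`.
#' @return the subset of `te_table` for the retained genes.
#' @export
filter_expressed <- function(te_table, min_log2_rna = 1) {
  lev <- log2(te_table$rna_rpkm)
  best <- tapply(lev, te_table$gene_id, max)
  keep_genes <- names(best)[best >= min_log2_rna]
  te_table[te_table$gene_id %in% keep_genes, , drop = FALSE]
}

#' Resample expression-matched control genes
#'
#' Controls matched to a target set on a feature (by default RNA level):
#' pool members below the target minimum are removed, the target feature is
#' cut into `n_quantiles` quantile bins (boundary values to the lower bin),
#' and each pool member is weighted by (target fraction in its bin) /
#' (pool count in its bin). `n_draws` controls are drawn without replacement
#' (with replacement, with a message, if the pool is smaller).
#'
#' @param target named numeric vector of the matching feature for target
#'   genes (names = gene ids), e.g. `rna_level` from [build_te_table()].
#' @param pool named numeric vector for candidate control genes (disjoint
#'   from the target set).
#' @param n_quantiles number of quantile bins.
#' @param n_draws number of controls to draw (default `length(target)`).
#' @param seed optional integer seed for reproducible draws.
#' @return list with `control_ids`, per-bin `target_counts` /
#'   `pool_counts` / `control_counts`, and the bin `breaks`.
#' @export
resample_matched_controls <- function(target, pool, n_quantiles = 10L,
                                      n_draws = length(target),
                                      seed = NULL) {
  if (any(names(pool) %in% names(target)))
    stop("pool must be disjoint from the target set")
  pool <- pool[pool >= min(target)]
  if (!length(pool)) stop("no pool genes at or above the target minimum")
  breaks <- stats::quantile(target, probs = seq(0, 1, length.out =
                                                  n_quantiles + 1L),
                            names = FALSE)
  # duplicated boundaries (heavily tied or tiny target sets) collapse into
  # wider bins instead of starving a zero-width quantile
  inner <- unique(breaks[-c(1L, length(breaks))])
  inner <- inner[inner < max(target)]
  n_bins <- length(inner) + 1L
  bin_of <- function(x) findInterval(x, inner, left.open = TRUE) + 1L
  t_bin <- bin_of(target)
  p_bin <- bin_of(pool)
  t_counts <- tabulate(t_bin, nbins = n_bins)
  p_counts <- tabulate(p_bin, nbins = n_bins)
  starved <- which(t_counts > 0L & p_counts == 0L)
  if (length(starved))
    stop("no control genes available in target quantile(s) ",
         paste(starved, collapse = ", "))
  w <- (t_counts / sum(t_counts))[p_bin] / p_counts[p_bin]
  if (!is.null(seed)) set.seed(seed)
  replace <- n_draws > length(pool)
  if (replace)
    message("pool smaller than n_draws; sampling with replacement")
  ids <- sample(names(pool), n_draws, replace = replace, prob = w)
  list(control_ids = ids,
       target_counts = t_counts, pool_counts = p_counts,
       control_counts = tabulate(bin_of(pool[ids]), nbins = n_bins),
       breaks = breaks, n_bins = n_bins)
}

#' Compare a target group against a control group
#'
#' Two-sided Wilcoxon rank-sum test (exact when both groups have at most 25
#' tie-free values, normal approximation with continuity correction
#' otherwise) plus group medians and their difference.
#'
#' @param values_target,values_control numeric vectors (e.g. TE values).
#' @return object of class `group_comparison`.
#' @export
compare_groups <- function(values_target, values_control) {
  if (!length(values_target) || !length(values_control))
    stop("both groups must be nonempty")
  exact <- length(values_target) <= 25L && length(values_control) <= 25L &&
    !anyDuplicated(c(values_target, values_control))
  wt <- stats::wilcox.test(values_target, values_control, exact = exact,
                           correct = TRUE)
  structure(list(
    n_target = length(values_target), n_control = length(values_control),
    median_target = stats::median(values_target),
    median_control = stats::median(values_control),
    delta_median_log2 = stats::median(values_target) -
      stats::median(values_control),
    p_value = wt$p.value, statistic = unname(wt$statistic)),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(paste0("Group comparison: n = %d vs %d; medians %.4f vs %.4f",
                     " (delta %.4f); Wilcoxon rank-sum p = %.3g\n"),
              x$n_target, x$n_control, x$median_target, x$median_control,
              x$delta_median_log2, x$p_value))
  invisible(x)
}

#' Cumulative-distribution table for plotting
#'
#' @param groups named list of numeric vectors.
#' @return data.frame `group`, `value`, `cum_fraction` (empirical CDF).
#' @export
cumulative_table <- function(groups) {
  do.call(rbind, lapply(names(groups), function(g) {
    v <- sort(groups[[g]])
    data.frame(group = g, value = v,
               cum_fraction = seq_along(v) / length(v),
               stringsAsFactors = FALSE)
  }))
}

#' Assign one stratum label per dORF-containing gene
#'
#' `count` bins genes by their number of retained dORFs (1 / 2 / 3+);
#' `start_codon` and `confidence` label each gene by its best-scoring dORF so
#' that the strata partition the gene set.
#'
#' @param retained_dorfs scored, overlap-pruned dORF rows.
#' @param by one of "count", "start_codon", "confidence".
#' @return data.frame `gene_id`, `stratum`.
#' @export
dorf_strata <- function(retained_dorfs,
                        by = c("count", "start_codon", "confidence")) {
  by <- match.arg(by)
  if (by == "count") {
    n <- table(retained_dorfs$gene_id)
    lab <- ifelse(n >= 3, "3+", as.character(n))
    return(data.frame(gene_id = names(n), stratum = unname(lab),
                      stringsAsFactors = FALSE))
  }
  sc <- retained_dorfs$orfscore
  sc[is.na(sc)] <- -Inf
  ord <- order(retained_dorfs$gene_id, -sc)
  best <- retained_dorfs[ord, ][!duplicated(retained_dorfs$gene_id[ord]), ]
  data.frame(gene_id = best$gene_id,
             stratum = if (by == "start_codon") best$start_codon
                       else best$confidence,
             stringsAsFactors = FALSE)
}

#' Quantile count adapted to the target-set size
#'
#' Expression matching uses `n_quantiles` bins, but never fewer than
#' `min_per_bin` targets per bin: small target sets fall back to coarser
#' matching (down to a single bin) instead of erroring on empty zero-width
#' quantiles.
#'
#' @param n_target number of target genes.
#' @param n_quantiles requested bin count.
#' @param min_per_bin minimum targets per bin.
#' @return integer bin count in `[1, n_quantiles]`.
#' @export
adaptive_quantiles <- function(n_target, n_quantiles = 10L,
                               min_per_bin = 10L) {
  max(1L, min(as.integer(n_quantiles), n_target %/% min_per_bin))
}

#' Matched-control TE comparison per stratum
#'
#' For each stratum of target genes, draws its own RNA-level-matched control
#' set from the pool (bin count adapted to the stratum size, see
#' [adaptive_quantiles()]) and compares TE distributions; raw rank-sum
#' p-values are reported alongside a Benjamini-Hochberg-adjusted column.
#'
#' @param te_table TE table (one row per gene) covering targets and pool.
#' @param strata data.frame `gene_id`, `stratum` (see [dorf_strata()]); use a
#'   single stratum for an unstratified comparison.
#' @param pool_ids gene ids eligible as controls (e.g. genes without dORFs).
#' @param n_quantiles,seed passed to [resample_matched_controls()]; the seed
#'   is advanced per stratum.
#' @param min_stratum warn below this target count (still computed).
#' @return data.frame, one row per stratum, plus a `comparisons` attribute
#'   holding the `group_comparison` objects.
#' @export
stratify_and_compare <- function(te_table, strata, pool_ids,
                                 n_quantiles = 10L, seed = 1L,
                                 min_stratum = 20L) {
  te <- stats::setNames(te_table$te, te_table$gene_id)
  lev <- stats::setNames(te_table$rna_level, te_table$gene_id)
  pool_ids <- intersect(pool_ids, te_table$gene_id)
  labs <- unique(strata$stratum)
  comps <- list()
  rows <- lapply(seq_along(labs), function(k) {
    ids <- intersect(strata$gene_id[strata$stratum == labs[k]],
                     te_table$gene_id)
    if (length(ids) < min_stratum)
      warning("stratum '", labs[k], "' has only ", length(ids), " genes")
    ctl <- resample_matched_controls(
      lev[ids], lev[pool_ids],
      n_quantiles = adaptive_quantiles(length(ids), n_quantiles),
      seed = seed + k)
    cmp <- compare_groups(te[ids], te[ctl$control_ids])
    comps[[labs[k]]] <<- cmp
    data.frame(stratum = labs[k], n_target = cmp$n_target,
               n_control = cmp$n_control,
               median_target = cmp$median_target,
               median_control = cmp$median_control,
               delta_median_log2 = cmp$delta_median_log2,
               p_value = cmp$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj_bh <- stats::p.adjust(out$p_value, method = "BH")
  attr(out, "comparisons") <- comps
  out
}
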