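#' Analysis configuration with the published defaults
#'
#' Collects the fixed constants of the analysis in one place: read-length
#' range and P-site offset, dORF codon bounds, per-species ORFscore tiers,
#' the TE pseudocount and expression floor, matching quantiles, metagene and
#' context-window settings, and the bootstrap iteration count.
#'
#' @param species "human", "zebrafish" or "custom".
#' @param ... overrides of individual fields.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(species = c("human", "zebrafish", "custom"),
                            ...) {
  species <- match.arg(species)
  cfg <- list(
    species = species,
    length_range = if (species == "zebrafish") c(28L, 29L) else c(28L, 30L),
    psite_offset = 12L,
    min_codons = 10L, max_codons = 100L,
    thresholds = species_thresholds(
      if (species == "zebrafish") "zebrafish" else "human"),
    min_psites = 10L,
    te_pseudocount = 0.05,
    min_log2_rna = 1,
    n_quantiles = 10L,
    metagene_top_n = 2000L, metagene_window = 100L,
    metagene_min_feature_len = 50L,
    context_up = 10L, context_down = 7L,
    bootstrap_iter = 1000L,
    seed = 1L)
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "analysis_config"
  cfg
}

#' Stage 1: candidate small-ORF discovery
#'
#' Wraps representative-isoform selection and catalog enumeration; the
#' summary reports the fraction of mRNAs carrying at least one candidate
#' dORF.
#'
#' @param models a `transcript_models` table (all isoforms).
#' @param config an [analysis_config()].
#' @return list with `models` (representatives), `catalog`, `summary`.
#' @export
run_discover <- function(models, config = analysis_config()) {
  if (!nrow(models)) stop("empty transcript set")
  reps <- select_representative_isoform(models)
  catalog <- build_orf_catalog(reps, config$min_codons, config$max_codons)
  n_dorf_genes <- length(unique(
    catalog$gene_id[catalog$region_class == "dORF"]))
  list(models = reps, catalog = catalog,
       summary = list(
         n_genes = nrow(reps),
         n_candidates = nrow(catalog),
         n_genes_with_dorf = n_dorf_genes,
         fraction_mrnas_with_dorf = n_dorf_genes / nrow(reps)))
}

#' Stage 2: ORFscore translation calling
#'
#' Scores every candidate against the P-site profiles, prunes overlapping
#' dORFs per transcript, and tabulates confidence tiers ("donut" summary)
#' and the reading-frame distribution of translated dORFs relative to the
#' canonical CDS.
#'
#' @param catalog candidate catalog from [run_discover()].
#' @param profiles a `psite_profiles` object.
#' @param config an [analysis_config()].
#' @return list with `scored`, `retained` (overlap-pruned), `dorfs`
#'   (retained translated dORFs), `tier_table`, `frame_table`.
#' @export
run_score <- function(catalog, profiles, config = analysis_config()) {
  scored <- score_orfs(catalog, profiles,
                       min_psites = config$min_psites,
                       thresholds = config$thresholds)
  retained <- select_nonoverlapping_dorfs(scored)
  dorfs <- retained[retained$region_class == "dORF" &
                      retained$confidence != "none", , drop = FALSE]
  tier_table <- as.data.frame(table(
    confidence = factor(dorfs$confidence,
                        levels = c("high", "medium", "low")),
    start_codon = factor(dorfs$start_codon,
                         levels = c("ATG", "CTG", "GTG", "TTG"))),
    stringsAsFactors = FALSE)
  frame_table <- as.data.frame(table(
    frame_rel_cds = factor(dorfs$frame_rel_cds, levels = 0:2)),
    stringsAsFactors = FALSE)
  list(scored = scored, retained = retained, dorfs = dorfs,
       tier_table = tier_table, frame_table = frame_table)
}

#' Stage 3: matched-control TE comparisons
#'
#' Applies the expression floor, then compares TE of translated-dORF genes
#' against RNA-level-matched resampled controls: overall and stratified by
#' dORF count, start codon and confidence tier.
#'
#' @param te_table per-gene TE table (see [build_te_table()]).
#' @param dorfs retained translated dORFs from [run_score()].
#' @param config an [analysis_config()].
#' @return list with `te_table` (filtered), `overall`
#'   (a `group_comparison`), `by_count`, `by_start_codon`, `by_confidence`
#'   (stratified tables), and `cumulative` (ECDF table of the overall
#'   comparison).
#' @export
run_te <- function(te_table, dorfs, config = analysis_config()) {
  te_table <- filter_expressed(te_table, config$min_log2_rna)
  target_ids <- intersect(unique(dorfs$gene_id), te_table$gene_id)
  if (!length(target_ids)) stop("no expressed dORF gene to compare")
  pool_ids <- setdiff(te_table$gene_id, unique(dorfs$gene_id))
  lev <- stats::setNames(te_table$rna_level, te_table$gene_id)
  te <- stats::setNames(te_table$te, te_table$gene_id)

  ctl <- resample_matched_controls(
    lev[target_ids], lev[pool_ids],
    n_quantiles = adaptive_quantiles(length(target_ids),
                                     config$n_quantiles),
    seed = config$seed)
  overall <- compare_groups(te[target_ids], te[ctl$control_ids])
  strat <- function(by) {
    s <- dorf_strata(dorfs[dorfs$gene_id %in% target_ids, , drop = FALSE],
                     by)
    stratify_and_compare(te_table, s, pool_ids,
                         n_quantiles = config$n_quantiles,
                         seed = config$seed)
  }
  list(te_table = te_table, overall = overall,
       by_count = strat("count"),
       by_start_codon = strat("start_codon"),
       by_confidence = strat("confidence"),
       cumulative = cumulative_table(list(
         dorf = unname(te[target_ids]),
         control = unname(te[ctl$control_ids]))))
}

#' Stage 4: JSON-ready analysis report
#'
#' Gathers the headline quantities of a run: candidate and translated-dORF
#' counts by tier and start codon, dORF/iUTR length medians with a
#' translated-vs-untranslated rank-sum test, the Pearson correlation between
#' 3'UTR length and dORF candidate count, and the TE comparison results;
#' optional metagene/context/bootstrap blocks are passed through.
#'
#' @param discover,scorestage,te outputs of the first three stages.
#' @param metagene,context,bootstrap optional extra result blocks.
#' @return list of class `dorf_report` (JSON-serializable).
#' @export
run_report <- function(discover, scorestage, te,
                       metagene = NULL, context = NULL, bootstrap = NULL) {
  models <- discover$models
  retained <- scorestage$retained
  dorf_all <- retained[retained$region_class == "dORF", , drop = FALSE]
  translated <- dorf_all$confidence != "none"

  length_tests <- list()
  for (feat in c("dorf_length", "iutr_length")) {
    v <- if (feat == "dorf_length") dorf_all$orf_end - dorf_all$orf_start
         else dorf_all$iutr_length
    lt <- list(median_translated = stats::median(v[translated]),
               median_untranslated = stats::median(v[!translated]),
               p_value = if (any(translated) && any(!translated))
                 suppressWarnings(stats::wilcox.test(
                   v[translated], v[!translated])$p.value) else NA_real_)
    length_tests[[feat]] <- lt
  }

  n_dorf <- table(factor(dorf_all$gene_id, levels = models$gene_id))
  u3 <- utr3_length(models)
  cor_res <- suppressWarnings(
    stats::cor.test(u3, as.numeric(n_dorf), method = "pearson"))

  report <- list(
    n_genes = nrow(models),
    n_candidates = discover$summary$n_candidates,
    fraction_mrnas_with_dorf = discover$summary$fraction_mrnas_with_dorf,
    n_translated_dorfs = sum(translated),
    tier_table = scorestage$tier_table,
    frame_table = scorestage$frame_table,
    length_tests = length_tests,
    utr3_dorf_correlation = list(pearson_r = unname(cor_res$estimate),
                                 p_value = cor_res$p.value),
    te_overall = unclass(te$overall),
    te_by_count = te$by_count,
    te_by_start_codon = te$by_start_codon,
    te_by_confidence = te$by_confidence)
  if (!is.null(metagene)) report$metagene <- as.data.frame(metagene)
  if (!is.null(context)) report$context <- context
  if (!is.null(bootstrap))
    report$bootstrap <- unclass(bootstrap)[c("observed", "null_mean", "ci",
                                             "p_value", "n_iter")]
  class(report) <- "dorf_report"
  report
}

#' Validate and write an analysis report as JSON
#'
#' `validate_report()` checks the report against the field manifest shipped
#' in `inst/extdata/report_schema.json` (required names and numeric
#' finiteness); `write_report()` validates and serializes.
#'
#' @param report a `dorf_report`.
#' @param path output JSON path.
#' @export
write_report <- function(report, path) {
  validate_report(report)
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", force = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
validate_report <- function(report) {
  schema <- jsonlite::read_json(
    system.file("extdata", "report_schema.json", package = "dorfscan"))
  missing <- setdiff(unlist(schema$required), names(report))
  if (length(missing))
    stop("report is missing required field(s): ",
         paste(missing, collapse = ", "))
  num <- c(report$fraction_mrnas_with_dorf, report$n_translated_dorfs,
           report$utr3_dorf_correlation$pearson_r,
           report$te_overall$delta_median_log2, report$te_overall$p_value)
  if (any(!is.finite(num)))
    stop("report contains non-finite headline values")
  invisible(TRUE)
}
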