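#' Assign ribosome P-sites from transcriptomic alignments
#'
#' Primary, forward-strand alignments with read length inside `length_range`
#' are reduced to a single P-site position per read: the 0-based 5' end plus
#' `offset` (default +12 nt). Counts are accumulated per transcript position;
#' P-sites falling off the transcript are discarded. Alignments to references
#' absent from `models` are skipped with a warning.
#'
#' @param path SAM or BAM file of single-segment alignments to transcript
#'   references.
#' @param models a `transcript_models` table naming the expected references.
#' @param length_range integer c(min, max) of retained read lengths
#'   (e.g. c(28, 30) for human footprints, c(28, 29) for zebrafish).
#' @param offset P-site offset from the read 5' end, in nt.
#' @return object of class `psite_profiles`: list with `counts` (named list
#'   of per-position integer vectors), `library_total`, `length_range`,
#'   `offset`.
#' @export
assign_psites <- function(path, models, length_range = c(28L, 30L),
                          offset = 12L) {
  if (length(length_range) != 2L || length_range[1] > length_range[2])
    stop("length_range must be c(min, max) with min <= max")
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else path
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag,
                                   what = c("rname", "pos", "qwidth",
                                            "strand"))
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  keep <- !is.na(rec$pos) & rec$strand == "+" &
    rec$qwidth >= length_range[1] & rec$qwidth <= length_range[2]
  rname <- as.character(rec$rname)[keep]
  psite <- rec$pos[keep] - 1L + as.integer(offset)

  counts <- lapply(models$length, function(n) integer(n))
  names(counts) <- models$transcript_id
  unknown <- setdiff(unique(rname), models$transcript_id)
  if (length(unknown)) {
    warning("skipping alignments to ", length(unknown),
            " unknown reference(s): ",
            paste(utils::head(unknown), collapse = ", "))
    in_set <- rname %in% models$transcript_id
    rname <- rname[in_set]; psite <- psite[in_set]
  }
  total <- 0L
  for (tx in unique(rname)) {
    p <- psite[rname == tx]
    p <- p[p >= 0L & p < length(counts[[tx]])]
    counts[[tx]] <- counts[[tx]] + tabulate(p + 1L, nbins = length(counts[[tx]]))
    total <- total + length(p)
  }
  structure(list(counts = counts, library_total = total,
                 length_range = as.integer(length_range),
                 offset = as.integer(offset)),
            class = "psite_profiles")
}

#' @export
print.psite_profiles <- function(x, ...) {
  cat("P-site profiles for", length(x$counts), "transcripts;",
      x$library_total, "P-sites (read lengths",
      paste(x$length_range, collapse = "-"), "nt, offset +", x$offset,
      "nt)\n")
  invisible(x)
}

#' Signed 3-nt periodicity ORFscore from frame counts
#'
#' With per-frame P-site totals (F0 in the ORF's own frame) and
#' Fbar = (F0+F1+F2)/3, the score is
#' `log2(sum_i (Fi - Fbar)^2 / Fbar + 1)`, negated when `F0 < F1` or
#' `F0 < F2`. Undefined (NA) when no P-sites fall in the ORF.
#'
#' @param f0,f1,f2 numeric vectors of frame counts.
#' @return numeric vector of signed scores.
#' @export
orfscore <- function(f0, f1, f2) {
  n <- f0 + f1 + f2
  fbar <- n / 3
  dev <- ((f0 - fbar)^2 + (f1 - fbar)^2 + (f2 - fbar)^2) / fbar
  s <- log2(dev + 1)
  s[n == 0] <- NA_real_
  ifelse(f0 < f1 | f0 < f2, -s, s)
}

# Frame counts of one ORF over its scored span.
orf_frame_counts <- function(counts, orf_start, orf_end,
                             exclude_terminal_codons = TRUE) {
  span_start <- orf_start + if (exclude_terminal_codons) 3L else 0L
  span_end <- orf_end - if (exclude_terminal_codons) 3L else 0L
  if (span_end <= span_start) return(c(0L, 0L, 0L))
  idx <- seq.int(span_start, span_end - 1L)
  fr <- (idx - orf_start) %% 3L
  v <- counts[idx + 1L]
  c(sum(v[fr == 0L]), sum(v[fr == 1L]), sum(v[fr == 2L]))
}

#' Species-specific ORFscore confidence thresholds
#'
#' High/medium/low tiers: > 6 / > 4 / > 2 for human, > 5.5 / > 4.5 / > 3 for
#' zebrafish (strict inequalities).
#'
#' @param species "human" or "zebrafish".
#' @return list with `high`, `medium`, `low`.
#' @export
species_thresholds <- function(species = c("human", "zebrafish")) {
  species <- match.arg(species)
  switch(species,
         human = list(high = 6, medium = 4, low = 2),
         zebrafish = list(high = 5.5, medium = 4.5, low = 3))
}

#' Confidence tier of an ORFscore
#'
#' @param score numeric vector of ORFscores (NA allowed).
#' @param thresholds list with `high > medium > low`, see
#'   [species_thresholds()].
#' @return character vector over \{high, medium, low, none\}.
#' @export
classify_confidence <- function(score, thresholds) {
  stopifnot(thresholds$high > thresholds$medium,
            thresholds$medium > thresholds$low)
  out <- rep("none", length(score))
  out[!is.na(score) & score > thresholds$low] <- "low"
  out[!is.na(score) & score > thresholds$medium] <- "medium"
  out[!is.na(score) & score > thresholds$high] <- "high"
  out
}

#' Score a candidate-ORF catalog against P-site profiles
#'
#' Adds per-ORF frame counts, the signed ORFscore, the in-frame proportion
#' and a confidence tier. The scored span excludes the first and last codon
#' of the ORF by default (avoids initiation/termination peaks). ORFs with
#' fewer than `min_psites` P-sites get an undefined score and tier "none".
#'
#' @param catalog an ORF catalog (see [build_orf_catalog()]).
#' @param profiles a `psite_profiles` object.
#' @param exclude_terminal_codons drop the first and last codon from scoring.
#' @param min_psites minimum P-sites for a defined score.
#' @param thresholds confidence thresholds, see [species_thresholds()].
#' @return the catalog with columns `f0,f1,f2,n_psites,orfscore,
#'   in_frame_proportion,confidence` appended.
#' @export
score_orfs <- function(catalog, profiles,
                       exclude_terminal_codons = TRUE, min_psites = 10L,
                       thresholds = species_thresholds("human")) {
  n <- nrow(catalog)
  fmat <- matrix(0L, nrow = n, ncol = 3)
  for (i in seq_len(n)) {
    cnt <- profiles$counts[[catalog$transcript_id[i]]]
    if (is.null(cnt))
      stop("no profile for transcript ", catalog$transcript_id[i])
    fmat[i, ] <- orf_frame_counts(cnt, catalog$orf_start[i],
                                  catalog$orf_end[i],
                                  exclude_terminal_codons)
  }
  npsites <- rowSums(fmat)
  score <- orfscore(fmat[, 1], fmat[, 2], fmat[, 3])
  score[npsites < min_psites] <- NA_real_
  out <- catalog
  out$f0 <- fmat[, 1]; out$f1 <- fmat[, 2]; out$f2 <- fmat[, 3]
  out$n_psites <- npsites
  out$orfscore <- score
  out$in_frame_proportion <- ifelse(npsites > 0, fmat[, 1] / npsites,
                                    NA_real_)
  out$confidence <- classify_confidence(score, thresholds)
  out
}

#' Prune overlapping dORFs per transcript
#'
#' Greedy selection: per transcript, dORFs are ordered by decreasing
#' ORFscore; the best is kept and every dORF overlapping it (half-open
#' intervals) removed, then the procedure repeats on the remainder. Ties are
#' broken by 5'-most start, then start-codon priority ATG > CTG > GTG > TTG.
#' Undefined scores rank below every defined score.
#'
#' @param scored a scored catalog (rows of class dORF; other rows are passed
#'   through untouched).
#' @return the catalog with overlapping dORFs removed.
#' @export
select_nonoverlapping_dorfs <- function(scored) {
  is_dorf <- scored$region_class == "dORF"
  dorfs <- scored[is_dorf, , drop = FALSE]
  others <- scored[!is_dorf, , drop = FALSE]
  if (!nrow(dorfs)) return(scored)
  codon_rank <- match(dorfs$start_codon, c("ATG", "CTG", "GTG", "TTG"))
  sc <- dorfs$orfscore
  sc[is.na(sc)] <- -Inf
  kept <- unlist(lapply(split(seq_len(nrow(dorfs)), dorfs$transcript_id),
                        function(idx) {
    ord <- idx[order(-sc[idx], dorfs$orf_start[idx], codon_rank[idx])]
    keep <- integer(0)
    while (length(ord)) {
      best <- ord[1]
      keep <- c(keep, best)
      ov <- dorfs$orf_start[ord] < dorfs$orf_end[best] &
        dorfs$orf_start[best] < dorfs$orf_end[ord]
      ord <- ord[!ov]
    }
    keep
  }))
  out <- rbind(others, dorfs[sort(kept), , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Metagene profile around start/stop anchors
#'
#' Transcripts are filtered to those whose 5'UTR, CDS and 3'UTR are all at
#' least `min_feature_len` nt, then the `top_n` by footprint RPKM (computed
#' on the same library) are kept. Two windows of length `window` are placed
#' at the CDS start anchor (`cds_start`) and the stop anchor (first base of
#' the stop codon); per transcript, window counts are normalized by the total
#' over both windows (zero-total transcripts excluded) and the profile is the
#' positionwise mean over transcripts, so it sums to 1 across both windows.
#'
#' @param profiles a `psite_profiles` object (or RNA coverage in the same
#'   shape).
#' @param models a `transcript_models` table.
#' @param window even window length in nt, `[anchor - window/2,
#'   anchor + window/2)`.
#' @param top_n number of top-expressed transcripts used.
#' @param min_feature_len minimum 5'UTR/CDS/3'UTR length in nt.
#' @param anchors optional data.frame (`transcript_id`, `start_anchor`,
#'   `stop_anchor`) overriding the CDS anchors (e.g. dORF anchors).
#' @return data.frame of class `metagene_profile`: `anchor`, `rel_pos`,
#'   `frame` (relative to the anchor frame), `in_cds`, `mean_value`; the
#'   number of transcripts used is in `attr(, "n_transcripts")`.
#' @export
metagene_profile <- function(profiles, models, window = 100L, top_n = 2000L,
                             min_feature_len = 50L, anchors = NULL) {
  if (window %% 2L != 0L) stop("window must be even")
  half <- window %/% 2L
  ok <- utr5_length(models) >= min_feature_len &
    (models$cds_end - models$cds_start) >= min_feature_len &
    utr3_length(models) >= min_feature_len
  sel <- models[ok, , drop = FALSE]
  if (!nrow(sel)) stop("no transcript passes the metagene length filters")
  tot <- vapply(profiles$counts[sel$transcript_id], sum, numeric(1))
  rpkm <- compute_rpkm(tot, sel$length, max(profiles$library_total, 1L))
  sel <- sel[order(-rpkm)[seq_len(min(top_n, nrow(sel)))], , drop = FALSE]

  if (is.null(anchors)) {
    anchors <- data.frame(transcript_id = sel$transcript_id,
                          start_anchor = sel$cds_start,
                          stop_anchor = sel$cds_end - 3L,
                          stringsAsFactors = FALSE)
  } else {
    sel <- sel[sel$transcript_id %in% anchors$transcript_id, , drop = FALSE]
    anchors <- anchors[match(sel$transcript_id, anchors$transcript_id), ]
  }
  acc <- matrix(0, nrow = 2L, ncol = window)
  used <- 0L
  for (i in seq_len(nrow(sel))) {
    cnt <- profiles$counts[[sel$transcript_id[i]]]
    w1 <- window_counts(cnt, anchors$start_anchor[i], half)
    w2 <- window_counts(cnt, anchors$stop_anchor[i], half)
    tot <- sum(w1) + sum(w2)
    if (tot == 0) next
    acc[1, ] <- acc[1, ] + w1 / tot
    acc[2, ] <- acc[2, ] + w2 / tot
    used <- used + 1L
  }
  if (used == 0L) stop("no transcript with nonzero window counts")
  rel <- seq.int(-half, half - 1L)
  out <- data.frame(
    anchor = rep(c("start", "stop"), each = window),
    rel_pos = rep(rel, 2L),
    frame = rep(rel %% 3L, 2L),
    in_cds = c(rel >= 0L, rel < 0L),
    mean_value = c(acc[1, ] / used, acc[2, ] / used))
  attr(out, "n_transcripts") <- used
  class(out) <- c("metagene_profile", "data.frame")
  out
}

window_counts <- function(counts, anchor, half) {
  pos <- seq.int(anchor - half, anchor + half - 1L)
  v <- numeric(length(pos))
  inside <- pos >= 0L & pos < length(counts)
  v[inside] <- counts[pos[inside] + 1L]
  v
}

#' Per-region RNA coverage bias relative to the CDS 3' end
#'
#' For each named region, `log2((mean coverage in region + eps) /
#' (mean coverage in reference + eps))`, with the reference defaulting to the
#' last 100 nt of the CDS. Zero everywhere under uniform coverage.
#'
#' @param coverage per-position numeric vector for one transcript.
#' @param regions named list of `c(start, end)` 0-based half-open intervals.
#' @param reference reference interval, default last 100 nt of the CDS.
#' @param cds_start,cds_end CDS interval (used for the default reference).
#' @param eps pseudo-coverage added to both means.
#' @return named numeric vector of log2 coverage differences.
#' @export
region_coverage_bias <- function(coverage, regions, cds_start = NULL,
                                 cds_end = NULL, reference = NULL,
                                 eps = 0.05) {
  if (is.null(reference)) {
    if (is.null(cds_end)) stop("need cds_end (or an explicit reference)")
    if (cds_end - cds_start < 100L) stop("CDS shorter than 100 nt")
    reference <- c(cds_end - 100L, cds_end)
  }
  region_mean <- function(iv) {
    if (iv[1] < 0 || iv[2] > length(coverage) || iv[1] >= iv[2])
      stop("region outside transcript")
    mean(coverage[(iv[1] + 1L):iv[2]])
  }
  ref <- region_mean(reference)
  vapply(regions, function(iv) log2((region_mean(iv) + eps) / (ref + eps)),
         numeric(1))
}
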