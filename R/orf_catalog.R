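STOP_CODONS <- c("TAA", "TAG", "TGA")
NTG_STARTS <- c("CTG", "GTG", "TTG")

# Scan one reading frame of sequence[region_start, region_end) (0-based,
# half-open) and return, per in-frame stop codon, the single ORF whose start
# is the 5'-most start codon after the previous in-frame stop. Codons
# containing N never match a start or stop codon.
scan_frame_orfs <- function(sequence, region_start, region_end, frame_offset,
                            start_codons) {
  empty <- data.frame(orf_start = integer(0), orf_end = integer(0),
                      start_codon = character(0), atg_inside = logical(0),
                      stringsAsFactors = FALSE)
  first <- region_start + frame_offset
  if (region_end - first < 6L) return(empty)
  pos <- seq.int(first, region_end - 3L, by = 3L)
  cod <- substring(sequence, pos + 1L, pos + 3L)
  is_stop <- cod %in% STOP_CODONS
  is_start <- cod %in% start_codons
  stop_idx <- which(is_stop)
  start_idx <- which(is_start)
  if (!length(stop_idx) || !length(start_idx)) return(empty)
  # group = number of stops at or before a codon index; a start pairs with the
  # next stop of its group
  g_start <- findInterval(start_idx, stop_idx)
  first_per_grp <- tapply(start_idx, g_start, min)
  g <- as.integer(names(first_per_grp))
  closing <- g + 1L
  valid <- closing <= length(stop_idx)
  if (!any(valid)) return(empty)
  a_i <- as.integer(first_per_grp[valid])
  s_i <- stop_idx[closing[valid]]
  atg_cum <- cumsum(cod == "ATG")
  atg_inside <- (atg_cum[s_i - 1L] - atg_cum[a_i]) > 0L
  data.frame(orf_start = pos[a_i], orf_end = pos[s_i] + 3L,
             start_codon = cod[a_i], atg_inside = atg_inside,
             stringsAsFactors = FALSE)
}

#' Classify an ORF interval relative to the canonical CDS
#'
#' With 0-based half-open intervals: a dORF starts at or after `cds_end`
#' (start codon in the 3'UTR), a uORF ends at or before `cds_start`, an exact
#' match of the CDS interval is `CDS`, and anything else overlaps the CDS
#' (`oORF`).
#'
#' @param orf_start,orf_end ORF interval (half-open, stop codon included).
#' @param cds_start,cds_end CDS interval of the same transcript.
#' @return character vector over \{uORF, oORF, dORF, CDS\}.
#' @export
classify_region <- function(orf_start, orf_end, cds_start, cds_end) {
  ifelse(orf_start == cds_start & orf_end == cds_end, "CDS",
    ifelse(orf_start >= cds_end, "dORF",
      ifelse(orf_end <= cds_start, "uORF", "oORF")))
}

#' iUTR of a dORF
#'
#' The internal UTR is the region between the canonical stop codon and the
#' dORF's start codon: interval `[cds_end, orf_start)`.
#'
#' @param orf_start dORF start coordinate(s); must be `>= cds_end`.
#' @param cds_end canonical CDS end (one past the stop codon).
#' @return list with `start`, `end`, and `length` (nt) vectors.
#' @export
iutr_of <- function(orf_start, cds_end) {
  if (any(orf_start < cds_end))
    stop("iUTR is defined only for dORFs (orf_start >= cds_end)")
  list(start = cds_end, end = orf_start, length = orf_start - cds_end)
}

#' Enumerate candidate ATG ORFs on one transcript
#'
#' For every stop codon in each of the three absolute reading frames of the
#' mRNA, emits at most one ORF: from the 5'-most in-frame ATG after the
#' previous in-frame stop ("most distal ATG" relative to that stop) to the
#' stop codon. ORFs truncated by the transcript end are discarded; codon
#' bounds count sense codons only (stop excluded).
#'
#' @param model one row of a `transcript_models` table.
#' @param min_codons,max_codons retained codon-count bounds.
#' @return data.frame of candidates with region class and frame.
#' @export
enumerate_atg_orfs <- function(model, min_codons = 10L, max_codons = 100L) {
  seq <- model$sequence
  len <- nchar(seq)
  hits <- do.call(rbind, lapply(0:2, function(f)
    scan_frame_orfs(seq, 0L, len, f, "ATG")))
  finish_candidates(hits, model, min_codons, max_codons)
}

#' Enumerate candidate near-cognate (CTG/GTG/TTG) dORFs
#'
#' Only the annotated 3'UTR is scanned. For each in-frame stop the 5'-most
#' CTG/GTG/TTG after the previous in-frame stop is taken; candidates
#' containing an in-frame ATG within their span are excluded, as are
#' candidates whose interval overlaps a retained ATG dORF (half-open
#' overlap — ORFs merely adjacent are kept).
#'
#' @param model one row of a `transcript_models` table.
#' @param atg_orfs the retained ATG candidates from [enumerate_atg_orfs()].
#' @inheritParams enumerate_atg_orfs
#' @return data.frame of candidates.
#' @export
enumerate_non_atg_dorfs <- function(model, atg_orfs,
                                    min_codons = 10L, max_codons = 100L) {
  seq <- model$sequence
  len <- nchar(seq)
  hits <- do.call(rbind, lapply(0:2, function(f)
    scan_frame_orfs(seq, model$cds_end, len, f, NTG_STARTS)))
  if (!is.null(hits) && nrow(hits)) hits <- hits[!hits$atg_inside, ]
  out <- finish_candidates(hits, model, min_codons, max_codons)
  if (!nrow(out)) return(out)
  atg_dorfs <- atg_orfs[atg_orfs$region_class == "dORF", , drop = FALSE]
  if (nrow(atg_dorfs)) {
    ov <- vapply(seq_len(nrow(out)), function(i)
      any(out$orf_start[i] < atg_dorfs$orf_end &
            atg_dorfs$orf_start < out$orf_end[i]), logical(1))
    out <- out[!ov, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

finish_candidates <- function(hits, model, min_codons, max_codons) {
  cols <- c("transcript_id", "gene_id", "region_class", "start_codon",
            "orf_start", "orf_end", "n_codons", "frame_rel_cds",
            "iutr_length")
  empty <- data.frame(transcript_id = character(0), gene_id = character(0),
                      region_class = character(0), start_codon = character(0),
                      orf_start = integer(0), orf_end = integer(0),
                      n_codons = integer(0), frame_rel_cds = integer(0),
                      iutr_length = integer(0), stringsAsFactors = FALSE)
  if (is.null(hits) || !nrow(hits)) return(empty[, cols])
  n_codons <- (hits$orf_end - hits$orf_start) %/% 3L - 1L
  keep <- n_codons >= min_codons & n_codons <= max_codons
  hits <- hits[keep, , drop = FALSE]
  n_codons <- n_codons[keep]
  if (!nrow(hits)) return(empty[, cols])
  region <- classify_region(hits$orf_start, hits$orf_end,
                            model$cds_start, model$cds_end)
  out <- data.frame(
    transcript_id = model$transcript_id, gene_id = model$gene_id,
    region_class = region, start_codon = hits$start_codon,
    orf_start = hits$orf_start, orf_end = hits$orf_end,
    n_codons = n_codons,
    frame_rel_cds = (hits$orf_start - model$cds_start) %% 3L,
    iutr_length = ifelse(region == "dORF",
                         hits$orf_start - model$cds_end, NA_integer_),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[, cols]
}

#' Build the candidate small-ORF catalog for a transcriptome
#'
#' Runs ATG enumeration over every representative transcript and, optionally,
#' near-cognate dORF enumeration over 3'UTRs, applying the codon-count bounds
#' (default 10–100 sense codons).
#'
#' @param models a `transcript_models` table (one row per gene).
#' @inheritParams enumerate_atg_orfs
#' @param include_non_atg also enumerate CTG/GTG/TTG dORFs.
#' @return a catalog data.frame (one row per candidate ORF).
#' @export
build_orf_catalog <- function(models, min_codons = 10L, max_codons = 100L,
                              include_non_atg = TRUE) {
  pieces <- lapply(seq_len(nrow(models)), function(i) {
    m <- models[i, , drop = FALSE]
    atg <- enumerate_atg_orfs(m, min_codons, max_codons)
    if (!include_non_atg) return(atg)
    rbind(atg, enumerate_non_atg_dorfs(m, atg, min_codons, max_codons))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Write an ORF catalog as TSV
#' @param catalog an ORF catalog data.frame.
#' @param path output path.
#' @export
write_orf_catalog <- function(catalog, path) {
  utils::write.table(catalog, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(catalog)
}
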