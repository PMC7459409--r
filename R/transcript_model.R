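#' Construct a table of transcript models
#'
#' A transcript model is one mRNA: its spliced sequence (5'->3', uppercase
#' A/C/G/T/N) together with the transcript-space CDS interval. Coordinates are
#' 0-based, half-open: `cds_start` is the first base of the start codon and
#' `cds_end` is one past the last base of the stop codon, so the 5'UTR is
#' `[0, cds_start)` and the 3'UTR is `[cds_end, length)`.
#'
#' @param transcript_id,gene_id character vectors of identifiers.
#' @param sequence character vector of spliced transcript sequences.
#' @param cds_start,cds_end integer vectors, 0-based half-open CDS interval
#'   (stop codon included).
#' @param genomic_stop optional numeric vector: genomic coordinate of the 3'
#'   end of the stop codon (strand-aware), used only for isoform selection.
#' @param strand optional character vector, "+" or "-".
#' @return A `data.frame` of class `transcript_models` with one row per
#'   transcript and a `length` column.
#' @export
transcript_models <- function(transcript_id, gene_id, sequence,
                              cds_start, cds_end,
                              genomic_stop = NA_real_, strand = "+") {
  sequence <- toupper(as.character(sequence))
  genomic_stop <- rep_len(as.numeric(genomic_stop), length(sequence))
  strand <- rep_len(as.character(strand), length(sequence))
  df <- data.frame(
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    sequence = sequence,
    length = nchar(sequence),
    cds_start = as.integer(cds_start),
    cds_end = as.integer(cds_end),
    genomic_stop = as.numeric(genomic_stop),
    strand = as.character(strand),
    stringsAsFactors = FALSE
  )
  validate_transcript_models(df)
  class(df) <- c("transcript_models", "data.frame")
  df
}

validate_transcript_models <- function(df) {
  if (anyDuplicated(df$transcript_id))
    stop("duplicated transcript_id in transcript models")
  bad_chr <- grepl("[^ACGTN]", df$sequence)
  if (any(bad_chr))
    stop("sequence contains characters outside A/C/G/T/N: ",
         paste(utils::head(df$transcript_id[bad_chr]), collapse = ", "))
  ok <- df$cds_start >= 0 & df$cds_start < df$cds_end & df$cds_end <= df$length
  if (!all(ok))
    stop("invalid CDS interval for: ",
         paste(utils::head(df$transcript_id[!ok]), collapse = ", "))
  len3 <- (df$cds_end - df$cds_start) %% 3L == 0L &
    (df$cds_end - df$cds_start) >= 6L
  if (!all(len3))
    stop("CDS length not a multiple of 3 (>= 6) for: ",
         paste(utils::head(df$transcript_id[!len3]), collapse = ", "))
  invisible(df)
}

#' 5'UTR and 3'UTR lengths of transcript models
#' @param models a `transcript_models` table.
#' @return integer vector of lengths in nucleotides.
#' @export
utr5_length <- function(models) models$cds_start

#' @rdname utr5_length
#' @export
utr3_length <- function(models) models$length - models$cds_end

#' Load a transcriptome from annotation + sequence files
#'
#' Two input dialects are supported and yield identical models:
#' * a GTF/GFF file with `exon`/`CDS` (and optionally `stop_codon`) features
#'   plus a genome FASTA — exons are spliced in transcript orientation and
#'   minus-strand transcripts reverse-complemented;
#' * a transcript-level TSV (`transcript_id`, `gene_id`, `cds_start`,
#'   `cds_end`; 0-based half-open, stop codon included) plus a transcript
#'   FASTA.
#'
#' Transcripts with no CDS, or a CDS whose length is not a multiple of 3, are
#' skipped with a warning. An annotation/sequence identifier mismatch is an
#' error. Annotated non-ATG start codons are tolerated but reported.
#'
#' @param annotation_path path to a GTF/GFF3 file or a model TSV.
#' @param sequence_path path to a genome FASTA (GTF input) or transcript
#'   FASTA (TSV input).
#' @return a `transcript_models` table.
#' @export
load_transcriptome <- function(annotation_path, sequence_path) {
  if (grepl("\\.g[tf]f3?(\\.gz)?$", annotation_path, ignore.case = TRUE)) {
    models <- read_transcriptome_gtf(annotation_path, sequence_path)
  } else {
    models <- read_transcript_table(annotation_path, sequence_path)
  }
  report_nonstandard_starts(models)
  models
}

report_nonstandard_starts <- function(models) {
  sc <- substr(models$sequence, models$cds_start + 1L, models$cds_start + 3L)
  odd <- sc != "ATG"
  if (any(odd))
    message(sum(odd), " transcript(s) with annotated non-ATG start codon: ",
            paste(utils::head(models$transcript_id[odd], 5), collapse = ", "))
  invisible(models)
}

#' @rdname load_transcriptome
#' @export
read_transcript_table <- function(annotation_path, sequence_path) {
  tab <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "gene_id", "cds_start", "cds_end")
  if (!all(need %in% names(tab)))
    stop("model TSV must have columns: ", paste(need, collapse = ", "))
  seqs <- Biostrings::readDNAStringSet(sequence_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  missing <- setdiff(tab$transcript_id, names(seqs))
  if (length(missing))
    stop("transcripts missing from FASTA: ",
         paste(utils::head(missing), collapse = ", "))
  gstop <- if ("genomic_stop" %in% names(tab)) tab$genomic_stop else NA_real_
  strand <- if ("strand" %in% names(tab)) tab$strand else "+"
  transcript_models(tab$transcript_id, tab$gene_id,
                    as.character(seqs[tab$transcript_id]),
                    tab$cds_start, tab$cds_end,
                    genomic_stop = gstop, strand = strand)
}

#' @rdname load_transcriptome
#' @export
read_transcriptome_gtf <- function(annotation_path, sequence_path) {
  gr <- rtracklayer::import(annotation_path)
  genome <- Biostrings::readDNAStringSet(sequence_path)
  names(genome) <- sub("\\s.*$", "", names(genome))

  meta <- as.data.frame(gr)
  meta$type <- as.character(meta$type)
  exons <- meta[meta$type == "exon", ]
  cds <- meta[meta$type == "CDS", ]
  stops <- meta[meta$type == "stop_codon", ]
  if (!nrow(exons)) stop("no exon features in annotation")

  out <- vector("list", 0L)
  skipped <- character(0)
  for (tx in unique(exons$transcript_id)) {
    ex <- exons[exons$transcript_id == tx, ]
    ex <- ex[order(ex$start), ]
    chr <- as.character(ex$seqnames[1])
    strand <- as.character(ex$strand[1])
    if (!chr %in% names(genome))
      stop("chromosome ", chr, " missing from genome FASTA")
    pieces <- substring(as.character(genome[[chr]]), ex$start, ex$end)
    spliced <- paste(pieces, collapse = "")
    if (strand == "-")
      spliced <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(spliced)))

    cd <- cds[cds$transcript_id == tx, ]
    if (!nrow(cd)) { skipped <- c(skipped, tx); next }
    st <- stops[stops$transcript_id == tx, ]
    gmin <- min(cd$start); gmax <- max(cd$end)
    if (nrow(st)) { gmin <- min(gmin, st$start); gmax <- max(gmax, st$end) }

    tx_first <- genomic_to_tx(if (strand == "+") gmin else gmax, ex, strand)
    tx_last <- genomic_to_tx(if (strand == "+") gmax else gmin, ex, strand)
    cds_start <- tx_first
    cds_end <- tx_last + 1L
    # annotations that exclude the stop codon: extend when the next codon is
    # a stop
    if (!nrow(st)) {
      tail_codon <- substr(spliced, cds_end - 2L, cds_end)
      next_codon <- substr(spliced, cds_end + 1L, cds_end + 3L)
      if (!tail_codon %in% STOP_CODONS && next_codon %in% STOP_CODONS)
        cds_end <- cds_end + 3L
    }
    if ((cds_end - cds_start) %% 3L != 0L) { skipped <- c(skipped, tx); next }
    genomic_stop <- if (strand == "+") gmax else gmin
    out[[tx]] <- data.frame(
      transcript_id = tx, gene_id = cd$gene_id[1], sequence = toupper(spliced),
      cds_start = cds_start, cds_end = cds_end,
      genomic_stop = genomic_stop, strand = strand,
      stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("skipped ", length(skipped),
            " transcript(s) without a usable CDS: ",
            paste(utils::head(skipped), collapse = ", "))
  if (!length(out)) stop("no usable transcripts in annotation")
  df <- do.call(rbind, out)
  transcript_models(df$transcript_id, df$gene_id, df$sequence,
                    df$cds_start, df$cds_end,
                    genomic_stop = df$genomic_stop, strand = df$strand)
}

# Map a genomic position to a 0-based transcript coordinate given the exon
# table of one transcript (sorted by genomic start).
genomic_to_tx <- function(pos, ex, strand) {
  w <- ex$end - ex$start + 1L
  hit <- which(pos >= ex$start & pos <= ex$end)
  if (!length(hit)) stop("position ", pos, " not in any exon")
  if (strand == "+") {
    before <- if (hit > 1) sum(w[seq_len(hit - 1L)]) else 0L
    as.integer(before + (pos - ex$start[hit]))
  } else {
    after <- if (hit < nrow(ex)) sum(w[seq(hit + 1L, nrow(ex))]) else 0L
    as.integer(after + (ex$end[hit] - pos))
  }
}

#' Select one representative isoform per gene
#'
#' Keeps, for each gene, the isoform whose stop codon is 3'-most in genomic,
#' strand-aware terms ("most distal stop codon"). Ties are broken by longer
#' 3'UTR, then lexicographically smallest `transcript_id`. Isoforms without a
#' genomic stop coordinate (TSV input) fall through to the tie-break rules.
#'
#' @param models a `transcript_models` table (possibly many isoforms/gene).
#' @return a `transcript_models` table with one row per gene.
#' @export
select_representative_isoform <- function(models) {
  if (!nrow(models)) stop("no isoforms supplied")
  distal <- ifelse(models$strand == "-", -models$genomic_stop,
                   models$genomic_stop)
  distal[is.na(distal)] <- -Inf
  u3 <- utr3_length(models)
  ord <- order(models$gene_id, -distal, -u3, models$transcript_id)
  sorted <- models[ord, , drop = FALSE]
  keep <- sorted[!duplicated(sorted$gene_id), , drop = FALSE]
  rownames(keep) <- NULL
  class(keep) <- c("transcript_models", "data.frame")
  keep
}

#' Write / read transcript models in the package TSV + FASTA dialect
#'
#' The TSV carries `transcript_id`, `gene_id`, `length`, `cds_start`,
#' `cds_end` (plus `genomic_stop` and `strand` when known); sequences go to a
#' transcript FASTA. Reloading with [read_transcript_table()] reproduces the
#' models exactly.
#'
#' @param models a `transcript_models` table.
#' @param tsv_path,fasta_path output paths.
#' @export
write_transcript_models <- function(models, tsv_path, fasta_path) {
  tab <- models[, c("transcript_id", "gene_id", "length",
                    "cds_start", "cds_end", "genomic_stop", "strand")]
  utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  seqs <- Biostrings::DNAStringSet(models$sequence)
  names(seqs) <- models$transcript_id
  Biostrings::writeXStringSet(seqs, fasta_path)
  invisible(models)
}
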