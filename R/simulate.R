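SENSE_CODONS <- setdiff(
  apply(expand.grid(BASES, BASES, BASES)[, 3:1], 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

# Stops in all three reading frames; blocks ORFs in any frame from running
# across it into a planted region. Contains no ATG.
TRIPLE_STOP_PAD <- "TAACTAACTAA"

#' Configuration for the synthetic ribosome-profiling generator
#'
#' Defaults describe a deep vertebrate-like ribosome-profiling experiment:
#' log-normal UTR/CDS lengths, 3-nt periodic P-sites with frame-0 fraction
#' 0.85, initiation/termination peaks at 3x/2x the interior codon density,
#' negative-binomial gene-level counts, uniform RNA coverage, and planted
#' translated dORFs (10-100 codons, mixed ATG/CTG/GTG/TTG starts) receiving
#' `dorf_te_fraction_of_cds * mean_depth` expected P-sites.
#'
#' @param n_genes number of genes (one transcript each).
#' @param utr5_meanlog,utr5_sdlog,cds_meanlog,cds_sdlog,utr3_meanlog,utr3_sdlog
#'   log-normal length parameters (nt).
#' @param base_probs background base composition (A/C/G/T).
#' @param fraction_dorf_genes,fraction_uorf_genes fractions of genes with a
#'   planted translated dORF / uORF.
#' @param dorf_codon_range planted dORF sense-codon bounds.
#' @param start_codon_mix sampling weights of planted dORF start codons.
#' @param frame0_fraction probability that a P-site falls on the first base
#'   of its codon (1/3 = no periodicity).
#' @param start_peak,stop_peak density multipliers of the first / last sense
#'   codon.
#' @param mean_depth expected P-sites per CDS.
#' @param rna_depth expected RNA fragments per transcript.
#' @param te_multiplier_dorf multiplicative footprint effect on dORF genes.
#' @param dorf_te_fraction_of_cds expected P-sites of a translated dORF as a
#'   fraction of `mean_depth`.
#' @param utr_noise background P-sites per untranslated UTR nucleotide.
#' @param dispersion negative-binomial overdispersion (0 = Poisson).
#' @param read_lengths footprint read lengths emitted.
#' @param psite_offset P-site offset from the read 5' end.
#' @param rna_read_length RNA fragment length emitted.
#' @param seed integer seed; equal seeds give byte-identical output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500L,
                       utr5_meanlog = log(150), utr5_sdlog = 0.4,
                       cds_meanlog = log(900), cds_sdlog = 0.35,
                       utr3_meanlog = log(700), utr3_sdlog = 0.45,
                       base_probs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                       fraction_dorf_genes = 0.3,
                       fraction_uorf_genes = 0.1,
                       dorf_codon_range = c(10L, 100L),
                       start_codon_mix = c(ATG = 0.55, CTG = 0.20,
                                           GTG = 0.15, TTG = 0.10),
                       frame0_fraction = 0.85,
                       start_peak = 3, stop_peak = 2,
                       mean_depth = 500,
                       rna_depth = 300,
                       te_multiplier_dorf = 2,
                       dorf_te_fraction_of_cds = 0.2,
                       utr_noise = 0.02,
                       dispersion = 0.05,
                       read_lengths = 28:30,
                       psite_offset = 12L,
                       rna_read_length = 30L,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$fraction_dorf_genes >= 0, cfg$fraction_dorf_genes <= 1,
            cfg$fraction_uorf_genes >= 0, cfg$fraction_uorf_genes <= 1,
            cfg$frame0_fraction > 0, cfg$frame0_fraction <= 1,
            cfg$te_multiplier_dorf > 0, cfg$dispersion >= 0)
  class(cfg) <- "sim_config"
  cfg
}

# draw one element; never falls into sample()'s scalar-as-range behaviour
sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

rand_bases <- function(n, probs) {
  if (n <= 0L) return("")
  intToUtf8(utf8ToInt("ACGT")[sample.int(4L, n, replace = TRUE,
                                         prob = probs)])
}

# ORF body of n sense codons after the start codon; optionally free of ATG at
# every offset (needed so planted near-cognate dORFs survive the in-frame-ATG
# and ATG-overlap exclusion rules).
orf_body <- function(n, avoid_atg) {
  pool <- if (avoid_atg) setdiff(SENSE_CODONS, "ATG") else SENSE_CODONS
  cods <- sample(pool, n, replace = TRUE)
  body <- paste(cods, collapse = "")
  if (avoid_atg) {
    for (it in 1:1000) {
      m <- regexpr("ATG", body, fixed = TRUE)[1]
      if (m < 0) break
      j <- (m - 1L) %/% 3L + 1L
      cods[j] <- sample(pool, 1L)
      body <- paste(cods, collapse = "")
    }
  }
  body
}

plant_orf <- function(n_codons, start_codon) {
  avoid <- start_codon != "ATG"
  body <- orf_body(n_codons - 1L, avoid)
  stop_codon <- sample(STOP_CODONS, 1L)
  # an A just before TGA would spell ATG across the junction
  if (avoid && stop_codon == "TGA" &&
      substr(body, nchar(body), nchar(body)) == "A")
    stop_codon <- "TAA"
  paste0(start_codon, body, stop_codon)
}

#' Simulate a transcriptome with planted small ORFs
#'
#' Generates one transcript per gene (background composition per
#' `base_probs`, clean ATG...stop CDS without internal in-frame stops) and
#' plants translated dORFs/uORFs with known coordinates. Each planted ORF is
#' preceded by an in-frame stop codon so that enumeration recovers exactly
#' the planted interval; near-cognate dORFs are additionally preceded by
#' stops in all three frames and built ATG-free so the published exclusion
#' rules cannot remove them. Untranslated decoy candidates arise naturally
#' from the background sequence.
#'
#' @param config a [sim_config()].
#' @return list with `models` (a `transcript_models` table), `truth` (list
#'   of `orfs` and `genes` data.frames), and `config`.
#' @export
simulate_transcriptome <- function(config) {
  set.seed(config$seed)
  n <- config$n_genes
  bp <- config$base_probs
  gene_id <- sprintf("G%05d", seq_len(n))
  tx_id <- sprintf("T%05d", seq_len(n))
  has_dorf <- stats::runif(n) < config$fraction_dorf_genes
  has_uorf <- stats::runif(n) < config$fraction_uorf_genes

  seqs <- character(n)
  cds_start <- cds_end <- integer(n)
  orf_rows <- list()
  for (i in seq_len(n)) {
    l5 <- max(30L, round(stats::rlnorm(1, config$utr5_meanlog,
                                       config$utr5_sdlog)))
    n_sense <- max(60L, round(stats::rlnorm(1, config$cds_meanlog,
                                            config$cds_sdlog) / 3))
    l3 <- max(60L, round(stats::rlnorm(1, config$utr3_meanlog,
                                       config$utr3_sdlog)))

    uorf <- NULL
    if (has_uorf[i]) {
      nc <- sample(10:40, 1L)
      need <- 3L + 3L * (nc + 1L) + 6L
      l5 <- max(l5, need + 20L)
      g <- sample.int(l5 - need - 3L, 1L) - 1L
      orf_seq <- plant_orf(nc, "ATG")
      utr5 <- paste0(rand_bases(g, bp), "TAA", orf_seq,
                     rand_bases(l5 - g - 3L - nchar(orf_seq), bp))
      uorf <- list(start = g + 3L, n_codons = nc, start_codon = "ATG")
    } else {
      utr5 <- rand_bases(l5, bp)
    }

    cds <- paste0("ATG", paste(sample(SENSE_CODONS, n_sense - 1L,
                                      replace = TRUE), collapse = ""),
                  sample(STOP_CODONS, 1L))

    dorf <- NULL
    if (has_dorf[i]) {
      nc <- sample1(config$dorf_codon_range[1]:config$dorf_codon_range[2])
      sc <- sample(names(config$start_codon_mix), 1L,
                   prob = config$start_codon_mix)
      pad <- if (sc == "ATG") "TAA" else TRIPLE_STOP_PAD
      orf_seq <- plant_orf(nc, sc)
      # 1 nt "C" guard after the stop, >= 20 nt tail for read feasibility
      need <- nchar(pad) + nchar(orf_seq) + 21L
      l3 <- max(l3, need + 20L)
      g <- sample.int(l3 - need, 1L) - 1L
      utr3 <- paste0(rand_bases(g, bp), pad, orf_seq, "C",
                     rand_bases(l3 - g - nchar(pad) - nchar(orf_seq) - 1L,
                                bp))
      dorf <- list(gap = g + nchar(pad), n_codons = nc, start_codon = sc)
    } else {
      utr3 <- rand_bases(l3, bp)
    }

    seqs[i] <- paste0(utr5, cds, utr3)
    cds_start[i] <- l5
    cds_end[i] <- l5 + nchar(cds)
    if (!is.null(uorf))
      orf_rows[[length(orf_rows) + 1L]] <- data.frame(
        gene_id = gene_id[i], transcript_id = tx_id[i], class = "uORF",
        start_codon = uorf$start_codon,
        orf_start = uorf$start,
        orf_end = uorf$start + 3L * (uorf$n_codons + 1L),
        n_codons = uorf$n_codons, stringsAsFactors = FALSE)
    if (!is.null(dorf))
      orf_rows[[length(orf_rows) + 1L]] <- data.frame(
        gene_id = gene_id[i], transcript_id = tx_id[i], class = "dORF",
        start_codon = dorf$start_codon,
        orf_start = cds_end[i] + dorf$gap,
        orf_end = cds_end[i] + dorf$gap + 3L * (dorf$n_codons + 1L),
        n_codons = dorf$n_codons, stringsAsFactors = FALSE)
  }
  orfs <- if (length(orf_rows)) do.call(rbind, orf_rows) else
    data.frame(gene_id = character(0), transcript_id = character(0),
               class = character(0), start_codon = character(0),
               orf_start = integer(0), orf_end = integer(0),
               n_codons = integer(0), stringsAsFactors = FALSE)
  orfs$translated <- rep(TRUE, nrow(orfs))
  genes <- data.frame(
    gene_id = gene_id, transcript_id = tx_id,
    has_dorf = has_dorf, has_uorf = has_uorf,
    te_multiplier = ifelse(has_dorf, config$te_multiplier_dorf, 1),
    stringsAsFactors = FALSE)
  models <- transcript_models(tx_id, gene_id, seqs, cds_start, cds_end)
  list(models = models, truth = list(orfs = orfs, genes = genes),
       config = config)
}

rnb <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

# P-site positions of one translated ORF: codon chosen with start/stop peak
# weights, frame per the periodicity mix.
orf_psites <- function(n_psites, orf_start, n_sense, config) {
  if (n_psites == 0L) return(integer(0))
  w <- rep(1, n_sense)
  w[1] <- config$start_peak
  w[n_sense] <- config$stop_peak
  codon <- sample.int(n_sense, n_psites, replace = TRUE, prob = w)
  f0 <- config$frame0_fraction
  frame <- sample.int(3L, n_psites, replace = TRUE,
                      prob = c(f0, (1 - f0) / 2, (1 - f0) / 2)) - 1L
  orf_start + 3L * (codon - 1L) + frame
}

#' Simulate footprint and RNA signal over a synthetic transcriptome
#'
#' Per gene, the CDS receives a negative-binomial number of P-sites around
#' `mean_depth * te_multiplier`, placed per codon with initiation/termination
#' peaks and the configured 3-nt frame bias; planted translated small ORFs
#' receive `dorf_te_fraction_of_cds * mean_depth * te_multiplier` expected
#' P-sites with the same shape; untranslated UTR positions receive low
#' uniform Poisson noise. RNA fragments are uniform across the transcript.
#' P-sites that no read of the configured lengths could produce (too close
#' to a transcript end for 5' + offset placement) are dropped, so SAM
#' round-trips are exact.
#'
#' @param models,truth output of [simulate_transcriptome()].
#' @param config the [sim_config()] used.
#' @param seed seed for the signal draw (default derives from the config
#'   seed).
#' @return list with `rpf` and `rna` `psite_profiles` objects.
#' @export
simulate_signal <- function(models, truth, config,
                            seed = config$seed + 1L) {
  set.seed(seed)
  n <- nrow(models)
  p_min <- config$psite_offset
  rpf <- rna <- vector("list", n)
  names(rpf) <- names(rna) <- models$transcript_id
  for (i in seq_len(n)) {
    len <- models$length[i]
    mult <- truth$genes$te_multiplier[i]
    p_max <- len - (min(config$read_lengths) - config$psite_offset)
    pos <- orf_psites(rnb(1L, config$mean_depth * mult, config$dispersion),
                      models$cds_start[i],
                      (models$cds_end[i] - models$cds_start[i]) %/% 3L - 1L,
                      config)
    planted <- truth$orfs[truth$orfs$transcript_id ==
                            models$transcript_id[i], , drop = FALSE]
    for (k in seq_len(nrow(planted))) {
      mu <- config$dorf_te_fraction_of_cds * config$mean_depth * mult
      pos <- c(pos, orf_psites(rnb(1L, mu, config$dispersion),
                               planted$orf_start[k], planted$n_codons[k],
                               config))
    }
    utr_pos <- c(seq_len(models$cds_start[i]) - 1L,
                 seq.int(models$cds_end[i], len - 1L))
    for (k in seq_len(nrow(planted)))
      utr_pos <- utr_pos[utr_pos < planted$orf_start[k] |
                           utr_pos >= planted$orf_end[k]]
    n_noise <- stats::rpois(1L, config$utr_noise * length(utr_pos))
    if (n_noise > 0L)
      pos <- c(pos, sample(utr_pos, n_noise, replace = TRUE))
    pos <- pos[pos >= p_min & pos < p_max]
    rpf[[i]] <- tabulate(pos + 1L, nbins = len)

    n_r <- rnb(1L, config$rna_depth, config$dispersion)
    rpos <- if (n_r > 0L)
      sample.int(len - config$rna_read_length, n_r, replace = TRUE) - 1L
    else integer(0)
    rna[[i]] <- tabulate(rpos + 1L, nbins = len)
  }
  list(
    rpf = structure(list(counts = rpf,
                         library_total = sum(vapply(rpf, sum, numeric(1))),
                         length_range = range(config$read_lengths),
                         offset = config$psite_offset),
                    class = "psite_profiles"),
    rna = structure(list(counts = rna,
                         library_total = sum(vapply(rna, sum, numeric(1))),
                         length_range = rep(config$rna_read_length, 2L),
                         offset = 0L),
                    class = "psite_profiles"))
}

#' Write simulated profiles as a SAM file
#'
#' Emits one single-segment forward alignment per P-site (or RNA fragment):
#' footprint reads are placed so that 5' end + offset recovers the P-site,
#' with read lengths cycling deterministically through the configured set
#' (clipped to what fits the transcript); RNA reads start at the stored
#' fragment position. Running [assign_psites()] on the output reproduces the
#' profile counts exactly.
#'
#' @param profiles a `psite_profiles` object from [simulate_signal()].
#' @param models the `transcript_models` table.
#' @param path output SAM path.
#' @param read_lengths lengths to emit (default: the profile's range).
#' @return `path`, invisibly.
#' @export
write_sim_sam <- function(profiles, models, path,
                          read_lengths = seq(profiles$length_range[1],
                                             profiles$length_range[2])) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", models$transcript_id,
                     models$length), con)
  qn <- 0L
  for (i in seq_len(nrow(models))) {
    tx <- models$transcript_id[i]
    cnt <- profiles$counts[[tx]]
    p <- rep.int(which(cnt > 0L) - 1L, cnt[cnt > 0L])
    if (!length(p)) next
    five <- p - profiles$offset
    len <- models$length[i]
    rl <- read_lengths[(p %% length(read_lengths)) + 1L]
    over <- five + rl > len
    rl[over] <- pmax(read_lengths[1], len - five[over])
    seqs <- substring(models$sequence[i], five + 1L, five + rl)
    writeLines(sprintf("r%07d\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s",
                       qn + seq_along(p), tx, five + 1L, rl, seqs,
                       strrep("I", rl)), con)
    qn <- qn + length(p)
  }
  invisible(path)
}

#' Write the ground-truth tables of a simulation
#' @param truth the `truth` element of [simulate_transcriptome()].
#' @param orf_path,gene_path output TSV paths.
#' @export
write_sim_truth <- function(truth, orf_path, gene_path) {
  utils::write.table(truth$orfs, orf_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth$genes, gene_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(truth)
}
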