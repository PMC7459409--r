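# Independent oracles and fixture builders. Everything here is written
# against the definitions directly, not by calling package internals, so the
# implementation under test has a genuinely independent reference.

ORACLE_STOPS <- c("TAA", "TAG", "TGA")

random_seq <- function(n, probs = c(0.3, 0.2, 0.2, 0.3)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

# Build a single-row transcript model from explicit UTR5/CDS/UTR3 pieces.
toy_model <- function(utr5, cds, utr3, transcript_id = "tx1",
                      gene_id = "g1") {
  transcript_models(transcript_id, gene_id, paste0(utr5, cds, utr3),
                    nchar(utr5), nchar(utr5) + nchar(cds))
}

# Exhaustive ORF scan: every position carrying a start codon is extended
# codon by codon to the first in-frame stop; per stop, the 5'-most start
# wins (one ORF per stop).
oracle_scan <- function(seq, start_codons, region_start = 0L,
                        region_end = nchar(seq)) {
  n <- nchar(seq)
  if (n < 3L) return(data.frame(orf_start = integer(0),
                                orf_end = integer(0),
                                start_codon = character(0)))
  cods <- substring(seq, seq_len(n - 2L), seq_len(n - 2L) + 2L)
  out <- NULL
  last <- region_end - 3L
  for (p in seq.int(region_start, last)) {
    cod <- cods[p + 1L]
    if (cod %in% start_codons) {
      q <- p + 3L
      while (q <= last && !cods[q + 1L] %in% ORACLE_STOPS) q <- q + 3L
      if (q <= last)
        out <- rbind(out, data.frame(orf_start = p, orf_end = q + 3L,
                                     start_codon = cod,
                                     stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) return(data.frame(orf_start = integer(0),
                                      orf_end = integer(0),
                                      start_codon = character(0)))
  out <- out[order(out$orf_end, out$orf_start), ]
  out <- out[!duplicated(out$orf_end), ]
  rownames(out) <- NULL
  out
}

# Full catalog oracle mirroring the published rules: ATG ORFs over the whole
# mRNA; near-cognate dORFs over the annotated 3'UTR only, minus those with
# an in-frame ATG inside and those overlapping a retained ATG dORF.
oracle_catalog <- function(seq, cds_start, cds_end, min_codons = 10L,
                           max_codons = 100L) {
  bound <- function(df) {
    if (!nrow(df)) return(df)
    nc <- (df$orf_end - df$orf_start) %/% 3L - 1L
    df[nc >= min_codons & nc <= max_codons, , drop = FALSE]
  }
  atg <- bound(oracle_scan(seq, "ATG"))
  ntg <- bound(oracle_scan(seq, c("CTG", "GTG", "TTG"), cds_end))
  if (nrow(ntg)) {
    has_atg <- vapply(seq_len(nrow(ntg)), function(i) {
      p <- seq.int(ntg$orf_start[i] + 3L, ntg$orf_end[i] - 6L, by = 3L)
      any(substring(seq, p + 1L, p + 3L) == "ATG")
    }, logical(1))
    ntg <- ntg[!has_atg, , drop = FALSE]
  }
  atg_dorf <- atg[atg$orf_start >= cds_end, , drop = FALSE]
  if (nrow(ntg) && nrow(atg_dorf)) {
    ov <- vapply(seq_len(nrow(ntg)), function(i)
      any(ntg$orf_start[i] < atg_dorf$orf_end &
            atg_dorf$orf_start < ntg$orf_end[i]), logical(1))
    ntg <- ntg[!ov, , drop = FALSE]
  }
  rbind(atg, ntg)
}

orf_key <- function(df) sort(paste(df$orf_start, df$orf_end, df$start_codon))

# Scalar ORFscore recomputation by plain loop arithmetic.
orfscore_oracle <- function(f0, f1, f2) {
  n <- f0 + f1 + f2
  if (n == 0) return(NA_real_)
  fbar <- n / 3
  s <- 0
  for (f in c(f0, f1, f2)) s <- s + (f - fbar)^2 / fbar
  sc <- log2(s + 1)
  if (f0 < f1 || f0 < f2) -sc else sc
}

# Exact two-sided rank-sum p-value by enumerating every split of the pooled
# sample (tie-free input only).
perm_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n <- length(x)
  splits <- utils::combn(length(pooled), n)
  stats <- apply(splits, 2, function(idx) sum(r[idx]))
  e <- n * (length(pooled) + 1) / 2
  obs <- sum(r[seq_len(n)])
  mean(abs(stats - e) >= abs(obs - e) - 1e-9)
}

# Exact two-sided binomial tail sum (minimum-likelihood convention, the
# same relative tolerance as the classical test).
binom_p_oracle <- function(k, n, p) {
  d <- stats::dbinom(0:n, n, p)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# psite_profiles-shaped object from explicit count vectors.
make_profiles <- function(counts, offset = 12L, length_range = c(28L, 30L)) {
  structure(list(counts = counts,
                 library_total = sum(vapply(counts, sum, numeric(1))),
                 length_range = length_range, offset = offset),
            class = "psite_profiles")
}

# Minimal SAM writer for hand-built alignment records.
write_hand_sam <- function(path, refs, lens, records) {
  lines <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", refs, lens))
  for (r in records) {
    seq <- strrep("A", r$len)
    lines <- c(lines, sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s",
                              r$qname, r$flag %||% 0L, r$rname, r$pos,
                              r$len, seq, strrep("I", r$len)))
  }
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared medium-sized simulation reused across test files (built once).
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_genes = 150L, seed = 42L)
      sim <- simulate_transcriptome(cfg)
      sig <- simulate_signal(sim$models, sim$truth, cfg)
      cache <<- list(cfg = cfg, sim = sim, sig = sig)
    }
    cache
  }
})
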