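# dorfscan

Detection and analysis of translated small open reading frames in mRNA
3'UTRs (downstream ORFs, **dORFs**) from ribosome profiling data.

Most vertebrate mRNAs carry short start–stop codon pairs in their 3'UTRs.
A subset of these dORFs is actively translated, and genes carrying
translated dORFs tend to show *higher* translation efficiency of their
canonical ORF than expression-matched genes without them. `dorfscan`
implements the computational side of that analysis as a reusable, fully
tested R pipeline:

* **Candidate enumeration** — per gene, the isoform with the most distal
  stop codon is selected; ATG ORFs are enumerated over the whole mRNA
  (one ORF per stop codon per frame, from the 5'-most in-frame ATG after
  the previous in-frame stop), near-cognate (CTG/GTG/TTG) dORFs over the
  annotated 3'UTR only, excluding candidates with an in-frame ATG or an
  overlap with a retained ATG dORF. Retained dORFs span 10–100 sense
  codons.
* **Translation calling** — footprints are reduced to P-sites
  (5' end + 12 nt), and each candidate is scored with the signed 3-nt
  periodicity **ORFscore**. With per-frame P-site totals F0, F1, F2
  (F0 in the ORF's own frame) and F̄ = (F0+F1+F2)/3:

      ORFscore = log2( Σᵢ (Fᵢ − F̄)² / F̄ + 1 ),   negated if F0 < F1 or F0 < F2

  Calls are tiered high/medium/low at ORFscore > 6 / > 4 / > 2 (human)
  or > 5.5 / > 4.5 / > 3 (zebrafish); per transcript, dORFs overlapping a
  better-scoring dORF are greedily removed.
* **Translation efficiency** — per gene,
  `TE = log2((RPF RPKM + 0.05) / (RNA RPKM + 0.05))` over the CDS
  excluding the first and last coding codons; genes below
  log2(RNA RPKM) ≥ 1 in every sample are dropped. dORF genes are compared
  to control genes resampled from RNA-level deciles with weights
  (target fraction in bin)/(pool count in bin), via a two-sided Wilcoxon
  rank-sum test — overall and stratified by dORF count, start codon and
  confidence tier.
* **Profiles and context** — metagene profiles around start/stop anchors
  (100-nt windows, per-transcript normalization, top-2000 transcripts by
  RPKM), RNA-coverage uniformity statistics, positional chi-squared tests
  of the 20-nt start-codon context against 3'UTR base composition, 4-mer
  (positions −3…−1 and +1 around the start codon) binomial enrichment in
  translated vs untranslated dORFs, and a PCA over context profiles with
  a Kozak reference.
* **Ortholog-presence bootstrap** — observed overlap of dORF genes across
  a one-to-one ortholog table vs 1,000 random same-size gene draws.
* **Synthetic data** — a seeded generator
  (`simulate_transcriptome()` / `simulate_signal()`) producing
  transcriptomes with planted uORFs/dORFs and periodic footprint signal
  with known ground truth, so every stage is testable without external
  data, plus SAM/FASTA/TSV writers for round-trip testing.

## Worked example

```r
library(dorfscan)

cfg <- sim_config(n_genes = 300, seed = 1)     # planted truth: 30% dORF genes,
sim <- simulate_transcriptome(cfg)             # TE multiplier 2, frame-0 0.85
sig <- simulate_signal(sim$models, sim$truth, cfg)

config <- analysis_config("human")
disc <- run_discover(sim$models, config)
disc$summary$fraction_mrnas_with_dorf
#> [1] 0.9966667

sc <- run_score(disc$catalog, sig$rpf, config)
table(confidence = sc$dorfs$confidence, start_codon = sc$dorfs$start_codon)
#>           start_codon
#> confidence ATG CTG GTG TTG
#>       high  44  19  17  10

te <- build_te_table(sim$models, sig$rpf, sig$rna)
tr <- run_te(te, sc$dorfs, config)
tr$overall
#> Group comparison: n = 90 vs 90; medians 1.3776 vs 0.4943 (delta 0.8832);
#> Wilcoxon rank-sum p = 2.3e-18
```

Nearly every simulated mRNA carries at least one *candidate* dORF (decoy
start–stop pairs arise freely in random 3'UTR sequence), but only the 90
planted translated dORFs are called — all at high confidence, across all
four start codons. The TE comparison recovers the planted 2-fold effect:
the median TE of dORF genes exceeds the matched controls by 0.88 log2
units (planted: log2 2 = 1, estimated here from one noisy library), with
a vanishing rank-sum p-value. `run_report()` collects these quantities
(plus dORF/iUTR length statistics, the 3'UTR-length correlation, and
optional metagene/context/bootstrap blocks) into a validated JSON report.

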