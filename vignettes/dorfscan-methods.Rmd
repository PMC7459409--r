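---
title: "dorfscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dorfscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical procedures implemented in
`dorfscan`, the conventions and defaults behind them, what the synthetic
data generator does and does not emulate, and the numerical choices made
where the design was genuinely open. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## Coordinates and transcript models

All downstream arithmetic uses 0-based, half-open transcript coordinates:
`cds_start` is the first base of the start codon, `cds_end` one past the
last base of the stop codon, so the 5'UTR is `[0, cds_start)`, the 3'UTR
`[cds_end, length)`, and the internal UTR of a dORF — the stretch between
the canonical stop codon and the dORF start — is `[cds_end, orf_start)`.
Genomic coordinates appear only inside the annotation reader; "most
distal stop codon" for isoform selection is interpreted strand-aware
(genomically largest on `+`, smallest on `-`). Ties are broken
deterministically: longer 3'UTR, then lexicographically smallest
transcript id. When the annotation dialect excludes the stop codon from
CDS features, the interval is extended by the `stop_codon` features or,
failing that, by 3 nt when the adjacent codon is a stop.

Ambiguous bases (`N`) are allowed in UTRs; a codon containing `N` never
matches a start or stop codon.

## Candidate enumeration

ATG ORFs are enumerated over the entire mRNA in all three absolute
frames: for each stop codon, at most one ORF is emitted, anchored at the
5'-most in-frame ATG after the previous in-frame stop. We read "most
distal ATG" as this maximal ORF per stop — the reading under which each
stop codon yields a single candidate. Near-cognate (CTG/GTG/TTG)
candidates are restricted to the annotated 3'UTR; a candidate containing
an in-frame ATG anywhere in its span is discarded, as is any candidate
whose interval overlaps (half-open) a retained ATG dORF — merely adjacent
intervals are kept. ORFs truncated by the transcript end (no stop codon)
are never emitted.

The retained codon-count window is 10–100 sense codons, counting the
start codon and excluding the stop (`n_codons = span/3 - 1`); the bound
is applied to uORF/oORF candidates as well for symmetry, and both bounds
are configurable. A 9-sense-codon candidate is excluded, a 10-codon one
retained. The enumeration is validated against an independent
exhaustive-scan oracle (every position extended to its first in-frame
stop, longest ORF per stop kept) on 200 seeded sequences up to 2 kb.

## P-sites and the ORFscore

Footprints of 28–30 nt (human) or 28–29 nt (zebrafish) are reduced to a
single P-site at the 5' end + 12 nt; only primary, forward-strand
alignments count. The source material describes a −12/−15 dual shift for
metagene construction without fully specifying which ends it applies to;
we adopt the single 5'+12 convention everywhere and note the discrepancy
— the offset is a parameter of `assign_psites()`.

The ORFscore is computed from per-frame P-site totals over the ORF span
with the first and last codon excluded (the "first and last codon" being
the start codon and the stop codon). This mirrors the terminal-codon
exclusion of the TE computation and keeps initiation/termination peaks
out of the frame statistics. An ORF with fewer than `min_psites`
(default 10) P-sites has an undefined score and tier `none`: the source
analysis gates calls by tiers alone, but a floor prevents a single read
from producing a +5 score. Tier thresholds are strict inequalities
(> 6/4/2 human, > 5.5/4.5/3 zebrafish); a score exactly at a threshold
falls to the lower tier. Overlap pruning is greedy per transcript —
keep the best-scoring dORF, drop everything overlapping it, repeat — with
ties broken by 5'-most start, then start-codon priority
ATG > CTG > GTG > TTG.

## Metagene profiles

Transcripts with 5'UTR, CDS and 3'UTR all ≥ 50 nt are ranked by footprint
RPKM on the same library and the top 2,000 kept. Two 100-nt windows are
centered on the CDS start anchor (`cds_start`) and the stop anchor (the
first base of the stop codon — both anchors are frame-0 positions, so a
single frame labeling applies to every transcript). Each transcript's
window counts are divided by its total over both windows (zero-total
transcripts excluded), and the profile is the positionwise mean, so the
output sums to exactly 1 across both windows and is not dominated by
high-count transcripts. RNA-coverage uniformity uses
`log2((mean(region)+0.05)/(mean(reference)+0.05))` against the last
100 nt of the CDS.

## Translation efficiency and matched controls

`TE = log2((RPF RPKM + 0.05)/(RNA RPKM + 0.05))` over
`[cds_start+3, cds_end-6)` — the CDS minus the first and last coding
codons — for both layers; the pseudocount 0.05 makes TE exactly 0 for
equal densities including the all-zero case. Genes with
`log2(RNA RPKM) < 1` in every sample are removed; with one sample the
rule reduces to that sample.

Controls are resampled to match the target set's RNA level
(`log2(RNA RPKM + 0.05)`, the same pseudocount as TE): pool genes below
the target minimum are removed, the target distribution is cut into 10
quantile bins (boundary values fall to the lower bin; duplicated
boundaries collapse into wider bins instead of creating zero-width
quantiles), and each pool gene is weighted by (target fraction in its
bin)/(pool count in its bin). Draws are without replacement, switching
to with-replacement (with a message) only when the pool is smaller than
the number of draws; a populated target bin with no pool members is an
error naming the bin. Because ten deciles are meaningless for a
20-gene stratum, the pipeline callers scale the bin count to at least
ten targets per bin (`adaptive_quantiles()`), down to a single bin —
matching degrades gracefully rather than failing on small strata.

Group comparisons use the two-sided Wilcoxon rank-sum test: exact when
both groups have ≤ 25 tie-free values, otherwise the normal approximation
with continuity correction; the exact branch is verified against a
complete permutation enumeration in the tests. Stratified outputs
(dORF count 1/2/3+, start codon, confidence tier — each gene labeled by
its best-scoring dORF so strata partition the gene set) report raw
p-values as well as a Benjamini–Hochberg column.

## Initiation context and ortholog bootstrap

The 20-nt context window is laid out as 10 bases upstream, the 3-base
start codon, and 7 bases downstream — the source states a 20-nt window
without fixing the asymmetry; this layout is our documented choice.
Windows reaching past a transcript end are padded with `N`, excluded from
all counts. Positional bias is a chi-squared test (3 df) per unmasked
position against the pooled 3'UTR base composition; the three codon
positions are masked. The initiation 4-mer is positions −3…−1 plus the
base immediately 3' of the start codon; each of the 256 4-mers is tested
two-sided (minimum-likelihood convention) against its frequency among
untranslated dORFs of the same start-codon class, with a pseudocount
success probability (flagged) when a 4-mer is absent from controls, and a
log2 fold change with pseudocount 0.5 on counts. The context PCA centers
feature columns, drops constant ones, and fixes signs by making each
axis's largest-magnitude loading positive, so coordinates are
reproducible.

The ortholog bootstrap counts pairs with both members in their species'
dORF set, against 1,000 same-size uniform draws from the one-to-one
ortholog universe; it reports the null mean, a percentile 95% CI and a
one-sample t-test of the draws against the observed overlap. The
sampling universe is the ortholog table itself; other universes change
the null mean, so the choice is explicit and configurable rather than
implicit.

## The synthetic data generator

`simulate_transcriptome()` emulates: log-normal 5'UTR/CDS/3'UTR lengths,
background base composition (default A 0.30, C 0.20, G 0.20, T 0.30,
UTR-like), clean ATG…stop CDSs without internal in-frame stops, and
planted translated dORFs (default 30% of genes; 10–100 codons; start mix
ATG 0.55 / CTG 0.20 / GTG 0.15 / TTG 0.10) and uORFs (10%). Each planted
ORF is preceded by an in-frame stop so enumeration recovers exactly the
planted interval; near-cognate dORFs are built ATG-free and preceded by
stops in all three frames, so the published exclusion rules cannot
silently delete a planted "translated" ORF. Decoy candidates are *not*
suppressed — background sequence supplies the untranslated control
population for calling and context statistics.

`simulate_signal()` draws negative-binomial gene-level counts
(dispersion 0.05; the overdispersion is needed for realistic rank-sum
behaviour) around `mean_depth` = 500 P-sites per CDS, placed per codon
with 3×/2× initiation/termination peaks and frame probabilities
(f0, (1−f0)/2, (1−f0)/2) with f0 = 0.85 — a strongly periodic, deep
library. Translated dORFs receive `dorf_te_fraction_of_cds` ×
`mean_depth` = 0.2 × 500 = 100 expected P-sites. This level is the
deliberate "well-covered dORF" condition: the expected ORFscore at
frame-0 fraction f0 with n scored P-sites is ≈ log2(1 + 3nΣ(pᵢ−⅓)²)
≈ log2(1 + 1.2n) at f0 = 0.85, so a score above the human high tier
(> 6) requires n ≳ 53 — a dORF with barely 30 P-sites *cannot* reach
high confidence at this periodicity, which is why the defaults place the
expectation at 100 rather than at the floor. Untranslated UTR positions
receive 0.02 P-sites/nt of uniform noise; RNA fragments are uniform.
P-sites that no 28–30-nt read could generate (too close to a transcript
end) are dropped from the count tables, so SAM emission and
`assign_psites()` round-trip exactly.

Not emulated: sequencing errors, UMI structure, spliced (genome-space)
alignment, RNase digestion bias, length-dependent P-site offsets,
multi-isoform genes, and readthrough translation. Passing tests
therefore demonstrate correctness of the statistical machinery under
idealized periodic signal — not robustness to the full noise structure
of real libraries.

## Problem sizes and tolerances in the test suite

The suite validates, among others: the ORFscore against brute-force
arithmetic on 1,000 random triples (1e-9) and exhaustively for all
triples ≤ 30 (sign rule, F1/F2 symmetry); enumeration against the
exhaustive-scan oracle on 200 sequences ≤ 2 kb; planted-dORF recovery on
a 500-gene simulation (sensitivity ≥ 0.9, false-discovery proportion
≤ 0.1 at the human high tier; high-tier rate ≤ 5% at f0 = 1/3); control
matching by chi-squared goodness-of-fit over 200 seeded resamplings of
1,000 controls (non-significant at α = 0.001 in ≥ 99%); recovery of
planted TE effects θ ∈ {1.5, 2, 3} within ±0.15 of log2 θ across 10
signal draws each (~300 target genes); metagene normalization to 1 ±
1e-9 and frame-0 recovery within ±0.02; positional chi-squared type-I
error 5% ± 3% under the null; exact binomial oracle agreement for counts
≤ 200; and bootstrap null means within 3 SE of m·n/N. These sizes were
chosen so the whole suite runs in about a minute on one CPU while the
stochastic assertions retain comfortable margins.

## Known limitations

* Genome-space (spliced) dORF coordinates, amino-acid-level conservation
  scoring and GO enrichment are out of scope.
* The expression floor uses raw `log2(RNA RPKM)` (not the pseudocounted
  level) — the literal published rule; genes with RPKM in (0, 2) survive
  only via another sample.
* `select_representative_isoform()` uses the selected isoform's own UTRs;
  conflicting UTR annotations across isoforms are not merged.
* The bootstrap's null depends on the declared ortholog universe; with a
  universe much larger than the genes actually analyzable, the analytic
  expectation m·n/N is the right sanity check, not any particular
  published overlap.
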