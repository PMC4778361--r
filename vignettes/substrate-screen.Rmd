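---
title: "Screening for E3 ubiquitin ligase substrates by integrated proteomics and transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for E3 ubiquitin ligase substrates by integrated proteomics and transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubiscreen)
```

## The screening logic

SCF-type E3 ubiquitin ligases mark their substrates for proteasomal
degradation. In a mutant lacking a core SCF adaptor subunit (such as the
*Arabidopsis* SKP1-like protein ASK1), substrates of the affected ligases
should accumulate. `ubiscreen` implements the comparative screen that turns
this idea into candidate lists:

1. **Detect** proteins in replicate label-free MS (MudPIT) runs of mutant
   and wild-type tissue, accepting identifications with local FDR < 1 %.
2. **Quantify** relative protein abundance within each run by spectral
   counting, and average across replicate runs per genotype.
3. **Compare** the genotype proteomes: proteins detected only in the
   mutant (against a pooled wild-type reference) and proteins at least
   1.5-fold more abundant in the mutant are the accumulation classes.
4. **Filter** by transcript level: a protein whose mRNA is unchanged
   between genotypes cannot owe its accumulation to transcription, so it
   is a *protein-level* candidate — the signature of a degradation
   substrate. Genes called differentially expressed (≥ 2-fold and
   *t*-test p < 0.05) are excluded; genes without array probes are
   counted separately because the filter cannot assess them.
5. **Characterize** the resulting gene sets by promoter hexamer
   enrichment (binomial statistics) and GO overrepresentation (Fisher's
   exact test).

Because each MS run samples the proteome incompletely and stochastically,
replicate runs detect partially overlapping protein sets; the package
reports this overlap partition explicitly, and treats "detected once at
FDR < 1 %" as detected.

## Spectral-counting normalization

Within one run, raw spectral counts confound abundance with protein
length: longer proteins yield more tryptic peptides and therefore more
spectra at equal molar abundance. The normalization divides each
protein's share of the run's spectra by its share of the run's
theoretical tryptic peptides:

$$ A_K \;=\; \frac{s_K / S}{t_K / T} $$

where $s_K$ is the spectra matched to protein $K$, $t_K$ its theoretical
peptide count, and $S$, $T$ the totals over all proteins detected in that
run (totals are per run: each run is its own dataset). $A_K$ is
dimensionless; $A_K = 1$ means the protein's spectral share equals its
peptide share, and the $t$-weighted mean of $A_K$ over a run is exactly 1.
Proteins whose digestion yields no theoretical peptide cannot be
normalized; they are excluded from the abundance table and reported as
unquantifiable.

Theoretical peptides come from in-silico trypsin digestion: cleave after
every K or R not followed by P, no missed cleavages, and keep fragments of
at least 6 residues. Counting is of peptide occurrences, not distinct
sequences, and identifiers are kept at the isoform level as given
(a configurable gene-level mode strips AGI isoform suffixes when
reconciling datasets with different conventions).

```{r digest}
tryptic_peptides("MKPAAAAR")   # K followed by P is protected
normalize_run(
  data.frame(protein_id = c("P1", "P2"), spectra = c(20L, 20L)),
  data.frame(protein_id = c("P1", "P2"), n_peptides = c(2L, 6L))
)$abundance
```

Replicate averaging uses the runs in which a protein was detected
(no zero-imputation for missed runs); imputing zeros would conflate
detection failure with absence under incomplete sampling. The
zero-imputation convention is available via `zero_impute = TRUE` for
sensitivity analysis. A reduced-input test run can be carried through set
unions while being excluded from quantification via its
`include_in_quant` flag. The mutant-higher cutoff is inclusive
(`mean_mut / mean_wt >= 1.5`).

## Transcript-level exclusion

Differential expression uses the classical equal-variance two-sample
*t*-test (Welch available via `var_equal = FALSE`) on a linear-scale
matrix, with fold change as the ratio of group means; inputs already in
log2 are supported via `log2_input = TRUE`, which back-transforms the
mean difference. Both the fold (≥ 2, inclusive) and significance
(p < 0.05, raw) criteria must hold jointly; no multiple-testing
correction is applied anywhere, matching the screen's use of raw
p-values. Genes with a non-positive wild-type mean have no defined ratio
and are flagged rather than called.

`candidate_accounting()` then enforces the bookkeeping identity per
class: candidates + no-probe + DE-excluded = class size. For example, a
mutant-only class of 236 proteins with 11 genes lacking probes and none
differentially expressed leaves 225 protein-level candidates.

## Promoter and GO enrichment

All $4^6 = 4096$ hexamers are scored in the query promoter set. The
statistic is the binomial point probability
$P(X = k) = \binom{n}{k} p_0^k (1-p_0)^{n-k}$ with $p_0 = K/N$, where
$k$ of $n$ query promoters and $K$ of $N$ background promoters contain
the motif. The point formulation (rather than the upper tail
$P(X \ge k)$, which remains available via `tail = TRUE`) is the default
because it is the formulation that reproduces the reference promoter
statistics this implementation was validated against; occurrence totals
are reported alongside but do not enter the probability. The probability
is evaluated in log space, which agrees with direct products to at least
ten significant digits for $n \le 100$ and normalizes to 1 over
$k = 0..n$. Scanning is forward-strand by default (both-strand mode
available); overlapping occurrences count and N never matches.

```{r motif}
binomial_motif_p(12, 42, 3253, 33602)
```

GO overrepresentation is a one-sided Fisher's exact test per term on the
2×2 table (query-with-term, query-without, background-only-with,
background-only-without), with the gene universe supplied explicitly —
conventionally the set of genes represented on the expression platform.

## The synthetic-data generators

All inputs can be simulated from one `simulation_config()`, with every
planted entity traceable, so the full screen is testable without any
external download. The generators emulate:

* **Proteome**: random sequences over the 20 standard amino acids,
  lengths uniform on 50–500 residues, each guaranteed at least one K/R.
* **MS runs**: protein $K$ has latent wild-type abundance
  $A \sim \mathrm{lognormal}(0, 1)$; a planted 5 % of proteins (the
  substrates) have mutant abundance `substrate_fold` (default 4) times
  wild type — the strong accumulation expected when degradation is lost.
  Per-run detection is Bernoulli with the saturating probability
  $p = cA/(1+cA)$ (default $c = 2$); this is the simplest model that
  reproduces the partial replicate overlap characteristic of shotgun
  proteomics, with abundant proteins detected consistently and rare ones
  sporadically. Spectral counts are Poisson with mean
  $\mathrm{count\_rate} \times A \times t_K$ (floored at 1), the simplest
  count model consistent with the normalization's assumption that
  expected spectra scale with abundance × peptide yield.
* **Local FDR**: a 90/10 mixture of confident (U(0, 1) %) and marginal
  (U(1, 5) %) identifications, so the standard < 1 % filter removes a
  predictable ~10 % of detections per run while leaving detection power
  for every abundance class. (A single uniform FDR distribution on
  0–5 % would make the filter discard 80 % of true detections —
  behaviour no identification engine exhibits — and would make
  end-to-end recovery essentially impossible by construction.)
* **Expression**: baselines uniform on 0.5–2 (linear scale), planted DE
  genes at `de_fold` (default 2) in the mutant, additive Gaussian noise
  with SD 0.2, 4 wild-type vs 3 mutant replicates, and 2 % of genes
  withheld from the probe map. Note that planted 2-fold genes sit exactly
  on the inclusive fold cutoff, so the DE caller recovers only about half
  of them under default noise (the estimated fold falls below 2 whenever
  the noise is unfavourable); planted 4-fold genes are recovered with
  > 90 % power. This boundary behaviour is intrinsic to a hard fold
  cutoff, not a defect.
* **Promoters**: background promoters i.i.d. uniform over ACGT; each of
  42 query promoters receives one planted G-box (CACGTG) insertion with
  probability 0.3. The background set defaults to 2000 promoters of
  500 bp — enough to estimate per-hexamer containment rates to a relative
  error of a few percent; the enrichment statistic takes the background
  counts as data, so no result depends on simulating a genome-scale
  promoter complement.

Determinism: every generator derives an independent RNG stream from the
configuration seed, so outputs are byte-identical across runs and
insensitive to call order.

### What the simulation does and does not show

Passing tests on these generators demonstrate that the pipeline's logic
is correct under its own model: set algebra, normalization identities,
filter arithmetic, and recovery of planted signal. Real data differ in
ways the generators deliberately ignore: correlated detection across
runs (shared sample preparation), peptide-level detectability biases
(hydrophobicity, charge), non-Poisson overdispersion of spectral counts,
probe-level microarray artifacts, and promoter base composition that is
far from i.i.d. uniform (real promoters are AT-rich with strong local
structure). Results on synthetic data therefore validate the
*implementation*, not the biological sensitivity or specificity of the
screen on any particular tissue.

A known property of the screen worth restating: with ~12–16 of 42 query
promoters containing a planted motif against an ~11 % background
containment rate, the planted hexamer ranks first among all 4096 only
about three times out of four — the minimum over four thousand null
competitors is a strong order statistic. Stronger planting rates or
larger query sets make rank-1 recovery near-certain; at the default
(deliberately modest) planting rate the correct reading is "planted
motif in the top handful", which is also how promoter-motif tables are
used in practice.

## Numerical and design choices

* FDR threshold comparison is strict (< 1 %); fold cutoffs are inclusive
  (≥ 1.5, ≥ 2), following the "at least" convention.
* Reported percentages are rounded half-up to one decimal
  (`round_half_up()`), the convention of the tables this mirrors; base
  R's round-half-to-even would print 42.75 % as 42.7 %.
* A terminal K/R yields no empty fragment; ambiguous residues
  (B/J/O/U/X/Z) are accepted as non-cleaving with a warning; a trailing
  `*` stop is stripped with a warning.
* Motif ranking breaks p-value ties lexicographically so output is
  order-invariant.
* In noiseless end-to-end checks, "noiseless" includes removing count
  quantization (deterministic counts at a high count rate) and giving
  every gene a probe: with integer spectral counts floored at 1, a
  sufficiently rare protein's fold is inexpressible at low count rates,
  and an unprobed gene can never pass a transcript filter — both are
  properties of the method, not of the implementation.
* Test problem sizes (1000 proteins, 2000 genes, 2000 background
  promoters, 10–20 simulation seeds) were chosen as the smallest sizes at
  which the statistical checks have adequate resolution.

## Limitations

The package consumes identification reports (protein, spectral count,
local FDR) and a normalized expression matrix; database searching, FDR
estimation and array normalization are upstream concerns. Quantification
is protein-level spectral counting with a plain ratio cutoff — no
statistical test on abundance ratios, no peptide-level or isobaric
quantification. Promoter analysis is exhaustive fixed-length k-mer
counting, not motif discovery, and GO annotations are taken as given
without graph propagation.
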