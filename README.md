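# ubiscreen

Integrated proteomic/transcriptomic screening for substrates of SCF-type
E3 ubiquitin ligases.

## The problem

SCF (SKP1–Cullin1–F-box) E3 ubiquitin ligases tag proteins for
proteasomal degradation. In a mutant lacking a core SCF adaptor (e.g. the
*Arabidopsis* SKP1-like protein ASK1), substrates of the affected ligase
complexes should accumulate. A comparative screen therefore looks for
proteins that are **detected only in the mutant** or are **≥ 1.5-fold
more abundant in the mutant** across replicate label-free MS runs — and
then removes any whose **transcripts** also changed, because those could
be explained by transcription rather than degradation. What survives is
a list of *protein-level* candidates: likely substrates of the ligase.

`ubiscreen` implements every computational stage of that screen, for
researchers running (or re-analysing) mutant-vs-wild-type shotgun
proteomics with matched expression data:

- **In-silico tryptic digestion** — cut after K/R unless followed by P, no
  missed cleavages, peptides ≥ 6 residues (`tryptic_peptides()`,
  `theoretical_counts()`).
- **Spectral-counting normalization** — per-run relative abundance
  `A_K = (s_K/S) / (t_K/T)` with per-run totals, replicate averaging over
  detected runs, inclusive 1.5-fold mutant-higher calls
  (`normalize_run()`, `average_abundance()`, `classify_higher()`).
- **Proteome set comparison** — replicate merging at local FDR < 1 %,
  detection-multiplicity (Venn) partitions, a pooled wild-type reference,
  mutant-only classification (`merge_runs()`, `overlap_partition()`,
  `pool_wildtype()`, `mutant_only()`).
- **Transcript-level exclusion** — equal-variance *t*-test with an
  inclusive 2-fold cutoff on raw p < 0.05, per-class candidate accounting
  including genes without probes (`differential_expression()`,
  `transcript_status()`, `candidate_accounting()`).
- **Enrichment** — exhaustive promoter hexamer scoring with binomial point
  probabilities on promoter-containing counts, and one-sided Fisher GO
  overrepresentation against an explicit gene universe (`rank_motifs()`,
  `binomial_motif_p()`, `fisher_go()`).
- **Synthetic data** — generators for proteomes, run reports, expression
  matrices and promoter sets with planted, traceable signal
  (`simulation_config()` and friends), so the whole screen is testable
  end to end (`simulate_and_screen()`, `run_screen()`).

## Worked example

```r
library(ubiscreen)

cfg <- simulation_config(seed = 42)   # 1000 proteins, 4 WT + 5 mutant runs,
                                      # 50 planted substrates at 4-fold
res <- simulate_and_screen(cfg)
res$summary
#> Substrate screen summary
#>   wild-type proteome: 918 proteins; mutant: 927
#>   pooled wild type: 918 (own contribution 100.0 %)
#>   mutant-only: 64, mutant-higher: 82
#>   protein-level candidates after transcript filter: 140
mean(res$truth$substrates %in% res$summary$candidates)
#> [1] 0.92
```

Of 1000 simulated proteins, ~92 % are ever detected per genotype at
FDR < 1 %; 64 + 82 = 146 proteins land in the two accumulation classes,
and the transcript filter passes 140 protein-level candidates, which
recover 92 % of the 50 planted substrates (the rest is the false-positive
background a plain ratio cutoff admits at these run counts).

The planted G-box is recovered by promoter enrichment:

```r
head(res$summary$motifs, 3)[, c("oligomer", "query_promoters_with", "p_value")]
#>   oligomer query_promoters_with      p_value
#> 1   CACGTG                   18 3.417856e-07
#> 2   GTAGGA                   14 1.116712e-04
#> 3   ACAACC                   14 1.222673e-04
```

18 of 42 query promoters contain CACGTG versus 236 of 2000 background
promoters; its binomial point probability separates it cleanly from the
4095 null hexamers. On published promoter counts the same statistic gives,
e.g., `binomial_motif_p(24, 74, 3253, 33602)` → `4.95e-08`.

## The analysis workflow

The `analysis/` directory holds the screen as numbered, narrative
stages, each a thin driver over the package that prints what it found
and writes its tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # synthetic study dataset + truth files
Rscript analysis/02_digest_quantify.R   # digestion, per-run abundances, genotype means
Rscript analysis/03_proteome_sets.R     # merges, overlap partitions, mutant-only/higher
Rscript analysis/04_transcript_filter.R # DE calls, exclusion filter, candidate lists
Rscript analysis/05_enrichment.R        # top hexamers, GO overrepresentation
```

To run the same stages on real data, replace the stage-1 outputs with
your own files in the same plain formats (FASTA; TSV run reports with
`protein_id`, `spectra`, `local_fdr_pct`; a gene × sample expression TSV;
promoter FASTA; a `gene_id`/`term_id` annotation TSV).

## Scope

The package consumes identification reports and a normalized expression
matrix; database searching, FDR estimation and array normalization are
upstream tools' jobs. See the methods vignette
(`vignettes/substrate-screen.Rmd`) for the model, parameter defaults,
generator assumptions and known limitations.
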