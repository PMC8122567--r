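# spliceshift

Splicing factors such as the SR protein family reshape the transcriptome by
activating or repressing the inclusion of individual exons; knocking one
down and sequencing RNA before and after is the standard way to map its
regulatory program. spliceshift packages that computational workflow — from
junction read counts to binding-motif discovery and patient risk
stratification — for bioinformaticians who want a tested, reproducible,
download-free implementation of each stage, exercised end to end on a
synthetic-data generator with known ground truth.

## What it computes

**PSI.** Percent-spliced-in of an alternative-splicing (AS) event from
inclusion/exclusion junction reads,

    PSI = inclusion / (inclusion + exclusion)

optionally normalised by the number of junction forms supporting each
isoform. Events are one of the five standard categories: skipped exon (SE),
retained intron (RI), alternative 5'/3' splice site (A5SS/A3SS), mutually
exclusive exons (MXE).

**Differential screen.** Per event, a two-sided Fisher's exact test on the
2x2 inclusion/exclusion table across conditions, Benjamini–Hochberg FDR,
and the rule *FDR < 0.05 and |ΔPSI| ≥ 0.1* with ΔPSI = PSI(knockdown) −
PSI(control): significant negative shifts are factor-**activated** exons,
positive ones factor-**repressed**.

**Motif discovery.** The candidate binding-site class is GA-rich hexamers
(≥1 G, ≥1 A, G+A ≥ 50%; exactly 2222 of the 4096 hexamers). The top 50
activated and 50 repressed SE events are scanned with overlapping windows;
per-word binomial z-scores against unregulated-event background rank the
candidates; hit densities per region call the positional preference
(cassette exon versus flanking constitutive exons); and a
one-occurrence-per-sequence EM elicits a position weight matrix whose
consensus summarises the motif.

**Minigene quantification.** The In/Ex index of a gel lane,
(inclusion + ε)/(exclusion + ε), and a fold-response classification of
minigene deletion mutants against a splicing-factor perturbation.

**Clinical scoring.** H-score = Σ(PI×I) (range 0–300), xenograft volume =
length·width²/2, wound closure percentage, and PSI + expression
median-cutoff risk groups (high risk = low PSI and high expression)
compared by Kaplan–Meier curves and the log-rank test.

## Worked example

```r
library(spliceshift)

cfg <- pipeline_config(sim_config(n_events = 2000, seed = 42), cohort_n = 300)
rep <- run_pipeline(cfg, outdir = "demo_out")
print(rep)
```

```
spliceshift pipeline report (seed 42 )
  events per category: SE=1504 RI=36 A5SS=106 A3SS=103 MXE=251
  screen: 205 activated, 209 repressed of 2000 tested
  motifs: GCAGGG ( cassette ) / GCTGGA ( flank )
  minigene responsive constructs: FL, dE3F2
  risk groups: 150 high / 150 low; log-rank p = 2.91e-19
```

Reading the report: 2000 simulated events split across the five AS
categories in the default proportions; the screen calls 205 + 209 events
regulated (the simulation plants 10% + 10% true effects, so calls track
truth); motif discovery recovers the planted activated hexamer `GCAGGG`
with cassette-exon preference and the repressed hexamer `GCTGGA` with
flanking-exon preference; the full-length minigene construct and the
non-functional-deletion mutant respond to knockdown while the
binding-site-deletion mutant does not; and the median-cutoff risk groups
separate sharply on survival. Each stage's table (events, counts, PSI,
screen results, enrichment, positional profile, MEME motif, lanes, cohort,
log-rank) lands in `demo_out/`, and `demo_out/report.json` holds the
aggregate. The same config and seed reproduce every file byte for byte.

A command-line wrapper with `simulate`, `psi`, `screen`, `motif`,
`minigene`, `clinic`, `run-all` and `report` subcommands is installed at
`inst/cli/spliceshift.R`:

```sh
Rscript inst/cli/spliceshift.R run-all --seed 5 --outdir out
```

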