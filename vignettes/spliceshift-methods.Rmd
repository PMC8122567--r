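---
title: "Models and methods behind spliceshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spliceshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceshift)
```

spliceshift re-implements, as a tested and reusable pipeline, the
computational workflow of a splicing-factor perturbation study: quantify
percent-spliced-in (PSI) of alternative-splicing (AS) events from junction
read counts, screen for events whose inclusion the factor activates or
represses, discover the factor's candidate binding hexamers and their
positional preference (cassette exon versus flanking constitutive exon),
elicit a position weight matrix (PWM) motif by expectation-maximisation,
quantify minigene reporter switching as an inclusion/exclusion (In/Ex)
index, and stratify a survival cohort by a combined PSI + expression risk
score. A synthetic-data generator provides all inputs with known ground
truth, so every stage is testable without downloads.

This vignette explains the models, the defaults and the design choices; it
states no empirical result that the test suite and the acceptance script do
not themselves compute.

## The synthetic-data generator

The generator defines the conditions everything downstream is validated
under. It emulates a two-condition (control vs factor-knockdown) bulk
RNA-seq screen over the five standard AS categories — skipped exon (SE),
retained intron (RI), alternative 5'/3' splice sites (A5SS/A3SS) and
mutually exclusive exons (MXE).

**Event catalog.** `generate_event_catalog()` apportions `n_events` across
the five categories by largest-remainder rounding, so a rational mix is
reproduced exactly. The default mix, (5038, 121, 354, 345, 841)/6699, is
the composition this class of knockdown screens reports, with SE dominating
at about 75%. Coordinates are 0-based half-open (BED convention), three
non-overlapping regions per event — upstream flanking exon, alternative
(cassette) region, downstream flanking exon — separated by fixed-length
introns. All five categories share this three-region, two-count
abstraction; only the biological interpretation of the middle region
differs, which is all the single-PSI screen needs.

**Regulation truth.** A fraction of events (default 10% + 10%) is labelled
activated or repressed; labels partition the events exactly. The true
knockdown effect is a PSI shift of magnitude `true_delta_psi` (default
0.4): activated events move down under knockdown (the factor promoted
their inclusion), repressed events move up. Control PSI is drawn uniformly
on a range that leaves room for the full shift (e.g. activated events start
in [0.05 + delta, 0.95]), so the realised effect size equals the nominal one
rather than being silently clipped; unchanged events share one PSI across
conditions.

**Motif planting.** Region sequences are i.i.d. with configurable base
composition (uniform by default). Activated events receive at least one
copy of the activated hexamer (default `GCAGGG`) in the cassette exon and
none elsewhere; repressed events receive the repressed hexamer (default
`GCTGGA`) in one flanking exon, chosen at random, and none in the cassette;
unchanged events carry no planted copy. Background windows that spell
either planted word by chance are rejected and re-sampled, so a full-text
scan finds planted copies exactly where the truth says — the planted signal
is the unique ground truth, which is what makes end-to-end motif-recovery
tests meaningful. Minus-strand events store sense-strand sequences, and all
scans are sense-strand only.

**Read model.** Per event and condition, the total junction count is
Poisson with mean `coverage` (default 100, a realistic junction depth for a
well-expressed exon); inclusion reads are binomial with the true PSI. There
is no overdispersion by default because the default design has one library
per condition — the replicate structure such screens typically report — so
biological variance between replicates is not identifiable; negative
binomial totals are available via `overdispersion` for replicate designs.

**Survival cohort.** `simulate_survival_cohort()` draws exponential event
times per latent risk group and independent exponential censoring
calibrated so the expected censored fraction equals `censor_rate`; with
event hazard λ and censoring hazard μ, P(censored) = μ/(λ+μ), so μ =
λ·r/(1−r). PSI and expression are drawn on disjoint sides of 0.5 and 50
respectively (swapped with probability `label_noise`), so the median-cutoff
risk rule recovers the latent groups.

**What the generator does not emulate.** Real junction counts share reads
across overlapping events, have position-dependent coverage bias and
mapping ambiguity; real exonic sequence is far from i.i.d. (codon
structure, CpG suppression, repeat content), and real binding motifs are
degenerate families, not exact words. Passing tests therefore demonstrate
that the algorithms are implemented correctly and recover truth under the
stated statistical model — not that the pipeline's thresholds are optimal
on real tissue data.

## PSI quantification

The default PSI is the raw junction ratio inclusion/(inclusion +
exclusion). An effective-length-normalised form — each count divided by the
number of junction forms supporting its isoform, the common SE correction
where inclusion is supported by two junctions and exclusion by one — is
provided with `normalize = TRUE`. The raw ratio is the default because it
is the minimal defensible estimator when the upstream counting convention
is unknown, and because the simulator generates counts with no
junction-form asymmetry. Zero-coverage events return `NA`, never 0/0.
Events under `min_reads` (default 10) total reads are flagged, not
dropped: filtering is a screening decision, and the screen is where it
belongs.

## The differential screen

With one library per condition, the natural per-event test is Fisher's
exact test on the 2x2 table of inclusion/exclusion counts by condition —
exact at any coverage and assumption-light. A binomial likelihood-ratio
test (`method = "lrt"`) is provided as an asymptotic alternative. P-values
are Benjamini–Hochberg adjusted.

The screening rule is FDR < 0.05 and |ΔPSI| ≥ 0.1, with ΔPSI = PSI(knockdown)
− PSI(control). The delta threshold is inclusive at 0.1, matching a rule
stated as "≥ 0.1". The sign convention makes direction calls read
biologically: q < α and ΔPSI ≤ −0.1 means knockdown reduced inclusion, so
the factor *activates* that exon; q < α and ΔPSI ≥ +0.1 means the factor
*represses* it. Everything else, including untestable events, is
"unchanged".

`expression_screen()` is the companion gene-level threshold screen
(|log2FC| and FDR cutoffs on group means with a pseudocount and a Welch
t-test on log scale), the standard volcano-plot rule.

## Motif discovery

**Candidate class.** The candidate binding words are GA-rich hexamers: at
least one G, at least one A, G+A fraction ≥ 50%. `enumerate_filtered_kmers()`
enumerates the class exactly (2222 of the 4096 hexamers at the defaults)
rather than filtering observed words, so membership is deterministic and
testable against brute force.

**Event sets.** Motif discovery uses the top 50 activated and top 50
repressed SE events, ranked by q-value with ties broken by |ΔPSI| then
event id — the same ordering such studies use to pick events for
validation. Requesting more events than exist takes all and warns.

**Enrichment.** Occurrences are counted with overlapping windows (standard
for short, self-overlapping motifs). For each word, the foreground
occurrence frequency is compared against a background with a binomial
z-score under the background frequency (normal approximation), two-sided
p, BH q, ranked by z. The background is the corresponding regions of
*unchanged* SE events, subsampled to the foreground set size: unregulated
events from the same experiment are the least-biased internal control and
share the simulator's base composition. A word never seen in the background
gets a pseudo-frequency of one occurrence over the background windows
before the z-score.

**Positional preference.** Hit densities (per kb) are computed per region
and per event set over one identical word list, and each set's call is the
denser of cassette versus pooled flanks. The scanned list should be the top
enriched candidates (the pipeline uses the top 5 per direction): scanning
the entire 2222-word catalog buries the positional signal of one planted
word under the catalog's background hit density, which is more than two
orders of magnitude larger. Sets with no hits at all get an `NA` call
rather than an arbitrary one. Flanking *introns* can be included in the
repressed-set search space by passing intronic sequences; the default
region set is exonic because that is where the positional contrast of
interest lies.

**EM elicitation.** `elicit_motif()` fits a one-occurrence-per-sequence
(OOPS) PWM model with a uniform 0.25 background. The E-step computes the
posterior over start positions per sequence; the M-step re-estimates the
PWM from posterior-weighted counts with a Dirichlet pseudocount (default
0.1 per base). Initialisation is deterministic, from a seed word (its base
given probability 0.7 per column); the intended seed is the top enriched
k-mer, which makes the whole discovery path reproducible without random
restarts. The recorded `loglik_trace` is the observed-data log-likelihood
plus the Dirichlet prior term — the objective EM provably never decreases;
the raw likelihood alone is not guaranteed monotone under a pseudocount
M-step. Iteration stops at `max_iter` (200) or when the objective improves
by less than `tol` (1e-6). The consensus is the per-column argmax. ZOOPS
and multi-occurrence models, Markov backgrounds and multi-width search are
deliberately out of scope.

## Minigene quantification

The In/Ex index of a gel lane is (inclusion + ε)/(exclusion + ε) with ε a
pseudo-intensity of 1e-6 times the lane's maximum band: gels report
detection-limited zeros, and the regularisation keeps the index finite and
strictly positive while changing well-measured ratios by well under 1%. No
molar correction for amplicon length is applied by default (band ratios
are reported raw); a correction factor can be folded into the intensities
by the caller. A construct's fold response is oriented so that the expected
response of an inclusion-promoting factor exceeds one — control/perturbed
for knockdowns, perturbed/control for overexpression — and "responsive"
means fold ≥ `min_fold` (default 2, inclusive up to the ε-regularisation
error). The threshold is an explicit reporting convention, configurable,
because "responds" is not otherwise quantified for deletion-mutant series.

## Clinical scoring and survival

The closed-form scores follow their standard conventions: H-score =
Σ(PI×I) with PI in percent (0–100) and intensity grades 0–3, hence a 0–300
range; xenograft volume = length × width²/2 (length the larger axis,
swapped with a warning if reversed); wound closure = (W0 − Wt)/W0 × 100.

Risk stratification uses cohort medians as cutoffs: high risk = PSI below
the PSI median *and* expression above the expression median; low risk = the
opposite corner. Mixed profiles and exact ties are excluded — the two
extreme groups are the only ones the stratification defines, and ties have
no principled home on either side. Kaplan–Meier curves use the
product-limit estimator (via the survival package) and groups are compared
with the two-group log-rank test, p from the asymptotic χ²(1); a
permutation p-value (random relabelling) is available for small cohorts
where the asymptotic reference is questionable.

## Problem sizes and numerical choices

The validation suite runs the screen's specificity check on 10,000 all-null
events and its recovery check on 10,000 events with 1,000 true effects at
coverage 100 and |ΔPSI| = 0.4; motif recovery uses 800 events (yielding the
full 50 + 50 discovery sets); Fisher p-values are checked against
exhaustive hypergeometric enumeration over every 2x2 table whose four
margins are at most 30; the log-rank permutation p is checked against
exhaustive enumeration of all 70 relabelings of an 8-patient cohort. These
sizes give stable Monte-Carlo margins while keeping a full run in minutes
on one core.

Ties and degenerate inputs are resolved explicitly throughout: category
apportionment breaks remainder ties by position order; event-set ranking
breaks ties lexicographically; risk-group ties are excluded; zero-coverage
events are `NA`; zero-sum category mixes, infeasible k-mer filters and
too-short sequences are errors or warnings at configuration time, never
silent.

## Reading and writing

Tabular artifacts are TSV/CSV with a schema-version comment line
(`# spliceshift_schema <kind> <version>`); sequences are FASTA
(`event_id|region` records), written and read with Biostrings — FASTA
carries no schema comment because comment lines are not part of the
de-facto format. Motifs export in minimal MEME text format; hit locations
export as 0-based half-open BED intervals. `run_pipeline()` orchestrates
the stages, writes one artifact per stage plus an aggregated `report.json`,
and is byte-deterministic given config and seed; a thin command-line
wrapper with subcommands ships in `inst/cli/spliceshift.R`.

## Known limitations

The screen models two pooled libraries; replicate-aware hierarchical tests
and paired designs are out of scope. The enrichment statistic is a
normal-approximation z-score against an internal background, a documented
stand-in where the field has no single canonical choice. PSI here is the
two-count abstraction — multi-isoform events and junction extraction from
alignments are upstream of this package. Survival analysis is two-group
Kaplan–Meier/log-rank only; no Cox adjustment.
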