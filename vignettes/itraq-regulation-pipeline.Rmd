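---
title: "Reporter-ion quantification and 2-SD regulation calling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reporter-ion quantification and 2-SD regulation calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itraqpipe)
```

## The problem

After subarachnoid hemorrhage (SAH), the walls of the large cerebral
arteries remodel their proteome, and much of that remodeling is driven by
MEK-ERK1/2 signalling: blocking MEK1/2 with U0126 returns a large set of
proteins to their sham level. The experimental readout is a four-plex
isobaric-tag (iTRAQ) shotgun proteomics design in which U0126-treated,
vehicle-treated and sham-operated samples are labeled on reporter channels
114, 115 and 116 respectively (117 is quantified but unassigned), pooled
1:1:1 and measured together, in duplicate labeling experiments.

`itraqpipe` implements the downstream analysis of that design as a tested,
reusable pipeline: identification filtering, protein-level reporter
quantification, normalization, regulation calling, and the two-criteria
contrast classification that defines the treatment-sensitive protein sets.

## The analysis model, stage by stage

### Identification filtering

Peptide-spectrum matches (PSMs) are filtered in two stages. First,
target-decoy q-values: for a score threshold $t$,

$$\mathrm{FDR}(t) = \frac{\#\{\text{decoys with score} \ge t\}}
                         {\max(1, \#\{\text{targets with score} \ge t\})},$$

and a PSM's q-value is the minimum FDR over all observed thresholds at or
below its score, which makes q monotone non-increasing in score. Second, a
hard score floor. The defaults — q $\le$ 0.01 and score $\ge$ 18 — are the
filter the pipeline is designed around (1% "peptide" FDR plus a
Mascot-score floor of 18). Two deliberate simplifications:

* **No semi-supervised rescoring.** The original identification workflow
  used a percolator-style rescorer; the filter's *effect* (1% FDR + score
  floor) is reproducible without the learning step, and re-implementing a
  rescorer is out of scope.
* **PSM-level q-values, labeled peptide FDR.** No peptide-level collapsing
  rule is applied, because none is specified for this design; q-values are
  computed per PSM.

Q-values are estimated **per labeling experiment** by default
(`per_experiment = TRUE`), on the reading that the decoy competition is a
property of one search of one labeled mixture; `per_experiment = FALSE`
pools everything.

### Quantification and normalization

Reporter ratios are formed **per PSM** as
$\log_2(I_\text{channel} / I_\text{116})$ — missing or zero intensities
give a missing ratio, never an error — and aggregated to the protein level
by the **median** across a protein's PSMs. The alternative (summing
intensities, then one ratio) weights spectra by intensity; the median was
chosen because it is robust to single aberrant spectra, and the two agree
in the noiseless limit.

Each channel of each labeling experiment is then centered so its median
protein log2 ratio is zero ("median normalization"), which removes loading
and labeling bias; the subtracted offsets are reported. Normalization is
idempotent and shift-equivariant, and the post-normalization median is
zero to floating tolerance (1e-12). Duplicate experiments are merged
**after** normalization by averaging a protein's log2 ratios across the
experiments in which it was quantified; `strict = TRUE` instead demands
presence in every experiment with sign-concordant ratios — a stricter
reading of how duplicate runs might have been reconciled, left off by
default because averaging is the weakest assumption that yields one value
per protein.

### The regulation statistic

For a channel with protein log2 ratios $x_1, \dots, x_n$, the pipeline
fits a per-tag distribution with center $\tilde{x}$ = median and scale $s$
= ordinary sample standard deviation (the $n-1$ denominator), and calls a
protein regulated when

$$\left| \frac{x_i - \tilde{x}}{s} \right| > 2.$$

Two points deserve emphasis:

* **The hybrid center/scale is intentional.** "Two standard deviations
  from the median" mixes a robust center with a non-robust scale. The
  package implements that literal hybrid as the default and exposes
  `robust = TRUE` (MAD $\times$ 1.4826) for users who want a fully robust
  scale; on contaminated channels the MAD is smaller and flags more.
* **The threshold is a strict inequality.** A deviation of exactly 2.0 is
  "unchanged". The threshold is configurable (`threshold` argument).

Under a Gaussian null the expected flagged fraction is
$2\Phi(-2) \approx 4.55\%$; the test suite checks this calibration on
50,000 null ratios, and checks affine equivariance (rescaling a channel
never changes a status).

A channel needs at least 3 proteins and non-zero spread to be fitted;
degenerate inputs are errors, not silent NA propagation.

### Contrast classification

Each protein's two regulation calls (vehicle vs sham, U0126 vs sham)
are combined by literal case analysis:

| vehicle | U0126           | label           |
|---------|-----------------|-----------------|
| up      | down/unchanged  | group1          |
| down    | up/unchanged    | group2          |
| up      | up              | persistent_up   |
| down    | down            | persistent_down |
| unchanged | any           | none            |

group1 and group2 are disjoint by construction (a property test hammers
this on random call pairs). A protein quantified in the vehicle channel
but absent from the U0126 channel is **excluded** from classification and
returned in the `"unpaired"` attribute: "not affected by treatment"
cannot be evidenced by a missing measurement, and inventing an unchanged
call would inflate group 1. Regulation is called on duplicate-merged
ratios, not per experiment, matching the single value per protein the
reference tables report.

## The packaged reference tables

`inst/extdata/table{1a,1b,2,3}.tsv` are verbatim transcriptions of the
printed protein tables of the source study (ten most up-/downregulated
proteins, and the group-1/group-2 tables), with unicode minus normalized
to ASCII and each file's md5 pinned in the loader — a modified fixture
fails loudly. Transcription surfaced several internal inconsistencies of
the printed tables, which the fixtures deliberately preserve:

* The group-1 table contains **139 entries** (135 unique accessions; four
  accessions are listed twice with different values) although its caption
  and the study's text say 133 proteins; the group-2 table contains **50
  entries** against a stated 51. `reproduce_paper_groups()` therefore
  reports the transcribed row counts next to the stated counts
  (133/51/184) with a `concordant` flag instead of failing, and the
  acceptance test that asserts the stated counts is expected to flag the
  discrepancy.
* Two accessions (P05811, Q5U2R0) appear in **both** group tables, which
  the classification logic itself cannot produce — the implementation's
  disjointness is proven by case analysis, the printed tables' is not.
* One value (Protein S100-A9, 3.96) prints flush against the following
  accession; the transcription notes this in a fixture comment.
* The same protein occasionally carries different accessions in different
  tables (e.g. Histone H2B type 1-H as D3ZLY9 vs Q64478); fixtures keep
  each table's own accession, so cross-table joins should use protein
  name + value.

`demo_annotation_synthetic.tsv` and `demo_edges_synthetic.tsv` are
small, hand-built **synthetic** stand-ins for the molecular-function
annotation and interaction network used downstream (the study's own
lookups were against live databases whose contents are version-dependent
and are explicitly not reproduction targets). They cover fixture proteins
— e.g. the three 14-3-3 isoforms as one interconnected cluster — so the
offline summaries are exercisable end to end.

## What the synthetic generator emulates — and what it does not

`generator_config()` defaults encode the study conditions: 2 labeling
experiments; channels 114/115/116 assigned, 117 empty; 2,000 proteins of
which 10% are truly regulated (5% up, 5% down in vehicle vs sham) with
|log2| effect 1.5; all regulated effects absent in the U0126 channel
(`frac_reversed = 1`); multiplicative reporter noise with
`noise_sd = 0.3` on the log2 scale per PSM per channel; 10% decoy PSMs
with scores Normal(10, 5) against targets Normal(40, 5). Peptides per
protein follow a negative binomial with mean 4 — a deliberate guess for
test ergonomics, since typical PSM depth is not stated for this design.
Protein reference abundances are log-normal (meanlog = log(1e5),
sdlog = 1), a conventional shape for shotgun-proteomics intensity
distributions.

Because noise is drawn independently in every channel including the
reference, a per-PSM ratio has standard deviation
$\sqrt{2}\,\cdot$ `noise_sd`; with `noise_sd = 0` all ratios are exact,
which the tests exploit for closed-form checks.

The generator does **not** simulate: spectra (m/z peaks, isotope impurity
and its correction), retention time or fractionation, shared peptides and
protein-inference ambiguity, missing-value mechanisms that depend on
abundance, or correlated noise between channels. Consequently, passing
recovery tests demonstrate that the *pipeline logic* is correct under the
stated noise model — not that the statistic is robust to ratio
compression, interference or inference errors in real data.

## Numerical and design choices

* **Ties and boundaries.** Q-value thresholds are evaluated on observed
  scores with ties handled as blocks; deviation exactly at the regulation
  threshold is unchanged; network components order by size then
  lexicographically smallest member, so all outputs are deterministic.
* **Determinism.** `generate_experiment()` seeds R's RNG from
  `config$seed`; identical config gives byte-identical tables, and
  `run_pipeline()` is deterministic end to end.
* **Problem sizes in the test suite** were chosen so closed-form and
  oracle comparisons are exact and stochastic checks have comfortable
  margins: 50,000 null ratios for calibration (3-binomial-SD band around
  4.55%), 1,000 random instances of $\le 8$ PSMs for exhaustive q-value
  enumeration, and the full default design (2,000 proteins) for group
  recovery, where sensitivity and specificity are required to reach 0.9.
* **Dependencies.** Connected components and degrees come from igraph;
  YAML configs via yaml; JSON reports via jsonlite. The q-value
  computation, normalization, regulation statistic and contrast logic are
  implemented in the package itself — they *are* the method.

## Limitations

The 2-SD rule is a calibration of the null flag rate, not an error-rate
control: it has no per-protein variance moderation, no multiple-testing
correction and no p-values, faithfully mirroring the procedure it
re-implements. With only duplicate experiments and median aggregation,
low-PSM proteins have noisy ratios that the global SD does not
acknowledge. The contrast classification inherits any miscall from either
channel; its "unchanged under treatment" arm is especially sensitive to
the U0126 channel's variance. These are properties of the original
procedure that the package preserves on purpose; the `robust_sd`,
`threshold`, `strict_merge` and `pool_fdr` knobs exist to probe them.
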