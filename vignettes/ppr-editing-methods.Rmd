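---
title: "Methods: the PPR recognition code and differential C-to-U editing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the PPR recognition code and differential C-to-U editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppredit)
```

## The biological model

PLS-class PPR proteins are tandem arrays of degenerate ~35-amino-acid
helical repeats (P, L and S variants) ending in E1/E2 motifs and, for
DYW-class editing factors, a catalytic DYW domain. Each repeat contacts one
ribonucleotide, and the base bound is correlated with two "code" residues:
the amino acids at motif position 5 and at the motif's last position. The
package treats this correlation purely statistically — no structural
modelling — and treats motif boundaries as given by an upstream annotation
(`parse_ppr_annotation()` never infers motifs from sequence).

C-to-U editing is read out of RNA-seq as apparent C-to-T conversion on the
transcript strand. A site's editing extent is the fraction of edited reads
among the informative ones.

## The scoring model

`build_scoring_tables()` estimates, separately for each motif type, a table
of scores

$$s(\mathrm{aa5},\mathrm{aaLast}, N) \;=\;
  \ln\frac{p + o_{\mathrm{pair},N}}{p + e_{\mathrm{pair},N}},
  \qquad p = 10,$$

from weighted counts $o$ of amino-acid-pair/base co-occurrences in
alignments of known factors to their targets. The published description of
the expected count ("from overall amino acid frequencies") does not pin
down the null precisely; we use the two-way independence expectation
$e = (\text{row total} \times \text{column total}) / \text{grand total}$
within each motif type, the standard null for a contingency table, and keep
it isolated in one place so an alternative marginalisation could be
substituted. Three consequences worth knowing:

* a cell with $o = e$ scores exactly 0 (so a perfectly uninformative pair
  is neutral);
* a pair never seen in training has $o = e = 0$ for every base and scores
  0 — unknown combinations neither help nor hurt a candidate;
* the pseudocount $p$ (default 10, the published value) shrinks scores for
  rare pairs toward 0; it is a tuning parameter of the code, not of this
  implementation, and we do not alter it.

**Alignment convention.** Site windows always end at the edited C (offset
0). The E2 motif is anchored at offset −2, E1 at −3, the C-terminal-most
P/L/S motif at −4, one base further 5′ per motif toward the N terminus.
Proteins lacking E2 (the published factors all have one) anchor their
C-terminal-most motif at −4; both offsets are arguments
(`anchor_offset`, `no_e2_anchor`). Motifs falling 5′ of the window, motifs
with gap code residues, and — by default — E1/E2/DYW motifs contribute
exactly 0 rather than being dropped, so motif counts stay comparable across
proteins. Whether E1/E2 should be scored at all is not settled in the
literature; `score_terminal = TRUE` enables it when tables for those types
exist. Ranking uses competition ranks (ties share the minimum rank), so "k
proteins score better" maps to rank k + 1.

All RNA input is uppercased and T is read as U at ingestion; genome
coordinates are bookkeeping only and never affect scores.

## Differential editing

`editing_extent()` uses the two informative bases as denominator: edited =
T and unedited = C on the forward strand (A and G on the reverse). Other
bases at the position are treated as sequencing noise; `denominator =
"all"` is available where the all-bases convention is wanted. A site with
no informative reads is flagged undefined, never an error.

`fisher_differential()` is the two-sided exact Fisher test computed by
hypergeometric enumeration in log space with the minimum-likelihood
two-sided convention (sum the probabilities of all tables with the observed
margins that are no more probable than the observed one). Two numerical
choices matter: probabilities are compared with a relative guard of
1 + 1e-7 so that floating-point noise cannot exclude tables that are
exactly tied, and the sum is clipped at 1. The test suite checks the
implementation against exhaustive enumeration over every 2x2 table with
grand total up to 60 and against the reference implementation in `stats`.

Multiple testing uses the Simes-Hochberg step-up procedure
(`stats::p.adjust(method = "hochberg")` behind `adjust_pvalues()`), applied
across the whole family of positions showing C/U variation, not only
annotated sites. Odds ratios add a pseudocount of 0.5 to all four cells
(the published convention), so they are always finite and positive.

`call_differential_sites()` applies three thresholds that the original
analysis left implicit, exposed as arguments:

* `min_total = 10` informative reads per genotype — below this the exact
  test has essentially no power and extents are unstable; skipped sites are
  reported, not silently dropped;
* `delta_min = 0.10` absolute extent change — a pure significance filter
  would flag biologically negligible shifts at very high coverage;
* `lost_factor = 0.05` — a significant site is "lost" when the second
  genotype retains at most 5% of the first's extent, capturing a collapse
  of editing as opposed to a partial decrease. Note that a site with
  several percent residual editing can be a true direct target yet fall
  outside this strict definition.

When reproducing a published Fisher-only analysis, set `delta_min = 0`.

## Orthologue comparison

Species where a site is no longer editable (genomic T/A/G) are expected to
lose the selective constraint on the upstream binding sequence. The test
(`editable_vs_noneditable_test()`) is a one-sided two-sample t-test of
orthologue scores, alternative mean(editable) > mean(non-editable). The
Welch unequal-variance form is the default because species panels are
small, unbalanced and heteroscedastic; the pooled form is available via
`var_equal = TRUE`. Groups with fewer than two observations are flagged
untestable rather than raising. If both groups are exactly constant the
t statistic is degenerate; we return p = 0.5 when the means are equal (the
symmetric null) and 0 or 1 otherwise.

## The synthetic-data module

The generators are pure functions of a `generator_config()`; one master
seed fans out to fixed per-generator substreams, so adding a generator
never perturbs existing draws. Defaults are chosen to mirror the scale of
the motivating study rather than to be easy:

* training: 6 motif types x 20 amino-acid pairs x 40 observations, with
  the preferred base carrying multinomial weight `exp(contrast)`
  (default contrast 3, i.e. the preferred base is drawn ~87% of the time);
* ranking: a 17-motif planted factor (the motif count of the motivating
  factor) with E1/E2, against 204 decoys — a 205-protein candidate set, the
  size of the PLS-PPR complement screened in the study;
* counts: 4 planted lost sites (editing rate 0.95 versus 0.00) among 200
  unchanged sites, coverage uniform in 500-1000, symmetric miscall rate
  0.1%;
* orthologue panel: 20 editable + 20 non-editable species; non-editable
  windows drift at `divergence_rate = 0.3` per position while editable ones
  drift at one tenth of that (`conservation_factor = 0.1`), emulating
  purifying selection on a functional binding site.

What the simulations do **not** emulate: mapping artefacts and strand
bias, overdispersed coverage, linked editing sites on one transcript,
phylogenetic correlation between species (panel records are independent),
and realistic amino-acid composition of PPR motifs. Passing the synthetic
benchmarks therefore demonstrates the correctness and power of the
statistical machinery under the stated generative model, not performance
on any particular real dataset.

## Problem sizes and determinism in the checks

The test suite and the acceptance script run the Fisher oracle over all
2x2 tables up to grand total 60 (~630k tables), 1000 random p-vectors for
the Hochberg oracle, 100 seeded ranking trials at the 205-protein scale,
and 1000 label permutations for the t-test calibration; these sizes give
stable pass/fail behaviour at the asserted tolerances while keeping a full
run in well under a minute per property. All stochastic checks fix their
seeds; `scripts/acceptance.R` derives every stream from its `--seed`
argument.

## Known limitations

* The shipped motif annotation fixture is synthetic/illustrative: the
  motivating factor's actual code residues are not published as text, so
  the fixture reproduces the architecture (motif types and C-terminus)
  with plausible residues, and is named and documented accordingly.
* The scoring code is count-based; no attempt is made to learn
  interactions between motifs or position-specific weights.
* Editing-site discovery from a single sample, read trimming/mapping, and
  orthologue identification are out of scope: the pipeline starts from
  count tables (or a SAM/BAM via the optional `Rsamtools` adapter), motif
  annotations and orthologue assignments.
* Printed p-values in published per-site tables are typically adjusted
  over an unprinted family and cannot be recomputed from the printed 2x2
  counts alone; the package reproduces count-derived percentages exactly
  and treats published p-values as qualitative context only.
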