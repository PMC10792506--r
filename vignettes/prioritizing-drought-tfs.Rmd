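---
title: "Prioritizing transcription factors and cell wall genes under water deficit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing transcription factors and cell wall genes under water deficit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfprio)
```

## The model

`tfprio` asks which transcription factors (TFs) orchestrate the expression
response of cell-wall-protein (CWP) genes to water deficit, given two kinds
of evidence: a compendium of independent two-group (control vs stress)
expression experiments, and a directed regulatory network of TF → target
interactions in which targets carry one of nine cell wall functional
classes.

The statistical core is deliberately simple and exact:

**Vote counting across experiments.** Each experiment yields directional
DEG calls (`p < p_threshold` and `|log2FC| > lfc_threshold`, both strict).
Under the null hypothesis that an experiment calls a gene by chance with
probability $p_0$, the number of calls across $n$ experiments is
$X \sim \mathrm{Binomial}(n, p_0)$. A gene whose calls all share one sign
and number $k \ge k^*$, where $k^*$ is the smallest $k$ with
$P(X \ge k) < \alpha$, is a *stable unidirectional DEG*. With
$n = 5, p_0 = \alpha = 0.05$ the cutoff is $k^* = 2$
(tail $\approx 0.0226$). Effect sizes are never pooled across experiments;
only the binary calls are, which is appropriate when the experiments differ
in platform processing, stress duration and severity.

**Hypergeometric target-set enrichment.** For a TF with $K$ CWP targets
inside a universe of $N$ genes, of which $n$ are DEGs in one experiment, the
probability of an overlap at least as large as the observed $k$ is the exact
upper tail $P(X \ge k)$ of the hypergeometric distribution. The **STF**
(score of the transcription factor) counts the experiments with
$p < \alpha_{\text{enrich}}$; TFs with $\mathrm{STF} \ge 1$ are *priority
TFs*. After reducing the network to priority TFs and their targets, the
**SCWP** (score of the cell wall protein) of a gene is its TF in-degree —
the number of distinct TFs regulating it.

The pipeline (`run_pipeline()`) applies the stages in a fixed order: DEG
calling → stable-DEG calling → orphan-CWP pruning → drought-process TF
filter → stable-DEG TF restriction → enrichment → STF → priority selection →
network reduction → SCWP → ranking and class summaries. The process filter
runs before the stable-DEG restriction, and each TF-removal stage re-prunes
CWP genes left without regulators, so the funnel of node counts is monotone
by construction (exposed in `result$stages`).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `p_threshold` | 0.05 | per-experiment DEG p-value cutoff (strict) |
| `lfc_threshold` | 1.0 | log2 fold-change magnitude cutoff (strict) |
| `p0` | 0.05 | null per-experiment probability of a directional call |
| `alpha_stable` | 0.05 | significance of the binomial vote-counting rule |
| `alpha_enrich` | 0.05 | per-(TF, experiment) enrichment significance |
| `universe` | `"pruned"` | gene universe of the enrichment test (below) |
| `scwp_mode` | `"reduced"` | network on which SCWP is computed (below) |

All tests use raw (unadjusted) p-values by default: the "priority if
enriched in at least one experiment" rule is a screening criterion, not a
confirmatory family of tests. Benjamini–Hochberg adjustment across TFs
within an experiment is available via `adjust = "BH"` for users who prefer
controlled false discovery at this stage.

Two genuinely open design choices deserve explanation:

**The enrichment universe.** The narrowest defensible universe — only the
CWP genes that survive the drought-process filter — sounds attractive but is
self-defeating: those genes are precisely the targets of drought TFs, so in
strongly responding data nearly the whole universe is differentially
expressed and no target set can be enriched (if $n \approx N$, the tail is
$\approx 1$ for every TF; the test loses all discrimination exactly when the
signal is strongest). The default is therefore the set of CWP genes with at
least one TF interaction (the orphan-pruned network) that were measured in
the experiment: a TF's target list is judged against the cell wall gene
population at large, which keeps contrast regardless of how aggressive the
upstream TF filters were. `universe = "filtered"` (the narrow set) and
`universe = "measured"` (every measured gene) remain available.

**The SCWP network.** Counting regulators on the reduced (priority-TF)
network ranks genes by their connectivity to the *prioritized* regulators;
counting on the pre-reduction network credits connections to
non-priority TFs as well and can only give larger values. Both readings are
legitimate summaries; the package defaults to the reduced network
(`scwp_mode = "reduced"`) because the reduced network is the pipeline's
final object of interest, and offers `"prefilter"` for the broader count.
Reduction never increases any gene's SCWP, a property the test suite checks.

Other decided points: the `|logFC|` reading of the fold-change threshold
(both activated and suppressed genes are DEGs); strict inequalities at every
threshold, so boundary values never pass; a logFC of exactly 0 is never a
call even at tiny p; unidirectionality is all-or-nothing — a single
discordant experiment disqualifies a gene regardless of how many concordant
calls it has; genes absent from an experiment reduce that gene's $n$ in the
binomial rule instead of counting as a non-call, because absence from a
platform is not evidence of non-regulation; and ranking ties are broken
lexicographically by identifier, so all outputs are deterministic.

## What the synthetic generator emulates

`sim_params()` / `simulate_study()` produce the study conditions the
package is designed around: 5 experiments, 60 TFs of which 6 are planted
drought regulators, 800 CWP genes, 3 replicates per group. Each planted TF
receives exactly 30 targets (without replacement); background regulation is
an independent 0.02-probability edge per TF/gene pair, giving background
in-degrees comparable to the planted ones so that recovery is not trivial.
Expression is Gaussian on the log2 scale: per-gene baselines from
$\mathcal{N}(8, 1)$ (the scale is immaterial — every downstream statistic is
shift-based), within-group noise $\sigma = 0.5$, and a $\pm\Delta$ shift
($\Delta = 2$) in the stress group of true DEGs. A gene is a true DEG per
experiment with probability $q_{hi} = 0.5$ if it is a planted TF or one of
its targets, else $q_{lo} = 0.05$; these base rates are calibration choices
for a realistic middle ground (drought regulons respond in roughly half the
heterogeneous experiments; background differential expression is at the
nominal test level). Each gene's response direction is drawn once and shared
across experiments, so planted signal is unidirectional by construction —
this is the structure the vote-counting rule is designed to detect, and the
generator plants planted TFs themselves as responders because a regulator
that never responds would be eliminated by the stable-DEG restriction that
the pipeline applies to TFs.

Randomness is plumbed as one master seed with per-experiment streams at
`seed + experiment index`, so extending a compendium never perturbs
already-generated experiments.

The generator deliberately does **not** emulate probe-level microarray
structure, normalization artefacts, correlated noise between genes, batch
effects, or secondary (TF → TF) regulation cascading expression changes.
Passing tests therefore demonstrate that the statistical machinery recovers
planted structure under clean Gaussian noise — not that it is robust to the
full messiness of public microarray compendia, where upstream normalization
and moderated test statistics (outside this package's scope; precomputed DE
tables are accepted instead) do that work.

## Numerical choices and degenerate inputs

* Both discrete tails are computed exactly (`pbinom`/`phyper` upper tails);
  the test suite verifies them against exhaustive enumeration (all
  $\binom{N}{n}$ draws for $N \le 12$; all $2^n$ call patterns for
  $n \le 12$).
* The per-gene two-group comparison is a vectorised Welch test on log2
  values. Zero-variance rows are resolved deterministically ($p = 1$ if the
  group means agree, $p = 0$ otherwise) rather than propagating `NaN`.
  This plain test exists for synthetic and pre-normalized data; studies with
  their own DE pipeline should supply DE tables directly.
* TFs with no targets in the universe get $p = 1$, `degenerate = TRUE`, are
  never enriched, and are retained in score tables with STF 0 so reports
  stay complete.
* Report files print doubles at 6 significant digits and sort rows
  deterministically; identical inputs give byte-identical outputs.

## Problem sizes used in the checks

The package's statistical checks run at sizes chosen to make their Monte
Carlo error small relative to the margins being tested: null calibration
uses 50 replicates of 400 genes × 5 experiments (stable-DEG rate compared to
its exactly enumerated expectation within 3 standard errors) and 50
replicates of a 40-TF/300-gene network for the enrichment false-positive
rate; recovery uses 20 replicates of the default scenario above, requiring
all planted TFs in the STF top 10 in at least 90% of replicates. The same
quantities are recomputed from scratch by `scripts/acceptance.R`.

## Known limitations

* Vote counting discards effect sizes; a gene with huge but
  single-experiment response is invisible to the stable-DEG rule.
* The all-or-nothing unidirectionality rule is harsh at large $n$: one
  discordant platform among many vetoes a gene.
* STF saturates at the number of experiments; it cannot distinguish TFs
  beyond that ceiling (ties are broken lexicographically, not biologically).
* SCWP is a raw degree count and inherits any ascertainment bias in the
  input network: heavily studied TFs contribute more edges.
* The hypergeometric test assumes exchangeable genes within the universe;
  co-regulation violates this and makes the nominal level approximate on
  real data.
```{r session}
sessionInfo()
```
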