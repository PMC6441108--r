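---
title: "Methods: promoter bivalency, resampled enrichment, and limiting-dilution statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter bivalency, resampled enrichment, and limiting-dilution statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bivalency)
```

# Scope

`bivalency` implements the downstream statistics of a common epigenomics
study design: H3K4me3/H3K27me3 ChIP-seq peak calls from two replicates are
reduced to a five-state promoter chromatin classification, crossed against
an RNA-seq differential-expression (DE) table, tested for enrichment by
gene-set-permutation GSEA with subset resampling, and complemented by
single-hit limiting-dilution analysis (LDA) of self-renewal assays and by
composite immunohistochemistry (IHC) scoring of a clinical cohort. A
synthetic-data module generates every input with planted ground truth, so
the full pipeline is exercisable and testable without any external data.

# Promoter windows and coordinates

Promoters are windows around the transcription start site (TSS), by
default 2500 bp upstream to 500 bp downstream **in the direction of
transcription**: for a + gene with TSS $t$ the window is $[t-2500,\,
t+500)$ in 0-based half-open coordinates; the minus-strand window is its
mirror image. Annotation formats are silent on which convention a window
rule was written in, so the package fixes one: internally everything is a
`GRanges` (1-based, closed — the Bioconductor convention), and BED-family
files (0-based half-open) or GTF (1-based inclusive) are converted at the
I/O boundary. Overlap always means at least one shared base; half-open
abutment is not overlap. Windows are clipped to chromosome bounds when
sizes are known; a window falling entirely off its chromosome is an
error rather than a silent empty window.

One TSS per gene id is assumed. Annotations with multiple isoforms per
gene must be reduced to one record per gene (or supplied per transcript)
by the caller; the package does not choose a canonical isoform.

# Five-state classification

Peaks are first filtered for replicate consistency: a replicate-1 peak is
**retained** (coordinates unchanged) when it shares at least one base with
any replicate-2 peak. Retention, not union or intersection, is the minimal
operation consistent with keeping "peaks identified in both replicates";
merging would manufacture coordinates no caller produced.

Each promoter window is then labelled:

* `NONE` — no retained peak of either mark overlaps the window;
* `K4_ONLY` / `K27_ONLY` — only one mark present;
* `BIVALENT` — some H3K4me3 peak and some H3K27me3 peak overlapping the
  window also overlap **each other**, with their intersection intersecting
  the window;
* `MIXED` — both marks present, but no such pair.

A `bivalent_scope` switch offers `"in_window"` (the intersection must
touch the window; default) and `"anywhere"` (any direct overlap between
two window-touching peaks). These two readings are in fact provably
equivalent: if intervals $A$ and $B$ each intersect window $W$ and
intersect each other, then $\max(l_A,l_B) \le \text{end}(W)$ and
$\min(r_A,r_B) \ge \text{start}(W)$, so $A\cap B$ intersects $W$. The
switch is retained for interface clarity, and the equivalence is asserted
by a randomised test rather than assumed.

DE classes use strict thresholds: *up* means $q < q_\text{thr}$ (default
0.05) and $\log_2\text{FC} > 0$; *down* the mirror; everything else —
including $q$ exactly at the threshold or a significant gene with exactly
zero fold change (flagged) — is *unchanged*.

# Enrichment analysis

The enrichment score (ES) is the classic weighted Kolmogorov–Smirnov
running-sum statistic: walking down the list ranked by a signed DE metric,
a set member at position $i$ adds $|m_i|^p / \sum_{\text{hits}} |m|^p$
and a non-member subtracts $1/(N - n_\text{set})$; ES is the signed
maximum deviation, with ties resolved to the earliest list position
(matching a left-to-right scan). The default weight exponent is $p = 1$;
$p = 0$ gives the unweighted KS statistic. The default ranking metric is
signed $\log_2$ fold change, with signed $-\log_{10} q$ available; the
choice is recorded on the ranked list because results are not invariant
to it.

The null model is **gene-set permutation**: random same-size sets drawn
without replacement from the ranked universe. With $n = 3$ RNA-seq
replicates per condition, phenotype permutation would admit too few
distinct relabellings to be meaningful, so it is out of scope. NES divides
ES by the mean $|$null ES$|$ of the same sign (the standard signed-mean
normalisation), and the nominal p-value is add-one smoothed within the
same-sign null, $p = (1 + a)/(1 + m)$, so $p > 0$ always and the smallest
attainable value is $1/(m+1)$.

Family-wise error control uses the max-statistic method: each permutation
round's null ES values are normalised per set, the family maximum of
$|$null NES$|$ per round forms the reference distribution, and a set's
FWER p is the add-one-smoothed fraction of rounds reaching its $|$NES$|$.
Because a multiplicity correction should never increase significance, the
corrected value is floored at the nominal p (the same monotonicity
convention `p.adjust` enforces).

**Resampled subset enrichment** summarises a large promoter-state pool by
repeatedly (default 30 times) drawing random subsets (default 200 genes),
testing each, and reporting the NES quartiles, the least significant
subset (largest nominal p — the most conservative single answer), and the
percentage of subsets significant at `alpha` (default 0.25, the usual
exploratory GSEA cut) in each direction. The percentages are computed
within direction: among positively enriched subsets, the share with
$p < \alpha$, and likewise for negative. Under a null list roughly half
the subsets land on each side, so this conditional definition — not the
unconditional one — is the quantity that calibrates to $\alpha$ in the
null simulations the tests run. Subsets are drawn independently and may
share genes across draws; partitioning would cap the number of subsets at
pool size / subset size and is not what repeated random subsetting means.

# Limiting-dilution statistics

The single-hit Poisson model says a well (or injection site) is positive
iff it received at least one initiating cell:
$P(\text{positive} \mid d) = 1 - e^{-f d}$ for dose $d$ cells and
initiating frequency $f$. The MLE of $\log f$ is the intercept of a
binomial GLM with complementary log-log link and offset $\log d$ — the
same formulation the standard ELDA tool uses. IRLS can diverge when the
data contradict the dose response (e.g. fewer positives at higher dose),
claiming convergence at an absurd intercept, so the GLM solution is
accepted only if it zeroes the exact score function; otherwise the score
equation is solved directly by root-finding, with the standard error from
the observed information. The single-dose closed form
$\hat f = -\ln(\text{fraction negative})/d$ and the iterative fit agree to
$|\Delta \log f| < 10^{-6}$ by test.

Confidence intervals are Wald on $\log f$ (ELDA's default behaviour),
reported on the "1 in $N$" scale. All-negative or all-positive data sit on
the likelihood boundary: the fit is flagged and a one-sided exact bound is
returned instead (the frequency at which the observed extreme outcome has
probability 0.025). Group comparison is a 1-df likelihood-ratio test of a
shared frequency against per-group frequencies, computed from exact
binomial log-likelihoods, plus the frequency ratio with a Wald CI from the
difference of $\log f$. A deviance goodness-of-fit check against
$\chi^2_{(\text{doses}-1)}$ warns when the single-hit assumption itself
fits poorly or the dose response is inverted.

# Clinical association

The composite IHC score is the product of the percent-positive class P
(0–4) and intensity class I (0–3), range 0–12. Quintile grouping ranks by
composite score, takes the lowest and highest $\lceil n/5 \rceil$, pulls
records tied with a cut into the nearer extreme group, and reports the
realised cuts; fully degenerate scores are an error rather than an
arbitrary split. Recurrence is compared by Pearson chi-square without
continuity correction (expected counts are large at cohort scale; a
`correct` flag exposes the Yates variant). Signature correlation is plain
Pearson $r$ of the target gene's row against each signature gene's row,
computed on values as provided — normalisation or log-transformation is
the caller's decision — with missing signature genes listed, zero-variance
rows flagged as NA, and output ordered by $r$ for heat-strip display.

# The synthetic-data generator

The generator emulates the downstream products of such a study, not its
raw sequencing: replicate peak sets with planted promoter states, a DE
table, LDA outcome tables, and a clinical cohort.

* **Genome layout.** Genes are placed so all promoter windows are pairwise
  disjoint and fully on-chromosome, making planted labels unambiguous and
  the recovery property exact. Requesting more windows than fit is a
  capacity error.
* **Peaks.** Planted peak width defaults to 500 bp, a typical sharp-mark
  peak breadth. Bivalent promoters get a K4/K27 pair overlapping by half a
  peak width inside the window; mixed promoters two well-separated peaks;
  decoy intergenic peaks (default 100 per mark per replicate, fewer when
  the genome is too crowded to host them) exercise the window lookup.
  Noise is opt-in and per replicate: a normal position jitter (sd
  `peak_jitter_sd`) and a drop probability. The defaults are noiseless
  because no noise model for peak calls can be inferred from published
  peak tracks; the jitter/drop model is an artifact convention for
  stress-testing replicate retention, not a claim about real data.
* **DE response.** Planted direction follows a logistic model:
  $P(\text{up}) = \text{logit}^{-1}(\beta_0 + \beta_1 \cdot
  \text{K27-bearing})$ with defaults $\beta_0 = -3$, $\beta_1 = 3$, so
  background genes are upregulated with probability $\approx 0.047$ and
  H3K27me3-bearing genes with probability $0.5$. In strict-derepression mode no
  K27-bearing gene is planted downregulated, mirroring the qualitative
  signature of EZH2-inhibition studies. Significant genes draw $q$
  uniformly on $(0, 0.05)$ and others on $(0.05, 1]$: only the threshold
  partition matters downstream, so a realistic q distribution would add
  nothing the pipeline can detect.
* **LDA.** Doses default to the in vitro ladder 1000/100/10/1 cells per
  well (the in vivo ladder 10000/1000/100/10 is one argument away), 24
  wells per dose, and true frequencies 1/200 (control) vs 1/800
  (treated) — a fourfold difference of the magnitude such studies report.
  Positives are Binomial$(n, 1 - e^{-f d})$.
* **Clinical.** 250 patients; P and I uniform over their ranges;
  recurrence Bernoulli with logit $-2.2 + 0.15 \cdot P \cdot I$, chosen
  once so the cohort-wide recurrence rate is modest and the top-vs-bottom
  quintile contrast is about twofold to threefold, the regime reported for
  EZH2 IHC cohorts.

Every generator derives an independent RNG substream from the root seed,
keyed by stage name, so adding one stage never perturbs another, and all
outputs are bit-reproducible under a fixed seed. Generated files round-trip
through the package's readers warning-free.

What passing tests on these data do **not** show: robustness to realistic
peak-caller artefacts (summit shifts, merged peaks, blacklist effects),
to DE misestimation, or to non-single-hit biology (e.g. cooperative
initiation in LDA). The generator plants the model the statistics assume;
tests on it validate the implementation, not the model.

# Numerical choices

* ES running sums are exact rational-weight arithmetic in double
  precision; the profile ends at 0 within $10^{-9}$ and the brute-force
  oracle agreement is asserted to $10^{-12}$.
* Permutation nulls are vectorised from sorted hit positions
  ($O(k)$ per permutation, not $O(N)$), so 10,000-permutation runs stay
  interactive.
* Score root-finding for the LDA fit brackets $\log f \in [-50, 10]$ with
  tolerance $10^{-12}$; boundary bounds solve the exact binomial tail
  equation by `uniroot`.
* Ties: gene ranking breaks metric ties lexicographically by id; the ES
  extreme takes the earliest position; duplicate peaks are deduplicated on
  load with a warning; duplicate gene ids are an error.

# Problem sizes

The shipped tests run the classification oracle on 100 random genomes (up
to 50 genes, 600 peaks), permutation calibration at 200 draws of 999
permutations, resampling nulls over 300 subsets, and LDA recovery over 500
simulated replicates per property — sizes chosen so the full suite
completes in about two minutes on one core while keeping Monte-Carlo error
well inside the asserted bands. The acceptance script analyses a 2500-gene
synthetic study end to end.

# Known limitations

* Classification is promoter-window based only; genome-wide bivalent
  domain calling outside promoters is out of scope.
* Gene-set permutation is the only null; phenotype permutation and
  leading-edge reporting are not implemented.
* The LDA model is strictly single-hit; multi-hit and heterogeneity
  models are not fitted (the goodness-of-fit check at least flags gross
  violations).
* Quintile cuts operate on the integer composite scores as given;
  fractional published cuts arising from averaged duplicate stains cannot
  be reproduced without the averaging scheme.
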