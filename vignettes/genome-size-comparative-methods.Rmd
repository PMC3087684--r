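---
title: "Genome-size evolution across a cryptic species complex: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-size evolution across a cryptic species complex: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BrachioGS)
```

## The scientific problem

Haploid genome size (the C-value) varies enormously across eukaryotes, but
most of what is known comes from comparisons between genera, families or
classes. The *Brachionus plicatilis* rotifer complex — at least a dozen
cryptic species spanning three deeply diverged clades — offers a rare look
at genome-size evolution right at the speciation level. BrachioGS
implements the full analysis chain for such a data set: estimating genome
sizes by internal-standard flow cytometry, decomposing their variance
across taxonomic levels, testing for whole-genome duplications, and asking
whether genome size covaries with egg and body size once phylogeny is
accounted for.

## Flow-cytometry genome-size estimation

Propidium-iodide fluorescence of isolated nuclei is proportional to DNA
content, so co-preparing the sample with a standard of known genome size
turns peak positions into picograms:

$$\mathrm{pg} = \frac{\text{sample peak channel}}{\text{standard peak channel}}
  \times \mathrm{pg}_{\text{standard}},\qquad 1\ \mathrm{pg} = 978\ \mathrm{Mbp}.$$

The default standard is *Drosophila melanogaster* ISO-1 at 0.35 pg. Whether
that figure denotes the 1C or 2C content — and the matching assumption that
sample and standard peaks represent the same C-level — is not decidable
from the calibration itself, so `genomeSizeFromPeaks()` carries it as an
explicit `assumption` field rather than silently.

`detectPeaks()` is a documented operationalization (cytometer acquisition
software does this step opaquely in practice): counts are smoothed with a
5-bin moving average; local maxima qualify as peaks when (i) their
topographic prominence reaches 10% of the largest smoothed count and
(ii) they rise above a flat-background (Poisson) expectation of
$\lambda + 5\sqrt{\lambda}$ with $\lambda$ = mean events per bin. Criterion
(ii) is what makes a noise-only histogram return no peaks: prominence alone
cannot, because the global maximum's prominence is always its full height.
Peak moments are then computed from the raw counts inside a gate of
mean ± 2.5 local standard deviations, seeded by the smoothed peak's FWHM
and refined once. Two consequences worth knowing:

- the ±2.5-sd gate truncates Gaussian tails, so reported CVs understate the
  true peak CV by about 4% of its value (a 4.0% peak reads ≈ 3.8%);
- all three thresholds (window 5, prominence 0.10, gate 2.5 sd) are
  arguments; the defaults recover synthetic peaks with CVs in the 2–6%
  range typical of good acquisitions.

Reporting convention throughout: rounding is half-away-from-zero
(`roundHalfAway()`), one decimal for Mbp, three for pg, applied only at
reporting — never inside computations.

## Morphometrics

Both body and egg shapes are ellipsoids specified by measured *diameters*
(total length and breadths), so the semi-axes are half the measurements and
the volumes reduce to $(\pi/6)$ times the product of diameters:
$V_{\text{body}} = (\pi/6)\,L\,B_1 B_2$ (general ellipsoid) and
$V_{\text{egg}} = (\pi/6)\,L\,B^2$ (ellipsoid of revolution). This is the
only reading under which "polar radius = total length" is dimensionally
sane; with $B_1 = B_2$ the two formulas agree, which the tests check.

## Nested variance components

Genome-size variation is decomposed over the taxonomic hierarchy with the
four-level nested random-effects model

$$y = \mu + a_{\text{clade}} + b_{\text{species|clade}}
      + c_{\text{clone|species}} + e,$$

fitted by REML (the right estimator for unequal group sizes) via
`lme4::lmer`, with all components constrained non-negative. Percentage
shares are $100\,\sigma^2_\ell/\sum\sigma^2$.

**Analysis scale.** The decomposition is run on ln genome size by default.
Two reasons: shares on the log scale are invariant to the measurement unit
(pg vs Mbp differ by an additive constant in logs), and the magnitude of
the published total variance is consistent with a log scale given the
seven-fold spread of the data. `scale = "raw"` is available.

**Reconstruction from printed summaries.** Published tables give per-clone
mean, s.e.m. and n rather than raw replicates. All nested sums of squares
depend on the replicates only through their first two moments, so
`reconstructReplicates()` places a canonical deterministic symmetric set —
pairs mean ± δ (plus one value at the mean for odd n) with δ chosen so the
sample sd equals sem·√n exactly — and the refit is exact with respect to
the information the table carries. A caveat: the reconstruction is applied
on the Mbp scale and the model is fitted on the ln scale, so within-clone
log-moments are approximations (second-order in sem/mean, i.e. negligible
at the ≤ 4% relative s.e.m.s of these data).

**Degenerate designs.** A single clade (or any level without replication)
makes that component unidentifiable: it is dropped, reported as 0, and a
reduced-model warning raised. All-equal data short-circuit to four zero
components with percentages flagged undefined.

The estimator is validated two ways: against a hand-coded closed-form
balanced nested-ANOVA moment oracle (the two must agree when all components
are interior), and by parameter-recovery simulation. On recovery design
sizes: variance components at a level with $k$ groups carry only $k-1$
degrees of freedom, and the sampling *median* of a $\chi^2_{k-1}$-dominated
estimate sits well below its mean for small $k$ (≈ 55–69% of the truth at
$k = 3$). Median-recovery benchmarks therefore use a balanced
12 clades × 4 species × 3 clones × 4 replicates design, where all
components are comfortably identified; at a paper-like 3-clade design only
the species- and clone-level medians are informative, while the clade
component is unbiased in mean but strongly right-skewed. This is a property
of variance estimation with two degrees of freedom, not of the estimator.

## Independent contrasts

`computeContrasts()` implements the pruning recursion: for children $i, j$
of a node, with adjusted branch lengths $b_i, b_j$,

$$u = \frac{x_i - x_j}{\sqrt{b_i + b_j}}, \qquad
  \hat x_{\text{anc}} = \frac{x_i/b_i + x_j/b_j}{1/b_i + 1/b_j}, \qquad
  b_{\text{anc}} \mathrel{+}= \frac{b_i b_j}{b_i + b_j},$$

yielding exactly $n-1$ standardized contrasts on a bifurcating $n$-tip
tree. Polytomies (forced in parsimony trees wherever support is weak) are
first resolved deterministically by `resolvePolytomies()`: left-to-right
pairing of children on zero-length branches, which preserves all patristic
distances and keeps contrast counts reproducible, as opposed to randomized
resolution.

**Sign convention.** Contrast sign is first child minus second child in
stored order. It is arbitrary — rotating a node flips it — so every
reported quantity (|u|, r², p) is rotation-invariant, and the contrast
correlation is computed *through the origin*,
$r = \sum u_x u_y / \sqrt{\sum u_x^2 \sum u_y^2}$, with a two-sided p from
$t = r\sqrt{n-1}/\sqrt{1-r^2}$ on $n_{\text{contrasts}} - 1$ df (one df
is absorbed by the suppressed intercept).

**Zero and missing branch lengths.** Parsimony branch lengths can be zero,
which would zero a contrast denominator. The default `"epsilon"` policy
substitutes $\varepsilon = 10^{-6} \times$ tree height for both child
branches *only at nodes where the denominator would vanish*, leaving every
other branch untouched; `"all_one"` sets every branch to 1 (and is the only
policy usable when lengths are missing — missing is deliberately distinct
from zero); `"raw"` turns the condition into an error naming the node.
Whether the original PDAP-style analyses transformed parsimony branch
lengths is not recoverable, so the choice is exposed rather than hidden.

Calibration facts used as tests: on a star phylogeny with equal branch
lengths the contrasts are a Helmert (orthogonal) transform of the centered
tip values, so the contrast correlation equals the ordinary Pearson
correlation to machine precision; and under Brownian motion with rate
$\sigma^2$ the standardized contrasts are i.i.d. Normal(0, $\sigma^2$).

## The serial-independence test

The TFSI statistic is the first-order von Neumann ratio
$\eta = \sum (x_{i+1}-x_i)^2 / \sum (x_i - \bar x)^2$ of the trait along
the tree's tip order (depth-first, honoring child order). Since any tip
order is one arbitrary member of the rotation class of the topology, the
observed statistic averages $\eta$ over `nRotations` random rotations
(each internal node's children reversed independently with probability
1/2). The null distribution permutes values across tips and recomputes the
same rotation-averaged statistic; the p-value is one-tailed toward
*positive* autocorrelation (small $\eta$), with the +1 correction so
p ∈ (0, 1].

Pinned design choices, each configurable:

- the rotation set is drawn once per test and shared between the observed
  statistic and every permutation replicate ("average over rotations inside
  each permutation"); this removes one layer of Monte-Carlo noise from the
  observed/null comparison;
- defaults `nRotations = 1000`, `nPermutations = 999`;
- in contrasts mode each rotation replicate additionally re-randomizes
  every contrast's sign with probability 1/2, removing the sign-convention
  artifact noted above;
- all randomness flows from one mandatory integer seed; reruns are
  bit-identical.

The test is calibrated by simulation: under i.i.d. data it holds its
nominal size (the permutation construction makes the size exact up to
Monte-Carlo error), and under Brownian motion on a deep tree it detects
strong serial dependence in tip data which drops to the nominal rate after
contrasts — the before/after pattern the workflow is built to exhibit.

## Ploidy multiples

`fitPloidyMultiples()` scores a candidate base $\beta$ by assigning each
size the multiplier $m = \max(1, \mathrm{round}(size/\beta))$ and averaging
$|size - m\beta|/(m\beta)$. Score ties over a grid go to the *largest*
base: any exact base fits equally well at half its value with doubled
multipliers, so preferring the coarsest consistent base is the only
convention under which "the base genome" is well defined. With
`fixedBase` the search is skipped — the analysis of the B. 'Austria'
lineage fixes $\beta$ = 117 Mbp, the mean of its three closest relatives'
species means, making the test external rather than circular.

## Synthetic data: what it emulates, and what it does not

The generators cover every distributional assumption the statistics make:
`simulateBM()` (recursive Gaussian increments, via `phytools::fastBM`);
`simulateCorrelatedBM()` (an exact matrix-square-root transform of two
independent unit-rate BM traits — exact because BM is linear-Gaussian, and
tolerant of singular covariances); `simulateNestedDataset()` (independent
Gaussian level effects, balanced or arbitrary skeletons);
`simulateHistogram()` (Gaussian peaks with specified mean/CV/events plus a
uniform noise floor); `simulateYuleTree()`. Every generator takes a
mandatory seed and reruns bit-identically; sub-streams are derived from a
single master seed in the workflow.

What passing tests on these generators does *not* show about real data:
real fluorescence histograms have debris tails, doublet (G2) peaks and
drift, not a clean uniform floor; real genome-size evolution in a lineage
with whole-genome duplications is saltational, the strongest possible
violation of the BM model (which is precisely why the workflow supports
re-running after excluding such a lineage); and the bundled companion tree
is approximate below the species level — ladders with unit branch lengths —
so tree-based results on the fixture exercise the machinery rather than
reproduce published statistics. The published per-clone body- and egg-size
measurements were never printed, so the corresponding correlation tables
can only be checked as procedures (via simulation with known truth), not as
numbers.

## Problem sizes and numerical choices

Simulation-based checks in the test and acceptance suites use sizes chosen
to make Monte-Carlo error a small fraction of the tolerance they assert:
500 replicates on a 64-tip Yule tree for correlation recovery (tolerance
0.05 against a truth of 0.8), 1000 replicates for the TFSI size (binomial
s.e. ≈ 0.007 at the 0.05 ± 0.02 band), 100 replicates for the
before/after-contrast pattern, 200 replicates for variance-component
recovery, with TFSI settings of 20–100 rotations and 199 permutations in
simulation studies (the defaults of 1000/999 are for single analyses).
Other numerics: REML convergence is lme4's default; the ε substitution is
$10^{-6}\times$ tree height (with a $10^{-30}$ floor for all-zero trees);
grid ties in the ploidy fit resolve to the largest base within $10^{-12}$
of the minimum score; `roundHalfAway()` adds $10^{-12}$ before flooring to
absorb binary representation error at the half-way points.

## Known limitations

- Raw FCS binary parsing is out of scope; histograms enter as two-column
  CSV/data.frame exports. No cell-cycle deconvolution or compensation.
- The variance model is strictly nested; crossed designs are not supported,
  and no confidence intervals on components are provided.
- PIC assumes Brownian motion; no Pagel's λ or other signal corrections are
  offered beyond the exclude-and-rerun workflow.
- p-values are reported unadjusted (matching standard practice for these
  small families of tests); apply `p.adjust` downstream if required.
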