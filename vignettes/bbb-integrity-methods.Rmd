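---
title: "Methods: quantifying in vitro blood-brain barrier integrity with ibbb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying in vitro blood-brain barrier integrity with ibbb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ibbb` quantifies whether an induced in vitro blood-brain barrier (iBBB) —
a brain microvascular endothelial monolayer grown on a Transwell insert —
is compromised in patient-derived lines relative to matched controls. This
vignette documents the models behind each stage, the parameters that
matter, the synthetic-data generators used for verification, and the
numerical and design choices a maintainer should know about.

## 1. Barrier function: permeability and TEER

### Model

In a Transwell assay a tracer (sodium fluorescein for small solutes,
70 kDa FITC-dextran for large ones) is loaded in the upper (donor) chamber
at concentration $C_U$ and accumulates in the lower (receiver) chamber.
Under sink conditions the apparent permeability of monolayer plus insert
is

$$P_t = \frac{\Delta C_L}{\Delta t}\,\frac{V_L}{C_U\,S},$$

with $V_L$ the receiver volume (mL $=$ cm$^3$), $S$ the membrane area
(cm$^2$), and $\Delta C_L/\Delta t$ the accumulation slope (`permeabilityTotal()`,
least-squares over all timepoints with time in seconds, giving $P$ in
cm/s). The monolayer and the bare insert are barriers in series, so
reciprocal permeabilities add; `permeabilityBarrier()` inverts

$$\frac{1}{P_t} = \frac{1}{P_{iBBB}} + \frac{1}{P_i}$$

to isolate the monolayer value $P_{iBBB}$ from a blank-insert measurement
$P_i$. TEER is reported area-normalized after blank subtraction,
$(R_{total}-R_{blank})\times S$ in $\Omega\,$cm$^2$ (`teerArea()`).

### Draw-and-replace dilution correction

Sampling the receiver (50 µL drawn every 10 min and replaced with fresh
medium, against $V_L = 1.5$ mL) removes $\approx 3.3\%$ of the accumulated
tracer at every draw, which would bias a naive slope downward.
`correctedCumulative()` restores the withdrawn tracer:

$$C_{corr}(t_k) = C_L(t_k) + \frac{V_s}{V_L}\sum_{j<k} C_L(t_j),$$

which is exactly linear in $t$ under constant flux (the test suite checks
the closed form of this recurrence). An uncorrected mode is kept for
sensitivity checks.

### Validity envelope of the single-slope estimator

The synthetic generator (`simulateTranswell()`) deliberately does **not**
assume sink conditions: it integrates the full two-compartment mass
balance $J = P\,S\,(C_U - C_L)$ with explicit sub-stepping ($\le 1$ s),
finite donor volume and instantaneous, perfectly mixed draw events, and it
conserves tracer mass to $10^{-10}$ relative. As a consequence the linear
estimator is *expected* to degrade as $P$ grows: with the default geometry
(0.9 cm$^2$, 1.5/0.5 mL, 90 min) donor depletion plus receiver
back-gradient make the recovered $P$ under-read truth by $<2\%$ only up to
roughly $3\times10^{-6}$ cm/s; at $2\times10^{-5}$ cm/s the bias reaches
about $-12\%$. This is a property of the assay design, not of the code,
and it is precisely what the mass-balance generator lets the tests probe.
The suite therefore checks (a) absolute recovery to 2% in the
sink-condition regime, (b) agreement to 2% between the pipeline estimate
on generated series and on series produced by an independent
`deSolve::ode()` integration across the whole
$[10^{-6}, 2\times10^{-5}]$ cm/s range, and (c) monotonicity of the
recovered value in the true one. `permeabilityTotal()` warns whenever the
corrected receiver concentration exceeds 10% of $C_U$.

### Group statistics

Patient/control comparisons on paired samples use an exact Wilcoxon
matched-pairs signed-rank test (`wilcoxonExactSignedRank()`): zeros are
dropped, tied absolute differences get mid-ranks, the null distribution of
$W$ is built by convolution over all $2^n$ sign assignments (exact for
arbitrary mid-ranks, $n \le 20$), and the two-sided p is
$\min(1, 2\min(P(W\le w), P(W\ge w)))$. Six concordant pairs give
$p = 2/64 = 0.03125$. Group ratios are reported both ways a study might
reduce them — ratio of group means and mean of per-pair ratios
(`compareGroups()`) — because the two differ for noisy data and published
fold values do not always state which was used.

## 2. Barrier structure: junction and glycocalyx imaging

Tight-junction protein staining (ZO-1, occludin) concentrates along
cell-cell borders. Quantification follows the line-profile protocol:
maximum-intensity z-projection (`projectStack()`; junction signal is
sparse and bright, which favours max over sum — sum remains available),
then for each border segment 3–5 perpendicular lines of ~3 µm, equally
spaced along the segment, sampled by bilinear interpolation and averaged
into one profile per junction (`sampleJunctionProfiles()`); the junction's
intensity is the maximum of the averaged profile. Background is the median
intensity of pixels farther than 2 µm from every segment
(`subtractBackground()`; median for robustness, the margin configurable),
and peaks are clamped at zero after subtraction. Patient values are
normalized to the mean of the control samples (`normalizeToControl()`), so
the control group has mean 1 by construction; per-group excess kurtosis
($g_2 = m_4/m_2^2 - 3$, population moments; `kurtosisExcess()`) compares
distribution shapes. Glycocalyx (heparan sulfate) staining is diffuse, so
it is quantified as per-field projected means, averaged per sample and
normalized to the control mean (`esgFieldIntensity()`).

Numerical choices: profile sampling steps at a quarter pixel so the
profile maximum is not undersampled (checked against a dense 0.1-px
resampling oracle to 1%); lines leaving the image are clipped and flagged;
segments shorter than 2 px are excluded. Bilinear interpolation attenuates
a ~1 µm-wide ridge peak by a few percent at 0.5 µm/px; this attenuation is
multiplicative and identical for both groups, so it cancels in all
control-normalized outputs (the suite asserts scale equivariance and
end-to-end deficit recovery to ±0.05 across deficits 0.3–1.0 at 5% noise).

### What the image generators emulate, and what they do not

`simulateJunctionField()` builds a Voronoi mosaic from random sites with a
minimum-separation rule (each cell one endothelial cell; borders computed
by half-plane clipping, so ground-truth segments are exact), renders
borders as ridges with a Gaussian cross-section of 1.0 µm FWHM
(sub-resolution junctions appear PSF-widened; the width is configurable)
at peak `amplitude * deficit` above background, and stacks z-slices under
an intensity envelope in which out-of-focus slices are dimmer
*everywhere*. That last point matters: if only the ridge were enveloped,
a max projection would inflate the background by the expected maximum of
the per-slice noise and bias background subtraction. With the whole-plane
envelope the projection recovers the focal plane essentially
noise-bias-free. `simulateEsgField()` produces a smooth zero-mean texture
around the ground-truth mean, so the field mean above background is exact
at zero noise. Noise is additive Gaussian in both generators (the
simplest defensible choice; the assay literature rarely states a noise
model), negative-binomial for counts.

Not emulated: optical PSF physics, photobleaching, uneven illumination,
cell-shape dynamics, and automatic junction segmentation (segments are
ground truth for synthetic data and user-supplied annotations for real
images). Passing tests therefore demonstrate correctness of the
quantification chain, not robustness to every imaging artifact of real
confocal data.

## 3. Expression stage

`nbDeTest()` is a deliberately minimal two-group negative-binomial Wald
test so synthetic counts can flow end to end: median-of-ratios size
factors, per-gene moment dispersion
$\hat\alpha = (s^2 - \mu)/\mu^2$ moderated toward a common clipped-mean
value, delta-method variance
$\mathrm{Var}(\log\hat\mu) = 1/(n\mu) + \alpha/n$ per group, normal
reference, Benjamini–Hochberg adjustment. With three samples per group a
raw per-gene moment dispersion is far too noisy to calibrate a Wald test
(it floors at zero often enough to inflate type-I error several-fold), so
the default is full moderation (`moderation = 1`); the suite pins the null
type-I error at $0.05 \pm 0.01$ over 50 simulations. The flip side is
power: at dispersion 0.05 and $n=3$/group the standard error of a log2
fold change is floored at $\sqrt{2\alpha/n}/\ln 2 \approx 0.26$, so a
half-dosage block ($|\log_2 FC| = 1$, $|z| \approx 3.8$) sits near the
BH-at-0.01 detection threshold and only a majority — not all — of
deletion genes is detected per run; the suite asserts the majority, and
that every detected deletion gene is down-regulated
(`deletionRegionCheck()`, the stage's positive control). For real data the
intended path is an externally produced DEG table (e.g. from a
shrinkage-based NB fit), which `filterDegs()`/`splitByFold()` accept
unchanged; the printed thresholds (FDR $<$ 0.01, baseMean $>$ 100, folds
$>2$ / $<0.5$) are applied as strict inequalities exactly as written, and
are configuration, not constants.

Enrichment (`enrichHyper()`) is a one-sided hypergeometric upper tail per
term with BH across terms; the universe defaults to the annotation's gene
union intersected with the tested genes, since web-service defaults are
not reproducible offline. Sample PCA (`pcaSamples()`) operates on
$\log_2(\text{normalized count}+1)$ with genes centered; variance
fractions sum to 1.

## 4. Network influence stage

The deletion-region gene most responsible for a disturbed junction/adhesion
network is nominated by topology. `computeCentralities()` evaluates a
documented catalog of 13 measures (degree, closeness, harmonic,
betweenness, eigenvector, Katz, PageRank, subgraph, semi-local, leverage,
lobby, Laplacian, diffusion degree) on the largest connected component
(disconnected input triggers a warning, since shortest-path measures are
undefined across components; edge weights are ignored — confidence
filtering is an upstream choice). Standard measures delegate to igraph;
the rest are implemented from their definitions and validated against
brute-force oracles on exhaustively enumerated small graphs. Columns are
z-scored by default (min-max optional) before
`selectInformativeMeasure()` runs a PCA and picks the measure with the
largest absolute PC1 loading, sign-aligned so PC1 correlates positively
with degree; ties are broken by catalog order and reported. Diffusion
degree,

$$DD(v) = \lambda\,d(v) + \sum_{u\in N(v)} \lambda\,d(u), \qquad \lambda > 0,$$

is the ranking measure of interest; $\lambda$ defaults to 1 and is
constant across nodes (no principled per-node value exists without kinetic
data), and since $\lambda$ scales all scores linearly the ranking is
$\lambda$-invariant. `rankNodes()` sorts by the selected measure's raw
score, breaks ties lexicographically by node id (making rankings invariant
under relabeling), and highlights the top deletion-flagged node.
`clusterNodes()` uses Ward linkage (`ward.D2` on Euclidean distances) with
$k$ chosen by maximum mean silhouette over $k \in 2..n-1$ (degenerate
$k = 1$ and $k = n$ are excluded by the definition of the silhouette);
`jaccardClusterSimilarity()` compares partitions by co-clustered pairs,
$|$together in both$|/|$together in at least one$|$, with two all-singleton
partitions defined as identical (similarity 1).

## 5. Pipeline, seeds and reproducibility

`runPipeline()` executes the stages in dependency order from a single
configuration (`pipelineConfig()`, storable as YAML) whose defaults are
the characteristic compromised-barrier setpoints: TEER at 62% of control,
permeability 1.3-fold, junction deficit 0.6, glycocalyx deficit 0.42,
half-dosage deletion expression, planted CRKL hub. One global seed fans
out to per-stage seeds via a fixed affine rule
(`seed * 1009 + stage * 9973 mod 2^31-1`), so stages are individually
reproducible and mutually decoupled; the whole report is byte-identical
given config + seed and carries an FNV-1a fingerprint of the
configuration. A failed stage aborts with a stage-tagged error after
writing the partial report.

## 6. Problem sizes and test design

The verification suite favours many small, fully checked cases: simulated
counts use 400–1000 genes at 3 samples/group (type-I calibration pools
50 simulations); image recovery uses 64–96 px fields over 20 seeds;
permeability recovery spans $10^{-6}$–$2\times10^{-5}$ cm/s against the
independent ODE oracle; diffusion degree is checked exhaustively on all
connected 4- and 5-node graphs and on large samples of 6-node graphs;
planted-hub recovery uses 100 seeded 50-node networks. These sizes were
chosen so each property is established with comfortable statistical margin
while the whole suite stays quick enough to run on every change.

## 7. Known limitations

* The permeability estimator is the standard single-slope formula; it does
  not fit the two-compartment ODE to data, so its accuracy is bounded by
  the sink-condition envelope quantified above.
* The NB test is intentionally minimal (no trended dispersion, no LFC
  shrinkage, no outlier handling); it exists for synthetic end-to-end
  verification and small pilot analyses, not as a replacement for a full
  DE framework on real data.
* Junction quantification requires border segments; automatic junction
  tracing is out of scope.
* The centrality catalog is a documented selection, extensible but not
  exhaustive; which measures a given external tool would have used is not
  recoverable, so cross-study score comparisons should be made at the
  ranking level, not the score level.
* The synthetic networks plant an unambiguous hub; real PPI networks have
  more graded influence structure, so hub-recovery rates on synthetic data
  overstate certainty on real networks.
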