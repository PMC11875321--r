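---
title: "Models and methods behind myoCytokines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind myoCytokines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

myoCytokines analyzes the expression of a curated panel of cytokine,
cytokine-receptor and immune-checkpoint genes in bulk RNA-seq of muscle
biopsies from myositis patients, stratified into clinical groups (DM, IMNM,
ASyS, IBM, PM/Scl) and autoantibody subgroups (Mi2, MDA5, NXP2, TIF1 under
DM; HMGCR, SRP under IMNM; Jo1 under ASyS; PM/Scl doubling as its own
subgroup). The pipeline starts from a genes × samples count matrix;
read-level processing, panel curation and clinical classification are out
of scope. Two further cohorts participate without being analyzed: background
myopathies ("other inflammatory", "genetic") that only widen the reference
pool, and normal-tissue controls (NT).

# Normalization

Between-sample normalization uses the trimmed mean of M-values (TMM). The
reference sample is the one whose upper-quartile count-per-million is
closest to the cohort mean (genes unobserved everywhere are dropped first,
as the canonical implementation does). For sample $j$ against reference
$r$, over genes positive in both,

$$M_g = \log_2\frac{y_{gj}/N_j}{y_{gr}/N_r},\qquad
  A_g = \tfrac12\log_2\!\Big(\frac{y_{gj}}{N_j}\frac{y_{gr}}{N_r}\Big),$$

the genes are doubly trimmed — 30% from each tail of $M$, 5% from each
tail of $A$, by midrank so ties are kept or cut together — and the factor
is $2^{\bar M}$ with $\bar M$ the mean of the retained $M_g$ weighted by
the inverse of the delta-method variance
$v_g = \frac{N_j-y_{gj}}{N_j y_{gj}} + \frac{N_r-y_{gr}}{N_r y_{gr}}$.
Factors are rescaled to geometric mean one. The test suite checks this
implementation against both a hand-coded brute-force oracle (1e-10) and
edgeR's `calcNormFactors` (bit-level on simulated matrices).

Log-expression is $\log_2$ CPM on TMM-effective libraries with a
library-scaled prior count (default 0.5) so zero counts stay finite. One
subtlety worth stating: with inverse-variance weights, TMM factors are only
*approximately* invariant to rescaling a single sample's counts (the
weights depend on absolute counts); the unweighted variant is exactly
invariant, and both behaviours are asserted in the tests at their own
tolerances.

Design note: the source analysis names TMM "for graphical analysis" and is
silent on what normalization the DE model saw. This package uses TMM
log-CPM for *both* visualization and DE — the simplest self-consistent
reading, recorded here as a deliberate choice.

# Differential expression

Every analyzed group is tested twice: **one-vs-rest** (group vs all other
samples, including background groups and NT) and **vs-NT** (group vs
controls). Clinical-group membership includes the group's subgroups'
samples, and a subgroup's reference side keeps the remainder of its own
clinical group — "all samples" admits no exclusion. The alternative reading
of "versus all samples" (reference including the group itself) does not
yield a well-defined two-group model and is not implemented.

Per gene, an ordinary equal-variance two-group linear model on log-CPM
gives $\beta_g$ (group minus reference mean), $s^2_g$ on $d = n-2$ df.
Variances are shrunk toward a prior $(d_0, s_0^2)$ estimated by
moment-matching the distribution of $\log s^2_g$ (digamma/trigamma
identities, with Newton inversion of the trigamma function):

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},\qquad
  \tilde t_g = \frac{\beta_g}{\tilde s_g\sqrt{1/n_1 + 1/n_2}},$$

two-sided p-values on $d_0 + d$ df, Benjamini–Hochberg q-values (step-up,
implemented in-package and checked against an $O(m^2)$ brute force). This
is the trend-free ("limma-trend"-style) model on normalized log-counts; no
precision weights, covariates or batch terms — none are part of the modeled
design. Numerical corner cases: if the spread of $\log s^2$ does not exceed
its sampling noise, $d_0 = \infty$ (full pooling); if prior estimation
fails, the engine falls back to $d_0 = 0$ (ordinary t) with a warning;
all-zero residual variance is rejected as degenerate input. Both limits are
directly reachable via `prior_df` for testing, where the engine provably
reduces to the ordinary t statistic ($d_0=0$) and to the fully pooled
statistic ($d_0=\infty$).

# Group sets, families and specificity

The calling rule (α = 0.001 on q-values, configurable) requires
significance in *both* contrasts with sign-concordant fold changes; genes
significant with discordant signs are excluded and reported. The stated
direction rule for underexpression contains an obvious sign typo in the
source ("log-fold change > 0" for both directions); underexpression here
means negative in both. Output sets are ordered by ascending q versus all
samples. NT's pan-myositis surrogate sets come from its single one-vs-rest
contrast.

Specificity is evaluated at the **family** level (a clinical group together
with its subgroups): a clinical group's specific genes are called by no
group outside its family; a subgroup's specific genes by no group other
than itself and its parent — sibling subgroups *do* disqualify. NT's sets
never disqualify (configurable), and directions are handled independently.
Exclusive Venn regions over the five family-collapsed sets follow plain set
algebra: region($S$) = $\bigcap_{f\in S}\mathrm{set}_f \setminus
\bigcup_{f\notin S}\mathrm{set}_f$. Family collapse is the only reading
under which the packaged reference lists reproduce every published overlap
count; raw clinical-group Venn does not, so the family reading is the
package default and no alternative is offered.

Two verbatim fixtures ship with the package: the per-group called lists and
the per-group specific lists of the source study. Running the classifier on
the former reproduces the latter cell for cell, with one documented
exception: the printed IBM-specific cell shows the ligand TNFSF13B — which
the reference lists themselves also call in DM, so the stated rule excludes
it — in place of its receptor TNFRSF13B, which IBM alone calls. The printed
cell sits exactly at TNFSF13B's q-rank, so this is a one-symbol
ligand/receptor swap somewhere in the source tables. The fixtures stay
verbatim, the classifier follows the stated rule, and the regression test
asserts the discrepancy explicitly rather than patching either side. No
published *count* is affected.

# The synthetic cohort

Because the study's counts are not public, a generative stand-in makes the
pipeline testable. Counts are negative binomial,
$\mu_{gj} = L_j\,2^{\,b_g + \Delta_{gj} + \lambda_g u_j + \rho_g v_j}$,
variance $\mu + \phi_g\mu^2$, with:

* baselines $b_g \sim N(5, 2^2)$ log2-CPM and dispersions
  $\phi_g \sim \mathrm{logNormal}(\log 0.1,\, 0.5^2)$ — typical bulk
  RNA-seq magnitudes;
* library sizes log-normal around $10^6$ (sd 0.35 on the log scale), so
  TMM is exercised nontrivially;
* planted group effects $\Delta$ (log2 fold changes applied to a group's
  samples, family-wide for clinical groups);
* two latent per-sample factors: immune infiltration $u_j$ (loading 0.8 on
  leukocyte markers and planted cytokines, group mean highest in IBM,
  negative in NT) and muscle regeneration $v_j$ (positive on regeneration
  markers, negative on mature-muscle and mitochondrial markers), inducing
  the marker-correlation structure the real biopsies show.

`make_table1_scenario(scale)` reproduces the study's group sizes times
`scale` (quarter scale by default, keeping tests fast), with planted
modules mirroring the qualitative published structure: a type-1 module in
IBM (CCL5, CCR5, CXCR3, IFNG, CD27, IL2RG, shared CXCL9), a distinct
type-1 + IFNB1 module in DM, small Jo1 and PM/Scl modules, and a
near-empty IMNM module (SPP1), all at log2FC 3 by default.

What a green test on this cohort does **not** establish: the simulator has
no batch effects, no varying gene length or GC structure, no
zero-inflation beyond NB, independent genes given the two latent factors,
and no attempt to match the real study's unpublished expression values.
Dispersions and library sizes are stand-ins, not estimates. Green means
the *machinery* (normalization → moderated t → dual-contrast calling →
specificity) behaves as specified under a realistic noise model, not that
the biological findings are re-derived.

One measured property of this world is worth recording: with one third of
all genes planted in one direction (200 of 600), TMM's trimmed correction
is overwhelmed by construction and fold-change estimates are biased low.
The parameter-recovery test therefore plants 200 genes in a
2000-gene background (10% DE, a realistic fraction), where the mean
estimated log2FC falls within ±0.15 of truth.

# Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| M-trim / A-trim | 0.30 / 0.05 | canonical TMM trim fractions |
| prior count | 0.5 | finite log-CPM at zero, standard practice |
| α (q threshold) | 0.001 | the study-wide calling threshold |
| `prior_df` | estimated | 0 / Inf reachable for the no- and full-shrinkage limits |
| correlation method | Pearson | source does not name one; Spearman by flag, method recorded in output metadata |
| correlation samples | group's own | the figures are per-group; all-samples by flag |
| simulation scale | 0.25 | desk-scale runtime with every subgroup ≥ 2 samples |

Correlations are reported NA (never 0) for constant expression vectors.
Median-expression heatmaps carry both raw medians and a per-gene z-score
across group columns (constant rows flagged degenerate, z set to 0) — the
display convention of the source figure is unstated, so raw values are
always preserved for audit.

# Known limitations

* The packaged default gene panel is a stand-in (union of the reference
  lists plus markers, heuristic category labels); the full curated
  338-gene panel lives in an unavailable supplement and must be supplied
  by the user for a faithful reanalysis.
* The one-vs-rest reference mixes background myopathies and controls, so
  "rest" is not a homogeneous comparator — inherited from the modeled
  design, not a choice this package can undo.
* Group sizes differ widely; q-values are not comparable across groups of
  different size.
* The versioned Ensembl identifier in the reference lists is treated as an
  opaque symbol; no identifier mapping is attempted.
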