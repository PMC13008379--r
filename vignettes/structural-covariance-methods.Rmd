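---
title: "Structural covariance networks and individual differential networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural covariance networks and individual differential networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scovnet)
```

## The model

Structural covariance (SC) treats the correlation of regional brain
volumes across subjects as a network: nodes are regions, and the edge
between regions $i$ and $j$ is the Pearson correlation $r_{ij}$ of
their residualized volumes over the subjects of one group. `scovnet`
analyses three such networks built around the 50 thalamic nuclei
(25 per hemisphere): the intrathalamic network (all
$\binom{50}{2} = 1{,}225$ nucleus pairs), and two bipartite networks in
which only thalamo-cortical ($50 \times 68 = 3{,}400$ edges, with the
68 Desikan–Killiany cortical regions) or thalamo-subcortical
($50 \times 12 = 600$ edges) connections are retained; within-set edges
are removed so the networks isolate the connection class of interest.

Three inferential layers sit on top of these matrices:

1. **Group comparison.** Strength-type measures — graph strength (sum
   of unique edge weights), node strength (weighted degree), and
   per-edge differences $\mathrm{SC}_{\mathrm{diff}} =
   r^{\mathrm{case}}_{ij} - r^{\mathrm{ctrl}}_{ij}$ — are compared
   between diagnostic groups by subject-relabeling permutation tests.
2. **Individual differential SCNs (IDSCN).** Template network
   perturbation: adding one case subject $k$ to the $n$ controls gives
   a perturbed network $\mathrm{SCN}_{n+1}$, and
   $\mathrm{IDSCN}_k = \mathrm{SCN}_{n+1} - \mathrm{SCN}_n$
   quantifies how that single subject shifts each control edge. The
   per-edge perturbation is standardized to a $Z$ score, converted to
   two-sided normal $p$-values, and FDR-called within the network's
   edge family. Altered-edge counts and edge $Z$ values are then
   correlated with symptom severity.
3. **Clustering.** Thalamic nuclei are hierarchically clustered by the
   similarity of their $\mathrm{SC}_{\mathrm{diff}}$ profiles, with the
   cluster count selected by the Kelley–Gardner–Sutcliffe (KGS)
   penalty, and clusterings over different networks compared by
   cophenetic correlation.

## Data preparation

Volumes arrive as a tabular `FeatureTable` (subject id, site, group,
age, sex, intracranial volume, severity, one column per region).
Preparation follows four steps, each an exported function:

* **Outlier screening** (`remove_outliers`): a subject is removed iff
  any region deviates more than 2.698 sample SDs from that region's
  full-sample mean (the normal-theory equivalent of the 3×IQR rule).
  Statistics are computed once on the pooled sample — a single pass,
  not an iterative trim — and screening is applied per network
  analysis, so a subject may be excluded from one network and retained
  in another. Pooled rather than per-group reference statistics are
  used; with balanced groups and modest effect sizes the two choices
  remove nearly identical sets, and pooling avoids moving the goalposts
  per diagnosis.
* **Site harmonization** (`harmonize_sites`): empirical-Bayes
  location/scale batch adjustment (ComBat, via the `sva` package)
  removing site and scanner effects while preserving covariate-explained
  variation. The covariate basis is linear in sex, ICV and group with a
  polynomial age basis (degree 2 by default, configurable via
  `age_basis_degree`). A polynomial basis stands in for spline bases:
  the pipeline contract tested downstream — site mean differences
  removed, covariate slopes preserved — is basis-agnostic, and degree 2
  matches the age + age² covariate model used at the residualization
  step.
* **Residualization** (`residualize`): per region, OLS of volume on
  `[1, age, age², sex, ICV]` over all subjects pooled; the residuals
  are the SC inputs. A `per_group` mode refits within each diagnostic
  group for sensitivity analyses. Sex is coded 0/1 and ICV enters
  untransformed. The design matrix is rejected if its (column-scaled)
  condition number exceeds `max_condition` (default 1e10).
* **Severity normalization** (`normalize_severity`): raw instrument
  scores map linearly onto [0, 1] using the instrument's min/max, so
  severities from different assessments can be pooled.

## Networks, thresholds, wiring cost

`build_scn` computes the group correlation matrix;
`extract_bipartite` masks within-set edges. `threshold_graph` retains
edges with weight **strictly** above `t` (the tie rule is a
convention; strictness makes `t = 0` behave sensibly for negative
weights), and `t = NULL` is the *unthresholded* sentinel: the network
is analysed as-is, negative correlations contributing their sign to
strength sums. Dropping negatives would silently threshold at zero,
so the unthresholded graph keeps them; this is an interpretation the
user can avoid by starting the sweep at `t = 0`.

The threshold sweep starts at 0 and rises in steps of 0.025 until the
**minimum wiring cost** is reached: the largest grid threshold at
which the binarized graph still has no disconnected nodes (bipartite
graphs are assessed over both node sets jointly, so an isolated
cortical node also stops the sweep). For group comparison the same
grid is applied to both groups and capped at the smaller of the two
groups' wiring-cost thresholds (`threshold_sweep`).

## Permutation inference

The exchangeable unit is the subject: permutation tests shuffle
diagnostic labels (group sizes fixed) and rebuild both group networks
from the residuals at every shuffle — edge weights are never permuted
directly, because the statistic is a between-group difference of
subject-level correlation estimates. The two-sided $p$-value uses the
add-one estimator $p = (b + 1)/(m + 1)$, where $b$ counts null
differences whose magnitude equals or exceeds the observed one;
"equals or exceeds" is read on absolute values since effects in both
directions are of interest. When a statistic is a family (thresholds,
50 nodes, or an edge set), the same labelings are reused across all
components and the family is Benjamini–Hochberg corrected jointly at
$q = 0.05$. Reference permutation counts are 5,000 (graph/node) and
100,000 (edge level); both are configuration keys, and the package's
own validation experiments use smaller counts suited to their
effect sizes (Section *Validation harness*).

## IDSCN standardization: the two Z variants

The printed form of the perturbation Z is

$$Z = \frac{\mathrm{IDSCN}_k}{(1 - \mathrm{SCN}_{n+1}^2)/(n-1)},$$

which `idscn_z(variant = "printed")` implements verbatim and the
pipeline uses by default. The method literature from which template
network perturbation originates also contains a
$(1-r^2)/\sqrt{n-1}$ scaling, available as `variant = "sqrt"`; the
two differ by the factor $\sqrt{n-1}$, and the typography of the
source formula does not settle which was intended. Rather than assert
one as correct, `idscn_null_calibration` reports the empirical null SD
of both: for subjects drawn from the control distribution the printed
variant has null SD near 1 (e.g. ≈ 1.02 at $n = 800$, 50 nuclei,
compound-symmetric $r = 0.6$), i.e. it behaves like an approximate
z-statistic, while the sqrt variant is strongly conservative
(null SD ≈ 0.036 at the same size). Altered edges are called from
two-sided standard-normal $p$-values, BH-corrected across the
network's edges; with the printed variant this calling is
approximately calibrated, with the sqrt variant it is essentially
silent — a config switch (`idscn.z_variant`) exposes both. Severity
associations use the $Z$ matrix (standardized perturbation) as "edge
strength"; raw deltas are available via
`idscn_edge_matrix(what = "delta")`.

## Clustering choices

Profiles are rows of the $\mathrm{SC}_{\mathrm{diff}}$ matrix: for
intrathalamic clustering a nucleus's profile spans all other nuclei
(self-entries are excluded through the NA mask and pairwise-complete
correlation); for thalamocortical clustering it spans the 68 cortical
columns. Left- and right-hemisphere nuclei are clustered separately.
The default distance is correlation distance $1 - r$ — the *pattern*
of SC change, not its magnitude — with Euclidean distance available by
option. Trees are unweighted average linkage (UPGMA). The KGS penalty
evaluates every cut $k \in [2, L-1]$: the spread at $k$ is the mean
(over clusters with ≥ 2 members) of mean within-cluster pairwise
distance, spreads are rescaled linearly onto $[1, L-1]$, and the
penalty $\alpha \cdot \mathrm{spread}^\ast(k) + k$ is minimized with
$\alpha = 1$; ties take the smallest $k$ (parsimony), and a degenerate
rescaling (all spreads equal) falls back to $k = 2$ with a warning.
Tree pairs are compared by the correlation of their cophenetic
distance matrices, and `cluster_pairing_export` provides a
machine-readable account of which leaves keep the same lowest-level
partners across two trees — the information a tanglegram renders
graphically.

## The synthetic cohort generator

Real consortium volumetrics are not redistributable, so validation
rests on `cohort_spec`/`generate_cohort`, which emulate the
data-generating situation: group-specific multivariate-normal volumes
(control correlation structure built by `build_base_covariance`, case
structure derived from it by `implant_edge_effects`), region-wise
affine site effects (the additive/multiplicative batch model ComBat
assumes), additive covariate effects in age, age², sex and ICV, and
severity scores in [0, 1]. Everything derives from one spec-level seed
through `derive_seed`, so every stage is individually reproducible.

Numerical choices worth stating:

* **PSD repair** is eigenvalue clipping at zero followed by
  re-normalization to unit diagonal; the maximum entry displacement is
  reported (`repair_drift`) so implanted ground truth stays auditable.
* **Severity link.** A subject's latent perturbation score at the
  linked edge $(i, j)$ is its *realized* standardized cross-deviation
  $z_i z_j - \rho_{ij}$ — exactly the quantity an IDSCN delta at that
  edge measures. Severity is a clamped linear map of
  `link · latent + noise`, with noise chosen as $\sqrt{1 - r^2}$ so the
  implanted latent–severity correlation equals the requested link
  $r$; this makes the implanted correlation the direct recovery
  target. A logistic map is available by option.
* **Graded perturbations.** In `perturb_grades` mode each case
  subject receives a grade $m_k \sim U(0,1)$; its covariance is the
  convex combination control $+\,m_k\,($case $-$ control$)$ *and* its
  deviation amplitude is scaled by $1 + m_k$. The amplitude term is
  essential: a single subject's influence on a correlation estimate is
  a leverage effect, so a subject near the control centroid barely
  perturbs any edge no matter how case-like its correlation pattern
  is. With amplitude grading, total altered-edge counts track the
  implanted grades (rank correlation ≈ 0.8 at 200 controls).
* **Effect-size scale.** No published effect sizes exist for
  $\mathrm{SC}_{\mathrm{diff}}$ in correlation units; implanted deltas
  in the 0.05–0.3 range are chosen for testability, not realism.

What the generator does **not** emulate: non-Gaussian volume
distributions, segmentation failure modes (beyond what outlier
screening models), site-by-covariate interactions, spatially
structured scanner effects, and missing-data mechanisms. Passing
validation therefore shows the pipeline recovers what it is supposed
to recover under a faithful, well-specified generative model — not
that any particular clinical result would replicate.

## Validation harness and problem sizes

The `validation_*`/`recover_*`/`calibrate_*` functions run the
package's standard simulation experiments end to end. The base
condition is a compound-symmetric correlation of 0.6 across the 50
nuclei — chosen because observed intrathalamic networks remain fully
connected at thresholds above $r = 0.40$, implying typical edge
weights well above that — and the experiments are:

* `calibrate_null_rejection`: 200 null cohorts of 2 × 50 subjects,
  500 permutations each; the graph-strength test's rejection rate at
  $\alpha = 0.05$ should sit near 0.05.
* `power_strength_elevation`: 100 cohorts of 2 × 500 with a +0.1
  elevation on every intrathalamic edge; detection rate of the
  graph-strength test (199 permutations suffice at this effect size).
* `recover_top_edge`: 100 cohorts of 2 × 500 with one edge elevated
  by +0.2; how often that edge ranks first by
  $|\mathrm{SC}_{\mathrm{diff}}|$ among all 1,225.
* `recover_severity_link`: one cohort of 2 × 400 with a
  severity-linked edge (link $r = 0.3$); the linked dyad sits in its
  own low-correlation block ($r = 0.3$) because under strong global
  covariance the products $z_i z_j$ of edges sharing a node are
  correlated, which would smear an edge-specific severity association
  across neighbors.
* `idscn_null_calibration`: control-group sizes 50/200/800, 100 probe
  subjects each; perturbation magnitudes must shrink with $n$ and both
  Z variants' null SDs are reported.
* `recover_profile_groups`: 50 replicates of 60 leaves in 6 implanted
  profile groups (centers SD 5, noise SD 0.05); KGS must select
  $k = 6$ and reproduce the groups exactly (adjusted Rand index 1).

These sizes keep the full validation suite at a few minutes on one
CPU while leaving each experiment's Monte-Carlo error well inside its
decision margin. `scripts/acceptance.R` reruns all of them from
scratch and writes the resulting rates as JSON.

## Known limitations

* The printed IDSCN Z is used as published; users wanting strictly
  conservative calling should inspect the calibration report and
  consider the `sqrt` variant with an empirical (simulation-based)
  threshold.
* ComBat here is the classic location/scale model with a polynomial
  covariate basis, not the spline-based GAM variant; strongly
  non-polynomial age trends may leak into harmonized volumes.
* Whether "edge strength" in severity associations means $Z$ or raw
  delta is a modelling choice; $Z$ is the default, both are exposed.
* Correlation-based profile distance is undefined for constant
  profiles; such leaves raise an error rather than being silently
  dropped.
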