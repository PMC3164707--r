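---
title: "Methods: hub-anchored mutual-information networks for multi-modal muscle cohorts"
author: "muscleNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hub-anchored mutual-information networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muscleNet)
```

## The scientific problem

Skeletal-muscle dysfunction is a common systemic consequence of chronic
obstructive pulmonary disease (COPD).  A useful way to study it is to profile
the same subjects on several levels at once — whole-body physiology (peak
oxygen uptake, arterial oxygen tension, fat-free-mass index), circulating
inflammatory mediators in serum, and muscle gene expression — before and
after an endurance-training programme, in healthy controls and in COPD
patients with preserved (`COPD_N`) or wasted (`COPD_L`) muscle mass.

`muscleNet` implements the statistical machinery for this design:

1. put all measurements on a common scale,
2. infer a **hub-anchored interaction network** with a kernel
   mutual-information (MI) estimator and permutation-calibrated edge
   significance,
3. quantify the **coupling** between the tissue-remodelling sub-network
   (serum cytokines, muscle-expressed cytokine/growth-factor receptor genes)
   and the bioenergetics sub-network (physiology, glycolysis enzymes),
4. map differential-expression (DE) contrasts onto the network and score how
   consistently a hub's neighbourhood moves in the direction its edge signs
   predict,
5. classify samples from small gene panels with cross-validated k-nearest
   neighbours,

and it ships a **synthetic cohort generator** with planted ground truth so
that every one of these stages can be validated end to end.

## Data model and standardization

A `measurement_matrix` stores a variables-by-samples matrix with per-variable
modality (`physiology`, `serum_protein`, `gene_expression`) and per-sample
subject/group/timepoint annotation.  Because the three modalities live on
incommensurable scales, each variable is standardized across **all** samples
to mean 0 and standard deviation 1 (sample SD, `n - 1` denominator — the
conventional choice for cohort samples).  Group-wise standardization is
available behind a flag but off by default: network inference is meant to
exploit between-group variation, not remove it.  Constant variables and
variables with more than 20% missing entries cannot be standardized and are
dropped with a warning rather than silently zero-filled.  Standardization is
idempotent and commutes with sample reordering; both properties are tested.

## The mutual-information estimator

MI is the dependence measure behind every edge:
\[
I(X;Y) = \iint f_{XY}\,\log\frac{f_{XY}}{f_X f_Y}, \qquad
I \ge 0,\; I = 0 \iff X \perp Y,
\]
in nats throughout.  For bivariate Gaussians \(I = -\tfrac12\log(1-\rho^2)\),
which is the closed form the estimator is validated against.

The default estimator (`gaussian_kernel`):

* **Copula step.** Each variable is rank-transformed and mapped to normal
  scores \(z_i = \Phi^{-1}((r_i - 0.5)/n)\).  MI is invariant under monotone
  marginal transforms, so nothing is lost, and physiology, serum and
  expression variables become commensurable beyond what z-scoring achieves;
  the estimator also inherits robustness to monotone distortions and heavy
  tails.
* **Whitened joint KDE.** With \(r\) the Pearson correlation of the scores,
  the joint density is estimated on the whitened coordinates
  \(u = (z_x+z_y)/\sqrt{2(1+r)}\), \(v = (z_x-z_y)/\sqrt{2(1-r)}\) with a
  Gaussian product kernel and Silverman-type bandwidths
  \(h = \mathrm{sd}\cdot n^{-1/6}\).  The Jacobian of the whitening
  contributes the Gaussian-copula term \(-\tfrac12\log(1-r^2)\) exactly, and
  the KDE part measures residual, non-Gaussian dependence.  An axis-aligned
  kernel on the raw scores oversmooths the narrow ridge of a strongly
  correlated pair and underestimates its MI; whitening removes that bias
  while leaving the estimate exactly symmetric in its arguments (the
  transform only flips the sign of \(v\)).
* **Leave-one-out evaluation.** Densities are evaluated at the sample points
  with the self-contribution removed, which removes the upward bias of the
  naive plug-in; the average log density ratio, clamped at 0, is the
  estimate.

Two simpler estimators are provided: `rank_bins` (equal-frequency binning of
ranks, cube-root-of-n bins, then the discrete plug-in) and `discrete_plugin`
(exact plug-in MI of the contingency table, for categorical data).  The
plug-in is tested exhaustively against an independent entropy-identity
oracle on small tables; the kernel estimator is tested against the Gaussian
closed form at \(\rho \in \{0, 0.5, 0.9\}\), \(n = 10^4\), tolerance
\(\pm 0.05\).

## Permutation calibration and extreme thresholds

Edge significance is calibrated per matrix: random variable pairs are drawn,
one member is independently permuted, and the MI of the permuted pair is
recorded (default \(10^5\) draws).  Selecting edges above the \(1-p\)
quantile of this null keeps the pairwise false-positive rate below \(p\).

Genome-scale analyses of this design use edge thresholds around
\(p < 10^{-7}\) — far beyond any feasible permutation count.  The calibration
therefore fits an exponential tail to the top 5% of the null (maximum
likelihood on the excesses over the 95% quantile \(u\)) and extrapolates:
\[
t(p) = u + \frac{1}{\lambda}\,\log\frac{0.05}{p}, \qquad p < 0.05 .
\]
For \(p \ge 0.05\), the empirical quantile is used directly, so `mi_threshold_at`
is continuous at \(p = 0.05\) and monotone in \(p\); `mi_p_value` is its
inverse.  The exponential form is the standard peaks-over-threshold
approximation for light-tailed statistics; the anchor property (threshold at
\(p = 1/N\) close to the largest observed null MI) is tested, and the
false-positive guarantee is tested directly on an i.i.d. 100-variable matrix.

## Hub modules, merging and DPI

Inference is hub-anchored: MI is computed only between each pre-chosen hub
(physiology measure, serum cytokine, receptor gene, glycolysis gene) and
every other variable, keeping the cost linear in the number of hubs.  A
module is the set of targets above the calibrated threshold.  Each edge
carries a sign from the Pearson correlation of the pair; a pair with
significant MI but exactly zero Pearson correlation falls back to the
Spearman sign, then to +1 with a flag — the data that motivated this package
report signed hub relationships without defining a sign rule, so the package
fixes one deterministically.

`merge_modules` takes the union of the modules as an undirected signed
weighted graph: duplicate unordered pairs collapse to one edge keeping the
maximum-MI record, provenance lists every contributing hub, and hubs with no
significant edges remain as isolated nodes.  Exports are GraphML (all
attributes) and SIF for Cytoscape.

Data-processing-inequality pruning (`apply_dpi`) is implemented but **off by
default**: in every triangle the weakest edge is removed when its MI is below
\((1-\mathrm{tolerance})\) times the smaller of the other two, scanning all
triangles against the original weights before removing anything, with
deterministic lexicographic tie-breaking.  Hub-anchored modules are
star-shaped and form few triangles, so keeping every significant edge is
the natural default for this design.  Correctness is tested on exact binary
Markov chains whose pairwise MIs are enumerated by an oracle: DPI must
remove exactly the non-adjacent edges.

## Coupling between sub-networks

The package's coupling statistic formalizes what force-directed layouts show
qualitatively.  With \(T_A\) the union of targets of the remodelling hubs and
\(T_B\) that of the bioenergetics hubs,
\[
J = \frac{|T_A \cap T_B|}{|T_A \cup T_B|}
\]
is the primary statistic (the fraction of targets linked to both categories
among targets linked to either is reported alongside).  Healthy-muscle-like
networks share many targets across the two sides; the COPD-like signature is
\(J \approx 0\).  Significance comes from a degree-preserving permutation
null: every hub redraws its degree-many targets uniformly without
replacement from the candidate pool (all variables the modules scanned — not
merely the nodes that happened to gain an edge, which would bias the null
towards overlap), and the empirical p-value is
\((1 + \#\{J^{null} \ge J\})/(1 + n_{null})\).  Hub degrees are sorted before
the redraw so the report is invariant under relabelling hubs within a
category.

## Differential expression, enrichment, and mapping

* `train_response` tests each gene for a pre/post change within one group.
  The default is a **paired t-test by subject** — the design samples the same
  subjects at both timepoints — with an unpaired Welch variant behind a flag.
  Zero-variance genes get \(p = 1\) and a flag rather than NaN.  Fold changes
  are linear-scale group-mean ratios (anti-logged when the matrix is flagged
  log2, the default for normalized arrays), and ratios below 1 are folded to
  negative reciprocals so a halving prints as \(-2\).
* `bh_fdr` exposes Benjamini-Hochberg step-up q-values (delegating to
  `stats::p.adjust`); the test suite checks it against an independent
  brute-force step-up oracle, and directions are only called below the FDR
  gate.
* `two_factor_anova` fits the additive fixed-effects model (disease +
  training, no interaction by default; type-II sums of squares) to every
  variable at once via QR projections of the shared design, with per-factor
  BH correction across variables.  It reduces exactly to the pooled t-test
  when one factor has a single level, and is cross-checked against
  `car::Anova`.
* `filter_targets` applies joint FDR and fold thresholds to a curated list
  (the pattern used for validated NF-kB target panels: q below 10% and fold
  above 1.5).
* `enrich` is the exact one-sided hypergeometric test per gene set
  (GMT input), BH-corrected across sets, against an **explicit** universe —
  web annotation tools hide their universe; this package refuses to.
* `map_ids` joins DE results through a user-supplied two-column identifier
  map (e.g. mouse-to-human homologues): one-to-many expands, many-to-one
  keeps the smallest p, and the mapped fraction is reported.

`map_de` paints DE calls onto network nodes and counts regulated neighbours
per hub; `direction_consistency` scores the distance-1 neighbourhood of one
hub against an external contrast — a regulated neighbour is concordant when
a positive edge meets an up call or a negative edge meets a down call.
"Neighbourhood" means direct neighbours only; the statistic answers the
question "of the genes the network ties to this hub, how many respond, and
how many respond the way the edge sign predicts?"

## KNN classification

`knn_cv` is a deliberately small, fully deterministic k-NN: Euclidean
distance on row-standardized panel values, odd \(k\) (default 3, so
two-class vote ties cannot occur), distance ties broken by smallest sample
index, leave-one-out CV by default (natural at cohort sizes of a few dozen)
with a seeded stratified k-fold alternative.  The published analyses this
mirrors state neither \(k\), metric nor CV scheme, so the package fixes
defensible defaults and documents them.  A brute-force neighbour-search
oracle checks exact agreement on small instances.

## The synthetic cohort generator

`generate_cohort` emulates the study design: three groups, a configurable
number of subjects per group, pre and post samples per subject, three
modalities, hubs of the four categories.

The generative model, in population terms:

* Every hub \(h\) owns a latent factor per sample.  Pre/post samples of a
  subject share a subject-level component with weight `subject_corr`
  (default 0.5): \(F_{h,s} = \sqrt{w}\,Z_{h,\mathrm{subj}(s)} +
  \sqrt{1-w}\,E_{h,s}\).  How correlated repeat biopsies of one subject are
  is not established, so it is an explicit parameter rather than a constant.
* **Coupling is pairwise.** Remodelling hub factors are matched round-robin
  with bioenergetics hub factors and each matched pair is drawn with
  correlation `coupling`; within-category hub factors are independent.  An
  earlier design with one shared super-factor per side was rejected: a
  super-factor with loading \(a\) forces within-category hub correlation
  \(a^2\) to be at least the cross-category correlation \(a^2 c\), so any
  coupling strong enough to detect also bleeds every hub's module into its
  same-side siblings, confounding module recovery with coupling.  Pairwise
  coupling keeps modules crisp at any coupling level and makes `coupling`
  the exact population cross-correlation.
* Each hub gets `module_size` disjoint target genes:
  \(T = s\,(r\,F_h) + \sigma\sqrt{1-r^2}\,\varepsilon\) with
  \(r\) = `hub_target_corr` (default 0.8), sign \(s = \pm 1\)
  (`neg_target_frac`, default 0.3, negative), and \(\sigma\) = `noise_sd`
  (default 1, at which the population hub-target correlation is exactly
  \(r\)).  Remaining genes are i.i.d. Gaussian noise — clean false-positive
  accounting.
* Gene variables ride on a log2-microarray-like baseline
  (\(\mathcal{N}(7,1)\)); physiology and serum variables are pushed onto
  arbitrary scales with random positive scale and offset so that
  standardization is genuinely exercised, not decorative.
* Designated training-responsive genes (defaults 40/12/2 for
  healthy/COPD_N/COPD_L — a broad healthy response, a reduced
  preserved-mass response, almost none with muscle wasting, mirroring the
  gradient such cohorts show) are shifted at the post timepoint by
  `train_effect_sd_units` (default 2) pre-SDs, signed by direction
  (70% up).  Hub genes are never designated, so the anchors stay clean.
  `inject_de` applies the same shift to an arbitrary matrix and is what the
  generator uses internally.
* The default `coupling` is 0.3 — intermediate between the uncoupled
  COPD-like regime (0) and the strongly coupled healthy-like regime (0.9),
  so downstream stages see non-trivial but not dominant cross-category
  structure by default.  Validation of the coupling statistic sweeps
  \(\{0, 0.3, 0.6, 0.9\}\) explicitly.

Identical spec + seed reproduces the cohort bit-for-bit; the ground truth
(module membership, target signs, coupling, DE directions) is returned and
serialized with the data.

**What the generator does not emulate:** array probe effects and batch
structure, realistic (skewed, heteroscedastic) cytokine distributions,
fibre-type biology, correlated noise between non-module genes, and any
mean-variance relationship of expression data.  Passing tests on these
cohorts demonstrates that the estimators and statistics behave as designed
under a controlled truth — not that a particular clinical dataset will
reproduce any specific published number.

## Numerical choices and degenerate inputs

* All randomness flows from integer seeds; every stochastic stage of
  `run_pipeline` logs its seed, and re-running a config reproduces
  byte-identical outputs.
* Zero-variance guards: constant vectors give MI 0 with a warning; constant
  genes get \(p = 1\) (flagged) in t-tests and are excluded (flagged) from
  the ANOVA; constant panel genes trigger a warning in `knn_cv`.
* Ties: DPI triangles break MI ties by removing the lexicographically last
  edge by (min id, max id); k-NN breaks distance ties by smallest sample
  index.
* Thresholds live in `run_config` with conventional genome-scale defaults
  (edge \(p < 10^{-7}\), DE \(q < 0.10\), ANOVA \(P < 0.01\), enrichment
  FDR \(< 0.01\), fold \(> 1.5\)).  The scaled-down validation cohorts
  (about 200 genes, 48 samples) use an edge threshold of \(10^{-3}\):
  with two hundred variables rather than tens of thousands, the
  genome-scale threshold would be needlessly conservative.

## Problem sizes used in validation

The shipped tests and the acceptance script run, by choice, at desk scale:
cohorts of 8-12 subjects per group (48-72 samples) and about 200 genes;
1500-20000 permutations per calibration; 20 seeds for module-recovery and
coupling sweeps; 200 replicates for DE power/FDR; \(n = 10^4\) for the
kernel-MI accuracy check.  These sizes make the whole validation suite run
in minutes while keeping every statistical claim testable.

## Known limitations

* The exponential tail extrapolation to \(p = 10^{-7}\) is an approximation;
  its anchor is tested at \(p = 1/N\), but seven orders of magnitude beyond
  the permutation count the threshold inherits model error from the
  exponential form.
* Hub-anchored inference does not see target-target dependence; DPI can only
  prune triangles that include at least two hub edges.
* The coupling null preserves hub degrees but not the correlation structure
  among targets.
* `map_ids` treats homology as a flat table; paralogy-aware mapping is out
  of scope.
* The package consumes normalized expression matrices; array normalization
  and batch correction are upstream concerns.
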