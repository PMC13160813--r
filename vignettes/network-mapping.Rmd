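---
title: "Mapping functional brain networks and benchmarking their reproducibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping functional brain networks and benchmarking their reproducibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

netmapr implements, at desk scale, the analysis chain used to map
population-level functional brain networks from resting-state fMRI and to
quantify how reproducible the resulting maps are across independent
cohorts: motion censoring, denoising, group-average functional connectivity
(FC), multi-density map-equation community detection with template
matching, winner-take-all (WTA) extension of cortical networks into
subcortical structures, and a similarity/integration suite. Because the
cohort data that motivate this pipeline are access-controlled, the package
ships a synthetic-cohort generator so that every stage can be exercised,
tested, and benchmarked end to end on a laptop. This vignette documents
the models, the tunable parameters, and the design decisions.

## The synthetic cohort model

Each cohort lives on a unit icosphere (`make_icosphere()`); the default
experiments use 3 subdivisions, i.e. 642 vertices. A planted template of K
spatially contiguous networks is grown by synchronized breadth-first
accretion from random seed vertices (`make_template()`): the K patches take
turns claiming one unlabeled neighbor, which guarantees contiguity and
roughly balanced sizes. Real canonical network templates are derived from
large reference datasets and are not redistributable; the planted template
plays their role and doubles as ground truth.

A subject's vertex time series follow a shared-latent model. Network $s$
carries a unit-variance latent signal $L_s$, one global signal $G$ is
shared by every vertex, and vertex $v$ in network $s$ emits

$$ y_v(t) = a\,L_s(t) + b\,G(t) + \sigma\,\varepsilon_v(t), $$

with $a, b$ solved from the target correlations: writing $V = a^2 + b^2 +
\sigma^2$, same-network pairs correlate at $(a^2+b^2)/V$ and cross-network
pairs at $b^2/V$, so given `within_network_corr` $w$, `between_network_corr`
$\beta$ and `noise_sd` $\sigma$ we set $V = \sigma^2/(1-w)$, $a^2 =
(w-\beta)V$, $b^2 = \beta V$. Targets with $\beta > w$ are rejected as
unreachable. The defaults $w = 0.35$, $\beta = 0.05$, $\sigma = 1$
reproduce the magnitude of within- versus between-network coupling typical
of group-average cortical FC. Subcortical voxels (300 per subject by
default) couple to their true network's latent with the same coefficients;
they are points without a mesh and never enter spin rotations.

Framewise displacement (FD) traces are folded-Gaussian baseline jitter
(|N(0, 0.05 mm)|) plus Poisson-placed bursts of 1–3 frames at 0.35–1.0 mm
(two bursts per run on average). The burst amplitudes were chosen so both
censoring stages are exercised: the 0.3 mm processing mask and the 0.2 mm
final analysis mask.

What the generator does *not* emulate: hemodynamic response shapes,
physiological (cardiac/respiratory) noise, spatial autocorrelation of the
noise field, scanner or site effects, and distance-dependent FC decay.
Planted networks are equicorrelated blocks ("cliques"), which is harsher
on density thresholding than real FC (see the degenerate-ties note below)
but makes ground truth exact. Passing the split-half benchmarks therefore
demonstrates that the *pipeline* is correct and stable under realistic
noise and motion levels, not that real cohorts of this size would reach
the same similarity values.

## Censoring and denoising

Frames are retained iff FD is strictly below threshold (`flag_frames()`;
the inclusion rule is written "FD < 0.2 mm", so equality censors). Retained
runs shorter than `min_contig` frames (default 5) are censored
(`enforce_contiguity()`), and subjects need `min_retained` retained frames
for inclusion. The denoising chain (`preprocess_subject()`) applies, in
order:

1. a processing mask at FD > 0.3 mm — this mask drives interpolation and
   regression, without the contiguity rule (the rule is applied only at the
   final analysis mask; whether it also applies at the processing stage is
   not specified by the protocols this mirrors, and applying it there would
   only discard extra frames from estimation);
2. demeaning and detrending, with the linear fit estimated on retained
   frames only and subtracted from all frames;
3. least-squares spectral interpolation across censored frames: a basis of
   sines and cosines at Fourier frequencies $k/(N\,\mathrm{TR})$ spanning
   the pass-band plus a 20% guard is fit to retained frames by
   ridge-regularized least squares (ridge $10^{-6}$ for stability; the
   basis size is otherwise ill-conditioned when censored runs are long).
   Retained frames are returned unchanged, so later filtering cannot smear
   motion artifacts into clean frames;
4. nuisance regression of the global (across-node mean) signal and its
   backward-difference derivative (first element zero), betas estimated on
   retained frames, residualization applied to all frames;
5. a zero-phase band-pass filter, 0.008–0.10 Hz: a Butterworth filter of
   order 2 per pass run forward and backward (`signal::filtfilt`). No
   filter family or order is prescribed by the protocols this mirrors;
   order 2 per pass is the common choice. Each series is demeaned before
   filtering, which removes DC exactly and keeps edge transients small —
   with a 0.008 Hz low edge the filter's settling time is a large fraction
   of a 600-frame run, so feeding it a nonzero mean would otherwise ring;
6. the final analysis mask at FD < 0.2 mm with the 5-contiguous-frame rule,
   used for all subsequent correlations.

The chain is linear for fixed masks and regressors (tested to $10^{-8}$).

For the desk-scale experiments the inclusion floor defaults to 240 of 600
frames — the same 40% retention fraction the real acquisitions required
(600 of roughly 1,500 frames); requiring 600 of 600 would exclude every
subject whose trace contains a single burst.

## Connectivity

Subject FC is the Pearson correlation of node time series over retained
frames (`subject_fc()`, at least 3 frames). Group matrices are element-wise
means of raw correlations (`group_average_fc()`); Fisher-z averaging is
available but off by default, matching the convention of averaging raw r.
Parcel-level FC (`parcel_fc()`) averages member-vertex series into one
series per parcel before correlating — the alternative (averaging
vertex-pair correlations into parcel blocks) is not used; parcel series are
unweighted vertex means since icosphere vertex areas are nearly uniform.
Reproducibility between two group matrices is the Pearson correlation of
their strictly-upper-triangle entries (`fc_similarity()`).

## Network identification

`map_networks()` composes four steps across an edge-density grid (default
0.1%–5%: 0.001, 0.002, 0.005, 0.01, 0.02, 0.03, 0.04, 0.05; the exact
intermediate values inside that range are a package choice):

- **Thresholding** (`threshold_at_density()`): negative correlations are
  excluded first — density is defined over the positive node pairs, since
  the handling of negative edges is a genuine ambiguity of
  density-thresholded community detection and excluding them is the common
  convention. The $\lceil d\,E \rceil$ largest-weight edges are kept with
  weights preserved; ties break deterministically (weight descending, then
  node pair lexicographically), which makes edge sets nested across
  densities.
- **Community detection** (`infomap_partition()`): a two-level map-equation
  minimizer. Flow is edge-weight proportional — node visit rates are
  strengths over total strength, module exit rates are boundary-crossing
  weight over total strength — which avoids a teleportation parameter on
  undirected graphs. The optimizer runs seeded random-order node-to-module
  moves, aggregates modules into supernodes, and repeats until no move
  lowers the codelength; the best of 10 restarts is kept. The greedy result
  matches exhaustive partition search on small graphs and an independent
  Infomap implementation on planted structures (see the test suite).
- **Template matching** (`template_match()`): each community of at least 5
  nodes (smaller ones are unmatchable and noisy) inherits the name of the
  template network with maximal Jaccard overlap iff that overlap strictly
  exceeds 0.15; otherwise its nodes stay unassigned. Two communities may
  claim the same name, as in the template-matching literature. Argmax ties
  go to the first-listed network.
- **Consensus** (`consensus_labels()`): each vertex takes its label from
  the sparsest density at which it received a named match; vertices never
  matched stay unassigned.

A degenerate regime worth knowing about: with exactly zero observation
noise all within-network correlations are identical, the threshold
tie-break becomes lexicographic, and networks fragment arbitrarily. Any
nonzero noise breaks the ties; the package's limit tests therefore use
small nonzero noise. Relatedly, with planted equicorrelated networks the
within-network pairs can exceed 5% of all pairs, in which case the default
grid cannot retain whole networks and a few vertices stay unassigned at
every density — this mirrors the unassigned vertices real pipelines
produce and is why map agreement is evaluated on jointly assigned vertices.

## Subcortical winner-take-all assignment

`network_mean_series()` averages vertex series per named cortical network;
`wta_assign()` gives each voxel the network with the highest Pearson
correlation over retained frames. At the cohort level (`group_wta()`) the
per-subject voxel-by-network correlation matrices are averaged before the
argmax — this matches a group-average-correlation framing; per-subject
assignment with plurality voting would be the alternative. There is no
minimum-correlation floor for assignment. Exact ties go to the first
network in name order, with a warning.

## Similarity statistics

- **NMI** (`nmi()`): mutual information normalized by the arithmetic mean
  of the marginal entropies, $2I/(H_a+H_b)$; max- and min-entropy variants
  are selectable, as no single variant is canonical. Nodes unassigned in
  either map are excluded pairwise; a single-label map has zero entropy and
  NMI 0 by convention.
- **Dice** (`dice()`, `dice_by_network()`): $2|A\cap B|/(|A|+|B|)$ per
  network.
- **Spin tests** (`spin_rotations()`, `rotate_labelmap()`,
  `spin_pvalue()`): uniformly random rotations (normalized Gaussian
  quaternions) applied to one map only — map `a` is rotated against a fixed
  `b`, mirroring the convention of rotating one group's labels against the
  other's. Rotated vertices take the label of the nearest original vertex
  by dot product; unassigned labels rotate like any label, and rotated
  vertices landing on excluded territory are dropped pairwise by the
  statistic — the principal known ambiguity of spin methods, made explicit
  here. Nearest-neighbor quantization flips a small fraction of boundary
  vertices per rotation (a few percent on a 642-vertex sphere with 12
  networks), so label proportions are preserved only to about 2%. The
  p-value counts null statistics at least as large as the observed one;
  the default add-one convention $(k+1)/(n+1)$ avoids p = 0, and the raw
  proportion $k/n$ is selectable.
- **Mantel tests** (`mantel()`): Spearman (rank) or Pearson (linear)
  correlation of upper-triangle entries, with nulls built by permuting the
  node labels of one matrix jointly over rows and columns. Permuting one
  matrix (not both) suffices to break the alignment and is the convention
  adopted here.
- **Bonferroni control** for per-network Dice tests is $\alpha/K$; K, the
  number of tested networks, is deliberately a required argument of the
  analyst rather than a default, because the tested-network count depends
  on which networks a study reports.

Calibration: under a rotational null (a map whose orientation is uniformly
random), spin p-values are uniform to Kolmogorov distance < 0.1 over 200
replicates, and the same holds for Mantel p-values under independence —
both are asserted in the test suite. One subtlety discovered during
validation: two templates grown by breadth-first accretion on the *same*
mesh are not rotationally independent (both align with the mesh's vertex
indexing), so a naive "two independent templates" null is slightly
anti-conservative; calibration must randomize orientation.

## Participation coefficient

`participation_coefficient()` computes $PC_i = 1 - \sum_s (k_{is}/k_i)^2$
on the group-average parcel matrix, with negative correlations set to zero
beforehand (the common practice for PC on correlation graphs; a
binarizing mode is available). Both groups are evaluated on one shared
parcellation and label set so that $\Delta PC$ is comparable across
groups. Unassigned parcels are excluded from the network sums and from
network means; isolated parcels get missing values.

## The experiments

`run_splithalf_experiment()` simulates two cohorts from one template
(seeds `seed` and `seed + 1`), preprocesses every subject, builds group
vertex- and parcel-level FC, maps networks per cohort, extends them into
the subcortical voxels by group WTA, and reports: vertex/parcel FC
correlation, cortical consensus NMI with a 1,000-rotation spin p-value,
subcortical NMI, and per-network Dice. The standard conditions are 40
subjects per cohort, 642 vertices, 12 networks, 40 parcels, 600 frames at
TR 0.8 s — sizes chosen so the full experiment, including the spin null,
completes in minutes on one CPU while leaving the group-level statistics
well out of the noise.

`run_crossgroup_experiment()` adds a second population whose template has
a fraction of vertices shifted across network boundaries
(`perturb_template()`), emulating a group whose topography differs (e.g.
adults versus children), and reports within-group versus cross-group NMI
and Dice, Mantel tests on parcel matrices, and PC with per-parcel and
per-network differences. Increasing the perturbation lowers cross-group
overlap monotonically while leaving within-group reproducibility
untouched.

Cohort demographics (`simulate_demographics()`, `matched_split()`) support
the matched-split design: families are kept intact, halves carry equal
(within one) numbers of singletons and family groups, and the best of
1,000 randomized candidate splits by a summed balance score (chi-square
statistics for categorical variables plus squared standardized mean
differences for numeric ones) is kept — the matching algorithm behind the
real cohorts' split is not published, so this is the package's own
construction. The number and identity of matching variables is
configurable rather than fixed. Balance is verified with
`contingency_chi2()` (classical Pearson chi-square, no continuity
correction) and `summary_t_test()` (Student's pooled form by default,
because the real cohort tables report plain "independent samples t-test";
Welch is available).

## Known limitations

- The map-equation optimizer is two-level only; hierarchical (multi-level)
  solutions and directed flow are out of scope.
- Spin nulls inherit nearest-neighbor quantization error; on meshes much
  coarser than 642 vertices the label-proportion drift grows accordingly.
- The generator's clique-like networks make density thresholding behave
  more abruptly than smooth real-data FC; absolute Dice/NMI values from
  synthetic runs should not be read as predictions for real cohorts.
- Group-average maps smooth over individual variability by construction;
  nothing here addresses individual-level mapping.
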