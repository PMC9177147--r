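---
title: "Boundary-locked pattern analysis: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boundary-locked pattern analysis: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boundarypattern)
```

## The scientific problem

When people watch a series of short movies and later recount them aloud in an
order of their choosing, the transition from recalling one movie to the next is
a purely internally generated boundary between mental contexts: no stimulus
marks it. This package implements a multivariate fMRI analysis of such
boundaries. Its core quantity is the **boundary pattern**: the mean spatial
activation pattern over a fixed window following the offset of a watched or
recalled movie. The analyses ask

1. whether boundary patterns are *consistent across different movies* and
   *across tasks* (movie watching vs. spoken recall), measured as Pearson
   correlations between spatial patterns (an RSA-style pattern similarity
   analysis);
2. when the boundary pattern emerges relative to offsets and onsets
   (time-time correlation matrices of peri-event pattern time series);
3. whether boundaries between narratives resemble event boundaries *within*
   a narrative (within- vs. between-movie boundary templates); and
4. whether the boundary pattern is an artifact of silence (audio-envelope
   controls).

## Windows and timing conventions

All event times live on the *run clock*: the acquisition of the first volume
of a run is time 0, and during encoding the stimulus starts 3 s later
(`stim_to_run_clock()` makes the conversion explicit). The analysis windows
are:

* **Boundary period**: `[offset + 4.5 s, offset + 4.5 s + 15 s)`. The 4.5-s
  shift compensates the haemodynamic delay; a 4.5-s window variant
  (`window_spec(4.5, 4.5)`) is available for control analyses.
* **Non-boundary period**: a 15-s window centred on the temporal midpoint of
  the movie, then shifted by 4.5 s. Midpoint centring is a documented
  convention; the anchoring of the "middle 15 s" is otherwise underdetermined
  and no snapping to volume boundaries is applied.
* A volume belongs to a window iff its acquisition onset falls inside the
  half-open interval. This is deterministic and immune to off-by-one
  ambiguity; a 15-s window aligned to the 1.5-s TR grid contains exactly 10
  volumes. Windows are used as-is even when they extend past the end of a
  movie into the following title scene (that is part of the design); they are
  clipped only at run boundaries.

Preprocessing mirrors the standard surface pipeline downstream of motion
correction: the first 5 volumes of encoding runs and 3 of recall runs are
discarded (`trim_initial_volumes()`), slow drifts are removed by regressing
out a discrete-cosine basis containing all frequencies up to 1/140 s
(`highpass_dct()`; a DCT projection is deterministic and edge-stable, unlike
an IIR filter), and each vertex is z-scored within each run (`zscore_run()`).
Trimming precedes normalisation; whether the original pipeline normalised
before trimming is unknowable from the description, and the difference is a
few volumes of baseline.

## The synthetic experiment

`generate_experiment()` builds a complete synthetic study so that every stage
is testable without access to neuroimaging data. Its defaults *are* the study
conditions and are not tuned per analysis:

* 15 subjects; 10 movies with durations evenly spaced over 129-465 s
  (the reported 2.15-7.75 min range), each preceded by a 6-s silent title;
  two encoding runs of five movies; one recall run per subject in a random
  subject-specific order with lognormal inter-movie pauses matched to the
  reported mean 9.3 s and SD 16.8 s, truncated at 60 s (the strong positive
  skew implied by SD >> mean motivates the lognormal family; the true pause
  distribution is unknown beyond its first two moments).
* Recall of each movie lasts Uniform(0.3, 0.5) of its viewing duration -
  spoken recall is compressed relative to viewing. This is a modelling
  choice; nothing downstream depends on the exact compression.
* 40 parcels x 20 vertices. Parcels 1-4 carry the between-movie boundary
  pattern and the within-movie event pattern (a posterior-medial analogue),
  parcels 5-6 carry the silence-locked pattern (an auditory analogue), the
  rest are null. Vertices are assigned a surface area of 2.2 mm^2, the
  average vertex area of a standard high-resolution surface template, so the
  16-mm^2 component filter behaves realistically.
* Latent states: a shared boundary state active for 15 s after every movie
  offset in both phases (the latent dwell time is a knob; the analysis is
  agnostic about it), per-movie content states spanning each movie, event
  states after within-movie boundaries during encoding, and a silence state
  wherever the audio envelope is zero - titles, planted within-movie dips,
  and recall pauses. States are convolved with a double-gamma HRF (peak 6 s,
  undershoot 16 s, dispersions 1, ratio 6, 32-s kernel - the canonical
  parameterisation; only the family is prescribed), multiplied by unit-norm
  spatial patterns scaled so that amplitudes are per-vertex RMS values in z
  units, and buried in white noise (`noise_sd = 1`). The default amplitudes
  of 0.5 give the signal-to-noise ratio of 0.5 used by the recovery suites.
* Within-movie boundaries are planted at 25% and 70% of each of movies 1-7
  and at 70% of movies 8-10: 17 boundaries, of which 15 survive the 45-s
  carry-over exclusion - matching the coarse-event counts of the study
  design. The positions avoid the non-boundary windows so that the two
  pattern families stay separable.
* The within-movie event pattern is constructed by centred Gram-Schmidt
  mixing to have an exact Pearson correlation of `corr_event_boundary`
  (default -0.3) with the boundary pattern, mirroring the sign of the
  empirical within/between relationship.
* Boundary, event, and silence patterns are shared across subjects - group
  inference on vertices requires consistent topographies - whereas content
  patterns are subject-specific. Content patterns enter no cross-subject
  analysis, and making them subject-specific keeps the univariate null
  calibrated (shared content would otherwise produce spurious group-level
  boundary/non-boundary differences).
* All randomness derives from one master seed; regeneration is bit-identical.

What the generator does **not** emulate: spatial autocorrelation and
smoothness, physiological and motion artifacts, HRF variability across
regions and subjects, semantic structure in content patterns, and real
coder-derived event boundaries (boundaries are inputs, not modelled
behaviour). Passing recovery suites therefore demonstrates that the
*analysis logic* is correct and calibrated, not that the effects exist in
real data.

## Inference conventions

All group tests are two-tailed: one-sample t against zero for mean
correlations and paired t for condition contrasts, reported with Cohen's
d_z = t / sqrt(n) (the convention consistent with every reported effect
size), and 95% confidence intervals in raw r units. Group inference operates
on raw mean correlations rather than Fisher-z transforms, matching how the
quantities are reported. Parcel-wise maps use Bonferroni correction with a
strict `p < alpha/m` threshold; vertex-wise univariate maps use the
Benjamini-Hochberg step-up (non-strict, as in the original procedure) with
an optional minimum component-area filter whose connectivity is parcel-wise
cliques for synthetic data (no mesh exists) or a user-supplied vertex
adjacency. The conjunction map marks a parcel only if the boundary
correlation is significantly positive *and* significantly exceeds the
non-boundary correlation, both after correction.

Cross-phase between-movie averaging uses all 90 ordered (encoding i, recall
j != i) pairs; whether the original analysis symmetrised to 45 pairs is not
determinable, and the mean is identical in expectation. Time-time matrices
Bonferroni-correct over testable cells only (cells with every subject
finite); grid points that fall outside a run for some movie simply lose that
movie from the average, with `valid_counts` keeping score.

## Numerical and degenerate-input choices

Correlations of constant vectors are undefined and raise errors naming the
offending pattern rather than propagating NaN. Noiseless generator
configurations skip run z-scoring (null vertices would be constant); they
exist for exactness tests only. The silence threshold is computed on the
HRF-convolved, z-scored envelope regressor by default - the comparison is
made in processed space - with a raw-envelope option for constructed tests.
A boundary at exactly 45 s into a movie is *retained* by the carry-over
exclusion (the rule excludes boundaries strictly inside the first 45 s), and
non-boundary windows are excluded from the within-movie consistency analysis
on any positive-measure overlap with a boundary window, the general rule
behind the specific overlaps that motivated it.

Two systematic leakage effects of run-wise normalisation are worth knowing
about when interpreting synthetic results. First, z-scoring and high-pass
filtering push the filtered boundary state slightly negative *between*
boundaries, so mid-movie windows acquire a small shared negative component
of the boundary pattern; non-boundary similarities are therefore biased a
few hundredths above zero at high SNR. Second, mid-movie silent dips carry
full content signal, so silent-TR averages correlate weakly (negatively)
with boundary templates in regions where boundary or content signal is
planted. Both effects are properties of the measurement pipeline, not bugs;
the silence-dissociation suite therefore plants the silence pattern in
isolation, which is also the configuration that the dissociation logically
tests.

## Problem sizes used by the test suites

The recovery, null-calibration, sign-recovery, and silence-dissociation
suites each run 20 independent experiments at the full study conditions
(15 subjects, 40 parcels, 800 vertices, roughly 4,100 volumes per subject).
Unit tests use a miniature configuration (2-8 subjects, 8 parcels, movies of
90-180 s) chosen to keep the full suite fast while preserving every
structural property (10 movies, titles, pauses, dips, retained within-movie
boundaries).

## A worked example

```{r example, eval = FALSE}
library(boundarypattern)

config <- ground_truth_config(seed = 1)
experiment <- preprocess_experiment(generate_experiment(config))

# headline similarity quantities in the planted boundary ROI
roi <- experiment$truth$roi
similarity_result(experiment, region = roi$boundary)

# whole-brain cross-phase conjunction
sims <- parcelwise_similarity(experiment)
which(conjunction_map(sims$c, sims$d))

# within- vs between-movie boundary templates
template_similarity_stats(experiment, region = roi$boundary)$tests
```

## Known limitations

* No searchlight, cross-validated classification, TFCE, or cluster-extent
  permutation inference; corrections are Bonferroni/BH only, as in the
  analyses this package implements.
* Real-data ingestion expects surface-sampled matrices already projected to
  a parcellated surface; GIFTI/NIfTI conversion is left to upstream tools
  (`RNifti` and `oro.nifti` read the volumes; the container here stores
  plain matrices).
* The recall-pause distribution and the latent boundary dwell time are
  assumptions; both are exposed as configuration knobs.
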