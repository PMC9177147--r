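# boundarypattern

Multivariate analysis of cortical activation patterns at boundaries between
mental contexts in naturalistic fMRI. The package targets experiments in
which subjects watch a series of short movies (each preceded by a brief
silent title scene) and later recall them aloud, unprompted and in an order
of their choosing: the transition from recalling one movie to the next is an
*internally generated* event boundary, and the package quantifies the
transient spatial activation patterns these boundaries evoke.

It is written for cognitive-neuroscience researchers who want a tested,
reusable implementation of this analysis family — including a synthetic-data
generator that makes every stage verifiable without access to real data.

## The analysis

The core object is the **boundary pattern** of a movie: the mean spatial
pattern over the window `[offset + δ, offset + δ + w)` with haemodynamic
shift δ = 4.5 s and width w = 15 s; the **non-boundary pattern** is the
matching mid-movie window. For each subject and region, patterns are
compared by Pearson correlation *r* between movies, conditions, and task
phases:

- `a` — mean *r* between the boundary patterns of different recalled movies
  (45 pairs); `b` — the same for non-boundary patterns.
- `c` — mean *r* between encoding and recall boundary patterns of different
  movies (90 ordered pairs); `d` — the non-boundary analogue.
- Parcel-wise **conjunction maps**: parcels where the boundary correlation is
  significantly positive *and* exceeds the non-boundary correlation, both
  two-tailed one-sample/paired t-tests with Bonferroni correction.
- **Time–time matrices**: peri-event pattern time series from −30 s to +60 s
  around onsets/offsets, correlated time point by time point across phases,
  with cell-wise Bonferroni-corrected group t-tests.
- **Template comparisons**: within-movie event-boundary templates vs.
  between-movie boundary templates (the within/between distinction).
- **Silence controls**: Hilbert-envelope audio regressors (HRF-convolved,
  z-scored) classify silent time points, whose mean pattern is compared to
  the recall boundary template; plus the correlation between audio amplitude
  and the boundary-similarity time course.

Group statistics are two-tailed t-tests with Cohen's *d*_z = *t*/√*n* and
95% CIs; vertex-wise maps use Benjamini–Hochberg FDR plus a minimum
component-area filter.

## Worked example

```r
library(boundarypattern)

config <- ground_truth_config(seed = 1)           # 15 subjects, 40 parcels
experiment <- preprocess_experiment(generate_experiment(config))

roi <- experiment$truth$roi                       # planted parcel sets
similarity_result(experiment, region = roi$boundary)
```

```
Between-movie pattern similarity (group means):
  a (recall-recall, boundary)     = 0.4904
  b (recall-recall, non-boundary) = 0.0110
  c (encoding-recall, boundary)   = 0.4974
  d (encoding-recall, non-bound.) = -0.0001
  boundary > 0 (a): t(14) = 76.764, p = 8.812e-20, d_z = 19.820, mean = 0.4904, 95% CI [0.4767, 0.5042]
  boundary > non-boundary (a vs b): t(14) = 75.345, p = 1.144e-19, d_z = 19.454, mean = 0.4794, 95% CI [0.4658, 0.4931]
```

In the planted boundary region the boundary patterns of different movies are
strongly and consistently correlated within recall (`a`) and across phases
(`c`), while mid-movie patterns are not (`b`, `d`) — the signature the
pipeline is built to detect. The whole-brain conjunction recovers exactly
the parcels carrying boundary-locked structure:

```r
sims <- parcelwise_similarity(experiment)
which(conjunction_map(sims$c, sims$d))
#> [1] 1 2 3 4 5 6
```

Parcels 1–4 carry the planted boundary pattern; parcels 5–6 carry a
silence-locked pattern that recall pauses sweep into the boundary windows —
the auditory confound the silence controls are designed to expose.

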