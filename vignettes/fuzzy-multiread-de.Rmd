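---
title: "Possibilistic differential expression with multireads: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Possibilistic differential expression with multireads: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzydea)
```

This vignette explains the models implemented in `fuzzydea`, the
assumptions behind them, the tunable parameters and the design decisions
taken where the method left genuine freedom. It states no empirical
results beyond what the package's test suite and `scripts/acceptance.R`
compute.

## Why possibility, not probability

A multiread is a read whose gene of origin cannot be decided from the
alignment alone. Probabilistic resolution (EM-style estimators) must
assume a generative model of where multireads come from; the possibilistic
representation makes no such assumption. An alignment's accuracy is
rescaled to a **possibility degree** in (0, 1]: 1 means "this origin is
fully possible", smaller values mean "possible, but less supported".
Possibilities of alternatives need not sum to one — a read can be fully
possible on two paralogs at once, which is precisely the epistemic state
the data leave us in.

For BLAST-style tabular alignments the default score is
`identity/100 × coverage/100`; identity alone is available as a flag. The
product is the default because a full-length perfect match — and only
that — reaches possibility 1. For SAM input two conventions exist:
`mapq` scales the mapping quality by 255, which is the direct reading of
the format, but most aligners give multireads MAPQ 0, flattening exactly
the graded scores this model needs; `tag` mode divides the per-alignment
score (`AS` by default) by the read's best score. `mapq` is the default
as the more literal convention; `tag` is the recommended one in practice,
and neither is substituted silently.

Duplicate (read, gene) alignments collapse to the **maximum**
possibility: the possibility of an event is the possibility of the best
way it can occur. Per-read possibilities are *not* renormalized in BLAST
mode, so a read may have a best hit below 1.

## The trapezoidal fuzzy count

The exact possibility that a gene's true count equals *k* is a sup–min
over all size-*k* subsets of the reads touching it
(`count_possibility()`, exact enumeration, capped at 20 reads by
default). The "false match" possibility of an excluded read is its best
possibility on any *other* gene, 0 for reads mapping only to this gene —
the only reading under which a gene with a unique read has possibility 0
of count 0. The distribution always rises to a plateau and falls, so it
is summarized by four integers (`fuzzy_counts()`): A unique reads, B
strict best matches, C best matches with ties, D all reads. Two caveats
are worth knowing:

* Ties are decided with a tolerance `tie_tol` (default 1e-9) on the
  possibility scale, because scores are floating point: "strict best"
  means greater than every other record by more than `tie_tol`.
* The support/plateau equivalence between `fuzzy_counts()` and the exact
  distribution (support = [A, D], plateau = [B, C]) holds exactly when
  each read's best alignment has possibility 1 — the convention of the
  bundled generator, and of `tag`-mode SAM scoring. With best hits below
  1 the plateau of the exact distribution can be empty while B < C; the
  trapezoid is then the stated four-parameter summary rather than a
  literal plateau.

Membership evaluation extends the support by one count on each side
(A′ = A−1, D′ = D+1) so the extreme counts A and D keep non-null
possibility; the stored parameters are always A..D, the extension is
applied at evaluation time, and membership at negative counts is zero
(relevant once normalization makes parameters non-integer).

The **rescue-like centroid** distributes each read over its genes
proportionally to possibility. It conserves the total read count to
machine precision and always lies inside [A, D]; it feeds normalization,
the punctual fold change and the envelope fit, never the possibility
calls.

## Replicates and normalization

Technical replicates are merged by componentwise sum of A..D (and of
centroids) — the fuzzy analogue of summing counts. We sum the raw
parameters and re-derive the ±1 extension afterwards; summing the primed
values instead would shift each end by a constant 1 and break the
invariant A′ = A−1 after repeated merges.

Biological replicates are merged with the envelope
Tr[min A, min B, max C, max D]: every count fully possible in some
replicate stays fully possible, and when replicates are disjoint the
intermediate counts also receive full possibility, on the grounds that
expression varies continuously in the cells of one condition. This is
deliberately conservative — it widens, never narrows. The centroid of a
biological merge is the mean of the replicate centroids. Merging more
than two replicates folds pairwise; the trapezoid parameters are
min/max-based, so the fold order is immaterial.

Size factors are median-of-ratios: each sample's factor is the median
ratio of its counts to the per-gene geometric means, computed on genes
positive in every sample, with the even-length median taken as the mean
of the two middle values. The factors are computed from rescue-like
centroids when multireads exceed a *sporadic* threshold (1 % of reads by
default) and from multiread-free genes' counts otherwise. Trapezoids are
normalized by dividing all four parameters by the factor.

## The significance envelope

Fold change alone overstates change at low counts: in an MA plot of
replicate comparisons the null cloud widens hyperbolically toward low
mean expression. `fit_fc_threshold()` estimates that boundary:

1. bin points on log-spaced mean-expression bins (30 by default, reduced
   so each bin can hold about 10 points; bins with fewer than 5 points
   are skipped);
2. per bin, take the point attaining the `q`-th quantile of |log₂ FC|
   (q = 0.99 by default) and keep **that point's own coordinates**. This
   pairing matters: pairing the quantile with the bin center biases the
   envelope upward wherever the within-bin spread of means is large;
3. fit t(m) = a/(m + c) + b, a > 0, b, c ≥ 0, by least squares on log t,
   with under-coverage (a boundary point above the curve) weighted
   double so the curve envelops the cloud rather than bisecting it. The
   fit uses a Levenberg–Marquardt residual interface; if it fails or
   degenerates the envelope falls back, with a warning, to a monotone
   isotonic interpolation of the boundary points;
4. one outlier-rejection pass: points with |log₂ FC| above twice the
   first envelope are treated as genuine expression changes, removed,
   and the envelope refit.

The hyperbola family and this extraction procedure are this package's
own reconstruction of the envelope idea; both `q` and the family
parameters are recorded in the fitted object and can be serialized with
`write_threshold_json()`.

Inside `fuzzy_de()` the choice of fitting data follows the envelope's
meaning — *technical/replicate variability*: with at least two samples
in a condition, the envelope is fitted on all within-condition replicate
pairs (which carry no induced change by construction); with one sample
per condition it is fitted on the case–control cloud itself, relying on
the outlier pass to exclude the DE minority. Runs too small to fit
(fewer than 50 usable genes) fall back, with a warning, to a fixed
conservative envelope t(m) = 4/(m+1) + 1, whose floor of one log₂ unit
is the conventional two-fold cutoff.

The threshold is clamped to the fitted mean-expression range and floored
at `t_floor` (0.01 log₂ units) so the membership surfaces below remain
well-defined even when the envelope collapses (identical samples).

## The three DE possibilities

At mean expression m, three membership functions over log₂ FC encode the
DE concepts: a Gaussian for same-expression with σ = t(m)/√(2 ln 2), and
two mirrored sigmoids for over-/under-expression with steepness
s = ln(99)/t(m). All three equal 0.5 exactly at ±t(m); the Gaussian peaks
at 1 for FC = 0; the sigmoid choice of s makes over-expression worth 0.01
at FC = 0. Only the 0.5 crossing is dictated by the envelope
construction; the steepness rule is a design choice fixed for
reproducibility. All three functions have infinite support, so every
gene receives three graded degrees rather than a hard call.

A gene's counts in the two conditions form the joint relation
min(case(x), control(y)) — a truncated pyramid over the count plane. Each
DE possibility is the sup–min intersection of that relation with the
corresponding surface, evaluated at fc = log₂(x/y) and mean (x+y)/2 (the
arithmetic mean of the two normalized coordinates; a logarithmic mean
axis is a display convention, not part of the intersection). Numerics:

* the sup is taken on a per-axis grid (`grid_n` = 64) that always
  contains the trapezoid knots exactly — so core vertices are exact and
  max(under, same, over) ≥ 0.5 holds structurally — refined
  geometrically toward zero counts and across the membership shoulders,
  and then polished by a local Nelder–Mead search from the grid argmax,
  which removes the residual O(1/grid_n) error at shoulder crossings;
* cells with one zero coordinate evaluate the surfaces at the infinite-FC
  limit (Gaussian 0, sigmoids 0/1); the (0, 0) cell counts as FC 0 — no
  evidence of change;
* genes whose counts are points in both conditions (no multireads) are
  matched directly against the three membership functions, which is both
  exact and how point genes are described in the underlying method; a
  gene at the zero point in both conditions returns (0, 1, 0) by
  convention;
* "over-expression" means case above control; a `direction` flag relabels
  the two sigmoids for the opposite convention, since published result
  tables disagree on the orientation.

Results are ranked by ascending same-expression possibility (most
reliable DE events first), ties broken by |centroid log₂ FC| and gene
id. Optional cuts on over/under possibility and on |centroid FC| mirror
the filters commonly applied to such rankings. The run is fully
deterministic; the serialized table (6 significant digits, `Inf`
literals, size factors as header comments) is byte-identical across
reruns.

## The synthetic-experiment generator

`simulate_experiment()` emulates the stage of the analysis downstream of
alignment: it emits per-sample possibility tables directly, with no
sequences and no aligner. Reads are abstract records; each gene draws a
baseline level, induced genes get a log₂ FC split symmetrically across
conditions, per-replicate counts are Poisson, and genes in paralog
families share reads — a fraction of a family gene's reads gains a decoy
record on another member with possibility 1 − |N(0, score_noise)|
clamped to (0.5, 1), mimicking near-perfect secondary alignments, while
the true record keeps possibility 1.

The default configuration is the package's reference study condition: 250
genes, 50 paralog pairs, null baselines lognormal with median 120 reads
(sdlog 0.7), 10 over- and 10 under-expressed genes at log₂ FC ±1 with
baselines uniform on [1500, 2500], multiread fraction 0.2 on family
reads, decoy jitter 0.15, two biological replicates per condition. The
DE baselines are set high enough that two-replicate Poisson error on the
induced fold change is several times smaller than the ±0.15 band used to
judge recovery; the remaining parameters were chosen once as plausible
desk-scale values. At these sizes the full pipeline runs in seconds on
one core; the test suite uses the same configuration for the end-to-end
checks and smaller variants (60 genes) for interface tests.

What the generator does **not** emulate — and therefore what passing
tests do not show about real data: sequence-level error models and
quality strings, fragment-length effects, positional bias, isoform
structure, overdispersion beyond Poisson, and decoy possibilities
correlated with true expression. Its role is ground truth for the
calculus (counts, merging, normalization, possibility calls), not realism
of the read-generation process.

## Known limitations

* The biological-replicate envelope is deliberately coarse; with many
  replicates it can become wide enough to keep same-expression
  possibility high for nearly all genes. Ranking across genes remains
  informative, absolute possibility values less so in that regime.
* The hyperbola family decays like 1/m while pure Poisson spread decays
  like 1/√m; the asymmetric fit compensates by covering the boundary
  points, but the envelope remains a smooth compromise, not a per-bin
  quantile.
* Fuzzy fold-change endpoints are ±Inf whenever a support touches zero;
  that is a faithful report, but it makes the fuzzy FC columns unsuitable
  for naive numeric post-processing (the possibility engine never
  consumes them).
* Isoform-level deconvolution, EM count estimation, frequentist testing
  and multi-condition designs are out of scope.
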