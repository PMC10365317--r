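---
title: "Predicting phage host genus from receptor-binding protein embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting phage host genus from receptor-binding protein embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbphost)
```

## The problem

Tailed phages recognize their bacterial hosts through receptor-binding
proteins (RBPs) -- tail fibers, tailspikes and related adsorption proteins
that dock onto host-surface receptors and largely determine host range.
`rbphost` frames host prediction as multiclass classification at the genus
level: the input is a fixed-length vector representation of one RBP, the
output is the host genus of the phage that carries it. The package covers
the whole path from annotated phage proteomes to evaluated predictions:

1. **RBP mining** from GenBank flat files or annotated FASTA,
2. **host-label preprocessing** (genus standardization, polyvalent
   resolution),
3. **vectorization** by mean pooling of per-residue embeddings,
4. optional **handcrafted sequence properties** appended to the embedding,
5. a **class-weighted random forest** over the most frequent host genera,
6. **confidence-thresholded evaluation** with an `others` rejection class.

## RBP mining

Annotated proteins are screened by free-text product annotation: a record
is kept iff it matches at least one inclusion pattern (tail fiber/fibre,
tail spike/tailspike, receptor binding, RBP, host specificity, distal tail)
and no exclusion pattern (assembly, portal, chaperone, sheath, tape
measure, terminase). Exclusion dominates inclusion, because annotations
such as "tail fiber assembly protein" name proteins that interact with RBPs
without being RBPs. Matching is case-insensitive after whitespace
normalization, and both lists are plain regular expressions the user can
replace wholesale via `rbp_rules()`. The shipped lists are a practical
default, not a canonical definition of "RBP"; for a new corpus they should
be reviewed against the corpus's annotation vocabulary.

Two sequence-level filters follow. Sequences containing the undetermined
residue `X` are discarded, because downstream embedders and feature
calculators are defined on the 20-letter alphabet. Then lengths outside the
Tukey fence $[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]$ are
discarded, with quartiles computed by linear interpolation between order
statistics (the type-7 convention -- the dominant software default; the
choice is pinned by tests because other conventions move the fence). The
fence is computed once, on the annotated pool after the `X` filter, and the
interval is closed: a sequence exactly at the fence survives.

```{r}
corpus <- generate_corpus(corpus_spec(n_classes = 2, phages_per_class = 3,
                                      seed = 11))
mined <- mine_rbps(corpus$records)
table(mined$catalog$status)
```

## From sequence to vector

A per-residue embedder maps an $r$-residue sequence to an $r \times s$
matrix $M$; the protein vector is the column mean,
$v_j = \frac{1}{r}\sum_{i=1}^{r} M_{ij}$. Pooling is the unweighted
arithmetic mean only -- no first-token or CLS pooling, and no L2
post-normalization. Embedders with a maximum input length (`max_len`)
receive non-overlapping chunks of `max_len` residues plus a final remainder
chunk; the per-chunk matrices are stacked back into $M$ before pooling, so
for a position-independent embedder chunking cannot change the result (a
property the tests exercise for `max_len` 1, 7 and 1022, the last being the
input cap of common transformer encoders).

Pretrained protein language models plug in behind the `embedder()` contract
(a function from sequence to matrix plus a declared dimension); the package
deliberately does not ship model weights. For testing and simulation,
`fixture_embedder()` draws one fixed random vector per amino acid from a
seed -- deterministic, position-independent, and controllably
class-agnostic, which is exactly what the invariance tests need.

## Host labels

Raw host strings are standardized to genus by synonym-map lookup, falling
back to the first whitespace-delimited token with initial capitalization.
A polyvalent phage (several listed genera) is assigned the member genus
interacting with the most phages in the whole table; counts are global and
computed before any resolution, and exact ties break lexicographically so
resolution is deterministic and order-invariant. Non-bacterial or
isolation-host corrections are supplied as an override column in the input
TSV rather than by live taxonomy queries, keeping the module offline.

## Design construction

Host-genus frequencies are heavily skewed, so the class set is restricted
to the top fraction (default 25%) of genera by RBP count, ties broken
lexicographically; with 232 genera this keeps exactly 58 classes. In-set
examples (D1) are split 70/30 per class, allocating round-half-up
$\lfloor 0.7\,n_c + 0.5 \rfloor$ examples to training -- the unique rounding
rule consistent with all published per-class counts (e.g. 1,737 maps to
1,216 train). Out-of-set examples (D2) are appended to the test set under
the reserved label `others`, so evaluation confronts the model with genera
it was never trained on. Splitting is at the RBP level: two RBPs of one
phage may land in different partitions, which permits same-phage leakage;
a `group` argument to `stratified_split()` keeps a phage's RBPs together,
off by default to match the RBP-level design.

## Class-weighted forest

Training uses a probability random forest with per-class misclassification
weights

$$w_c = \frac{T}{t_c \cdot |C|},$$

where $T$ is the training-set size, $t_c$ the class count and $|C|$ the
number of classes. The weights satisfy $\sum_c t_c w_c = T$, are 1 for
balanced classes, and are invariant to scaling all counts -- three
properties the tests check on random count tables. The forest is ranger;
`min.node.size` and `min.bucket` carry the minimum-samples-to-split and
minimum-samples-per-leaf hyperparameters, and `mtry` is $\lfloor\sqrt p\rfloor$
or $\lfloor\log_2 p\rfloor$ by the split-feature rule. The search grid is
trees $\{50,100,150,200\}$ × rule $\{\log_2,\sqrt{}\}$ × min-split
$\{2,3,4\}$ × min-leaf $\{1,2,3,4\}$ (96 combinations), scored by 5-fold
stratified cross-validation on weighted F1 of plain arg-max predictions
(threshold 0): the rejection threshold is an evaluation-time device, so
model selection happens without it. When tuning is skipped the defaults are
150 trees, $\sqrt{}$, 2, 1. Grid scoring iterates in a canonical order so
tie-breaks do not depend on how the grid rows are arranged. Gini
(mean-impurity-decrease) importances are normalized to sum to 1 and drive
`top_gini_components()`, the substrate for embedding-component selection.

## Evaluation with rejection

Let $p_1 \ge p_2$ be the two largest predicted class probabilities. The
arg-max label is accepted iff $p_1 - p_2 \ge k$; otherwise the example is
relegated to `others`. Arg-max ties go to the first class in class order,
and since a tie forces $p_1 - p_2 = 0$, any $k > 0$ rejects it. Outcomes
are counted one-vs-rest over the *final* labels with `others` as a
first-class label -- the only reading consistent with metrics that sum over
"all classes including others". In particular a truly-`others` test sample
that the threshold rejects counts as a true positive for `others`; this
reconstruction of the outcome table is a documented design choice. Metrics
are class-size weighted:

$$\mathrm{WPrec}_k = \frac{1}{N}\sum_{c} n_c \frac{TP_{c,k}}{TP_{c,k}+FP_{c,k}},$$

and analogously for recall ($TP/(TP+FN)$), specificity ($TN/(TN+FP)$) and
F1 (harmonic mean of the per-class precision and recall). A per-class
ratio with zero denominator contributes 0 to the weighted sum, which keeps
every metric defined at extreme thresholds. `metrics_over_thresholds()`
sweeps $k$ from 0 to 1 (default step 0.1, both endpoints); $k=0$ disables
rejection entirely. Two monotonicity properties hold by construction and
are tested: the rejected count is non-decreasing in $k$, and each non-
`others` class's recall is non-increasing in $k$.

## Handcrafted sequence properties

The feature module implements the named properties used in the
embedding-integration experiments. Genomic (on the RBP's in-frame coding
sequence): A and C nucleotide frequency, GC content, TTA codon frequency,
and TTA codon usage bias, defined as relative synonymous usage -- the
codon's count over its synonymous family's count under the standard genetic
code, 0 when the family is absent. Protein: lysine frequency, isoelectric
point, mean fourth Sandberg Z-scale, and molecular weight (average residue
masses plus one water, 18.02 Da). The isoelectric point zeroes the
Henderson--Hasselbalch net charge over termini and ionizable side chains by
bisection on pH 0--14 to 1e-4; the pKa set, Z-scales and masses ship as TSV
files under `extdata` so tests and implementation read a single source.
These formulations are standard but not uniquely determined by the
integration experiments they mirror; they are explicit, pinned substitutes.
`concat_features()` appends any of them to an embedding in declared order.

## What the synthetic fixtures emulate

`generate_corpus()` plants RBP-annotated and decoy proteins with random
uniform sequences -- mining is annotation-driven and pooling is
content-agnostic, so no biological realism is needed or claimed.
`generate_separable_examples()` draws isotropic unit-variance Gaussian
clouds at the vertices of a regular simplex with pairwise center distance
`separation` (in noise-SD units): separation 0 makes the class-conditional
distributions identical (chance-level prediction), separation 8 makes them
essentially separable, and a geometric `skew` option shrinks successive
class sizes to exercise the minority-class weighting. What passing these
tests shows is that the pipeline's machinery is correct -- not that any
particular embedder separates real host genera; real-corpus performance
depends on the embedder and data, which the package intentionally leaves
pluggable. Default problem sizes in the shipped tests and acceptance script
(5 classes × 200 examples, dimension 16) are chosen so the full suite runs
in well under a minute on a laptop core while leaving the forest enough
data to saturate on separable classes.

## Numerical choices and degenerate inputs

* Quartiles: type 7; the fence interval is closed on both ends.
* Round-half-up (`floor(x + 0.5)`) for per-class train allocation; R's
  built-in banker's rounding would break the published per-class counts.
* All randomized steps (fixture tables, splits, folds, forests, corpora)
  derive child seeds from one master seed and restore the caller's RNG
  state, so two runs with one seed agree exactly and library calls do not
  disturb user code.
* Degenerate guards: fewer than two lengths for the fence, empty genus
  sets, classes smaller than 2 (split) or than the fold count (tuning),
  single-class training, probability vectors with fewer than two classes,
  and non-finite feature values all raise immediate errors.

## Limitations

The mining rules are annotation-dependent and miss RBPs labeled
"hypothetical protein"; detecting those requires a trained detector outside
this package's scope. Real protein-language-model adapters are not bundled.
Per-phage aggregation of per-RBP predictions is out of scope (the method
maps RBPs, not phages, to hosts), as are whole-genome baseline feature
sets and structure-derived properties such as solvent accessibility.
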