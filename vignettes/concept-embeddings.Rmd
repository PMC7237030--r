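---
title: "Concept embeddings from annotated biomedical text: models, evaluation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concept embeddings from annotated biomedical text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Ordinary word embeddings trained on biomedical text learn one vector per
surface form, so `p53`, `TP53` and `tumor protein p53` end up as three
unrelated entries and a normalized database identifier has no entry at all.
`conceptvec` follows the concept-embedding strategy: named-entity
annotations over the corpus (genes, diseases, chemicals, mutations, species,
cell lines, each normalized to a database identifier) are substituted into
the token stream as single *concept tokens* such as `Disease_MESH_D008288`
or `Gene_2099`, and embeddings are then trained on the rewritten corpus.
Every annotated mention of an entity, whatever its surface form, contributes
to one vector per concept.

The package implements the full desk-scale pipeline:

1. **corpus construction** — parse PubTator-format annotated abstracts,
   resolve overlapping annotations, substitute concept tokens, emit
   sentence-per-line training text (`parse_pubtator()`, `resolve_overlaps()`,
   `tokenize_corpus()`);
2. **training** — four embedding objectives behind one fitting function,
   `train_embeddings()`: cbow and skip-gram with negative sampling, GloVe,
   and a fastText variant whose character n-grams are disabled for concept
   tokens;
3. **intrinsic evaluation** — the group-level similarity-difference
   statistic over related/unrelated concept sets built from interaction
   tables or gene-set files (`build_groups()`,
   `group_similarity_difference()`);
4. **extrinsic evaluation** — a protein–protein interaction (PPI) pair
   classifier and a five-class drug–drug interaction (DDI) sentence
   classifier (`train_ppi_model()`, `train_sen()`);
5. **synthetic data** — seeded generators with planted structure for every
   stage, so each component is testable against a known ground truth.

## Corpus construction

PubTator blocks consist of a `PMID|t|` title line, a `PMID|a|` abstract
line, and tab-separated annotation lines carrying 0-based, end-exclusive
character offsets. Two offset conventions circulate for the concatenated
title+abstract coordinate space — a newline separator and a space
separator — and the parser accepts both via `corpus_rules(dialect =)`;
the newline convention is the default. Every mention is checked against the
referenced text slice at parse time: a disagreement aborts with an
integrity error rather than silently corrupting the training text.

Overlapping annotations (nested mentions, double annotation by different
taggers) are resolved by a deterministic rule: longest span wins, ties
broken by earliest start, then by a fixed type priority
(Gene > Mutation > Chemical > Disease > CellLine > Species), then by
lexicographic identifier. The rule is idempotent and makes corpus
construction reproducible byte-for-byte, which the round-trip tests rely
on. A learned disambiguator could be substituted upstream without changing
any interface.

Non-concept text is lowercased and punctuation is mapped to token
boundaries (digits kept); concept tokens are emitted case-preserved, which
is what makes the `is_concept` flag recoverable by pattern even from a bare
word2vec text file. Sentence splitting is on by default — training windows
then never cross sentence boundaries — but whole-abstract windows are one
configuration flag away (`corpus_rules(split_sentences = FALSE)`), since
published pipelines are not explicit about which convention was used and
the choice measurably affects co-occurrence statistics at window 20.

## Training objectives

`training_config()` carries the shared hyperparameters, with defaults that
are the conventional choice for PubMed-scale concept embeddings: dimension
200, window 20, 5 negative samples, down-sampling threshold 0.001, minimum
count 5, learning rate 0.025, 10 epochs, n-grams of length 2–3. The
negative-sampling and down-sampling parameters apply to the word2vec-family
objectives only; the n-gram bounds to fastText only; GloVe adds its
weighting parameters `glove_xmax = 10`, `glove_alpha = 0.75`.

All four trainers run single-threaded in compiled code with an internal
xorshift generator, so a fixed seed gives bit-identical vectors — a
deliberate trade of wall-clock speed for exact reproducibility at desk
scale.

**Skip-gram / cbow.** For input representation $u$, positive output vector
$v^{+}$ and negatives $v^{-}_1,\dots,v^{-}_k$ drawn from the
unigram$^{0.75}$ noise distribution, the per-pair loss is

$$\ell = -\log\sigma(u \cdot v^{+}) - \sum_{j=1}^{k}\log\sigma(-u \cdot v^{-}_j).$$

`sgns_step()` exposes this step with its exact analytic gradients; the test
suite verifies them against central-difference numerics, and the trainer
implements the same mathematics. Two deliberate conventions follow the
reference word2vec implementation rather than the textbook gradient:
(i) the effective window per center position is drawn uniformly from
`1..window` (dynamic window shrinking); (ii) in cbow mode the full
accumulated input-side update is applied to every context vector rather
than the $1/n$-distributed analytic share — with the analytic share the
input vectors underfit badly at desk scale (the within/cross-cluster
separation on the reference synthetic corpus collapses from 0.998/0.731 to
1.000/0.998), while `sgns_step()` still reports the exact per-context
gradient (`update_per_context`) for callers who want it. Frequent tokens
are discarded per occurrence with keep probability
$\min(1, \sqrt{t/f})$ — the original formulation of the down-sampling rule.
The learning rate decays linearly over the total token budget with a floor
of $10^{-4}\,\mathrm{lr}$.

**GloVe.** `build_cooccurrence()` accumulates the symmetric,
distance-weighted ($1/d$) global co-occurrence matrix within sentences;
training minimizes
$f(x_{ij})\,(w_i \cdot \tilde w_j + b_i + \tilde b_j - \log x_{ij})^2$
with $f(x) = (x/x_{\max})^{\alpha}$ capped at 1, AdaGrad per-parameter
steps (accumulators initialized at 1), and a seeded shuffle of the pair
order each epoch. The analytic gradient includes the factor 2 (the
reference C implementation folds it into the learning rate); final vectors
are $w + \tilde w$.

**fastText with concept masking.** An ordinary word is represented as its
word vector plus the sum of its character n-gram vectors, where the n-grams
of the boundary-padded token `<word>` of lengths 2–3 are stored in an
explicit dictionary (no hashing buckets — exactness over memory at desk
scale). The full padded token is excluded from the n-gram set because the
word vector plays that role. For concept tokens the n-gram set is empty by
construction: a normalized identifier like `Gene_2099` is an atomic unit,
and sharing character n-grams between, say, `Gene_2099` and `Gene_2098`
would leak surface similarity between unrelated concepts. The contract is
exact: a concept's composed representation equals its stored word vector
element-wise, which the tests assert on trained models, not just on the
composition function. The input-side update is normalized by the number of
input vectors (word + n-grams), the reference implementation's convention;
without it the summed representation takes an effectively
$(1+|G|)$-times larger step and the epoch loss drifts upward on small
corpora. Out-of-vocabulary ordinary words back off to their known n-gram
sum; concept tokens never back off.

**Sum versus mean.** The composed fastText representation uses word vector
plus the *sum* of n-gram vectors. The convention had to be fixed for the
exactness tests; the masking contract is unaffected by the choice.

## Intrinsic evaluation

The statistic asks a simple question: does the embedding place concepts
that are known to be related (genes interacting with the same drug, genes
sharing a gene-set annotation) closer together than matched random sets?

For each entity, `build_groups()` forms a *related set* (its members
intersected with the shared-vocabulary universe, randomly capped at 100)
and an equal-size *unrelated set* sampled from the universe minus the
entity's full membership — the complement of the entity's membership is a
property of the entity, not of the capped sample. Entities with fewer than
two usable members yield no group, since no within-set pair exists.

All within-set pair cosines of a dataset are normalized together, once per
(dataset, embedding): Z-score standardization followed by min-max scaling
to $[0,1]$. Both transforms are affine, so the statistic is invariant under
positive affine transforms of the raw cosines — different embeddings with
different cosine ranges become comparable, which is the point of the
normalization. The normalization population is the pairs of one dataset
(not pooled across datasets); pooling would let one dataset's score range
distort another's, and a self-contained population keeps each dataset
reproducible in isolation. Each group contributes
`set_similarity(related) − set_similarity(unrelated)` (means over all
$\binom{n}{2}$ pairs), and the dataset-level metric is the group mean in
percentage points.

Two calibration checks accompany the statistic. With i.i.d. random unit
vectors and hundreds of groups the metric sits within a fraction of a
percentage point of zero (exchangeability null). The *shuffled baseline*
(`shuffled_baseline()`) permutes the concept-to-vector assignment over the
dataset universe and averages the metric over many permutations: a single
shuffle of an 8-group dataset has a Monte-Carlo standard deviation of
several percentage points, so the baseline is reported as a
permutation-null mean (200 permutations by default in the acceptance
script), which is the quantity an informative embedding must exceed.

## Extrinsic harnesses

**PPI.** A scored pair table (STRING `protein.links` dialect) is cleaned
(self-pairs dropped, unordered duplicates merged keeping the maximum score)
and filtered into positives by one of two modes: any positive combined
score, or experimental score *strictly* greater than 700. Negatives are an
equal-count seeded uniform sample of unordered in-vocabulary pairs absent
from the positive set. The split is stratified 63/7/30
(train/validation/test): 70% train–30% test with a 10% validation carve-out
of the training portion, the arithmetic that the published split counts
imply. Features are the concatenation $[v(p_1); v(p_2)]$ — the minimal
reading of "the two protein vectors as inputs"; symmetric compositions
(`sum`, `absdiff`) are available behind a flag since pair order is
arbitrary. The classifier is a feed-forward network with two hidden layers
(defaults 256/64, ReLU, dropout 0.2, Adam at $10^{-3}$, early stopping on
validation AUC); the published architecture specifies "two hidden layers"
and the remaining details are this package's defaults, all exposed as
arguments. AUC is computed by the rank (Mann–Whitney) formulation with
ties averaged, and the tests pin it to the quadratic ordering oracle.

**DDI.** Instances are sentences with two drug mentions and a label in
{mechanism, effect, advice, int, negative}, consumed as JSON-lines. The SEN
model averages the word vectors of the sentence (the embedder is pluggable:
any token→vector table works, so a contextual embedder can be substituted
by precomputing vectors), optionally concatenates the two drug concept
vectors, and applies a softmax network (default one hidden layer of 128,
dropout 0.3). Evaluation is positive-class micro-F1: counts are pooled over
the four positive classes only, a gold-negative instance predicted positive
is a false positive, a gold-positive predicted negative a false negative,
and negative–negative outcomes contribute nothing. Seed sensitivity is
handled by `repeated_runs()`: five consecutive seeds, arithmetic mean of
each metric, per-run values retained. Whether drug mentions should appear
in the token stream as surface forms or concept tokens is not settled in
the literature this pipeline follows; the synthetic generator emits concept
tokens (matching what the corpus rewrite would produce), and the data model
carries the concept ids separately either way.

## The synthetic-data generators

The generators are first-class, tested code, and their defaults are the
package's reference study condition:

* **corpus** — 8 clusters × 5 gene concepts, 2,000 documents × 3 sentences,
  4 concept slots and 6 filler words per sentence, within-cluster
  probability 0.8, filler vocabulary 200, seed 7. Each sentence picks a
  home cluster; each concept slot is filled from the home cluster with
  probability 0.8, else from a uniform other cluster. Fillers are drawn
  uniformly, so every filler clears the min-count filter and the vocabulary
  is stable. These sizes are the smallest at which all four trainers
  reliably recover the clusters in minutes on one CPU; the
  within-cluster probability must exceed 0.5 for the structure to be
  identifiable at all, and effect size grows monotonically with it (a
  property the tests check at 0.6 versus 0.9).
* **gene sets** — one GMT line per cluster, members = the cluster's concept
  tokens, so intrinsic evaluation on the generated sets has a known planted
  answer.
* **pair table** — within-cluster pairs scored 900, sampled cross-cluster
  pairs 100, straddling the 700 cutoff so experimental-700 filtering
  recovers exactly the within-cluster pairs.
* **DDI sentences** — balanced five-class templated sentences with two
  synthetic drug mentions. In trigger mode a class-specific token
  determines the label (sentence features suffice); in concept-dependent
  mode the label is `(group(drug1) + group(drug2)) mod 5` for a latent
  drug attribute and the trigger slot is random, so sentence-only features
  are uninformative on held-out drugs while concept vectors that encode the
  latent group (`ddi_concept_embedding()`) make the task fully learnable.

What the generators deliberately do *not* emulate: Zipfian token
frequencies, realistic sentence grammar, annotation noise (wrong spans,
wrong identifiers), polysemous mentions, or biologically meaningful
identifiers. Passing tests on this ground truth therefore demonstrate that
each component implements its contract and that the pipeline recovers
planted signal end to end — not that any particular performance level
carries over to real literature, whose headline numbers depend on corpus
scale and external databases outside this package's scope.

## Numerical and design notes

* All analytic gradients (`sgns_step()`, `glove_step()`, the fastText
  composition) are tested against central-difference numerics at
  $10^{-5}$ relative tolerance on batches of random instances; the random
  vectors are drawn small (sd ≈ 0.5) because saturated sigmoids degrade
  finite differences, not the analytic forms.
* Degenerate inputs fail loudly: zero-norm vectors in cosines, all-equal
  raw scores in normalization (zero variance), missing pair scores, single
  class labels in AUC, fully out-of-vocabulary names or sentences.
* Epoch-mean losses are monitored and returned in the fitted object; on
  the reference corpus they are non-increasing up to per-epoch resampling
  noise (under 1% at 600 sentences), and the tests assert at most one
  larger inversion.
* The problem sizes used by the tests and the acceptance script — the
  default synthetic corpus, a 16×16-cluster pair table for the PPI checks
  (so the permutation-null AUC band is tight), 60/30 instances per class
  for DDI, 250 groups for the null calibration — were chosen once as the
  smallest sizes at which the statistical checks have comfortable margins.
* `negative_sampler()` keeps its own RNG stream, so drawing negatives does
  not perturb the caller's random state; the compiled trainers likewise
  never touch R's RNG.
* Seeded functions (`build_groups()`, the generators, the classifiers)
  save and restore `.Random.seed`, so calling them does not silently
  reseed the session.

## Known limitations

* Training is single-threaded by design; the implementation targets
  desk-scale corpora (10⁴–10⁶ tokens), not the 10⁹-token regime of the
  full literature, for which streaming multi-worker tools are the right
  instrument.
* The fastText n-gram dictionary is explicit; hashing buckets for
  large-vocabulary corpora are out of scope.
* Hierarchical softmax, GPU training, quantization and retro-fitting are
  not implemented.
* The DDI harness consumes JSON-lines; converting a SemEval-style XML
  corpus is left to an upstream script and does not affect the data model.
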