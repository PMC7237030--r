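# conceptvec

Concept embeddings from NER-annotated biomedical literature, in R.

A plain word embedding has no entry for a normalized database identifier:
`p53`, `TP53` and `tumor protein p53` are three unrelated vectors and
`NCBI Gene: 7157` is none at all. `conceptvec` takes the concept-embedding
route instead: annotated entity mentions (genes, diseases, chemicals,
mutations, species, cell lines) are substituted into the training text as
single normalized *concept tokens* — `Disease_MESH_D008288`, `Gene_2099` —
and embeddings are trained on the rewritten corpus, so every mention of an
entity contributes to one vector per concept. The package is aimed at
biomedical text-mining work that needs trainable, evaluable concept vectors
at desk scale, with every stage testable against synthetic data with a
known planted answer.

It implements, end to end:

* **Corpus construction** — a PubTator-format parser with strict
  mention/offset integrity checking (both title–abstract offset dialects),
  deterministic overlap resolution, concept-token substitution and
  sentence-per-line corpus output.
* **Four trainers behind one fitting function** (`train_embeddings()`,
  returning a `concept_embeddings` object with `print`/`summary`/
  `predict`/`as.matrix`/`plot` methods): cbow and skip-gram with negative
  sampling, GloVe over the distance-weighted global co-occurrence matrix,
  and a fastText variant in which character n-grams are **disabled for
  concept tokens** so each normalized concept is learned as an atomic unit.
  Skip-gram/cbow loss per pair:
  `-log σ(u·v⁺) − Σⱼ log σ(−u·v⁻ⱼ)` with unigram^0.75 negative sampling;
  GloVe loss per cell: `f(x)(wᵢ·w̃ⱼ + bᵢ + b̃ⱼ − log x)²`,
  `f(x) = (x/xmax)^α` capped at 1. Compiled single-threaded inner loops,
  bit-reproducible for a fixed seed.
* **Intrinsic evaluation** — the group-level similarity difference: for
  groups of related concepts (genes sharing a drug interaction or gene-set
  membership) paired with equal-size random unrelated sets, pair cosines
  are Z-score + min-max normalized per dataset and the statistic is the
  mean of (related − unrelated) set similarity, in percentage points, with
  a permutation-shuffled baseline and a random-vector null for calibration.
* **Extrinsic harnesses** — balanced PPI pair datasets from STRING-style
  scored tables (combined-score or strict experimental>700 positives,
  stratified 63/7/30 splits) classified by a two-hidden-layer feed-forward
  network over concatenated concept vectors; and five-class DDI sentence
  classification (mechanism / effect / advice / int / negative) with an
  averaged-sentence-embedding network, optional drug concept vectors,
  positive-class micro-F1 and five-seed averaging.
* **Synthetic generators** — seeded PubTator corpora with planted concept
  clusters, cluster-derived GMT gene sets, scored pair tables straddling
  the 700 cutoff, and templated DDI sentences (trigger-determined or
  drug-concept-determined labels).

## Worked example

Generate an annotated corpus with eight planted gene clusters, train
skip-gram concept embeddings, and check that the embedding separates
related from unrelated genes:

```r
library(conceptvec)

# 1. a PubTator-annotated corpus with planted cluster structure
config <- synth_config()          # 8 clusters x 5 gene concepts, 2,000 docs
docs   <- parse_pubtator(generate_corpus(config))
corpus <- tokenize_corpus(docs)
print(corpus)
#> <concept_corpus: 8000 sentence(s), 66000 token(s), 24000 concept token(s)>

# 2. train skip-gram concept embeddings
model <- train_embeddings(corpus, "skipgram", training_config(seed = 11))
print(model)
#> Concept embeddings (skipgram): 242 tokens x 200 dimensions
#>   concept tokens: 40; ordinary words: 202
#>   final mean epoch loss: 2.6137 (10 epochs)

# 3. concept vectors and cosines
genes <- synth_concepts(config)
v <- predict(model, genes$token[1:2])        # two concepts, same cluster
cosine_similarity(v[1, ], v[2, ])            # 0.981
w <- predict(model, genes$token[c(1, 40)])   # different clusters
cosine_similarity(w[1, ], w[2, ])            # 0.365

# 4. intrinsic evaluation: gene sets = the planted clusters
gmt <- tempfile(fileext = ".gmt"); generate_gene_sets(config, gmt)
groups <- build_groups(read_gmt(gmt), universe = genes$token, seed = 5)
group_similarity_difference(groups, model)$metric      # 75.7
shuffled_baseline(groups, model, n_perm = 200, seed = 6)$metric  # -0.30
```

The group similarity difference of ~76 percentage points says that, after
normalizing all pair cosines to [0, 1], related gene sets score on average
0.76 higher than matched random sets — while the label-shuffled baseline
sits at zero, as it must for any embedding. Embeddings loaded from
word2vec text files (`load_embeddings()`) drop into the same evaluators.

A thin command-line front end over the same functions is installed at
`inst/cli/conceptvec` (subcommands `build-corpus`, `train`,
`eval-intrinsic`, `eval-ppi`, `eval-ddi`, `synth`).

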