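---
title: "Methods: knowledge-graph classification and ranked explanation of variant pathogenicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: knowledge-graph classification and ranked explanation of variant pathogenicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its model and the design choices
behind it: what is computed, under which assumptions, which parameters
matter, and what the synthetic benchmark does and does not demonstrate.

## The problem and the data model

Deciding whether a single-nucleotide missense variant is pathogenic is the
hard case of clinical variant interpretation: the evidence is scattered
across databases with different schemas (assertions with confidence grades,
tumor registrations with sample counts, per-algorithm damage scores), and a
defensible call must cite that evidence, not just a score. `kgxplain`
therefore keeps the evidence as a graph all the way through. Each
annotation record becomes a typed node with literal children for its
fields; every record attaches to a canonical *variant hub* keyed by
`chrom:pos:ref>alt` (1-based, fully closed coordinates, uppercase alleles,
no `chr` prefix), and variant hubs attach to *gene hubs*. Hubs are the join
points: two databases that mention the same variant meet at its hub without
any schema alignment. Triples are stored with set semantics — re-asserting
an existing triple is a no-op — so triple counts are well defined.

Reachability in this graph follows edge direction, except that hubs are
crossed ignoring direction. Records point *to* their hub; to get from a
variant to the records of a neighboring variant one must travel
record-to-hub against an edge once. This single rule is what makes "all
nodes directly or indirectly referenced by the variant" a useful
explanation subgraph.

## Feature subgraphs and the two modes

The classifier never sees the whole graph; it sees a per-variant *feature
subgraph*: the target's permitted records, the ClinVar and COSMIC records
of every variant within 100 bases on the same chromosome (inclusive bound —
a neighbor at exactly 100 bases counts; a different allele at the same
position is a neighbor at distance 0), and explicit neighbor links that
carry the base-pair distance. Neighbor expansion is one hop: neighbors of
neighbors are not pulled in, because the neighborhood is evidence *about
the locus*, not a transitive closure.

Two modes exist because the training labels come from ClinVar:

* **estimation** — the mode whose accuracy is measured. The target's own
  ClinVar records are excluded (they encode the label), its dbscSNV splice
  scores are excluded, and its dbNSFP scores are restricted to six
  algorithms that are not themselves trained on ClinVar (SIFT, LRT,
  PROVEAN, phyloP100way_vertebrate, GERP++_RS, SiPhy_29way_logOdds).
  Ensemble meta-scores such as REVEL or MetaLR would leak the label back in
  (type-1 circularity) and are only available to the explanation model.
  Neighbor ClinVar records remain: a *different* variant's assertion is
  legitimate evidence.
* **explanation** — everything is admitted, because an explanation should
  cite the ClinVar assertion when one exists. To prevent the explanation
  model from collapsing onto "ClinVar says so" — which would leave it
  mute for unlisted variants — training applies a half-masking plan:
  exactly half (floor) of the training variants, chosen uniformly under a
  seed, have their own ClinVar records withheld.

## The classifier

The deep graph learner this design targets is proprietary; the package
defines the *contract* (train / predict / attribute) and ships two
reference backends:

* `graph_kernel_logistic` (default): each edge is reduced to a token —
  role (target-side or neighbor-side), subject node type, predicate, and
  the literal value for categorical fields — hashed into 512 buckets;
  numeric literals contribute their value (stars scaled by 1/4, submission
  counts log1p, sample counts log10/5, years centered on 2000) and
  everything else contributes 1. The graph vector is the sum over edges,
  and a ridge-penalized logistic regression (glmnet) sits on top. The
  model is linear in edge features by construction, which makes the
  attribution below exact rather than approximate. Fully deterministic.
* `gnn`: a randomized message-passing network — node states initialized
  from hashed node tokens, two rounds of undirected neighborhood averaging
  through fixed random projections drawn from the seed, tanh nonlinearity,
  mean-pool + target-hub readout into the same logistic head. It exists to
  show the contract supports a nonlinear graph backend; it is not tuned.

The capacity knob swept by the evaluation protocol is `epochs`: for the
logistic backend it relaxes the penalty as `lambda / sqrt(epochs)`, so the
sweep traces the same under/over-fitting axis a training-epoch sweep would.
Scores are the logistic response, inherently in [0, 1]; no further
calibration is applied and only rank-consistency is claimed for AUC. A
score of 0.5 or more is called pathogenic — the boundary itself is
pathogenic, and the threshold is a config field, not a constant scattered
through the code.

## Attribution and the explanation layer

Edge contributions are estimated by local surrogate regression (the LIME
idea specialized to edge masking): draw masks over the subgraph's edges,
re-score each masked graph, and regress the score on mask indicators. When
`2^E` fits within the perturbation budget (default 256) the full factorial
is enumerated and the fit is plain least squares — for a balanced factorial
each weight equals `mean(score | edge on) − mean(score | edge off)`, which
is also the independent oracle the tests use. Otherwise 256 uniform random
masks are drawn under the seed and a small ridge penalty (1e-3) stabilizes
the fit. Positive contribution pushes toward pathogenic.

Nodes inherit the signed maximum-magnitude contribution among their
incident edges. For a single-edge graph this makes node and edge
contribution equal, the identity the design is anchored to; among the
alternatives (sum, mean — both selectable) max-magnitude was chosen because
it preserves that identity and never double-counts an edge through both
endpoints.

Ten declarative rules (X-Rules) turn the explanation subgraph into
sentences: the target's ClinVar assertion with stars and submissions, its
COSMIC registration, per-algorithm and averaged dbNSFP scores, outstanding
algorithms with qualitative bands, neighbor tallies, same-base assertions,
literature references, and the variant type. Each rule is a matcher
(returning node sets with bound slots) plus a renderer. Renderers are
per-rule functions rather than a generic template engine because the
reference wording they reproduce is irregular: counts appear as hyphenated
English words in some rules and digits in others, sentence-initial counts
are capitalized, one rule uses typographic quotes and another straight
quotes. Score slots print to 2 decimals; qualitative bands are high ≥ 0.70
and moderate in [0.50, 0.70), scores below 0.50 are omitted — consistent
with every printed example. Where several neighbor significances compete,
the rule reports the most severe one present (Pathogenic before
Likely_pathogenic before VUS before Likely_benign before Benign), which is
what a clinician would ask about first.

Each sentence's relevance is

```
X-Factor = sigmoid(X-Contribution × X-Impact)
```

with the contribution aggregated over the sentence's supporting nodes
(max-magnitude again, consistent with the node rule) and the impact taken
from a per-node-type importance table. Published impact values do not
exist, so the defaults encode one ordinal judgment — a database listing
itself is important — as clinvar_record 2.0, cosmic_record 1.5,
dbnsfp_score 1.0, publication 1.0, baseline 0.5, all overridable in code or
YAML. Sentences are returned in descending X-Factor order (ties: rule
order, then text; the alternative ascending reading of the sort would put
the least relevant sentence first and was rejected), truncated to `top_n`.
Note the monotonicity caveat: raising a node type's impact promotes only
its positively-contributing sentences; for negative contributions the
sigmoid moves the other way, which is correct behavior (stronger emphasis
on exculpatory evidence should rank it as such).

## Evaluation protocol

The estimation answer set filters ClinVar records to review status ≥ 2
stars (multi-submitter agreement), definite Pathogenic/Benign assertions
(Likely_* and VUS excluded), and missense consequence. The explanation
answer set trades purity for volume: Likely_* map to their parent label and
all SNV consequences are admitted, with no star filter. Classes are
balanced by uniform seeded downsampling of the majority class only.

Cross-validation is chromosome-disjoint: chromosomes are packed into five
folds greedily (largest variant count first into the lightest fold — the
packing heuristic is a choice; any chromosome-preserving partition would
satisfy the protocol), every variant inherits its chromosome's fold, and
each fold's train/test chromosome sets are intersected before training —
overlap is a hard error, not a warning. This prevents the same-gene
memorization that random folds permit. Metrics are accuracy, precision,
recall and F1 at the 0.5 threshold with pathogenic positive, plus AUC via
the Mann–Whitney rank statistic with midrank tie handling (cross-checked in
the test suite against pROC and a brute-force all-pairs count). The
reported threshold-based metrics use 0.5 per the decision rule, not a
per-fold optimized threshold. The sweep harness re-runs the whole CV per
capacity value (epochs for the graph model, depth for rpart trees and
ranger forests) and reports the best mean accuracy.

## The synthetic benchmark

The generator emulates the statistical structure the feature set assumes,
with every knob tunable and the defaults defining the benchmark
conditions:

* ~2000 variants (10 chromosomes × 5 genes × 40 variants), gene loci 10^6
  bases apart, intra-gene gaps clumped (≤ 60 bases with probability 0.5,
  else 150–600) so 100-base neighborhoods are well populated; 3% of
  variants are second alleles at an existing base, exercising distance 0.
* labels drawn along each gene in position order with marginal pathogenic
  fraction 0.5; a variant within 100 bases of its predecessor is boosted to
  p + c(1−p) after a pathogenic one and damped to p(1−c) after a benign
  one (c = 0.5 by default). The symmetric form keeps the marginal exactly
  p, so clustering strength and class balance are independent dials.
* dbNSFP scores Beta-distributed (precision 8) with benign mean 0.40 and
  pathogenic mean 0.40 + separation (default 0.3) — bounded support matches
  rank-style scores; COSMIC sample counts log-uniform over 0–2 decades
  with a pathogenic exponent boost of 4 × separation × U(0,1), a heavy-tail
  analog of recurrence; ClinVar significance equals the true label with 5%
  noise, definite/likely/VUS in proportions 0.7/0.2/0.1, stars 0–4 with
  75% at ≥ 2; coverage per source 0.9/0.6/0.95/0.3.

Tying the COSMIC class shift to the score-separation dial is deliberate:
at separation 0 and clustering 0 *every* feature is uninformative by
construction, and the full pipeline's CV AUC sits at 0.5 — the global
negative control that no leakage path (through folds, features, or
bookkeeping) exists. Under the default planted signal, chromosome-disjoint
CV reaches mean AUC ≈ 0.92 for the graph classifier and ≈ 0.95 for the
forest baseline at these problem sizes (n ≈ 2000 generated variants,
~650 answer-set variants after filtering and balancing).

What passing these benchmarks does *not* show: real annotation data has
correlated algorithm scores, gene-level effects, population-frequency
structure and ascertainment bias that the generator does not emulate
(scores are conditionally independent given the label; genes are
exchangeable). The synthetic results validate the machinery — leakage
guards, feature plumbing, attribution, ranking — not clinical performance.

## Numerical and degenerate-input choices

* Hash collisions: 512 buckets over a vocabulary of a few hundred tokens;
  collisions merge features rarely and deterministically. The bucket map is
  cached per dimension.
* Score payloads are serialized with `%.17g`, so graph round trips through
  N-Triples or TSV are bit-exact for doubles.
* N-Triples: non-literal nodes carry id/type/provenance/value inside
  percent-encoded IRIs; literal leaves serialize as RDF string literals and
  are re-identified as `subject/predicate` on read. This supports exact
  round trips under the package's own construction convention (one literal
  child per record and field); isolated nodes need the TSV dialect.
* A hub-only feature graph (no annotations, no neighbors) is valid
  everywhere: it scores (at the model's intercept), flattens to the
  all-sentinel vector, and explains to at most the variant-type sentence.
* Missing numeric features in flattened vectors encode as −1; tree splits
  isolate the sentinel naturally. Distance bins default to 1–10, 11–25,
  26–50, 51–100 (per-base bins are configurable but multiply the schema by
  25 for little gain on desk-scale data).
* The two ClinVar cross features (consequence × significance, and
  consequence × star-band × significance) are the only generated
  interactions; star bands collapse to ≥ 2 vs < 2, the boundary the answer
  set itself uses.
* Sweep grids default to epochs 1–100 and depth 1–30.

## Known limitations

* The explanation model's contributions are local to one variant's
  subgraph; contributions are not comparable across variants.
* Impact defaults are an editorial choice, not fitted quantities; X-Factor
  rankings shift under other choices (by design — the table is the
  physician-preference input).
* The logistic backend cannot represent interactions between edges;
  attribution on the gnn backend is approximate where the factorial cannot
  be enumerated.
* Multi-allelic normalization, liftover, transcript-aware distances and
  haplotype phase are out of scope; neighbor distance for indels uses the
  leftmost reference position.
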