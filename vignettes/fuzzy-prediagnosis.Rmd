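---
title: "Fuzzy inference for canine pre-diagnosis: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy inference for canine pre-diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prediag)
```

## The problem

A casual dog owner notices abnormalities — tearing eyes, itching, coughing —
and wants an early hint of which diseases could explain them before seeing
a veterinarian. The input is inherently noisy: owners are untrained
observers, and a dog with a compound disease will have all its symptoms
attributed to one cause. `prediag` therefore treats pre-diagnosis as
*ranked retrieval under query corruption*: given a list of
(observed part, symptom) pairs, return the five most plausible diseases,
and evaluate engines by how slowly their accuracy decays as relevant query
symptoms are replaced with unrelated ones.

Two distinct body-part vocabularies structure the knowledge base. The
*observed part* (16 values: eye, skin, feces, breathing, ...) is where the
owner noticed the symptom; the *appeared part* (12 values: body systems in
the clinical classification) is where a disease manifests. The inference
engines reason in the appeared-part vocabulary, so a total map
observed → appeared is a required input. No published correspondence
between the two vocabularies exists, so we require it as an explicit
sixth table rather than guessing it; the synthetic generator emits a
random surjective map.

## The membership primitive

Every weight system reduces to the fuzzy c-means membership of a point
with distances $d_1, \dots, d_c$ to $c$ centroids:

$$u_i = \frac{1}{\sum_{j=1}^{c} \left(d_i/d_j\right)^{2/(m-1)}}$$

with fuzzifier $m > 1$. Memberships are non-negative and sum to one. When
the point coincides with one or more centroids, the unit membership is
split equally among the coincident clusters — the standard convention that
also removes the division by zero. The fuzzifier is nowhere prescribed for
this application, so we default to $m = 2$, the universal fuzzy-c-means
choice, exposed in `fuzzy_config()`.

## MNFL

The multi-layered neuro-fuzzy learner scores a query in four stages.

**W1 — symptom relevance.** Each symptom $s$ is placed at
$x = n_D(s)/N_D$ (fraction of diseases carrying it) and
$y = n_P(s)/N_P$ (fraction of the appeared-part vocabulary spanned by
those diseases). A rare, focused symptom sits near $(0,0)$ — the
*related* centroid — and a ubiquitous one near $(1,1)$, the *unrelated*
centroid. $w^{(1)}_k$ is the two-cluster membership to $(0,0)$.
Normalizing by the total disease count $N_D$ and the vocabulary size
$N_P$ keeps both coordinates in $[0,1]$, consistent with those centroids.

**W2 — part-consistent connection.** The query symptom's observed part is
mapped to an appeared part $p$. Every disease on a *different* part
receives the fixed penalty weight $-0.5$: the place the owner pointed at
is not where the disease manifests, and the weight is deliberately
negative so such evidence subtracts from the disease's activation instead
of merely not adding. Diseases on part $p$ share one unit of membership,
computed from the Euclidean distance between the symptom's one-hot
indicator and each candidate's L1-normalized symptom profile — the
connection is strongest to diseases in which the symptom is most
specific. The published description names the distance but not the
embedding; this profile embedding is our reconstruction, chosen because
it reproduces the stated behavior (zero membership exactly on part
mismatch, higher membership for diseases where the symptom is more
diagnostic) with a genuine Euclidean distance. Whether that space is one-
or two-dimensional cannot be determined from the description alone.

**N3 — activation.** $y_z = \frac{1}{n}\sum_{i=1}^{n} w^{(1)}_i
w^{(2)}_{zi}$ over all $n$ query symptoms (penalty terms included; an
alternative reading sums only part-matched symptoms, but including the
penalties lets erroneous input dilute the score honestly, which is the
design's stated purpose). A disease is *activated* iff $y_z > 0$,
strictly.

**W3 — neighborhood refinement.** For each activated candidate target
$t$, each activated disease $z$ is placed at

$$x_z = 1 - \frac{|S_z \cap S_t|}{\max(|S_z|, |S_t|)}, \qquad
  y_z = 1 - \frac{\,\bigl||S_z| - |S_t|\bigr|\,}{\max(|S_z|, |S_t|)},$$

so $z = t$ lands exactly on the target centroid $(0, 1)$; the
anti-centroid is $(1, 0)$. (The axes are oriented so that shared symptoms
and equal set sizes move a disease *toward* the target; two empty symptom
sets are treated as identical.) The final score of $t$ is the mean of
membership-weighted activations over the $n_{\mathrm{act}}$ activated
nodes. Rankings sort by descending score, break ties by ascending disease
id (deterministic), and truncate to five. An empty activated set yields
an empty ranking — "no inference possible" — rather than an arbitrary
guess.

## FHAL

The hybrid fuzzy association learner is a three-layer associative
network: symptoms → appeared parts → diseases, plus a direct
symptom → disease shortcut. The weight constructions (the originals are
published elsewhere; these are reconstructions from the description):

* $w_1[s,p]$ — fraction of the diseases carrying $s$ that appear on part
  $p$ (rows of occurring symptoms sum to 1);
* $w_2[p,z]$ — disease $z$'s share of part $p$'s symptom mass
  ($|S_z| / \sum_{z' \text{ on } p} |S_{z'}|$);
* $w_3[s,z] = 1/|S_z|$ if associated, else 0.

At query time the dominant part $p^\ast$ maximizes the accumulated first-
layer support $A_p$ (ties to the smaller part id), and a query symptom
survives only if $w_1[s,p^\ast] \ge \tau \cdot A_{p^\ast}/n$ — that is,
$\tau$ times the query's mean support on the dominant part. The
"relatively high association" cut is not quantified in the description;
$\tau = 0.5$ is the default and is configurable. The final score blends
$\alpha \cdot \mathrm{direct} + (1-\alpha) \cdot \mathrm{indirect}$ with
$\alpha = 0.5$; if everything is filtered the engine falls back to the
direct path (with a message). The second layer uses matrices precomputed
once per knowledge base rather than re-clustering per query: the
description leaves this open, and precomputation is deterministic and
fast.

## PFCM-R

The possibilistic fuzzy c-means family blends constrained memberships
$u$ with unconstrained typicalities $t$. The exact regularized objective
is published only in the original reference, so `pfcm_r_fit()` implements
the reconstruction

$$J = \sum_{ij}\bigl(a\,u_{ij}^m + b\,t_{ij}^\eta\bigr) d_{ij}^2
    + \sum_j \gamma_j \sum_i (1 - t_{ij})^\eta
    + \lambda \sum_{ij} u_{ij}^m$$

with defaults $a = b = 1$, $m = \eta = 2$, $\lambda = 0.1$. The
$\lambda$-term (quadratic in memberships at $m = 2$) folds into the
membership update as an additive distance offset
$\tilde d^2 = a d^2 + \lambda$, so every alternating update — memberships,
typicalities, centroids — is the exact minimizer of its block and the
objective trace is non-increasing by construction (asserted to $10^{-9}$
in the tests). $\gamma_j$ is initialized from an FCM pre-pass as the
within-cluster mean fuzzy squared distance; centroids are initialized by
seeded k-means++-style draws. With $b = 0$ and $\lambda = 0$ the model
reduces exactly to FCM.

As an inference engine, free clustering is not meaningful — the "clusters"
are the diseases — so `pfcmr_infer()` scores the query against *fixed*
prototypes: each disease's binary symptom profile and the query's
indicator are scaled to unit Euclidean norm (equal-norm embeddings make a
query orthogonal to every disease exactly equidistant from all
prototypes, so degenerate queries fall back to id order instead of being
biased toward large diseases), and
$\mathrm{score}_z = a u_z + b t_z$ with the typicality scale $\gamma$
fixed at the mean squared inter-prototype distance — a property of the
knowledge base, precomputed at construction.

## The noise protocol

For each target disease with at least `min_symptoms = 5` registered
symptoms, a Noise0 query of 5 of its symptoms is sampled uniformly (the
full set if it has exactly 5; whether the original experiment sampled or
fixed the five is unstated, so we sample, seeded). Level $L{+}1$ replaces
one uniformly chosen remaining relevant symptom with a uniform draw from
the symptoms *not* associated with the target — noise may belong to other
diseases or to no disease, since only "unrelated to the target" is
specified — so Noise3 holds 2 relevant and 3 unrelated symptoms and the
relevant sets are strictly nested across levels. Accuracy is the percent
of targets whose ranking contains the target in the top 1 (top 3),
averaged over replicates. The reference protocol evaluates exactly 50
target diseases; because the default synthetic base makes far more than
50 diseases eligible, `noise_protocol()` takes a seeded uniform subsample
of `n_targets = 50` (set `n_targets = NULL` to use all). Replicates
(default 1, mirroring the original single pass) enable the statistical
assertions; the protocol-scale checks use 10.

## The synthetic generator

No public symptom–disease database for this task exists, so
`generate_kb()` emulates the structural statistics the reference database
reports: 241 symptoms uniformly spread over 16 observed parts, 249
diseases over 12 appeared parts, a random surjective part map, and
per-disease symptom counts drawn uniformly from 3..12 — a range chosen so
that a clear majority of diseases support the 5-symptom protocol while
short profiles still occur. Each disease draws a fraction
$1-\rho$ of its symptoms from the pool whose observed part maps to its
own appeared part and $\rho = 0.2$ from elsewhere; cross-part
contamination is a real feature (diseases present symptoms away from the
primarily affected system) and 0.2 keeps queries predominantly
part-consistent without making part information infallible. Generation
retries with derived sub-seeds until at least 50 diseases have ≥ 5
symptoms (with the default range this virtually always holds on the first
draw). `generate_disjoint_kb()` builds the deliberately easy oracle
fixture — pairwise-disjoint, part-consistent symptom blocks — for which
the unique maximal-overlap disease of any clean query is its target.

What the generator does *not* emulate: real co-occurrence structure
(symptoms shared by clinically related diseases), frequency skew of
common symptoms, or clinical text. Passing benchmarks on synthetic bases
therefore demonstrate protocol correctness and relative engine behavior
under controlled noise, not clinical accuracy — the published accuracy
tables depend on a non-public textbook-derived database and are out of
reach by design.

## Numerical choices and edge cases

* Zero distances in any membership computation: equal split among
  coincident centroids.
* Ranking ties: ascending disease id, making every engine deterministic.
* Diseases with zero symptoms have zero profiles; they sit at distance 1
  from any one-hot symptom and never outrank a genuine candidate.
* Empty candidate set on a mapped part: all connections for that symptom
  are penalized (logged via `message()`).
* All benchmark randomness flows from `noise_protocol(seed)`; engines are
  deterministic given the knowledge base, so reports reproduce
  byte-identically under a repeated seed.
* Problem sizes in the test suite: the protocol-scale check runs the
  default 241 × 249 base with 50 targets, 4 levels, 10 replicates, all
  three engines (≈ 6000 inferences); clustering sanity uses 100 random
  40-point data sets and 5 planted-blob recoveries.

## Known limitations

* **MNFL at dense scale.** On the default synthetic base each appeared
  part hosts ≈ 21 diseases, so W2's candidate-normalized memberships are
  of order $1/21 \approx 0.05$ while a single part-mismatched symptom
  contributes a fixed $-0.5$. One cross-part symptom in a query (common
  at $\rho = 0.2$, and guaranteed for noisy levels) therefore deactivates
  most candidates, and MNFL frequently returns an empty or tiny ranking:
  its absolute accuracy on dense synthetic bases is far below the other
  engines, although it still satisfies every protocol property (monotone
  degradation, top-3 ≥ top-1) and recovers 100% of targets on the
  disjoint oracle base. The behavior is a consequence of composing the
  fixed −0.5 penalty with candidate-set-normalized memberships at this
  density; on sparse bases (few symptoms per disease, few diseases per
  part) the memberships concentrate and the engine behaves as described
  in its source. We keep the reconstruction faithful rather than
  rescaling the penalty, and flag the density sensitivity here.
* The observed→appeared part map is required, not learned; a wrong map
  silently degrades every part-aware engine.
* `pfcm_r_fit`'s k-means++-style initialization can seat a centroid on an
  extreme outlier (as any such initialization can); the typicality
  robustness property holds when the planted clusters own the centroids.
* Engines are untrained by design: all weights derive from knowledge-base
  counts, so nothing protects against a systematically mislabeled base.
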