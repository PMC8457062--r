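---
title: "Beam-search design and scoring with chemical language models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beam-search design and scoring with chemical language models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its methods: the model and its
assumptions, the decoding algorithms and their exact semantics, the
numerical and design choices that were genuinely open, what the synthetic
data emulate, and what the tests do and do not establish.

```{r setup, message = FALSE}
library(beamchem)
```

## The model

A chemical language model (CLM) factorizes the probability of a SMILES
string $s = (s_1, \dots, s_T)$ autoregressively,

$$p(s) = \prod_{t=1}^{T} p(s_t \mid s_1, \dots, s_{t-1}),$$

over a token alphabet built from the training corpus (bracket atoms,
`Cl`/`Br` and `%NN` ring labels as single tokens; all other characters as
single tokens; `BEGIN`/`END` delimiters, `PAD` for batching). The
conditional distributions come from a stacked LSTM: token embeddings feed
recurrent layers whose final hidden state is projected to a softmax over
the vocabulary. Training is teacher-forced maximum likelihood — the mean
per-token cross-entropy in nats — with Adam and global-norm gradient
clipping (at 5) for stability.

The LSTM is implemented in the package itself as vectorized base-R matrix
code: a batched forward pass, full backpropagation through time, and the
optimizer, in about two hundred lines. Two properties motivated writing
it this way rather than binding to an external framework: the decoder
needs cheap stateful single-token stepping for beam search, and the test
suite needs bit-level reproducibility across runs in the same session.
The backward pass is verified against central finite differences in
`test-clm.R`; the agreement is at the 1e-10 level on every parameter
block, so behavioural tests can attribute failures to modelling rather
than calculus.

### Defaults and their rationale

| Parameter | Default | Why |
|---|---|---|
| `num_layers` | 2 | the conventional depth for SMILES CLMs |
| `hidden_units` | 256 | full-scale width; tests and examples use 64 |
| `embedding_dim` | 64 | ample for vocabularies of 20–50 tokens |
| `learning_rate` | 0.005 | Adam; stable across the fixture corpora |
| `batch_size` | 32 | CPU-friendly; one update per 32 sequences |
| `max_length` | 140 tokens | covers drug-like SMILES; longer training strings are skipped, decoding stops here |
| seed | explicit | fixes initialization and shuffling; runs are exactly reproducible |

The full-scale campaign the package's protocol mirrors — pre-training on
365,063 bioactive molecules for 10 epochs, fine-tuning 20 epochs on 255
target ligands and then 16 epochs on 4 template molecules, beam sampling
over fine-tuning epochs 5–16 — is recorded as documentation constants in
`full_scale_defaults()`. Tests and the acceptance script run scaled-down
analogues (a 500-molecule synthetic pre-training corpus; 10–20 molecule
fine-tuning families), sizes chosen so the whole suite completes in
minutes on one CPU while still exhibiting the phenomena of interest:
memorization, transfer-learning bias, and cross-epoch pooling.

Fine-tuning freezes the vocabulary of the initial checkpoint. A
fine-tuning corpus containing unseen tokens is an explicit error listing
them — silently extending the vocabulary would invalidate the embedding
and softmax dimensions of every earlier checkpoint and make cross-stage
score comparisons meaningless.

## Beam search semantics

`beam_search()` is deterministic k-best decoding. At each step every live
hypothesis is expanded with every positive-probability token; expansions
ending in `END` move to a **completed pool**, and the `width_k` best
*incomplete* expansions (by cumulative log-probability) survive to the
next step. Three semantic details deserve emphasis because they are easy
to get subtly wrong:

* **Completed hypotheses do not consume beam slots.** Every `END`
  extension of a live hypothesis is archived, whatever its rank among the
  step's candidates. This is what the worked example requires: with
  $p(a)=0.5$, $p(b)=0.3$, $p(\mathrm{END})=0.2$ and $k=2$, the empty
  completion (probability 0.2) must be returned as the top design even
  though `END` is never among the two best continuations. The pool can
  therefore contain up to `width_k × max_length` strings, many of them
  low-probability early terminations — see the note on validity below.
* **No length normalization by default.** The beam score is the raw
  product of token probabilities, which systematically favours short
  strings. That bias is part of the method being implemented; an opt-in
  `length_normalize` flag ranks by per-token log-probability instead.
* **Deterministic tie-breaking.** Equal log-scores are ordered
  lexicographically by token-index sequence, so rankings are identical
  across platforms and runs. Hypotheses still alive at `max_length`
  without `END` are dropped (or returned flagged, with
  `keep_truncated = TRUE`).

Scores are accumulated in log space — the probability of a 60-token
string underflows double precision as a raw product — and every returned
score is re-verified against a fresh stepwise evaluation of the model
(`verify = TRUE`), which guards the beam bookkeeping against the model
interface.

Because toy models (`make_toy_model()`) expose exact conditional tables,
the decoder is tested against brute-force enumeration
(`enumerate_completions()`): with a beam wide enough to hold every
prefix, beam search must reproduce the enumeration ranking exactly, and
with narrow beams it must return order-consistent subsets. Those checks
run over dozens of randomly seeded i.i.d. and first-order-Markov models
in the suite.

A consequence of the archive-everything pool worth stating plainly: width-1
beam search is *not* literally the greedy argmax walk. The live path
follows the argmax over continuation tokens, while greedy decoding
(argmax including `END`) corresponds to one particular entry of the pool
— always present, with its exact score, but not necessarily ranked first,
because an earlier `END` can have higher raw probability. The temperature
sampler at $T \to 0$ reproduces the greedy walk, and the tests assert
exactly these relationships.

## Temperature sampling

The stochastic baseline draws tokens from $p^{1/T}$, renormalized, with
the temperature computation done in log space so that $T = 10^{-6}$ is
numerically exact argmax rather than overflow. Sampling is seeded and
restores the caller's RNG state. At $T = 1$ the first-token frequencies
over 10,000 draws are required (in the tests) to match the model's
probabilities within three binomial standard errors — a calibration check
rather than a distribution test, deliberately tolerant of simulation
noise.

## The design pipeline

`run_schedule()` executes fine-tuning stages sequentially, each
initialized from the previous stage's final checkpoint, decodes every
final-stage checkpoint in the sampling window, and pools the results.
The window starts at epoch 5 by convention: decoding earlier checkpoints
of a small fine-tuning set mostly samples the pre-training distribution.
`filter_and_rank()` then:

1. drops strings that fail chemical-validity parsing (counted, never
   thrown);
2. canonicalizes survivors;
3. merges duplicate molecules, keeping the **maximum** log-score and its
   epoch — scores from different checkpoints are pooled and compared
   directly, and a molecule's best score is the natural summary when the
   same structure is rediscovered at several epochs (the merge policy is
   a declared choice; ranking raw occurrences instead would multiply-count
   memorized structures);
4. flags molecules whose canonical form occurs in any training corpus
   (`is_novel = FALSE`) but **retains** them, so the memorization rate is
   reportable — in a strongly fine-tuned CLM the top of the ranking is
   *expected* to reproduce the fine-tuning set, and hiding that would
   hide the main diagnostic of fine-tuning success;
5. assigns ranks by descending score with the decoder's deterministic
   tie policy (lexicographic on canonical SMILES between equal scores).

Counts are conserved by construction (`raw = valid + invalid`,
`valid = unique + duplicate-merged`) and asserted in the tests, as is
byte-identical reproducibility of the ranked CSV across repeated seeded
runs.

### Validity dialect

A string counts as a valid molecule when (a) it passes a structural
well-formedness screen — balanced parentheses and every ring-closure
label opened and closed — and (b) Open Babel parses it under its default
valence model, with one tightening: molecules whose aromatic system
fails kekulization are rejected rather than accepted in Open Babel's
radical-"repaired" form (a lone aromatic carbon, for instance, would
otherwise silently become a methyl radical). The pre-screen exists
because Open Babel quietly repairs some malformed inputs (unbalanced
parentheses) that should count as invalid generations. Open Babel
remains more permissive than other toolkits — it kekulizes aromatic
chains into polyenes, for example — and the validity report records the
dialect string alongside the counts.

At desk scale the pipeline's raw validity fraction is low (a few per
cent) and should be read with the pool semantics in mind: most pool
entries are early-`END` truncations of aromatic prefixes, which are
syntactically incomplete almost by construction. The ranked unique
designs, not the raw pool, are the method's output.

## Descriptors

* **Fsp³** — the fraction of carbons that are sp³-hybridized, computed
  from the kekulized structure: a carbon counts as sp³ exactly when all
  its bonds are single (aromatic carbons never qualify; a carbon-free
  molecule is an error, not 0/0). Higher Fsp³ typifies the
  three-dimensionality of natural-product-like molecules.
* **Morgan-type fingerprints** — Open Babel's ECFP family (radius 2 =
  ECFP4 by default), folded from 4096 to `n_bits` (default 1024) by
  modular OR, the standard folding scheme.
* **Tanimoto** — $|a \cap b| / |a \cup b|$ on fingerprint bits; the
  undefined all-zero/all-zero case is declared 0. Distances are
  $1 - $ similarity; `distance_distribution()` summarizes all
  within-set or cross-set pairs with boxplot statistics (quartiles,
  mean, 1.5×IQR whiskers clipped to the observed range).

Descriptor plug-ins beyond these (3-D shape/electrostatics descriptors
and the like) are out of scope; `nearest_reference_similarity()` and
`distance_distribution()` accept any SMILES sets, so external descriptor
pipelines can be composed around the library CSV.

## Synthetic data: what it does and does not emulate

`make_corpus()` generates small, valid, unique, canonical corpora:
enumerable families in fixed order (linear alkanes, alcohols, ethers;
benzene-scaffold "aromatics" — mono-substituted first, then
para-disubstituted) and a seeded `"mixed"` family of random acyclic
C/N/O chains with occasional methyl branches plus roughly 15–30%
benzene-scaffold molecules. The generator uses its own small
multiplicative-congruential RNG so corpus generation never perturbs the
caller's RNG stream. The aromatic admixture matters: it is what lets a
pre-trained model acquire ring-closure syntax before fine-tuning narrows
it to the aromatic family, and the pool of aromatic structures is large
enough (~900) that a 500-molecule corpus genuinely contains them at that
rate.

The fixture chemistry is deliberately simple so enumeration oracles stay
exact and hand counts stay checkable. It does **not** emulate real
medicinal chemistry: no stereochemistry, charges, fused or bridged
rings, heteroaromatics, or drug-like size distributions. Consequently,
passing tests establish the *algorithmic* claims — decoder optimality
against enumeration, transfer-learning bias, conservation and
determinism of the pipeline, descriptor definitions — and say nothing
about design quality on real targets, which at full scale depends on
corpus curation and wet-lab validation.

Toy models are explicit conditional tables (i.i.d. or first-order
Markov) satisfying the same decoding interface as a trained checkpoint;
their sequence probabilities are available in closed form, which is what
makes exhaustive enumeration an *oracle* rather than a re-implementation
of the decoder.

## Numerical choices and degenerate inputs

* Softmax rows are max-shifted before exponentiation; training-loss
  probabilities are floored at 1e-300 before the log.
* A model emitting a distribution whose mass differs from 1 by more than
  1e-4 aborts decoding (defensive: toy tables and softmax outputs are
  both normalized by construction).
* `PAD` and `BEGIN` are masked to probability zero at decode time and
  the row renormalized.
* Empty corpora, carbon-free molecules, sub-2-molecule distance sets,
  out-of-vocabulary tokens, over-length prefixes and non-normalizable
  toy rows are all explicit errors rather than silent degradation.
* An overfit model's training loss is bounded below by the entropy of
  choosing among its training strings (for $n$ equiprobable strings,
  $n \log n$ nats spread over the total target tokens); the memorization
  test asserts convergence to within 0.05 nats of that bound, not to
  zero, which no model can reach.

## Known limitations

* Pure-R training is practical to roughly 10³–10⁴ molecules and
  64–256 hidden units; the full-scale 365k-molecule pre-training is out
  of reach without a compiled backend (the architecture and protocol are
  the same; only throughput differs).
* Open Babel's permissive SMILES dialect admits some strings other
  toolkits reject; validity statistics are therefore dialect-relative.
* Beam search explores a deterministic, narrow slice of sequence space;
  the number of distinct designs it can produce is bounded by
  `width_k × max_length`, unlike temperature sampling, which is
  unbounded. The two are complementary, which is why both are exposed.
* Sequence probabilities of different checkpoints are pooled as-is when
  ranking across epochs; they are likelihoods under *different* models,
  and the pooled ranking inherits that approximation deliberately.
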