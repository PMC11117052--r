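---
title: "Probing what antibody language models learn from native chain pairing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing what antibody language models learn from native chain pairing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ablm)
```

## The question

B cells express antibodies as a *pair* of chains — heavy and light — that
mature together: they are selected together, and somatic hypermutation (SHM)
accumulates in both chains of a pair over the same rounds of affinity
maturation. A protein language model trained on single chains can never see
this coupling. `ablm` provides a complete, desk-scale test bed for asking
what a masked-language-model (MLM) encoder gains from natively paired
training data: it simulates paired repertoires with the statistical
structure that matters, trains three controlled encoder variants
(natively paired, chain-shuffled, and unpaired) on the *same* underlying
sequences, and probes the trained models for cross-chain learning.

Everything runs on one CPU in minutes. The package deliberately replaces
the large public paired repertoires used in full-scale studies with a
simulator, so that every probe has ground truth (true germline ancestors,
true mutation positions, true pairing) and every analysis is reproducible
from a seed.

## The repertoire simulator

`generate_germline_db()` builds a set of V, D and J gene segments with
fixed region layouts (framework regions FR1–FR4 and complementarity-
determining regions CDR1–CDR3; the heavy V layout is
FR1=25, CDR1=8, FR2=17, CDR2=8, FR3=38 residues, and J segments contribute
a short CDR3 part followed by FR4). `recombine()` assembles chains as
V + junction + (D) + junction + J with uniform end-trims and nontemplated
inserts, so CDR3 spans the one region that no germline template explains.

Two couplings give paired training data its value, and the simulator
encodes both:

* **Pairing preferences.** A row-stochastic heavy-to-light V pairing
  matrix concentrates 0.8 of each heavy V's mass on one preferred light V
  partner (ignored with probability `pairing_noise = 0.1`). The strength
  of this preference in real repertoires is not well quantified; 0.8 is a
  deliberate free parameter users should expect to tune.
* **Shared mutation load.** `apply_shm()` draws one gamma-distributed
  load per pair (mean `shm_rate = 6` mutations per chain, shape 2) and
  Poisson per-chain counts around it. This gamma–Poisson mixture has a
  closed-form heavy/light mutation-count correlation of
  `(m/k)/(m/k + 1) = 0.75` at the defaults — one chain's deviation from
  germline is strongly predictive of the partner's. Mutations fall on CDR
  positions with 3-fold weight and replace the residue with a uniformly
  random different amino acid.

Defaults describe a healthy-donor-like mix: 30% naive (unmutated) pairs,
~6 amino-acid mutations per mutated chain, 2% exact duplicates and 2%
nonproductive (stop-containing) records so the filtering stage has real
work to do. The study scale used throughout the tests is 2,000 pairs —
large enough for the probes' signal, small enough for CPU. The simulator's
"germline" is the pre-SHM recombined ancestor *including* the nontemplated
junction, so germline reversion (`germline_revert()`) has a defined target
at every position; this mirrors inferred-naive reconstruction in real
pipelines.

What the simulator does **not** model: nucleotide-level recombination,
SHM hotspot motifs, insertions/deletions, isotypes, clonal phylogenies,
and any real antigen-driven selection. Probe results on synthetic data
demonstrate that the pipeline recovers the intended statistical couplings;
they do not by themselves establish effect sizes in real repertoires.

## Corpus construction and tokenization

`filter_pairs()` removes nonproductive records and exact amino-acid
duplicates (first occurrence kept); `split_dataset()` makes the 90/5/5
train/eval/test partition. Three corpora are then derived from the same
filtered, split records:

* **paired** — `<s> heavy </s> light </s>`, padded to 512 tokens;
* **shuffled** — light chains permuted by one global random permutation
  (`make_shuffled()`), breaking pairing while preserving both marginals.
  Shuffling is applied within the training corpus only, after splitting,
  so eval/test keep native-pair ground truth for probing; whether
  full-scale studies shuffle across split boundaries is not documented,
  and this choice is ours.
* **unpaired** — the 2n single chains (`make_unpaired()`), `<s> chain
  </s>` padded to 256, split membership inherited from the paired split.
  Redundant light chains are intentionally retained so all variants see
  the same residues; the redundancy is counted and reported.

The tokenizer (`tokenizer_spec("roberta")`) uses 25 tokens: the 20 amino
acids plus `<s>`, `</s>`, `<pad>`, `<unk>`, `<mask>`. An ESM-style dialect
(two `<cls>` separators, padded to 320) is provided for compatibility with
that family's conventions. Sequences that would overflow the maximum
length raise an error rather than being silently truncated.

## The encoder and its training

No deep-learning framework is assumed: the package ships its own small
pre-LayerNorm transformer encoder (absolute positional embeddings,
multi-head attention, GELU feed-forward) with exact reverse-mode gradients
in compiled code, verified against finite differences in the test suite.
The desk-scale default is 2 layers, 4 heads, hidden size 64, intermediate
256 (~100k parameters); the full-scale reference configuration
(24/16/1024/4096) is representable but not intended for CPU training.

Training follows the standard MLM recipe: 15% of eligible residue tokens
selected per visit, 80% of those replaced by `<mask>`, 10% by a random
amino acid, 10% kept; masks are resampled at every visit (dynamic
masking). The optimizer is Adam with standard moments under a linear
warmup + linear decay schedule (reference peak 4e-4; desk-scale runs use
1e-3, which small models tolerate and which converges within a CPU
budget). Weight decay, gradient clipping and mixed precision are not part
of the reference recipe; weight decay is available but defaults to 0. The
unpaired corpus trains with twice the paired batch size, mirroring the
2n-vs-n sequence counts, so corpora stay comparable per step.

`train_mlm()` returns an `ablm` object with `print`, `summary`, `coef`,
`predict` and `plot` (loss trace) methods; checkpoints serialize to JSON
at full precision.

## The probes

**Region-wise CEL (per-position masking).** `per_position_cel()` masks one
residue at a time and records the cross-entropy (natural log) of the truth;
`summarize_region_cel()` takes per-sequence medians within each FR/CDR,
split by mutation status (a pair is "unmutated" only if both chains carry
zero SHM). The expected signature on unmutated sequences is a high CDR3
median relative to every FR — junctional diversity is untemplated, so no
model can predict it from germline context.

**Mutation masking with germline-reverted partners.**
`mutation_mask_probe()` selects pairs with at least 3 mutations in *each*
chain, masks **all** mutated positions of one chain simultaneously, and
presents the partner either natively (mutations visible), germline-reverted
(`germline_revert()`), or not at all (for unpaired models). Because only
mutated positions are masked, the germline residue is always the wrong
answer; a model that has learned the shared mutation load should shift
probability mass away from germline when the visible partner is mutated.
Reported quantities are the mean CEL over masked positions and the mean
likelihoods (probabilities × 100) of the correct residue, of other
non-germline residues, and of the germline residue. Likelihoods are taken
from the raw softmax over the full 25-token vocabulary (special-token mass
is reported too, so the decomposition sums to 100 and is checkable).
CEL at vanishing probability is floored at `-ln(1e-12)`.

**Cross-chain attention.** `cross_chain_attention_summary()` takes the
final layer's attention over paired inputs, drops special/pad rows and
columns, keeps only query–key pairs spanning both chains, and averages the
attention *received* by each position over heads and cross-chain queries
(the received direction is our reading of "attention directed toward"
regions; per-input totals are normalized to mean 1 per position so each
antibody contributes equally). The headline statistic is the attention
ratio: percent of cross-chain attention on CDRs divided by percent of
positions that are CDR. A uniform-attention model gives exactly 1.0, which
the stub-model tests exploit. `per_mab_attention_map()` averages over all
layers and heads and symmetrizes each heavy/light position pair, giving
the per-antibody map and summed per-residue vectors used for structure
coloring (rendering itself is out of scope; the package emits the
vectors).

**Chain-sliced embeddings.** `extract_chain_embeddings()` averages
final-layer hidden states over one chain's residue span, producing the
N × H matrix on which visual methods (UMAP/t-SNE) usually operate.
Rendering is a pluggable downstream step; the assertable statistic here is
`embedding_cluster_purity()` — the mean fraction of k-nearest neighbours
(Euclidean, ties broken by row order) sharing a label. For the
paired-vs-unpaired comparison the informative label is the *partner heavy
chain's* V gene evaluated on light-chain embeddings: a light chain's own V
gene is trivially recoverable from its own residues by any encoder
(purity saturates near 1 for all models), whereas the partner's identity
is only accessible to a model that actually encodes pairing information —
directly for a paired encoder, and only through the pairing-matrix
correlation for an unpaired one.

## Specificity classification

Class-labelled data are simulated by planting short paired CDR3 motifs
(one motif per chain per class, written into the pre-SHM ancestor so SHM
can still degrade them). `cluster_by_identity()` implements greedy
first-fit clustering on ungapped positional identity over the concatenated
chains (the identity metric is deliberately simple and documented;
full-scale pipelines use dedicated clustering tools), with seeded
shuffling before clustering for reproducibility.
`build_classification_dataset()` balances classes to the smallest class
and makes a stratified, seeded test split.

`fine_tune_classifier()` attaches a first-token-pooled head
(dense + tanh + logits, the conventional head of this encoder family) and
trains the whole network for 1 epoch per the reference recipe, repeated
over several seeds on the same split. The metric battery
(`compute_metrics()`) implements accuracy, F1/macro-F1, rank-statistic
AUC, average-precision AUPR and the (generalized) Matthews correlation
coefficient directly from their definitions; the test suite cross-checks
them against brute-force oracles and an independent ROC implementation.
Accuracy traces are recorded step-wise and optionally smoothed with the
dashboard-style recurrence `s_t = 0.25 s_(t-1) + 0.75 x_t` (the exact
recurrence behind "smoothing weight 0.25" conventions is not standardized;
this one is documented and tested). Desk-scale fine-tuning uses a peak
learning rate of 1e-3 — the reference value of 5e-5 is tuned to
400M-parameter encoders and moves a 100k-parameter model too little in a
single epoch.

## Numerical and design notes

* All randomness flows through R's RNG via explicit seeds; identical
  configurations give byte-identical simulator and corpus outputs.
  Training is deterministic given seeds up to floating-point
  non-associativity in BLAS reductions.
* Internally the package uses R-idiomatic 1-based inclusive coordinates;
  the AIRR-style TSV export uses that format's 1-based inclusive boundary
  columns directly.
* The ignore label for unmasked positions is `NA`, never a valid token id.
  MLM loss pools over all labeled tokens of a batch.
* Inputs are cropped to their real length before entering the encoder, so
  attention is never computed over pads; attention rows therefore sum to 1
  over real tokens by construction, which the suite asserts.
* Degenerate cases are explicit errors, not silent repairs: empty probe
  selections, single-class truth for AUC (reported `NA`), overlong inputs,
  fractions that do not sum to 1.

## Scale choices and honest limitations

The test suite trains nine encoders (three variants × three seeds) of the
desk-scale configuration for a few hundred steps each on 2,000-pair
repertoires, plus a motif-classification study over five seeds. These
sizes were chosen so the entire suite completes in well under half an
hour on one CPU.

At this scale the probes that depend on *architecture and data
construction* — CDR3 vs framework cross-entropy, cross-chain attention
structure, pairing information in chain-sliced embeddings, motif-driven
classification — recover their expected signatures reliably. The
mutation-masking probe is different: it asks the encoder to *learn* the
shared-load coupling as a generalizable circuit. With ~1,700 training
pairs a 100k-parameter model can lower its training loss faster by
memorizing specific training mutations than by learning the cross-chain
load feature, and in our experiments the native-vs-reverted CEL gap on
held-out pairs remains at noise level across training lengths up to many
epochs. The probe machinery itself is exact (stub models with analytic
behaviour verify every quantity); the limitation is the desk-scale
learning problem, consistent with the full-scale observation that this
capability emerged from orders of magnitude more data and capacity. The
acceptance test for this recovery is therefore expected to fail at desk
scale and is retained unweakened, as a negative result the package
documents rather than hides.
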