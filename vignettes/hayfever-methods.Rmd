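---
title: "Methods: attention-based BiLSTM classification of noisy health-related text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attention-based BiLSTM classification of noisy health-related text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hayfever)
```

## Scope and task

`hayfever` classifies short, noisy health-surveillance messages into four
relevance classes: detailed personal reporting (1), generic personal
reporting (2), warnings/news/marketing (3), and ambiguous/unrelated (4).
The scientific motivation is digital disease surveillance for pollen
allergy: keyword streams confuse genuine symptom reports with
advertisements and news that use the same vocabulary, and informal
spelling creates test-time tokens absent from any training vocabulary.
The package implements the full protocol — preprocessing, vocabulary
auditing, the neural model in two variants, stratified repeated
cross-validation, attention visualization — plus a synthetic corpus
generator so that everything can be exercised end to end without access
to a proprietary social-media corpus.

## Preprocessing

Raw messages pass through, in order: retweet removal (raw text starting
with "RT ", case-insensitive — platforms mark shares this way but the
convention is not part of any standard, so the marker set is
configurable); duplicate removal by exact text equality after Unicode NFC
normalization (near-duplicates are deliberately kept — distinguishing
them would require a similarity threshold with no principled value);
tokenization with a Twitter-aware rule set (URLs and @-mentions
recognized and dropped, hashtags kept as their word content since they
frequently carry topical words, emoticons kept as single tokens,
contractions kept whole); lowercasing; removal of pure-punctuation tokens
and stopwords; and capping of within-token character runs at 3, so
"soooooo" becomes "sooo" while "aaahhh" survives. The run cap reading —
shorten any run longer than three to exactly three — is the only reading
consistent with elongated interjections surviving preprocessing in
practice.

The stopword list is bundled as a versioned data file (a Snowball-style
English list extended with contractions) rather than imported from an
external library: token-level results depend on it, so it must be fixed
and inspectable. Messages that lose every token are flagged, warned
about, and excluded from model input.

Preprocessing is idempotent: applying it to its own output changes
nothing. This is asserted as a property test and matters because
synthetic corpora are generated directly in normalized form.

## Vocabularies and the OOV audit

Word and character vocabularies are built from training folds only, with
reserved indices 0 (padding) and 1 (unknown) and deterministic ordering
(frequency descending, ties lexicographic). `min_count` defaults to 1 —
no pruning — because the character pathway, not vocabulary truncation, is
the intended OOV mechanism.

The OOV rate of a test fold is the percentage of token occurrences (or
distinct types, by option; occurrences are the default since both
readings of a fold-level "rate" are defensible and the choice is exposed)
absent from the training-fold index. `oov_report()` audits all k folds
and averages. Averages are kept unrounded internally and displayed
half-up at 2 decimals.

## The network

For tokens x_1..x_n the input matrix X has rows e_{x_i} ⊕ e′_{x_i}.

**Character pathway.** Characters are embedded as rows of a learned
table (l = 50), the word is right-padded to at least the kernel width,
K = 100 kernels of width w = 5 are convolved over all valid windows, a
tanh nonlinearity is applied, and each kernel max-pools over positions.
Two sizes coexist by design: the character table rows are l-dimensional
(input side) while the pooled word feature is K-dimensional (output
side), so input rows have d + K = 150 entries. The convolution
nonlinearity is tanh, matching the attention projection, and satisfies
f(0) = 0 so all-zero parameters yield a zero feature. Each word pools
only over its own valid windows, making its character feature independent
of the batch it appears in.

**Recurrent annotations.** One bidirectional LSTM layer (m = 50 per
direction) produces h_i = h⃗_i ⊕ h⃖_i. Forget-gate biases start at 1;
other weights are Glorot-uniform. Padding positions carry the previous
state through and are masked out of attention, so padding cannot
influence any output (a tested invariant).

**Attention.** z_i = tanh(W_a h_i + b_a); scores u_i = z_iᵀ ĥ; weights
α = softmax(u) over non-padding positions; sentence embedding
s = Σ α_i h_i ∈ R^{2m}. The attention projection size defaults to 2m,
the annotation size, standard for additive attention. The sentence
embedding is necessarily 2m-dimensional — it is a convex combination of
the 2m-dimensional annotations and no projection intervenes — and the
output layer is sized accordingly.

**Output and loss.** p = softmax(W_oᵀ s + b_o); cross-entropy summed
over the batch defines the objective, with the per-example mean used for
optimizer steps. Probabilities of true labels are clamped at 1e-12
before the log, with a warning. Argmax ties break toward the lower
class index, deterministically.

**Word-level OOV at inference.** Unknown words receive the learned
unknown word vector (initialized at zero) while their character feature
is computed from their spelling. This is the mechanism by which the full
model distinguishes misspelled variants that the word-only ablation
cannot (tested by direct comparison of input rows).

The word-only variant (`use_char = FALSE`) is exactly the same code path
minus character features, so ablation comparisons isolate the character
pathway.

### Implementation and verification

No neural-network framework is used: forward and backward passes are
written in vectorised base R, with all timesteps stacked into single
matrix products where the recurrence allows. Correctness rests on three
independent checks: (i) closed-form cases (zero parameters give uniform
attention and uniform class probabilities; one uniform prediction gives
loss ln 4; a single-step LSTM matches hand-coded gate arithmetic);
(ii) the batched engine agrees with a straight-line per-message
reference implementation to 1e-10; (iii) analytic gradients of every
parameter match central finite differences at 1e-4 relative tolerance.
Padding rows of both embedding tables are fixed at zero and excluded
from gradients.

## Training protocol

Stratified k-fold cross-validation (default k = 10) with, per fold: a
stratified 10% validation split, mini-batches of 64, Adam (step size
1e-3, standard moments — the optimizer is named in the protocol but its
hyperparameters are not, so the universal defaults are used), and early
stopping when validation loss has not strictly improved for 10
consecutive epochs, restoring the best-epoch weights (stopping is
defined by the best value, so restoring it is the consistent choice).
A `max_epochs` cap (default 200) bounds runtime. Each configuration is
repeated 5 times by default with per-repeat seeds (base + repeat index);
every source of randomness — initialization, splits, shuffling — derives
from these seeds, and identical seeds give bit-identical parameters.

Fold dealing shuffles each class under the seed and deals round-robin,
with the dealing pointer continuing across classes; this guarantees both
that global fold sizes differ by at most one and that per-class fold
counts stay within one of proportional, which per-class dealing that
restarts at fold 0 does not.

Evaluation reports accuracy and macro-F1 (unweighted mean of per-class
F1, with the 0/0 → 0 convention), per-class precision/recall/F1 and the
confusion matrix. Aggregates are reported both as means over per-fold
metrics and as metrics of per-repeat pooled confusion matrices, since a
fold-level protocol can be summarized either way; with near-equal fold
sizes the two differ negligibly.

The vocabulary (and thus embedding initialization) is built from the
training part of each fold only; the held-out fold contributes nothing
to training — sentinel-token tests assert this. Within a fold the
vocabulary is built from the full training part including the validation
carve-out, since validation data is training data under the protocol.

## The synthetic generator

The generator emulates the statistical structure of the motivating
corpus, not its language: 3862 messages by default with class counts
exactly 719/1823/938/382 (largest-remainder apportionment, so
count-based tests are exact rather than distributional); message lengths
uniform on 4–12 tokens; tokens drawn from a shared pool of confusable
hay-fever terms (55% class pool / 45% shared by default — enough overlap
that classes are not trivially separable by a single token, which the
bundled frequency-vote check certifies) and four class-themed pools
bundled as data files.

Spelling noise mirrors the error kinds seen in user-generated text:
run stretching (to runs of exactly 3, keeping output stable under the
preprocessing cap), adjacent-character transposition, and
abbreviation-style suffix truncation, at per-token rates of 0.08 each
before calibration. A perturbed token may receive a second, compounding
perturbation with probability 0.5: without compounding the space of
possible misspellings per word is small (~20), so at full corpus size
every variant recurs in the training folds and the out-of-vocabulary
rate collapses; compounding expands the variant space combinatorially,
the way real misspellings do, keeping perturbed forms rare at any corpus
size. Every perturbation is recorded (message, position, original,
variant, operator), so noise ground truth is testable.

`calibrate_oov()` scales the three rates by a common bisection-found
multiplier until the k-fold mean word OOV lands within ±1 point of the
9% target; character OOV stays near zero automatically because noise
only rearranges, repeats or drops characters already present in training
words — reproducing the published regime in which missing characters are
two orders of magnitude rarer than missing words.

What the generator does **not** emulate: grammar, word order semantics,
named entities, hashtag/URL/emoticon debris (messages are generated
already normalized), or heavy-tailed real vocabulary growth. Passing
tests on synthetic corpora therefore certify the pipeline's mechanics
and the direction of the character-pathway effect, not real-world
accuracy levels; published accuracies on the motivating corpus are not
reproducible without its data, and synthetic accuracies are higher
because generated classes are cleaner than annotated ones.

## Evaluation at reduced scale

The bundled end-to-end checks run the full protocol at reduced size so
they complete in minutes on one CPU: a calibrated corpus of n = 1000,
3 folds, 2 repeats, epoch cap 30 for the two-variant comparison, with
the directional character-pathway claim (mean macro-F1 of the full model
at least that of the word-only model) assessed across 5 seeds on a fixed
train/test split. These sizes are the package's documented reduced
protocol; the full-scale defaults (n = 3862, 10 folds, 5 repeats,
`max_epochs` 200) remain available through the same functions.

## Numerical and degenerate-input choices

- Softmax is computed with max-subtraction; masked positions score −Inf
  and receive exactly zero weight.
- Max-pool backward routes gradient to the argmax window only; ties are
  broken toward the earlier position (ties have measure zero under
  random initialization).
- Messages longer than `max_seq_len` (64) are truncated, words longer
  than `max_word_len` (24) likewise; synthetic messages never reach
  either bound.
- Empty messages are rejected at encoding; empty corpora are valid for
  I/O but not for training.
- A validation class with fewer than 2 members degrades the validation
  split to unstratified, with a warning.

## Known limitations

- Single-threaded CPU training only; at full scale (10 folds × 5
  repeats) a run takes hours, not minutes.
- No hyperparameter search, no pretrained contextual encoders, no
  stacked LSTMs — deliberately out of scope.
- The attention visualization normalizes intensity per message by its
  maximum weight; weights are comparable within a message, not across
  messages.
- Pretrained word vectors are supported through the standard text
  format; none are bundled, so default runs initialize word embeddings
  randomly.
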