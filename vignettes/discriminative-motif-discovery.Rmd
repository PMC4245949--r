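---
title: "Discriminative motif discovery with binding-site HMMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminative motif discovery with binding-site HMMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discrimotif)
```

## The problem and the model

High-throughput binding assays (ChIP-Seq, RIP-Chip, PAR-CLIP, SELEX)
produce large sequence sets in which true binding sites are frequent but
neither every positive sequence contains one, nor is the site location
within a sequence known. `discrimotif` treats motif discovery as a
discriminative feature-learning problem over a *contrast*: an ordered
collection of two or more condition-labelled sequence sets. The feature of
interest is whether a sequence has **at least one occurrence** of a motif;
motifs are sought whose occurrence frequency differs maximally between
conditions.

Two motif representations are used in sequence:

* **IUPAC words** (degenerate patterns over subsets of `{A,C,G,T}`) for
  fast discrete seed search, and
* **binding-site HMMs** — a background state plus a left-to-right chain of
  match states per motif — for probabilistic refinement.

### Binding-site HMM topology

The background state transitions to itself or to the first state of each
motif chain; chain states advance deterministically (optionally through
single, non-self-transiting insert states); the last chain state returns
to the background, with a tiny initial mass (1e-6, renormalized) on
chain-to-chain transitions so tandem arrangements stay learnable.
Start/end bookkeeping is realized as follows: the initial state
distribution is tied to the background's transition row (sequences begin
as if preceded by background context), and sequences may terminate only in
the background or in the final match state of a chain. The terminal
constraint matters: without it, a path ending mid-chain would let a
truncated prefix at the sequence end count as an "occurrence", and a
sequence shorter than the motif would receive positive occurrence
probability.

`N` residues are emission-marginalized (their emission factor is 1 in
every state), so ambiguity characters and masked regions neither favor nor
penalize any state. In double-stranded mode each sequence is extended with
`$` plus its reverse complement; inference splits at `$`, the two halves
are treated as one logical sequence for the occurrence feature, and no
site or HMM path can span the separator.

### Objectives

All discriminative objectives are driven by the posterior occurrence
probability `P(k > 0 | X, θ) = 1 − P_constrained(X)/P(X)`, where the
constrained forward pass sums only over paths that never enter the motif
chain(s). Summing these posteriors per condition gives fractional
("expected count") contingency tables of occurrence by condition, on
which the objectives are evaluated:

* **MICO** — mutual information of condition and occurrence (bits); the
  default, applicable to any number of conditions and to multiple jointly
  analyzed contrasts (objective values and test statistics add across
  contrasts, which makes the gradient additive and reduces the joint case
  to the single-contrast one);
* **DFREQ** — occurrence-frequency difference (binary contrasts; signal is
  the first listed condition);
* **MCC** — Matthews correlation (binary, single contrast);
* **DLOGL** — log-likelihood difference of signal and control;
* **MMIE** — maximization of the conditional class probability `P(C|X)`.
  No closed formulation was available for the auxiliary structure, so the
  package uses a per-sequence mixture over the occurrence indicator,
  `P(C|X) ∝ P(C) [P(M=1|C) p/z₁ + P(M=0|C)(1−p)/z₀]` with
  `p = P(k>0|X)` and `z₁` the pooled mean occurrence; class priors and
  `P(M|C)` are re-estimated after each HMM update. This formulation is
  validated by finite differences and by its fixed-point consistency, not
  against an external reference.
* **LOGL** — plain likelihood (generative, signal-only learning); during
  seeding LOGL and DLOGL fall back to occurrence frequency and DFREQ, and
  MMIE to MICO, since discrete words have no likelihood.

## Seed finding

Per length: count, for every occurring exact word, the number of
sequences containing it (presence, not position counts); score; retain the
top `n = 100`; then rounds of single-nucleotide IUPAC generalization.
A generalization matches a superset of its specialization's sequences, so
the scanner only rescans sequences not already known to match — this and
the bitmask matchers in C++ keep the search fast. Generalizations scoring
below **any** generating specialization are dropped (ties survive, so
plateaus are traversed); rounds continue until no candidate remains or a
degeneracy cap is reached. By default no cap is imposed (the cap is an
option, absolute or as a fraction of `3·length`). Ties in retention and in
the final selection break lexicographically on the IUPAC string, making
the whole search deterministic. For multiple seeds, occurrences of each
found motif are masked to `N`s (or carrier sequences discarded) before the
next round.

## Training: the hybrid scheme

Signal parameters (match-state emissions) and context parameters
(background emission and all transitions, including the occurrence prior
`B→chain`) address different questions, so they are optimized under
different objectives and alternated:

1. one gradient ascent step on the signal parameters under the chosen
   discriminative objective, using the analytic chain rule
   ∂obj/∂cells × ∂cells/∂p × ∂p/∂θ with expected-count forward–backward
   gradients, a strong-Wolfe line search (bracketing plus quadratic
   interpolation, Armijo backtracking as fallback), and
2. one Baum–Welch step on the context parameters under the likelihood of
   the configured context sets (all conditions by default; e.g. signal
   only for shuffled-control contrasts).

Iteration stops when the relative changes of both the objective and the
log-likelihood fall below the tolerance (default 1e-6; the scheme is not
guaranteed to terminate in general, so `max_iterations`, default 1000,
caps it and the best-objective iterate is returned on oscillation).

Numerical choices: probabilities are optimized through a per-row softmax
reparameterization, which keeps every transition and emission row exactly
on the simplex at all times; the forward–backward pass uses per-position
scaling constants; an emission floor of 1e-6 prevents absorbing zeros;
chain initialization uses `P(B→chain) = 1/(l − w + 1)` with `l` the mean
sequence length of the context-training sets, and seed-centered emissions
with pseudo-probability `α = 0.03` (so `A` gives 0.91/0.03/0.03/0.03 and
`W` 0.47/0.03/0.03/0.47). Everything is single-threaded with fixed
reduction order, so identical seeds give identical traces.

## Significance and motif-space correction

`G = 2 ln 2 · Σ_contrasts I·n` is compared with the χ² distribution at
`Σ (conditions − 1)` degrees of freedom; on integer 2×2 tables `G` is
algebraically the classical G-test statistic. All arithmetic is in log
space. The p-value is multiplied (Bonferroni-style) by the motif-space
size — the number of IUPAC words of the searched length with degeneracy up
to the cap actually used during seeding, counted by dynamic programming
over per-position subset multiplicities (4, 6, 4, 1 for degeneracy
contributions 0–3); without a cap this is `15^length`. This penalizes long
motifs, whose search space is larger, and makes lengths comparable. The
default acceptance threshold on the corrected p-value is 0.05. The filter
is applied regardless of the training objective.

## Multiple motifs

Candidates are seeded per length by repeated masked seed search (so the
`per_length` seeds describe different motifs, not variants of one),
plus 1-nt-shifted variants per seed (for each direction the best-scoring
single-nucleotide flank; 6 lengths × 3 seeds × 3 variants = 54
candidates in a typical run). Each candidate is trained independently; the
best corrected p-value wins. Growth candidates are gated twice:

* **cMICO** `I(condition; new occurrence | accepted occurrences)` must be
  significant (χ² with `(conditions−1) × patterns` degrees of freedom), and
* the ratio of cMICO over the **motif-pair cMI**
  `I(new; accepted | condition)` must reach a threshold (default 1),

pairwise against every accepted motif and jointly against all of them.
Joint occurrence tables across separately trained models use hard
occurrence calls (posterior > 0.5) by default: treating the posteriors of
different models as independent per-sequence Bernoullis would make the
pair cMI identically zero and disable the redundancy gate (the soft
construction remains available via the `occurrence` flag, and within a
single joint HMM the any-motif feature is computed exactly by constraining
all chains simultaneously). The gated winner's chain is added to the joint
HMM (warm-started from its fitted emissions), the joint model is
re-trained on the any-motif occurrence feature, and the result is accepted
only if the corrected p-value improves; otherwise the previous model is
reported.

## The synthetic benchmark

`generate_dataset()` draws signal and control sequences from a uniform
zeroth-order background (or an A/U-rich order-3 Markov surrogate for
3'UTR-like context — a stand-in chosen so no external sequence data are
required; a user FASTA can supply real background), polarizes a random
flat-Dirichlet PWM to a target information content by bisection on the
component-wise exponent, and implants at most one sampled occurrence per
selected signal sequence at a uniform position (overwrite semantics, sense
strand only). The decoy design implants a second PWM into both signal and
control sequences *before* the signal implants; a decoy overlapped by a
signal implant is removed from the truth. Dinucleotide-preserving shuffles
(uniform Eulerian-path, preserving exact dinucleotide counts and both
terminal residues) can synthesize controls.

**Recognizability** — the predictive performance of the true model — is
the reference: an HMM with the implanted PWM as emissions and
`implant_freq/seq_len` as the per-position background-to-motif transition
(0.1 × 0.01 = 0.001 for 10% implantation into 100-nt sequences), uniform
background (fitted by Baum–Welch for Markov backgrounds).

Evaluation: predictions are scored over **all** sequences of the contrast
(truth sites exist only in signal sequences; control predictions count as
false positives, penalizing non-discriminative predictors symmetrically
for discovery and the recognizability reference). Nucleotide level uses
the MCC of the positionwise confusion matrix (nCC; 0 when undefined);
site level requires an overlap of at least 50% of the truth site's length
with greedy one-to-one matching by decreasing overlap; sSn, sPPV and
their mean sAP follow. High-level summaries pool the raw confusion counts
across datasets and recompute the metrics (never averaging per-dataset
values).

### Benchmark scale and what it shows

The package's default replication grid (`reduced_basic_grid()`) is 18
datasets: 1000 + 1000 sequences of 100 nt, 8-nt motifs at IC 8, 10 and 12
bits, implantation 20% and 50%, three generation seeds each. At this
scale, MICO-trained discovery attains ~95% and the bare seed finder ~93%
of pooled recognizability nCC. The IC-8 / implant-20% cells are
information-limited: there the trained model's corrected MICO p-value
misses the 0.05 threshold by a fraction of a nat and the significance
filter zeroes its predictions, even though the trained model separates the
conditions *better* (G ≈ 44) than the true generating model evaluated the
same way (G ≈ 20). With more sequences those cells pass comfortably; the
decoy comparison therefore uses 3000 sequences per set (the smallest size
at which the filter retains power at 10% implantation), signal and decoy
IC 12, decoy implantation 50%. On that design, signal-only Baum–Welch
learning collapses onto the decoy (nCC ≈ 0 after filtering) while
discriminative MICO learning is unaffected relative to the decoy-free
control — the qualitative phase behavior expected when a non-discriminative
motif dominates the likelihood.

Passing these tests shows the machinery is correct and well-calibrated on
data that match the generator's assumptions — independent uniform (or
low-order Markov) backgrounds, positionally independent motif columns, at
most one implant per sequence. Real binding data violate all of these
(repeats, composition bias, dependent motif positions, multiple and
clustered sites), so benchmark numbers bound optimism rather than promise
field performance.

## Known limitations

* Match-state emissions are zeroth-order; interacting neighbor positions
  are not modeled.
* The hybrid scheme is a local search: with weak or low-IC signals it can
  converge to a sharp sub-motif of the true pattern (the benchmark's
  information-limited cells show exactly this), and restarting from
  several seeds is the practical remedy.
* The MMIE auxiliary-parameter structure is this package's own
  formulation (see above), validated only for self-consistency.
* The motif-space count is a package definition (degeneracy-limited IUPAC
  word count); with unlimited degeneracy the `15^L` correction is
  conservative.
* P-values are asymptotic (Wilks); no exact or permutation tests, and no
  FDR control across multiple reported motifs.
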