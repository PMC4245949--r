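# discrimotif

Discriminative discovery of nucleic acid binding-site motifs with
binding-site hidden Markov models.

Given a *contrast* — two or more sets of sequences, e.g. ChIP-Seq or
PAR-CLIP signal versus a control, rank groups of binding evidence, or
repeat experiments analyzed jointly — `discrimotif` finds sequence motifs
whose occurrence frequency differs between the conditions. It is aimed at
genome- and transcriptome-scale data where not every positive sequence
contains a site and negative sets contain false negatives, so the relevant
feature is whether a sequence carries **at least one occurrence** of a
motif, not where exactly.

The method has three parts:

1. **Seed finding.** All occurring exact words of a given length are scored
   on a contingency-table objective, the top *n* (default 100) retained,
   and then iteratively generalized over the IUPAC alphabet (one additional
   nucleotide per position per round); generalizations scoring below a
   generating specialization are dropped. This yields discriminative IUPAC
   regular expressions usable on their own or as seeds.
2. **Binding-site HMM optimization.** A hidden Markov model with a
   background state and one chain of match states per motif is seeded from
   an IUPAC word. Signal parameters (the match-state emissions) are trained
   by gradient ascent on a discriminative objective with a strong-Wolfe
   line search, while context parameters (background emission, all
   transitions) are updated by Baum–Welch — the hybrid learning scheme.
   The headline objective is **MICO**, the mutual information of condition
   and motif occurrence,

   `I(C; M) = Σ_{c,m} p(c,m) log2 [ p(c,m) / (p(c) p(m)) ]`,

   computed on expected counts of sequences with at least one occurrence,
   `P(k > 0 | X, θ)`, obtained from a constrained forward pass. DFREQ,
   MCC, MMIE, DLOGL and plain likelihood are also available.
3. **Significance filtering.** MICO links to the likelihood-ratio test via
   `log Λ = −I·n·log 2`, so `G = 2 ln 2 · I · n` is asymptotically
   χ²-distributed with (conditions − 1) degrees of freedom. P-values are
   Bonferroni-corrected by the motif-space size (the number of IUPAC words
   of the searched length and degeneracy), and a model is accepted only if
   the corrected p-value meets the threshold.

Multiple motifs are discovered iteratively: candidates must carry
significant *residual* discriminative information (conditional mutual
information of condition and new occurrence given accepted occurrences)
and must not be redundant with accepted motifs (motif-pair conditional MI
given the condition), enforced pairwise and jointly.

A full synthetic benchmark is included: IC-controlled PWM implantation
into uniform or Markov backgrounds, decoy designs, dinucleotide-preserving
shuffles, the *recognizability* reference (site prediction with the true
generating model, the ceiling for any discovery method) and
nucleotide/site-level metrics (nCC, sSn, sPPV, sAP).

## Worked example

```r
library(discrimotif)

# synthetic data: 8-nt motif of 10 bits IC implanted into half of the
# signal sequences
params <- bench_params(n_seq = 1000, seq_len = 100, motif_len = 8,
                       implant_prob = 0.5, signal_ic = 10)
ds <- generate_dataset(params, seed = 7)
ct <- contrast(ds$signal, ds$control, name = "demo")

# 1. discrete seed finding
seed <- find_seed(ct, lengths = 8, objective = "mico")
seed
#> <seed_result> AAWSRCMM  mico = 0.163739

# 2. HMM optimization under MICO
hmm <- add_motif_chain(train_background(ct$conditions), seed$word)
fitres <- fit(hmm, ct, training_config(objective = "mico",
                                       max_iterations = 100,
                                       tolerance = 1e-4))

# 3. significance
sig <- mico_log_pvalue(fitres$tables)
correct_and_filter(sig$log_p, motif_space_size(8), threshold = 0.05)
#> <significance_result> log10 p = -77.02 (raw -86.43, space 2,562,890,625); accepted

# predicted sites vs. the implanted truth
sites <- viterbi_sites(fitres$hmm, c(ds$signal$seqs, ds$control$seqs),
                       c(ds$signal$ids, ds$control$ids))
evaluate_sites(sites, ds$truth, total_nt = 2 * 1000 * 100)
#> <site_metrics> nCC 0.7721  sSn 0.6837  sPPV 0.8810  sAP 0.7824
```

The seed search returns the IUPAC word maximizing MICO (a degenerate
consensus of the implanted PWM), the fitted model's corrected p-value is
far below 0.05, and the Viterbi-decoded sites recover the implants at a
nucleotide-level correlation of 0.77 — 96% of the recognizability ceiling
(nCC 0.81) that the true generating model attains on the same data.

A command-line interface wrapping the same functions ships at
`system.file("cli", "discrimotif", package = "discrimotif")` with
`plasma`, `discover` and `bench` subcommands.

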