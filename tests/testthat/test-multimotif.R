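# small two-motif synthetic data shared across the multi-motif tests
two_motif_contrast <- function(n = 120, len = 36, seed = 51,
                               w1 = "TGTAAATA", w2 = "CCGGACGG",
                               p1 = 0.7, p2 = 0.7, correlated = FALSE) {
  set.seed(seed)
  sig <- vapply(seq_len(n), function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    put1 <- runif(1) < p1
    put2 <- if (correlated) put1 else runif(1) < p2
    if (put1) substr(s, 3, 2 + nchar(w1)) <- w1
    if (put2) {
      pos <- len - nchar(w2) - 1
      substr(s, pos, pos + nchar(w2) - 1) <- w2
    }
    s
  }, "")
  contrast(sequence_set(sig, name = "sig"),
           sequence_set(random_dna(n, len), name = "ctl"))
}

fast_config <- function() training_config(objective = "mico",
                                          max_iterations = 25,
                                          tolerance = 1e-4)

test_that("candidate pools reproduce the lengths x seeds x variants counts", {
  set.seed(52)
  ct <- contrast(sequence_set(random_dna(40, 30), name = "sig"),
                 sequence_set(random_dna(40, 30), name = "ctl"))
  pool <- candidate_pool(ct, 5:10, per_length = 3, shifts = 1)
  expect_length(pool, 6 * 3 * 3)
  pool2 <- candidate_pool(ct, 5:16, per_length = 3, shifts = 1)
  expect_length(pool2, 12 * 3 * 3)
  pool3 <- candidate_pool(ct, 6, per_length = 1, shifts = 0)
  expect_length(pool3, 1L)
})

test_that("the strongest planted motif is selected first", {
  ct <- two_motif_contrast(p2 = 0)
  pool <- candidate_pool(ct, 8, per_length = 2, shifts = 0)
  state <- select_first(pool, ct, fast_config())
  expect_s3_class(state, "motif_set_state")
  expect_true(state$sig$accepted)
  # the accepted word should overlap the planted one substantially
  seedword <- vapply(state$accepted, function(m) as.character(m$word), "")
  expect_gt(mico(count_table(ct, state$accepted[[1L]]$word)), 0.2)
})

test_that("no candidate survives on label-free data", {
  set.seed(53)
  seqs <- random_dna(40, 25)
  ct <- contrast(sequence_set(seqs, name = "a"),
                 sequence_set(seqs, name = "b"))
  pool <- candidate_pool(ct, 6, per_length = 2, shifts = 0)
  expect_null(select_first(pool, ct, fast_config()))
})

train_word <- function(word, ct) {
  discrimotif:::train_candidate(list(word = iupac_word(word), length = 8L),
                                contrast_collection(ct), fast_config())
}

state_of <- function(cand) {
  structure(list(accepted = list(cand), joint_hmm = cand$fit$hmm,
                 sig = cand$sig, pool = list(cand), threshold = 0.05,
                 alpha = 0.03),
            class = "motif_set_state")
}

test_that("cMI gates reject redundant and accept independent candidates", {
  ct <- two_motif_contrast()
  a <- train_word("CCGGACGG", ct)
  b <- train_word("TGTAAATA", ct)
  state <- state_of(a)
  # a candidate identical to the accepted motif carries no residual
  # information: cMICO ~ 0, rejected
  self_gate <- cmi_gate(state, a, ct)
  expect_false(self_gate$accept)
  expect_lt(self_gate$diagnostics$cmico[1L], 1e-6)
  # an independently implanted second motif passes the gate
  gate <- cmi_gate(state, b, ct)
  expect_true(gate$accept)
  expect_gt(gate$diagnostics$ratio[1L], 1)
})

test_that("perfectly co-occurring motifs fail the ratio gate", {
  ct <- two_motif_contrast(correlated = TRUE, seed = 54)
  a <- train_word("CCGGACGG", ct)
  b <- train_word("TGTAAATA", ct)
  gate <- cmi_gate(state_of(a), b, ct, ratio_threshold = 1)
  # co-implanted: motif-pair cMI dominates the residual contribution
  expect_false(gate$accept)
  expect_lt(gate$diagnostics$ratio[1L], 1)
})

test_that("growth stops when the p-value no longer improves", {
  ct <- two_motif_contrast(p2 = 0, seed = 55)
  state <- discover_motifs(ct, 8, per_length = 2, shifts = 0,
                           config = fast_config(), max_motifs = 3)
  expect_false(is.null(state))
  expect_length(state$accepted, 1L)
  report <- attr(state, "report")
  expect_equal(nrow(report), 1L)
})
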