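toy_hmm <- function(seed = "AWG", data = c("ACGTACGTTTAA"), avg_len = 8) {
  bg <- train_background(sequence_set(data, name = "bgset"))
  add_motif_chain(bg, seed, avg_len = avg_len)
}

test_that("background training reaches the empirical-frequency fixed point", {
  expect_equal(unname(train_background(sequence_set("AAAA"),
                                       pseudocount = 0)$emis[1L, ]),
               c(1, 0, 0, 0))
  set.seed(11)
  s <- sequence_set(random_dna(200, 50))
  bg <- train_background(s, pseudocount = 0)
  expect_equal(unname(bg$emis[1L, ]), rep(0.25, 4), tolerance = 0.02)
  # pooling over two sets
  a <- sequence_set("AAAA", name = "a"); cset <- sequence_set("CCCC", name = "c")
  bg2 <- train_background(list(a, cset), pseudocount = 0)
  expect_equal(unname(bg2$emis[1L, ]), c(0.5, 0.5, 0, 0))
  # one Baum-Welch step on a 1-state model does not move the fixed point
  upd <- baum_welch_update(bg, s, frozen = character(0))
  expect_equal(upd$emis, bg$emis, tolerance = 1e-6)
})

test_that("motif chain initialization reproduces the seeding arithmetic", {
  bg <- train_background(sequence_set(strrep("ACGT", 5)))
  h <- add_motif_chain(bg, "AWN", alpha = 0.03, avg_len = 10)
  m <- h$motifs[[1L]]
  expect_equal(unname(h$emis[m$states[1L], ]), c(0.91, 0.03, 0.03, 0.03))
  expect_equal(unname(h$emis[m$states[2L], ]), c(0.47, 0.03, 0.03, 0.47))
  expect_equal(unname(h$emis[m$states[3L], ]), rep(0.25, 4))
  # transition P = 1/(l - w + 1)
  expect_equal(h$trans[1L, m$states[1L]], 1 / (10 - 3 + 1))
  expect_error(add_motif_chain(bg, "ACGTACGT", avg_len = 5),
               "configuration error")
  expect_equal(unname(rowSums(h$trans)), rep(1, nrow(h$trans)))
  expect_equal(unname(rowSums(h$emis)), rep(1, nrow(h$emis)))
})

test_that("forward-backward matches closed forms and path enumeration", {
  bg <- discrimotif:::background_hmm(rep(0.25, 4))
  fb <- forward_backward(bg, "ACGT")
  expect_equal(fb$loglik, 4 * log(0.25))
  h <- toy_hmm()
  fb2 <- forward_backward(h, "ACGTAN")
  expect_equal(unname(rowSums(fb2$gamma)), rep(1, 6), tolerance = 1e-12)
  set.seed(12)
  for (s in c("ACGTAN", "AAGGTT", random_dna(5, 6))) {
    expect_equal(forward_backward(h, s)$loglik, log(brute_path_prob(h, s)),
                 tolerance = 1e-9)
  }
})

test_that("posterior occurrence equals the constrained-path ratio", {
  h <- toy_hmm()
  set.seed(13)
  for (s in random_dna(6, 6)) {
    expect_equal(posterior_occurrence(h, s), brute_p_occ(h, s),
                 tolerance = 1e-9)
  }
  # no admissible path: sequence shorter than the motif still has bg paths,
  # but a zero background-to-motif transition forces p = 0
  h0 <- h
  m <- h0$motifs[[1L]]
  h0$trans[1L, m$states[1L]] <- 0
  h0$trans[1L, 1L] <- 1 - sum(h0$trans[1L, -1L])
  expect_equal(posterior_occurrence(h0, "ACGTACGT"), 0)
  expect_equal(posterior_occurrence(h, "AC"), 0)  # shorter than motif
  # monotone in the background-to-motif transition probability
  ps <- vapply(c(0.001, 0.01, 0.1, 0.3), function(p) {
    h2 <- h
    h2$trans[1L, m$states[1L]] <- p
    h2$trans[1L, 1L] <- 1 - sum(h2$trans[1L, -1L])
    posterior_occurrence(h2, "CAAGCC")
  }, 0)
  expect_true(all(diff(ps) > 0))
})

test_that("expected tables sum posterior occurrences per condition", {
  h <- toy_hmm()
  set.seed(14)
  sig <- sequence_set(random_dna(8, 12), name = "sig")
  ctl <- sequence_set(random_dna(6, 12), name = "ctl")
  tb <- expected_tables(h, contrast(sig, ctl))[[1L]]
  expect_equal(tb["sig", "with"], sum(posterior_occurrence(h, sig)))
  expect_equal(tb["ctl", "with"], sum(posterior_occurrence(h, ctl)))
  expect_equal(unname(rowSums(tb)), c(8, 6))
})

test_that("viterbi decoding reports implant sites and respects the separator", {
  bg <- discrimotif:::background_hmm(rep(0.25, 4), avg_len = 20)
  h <- add_motif_chain(bg, "TGTAAATA", alpha = 0.01)
  expect_equal(nrow(viterbi_sites(h, "CCCCCCCCCCCCCCCC")), 0L)
  v <- viterbi_sites(h, "CCCCCTGTAAATACCCC")
  expect_equal(v[, c("start", "end")],
               data.frame(start = 5L, end = 13L), ignore_attr = TRUE)
  # double-stranded extension: a site on the rc half stays within it
  x <- extend_double_stranded("CCCCCTATTTACACCCC")  # rc contains TGTAAATA
  v2 <- viterbi_sites(h, x)
  L <- 17L
  expect_true(all(v2$end <= L | v2$start >= L + 1L))
  expect_true(any(v2$start >= L + 1L))
})

test_that("models serialize to JSON and back", {
  h <- toy_hmm()
  f <- withr::local_tempfile(fileext = ".json")
  write_hmm_json(h, f)
  h2 <- read_hmm_json(f)
  expect_equal(h2$trans, h$trans)
  expect_equal(h2$emis, h$emis)
  expect_equal(h2$motifs[[1L]]$states, h$motifs[[1L]]$states)
  expect_equal(posterior_occurrence(h2, "ACGTAA"),
               posterior_occurrence(h, "ACGTAA"))
})

test_that("insert states are wired when enabled and stay off by default", {
  bg <- train_background(sequence_set(strrep("ACGT", 10)))
  h <- add_motif_chain(bg, "ACGT", insert = TRUE, insert_prob = 0.1)
  m <- h$motifs[[1L]]
  expect_length(m$insert_states, 3L)
  expect_equal(unname(rowSums(h$trans)), rep(1, nrow(h$trans)))
  # insert states are not self-transiting
  for (i in m$insert_states) expect_equal(h$trans[i, i], 0)
  h0 <- add_motif_chain(bg, "ACGT")
  expect_length(h0$motifs[[1L]]$insert_states, 0L)
})
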