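toy_contrast <- function(seed = 21) {
  set.seed(seed)
  sig <- sequence_set(paste0(random_dna(6, 3), "AAGG", random_dna(6, 3)),
                      name = "sig")
  ctl <- sequence_set(random_dna(6, 10), name = "ctl")
  contrast(sig, ctl)
}

seeded_hmm <- function(ct, seed_word = "AAGG") {
  bg <- train_background(ct$conditions)
  add_motif_chain(bg, seed_word)
}

fd_check <- function(objective, scheme = "hybrid", tol = 1e-4) {
  ct <- toy_contrast()
  h <- seeded_hmm(ct)
  td <- discrimotif:::prepare_training_data(ct)
  mmie <- NULL
  if (objective == "mmie")
    mmie <- discrimotif:::eval_objective(h, td, "mmie")$mmie
  g <- grad_objective(objective, h, ct, mmie = mmie, scheme = scheme)
  blocks <- discrimotif:::active_blocks(h, scheme)
  z0 <- discrimotif:::pack_params(h, blocks)
  f <- function(z) discrimotif:::eval_objective(
    discrimotif:::unpack_params(h, blocks, z), td, objective, mmie)$J
  gfd <- fd_grad(f, z0)
  scale <- max(abs(gfd), 1e-3)
  expect_lt(max(abs(g - gfd)) / scale, tol,
            label = paste("relative gradient error for", objective, scheme))
}

test_that("objective gradients match central finite differences", {
  for (obj in c("mico", "dfreq", "mcc", "dlogl", "mmie")) fd_check(obj)
  fd_check("mico", scheme = "all")
  fd_check("logl", scheme = "all")
})

test_that("likelihood gradient vanishes at the one-state fixed point", {
  set.seed(22)
  s <- sequence_set(random_dna(10, 20))
  bg <- train_background(s, pseudocount = 0)
  g <- grad_log_likelihood(bg, s)
  expect_lt(max(abs(g$emis)), 1e-8)
})

test_that("an unreachable motif chain receives zero emission gradient", {
  ct <- toy_contrast()
  h <- seeded_hmm(ct)
  m <- h$motifs[[1L]]
  h$trans[1L, m$states[1L]] <- 0
  h$trans[1L, 1L] <- 1 - sum(h$trans[1L, -1L])
  g <- grad_log_likelihood(h, ct$conditions[[1L]])
  expect_equal(max(abs(g$emis[m$states, ])), 0)
})

test_that("posterior-occurrence gradients are consistent", {
  ct <- toy_contrast()
  h <- seeded_hmm(ct)
  g1 <- grad_posterior_occurrence(h, "ACAAGGTCAT")
  g2 <- grad_posterior_occurrence(h, "ACAAGGTCAT")
  expect_identical(g1, g2)  # identical sequences, identical gradients
  # finite differences on the match-state emissions
  m <- h$motifs[[1L]]
  blocks <- list(list(kind = "emis", rows = m$states))
  z0 <- discrimotif:::pack_params(h, blocks)
  f <- function(z) posterior_occurrence(
    discrimotif:::unpack_params(h, blocks, z), "ACAAGGTCAT")
  gfd <- fd_grad(f, z0)
  expect_lt(max(abs(as.numeric(g1$emis[m$states, ]) - gfd)) /
              max(abs(gfd), 1e-3), 1e-4)
})

test_that("MICO gradient is flat when signal equals control", {
  set.seed(23)
  seqs <- random_dna(8, 12)
  ct <- contrast(sequence_set(seqs, name = "a"),
                 sequence_set(seqs, name = "b"))
  h <- seeded_hmm(ct, "ACGT")
  g <- grad_objective("mico", h, ct)
  expect_lt(max(abs(g)), 1e-8)
})

test_that("line search solves a concave quadratic and detects stagnation", {
  smax <- 3.7
  fg <- function(a) list(f = -(a - smax)^2, g = -2 * (a - smax))
  r <- line_search(fg, f0 = -(0 - smax)^2, g0 = 2 * smax, c2 = 0.01)
  expect_true(r$converged)
  expect_lt(abs(r$step - smax) / smax, 0.01)
  # Wolfe conditions verified post hoc
  f0 <- -smax^2; g0 <- 2 * smax
  at <- fg(r$step)
  expect_gte(at$f, f0 + 1e-4 * r$step * g0)
  expect_lte(abs(at$g), 0.01 * abs(g0))
  # at a maximum already
  r0 <- line_search(fg, f0 = 0, g0 = 0)
  expect_identical(r0$step, 0)
  expect_true(r0$stagnated)
})

test_that("Baum-Welch updates are monotone and respect freezes", {
  set.seed(24)
  ct <- toy_contrast()
  h <- seeded_hmm(ct)
  ll <- function(h) sum(discrimotif:::cond_loglik(
    h, c(discrimotif:::hmm_parts(ct$conditions[[1L]]$seqs),
         list(name = "sig")), rep(TRUE, discrimotif:::n_states(h))))
  prev <- ll(h)
  for (i in 1:10) {
    h <- baum_welch_update(h, ct$conditions[[1L]], frozen = character(0))
    cur <- ll(h)
    expect_gte(cur, prev - 1e-9)
    prev <- cur
  }
  h2 <- seeded_hmm(ct)
  frozen_all <- baum_welch_update(h2, ct$conditions[[1L]],
                                  frozen = c("signal", "background",
                                             "transitions"))
  expect_identical(frozen_all$trans, h2$trans)
  expect_identical(frozen_all$emis, h2$emis)
})

test_that("hybrid fitting ascends the objective and keeps simplexes", {
  ct <- toy_contrast()
  h <- seeded_hmm(ct)
  td <- discrimotif:::prepare_training_data(ct)
  J0 <- discrimotif:::eval_objective(h, td, "mico")$J
  fr <- fit(h, ct, training_config(objective = "mico",
                                   max_iterations = 15, tolerance = 1e-5))
  expect_gte(fr$objective, J0 - 1e-12)
  expect_equal(unname(rowSums(fr$hmm$trans)), rep(1, nrow(fr$hmm$trans)),
               tolerance = 1e-12)
  expect_equal(unname(rowSums(fr$hmm$emis)), rep(1, nrow(fr$hmm$emis)),
               tolerance = 1e-12)
  expect_true(all(fr$hmm$emis >= 0 & fr$hmm$emis <= 1))
  expect_s3_class(fr$trace, "data.frame")
  expect_gte(nrow(fr$trace), 2L)
  # a 1-iteration budget performs exactly one alternation
  fr1 <- fit(seeded_hmm(ct), ct,
             training_config(objective = "mico", max_iterations = 1))
  expect_equal(max(fr1$trace$iteration), 1L)
})

test_that("fitting is deterministic under a fixed seed", {
  ct <- toy_contrast()
  cfg <- training_config(objective = "mico", max_iterations = 8, seed = 99)
  f1 <- fit(seeded_hmm(ct), ct, cfg)
  f2 <- fit(seeded_hmm(ct), ct, cfg)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$hmm$emis, f2$hmm$emis)
})

test_that("training recovers a planted high-IC motif", {
  set.seed(25)
  pwm <- polarize_pwm(random_pwm(6), 10)
  sig <- sequence_set(vapply(1:60, function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
               collapse = "")
    pos <- sample(1:25, 1)
    substr(s, pos, pos + 5) <- discrimotif:::sample_from_pwm(pwm)
    s
  }, ""), name = "sig")
  ctl <- sequence_set(random_dna(60, 30), name = "ctl")
  ct <- contrast(sig, ctl)
  sr <- find_seed(ct, 6, "mico")
  h <- add_motif_chain(train_background(ct$conditions), sr$word)
  fr <- fit(h, ct, training_config(objective = "mico",
                                   max_iterations = 60, tolerance = 1e-5))
  est <- motif_pwm(fr$hmm)
  tv <- rowSums(abs(est - unclass(pwm))) / 2
  expect_lt(mean(tv), 0.1)
})
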