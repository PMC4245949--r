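test_that("IUPAC words know their degeneracy and generalizations", {
  expect_equal(iupac_degeneracy("ACGT"), 0L)
  expect_equal(iupac_degeneracy("NNN"), 9L)
  expect_equal(iupac_degeneracy("TGTAHATA"), 2L)
  gens <- vapply(generalize("ACG"), as.character, "")
  expect_setequal(gens, c("MCG", "RCG", "WCG",   # [AC] [AG] [AT] at pos 1
                          "AMG", "ASG", "AYG",   # [AC] [CG] [CT] at pos 2
                          "ACR", "ACS", "ACK"))  # [AG] [CG] [GT] at pos 3
  expect_length(gens, 9L)
  expect_length(generalize("NNN"), 0L)
  set.seed(4)
  w <- paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE), collapse = "")
  expect_length(generalize(w), 3L * 6L)
})

test_that("word enumeration counts sequences, not positions", {
  ct <- contrast(sequence_set("ACGT", name = "s"),
                 sequence_set("TTTT", name = "c"))
  e <- enumerate_words(ct, 4)
  expect_true("ACGT" %in% e$words)
  expect_equal(e$counts[e$words == "ACGT", ], c(1L, 0L))
  ct2 <- contrast(sequence_set("AAAA", name = "s"),
                  sequence_set("CCCC", name = "c"))
  e2 <- enumerate_words(ct2, 2)
  expect_equal(e2$counts[e2$words == "AA", 1L], 1L)  # one sequence, not 3
  # double strand: rc of ACGT is itself
  e3 <- enumerate_words(ct, 4, strand = "double")
  expect_equal(e3$counts[e3$words == "ACGT", 1L], 1L)
})

test_that("score_and_retain sorts, truncates and breaks ties lexically", {
  ct <- contrast(sequence_set(c("AATT", "AACC", "AAGG"), name = "s"),
                 sequence_set(c("GGTT", "GGCC"), name = "c"))
  cand <- enumerate_words(ct, 2)
  top <- score_and_retain(cand, ct, "mico", n = 100)
  expect_lte(nrow(top), 100)
  expect_true(all(diff(top$score) <= 1e-12))
  ties <- top$score == max(top$score)
  expect_equal(top$word[ties], sort(top$word[ties]))
  expect_equal(nrow(score_and_retain(cand, ct, "mico", n = 1)), 1L)
})

test_that("find_seed attains the exhaustive IUPAC maximum on tiny data", {
  sig <- sequence_set(c("TACGT", "TAGGT", "AACGA", "CAGGC", "TACGG"),
                      name = "sig")
  ctl <- sequence_set(c("TTTTT", "CCCCC", "GTGTG", "CTCTC", "TCTCT"),
                      name = "ctl")
  ct <- contrast(sig, ctl)
  r <- find_seed(ct, 3, "mico", n = Inf)
  # regex-based exhaustive maximum over all 15^3 IUPAC words
  words <- all_iupac_words(3)
  scores <- vapply(words, function(w) {
    mico(contingency_table(c(regex_count_with(sig$seqs, w),
                             regex_count_with(ctl$seqs, w)), c(5, 5)))
  }, 0)
  expect_equal(r$score, max(scores), tolerance = 1e-12)
  expect_equal(r$score,
               aggregate_objective("mico", r$tables), tolerance = 1e-12)
})

test_that("find_seed is deterministic and degenerates correctly", {
  set.seed(5)
  seqs <- random_dna(10, 20)
  ct <- contrast(sequence_set(seqs, name = "a"),
                 sequence_set(seqs, name = "b"))
  r <- find_seed(ct, 4, "mico")
  expect_equal(r$score, 0, tolerance = 1e-12)  # identical sets: MICO 0
  sig <- sequence_set(c(paste0(random_dna(10, 5), "TGTAAATA"),
                        random_dna(5, 13)), name = "sig")
  ctl <- sequence_set(random_dna(15, 13), name = "ctl")
  ct2 <- contrast(sig, ctl)
  r1 <- find_seed(ct2, 8, "mico")
  r2 <- find_seed(ct2, 8, "mico")
  expect_identical(as.character(r1$word), as.character(r2$word))
  expect_identical(r1$score, r2$score)
  # the planted word is matched by the winner at least as well as by itself
  planted <- mico(count_table(ct2, "TGTAAATA"))
  expect_gte(r1$score, planted - 1e-12)
})

test_that("degeneracy caps are honored, absolute and relative", {
  expect_equal(discrimotif:::resolve_degeneracy_cap(NULL, 8), 24L)
  expect_equal(discrimotif:::resolve_degeneracy_cap(2, 8), 2L)
  expect_equal(discrimotif:::resolve_degeneracy_cap(0.25, 8), 6L)
  sig <- sequence_set(c("AAAT", "AAAG", "AAAC"), name = "s")
  ctl <- sequence_set(c("GGGG", "CCCC", "TTTT"), name = "c")
  r <- find_seed(contrast(sig, ctl), 4, "mico", max_degeneracy = 0)
  expect_equal(iupac_degeneracy(r$word), 0L)
})

test_that("multiple seeds are found by masking or discarding", {
  set.seed(6)
  left <- random_dna(12, 4)
  sig <- sequence_set(paste0(left, "TGTAAATA", random_dna(12, 4),
                             "CCGGCCGG"), name = "sig")
  ctl <- sequence_set(random_dna(12, 24), name = "ctl")
  ct <- contrast(sig, ctl)
  rs <- find_multiple_seeds(ct, 8, "mico", count = 2, mode = "mask")
  expect_length(rs, 2L)
  words <- vapply(rs, function(r) as.character(r$word), "")
  r1 <- find_seed(ct, 8, "mico")
  expect_identical(words[1L], as.character(r1$word))
  expect_false(words[1L] == words[2L])
  # count = 1 equals find_seed
  rs1 <- find_multiple_seeds(ct, 8, "mico", count = 1)
  expect_identical(as.character(rs1[[1L]]$word), as.character(r1$word))
  # discard mode with a word present everywhere exhausts the signal
  sig2 <- sequence_set(paste0("TGTAAATA", random_dna(8, 4)), name = "sig")
  ctl2 <- sequence_set(random_dna(8, 12), name = "ctl")
  rs2 <- find_multiple_seeds(contrast(sig2, ctl2), 8, "mico",
                             count = 3, mode = "discard")
  expect_lt(length(rs2), 3L)
})

test_that("masked counting agrees with the plain scanner", {
  set.seed(10)
  sets <- list(random_dna(15, 25), random_dna(10, 25))
  words <- c("AWGC", "NNAA", "SSWW", "ACGT")
  masks <- discrimotif:::iupac_mask_matrix(lapply(words, iupac_word))
  plain <- discrimotif:::count_words_sets_c(sets, masks)
  res <- discrimotif:::count_words_sets_masked_c(
    sets, masks, matrix(FALSE, length(words), 25))
  expect_equal(res$counts, plain)
  # seeding `known` with true matches must not change the counts
  res2 <- discrimotif:::count_words_sets_masked_c(sets, masks, res$hits)
  expect_equal(res2$counts, plain)
  # regex cross-check
  for (i in seq_along(words))
    expect_equal(plain[i, 1L], regex_count_with(sets[[1L]], words[i]))
})
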