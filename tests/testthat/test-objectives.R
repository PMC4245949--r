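tab <- function(with, n) contingency_table(with, n, c("signal", "control"))

test_that("mico reproduces closed forms and the summation oracle", {
  expect_equal(mico(tab(c(10, 0), c(10, 10))), 1.0)
  expect_equal(mico(tab(c(5, 5), c(10, 10))), 0.0)
  t <- tab(c(8, 3), c(10, 10))
  expect_equal(mico(t), brute_mi(unclass(t)), tolerance = 1e-12)
  set.seed(1)
  for (i in 1:20) {
    t <- contingency_table(runif(3, 0, 10), rep(12, 3))
    expect_equal(mico(t), brute_mi(unclass(t)), tolerance = 1e-10)
  }
})

test_that("dfreq and mcc match their formulas and domains", {
  expect_equal(dfreq(tab(c(10, 0), c(10, 10))), 1.0)
  expect_equal(dfreq(tab(c(5, 5), c(10, 10))), 0.0)
  expect_equal(dfreq(tab(c(8, 3), c(10, 10))), 0.5)
  expect_equal(mcc(tab(c(10, 0), c(10, 10))), 1.0)
  expect_equal(mcc(tab(c(5, 5), c(10, 10))), 0.0)
  expect_equal(mcc(tab(c(8, 3), c(10, 10))),
               (8 * 7 - 2 * 3) / sqrt(10 * 10 * 11 * 9))
  t3 <- contingency_table(c(1, 2, 3), c(5, 5, 5))
  expect_error(dfreq(t3), "binary")
  expect_error(mcc(t3), "binary")
  # zero marginal convention
  expect_equal(mcc(tab(c(0, 0), c(10, 10))), 0)
})

test_that("conditional_mi matches the summation oracle and degenerates", {
  # independent variables
  a <- array(1, dim = c(2, 2, 2))
  expect_equal(conditional_mi(a, 1, 2), 0)
  # conditioning on a constant reduces to plain MI
  m <- matrix(c(8, 2, 3, 7), 2, byrow = TRUE)
  a <- array(0, dim = c(2, 2, 1)); a[, , 1] <- m
  expect_equal(conditional_mi(a, 1, 2), brute_mi(m), tolerance = 1e-12)
  set.seed(2)
  for (i in 1:10) {
    a <- array(runif(8, 0, 5), dim = c(2, 2, 2))
    expect_equal(conditional_mi(a, 1, 2), brute_cmi(a), tolerance = 1e-10)
  }
})

test_that("objective aggregation sums contrasts and guards MCC", {
  t <- tab(c(8, 3), c(10, 10))
  expect_equal(aggregate_objective("mico", list(t)), mico(t))
  expect_equal(aggregate_objective("mico", list(t, t)), 2 * mico(t))
  expect_equal(aggregate_objective("dfreq", list(t, t)), 2 * dfreq(t))
  expect_error(aggregate_objective("mcc", list(t, t)), "invalid objective")
})

test_that("objective invariants hold on random tables", {
  set.seed(3)
  for (i in 1:30) {
    k <- sample(2:4, 1)
    n <- rep(10, k)
    t <- contingency_table(runif(k, 0, 10), n)
    expect_gte(mico(t), -1e-12)
    expect_lte(mico(t), 1 + 1e-12)  # log2 min(rows, 2) = 1 bit
    perm <- sample(k)
    tp <- contingency_table(t[perm, 1L], n[perm])
    expect_equal(mico(tp), mico(t), tolerance = 1e-12)
    if (k == 2L) {
      swapped <- contingency_table(t[2:1, 1L], n[2:1])
      expect_equal(dfreq(swapped), -dfreq(t), tolerance = 1e-12)
      if (abs(dfreq(t)) > 1e-9 && all(colSums(t) > 0))
        expect_equal(sign(dfreq(t)), sign(mcc(t)))
      expect_gte(mcc(t), -1)
      expect_lte(mcc(t), 1)
    }
  }
})

test_that("mico is continuous in fractional cell values", {
  t <- tab(c(6.25, 3.5), c(10, 10))
  eps <- 1e-7
  t2 <- tab(c(6.25 + eps, 3.5), c(10, 10))
  expect_lt(abs(mico(t2) - mico(t)), 1e-5)
})

test_that("count_table counts sequence-level presence per condition", {
  ct <- contrast(sequence_set(c("TGTA", "CCCC"), name = "signal"),
                 sequence_set("CCCC", name = "control"))
  t <- count_table(ct, "TGTA")
  expect_equal(unclass(t), cbind(with = c(1, 0), without = c(1, 1)),
               ignore_attr = TRUE)
  t0 <- count_table(ct, "GGGG")
  expect_equal(unname(t0[, 1L]), c(0, 0))
  # double-stranded: TACA contains rc(TGTA)
  ct2 <- contrast(sequence_set("TACA", name = "signal"),
                  sequence_set("GGGG", name = "control"))
  expect_equal(unname(count_table(ct2, "TGTA", strand = "double")[, 1L]),
               c(1, 0))
  expect_equal(unname(count_table(ct2, "TGTA", strand = "single")[, 1L]),
               c(0, 0))
})
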