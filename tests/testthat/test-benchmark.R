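test_that("polarization reaches target information content", {
  set.seed(41)
  raw <- random_pwm(8)
  expect_equal(pwm_ic(polarize_pwm(raw, 0)), 0, tolerance = 1e-9)
  hi <- polarize_pwm(raw, 15.9, tol = 1e-3)
  expect_equal(pwm_ic(hi), 15.9, tolerance = 1e-3)
  mid <- polarize_pwm(raw, 10, tol = 1e-3)
  expect_equal(pwm_ic(mid), 10, tolerance = 1e-3)
  for (i in 1:10) {
    target <- runif(1, 0.5, 15.5)
    p <- polarize_pwm(random_pwm(8), target, tol = 1e-3)
    expect_equal(pwm_ic(p), target, tolerance = 1e-3)
    expect_equal(unname(rowSums(p)), rep(1, 8), tolerance = 1e-12)
  }
})

test_that("dataset generation is reproducible and truthful", {
  p <- bench_params(n_seq = 100, seq_len = 40, implant_prob = 1,
                    signal_ic = 12)
  d1 <- generate_dataset(p, seed = 5)
  d2 <- generate_dataset(p, seed = 5)
  expect_identical(d1$signal$seqs, d2$signal$seqs)
  expect_identical(d1$truth, d2$truth)
  # 100% implantation: one site per signal sequence
  expect_equal(nrow(d1$truth), 100L)
  expect_true(all(d1$truth$kind == "signal"))
  expect_true(all(d1$truth$start >= 0 & d1$truth$end <= 40))
  # implanted occurrences carry the motif's consensus enrichment
  cons <- paste(NUCS[apply(d1$pwm, 1L, which.max)], collapse = "")
  hits <- sum(lengths(discrimotif:::match_positions_c(
    d1$signal$seqs, iupac_word(cons)$masks)) > 0)
  expect_gt(hits, 15)
})

test_that("implant counts follow the binomial design", {
  p <- bench_params(n_seq = 10000, seq_len = 20, implant_prob = 0.1,
                    signal_ic = 8)
  d <- generate_dataset(p, seed = 6)
  n <- sum(d$truth$kind == "signal")
  expect_lt(abs(n - 1000), 4 * sqrt(10000 * 0.1 * 0.9))
})

test_that("decoy design implants into both sets before the signal", {
  p <- bench_params(n_seq = 200, seq_len = 60, implant_prob = 0,
                    signal_ic = 10, decoy_prob = 0.5, decoy_ic = 12)
  d <- generate_dataset(p, seed = 7)
  expect_true(all(d$truth$kind == "decoy"))
  expect_true(any(grepl("^signal", d$truth$seq_id)))
  expect_true(any(grepl("^control", d$truth$seq_id)))
  # overlap removal: with signal implants, no decoy record overlaps a signal
  p2 <- bench_params(n_seq = 200, seq_len = 60, implant_prob = 0.8,
                     signal_ic = 10, decoy_prob = 0.8, decoy_ic = 12)
  d2 <- generate_dataset(p2, seed = 8)
  sg <- d2$truth[d2$truth$kind == "signal", ]
  dc <- d2$truth[d2$truth$kind == "decoy", ]
  for (i in seq_len(nrow(dc))) {
    same <- sg[sg$seq_id == dc$seq_id[i], , drop = FALSE]
    if (nrow(same))
      expect_true(all(same$start >= dc$end[i] | same$end <= dc$start[i]))
  }
})

test_that("dinucleotide shuffles conserve composition exactly", {
  expect_equal(dinucleotide_shuffle("AAAA", seed = 1), "AAAA")
  set.seed(42)
  for (s in random_dna(15, 40)) {
    sh <- dinucleotide_shuffle(s)
    expect_equal(dinuc_counts(sh), dinuc_counts(s))
    expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
    expect_equal(substr(sh, 40, 40), substr(s, 40, 40))
  }
  # all shuffles of a short word lie in the enumerable Eulerian set
  s <- "ACGCG"
  perms <- unique(apply(
    gtools_perms <- as.matrix(expand.grid(rep(list(c("A", "C", "G")), 3))),
    1L, function(mid) paste0("A", paste(mid, collapse = ""), "G")))
  valid <- perms[vapply(perms, function(x) {
    identical(sort(paste(names(dinuc_counts(x)), dinuc_counts(x))),
              sort(paste(names(dinuc_counts(s)), dinuc_counts(s)))) &&
      identical(table(strsplit(x, "")[[1]]), table(strsplit(s, "")[[1]]))
  }, TRUE)]
  for (i in 1:10)
    expect_true(dinucleotide_shuffle(s) %in% valid)
})

test_that("the recognizability model encodes the generation parameters", {
  set.seed(43)
  pwm <- polarize_pwm(random_pwm(8), 10)
  h <- recognizability_model(pwm, 0.1, 100)
  m <- h$motifs[[1L]]
  expect_equal(h$trans[1L, m$states[1L]], 0.001)  # 0.1 x 0.01
  expect_equal(recognizability_model(pwm, 1, 100)$trans[1L, 2L], 0.01)
  expect_equal(unname(motif_pwm(h)), unname(unclass(pwm)),
               ignore_attr = TRUE)
  expect_equal(unname(h$emis[1L, ]), rep(0.25, 4))
})

site_df <- function(...) {
  d <- data.frame(...)
  names(d) <- c("seq_id", "start", "end")
  d
}

test_that("site evaluation applies the 50% overlap rule", {
  truth <- site_df("s1", 10, 18)
  perfect <- evaluate_sites(truth, truth, 1000)
  expect_equal(perfect$nCC, 1)
  expect_equal(perfect$sSn, 1); expect_equal(perfect$sPPV, 1)
  expect_equal(perfect$sAP, 1)
  none <- evaluate_sites(truth[0, ], truth, 1000)
  expect_equal(none$nCC, 0)  # degenerate convention
  expect_equal(none$sSn, 0); expect_equal(none$sPPV, 0)
  # 4 of 8 nt overlap is a site TP, 3 of 8 is not
  at4 <- evaluate_sites(site_df("s1", 14, 22), truth, 1000)
  expect_equal(at4$counts[["site_tp"]], 1)
  expect_equal(at4$sSn, 1); expect_equal(at4$sPPV, 1)
  at3 <- evaluate_sites(site_df("s1", 15, 23), truth, 1000)
  expect_equal(at3$counts[["site_tp"]], 0)
  expect_equal(at3$sSn, 0)
  # greedy 1-to-1: two predictions over one truth site yield one TP
  two <- evaluate_sites(site_df(c("s1", "s1"), c(10, 12), c(18, 20)),
                        truth, 1000)
  expect_equal(two$counts[["site_tp"]], 1)
  expect_equal(two$sPPV, 0.5)
})

test_that("pooled summaries recompute metrics from summed counts", {
  truth <- site_df("s1", 10, 18)
  a <- evaluate_sites(truth, truth, 1000)
  expect_equal(summarize_performance(list(a)), a)
  expect_equal(summarize_performance(list(a, a))$nCC, a$nCC)
  b <- evaluate_sites(truth[0, ], truth, 1000)
  pooled <- summarize_performance(list(a, b))
  expect_gt(pooled$nCC, 0); expect_lt(pooled$nCC, 1)
  expect_equal(pooled$counts[["nt_tp"]],
               a$counts[["nt_tp"]] + b$counts[["nt_tp"]])
  expect_equal(pooled$sSn, 0.5)
})
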