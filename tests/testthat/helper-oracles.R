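# Independent oracles used across the suite: brute-force path enumeration
# for HMM likelihoods and posteriors, regex-based IUPAC matching, direct
# summation formulas for information measures, and finite differences.

# total path probability by explicit enumeration (tiny instances only)
brute_path_prob <- function(hmm, s, exclude = integer(0)) {
  x <- discrimotif:::encode_dna_c(s)[[1L]]
  S <- nrow(hmm$trans)
  T_ <- length(x)
  pi <- unname(hmm$trans[hmm$bg, ])
  endw <- discrimotif:::hmm_end_weights(hmm)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), T_)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    st <- paths[r, ]
    if (any(st %in% exclude)) next
    p <- pi[st[1L]] * (if (x[1L] == 0L) 1 else hmm$emis[st[1L], x[1L]])
    if (T_ > 1L) for (t in 2:T_) {
      p <- p * hmm$trans[st[t - 1L], st[t]] *
        (if (x[t] == 0L) 1 else hmm$emis[st[t], x[t]])
    }
    tot <- tot + p * endw[st[T_]]
  }
  unname(tot)
}

brute_p_occ <- function(hmm, s, motif = "any") {
  excl <- which(!discrimotif:::state_mask(hmm, motif))
  1 - brute_path_prob(hmm, s, excl) / brute_path_prob(hmm, s)
}

# direct-summation mutual information of a count matrix, in bits
brute_mi <- function(t) {
  n <- sum(t)
  p <- t / n
  pr <- rowSums(p); pc <- colSums(p)
  tot <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0)
      tot <- tot + p[i, j] * log2(p[i, j] / (pr[i] * pc[j]))
  }
  unname(tot)
}

# direct-summation conditional MI I(X;Y|Z) of a 3-way count array, in bits
brute_cmi <- function(a) {
  n <- sum(a)
  tot <- 0
  for (i in seq_len(dim(a)[1L])) for (j in seq_len(dim(a)[2L]))
    for (k in seq_len(dim(a)[3L])) {
      p <- a[i, j, k] / n
      if (p > 0) {
        pz <- sum(a[, , k]) / n
        pxz <- sum(a[i, , k]) / n
        pyz <- sum(a[, j, k]) / n
        tot <- tot + p * log2(p * pz / (pxz * pyz))
      }
    }
  unname(tot)
}

# IUPAC word matching via regular expressions (independent of the scanners)
iupac_regex <- function(word) {
  sets <- c(A = "A", C = "C", G = "G", T = "T", M = "[AC]", R = "[AG]",
            W = "[AT]", S = "[CG]", Y = "[CT]", K = "[GT]", V = "[ACG]",
            H = "[ACT]", D = "[AGT]", B = "[CGT]", N = "[ACGT]")
  paste(sets[strsplit(word, "")[[1L]]], collapse = "")
}

regex_count_with <- function(seqs, word) {
  sum(grepl(iupac_regex(word), seqs))
}

# all IUPAC words of a length (strings)
all_iupac_words <- function(len) {
  letters <- names(discrimotif:::IUPAC_MASKS)
  do.call(paste0, expand.grid(rep(list(letters), len),
                              stringsAsFactors = FALSE))
}

# central finite-difference gradient of f at z
fd_grad <- function(f, z, h = 1e-6) {
  vapply(seq_along(z), function(i) {
    zp <- z; zp[i] <- zp[i] + h
    zm <- z; zm[i] <- zm[i] - h
    (f(zp) - f(zm)) / (2 * h)
  }, 0)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), "")
}

dinuc_counts <- function(s) {
  ch <- strsplit(s, "")[[1L]]
  if (length(ch) < 2L) return(table(character(0)))
  table(paste0(ch[-length(ch)], ch[-1L]))
}
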