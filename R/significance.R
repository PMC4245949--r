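# Significance of association. Mutual information in a k x 2 contingency
# table is linked to the likelihood-ratio test by log Lambda = -I * n * log 2,
# and -2 log Lambda is asymptotically chi^2 with k - 1 degrees of freedom
# (Wilks). P-values are Bonferroni-corrected for motif space size so motifs
# of different lengths/degeneracies become comparable. All p-value
# arithmetic is in natural-log space.

#' MICO-based log p-value of a set of contingency tables
#'
#' Computes the likelihood-ratio statistic `G = 2 ln 2 * sum_t I_t * n_t`
#' (additive over jointly analyzed contrasts) and its chi-square survival
#' probability with `sum_t (rows_t - 1)` degrees of freedom. Works on
#' integer and fractional (expected) tables alike; on integer 2 x 2 tables
#' `G` coincides with the classical G-test statistic.
#'
#' @param tables A [contingency_table()] or list of them (one per
#'   contrast).
#' @return List with `log_p` (natural log), `G` and `dof`.
#' @export
mico_log_pvalue <- function(tables) {
  if (inherits(tables, "contingency_table")) tables <- list(tables)
  G <- 0; dof <- 0L
  for (t in tables) {
    n <- sum(t)
    stopifnot(n > 0)
    G <- G + 2 * log(2) * mico(t) * n
    dof <- dof + nrow(t) - 1L
  }
  list(log_p = pchisq(G, df = dof, lower.tail = FALSE, log.p = TRUE),
       G = G, dof = dof)
}

#' Number of IUPAC words of a given length and degeneracy limit
#'
#' Counts IUPAC words of the given length whose degeneracy (sum over
#' positions of allowed nucleotides minus 1) does not exceed the limit, by
#' dynamic programming over positions with per-position subset
#' multiplicities 4, 6, 4, 1 for degeneracy contributions 0, 1, 2, 3. This
#' is the motif-space size used for Bonferroni-style p-value correction;
#' with no limit it equals `15^length`.
#'
#' @param length Word length (>= 1).
#' @param degeneracy_limit Maximum total degeneracy (defaults to
#'   `3 * length`, i.e. no limit).
#' @return The count as a double (may exceed integer range).
#' @export
motif_space_size <- function(length, degeneracy_limit = 3 * length) {
  stopifnot(length >= 1)
  dmax <- min(degeneracy_limit, 3 * length)
  if (dmax < 0) return(0)
  mult <- c(4, 6, 4, 1)  # subsets of size 1..4 per position
  counts <- c(1, rep(0, dmax))  # counts[d+1] = words with degeneracy d
  for (pos in seq_len(length)) {
    nxt <- rep(0, dmax + 1L)
    for (d in 0:dmax) {
      if (counts[d + 1L] == 0) next
      for (add in 0:3) {
        if (d + add > dmax) break
        nxt[d + add + 1L] <- nxt[d + add + 1L] + counts[d + 1L] * mult[add + 1L]
      }
    }
    counts <- nxt
  }
  sum(counts)
}

#' Correct a log p-value for motif space size and apply the filter
#'
#' Bonferroni-style correction: the corrected p-value is
#' `min(1, p * space_size)`; the motif is accepted iff the corrected value
#' meets the threshold. This MICO-based filter applies regardless of the
#' objective used for seeding and optimization.
#'
#' @param raw_log_p Natural-log p-value.
#' @param space_size Motif space size (>= 1), from [motif_space_size()]
#'   with the degeneracy limit actually used during seeding.
#' @param threshold Acceptance threshold on the corrected p-value.
#' @param dof Degrees of freedom (carried through for reporting).
#' @return A `significance_result` list with `raw_log_p`,
#'   `corrected_log_p`, `motif_space_size`, `dof`, `threshold_log_p` and
#'   `accepted`.
#' @export
correct_and_filter <- function(raw_log_p, space_size, threshold = 0.05,
                               dof = NA_integer_) {
  stopifnot(space_size >= 1)
  corrected <- min(0, raw_log_p + log(space_size))
  structure(list(raw_log_p = raw_log_p, corrected_log_p = corrected,
                 motif_space_size = space_size, dof = dof,
                 threshold_log_p = log(threshold),
                 accepted = corrected <= log(threshold)),
            class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  cat("<significance_result> log10 p = ",
      signif(x$corrected_log_p / log(10), 4),
      " (raw ", signif(x$raw_log_p / log(10), 4),
      ", space ", format(x$motif_space_size, big.mark = ","), "); ",
      if (x$accepted) "accepted" else "rejected", "\n", sep = "")
  invisible(x)
}
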