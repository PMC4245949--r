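# Contingency tables of motif occurrence by condition, and the objective
# functions / association measures computed on them. All measures accept
# real-valued (expected) counts, so HMM posterior occurrence counts plug in
# unchanged alongside integer counts from discrete seed finding.

#' Construct a contingency table of motif occurrence by condition
#'
#' A k x 2 table whose rows are the conditions of one contrast and whose
#' columns count sequences with (>= 1 occurrence) and without the motif.
#' Counts may be fractional (expected counts of sequences).
#'
#' @param count_with Numeric vector: per condition, (expected) number of
#'   sequences with at least one occurrence.
#' @param n_seqs Numeric vector: number of sequences per condition.
#' @param conditions Condition names.
#' @param contrast_name Name of the contrast the table belongs to.
#' @return A numeric matrix of class `contingency_table` with columns
#'   `with` / `without`.
#' @export
contingency_table <- function(count_with, n_seqs,
                              conditions = names(count_with),
                              contrast_name = "contrast") {
  stopifnot(length(count_with) == length(n_seqs), length(n_seqs) >= 2L,
            all(count_with >= -1e-9), all(count_with <= n_seqs + 1e-9))
  count_with <- pmin(pmax(count_with, 0), n_seqs)
  t <- cbind(with = as.numeric(count_with),
             without = as.numeric(n_seqs - count_with))
  rownames(t) <- conditions %||% paste0("cond", seq_along(n_seqs))
  attr(t, "contrast") <- contrast_name
  class(t) <- c("contingency_table", class(t))
  t
}

#' Count sequences containing an IUPAC word, per condition
#'
#' For each condition of the contrast, counts the number of sequences with
#' at least one match of `w` (sequence-level presence, not position counts).
#' In double-stranded mode sequences are extended with their reverse
#' complement behind a `$` separator before scanning.
#'
#' @param contrast A [contrast()].
#' @param w An [iupac_word()] or IUPAC string.
#' @param strand `"single"` or `"double"`.
#' @return A [contingency_table()].
#' @export
count_table <- function(contrast, w, strand = c("single", "double")) {
  strand <- match.arg(strand)
  w <- iupac_word(w)
  seqs <- lapply(contrast$conditions, function(s) apply_strand(s, strand)$seqs)
  counts <- count_words_sets_c(seqs, iupac_mask_matrix(list(w)))
  contingency_table(as.numeric(counts[1L, ]),
                    vapply(seqs, length, 0L),
                    conditions = names(contrast$conditions),
                    contrast_name = contrast$name)
}

xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

#' Mutual information of condition and motif occurrence (MICO)
#'
#' The mutual information, in bits, between the condition a sequence
#' belongs to and whether it contains at least one motif occurrence,
#' computed from the empirical joint distribution of the table
#' (`0 log 0 = 0`). This is the method's headline discriminative objective:
#' it quantifies how much knowing occurrence status reduces uncertainty
#' about the condition.
#'
#' @param t A [contingency_table()] (any numeric k x 2 matrix works).
#' @return Mutual information in bits (>= 0).
#' @export
mico <- function(t) {
  n <- sum(t)
  stopifnot(n > 0)
  # I = (1/n) [ sum c ln c - sum_r R ln R - sum_c K ln K + n ln n ] / ln 2
  (sum(xlogx(t)) - sum(xlogx(rowSums(t))) - sum(xlogx(colSums(t))) +
     xlogx(n)) / (n * log(2))
}

#' Relative occurrence frequency difference (DFREQ)
#'
#' Occurrence frequency of the first (signal) condition minus that of the
#' second. Directional; binary contrasts only.
#'
#' @param t A 2 x 2 [contingency_table()].
#' @return Frequency difference in `[-1, 1]`.
#' @export
dfreq <- function(t) {
  if (nrow(t) != 2L)
    stop("invalid objective: DFREQ requires a binary contrast")
  t[1L, 1L] / sum(t[1L, ]) - t[2L, 1L] / sum(t[2L, ])
}

#' Matthews correlation coefficient (MCC) of a 2 x 2 table
#'
#' Correlation between motif occurrence and condition for binary contrasts;
#' defined as 0 when any marginal is 0.
#'
#' @param t A 2 x 2 [contingency_table()].
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(t) {
  if (nrow(t) != 2L)
    stop("invalid objective: MCC requires a binary contrast")
  a <- t[1L, 1L]; b <- t[1L, 2L]; cc <- t[2L, 1L]; d <- t[2L, 2L]
  denom <- (a + b) * (cc + d) * (a + cc) * (b + d)
  if (denom <= 0) return(0)
  (a * d - b * cc) / sqrt(denom)
}

#' Conditional mutual information from a joint expected-count array
#'
#' Computes `I(X; Y | Z)` in bits from a multi-way array of non-negative
#' (expected) counts, where `Z` is the joint state of all dimensions other
#' than `x` and `y`. Used both for cMICO (condition vs. new-motif occurrence
#' given previously accepted motifs) and for motif-pair cMI (new vs.
#' previous occurrence given the condition).
#'
#' @param joint Numeric array of non-negative counts.
#' @param x,y Dimension indices of the two variables.
#' @return Conditional mutual information in bits (>= 0).
#' @export
conditional_mi <- function(joint, x = 1L, y = 2L) {
  d <- dim(joint) %||% length(joint)
  nd <- length(d)
  stopifnot(nd >= 2L, x != y, x <= nd, y <= nd, all(joint >= 0))
  z <- setdiff(seq_len(nd), c(x, y))
  n <- sum(joint)
  if (n <= 0) return(0)
  if (length(z) == 0L)
    return(mico_raw(matrix(aperm(as.array(joint), c(x, y)), nrow = d[x])))
  # permute to (x, y, z...) and reshape so each z-slice is an x-by-y matrix
  a <- aperm(as.array(joint), c(x, y, z))
  dim(a) <- c(d[x], d[y], prod(d[z]))
  total <- 0
  for (k in seq_len(dim(a)[3L])) {
    m <- a[, , k, drop = TRUE]
    nz <- sum(m)
    if (nz > 0) total <- total + (nz / n) * mico_raw(matrix(m, nrow = d[x]))
  }
  total
}

# plain MI in bits of a k x m count matrix
mico_raw <- function(t) {
  n <- sum(t)
  if (n <= 0) return(0)
  (sum(xlogx(t)) - sum(xlogx(rowSums(t))) - sum(xlogx(colSums(t))) +
     xlogx(n)) / (n * log(2))
}

objective_kinds <- c("mico", "dfreq", "mcc", "mmie", "logl", "dlogl", "freq")

#' Aggregate an objective over the tables of several contrasts
#'
#' Joint analysis of multiple contrasts sums the per-contrast objective
#' values, so the joint objective reduces to the single-contrast case and
#' has an additive gradient. MCC supports a single contrast only.
#'
#' @param kind One of `"mico"`, `"dfreq"`, `"mcc"`.
#' @param tables List of [contingency_table()] objects, one per contrast.
#' @return Summed objective value.
#' @export
aggregate_objective <- function(kind, tables) {
  kind <- match.arg(kind, objective_kinds)
  if (inherits(tables, "contingency_table")) tables <- list(tables)
  if (kind == "mcc" && length(tables) > 1L)
    stop("invalid objective: MCC does not support multiple contrasts")
  f <- switch(kind,
    mico = mico, dfreq = dfreq, mcc = mcc,
    freq = function(t) sum(t[, 1L]) / sum(t),
    stop("objective '", kind, "' is not a contingency-table objective"))
  sum(vapply(tables, f, 0))
}

# d objective / d count_with per condition, holding row totals fixed
# (count_without = n_r - count_with). Used for the chain rule through the
# expected-count tables during gradient training.
table_grad <- function(kind, t, eps = 1e-12) {
  n <- sum(t)
  c1 <- pmax(t[, 1L], eps); c0 <- pmax(t[, 2L], eps)
  switch(kind,
    mico = {
      K1 <- max(sum(t[, 1L]), eps); K0 <- max(sum(t[, 2L]), eps)
      log(c1 * K0 / (c0 * K1)) / (n * log(2))
    },
    freq = rep(1 / n, nrow(t)),
    dfreq = c(1 / sum(t[1L, ]), -1 / sum(t[2L, ])),
    mcc = {
      a <- t[1L, 1L]; cc <- t[2L, 1L]
      n1 <- sum(t[1L, ]); n2 <- sum(t[2L, ])
      K1 <- max(a + cc, eps); K0 <- max(n - K1, eps)
      v <- sqrt(n1 * n2 * K1 * K0)
      u <- a * n2 - cc * n1
      common <- u * (K0 - K1) / (2 * v * K1 * K0)
      c(n2 / v - common, -n1 / v - common)
    },
    stop("no table gradient for objective '", kind, "'"))
}
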