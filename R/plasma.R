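# Discrete seed finding over IUPAC regular expressions ("plasma" module):
# enumerate occurring exact words, score them on the contingency-table
# objective, retain the top n, then iteratively generalize by allowing one
# additional nucleotide per round, dropping generalizations that score below
# any generating specialization, until no candidates remain or the
# degeneracy cap is reached.

# vectorized objective over a words-by-conditions count matrix
score_counts <- function(counts, layout, objective) {
  counts <- matrix(counts, ncol = length(layout$n))
  total <- numeric(nrow(counts))
  for (idx in layout$map) {
    W <- counts[, idx, drop = FALSE]
    nr <- layout$n[idx]
    total <- total + switch(objective,
      mico = {
        n <- sum(nr)
        K1 <- rowSums(W); K0 <- n - K1
        cells <- sum0 <- 0
        for (r in seq_along(idx))
          cells <- cells + xlogx(W[, r]) + xlogx(nr[r] - W[, r])
        (cells - sum(xlogx(nr)) - xlogx(K1) - xlogx(K0) + xlogx(n)) /
          (n * log(2))
      },
      freq = rowSums(W) / sum(nr),
      dfreq = {
        if (length(idx) != 2L)
          stop("invalid objective: DFREQ requires a binary contrast")
        W[, 1L] / nr[1L] - W[, 2L] / nr[2L]
      },
      mcc = {
        if (length(idx) != 2L)
          stop("invalid objective: MCC requires a binary contrast")
        a <- W[, 1L]; cc <- W[, 2L]
        K1 <- a + cc; K0 <- sum(nr) - K1
        den <- nr[1L] * nr[2L] * K1 * K0
        ifelse(den > 0, (a * nr[2L] - cc * nr[1L]) / sqrt(den), 0)
      },
      stop("objective '", objective, "' is not usable for seeding"))
  }
  total
}

# seeding fallbacks for objectives that need a probabilistic model
seeding_objective <- function(objective) {
  switch(objective,
         logl = "freq", dlogl = "dfreq", mmie = "mico",
         match.arg(objective, objective_kinds))
}

resolve_degeneracy_cap <- function(max_degeneracy, len) {
  if (is.null(max_degeneracy)) return(3L * len)
  if (max_degeneracy < 1) return(max(0L, floor(max_degeneracy * 3 * len)))
  min(as.integer(max_degeneracy), 3L * len)
}

run_seed_length <- function(layout, len, objective, n, cap, keep = 200L) {
  ew <- enum_words_sets_c(layout$seqs, len)
  if (length(ew$words) == 0L) return(NULL)
  score <- score_counts(ew$counts, layout, objective)
  ord <- order(-score, ew$words)
  retain <- if (is.finite(n)) head(ord, n) else ord
  top <- data.frame(word = ew$words[head(ord, keep)],
                    score = score[head(ord, keep)],
                    degeneracy = 0L, stringsAsFactors = FALSE)
  cur_words <- ew$words[retain]
  cur_score <- score[retain]
  best <- list(word = cur_words[1L], score = cur_score[1L])
  deg <- 0L
  n_total <- sum(layout$n)
  # per-sequence hit vectors of the retained words: a generalization matches
  # every sequence a generating specialization matches, so later rounds only
  # scan the complement
  cur_hits <- count_words_sets_masked_c(
    layout$seqs, iupac_mask_matrix_str(cur_words),
    matrix(FALSE, length(cur_words), n_total))$hits
  cur_masks <- iupac_mask_matrix_str(cur_words)
  while (length(cur_words) > 0L && deg < cap) {
    deg <- deg + 1L
    # all single-step generalizations of the retained set; remember the best
    # generating specialization's score (drop threshold) and all parents
    gen <- generalize_all(cur_masks)
    if (is.null(gen$masks)) break
    gstr <- mask_row_strings(gen$masks)
    grp <- split(seq_along(gstr), gstr)  # lexicographic candidate order
    cands <- names(grp)
    first_idx <- vapply(grp, `[`, 0L, 1L)
    pmax_score <- vapply(grp, function(ix) max(cur_score[gen$parent[ix]]), 0)
    known <- matrix(FALSE, length(cands), n_total)
    for (i in seq_along(grp)) {
      pr <- unique(gen$parent[grp[[i]]])
      k <- cur_hits[pr[1L], ]
      for (p in pr[-1L]) k <- k | cur_hits[p, ]
      known[i, ] <- k
    }
    cand_masks <- gen$masks[first_idx, , drop = FALSE]
    res <- count_words_sets_masked_c(layout$seqs, cand_masks, known)
    cscore <- score_counts(res$counts, layout, objective)
    ok <- cscore >= pmax_score
    if (!any(ok)) break
    cands <- cands[ok]
    cscore <- cscore[ok]
    cand_masks <- cand_masks[ok, , drop = FALSE]
    hits <- res$hits[ok, , drop = FALSE]
    ord <- order(-cscore, cands)
    retain <- if (is.finite(n)) head(ord, n) else ord
    cur_words <- cands[retain]
    cur_score <- cscore[retain]
    cur_hits <- hits[retain, , drop = FALSE]
    cur_masks <- cand_masks[retain, , drop = FALSE]
    top <- rbind(top, data.frame(word = head(cands[ord], keep),
                                 score = head(cscore[ord], keep),
                                 degeneracy = deg, stringsAsFactors = FALSE))
    if (cur_score[1L] > best$score ||
        (cur_score[1L] == best$score && cur_words[1L] < best$word))
      best <- list(word = cur_words[1L], score = cur_score[1L])
  }
  top <- top[order(-top$score, top$word), , drop = FALSE]
  top <- top[!duplicated(top$word), , drop = FALSE]
  list(best = best, top = top, degeneracy_reached = deg)
}

#' Enumerate occurring exact words with per-condition sequence counts
#'
#' For each word of the given length that occurs anywhere in the collection,
#' counts the number of sequences containing it (sequence-level presence) in
#' every condition. Words absent everywhere are not returned.
#'
#' @param contrasts A [contrast()] or [contrast_collection()].
#' @param length Word length in nt.
#' @param strand `"single"` or `"double"`.
#' @return A list with `words` (character) and `counts` (integer matrix,
#'   words by conditions in collection order).
#' @export
enumerate_words <- function(contrasts, length, strand = c("single", "double")) {
  layout <- collection_layout(as_contrast_collection(contrasts),
                              match.arg(strand))
  ew <- enum_words_sets_c(layout$seqs, length)
  ord <- order(ew$words)
  list(words = ew$words[ord],
       counts = ew$counts[ord, , drop = FALSE])
}

#' Score candidate words and retain the best n
#'
#' @param candidates Result of [enumerate_words()] (or a compatible list
#'   with `words` and `counts`).
#' @param contrasts The contrast collection the counts were computed from.
#' @param objective Objective kind (see [aggregate_objective()]).
#' @param n Number of words to retain (default 100). Ties are broken
#'   lexicographically on the IUPAC string.
#' @return A data.frame of `word` and `score`, sorted by descending score.
#' @export
score_and_retain <- function(candidates, contrasts, objective = "mico",
                             n = 100L) {
  stopifnot(n >= 1L)
  layout <- collection_layout(as_contrast_collection(contrasts))
  objective <- seeding_objective(objective)
  score <- score_counts(candidates$counts, layout, objective)
  ord <- order(-score, candidates$words)
  keep <- if (is.finite(n)) head(ord, n) else ord
  data.frame(word = candidates$words[keep], score = score[keep],
             stringsAsFactors = FALSE)
}

#' Find the best discriminative IUPAC seed word
#'
#' Heuristic search maximizing a contingency-table objective: per length,
#' exact occurring words are scored and the top `n` retained, then rounds of
#' single-nucleotide generalization, rescanning, pruning (generalizations
#' scoring below any generating specialization are dropped) and top-`n`
#' retention continue until no candidates remain or the degeneracy cap is
#' reached. The best-scoring word over all rounds and lengths is returned.
#'
#' @param contrasts A [contrast()] or [contrast_collection()].
#' @param lengths Integer vector of motif lengths to consider.
#' @param objective Objective kind; `"logl"`, `"dlogl"` and `"mmie"` fall
#'   back to their discrete seeding surrogates (`"freq"`, `"dfreq"`,
#'   `"mico"`).
#' @param n Number of words retained per round (default 100); `Inf`
#'   disables truncation.
#' @param max_degeneracy Maximum allowed degeneracy: an integer >= 1 for an
#'   absolute limit, a value in (0, 1) for a fraction of `3 * length`
#'   (rounded down), or `NULL` for no limit.
#' @param strand `"single"` or `"double"`.
#' @return A `seed_result` list (`word`, `score`, `tables`, `counts`,
#'   `length`, `objective`, `top_words` per length), or `NULL` if no word
#'   occurs anywhere.
#' @export
find_seed <- function(contrasts, lengths, objective = "mico", n = 100L,
                      max_degeneracy = NULL, strand = c("single", "double")) {
  stopifnot(length(lengths) >= 1L, n >= 1L)
  strand <- match.arg(strand)
  cc <- as_contrast_collection(contrasts)
  layout <- collection_layout(cc, strand)
  objective <- seeding_objective(objective)
  best <- NULL; per_length <- list()
  for (len in sort(unique(as.integer(lengths)))) {
    cap <- resolve_degeneracy_cap(max_degeneracy, len)
    r <- run_seed_length(layout, len, objective, n, cap)
    if (is.null(r)) next
    per_length[[as.character(len)]] <- r$top
    if (is.null(best) || r$best$score > best$score) {
      best <- r$best
      best$length <- len
    }
  }
  if (is.null(best)) return(NULL)
  word <- iupac_word(best$word)
  tables <- lapply(cc, count_table, w = word, strand = strand)
  structure(list(word = word, score = best$score, tables = tables,
                 counts = vapply(tables, function(t) t[, 1L],
                                 numeric(nrow(tables[[1L]]))),
                 length = best$length, objective = objective,
                 strand = strand, top_words = per_length),
            class = "seed_result")
}

#' @export
print.seed_result <- function(x, ...) {
  cat("<seed_result> ", as.character(x$word), "  ", x$objective, " = ",
      signif(x$score, 6), "\n", sep = "")
  invisible(x)
}

#' Find several seeds by iterated masking or discarding
#'
#' Repeats [find_seed()]; between iterations either all occurrences of the
#' found motif are masked with `N`s, or sequences containing occurrences are
#' discarded, so later iterations cannot rediscover the same signal.
#'
#' @inheritParams find_seed
#' @param count Number of seeds sought.
#' @param mode `"mask"` or `"discard"`.
#' @return List of `seed_result` objects (may be shorter than `count` when
#'   the sequence data are exhausted).
#' @export
find_multiple_seeds <- function(contrasts, lengths, objective = "mico",
                                n = 100L, max_degeneracy = NULL,
                                strand = c("single", "double"),
                                count = 1L, mode = c("mask", "discard")) {
  stopifnot(count >= 1L)
  strand <- match.arg(strand)
  mode <- match.arg(mode)
  cc <- as_contrast_collection(contrasts)
  out <- list()
  for (i in seq_len(count)) {
    r <- find_seed(cc, lengths, objective, n, max_degeneracy, strand)
    if (is.null(r)) break
    out[[i]] <- r
    if (i == count) break
    cc2 <- lapply(cc, function(ct) {
      conds <- lapply(ct$conditions, function(set) {
        if (mode == "mask") {
          mask_occurrences(set, r$word, both_strands = strand == "double")
        } else {
          scan_set <- apply_strand(set, strand)
          hit <- vapply(match_positions_c(scan_set$seqs, r$word$masks),
                        function(p) length(p) > 0L, TRUE)
          if (all(hit)) return(NULL)
          sequence_set(set$seqs[!hit], ids = set$ids[!hit], name = set$name)
        }
      })
      if (any(vapply(conds, is.null, TRUE))) return(NULL)
      contrast(conds, name = ct$name)
    })
    if (any(vapply(cc2, is.null, TRUE))) break
    cc <- contrast_collection(cc2)
  }
  out
}
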