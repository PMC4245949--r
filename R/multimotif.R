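# Iterative discovery of a non-redundant set of discriminative motifs.
#
# Candidates are seeded from the most discriminative IUPAC words per length
# (plus 1-nt-shifted variants), trained independently, and the best by
# corrected MICO p-value is accepted first. Further candidates must pass
# two conditional-mutual-information gates -- pairwise against each accepted
# motif and jointly against all of them: (a) the cMI of condition and new
# occurrence given previous occurrences (cMICO) must be significant, and
# (b) the ratio of cMICO over the motif-pair cMI (new vs. previous
# occurrence given condition) must meet a threshold. The gated winner is
# added to a joint HMM that is re-trained on the any-motif occurrence
# feature and accepted only if its corrected p-value improves.

#' Build the seed candidate pool for multiple-motif discovery
#'
#' For each length, the `per_length` most discriminative IUPAC words are
#' obtained by repeated seed search (masking occurrences of earlier seeds
#' so the seeds are diverse), together with their 1-nt-shifted variants
#' (for each shift direction the best-scoring single-nucleotide flank is
#' chosen), giving `lengths x per_length x (1 + 2*shifts)` candidates --
#' e.g. 6 lengths x 3 seeds x 3 variants = 54.
#'
#' @inheritParams find_seed
#' @param per_length Seeds kept per length.
#' @param shifts Number of shift steps per direction (0 disables variants).
#' @return List of candidate records (`word`, `score`, `length`, `origin`).
#' @export
candidate_pool <- function(contrasts, lengths, objective = "mico",
                           per_length = 3L, shifts = 1L, n = 100L,
                           max_degeneracy = NULL,
                           strand = c("single", "double")) {
  strand <- match.arg(strand)
  cc <- as_contrast_collection(contrasts)
  layout <- collection_layout(cc, strand)
  objective <- seeding_objective(objective)
  pool <- list()
  score_words_now <- function(words) {
    cnt <- count_words_sets_c(layout$seqs,
                              iupac_mask_matrix(lapply(words, iupac_word)))
    score_counts(cnt, layout, objective)
  }
  for (len in sort(unique(as.integer(lengths)))) {
    # masking between repetitions makes the per-length seeds diverse rather
    # than variants of one motif
    rs <- find_multiple_seeds(cc, len, objective, n, max_degeneracy, strand,
                              count = per_length, mode = "mask")
    for (i in seq_along(rs)) {
      w <- as.character(rs[[i]]$word)
      pool[[length(pool) + 1L]] <- list(word = rs[[i]]$word,
                                        score = rs[[i]]$score,
                                        length = as.integer(len),
                                        origin = "seed")
      if (shifts >= 1L) {
        L <- nchar(w)
        for (s in seq_len(shifts)) {
          core_l <- substr(w, 1L, L - s)   # shift right: new flank on left
          core_r <- substr(w, s + 1L, L)   # shift left: new flank on right
          lefts <- paste0(strrep("N", 0), sapply(NUCS, function(b)
            paste0(paste(rep(b, s), collapse = ""), core_l)))
          rights <- sapply(NUCS, function(b)
            paste0(core_r, paste(rep(b, s), collapse = "")))
          for (variant in list(lefts, rights)) {
            sc <- score_words_now(variant)
            bi <- order(-sc, variant)[1L]
            pool[[length(pool) + 1L]] <- list(word = iupac_word(variant[bi]),
                                              score = sc[bi],
                                              length = nchar(variant[bi]),
                                              origin = "shift")
          }
        }
      }
    }
    if (length(rs) < per_length)
      message("only ", length(rs), " seed(s) available for length ", len)
  }
  pool
}

# train one candidate: background + chain + fit
train_candidate <- function(cand, cc, config, alpha = 0.03,
                            context_sets = NULL) {
  all_sets <- unlist(lapply(cc, `[[`, "conditions"), recursive = FALSE)
  use <- if (is.null(context_sets)) all_sets
         else all_sets[vapply(all_sets, `[[`, "", "name") %in% context_sets]
  bg <- train_background(use)
  hmm <- add_motif_chain(bg, cand$word, alpha = alpha)
  fr <- fit(hmm, cc, config)
  sig <- mico_log_pvalue(fr$tables)
  cand$fit <- fr
  cand$sig <- correct_and_filter(
    sig$log_p, motif_space_size(length(cand$word$masks)), dof = sig$dof)
  cand
}

#' Select the first motif of a multi-motif analysis
#'
#' Every pool candidate is seeded and trained independently; the candidate
#' with the best motif-space-corrected MICO p-value wins and, if
#' significant, becomes the initial accepted motif set.
#'
#' @param pool Result of [candidate_pool()].
#' @param contrasts The contrast collection (strand-extended if needed).
#' @param config A [training_config()].
#' @param threshold Corrected p-value acceptance threshold.
#' @param alpha Emission pseudo-probability for seeding.
#' @return A `motif_set_state` (accepted motifs, joint HMM, significance),
#'   or `NULL` if no candidate is significant.
#' @export
select_first <- function(pool, contrasts, config = training_config(),
                         threshold = 0.05, alpha = 0.03) {
  stopifnot(length(pool) >= 1L)
  cc <- as_contrast_collection(contrasts)
  trained <- lapply(pool, function(cand) {
    if (is.null(cand$fit))
      cand <- train_candidate(cand, cc, config, alpha, config$context_sets)
    cand
  })
  lp <- vapply(trained, function(cand) cand$sig$corrected_log_p, 0)
  ord <- order(lp, vapply(trained, function(c) as.character(c$word), ""))
  best <- trained[[ord[1L]]]
  if (best$sig$corrected_log_p > log(threshold)) return(NULL)
  structure(list(accepted = list(best), joint_hmm = best$fit$hmm,
                 sig = best$sig, pool = trained, threshold = threshold,
                 alpha = alpha),
            class = "motif_set_state")
}

#' @export
print.motif_set_state <- function(x, ...) {
  cat("<motif_set_state> ", length(x$accepted), " accepted motif(s): ",
      paste(vapply(x$accepted, function(m) as.character(m$word), ""),
            collapse = ", "),
      "; log10 p = ", signif(x$sig$corrected_log_p / log(10), 4), "\n",
      sep = "")
  invisible(x)
}

# joint occurrence cell counts for one condition, as an array
# (2 x n_patterns): new occurrence x pattern of previous occurrences.
# Hard mode thresholds all posteriors at 0.5 (occurrence calls); soft mode
# treats the posteriors of separately trained models as independent
# Bernoullis per sequence -- which by construction zeroes the motif-pair
# cMI, so hard calls are the default for the gates.
joint_cells <- function(p_new, p_prev_list, hard) {
  m <- length(p_prev_list)
  pats <- as.matrix(expand.grid(rep(list(c(1, 0)), m)))  # 1 = occurs
  if (hard) {
    ind <- vapply(p_prev_list, function(p) as.numeric(p > 0.5),
                  numeric(length(p_new)))
    ind <- matrix(ind, ncol = m)
    nw <- as.numeric(p_new > 0.5)
    cells <- matrix(0, 2L, nrow(pats))
    for (k in seq_len(nrow(pats))) {
      inpat <- rowSums(abs(ind - matrix(pats[k, ], nrow(ind), m,
                                        byrow = TRUE))) == 0
      cells[1L, k] <- sum(nw[inpat])
      cells[2L, k] <- sum((1 - nw)[inpat])
    }
  } else {
    cells <- matrix(0, 2L, nrow(pats))
    for (k in seq_len(nrow(pats))) {
      w <- rep(1, length(p_new))
      for (j in seq_len(m)) {
        pj <- p_prev_list[[j]]
        w <- w * if (pats[k, j] == 1) pj else 1 - pj
      }
      cells[1L, k] <- sum(p_new * w)
      cells[2L, k] <- sum((1 - p_new) * w)
    }
  }
  cells
}

# cMI machinery over contrasts; p_new/p_prev are lists per condition index
cmi_stats <- function(td_like, p_new, p_prev_lists, hard) {
  # td_like: list(map, n per cond)
  G_cmico <- 0; dof <- 0L; sum_cmico <- 0; sum_pair <- 0
  for (idx in td_like$map) {
    k <- length(idx)
    npat <- 2L ^ length(p_prev_lists[[idx[1L]]])
    joint <- array(0, dim = c(k, 2L, npat))
    for (r in seq_along(idx)) {
      joint[r, , ] <- joint_cells(p_new[[idx[r]]], p_prev_lists[[idx[r]]],
                                  hard)
    }
    n <- sum(joint)
    cmico <- conditional_mi(joint, x = 1L, y = 2L)      # cond;new | prev
    pair <- conditional_mi(joint, x = 2L, y = 3L)       # new;prev | cond
    G_cmico <- G_cmico + 2 * log(2) * cmico * n
    dof <- dof + (k - 1L) * npat
    sum_cmico <- sum_cmico + cmico * n
    sum_pair <- sum_pair + pair * n
  }
  list(log_p = pchisq(G_cmico, df = dof, lower.tail = FALSE, log.p = TRUE),
       G = G_cmico, dof = dof, cmico = sum_cmico, pair_cmi = sum_pair)
}

#' Redundancy and residual-information gate for a candidate motif
#'
#' Computes the cMICO of condition and candidate occurrence given the
#' occurrences of previously accepted motifs, and the motif-pair cMI of
#' candidate and previous occurrences given the condition -- pairwise
#' against each accepted motif and jointly against all of them. The
#' candidate is rejected if any cMICO p-value is not significant or any
#' cMICO / pair-cMI ratio falls below the threshold. Joint tables use hard
#' occurrence calls (posterior > 0.5) by default; `occurrence = "soft"`
#' treats the posteriors of the separately trained models as independent
#' per-sequence Bernoullis instead, which cannot detect occurrence
#' correlation between models and is provided for inspection only.
#'
#' @param state A `motif_set_state`.
#' @param candidate A trained candidate (from the state's pool).
#' @param contrasts The contrast collection.
#' @param ratio_threshold Minimum cMICO / pair-cMI ratio (default 1).
#' @param p_threshold Significance threshold on the cMICO p-value.
#' @param occurrence `"hard"` (default) or `"soft"` joint-table counts.
#' @return List with `accept` and a per-test diagnostics data.frame.
#' @export
cmi_gate <- function(state, candidate, contrasts, ratio_threshold = 1,
                     p_threshold = 0.05,
                     occurrence = c("hard", "soft")) {
  occurrence <- match.arg(occurrence)
  stopifnot(inherits(state, "motif_set_state"), length(state$accepted) >= 1L)
  cc <- as_contrast_collection(contrasts)
  td <- prepare_training_data(cc)
  td_like <- list(map = td$map)
  p_new <- lapply(td$conds, function(cond)
    posterior_occurrence(candidate$fit$hmm, cond$set))
  p_acc <- lapply(state$accepted, function(m)
    lapply(td$conds, function(cond) posterior_occurrence(m$fit$hmm, cond$set)))
  tests <- list()
  run_test <- function(which_prev, label) {
    hard <- occurrence == "hard" || length(which_prev) > 2L
    p_prev_lists <- lapply(seq_along(td$conds), function(i)
      lapply(p_acc[which_prev], `[[`, i))
    st <- cmi_stats(td_like, p_new, p_prev_lists, hard)
    ratio <- if (st$pair_cmi <= 1e-12) Inf else st$cmico / st$pair_cmi
    data.frame(test = label, log_p = st$log_p, cmico = st$cmico,
               pair_cmi = st$pair_cmi, ratio = ratio,
               pass = st$log_p <= log(p_threshold) &
                 ratio >= ratio_threshold,
               stringsAsFactors = FALSE)
  }
  for (j in seq_along(state$accepted))
    tests[[length(tests) + 1L]] <-
      run_test(j, paste0("pairwise:",
                         as.character(state$accepted[[j]]$word)))
  if (length(state$accepted) > 1L)
    tests[[length(tests) + 1L]] <-
      run_test(seq_along(state$accepted), "joint")
  diagnostics <- do.call(rbind, tests)
  list(accept = all(diagnostics$pass), diagnostics = diagnostics)
}

#' Grow an accepted motif set by one motif
#'
#' Gates all remaining pool candidates with [cmi_gate()], selects the best
#' surviving candidate by cMICO p-value, adds its chain (warm-started from
#' its independently fitted emissions) to the joint HMM, re-trains the
#' joint model to optimize MICO for the feature of at least one occurrence
#' of any of its motifs, and accepts the result only if the corrected
#' MICO p-value improves over the current state's. Otherwise, or when all
#' candidates are discarded, the previous state is returned with attribute
#' `stopped = TRUE`.
#'
#' @param state A `motif_set_state`.
#' @param pool Ignored if the state carries its trained pool.
#' @param contrasts The contrast collection.
#' @param config A [training_config()].
#' @param ratio_threshold,p_threshold Gate thresholds (see [cmi_gate()]).
#' @return The grown (or unchanged) `motif_set_state`.
#' @export
grow <- function(state, pool = NULL, contrasts, config = training_config(),
                 ratio_threshold = 1, p_threshold = 0.05) {
  stopifnot(inherits(state, "motif_set_state"))
  cc <- as_contrast_collection(contrasts)
  pool <- pool %||% state$pool
  used <- vapply(state$accepted, function(m) as.character(m$word), "")
  cands <- Filter(function(cand)
    !(as.character(cand$word) %in% used), pool)
  if (length(cands) == 0L) return(structure_stop(state))
  gated <- lapply(cands, function(cand)
    cmi_gate(state, cand, cc, ratio_threshold, p_threshold))
  ok <- vapply(gated, `[[`, TRUE, "accept")
  if (!any(ok)) return(structure_stop(state))
  cands <- cands[ok]; gated <- gated[ok]
  joint_p <- vapply(gated, function(g) min(g$diagnostics$log_p), 0)
  ord <- order(joint_p, vapply(cands, function(c) as.character(c$word), ""))
  pick <- cands[[ord[1L]]]
  # joint HMM: existing chains + warm-started new chain
  joint <- state$joint_hmm
  joint <- add_motif_chain(joint, pick$word, alpha = state$alpha,
                           name = paste0("motif", length(state$accepted) + 1L))
  new_name <- paste0("motif", length(state$accepted) + 1L)
  joint$emis[joint$motifs[[new_name]]$states, ] <- motif_pwm(pick$fit$hmm)
  fr <- fit(joint, cc, config)
  sig_raw <- mico_log_pvalue(fr$tables)
  log_space <- sum(vapply(c(state$accepted, list(pick)), function(m)
    log(motif_space_size(length(m$word$masks))), 0))
  corrected <- min(0, sig_raw$log_p + log_space)
  if (corrected >= state$sig$corrected_log_p) return(structure_stop(state))
  sig <- correct_and_filter(sig_raw$log_p, exp(log_space),
                            threshold = state$threshold, dof = sig_raw$dof)
  structure(list(accepted = c(state$accepted, list(pick)), joint_hmm = fr$hmm,
                 sig = sig, pool = state$pool, threshold = state$threshold,
                 alpha = state$alpha),
            class = "motif_set_state")
}

structure_stop <- function(state) {
  attr(state, "stopped") <- TRUE
  state
}

#' Discover a non-redundant set of discriminative motifs
#'
#' End-to-end multi-motif driver: candidate pool, independent training,
#' first selection by corrected MICO p-value, then growth gated by
#' conditional mutual information until the p-value no longer improves or
#' `max_motifs` is reached.
#'
#' @inheritParams candidate_pool
#' @param config A [training_config()].
#' @param threshold Corrected p-value acceptance threshold.
#' @param max_motifs Maximum number of motifs to report.
#' @param ratio_threshold,p_threshold Gate thresholds (see [cmi_gate()]).
#' @param alpha Emission pseudo-probability for seeding.
#' @return A `motif_set_state` (or `NULL` if no motif is significant), with
#'   a `report` data.frame attached: motif id, IUPAC seed, length, log10
#'   corrected p and per-condition expected counts in acceptance order.
#' @export
discover_motifs <- function(contrasts, lengths, objective = "mico",
                            per_length = 3L, shifts = 1L, n = 100L,
                            max_degeneracy = NULL,
                            strand = c("single", "double"),
                            config = training_config(objective = objective),
                            threshold = 0.05, max_motifs = 5L,
                            ratio_threshold = 1, p_threshold = 0.05,
                            alpha = 0.03) {
  strand <- match.arg(strand)
  cc <- as_contrast_collection(contrasts)
  if (strand == "double") {
    cc <- contrast_collection(lapply(cc, function(ct) {
      contrast(lapply(ct$conditions, apply_strand, strand = "double"),
               name = ct$name)
    }))
  }
  pool <- candidate_pool(cc, lengths, objective, per_length, shifts, n,
                         max_degeneracy, strand = "single")
  if (length(pool) == 0L) return(NULL)
  state <- select_first(pool, cc, config, threshold, alpha)
  if (is.null(state)) return(NULL)
  while (length(state$accepted) < max_motifs) {
    nxt <- grow(state, NULL, cc, config, ratio_threshold, p_threshold)
    if (isTRUE(attr(nxt, "stopped"))) break
    state <- nxt
  }
  tables <- expected_tables(state$joint_hmm, cc)
  counts <- do.call(cbind, lapply(tables, function(t) t[, 1L]))
  report <- data.frame(
    order = seq_along(state$accepted),
    motif = paste0("motif", seq_along(state$accepted)),
    seed = vapply(state$accepted, function(m) as.character(m$word), ""),
    length = vapply(state$accepted, function(m) length(m$word$masks), 0L),
    log10_corrected_p = state$sig$corrected_log_p / log(10),
    stringsAsFactors = FALSE)
  attr(state, "report") <- report
  attr(state, "expected_counts") <- counts
  state
}
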