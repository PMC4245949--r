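# Synthetic benchmark: PWM generation with information-content control,
# motif implantation into zeroth-order uniform or higher-order Markov
# backgrounds (with an optional decoy motif implanted into both signal and
# control), dinucleotide-preserving shuffles, the recognizability reference
# model (predictive performance of the true model), and nucleotide- and
# site-level evaluation metrics.

#' Random position weight matrix
#'
#' Columns are independent draws from a flat Dirichlet over the four
#' nucleotides.
#'
#' @param length Motif length (positions).
#' @return A `length x 4` matrix of column-stochastic rows (positions x
#'   A,C,G,T).
#' @export
random_pwm <- function(length) {
  m <- matrix(stats::rgamma(length * 4L, shape = 1), nrow = length,
              dimnames = list(NULL, NUCS))
  m / rowSums(m)
}

#' Information content of a PWM
#'
#' @param pwm Positions x 4 probability matrix.
#' @return IC in bits: `sum_pos (2 - H(position))`.
#' @export
pwm_ic <- function(pwm) {
  h <- -rowSums(xlogx(pwm)) / log(2)
  sum(2 - h)
}

#' Polarize a PWM to a target information content
#'
#' Exponentiates the matrix component-wise (`pwm^gamma`, renormalized per
#' position) and finds `gamma` by bisection so the IC meets the target:
#' `gamma -> 0` gives uniform columns (IC 0), `gamma -> Inf` point masses
#' (IC `2 * length`).
#'
#' @param raw Positions x 4 probability matrix with non-degenerate rows.
#' @param target_ic Desired IC in bits, in `[0, 2 * length]`.
#' @param tol Absolute IC tolerance.
#' @return The polarized PWM, with attribute `gamma`.
#' @export
polarize_pwm <- function(raw, target_ic, tol = 1e-3) {
  L <- nrow(raw)
  stopifnot(target_ic >= 0, target_ic <= 2 * L)
  lraw <- log(pmax(raw, 1e-300))
  pol <- function(g) {
    # component-wise power in log space for numerical stability at large g
    lm <- g * lraw
    m <- exp(lm - apply(lm, 1L, max))
    m / rowSums(m)
  }
  if (target_ic <= tol)
    return(structure(pol(0), gamma = 0))
  hi <- 1
  for (i in 1:80) {
    if (pwm_ic(pol(hi)) >= target_ic) break
    hi <- hi * 2
  }
  if (pwm_ic(pol(hi)) < target_ic - tol)
    stop("target IC unreachable: raw PWM too degenerate")
  lo <- 0
  mid <- hi
  for (i in 1:300) {
    mid <- (lo + hi) / 2
    ic <- pwm_ic(pol(mid))
    if (abs(ic - target_ic) <= tol) break
    if (ic < target_ic) lo <- mid else hi <- mid
  }
  structure(pol(mid), gamma = mid)
}

sample_from_pwm <- function(pwm) {
  paste(apply(pwm, 1L, function(p) sample(NUCS, 1L, prob = p)),
        collapse = "")
}

# order-k Markov background surrogate with an A/T-rich bias (stands in for
# sampled 3'UTR sequence without any external data)
markov_model <- function(order = 3L, at_bias = 0.35) {
  ctxs <- 4L ^ order
  base <- c(at_bias, 0.5 - at_bias, 0.5 - at_bias, at_bias)
  probs <- matrix(0, ctxs, 4L)
  for (i in seq_len(ctxs)) {
    d <- stats::rgamma(4L, shape = 5 * base)
    probs[i, ] <- d / sum(d)
  }
  list(order = order, probs = probs)
}

sample_markov <- function(model, len, n) {
  order <- model$order
  out <- character(n)
  for (s in seq_len(n)) {
    x <- integer(len)
    ctx <- 0L
    for (t in seq_len(len)) {
      p <- if (t <= order) rep(0.25, 4L) else model$probs[ctx + 1L, ]
      x[t] <- sample.int(4L, 1L, prob = p)
      if (t >= order)
        ctx <- sum((x[(t - order + 1L):t] - 1L) * 4L ^ ((order - 1L):0))
    }
    out[s] <- paste(NUCS[x], collapse = "")
  }
  out
}

#' Benchmark generation parameters
#'
#' One row of the synthetic-data design: sequence number and length,
#' implantation probability and information content of the signal motif,
#' optionally a decoy motif implanted into both signal and control, and the
#' background model (uniform zeroth-order Markov chain, or an A/U-rich
#' order-3 Markov surrogate standing in for 3'UTR sequence).
#'
#' @param n_seq Sequences per set.
#' @param seq_len Sequence length in nt.
#' @param motif_len Motif length in nt (signal and decoy).
#' @param implant_prob Signal implantation probability (fraction in
#'   `[0, 1]`; at most one implant per sequence, sense strand only).
#' @param signal_ic Signal motif IC in bits.
#' @param decoy_prob Decoy implantation probability (0 disables decoys).
#' @param decoy_ic Decoy motif IC in bits.
#' @param background `"uniform"` or `"markov"`.
#' @param markov_order Order of the Markov surrogate background.
#' @return A `bench_params` list.
#' @export
bench_params <- function(n_seq = 1000L, seq_len = 100L, motif_len = 8L,
                         implant_prob = 0.1, signal_ic = 10,
                         decoy_prob = 0, decoy_ic = NA_real_,
                         background = c("uniform", "markov"),
                         markov_order = 3L) {
  background <- match.arg(background)
  stopifnot(seq_len >= motif_len, implant_prob >= 0, implant_prob <= 1)
  structure(list(n_seq = as.integer(n_seq), seq_len = as.integer(seq_len),
                 motif_len = as.integer(motif_len),
                 implant_prob = implant_prob, signal_ic = signal_ic,
                 decoy_prob = decoy_prob, decoy_ic = decoy_ic,
                 background = background,
                 markov_order = as.integer(markov_order)),
            class = "bench_params")
}

uniform_seqs <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(NUCS, len, replace = TRUE), collapse = ""), "")
}

implant <- function(seqs, pwm, prob, ids, kind) {
  L <- nchar(seqs[1L])
  w <- nrow(pwm)
  pick <- runif(length(seqs)) < prob
  truth <- list()
  for (i in which(pick)) {
    pos <- sample.int(L - w + 1L, 1L)  # 1-based start
    occ <- sample_from_pwm(pwm)
    substr(seqs[i], pos, pos + w - 1L) <- occ
    truth[[length(truth) + 1L]] <- data.frame(
      seq_id = ids[i], start = pos - 1L, end = pos + w - 1L, kind = kind,
      stringsAsFactors = FALSE)
  }
  list(seqs = seqs,
       truth = if (length(truth)) do.call(rbind, truth)
               else data.frame(seq_id = character(), start = integer(),
                               end = integer(), kind = character(),
                               stringsAsFactors = FALSE))
}

#' Generate a synthetic signal/control dataset with ground truth
#'
#' Draws background sequences, polarizes a random PWM to the requested IC,
#' and implants at most one signal occurrence per selected signal sequence
#' at a uniform position (overwrite semantics, sense strand only). In the
#' decoy design a second PWM is implanted into both signal and control
#' sequences before the signal implants; a decoy overlapped by a signal
#' implant is removed from the truth. All randomness flows from `seed`.
#'
#' @param params A [bench_params()].
#' @param seed Integer seed.
#' @return A `synthetic_dataset`: `signal` and `control`
#'   [sequence_set()]s, `truth` data.frame (`seq_id`, `start`, `end`,
#'   `kind`), the signal `pwm` (and `decoy_pwm`), and the inputs.
#' @export
generate_dataset <- function(params, seed = 1L) {
  stopifnot(inherits(params, "bench_params"))
  set.seed(seed)
  w <- params$motif_len
  pwm <- polarize_pwm(random_pwm(w), params$signal_ic)
  decoy_pwm <- NULL
  if (params$decoy_prob > 0)
    decoy_pwm <- polarize_pwm(random_pwm(w), params$decoy_ic)
  gen_bg <- function(n) {
    if (params$background == "uniform") uniform_seqs(n, params$seq_len)
    else sample_markov(markov_model(params$markov_order), params$seq_len, n)
  }
  sig_ids <- sprintf("signal_%d", seq_len(params$n_seq))
  ctl_ids <- sprintf("control_%d", seq_len(params$n_seq))
  sig <- gen_bg(params$n_seq)
  ctl <- gen_bg(params$n_seq)
  truth <- list()
  if (!is.null(decoy_pwm)) {
    ds <- implant(sig, decoy_pwm, params$decoy_prob, sig_ids, "decoy")
    dc <- implant(ctl, decoy_pwm, params$decoy_prob, ctl_ids, "decoy")
    sig <- ds$seqs; ctl <- dc$seqs
    truth <- list(ds$truth, dc$truth)
  }
  si <- implant(sig, pwm, params$implant_prob, sig_ids, "signal")
  sig <- si$seqs
  truth <- c(truth, list(si$truth))
  truth <- do.call(rbind, truth)
  # a decoy overwritten (even partially) by a signal implant is removed
  if (nrow(truth) > 0L && any(truth$kind == "decoy")) {
    sg <- truth[truth$kind == "signal", , drop = FALSE]
    drop <- logical(nrow(truth))
    for (i in which(truth$kind == "decoy")) {
      ov <- sg$seq_id == truth$seq_id[i] &
        sg$start < truth$end[i] & truth$start[i] < sg$end
      drop[i] <- any(ov)
    }
    truth <- truth[!drop, , drop = FALSE]
  }
  rownames(truth) <- NULL
  structure(list(signal = sequence_set(sig, ids = sig_ids, name = "signal"),
                 control = sequence_set(ctl, ids = ctl_ids, name = "control"),
                 truth = truth, pwm = pwm, decoy_pwm = decoy_pwm,
                 params = params, seed = seed),
            class = "synthetic_dataset")
}

#' Dinucleotide-preserving shuffle
#'
#' Uniform random Eulerian-path shuffle (Altschul-Erickson) preserving the
#' exact dinucleotide count vector and the first and last nucleotide of
#' each sequence; commonly used to synthesize control sets.
#'
#' @param s Character vector of sequences (length >= 2 each).
#' @param seed Optional integer seed.
#' @return Character vector of shuffled sequences.
#' @export
dinucleotide_shuffle <- function(s, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(s, shuffle_one, "", USE.NAMES = FALSE)
}

shuffle_one <- function(s) {
  ch <- strsplit(s, "")[[1L]]
  n <- length(ch)
  if (n < 2L) return(s)
  verts <- unique(ch)
  succ <- split(ch[-1L], factor(ch[-n], levels = verts))
  last <- ch[n]
  # pick a random last-edge per non-terminal vertex until they form a
  # structure in which every vertex reaches the terminal vertex
  nonterm <- setdiff(names(Filter(length, succ)), last)
  for (try in 1:1000) {
    lastedge <- vapply(nonterm, function(v) sample(succ[[v]], 1L), "")
    reach <- function(v) {
      seen <- character(0)
      while (!(v %in% seen)) {
        if (v == last) return(TRUE)
        if (!(v %in% nonterm)) return(FALSE)
        seen <- c(seen, v)
        v <- lastedge[[v]]
      }
      FALSE
    }
    if (all(vapply(nonterm, reach, TRUE))) break
    if (try == 1000L) stop("shuffle failed to find an Eulerian arrangement")
  }
  edges <- lapply(verts, function(v) {
    e <- succ[[v]]
    if (v %in% nonterm) {
      # remove one instance of the chosen last edge, shuffle, append it
      i <- match(lastedge[[v]], e)
      rest <- e[-i]
      c(if (length(rest)) sample(rest, length(rest)), lastedge[[v]])
    } else {
      if (length(e) > 1L) sample(e, length(e)) else e
    }
  })
  names(edges) <- verts
  ptr <- setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1L] <- ch[1L]
  v <- ch[1L]
  for (t in 2L:n) {
    nxt <- edges[[v]][ptr[[v]]]
    ptr[[v]] <- ptr[[v]] + 1L
    out[t] <- nxt
    v <- nxt
  }
  paste(out, collapse = "")
}

# background-only HMM with explicit emissions (no training data needed)
background_hmm <- function(emis = rep(0.25, 4L), avg_len = 100) {
  emis <- matrix(emis / sum(emis), nrow = 1L,
                 dimnames = list("background", NUCS))
  trans <- matrix(1, 1L, 1L, dimnames = list("background", "background"))
  states <- data.frame(name = "background", motif = NA_character_,
                       role = "background", pos = 0L,
                       stringsAsFactors = FALSE)
  new_binding_hmm(trans, emis, states, list(), avg_len)
}

#' Recognizability reference model
#'
#' The predictive performance of the true model bounds what discovery can
#' achieve. This builds an HMM whose motif-chain emissions equal the
#' implanted PWM and whose background-to-motif transition makes the
#' expected number of motifs per sequence equal the implantation frequency:
#' the per-position transition probability is `implant_freq / seq_len`
#' (e.g. 0.1 x 0.01 = 0.001 for 10% implantation in 100-nt sequences). The
#' background emission is uniform, or fitted to data by Baum-Welch for
#' higher-order backgrounds.
#'
#' @param pwm The implanted PWM (positions x 4).
#' @param implant_freq Implantation frequency as a fraction.
#' @param seq_len Sequence length in nt.
#' @param background `"uniform"`, or `"fit"` to Baum-Welch the background
#'   emission on `sets` before evaluation.
#' @param sets Sequence sets for `background = "fit"`.
#' @return A `binding_hmm`.
#' @export
recognizability_model <- function(pwm, implant_freq, seq_len,
                                  background = c("uniform", "fit"),
                                  sets = NULL) {
  background <- match.arg(background)
  w <- nrow(pwm)
  bg <- if (background == "fit") train_background(sets)
        else background_hmm(avg_len = seq_len)
  bg$avg_len <- max(bg$avg_len %||% seq_len, w + 1)
  hmm <- add_motif_chain(bg, strrep("N", w), alpha = 0.03)
  m <- hmm$motifs[[1L]]
  hmm$emis[m$states, ] <- pwm
  p <- implant_freq / seq_len
  hmm$trans[1L, ] <- 0
  hmm$trans[1L, 1L] <- 1 - p
  hmm$trans[1L, m$states[1L]] <- p
  last <- m$states[m$length]
  hmm$trans[last, ] <- 0
  hmm$trans[last, 1L] <- 1
  hmm
}

#' Nucleotide- and site-level evaluation of predicted sites
#'
#' Nucleotide level: the confusion matrix over all positions yields the
#' nucleotide-level MCC (nCC; 0 when undefined). Site level: a predicted
#' site matches a truth site if their overlap covers at least 50% of the
#' truth site's length, with greedy one-to-one matching by decreasing
#' overlap; sSn is the matched fraction of truth sites, sPPV the matched
#' fraction of predictions (0 when there are none), and sAP their
#' arithmetic mean.
#'
#' @param predicted data.frame with `seq_id`, `start`, `end` (0-based,
#'   half-open).
#' @param truth data.frame with the same columns.
#' @param total_nt Total number of scanned nucleotides (for the TN count).
#' @return A `site_metrics` list with `nCC`, `sSn`, `sPPV`, `sAP` and the
#'   raw confusion `counts`.
#' @export
evaluate_sites <- function(predicted, truth, total_nt) {
  pr <- split(predicted, predicted$seq_id)
  tr <- split(truth, truth$seq_id)
  nt_tp <- 0; pred_nt <- 0; truth_nt <- 0
  site_tp <- 0L
  for (id in union(names(pr), names(tr))) {
    p <- pr[[id]]; t <- tr[[id]]
    pir <- if (is.null(p)) IRanges::IRanges() else
      IRanges::reduce(IRanges::IRanges(p$start + 1L, p$end))
    tir <- if (is.null(t)) IRanges::IRanges() else
      IRanges::IRanges(t$start + 1L, t$end)
    pred_nt <- pred_nt + sum(IRanges::width(pir))
    truth_nt <- truth_nt + sum(IRanges::width(IRanges::reduce(tir)))
    if (length(pir) && length(tir))
      nt_tp <- nt_tp +
        sum(IRanges::width(IRanges::intersect(pir, IRanges::reduce(tir))))
    # site-level greedy 1-to-1 matching at >= 50% of the truth length
    if (is.null(p) || is.null(t)) next
    pirs <- IRanges::IRanges(p$start + 1L, p$end)
    ov <- IRanges::findOverlaps(pirs, tir)
    if (length(ov) == 0L) next
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    w <- IRanges::width(IRanges::pintersect(pirs[qh], tir[sh]))
    need <- IRanges::width(tir[sh]) / 2
    keep <- w >= need
    qh <- qh[keep]; sh <- sh[keep]; w <- w[keep]
    o <- order(-w)
    used_p <- logical(length(pirs)); used_t <- logical(length(tir))
    for (k in o) {
      if (!used_p[qh[k]] && !used_t[sh[k]]) {
        used_p[qh[k]] <- TRUE; used_t[sh[k]] <- TRUE
        site_tp <- site_tp + 1L
      }
    }
  }
  counts <- c(nt_tp = nt_tp, nt_fp = pred_nt - nt_tp,
              nt_fn = truth_nt - nt_tp,
              nt_tn = total_nt - pred_nt - truth_nt + nt_tp,
              site_tp = site_tp, n_truth = nrow(truth),
              n_pred = nrow(predicted))
  metrics_from_counts(counts)
}

metrics_from_counts <- function(counts) {
  tp <- counts[["nt_tp"]]; fp <- counts[["nt_fp"]]
  fn <- counts[["nt_fn"]]; tn <- counts[["nt_tn"]]
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  ncc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0
  ssn <- if (counts[["n_truth"]] > 0)
    counts[["site_tp"]] / counts[["n_truth"]] else 0
  sppv <- if (counts[["n_pred"]] > 0)
    counts[["site_tp"]] / counts[["n_pred"]] else 0
  structure(list(nCC = ncc, sSn = ssn, sPPV = sppv,
                 sAP = (ssn + sppv) / 2, counts = counts),
            class = "site_metrics")
}

#' @export
print.site_metrics <- function(x, ...) {
  cat(sprintf("<site_metrics> nCC %.4f  sSn %.4f  sPPV %.4f  sAP %.4f\n",
              x$nCC, x$sSn, x$sPPV, x$sAP))
  invisible(x)
}

#' Pool site metrics across datasets
#'
#' High-level performance summaries pool the raw true/false prediction
#' counts across datasets and recompute the metrics on the pooled counts
#' (not averages of per-dataset metrics).
#'
#' @param metrics_list List of `site_metrics`.
#' @return A pooled `site_metrics`.
#' @export
summarize_performance <- function(metrics_list) {
  stopifnot(length(metrics_list) >= 1L)
  counts <- Reduce(`+`, lapply(metrics_list, `[[`, "counts"))
  metrics_from_counts(counts)
}

# most frequent IUPAC word of bounded degeneracy in a single set (seeding
# for signal-only generative learning)
most_frequent_word <- function(set, len, max_degeneracy = 2L) {
  layout <- list(seqs = list(set$seqs), n = length(set$seqs),
                 map = list(single = 1L))
  r <- run_seed_length(layout, len, "freq", n = 100L,
                       cap = resolve_degeneracy_cap(max_degeneracy, len))
  if (is.null(r)) return(NULL)
  iupac_word(r$best$word)
}

#' Run one synthetic benchmark experiment
#'
#' Generates a dataset, then runs the requested site predictors and
#' evaluates each against the implanted signal sites over all signal and
#' control sequences:
#' \describe{
#'   \item{`recognizability`}{the true-model reference HMM.}
#'   \item{`mico`}{discriminative discovery: MICO seed search, hybrid MICO
#'     HMM training, Viterbi site prediction; models failing the corrected
#'     MICO significance filter predict nothing.}
#'   \item{`plasma`}{the best IUPAC seed word alone, reporting all its
#'     matches as sites.}
#'   \item{`bw`}{signal-only generative learning: the most frequent
#'     low-degeneracy word seeds an HMM trained by Baum-Welch on the signal
#'     set only, with the same significance filter.}
#' }
#'
#' @param params A [bench_params()].
#' @param seed Integer seed for data generation.
#' @param methods Character vector of predictors to run.
#' @param config Training configuration for the HMM methods.
#' @param threshold Corrected significance threshold for the filter.
#' @return List of `site_metrics` keyed by method, with the dataset
#'   attached as attribute `dataset`.
#' @export
benchmark_run <- function(params, seed = 1L,
                          methods = c("recognizability", "mico", "plasma"),
                          config = training_config(objective = "mico",
                                                   max_iterations = 100L,
                                                   tolerance = 1e-4),
                          threshold = 0.05) {
  ds <- generate_dataset(params, seed)
  ct <- contrast(ds$signal, ds$control, name = "bench")
  all_seqs <- c(ds$signal$seqs, ds$control$seqs)
  all_ids <- c(ds$signal$ids, ds$control$ids)
  total_nt <- sum(nchar(all_seqs))
  truth <- ds$truth[ds$truth$kind == "signal", , drop = FALSE]
  space <- motif_space_size(params$motif_len)
  out <- list()
  evaluate <- function(sites) evaluate_sites(sites, truth, total_nt)
  no_sites <- data.frame(seq_id = character(), start = integer(),
                         end = integer(), motif = character(),
                         stringsAsFactors = FALSE)

  if ("recognizability" %in% methods) {
    bgmode <- if (params$background == "uniform") "uniform" else "fit"
    hmm <- recognizability_model(ds$pwm, params$implant_prob, params$seq_len,
                                 background = bgmode,
                                 sets = list(ds$signal, ds$control))
    out$recognizability <- evaluate(viterbi_sites(hmm, all_seqs, all_ids))
  }
  sr <- NULL
  if (any(c("mico", "plasma") %in% methods))
    sr <- find_seed(ct, params$motif_len, "mico")
  if ("plasma" %in% methods) {
    out$plasma <- if (is.null(sr)) evaluate(no_sites) else {
      hits <- match_positions_c(all_seqs, sr$word$masks)
      len <- length(sr$word$masks)
      sites <- do.call(rbind, lapply(which(lengths(hits) > 0L), function(i)
        data.frame(seq_id = all_ids[i], start = hits[[i]],
                   end = hits[[i]] + len, motif = "seed",
                   stringsAsFactors = FALSE)))
      evaluate(if (is.null(sites)) no_sites else sites)
    }
  }
  if ("mico" %in% methods) {
    out$mico <- if (is.null(sr)) evaluate(no_sites) else {
      bg <- train_background(list(ds$signal, ds$control))
      fr <- fit(add_motif_chain(bg, sr$word), ct, config)
      sig <- mico_log_pvalue(fr$tables)
      acc <- correct_and_filter(sig$log_p, space, threshold, sig$dof)
      evaluate(if (acc$accepted) viterbi_sites(fr$hmm, all_seqs, all_ids)
               else no_sites)
    }
  }
  if ("bw" %in% methods) {
    w <- most_frequent_word(ds$signal, params$motif_len, max_degeneracy = 2L)
    out$bw <- if (is.null(w)) evaluate(no_sites) else {
      bg <- train_background(list(ds$signal))
      # generative EM: likelihood magnitudes are huge, so the relative
      # convergence tolerance must be much tighter than for the
      # bounded discriminative objectives
      cfg <- training_config(objective = "logl", scheme = "all",
                             max_iterations = config$max_iterations,
                             tolerance = min(config$tolerance, 1e-7),
                             context_sets = "signal")
      fr <- fit(add_motif_chain(bg, w), ct, cfg)
      tables <- expected_tables(fr$hmm, ct)
      sig <- mico_log_pvalue(tables)
      acc <- correct_and_filter(sig$log_p, space, threshold, sig$dof)
      evaluate(if (acc$accepted) viterbi_sites(fr$hmm, all_seqs, all_ids)
               else no_sites)
    }
  }
  attr(out, "dataset") <- ds
  out
}

#' The reduced basic-design benchmark grid
#'
#' The package's default desk-scale replication of the basic synthetic
#' experiments: 1000 + 1000 sequences of 100 nt, 8-nt motifs with IC 8, 10
#' or 12 bits, implantation probability 20% or 50%, three generation seeds
#' each (18 datasets).
#'
#' @param base_seed Integer; dataset seeds are derived from it.
#' @return data.frame with one row per dataset (`ic`, `implant_prob`,
#'   `seed`).
#' @export
reduced_basic_grid <- function(base_seed = 1L) {
  g <- expand.grid(ic = c(8, 10, 12), implant_prob = c(0.2, 0.5),
                   rep = 1:3)
  g$seed <- (as.integer(base_seed) * 997L + seq_len(nrow(g)) * 101L) %%
    2147483647L
  g
}
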