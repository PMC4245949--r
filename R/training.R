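# Discriminative training of binding-site HMMs.
#
# Signal parameters (motif match-state emissions) are optimized by gradient
# ascent on the chosen discriminative objective with a strong-Wolfe line
# search; context parameters (background emission, all transitions) are
# updated by Baum-Welch iterations on the likelihood. The default hybrid
# scheme alternates one gradient step and one Baum-Welch step until both
# objective and likelihood have converged.
#
# All probability rows are optimized through a softmax reparameterization
# (z -> exp(z)/sum(exp(z))), which keeps every row on the simplex during
# unconstrained gradient ascent.

#' Training configuration
#'
#' @param objective One of `"mico"`, `"dfreq"`, `"mcc"`, `"mmie"`,
#'   `"logl"`, `"dlogl"`.
#' @param scheme `"hybrid"` (discriminative gradient on motif emissions,
#'   Baum-Welch on context parameters; the default), `"all"` (one objective
#'   for all parameters) or `"emissions"` (motif emissions only, context
#'   untouched).
#' @param max_iterations Maximum alternations.
#' @param tolerance Relative-change termination tolerance for both the
#'   objective and the log-likelihood.
#' @param context_sets Optional character vector naming the conditions used
#'   to train context parameters (default: all).
#' @param wolfe_c1,wolfe_c2 Sufficient-increase and curvature constants of
#'   the line search.
#' @param seed Integer seed controlling any stochastic choice.
#' @return A list of class `training_config`.
#' @export
training_config <- function(objective = "mico",
                            scheme = c("hybrid", "all", "emissions"),
                            max_iterations = 1000L, tolerance = 1e-6,
                            context_sets = NULL,
                            wolfe_c1 = 1e-4, wolfe_c2 = 0.9, seed = 1L) {
  stopifnot(max_iterations >= 1L, tolerance > 0)
  structure(list(objective = match.arg(objective, objective_kinds),
                 scheme = match.arg(scheme),
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, context_sets = context_sets,
                 wolfe_c1 = wolfe_c1, wolfe_c2 = wolfe_c2,
                 seed = as.integer(seed)),
            class = "training_config")
}

# precompute encoded sequence parts for every condition of the collection
prepare_training_data <- function(cc) {
  cc <- as_contrast_collection(cc)
  conds <- list(); map <- list(); cond_names <- character(0); k <- 0L
  for (ct in cc) {
    idx <- integer(0)
    for (cond in ct$conditions) {
      k <- k + 1L
      conds[[k]] <- c(hmm_parts(cond$seqs),
                      list(name = cond$name, set = cond))
      cond_names <- c(cond_names, cond$name)
      idx <- c(idx, k)
    }
    map[[ct$name]] <- idx
  }
  list(conds = conds, map = map, cond_names = cond_names, cc = cc)
}

# forward log-likelihood sums per logical sequence for one condition
cond_loglik <- function(hmm, cond, allowed) {
  lf <- hmm_loglik_c(cond$parts, hmm$trans, hmm$emis, hmm_pi(hmm),
                     hmm_end_weights(hmm), allowed)
  rowsum_vec(lf, cond$group, cond$n_seq)
}

# posterior occurrence per sequence for every condition
all_p_occ <- function(hmm, td, motif = "any") {
  full <- rep(TRUE, n_states(hmm))
  mask <- state_mask(hmm, motif)
  lapply(td$conds, function(cond) {
    lfs <- cond_loglik(hmm, cond, full)
    lcs <- cond_loglik(hmm, cond, mask)
    p <- 1 - exp(lcs - lfs)
    p[!is.finite(lfs)] <- 0
    pmin(pmax(p, 0), 1)
  })
}

tables_from_p <- function(td, p_occ) {
  lapply(names(td$map), function(ctn) {
    idx <- td$map[[ctn]]
    contingency_table(vapply(p_occ[idx], sum, 0),
                      vapply(td$conds[idx], `[[`, 0L, "n_seq"),
                      conditions = vapply(td$conds[idx], `[[`, "", "name"),
                      contrast_name = ctn)
  })
}

context_indices <- function(td, context_sets) {
  if (is.null(context_sets)) return(seq_along(td$conds))
  idx <- which(td$cond_names %in% context_sets)
  if (length(idx) == 0L) stop("no condition matches context_sets")
  idx
}

# ---- MMIE auxiliary parameters ---------------------------------------------

estimate_mmie <- function(td, p_occ) {
  lapply(names(td$map), function(ctn) {
    idx <- td$map[[ctn]]
    n <- vapply(td$conds[idx], `[[`, 0L, "n_seq")
    pm <- vapply(p_occ[idx], mean, 0)
    list(prior = n / sum(n),
         p_m_given_c = pmin(pmax(pm, 1e-6), 1 - 1e-6),
         z1 = min(max(sum(n * pm) / sum(n), 1e-6), 1 - 1e-6))
  })
}

# J = sum_X log P(C|X) and dJ/dp per sequence under the occurrence-indicator
# mixture: P(C|X) proportional to P(C) [P(1|C) p/z1 + P(0|C)(1-p)/z0]
mmie_objective <- function(td, p_occ, mmie, with_grad = FALSE) {
  J <- 0
  grads <- if (with_grad) vector("list", length(p_occ))
  for (ci in seq_along(td$map)) {
    idx <- td$map[[ci]]
    m <- mmie[[ci]]
    z1 <- m$z1; z0 <- 1 - z1
    for (r in seq_along(idx)) {
      p <- p_occ[[idx[r]]]
      fs <- matrix(0, length(p), length(idx))   # f_C'(p) for every class
      dfs <- numeric(length(idx))
      for (cp in seq_along(idx)) {
        fs[, cp] <- m$prior[cp] *
          (m$p_m_given_c[cp] * p / z1 + (1 - m$p_m_given_c[cp]) * (1 - p) / z0)
        dfs[cp] <- m$prior[cp] *
          (m$p_m_given_c[cp] / z1 - (1 - m$p_m_given_c[cp]) / z0)
      }
      D <- rowSums(fs)
      J <- J + sum(log(pmax(fs[, r], 1e-300)) - log(pmax(D, 1e-300)))
      if (with_grad) {
        dD <- sum(dfs)
        grads[[idx[r]]] <- dfs[r] / pmax(fs[, r], 1e-300) - dD / pmax(D, 1e-300)
      }
    }
  }
  list(J = J, dJ_dp = grads)
}

# ---- objective evaluation ---------------------------------------------------

table_objectives <- c("mico", "dfreq", "mcc", "freq")

eval_objective <- function(hmm, td, objective, mmie = NULL,
                           context_idx = seq_along(td$conds)) {
  if (objective %in% c(table_objectives, "mmie")) {
    p_occ <- all_p_occ(hmm, td)
    tables <- tables_from_p(td, p_occ)
    if (objective == "mmie") {
      if (is.null(mmie)) mmie <- estimate_mmie(td, p_occ)
      J <- mmie_objective(td, p_occ, mmie)$J
    } else {
      J <- aggregate_objective(objective, tables)
    }
    list(J = J, p_occ = p_occ, tables = tables, mmie = mmie)
  } else if (objective == "dlogl") {
    full <- rep(TRUE, n_states(hmm))
    J <- 0
    for (idx in td$map) {
      if (length(idx) != 2L)
        stop("invalid objective: DLOGL requires binary contrasts")
      J <- J + sum(cond_loglik(hmm, td$conds[[idx[1L]]], full)) -
               sum(cond_loglik(hmm, td$conds[[idx[2L]]], full))
    }
    list(J = J, p_occ = NULL, tables = NULL, mmie = NULL)
  } else { # logl
    full <- rep(TRUE, n_states(hmm))
    J <- sum(vapply(td$conds[context_idx],
                    function(cond) sum(cond_loglik(hmm, cond, full)), 0))
    list(J = J, p_occ = NULL, tables = NULL, mmie = NULL)
  }
}

# per-sequence weights dJ/dp for the chain rule through posterior occurrence
occurrence_weights <- function(td, objective, p_occ, tables, mmie) {
  if (objective == "mmie")
    return(mmie_objective(td, p_occ, mmie, with_grad = TRUE)$dJ_dp)
  w <- vector("list", length(p_occ))
  for (ci in seq_along(td$map)) {
    idx <- td$map[[ci]]
    u <- table_grad(objective, tables[[ci]])
    for (r in seq_along(idx))
      w[[idx[r]]] <- rep(u[r], td$conds[[idx[r]]]$n_seq)
  }
  w
}

# ---- parameter packing (softmax reparameterization) ------------------------

signal_rows <- function(hmm) {
  unlist(lapply(hmm$motifs, `[[`, "states"), use.names = FALSE)
}

# active parameter blocks for a scheme: list of (kind, rows)
active_blocks <- function(hmm, scheme) {
  blocks <- list(list(kind = "emis", rows = signal_rows(hmm)))
  if (scheme == "all") {
    blocks <- c(blocks, list(list(kind = "emis", rows = hmm$bg),
                             list(kind = "trans",
                                  rows = seq_len(n_states(hmm)))))
  }
  blocks
}

pack_params <- function(hmm, blocks) {
  unlist(lapply(blocks, function(b) {
    m <- if (b$kind == "emis") hmm$emis[b$rows, , drop = FALSE]
         else hmm$trans[b$rows, , drop = FALSE]
    log(pmax(m, 1e-300))[m > 0 | b$kind == "emis"]
  }))
}

unpack_params <- function(hmm, blocks, z) {
  pos <- 0L
  for (b in blocks) {
    if (b$kind == "emis") {
      k <- length(b$rows) * 4L
      m <- matrix(z[pos + seq_len(k)], nrow = length(b$rows))
      m <- exp(m - apply(m, 1L, max))
      hmm$emis[b$rows, ] <- m / rowSums(m)
      pos <- pos + k
    } else {
      support <- hmm$trans[b$rows, , drop = FALSE] > 0
      k <- sum(support)
      m <- hmm$trans[b$rows, , drop = FALSE]
      zm <- matrix(-Inf, nrow(m), ncol(m))
      zm[support] <- z[pos + seq_len(k)]
      zm <- exp(zm - apply(zm, 1L, max))
      hmm$trans[b$rows, ] <- zm / rowSums(zm)
      pos <- pos + k
    }
  }
  hmm
}

# z-space gradient from weighted expected counts:
# g = counts - p * rowSums(counts), rows restricted to the block
counts_to_zgrad <- function(counts, probs, support = NULL) {
  g <- counts - probs * rowSums(counts)
  if (!is.null(support)) g[!support] <- 0
  g
}

# weighted expected counts over conditions; weights per logical sequence
weighted_counts <- function(hmm, td, weights, allowed, cond_idx,
                            want_trans = TRUE) {
  S <- n_states(hmm)
  A <- matrix(0, S, S); E <- matrix(0, S, 4L)
  pi <- hmm_pi(hmm)
  endw <- hmm_end_weights(hmm)
  for (i in cond_idx) {
    cond <- td$conds[[i]]
    w_part <- weights[[i]][cond$group]
    if (all(w_part == 0)) next
    r <- hmm_fb_counts_c(cond$parts, hmm$trans, hmm$emis, pi, endw, w_part,
                         allowed, hmm$bg, want_trans)
    A <- A + r$A; E <- E + r$E
  }
  list(A = A, E = E)
}

# gradient of the objective over the active blocks, in z space
objective_gradient <- function(hmm, td, objective, scheme, mmie = NULL,
                               context_idx = seq_along(td$conds),
                               state = NULL) {
  blocks <- active_blocks(hmm, scheme)
  full <- rep(TRUE, n_states(hmm))
  if (objective %in% c(table_objectives, "mmie")) {
    st <- state %||% eval_objective(hmm, td, objective, mmie, context_idx)
    u <- occurrence_weights(td, objective, st$p_occ, st$tables,
                            st$mmie %||% mmie)
    # dJ/dtheta = sum_s u_s (1 - p_s) (dlogPf - dlogPc)
    wf <- lapply(seq_along(u), function(i) u[[i]] * (1 - st$p_occ[[i]]))
    cf <- weighted_counts(hmm, td, wf, full, seq_along(td$conds),
                          want_trans = scheme == "all")
    A <- cf$A; E <- cf$E
    if (scheme == "all") {
      mask <- state_mask(hmm, "any")
      ccst <- weighted_counts(hmm, td, lapply(wf, function(x) -x), mask,
                              seq_along(td$conds))
      A <- A + ccst$A; E <- E + ccst$E
    }
  } else if (objective == "dlogl") {
    w <- vector("list", length(td$conds))
    for (idx in td$map) {
      w[[idx[1L]]] <- rep(1, td$conds[[idx[1L]]]$n_seq)
      w[[idx[2L]]] <- rep(-1, td$conds[[idx[2L]]]$n_seq)
    }
    cf <- weighted_counts(hmm, td, w, full, seq_along(td$conds),
                          want_trans = scheme == "all")
    A <- cf$A; E <- cf$E
  } else { # logl
    w <- lapply(td$conds, function(cond) rep(0, cond$n_seq))
    for (i in context_idx) w[[i]] <- rep(1, td$conds[[i]]$n_seq)
    cf <- weighted_counts(hmm, td, w, full, context_idx)
    A <- cf$A; E <- cf$E
  }
  unlist(lapply(blocks, function(b) {
    if (b$kind == "emis") {
      g <- counts_to_zgrad(E[b$rows, , drop = FALSE],
                           hmm$emis[b$rows, , drop = FALSE])
      as.numeric(g)
    } else {
      support <- hmm$trans[b$rows, , drop = FALSE] > 0
      g <- counts_to_zgrad(A[b$rows, , drop = FALSE],
                           hmm$trans[b$rows, , drop = FALSE], support)
      g[support]
    }
  }))
}

#' Gradient of the summed log-likelihood of a sequence set
#'
#' Gradient of `sum_X log P(X | theta)` with respect to the softmax
#' reparameterization of the emission and transition rows, computed from
#' expected counts of the forward-backward pass (runtime linear in total
#' sequence length).
#'
#' @param hmm A `binding_hmm`.
#' @param set A [sequence_set()] or character vector of sequences.
#' @return List with z-space gradient matrices `emis` (states x 4) and
#'   `trans` (states x states, structural zeros excluded).
#' @export
grad_log_likelihood <- function(hmm, set) {
  seqs <- as_seqs(set)
  parts <- hmm_parts(seqs)
  full <- rep(TRUE, n_states(hmm))
  r <- hmm_fb_counts_c(parts$parts, hmm$trans, hmm$emis, hmm_pi(hmm),
                       hmm_end_weights(hmm), rep(1, length(parts$parts)),
                       full, hmm$bg)
  list(emis = counts_to_zgrad(r$E, hmm$emis),
       trans = counts_to_zgrad(r$A, hmm$trans, hmm$trans > 0),
       loglik = sum(r$loglik))
}

#' Gradient of the posterior occurrence probability of one sequence
#'
#' Chain rule through `P(k>0|X) = 1 - P_c(X)/P(X)`: the gradient equals
#' `(1 - p) (grad log P - grad log P_c)` in the softmax reparameterization.
#'
#' @param hmm A `binding_hmm` with motif chains.
#' @param s A single sequence (character).
#' @param motif Motif selector as in [posterior_occurrence()].
#' @return List with `p` and z-space gradients `emis` and `trans`.
#' @export
grad_posterior_occurrence <- function(hmm, s, motif = "any") {
  parts <- hmm_parts(as.character(s))
  full <- rep(TRUE, n_states(hmm))
  mask <- state_mask(hmm, motif)
  pi <- hmm_pi(hmm)
  endw <- hmm_end_weights(hmm)
  w <- rep(1, length(parts$parts))
  rf <- hmm_fb_counts_c(parts$parts, hmm$trans, hmm$emis, pi, endw, w, full,
                        hmm$bg)
  rc <- hmm_fb_counts_c(parts$parts, hmm$trans, hmm$emis, pi, endw, w, mask,
                        hmm$bg)
  p <- 1 - exp(sum(rc$loglik) - sum(rf$loglik))
  list(p = p,
       emis = (1 - p) * counts_to_zgrad(rf$E - rc$E, hmm$emis),
       trans = (1 - p) * counts_to_zgrad(rf$A - rc$A, hmm$trans,
                                         hmm$trans > 0))
}

#' Gradient of a discriminative objective
#'
#' Chain rule from the objective through the expected contingency-table
#' cells and the posterior occurrence probabilities (MICO, DFREQ, MCC,
#' MMIE), or directly through the likelihood (LOGL, DLOGL). Gradients are
#' in the softmax reparameterization of the active parameter blocks:
#' motif emissions for the hybrid scheme, all parameters for `scheme =
#' "all"`.
#'
#' @param kind Objective kind.
#' @param hmm A `binding_hmm`.
#' @param contrasts A [contrast()] or [contrast_collection()].
#' @param mmie Optional list of MMIE auxiliary parameters (class priors and
#'   conditional occurrence probabilities per contrast).
#' @param scheme `"hybrid"`, `"all"` or `"emissions"`.
#' @return Numeric z-space gradient vector over the active blocks.
#' @export
grad_objective <- function(kind, hmm, contrasts, mmie = NULL,
                           scheme = "hybrid") {
  kind <- match.arg(kind, objective_kinds)
  td <- prepare_training_data(contrasts)
  objective_gradient(hmm, td, kind, scheme, mmie)
}

# ---- line search ------------------------------------------------------------

#' Strong-Wolfe line search for gradient ascent
#'
#' Bracketing-and-zoom line search with quadratic interpolation ensuring
#' the strong Wolfe conditions (sufficient increase and curvature) along an
#' ascent direction; falls back to Armijo backtracking if bracketing fails.
#'
#' @param fg Function of the step length returning `list(f, g)`: objective
#'   value and directional derivative along the search direction.
#' @param f0,g0 Value and directional derivative at step 0 (`g0 > 0` for an
#'   ascent direction).
#' @param init Initial trial step.
#' @param c1,c2 Wolfe constants (`0 < c1 < c2 < 1`).
#' @param max_evals Maximum number of `fg` evaluations.
#' @param max_step Upper bound on the step.
#' @return List with `step` (0 signals stagnation), `value` and
#'   `converged` (Wolfe conditions met).
#' @export
line_search <- function(fg, f0, g0, init = 1, c1 = 1e-4, c2 = 0.9,
                        max_evals = 25L, max_step = 1e6) {
  if (!is.finite(g0) || g0 <= 1e-14)
    return(list(step = 0, value = f0, converged = FALSE, stagnated = TRUE))
  evals <- 0L
  phi <- function(a) { evals <<- evals + 1L; fg(a) }
  wolfe <- function(a, r) {
    r$f >= f0 + c1 * a * g0 && abs(r$g) <= c2 * abs(g0)
  }
  zoom <- function(lo, rlo, hi, rhi) {
    for (i in seq_len(max_evals)) {
      # quadratic interpolation from (lo, f, g) and (hi, f); safeguarded
      d <- hi - lo
      denom <- 2 * (rhi$f - rlo$f - rlo$g * d)
      a <- if (abs(denom) > 1e-300) lo - rlo$g * d * d / denom else lo + d / 2
      if (!is.finite(a) || a <= min(lo, hi) + 0.1 * abs(d) ||
          a >= max(lo, hi) - 0.1 * abs(d)) a <- lo + d / 2
      r <- phi(a)
      if (wolfe(a, r))
        return(list(step = a, value = r$f, converged = TRUE,
                    stagnated = FALSE))
      if (r$f < f0 + c1 * a * g0 || r$f <= rlo$f) {
        hi <- a; rhi <- r
      } else {
        if (r$g * d < 0) { hi <- lo; rhi <- rlo }
        lo <- a; rlo <- r
      }
      if (evals >= max_evals) break
    }
    if (rlo$f > f0)
      list(step = lo, value = rlo$f, converged = FALSE, stagnated = FALSE)
    else list(step = 0, value = f0, converged = FALSE, stagnated = TRUE)
  }
  a_prev <- 0; r_prev <- list(f = f0, g = g0)
  a <- min(init, max_step)
  for (i in seq_len(max_evals)) {
    r <- phi(a)
    if (r$f < f0 + c1 * a * g0 || (i > 1L && r$f <= r_prev$f))
      return(zoom(a_prev, r_prev, a, r))
    if (abs(r$g) <= c2 * abs(g0))
      return(list(step = a, value = r$f, converged = TRUE, stagnated = FALSE))
    if (r$g <= 0)
      return(zoom(a, r, a_prev, r_prev))
    a_prev <- a; r_prev <- r
    a <- min(2 * a, max_step)
    if (a_prev >= max_step) break
    if (evals >= max_evals) break
  }
  # fallback: backtracking on the sufficient-increase condition
  a <- init
  for (i in seq_len(max_evals)) {
    r <- fg(a)
    if (r$f >= f0 + c1 * a * g0)
      return(list(step = a, value = r$f, converged = FALSE,
                  stagnated = FALSE))
    a <- a / 2
  }
  list(step = 0, value = f0, converged = FALSE, stagnated = TRUE)
}

# ---- Baum-Welch -------------------------------------------------------------

#' One Baum-Welch update of HMM parameters
#'
#' Performs a single EM step on the selected sequence sets. Parameter
#' groups named in `frozen` are left untouched (`"signal"`: motif match
#' emissions; `"background"`: background emission; `"transitions"`). The
#' log-likelihood of the training sets is non-decreasing over unfrozen
#' updates. An emission floor of 1e-6 is maintained.
#'
#' @param hmm A `binding_hmm`.
#' @param sets A [sequence_set()] or list of them.
#' @param frozen Character vector of frozen parameter groups.
#' @return The updated `binding_hmm`.
#' @export
baum_welch_update <- function(hmm, sets,
                              frozen = c("signal")) {
  if (inherits(sets, "sequence_set")) sets <- list(sets)
  frozen <- intersect(frozen, c("signal", "background", "transitions"))
  S <- n_states(hmm)
  A <- matrix(0, S, S); E <- matrix(0, S, 4L)
  full <- rep(TRUE, S)
  pi <- hmm_pi(hmm)
  endw <- hmm_end_weights(hmm)
  for (set in sets) {
    parts <- hmm_parts(as_seqs(set))
    r <- hmm_fb_counts_c(parts$parts, hmm$trans, hmm$emis, pi, endw,
                         rep(1, length(parts$parts)), full, hmm$bg)
    A <- A + r$A; E <- E + r$E
  }
  if (!("transitions" %in% frozen)) {
    support <- hmm$trans > 0
    for (i in seq_len(S)) {
      tot <- sum(A[i, support[i, ]])
      if (tot > 0) {
        row <- pmax(A[i, ] * support[i, ] / tot, 0)
        row[support[i, ]] <- pmax(row[support[i, ]], 1e-9)
        hmm$trans[i, ] <- row / sum(row)
      }
    }
  }
  upd_rows <- integer(0)
  if (!("background" %in% frozen)) upd_rows <- c(upd_rows, hmm$bg)
  if (!("signal" %in% frozen)) upd_rows <- c(upd_rows, signal_rows(hmm))
  ins <- unlist(lapply(hmm$motifs, `[[`, "insert_states"))
  if (!("signal" %in% frozen) && length(ins)) upd_rows <- c(upd_rows, ins)
  for (i in upd_rows) {
    tot <- sum(E[i, ])
    if (tot > 0) {
      row <- pmax(E[i, ] / tot, EMIS_FLOOR)
      hmm$emis[i, ] <- row / sum(row)
    }
  }
  hmm
}

# ---- fit --------------------------------------------------------------------

#' Fit a binding-site HMM by the hybrid discriminative learning scheme
#'
#' Alternates a gradient ascent step on the signal parameters (motif
#' emissions, under the configured discriminative objective with a
#' strong-Wolfe line search) with a Baum-Welch step on the context
#' parameters (background emission and transitions, under the likelihood of
#' the configured context sets), until the relative changes of both the
#' objective and the log-likelihood fall below the tolerance or the
#' iteration cap is reached. For MMIE, class priors and conditional
#' occurrence probabilities are re-estimated after each HMM update. If the
#' iterations oscillate, the best-objective iterate is returned with a
#' warning.
#'
#' @param hmm A seeded `binding_hmm` (see [add_motif_chain()]).
#' @param contrasts A [contrast()] or [contrast_collection()], already
#'   strand-extended where applicable.
#' @param config A [training_config()].
#' @return List with the fitted `hmm`, final `objective` value, expected
#'   `tables`, `mmie` parameters (MMIE only), a per-iteration `trace`
#'   data.frame and a `converged` flag.
#' @export
fit <- function(hmm, contrasts, config = training_config()) {
  stopifnot(inherits(config, "training_config"))
  set.seed(config$seed)
  td <- prepare_training_data(contrasts)
  objective <- config$objective
  scheme <- config$scheme
  context_idx <- context_indices(td, config$context_sets)
  context_sets_list <- lapply(context_idx, function(i) td$conds[[i]]$set)
  gradient_objectives <- setdiff(objective_kinds, "logl")
  use_gradient <- objective %in% gradient_objectives

  blocks <- active_blocks(hmm, if (scheme == "all") "all" else "hybrid")
  st <- eval_objective(hmm, td, objective, NULL, context_idx)
  mmie <- st$mmie
  logL <- sum(vapply(context_idx, function(i)
    sum(cond_loglik(hmm, td$conds[[i]], rep(TRUE, n_states(hmm)))), 0))
  best <- list(hmm = hmm, J = st$J, tables = st$tables, mmie = mmie)
  trace <- data.frame(iteration = 0L, objective = st$J, loglik = logL,
                      step = NA_real_)
  converged <- FALSE
  for (it in seq_len(config$max_iterations)) {
    J_prev <- st$J; logL_prev <- logL
    step_len <- NA_real_
    if (use_gradient) {
      g <- objective_gradient(hmm, td, objective, scheme, mmie,
                              context_idx, state = st)
      gnorm <- sqrt(sum(g * g))
      if (gnorm > 1e-14) {
        d <- g / gnorm
        z0 <- pack_params(hmm, blocks)
        fg <- function(a) {
          h2 <- unpack_params(hmm, blocks, z0 + a * d)
          s2 <- eval_objective(h2, td, objective, mmie, context_idx)
          g2 <- objective_gradient(h2, td, objective, scheme, mmie,
                                   context_idx, state = s2)
          list(f = s2$J, g = sum(g2 * d))
        }
        ls <- line_search(fg, f0 = st$J, g0 = gnorm,
                          init = min(1, 1 / gnorm),
                          c1 = config$wolfe_c1, c2 = config$wolfe_c2)
        if (ls$step > 0) {
          hmm <- unpack_params(hmm, blocks, z0 + ls$step * d)
          step_len <- ls$step
        }
      }
    } else {
      # pure likelihood objective: EM steps in place of gradient ascent
      frozen <- switch(scheme,
                       emissions = c("background", "transitions"),
                       character(0))
      hmm <- baum_welch_update(hmm, context_sets_list, frozen = frozen)
    }
    if (scheme == "hybrid" && use_gradient)
      hmm <- baum_welch_update(hmm, context_sets_list, frozen = "signal")
    st <- eval_objective(hmm, td, objective, mmie, context_idx)
    if (objective == "mmie") {
      mmie <- estimate_mmie(td, st$p_occ)
      st <- eval_objective(hmm, td, objective, mmie, context_idx)
    }
    logL <- sum(vapply(context_idx, function(i)
      sum(cond_loglik(hmm, td$conds[[i]], rep(TRUE, n_states(hmm)))), 0))
    trace <- rbind(trace, data.frame(iteration = it, objective = st$J,
                                     loglik = logL, step = step_len))
    if (st$J >= best$J)
      best <- list(hmm = hmm, J = st$J, tables = st$tables, mmie = mmie)
    dJ <- abs(st$J - J_prev) / max(1e-12, abs(J_prev))
    dL <- abs(logL - logL_prev) / max(1e-12, abs(logL_prev))
    if (dJ < config$tolerance && dL < config$tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged && st$J < best$J - 1e-9)
    warning("training did not converge; returning the best-objective iterate")
  list(hmm = best$hmm, objective = best$J, tables = best$tables,
       mmie = best$mmie, trace = trace, converged = converged)
}
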