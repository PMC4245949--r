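# Binding-site HMM: a background state plus a chain of match states per
# motif (optionally with single, non-self-transiting insert states between
# adjacent match states). The background state transitions to itself or to
# the first state of each chain; the last state of each chain transitions
# back to the background or (with tiny initial mass) to the first state of
# any chain. Sequences start as if preceded by background context: the
# initial state distribution is tied to the background transition row.
#
# Parameters are split into signal parameters (motif match-state emissions)
# and context parameters (background emission and all transitions).

NUCS <- c("A", "C", "G", "T")
CHAIN_EPS <- 1e-6   # initial chain-to-chain transition mass
EMIS_FLOOR <- 1e-6  # emission floor maintained during training

new_binding_hmm <- function(trans, emis, states, motifs, avg_len) {
  structure(list(trans = trans, emis = emis, bg = 1L, states = states,
                 motifs = motifs, avg_len = avg_len),
            class = "binding_hmm")
}

hmm_pi <- function(hmm) hmm$trans[hmm$bg, ]

# terminal weights realizing the end-state wiring: sequences may end in the
# background or in the final match state of a chain, never mid-chain
hmm_end_weights <- function(hmm) {
  w <- numeric(n_states(hmm))
  w[hmm$bg] <- 1
  for (m in hmm$motifs) w[m$states[m$length]] <- 1
  w
}

n_states <- function(hmm) nrow(hmm$trans)

#' @export
print.binding_hmm <- function(x, ...) {
  cat("<binding_hmm> ", n_states(x), " states, ",
      length(x$motifs), " motif(s)",
      if (length(x$motifs))
        paste0(": ", paste(vapply(x$motifs, `[[`, "", "seed"),
                           collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

#' Train a background-only HMM
#'
#' Fits the single background emission state by Baum-Welch on the given
#' sequence sets; for a one-state model the Baum-Welch fixed point is the
#' pooled empirical nucleotide frequency, which is computed directly. The
#' mean sequence length of the training sets is stored for later motif
#' transition initialization.
#'
#' @param sets A [sequence_set()] or list of them (the sets chosen for
#'   context training).
#' @param pseudocount Added to each nucleotide count for regularization.
#' @return A `binding_hmm` with a single background state.
#' @export
train_background <- function(sets, pseudocount = 1) {
  if (inherits(sets, "sequence_set")) sets <- list(sets)
  stopifnot(length(sets) >= 1L)
  seqs <- unlist(lapply(sets, `[[`, "seqs"))
  counts <- setNames(numeric(4L), NUCS)
  tab <- table(strsplit(paste(seqs, collapse = ""), "")[[1L]])
  for (nuc in NUCS) counts[nuc] <- ifelse(nuc %in% names(tab), tab[[nuc]], 0)
  counts <- counts + pseudocount
  emis <- matrix(counts / sum(counts), nrow = 1L,
                 dimnames = list("background", NUCS))
  trans <- matrix(1, 1L, 1L, dimnames = list("background", "background"))
  states <- data.frame(name = "background", motif = NA_character_,
                       role = "background", pos = 0L,
                       stringsAsFactors = FALSE)
  avg_len <- mean(nchar(gsub("$", "", seqs, fixed = TRUE)))
  new_binding_hmm(trans, emis, states, list(), avg_len)
}

# emission row for one IUPAC position: disallowed nucleotides get alpha,
# the m allowed ones share (1 - alpha*(4-m))/m
seed_emission_row <- function(mask, alpha) {
  allowed <- bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0L
  m <- sum(allowed)
  row <- rep(alpha, 4L)
  row[allowed] <- (1 - alpha * (4 - m)) / m
  row
}

#' Add a motif chain to a binding-site HMM
#'
#' Appends a chain of match states seeded by an IUPAC word. The transition
#' probability from the background into the chain is initialized to
#' `1 / (l - w + 1)` (one expected transit per sequence of average length
#' `l` for a motif of length `w`). Each match state's emissions are centered
#' on the seed: nucleotides not allowed at the position get probability
#' `alpha`; the `m` allowed ones share `(1 - alpha * (4 - m)) / m` each
#' (alpha = 0.03 gives (0.91, 0.03, 0.03, 0.03) for `A` and
#' (0.47, 0.03, 0.03, 0.47) for `W`).
#'
#' @param hmm A `binding_hmm` (from [train_background()]).
#' @param seed An [iupac_word()] or IUPAC string.
#' @param alpha Pseudo-probability for disallowed nucleotides (0 < alpha <
#'   0.25).
#' @param avg_len Average sequence length `l`; defaults to the length
#'   recorded during background training. Must exceed the seed length.
#' @param name Motif name (default `motif1`, `motif2`, ...).
#' @param insert Allow single non-self-transiting insert states between
#'   adjacent match states (off by default).
#' @param insert_prob Entry probability of each insert state when enabled.
#' @return The extended `binding_hmm`.
#' @export
add_motif_chain <- function(hmm, seed, alpha = 0.03, avg_len = NULL,
                            name = NULL, insert = FALSE, insert_prob = 0.05) {
  stopifnot(inherits(hmm, "binding_hmm"), alpha > 0, alpha < 0.25)
  seed <- iupac_word(seed)
  w <- length(seed$masks)
  l <- avg_len %||% hmm$avg_len
  if (is.null(l) || l <= w)
    stop("configuration error: average sequence length (", l,
         ") must exceed the seed length (", w, ")")
  name <- name %||% paste0("motif", length(hmm$motifs) + 1L)
  if (name %in% names(hmm$motifs)) stop("duplicate motif name: ", name)
  P <- 1 / (l - w + 1)

  match_names <- paste0(name, ":", seq_len(w))
  ins_names <- if (insert && w > 1L) paste0(name, ":i", seq_len(w - 1L))
               else character(0)
  new_states <- data.frame(
    name = c(match_names, ins_names),
    motif = name,
    role = c(rep("match", w), rep("insert", length(ins_names))),
    pos = c(seq_len(w), seq_len(length(ins_names))),
    stringsAsFactors = FALSE)
  states <- rbind(hmm$states, new_states)
  S_old <- n_states(hmm)
  S <- nrow(states)
  trans <- matrix(0, S, S, dimnames = list(states$name, states$name))
  trans[seq_len(S_old), seq_len(S_old)] <- hmm$trans
  emis <- matrix(0.25, S, 4L, dimnames = list(states$name, NUCS))
  emis[seq_len(S_old), ] <- hmm$emis
  for (k in seq_len(w))
    emis[S_old + k, ] <- seed_emission_row(seed$masks[k], alpha)

  match_idx <- S_old + seq_len(w)
  ins_idx <- S_old + w + seq_along(ins_names)
  motifs <- hmm$motifs
  motifs[[name]] <- list(name = name, seed = as.character(seed), length = w,
                         states = match_idx, insert_states = ins_idx)

  # chain-internal wiring
  if (w > 1L) {
    for (k in seq_len(w - 1L)) {
      if (insert) {
        trans[match_idx[k], match_idx[k + 1L]] <- 1 - insert_prob
        trans[match_idx[k], ins_idx[k]] <- insert_prob
        trans[ins_idx[k], match_idx[k + 1L]] <- 1
      } else {
        trans[match_idx[k], match_idx[k + 1L]] <- 1
      }
    }
  }
  # background row: new chain gets P, self-transition absorbs the rest
  firsts <- vapply(motifs, function(m) m$states[1L], 0L)
  trans[1L, match_idx[1L]] <- P
  trans[1L, 1L] <- 1 - sum(trans[1L, firsts])
  if (trans[1L, 1L] <= 0)
    stop("configuration error: background self-transition would be <= 0")
  # every chain's last state: tiny mass to each chain start, rest to bg
  for (m in motifs) {
    last <- m$states[m$length]
    trans[last, ] <- 0
    trans[last, firsts] <- CHAIN_EPS
    trans[last, 1L] <- 1 - CHAIN_EPS * length(firsts)
  }
  new_binding_hmm(trans, emis, states, motifs, hmm$avg_len %||% l)
}

# split sequences at the strand separator; returns encoded parts plus the
# logical-sequence index of each part
hmm_parts <- function(seqs) {
  pieces <- strsplit(seqs, "$", fixed = TRUE)
  group <- rep(seq_along(pieces), lengths(pieces))
  flat <- unlist(pieces, use.names = FALSE)
  keep <- nzchar(flat)
  list(parts = encode_dna_c(flat[keep]), group = group[keep],
       n_seq = length(seqs))
}

# logical state mask excluding the given motif's (or all motifs') states
state_mask <- function(hmm, motif = "any") {
  allowed <- rep(TRUE, n_states(hmm))
  which_motifs <- if (identical(motif, "any")) names(hmm$motifs)
                  else intersect(motif, names(hmm$motifs))
  if (length(which_motifs) == 0L && !identical(motif, "any"))
    stop("unknown motif: ", motif)
  for (m in which_motifs)
    allowed[c(hmm$motifs[[m]]$states, hmm$motifs[[m]]$insert_states)] <- FALSE
  allowed
}

as_seqs <- function(x) {
  if (inherits(x, "sequence_set")) x$seqs else as.character(x)
}

#' Forward-backward inference for one sequence
#'
#' Numerically stable (scaled) forward-backward pass. `N` residues are
#' emission-marginalized (factor 1 in every state). Returns the
#' log-likelihood, per-position state posteriors and expected transition
#' counts. Intended for inspection and testing; bulk computations use the
#' compiled kernels directly.
#'
#' @param hmm A `binding_hmm`.
#' @param s A single sequence (character). Must not contain the strand
#'   separator; split extended sequences first.
#' @return List with `loglik`, `gamma` (T x states posterior matrix, rows
#'   sum to 1) and `xi` (states x states expected transition counts).
#' @export
forward_backward <- function(hmm, s) {
  stopifnot(length(s) == 1L, !grepl("$", s, fixed = TRUE))
  x <- encode_dna_c(s)[[1L]]
  T_ <- length(x)
  S <- n_states(hmm)
  B <- function(t) ifelse(rep(x[t] == 0L, S), 1, hmm$emis[, max(x[t], 1L)])
  alpha <- matrix(0, T_, S); scale <- numeric(T_)
  a <- hmm_pi(hmm) * B(1L)
  scale[1L] <- sum(a)
  if (scale[1L] <= 0) return(list(loglik = -Inf, gamma = NULL, xi = NULL))
  alpha[1L, ] <- a / scale[1L]
  for (t in seq_len(T_ - 1L) + 1L) {
    a <- as.numeric(alpha[t - 1L, ] %*% hmm$trans) * B(t)
    scale[t] <- sum(a)
    if (scale[t] <= 0) return(list(loglik = -Inf, gamma = NULL, xi = NULL))
    alpha[t, ] <- a / scale[t]
  }
  endw <- hmm_end_weights(hmm)
  c_end <- sum(alpha[T_, ] * endw)
  if (c_end <= 0) return(list(loglik = -Inf, gamma = NULL, xi = NULL))
  beta <- matrix(0, T_, S)
  beta[T_, ] <- endw / c_end
  xi <- matrix(0, S, S, dimnames = dimnames(hmm$trans))
  for (t in rev(seq_len(T_ - 1L))) {
    bb <- B(t + 1L) * beta[t + 1L, ]
    beta[t, ] <- as.numeric(hmm$trans %*% bb) / scale[t + 1L]
    xi <- xi + (alpha[t, ] %o% bb) * hmm$trans / scale[t + 1L]
  }
  gamma <- alpha * beta
  colnames(gamma) <- hmm$states$name
  list(loglik = sum(log(scale)) + log(c_end), gamma = gamma, xi = xi)
}

#' Posterior probability of at least one motif occurrence
#'
#' Computes `P(k > 0 | X, theta) = 1 - P_constrained(X) / P(X)`, where the
#' constrained likelihood sums over all state paths that never enter the
#' designated motif chain(s). Extended double-stranded sequences are split
#' at `$` and their halves treated as one logical sequence.
#'
#' @param hmm A `binding_hmm` with at least one motif chain.
#' @param x A [sequence_set()] or character vector of sequences.
#' @param motif A motif name, vector of names, or `"any"` (default): the
#'   occurrence of any of the named motifs.
#' @return Numeric vector of probabilities in `[0, 1]`, one per sequence.
#' @export
posterior_occurrence <- function(hmm, x, motif = "any") {
  if (length(hmm$motifs) == 0L) stop("model has no motif chains")
  seqs <- as_seqs(x)
  parts <- hmm_parts(seqs)
  pi <- hmm_pi(hmm)
  endw <- hmm_end_weights(hmm)
  full <- rep(TRUE, n_states(hmm))
  lf <- hmm_loglik_c(parts$parts, hmm$trans, hmm$emis, pi, endw, full)
  lc <- hmm_loglik_c(parts$parts, hmm$trans, hmm$emis, pi, endw,
                     state_mask(hmm, motif))
  lfs <- rowsum_vec(lf, parts$group, parts$n_seq)
  lcs <- rowsum_vec(lc, parts$group, parts$n_seq)
  p <- 1 - exp(lcs - lfs)
  bad <- !is.finite(lfs)
  if (any(bad)) {
    warning(sum(bad), " sequence(s) had zero probability under the model")
    p[bad] <- 0
  }
  pmin(pmax(p, 0), 1)
}

rowsum_vec <- function(v, group, n) {
  out <- numeric(n)
  s <- rowsum(v, group)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

#' Expected contingency tables from HMM posteriors
#'
#' For each condition, the expected number of sequences with at least one
#' motif occurrence is the sum of posterior occurrence probabilities; the
#' resulting fractional tables feed the discriminative objectives during
#' HMM optimization.
#'
#' @param hmm A fitted `binding_hmm`.
#' @param contrasts A [contrast()] or [contrast_collection()] (already
#'   strand-extended if applicable).
#' @param motif Motif selector as in [posterior_occurrence()].
#' @return List of [contingency_table()]s, one per contrast.
#' @export
expected_tables <- function(hmm, contrasts, motif = "any") {
  cc <- as_contrast_collection(contrasts)
  lapply(cc, function(ct) {
    pw <- vapply(ct$conditions,
                 function(set) sum(posterior_occurrence(hmm, set, motif)), 0)
    contingency_table(pw, vapply(ct$conditions, length, 0L),
                      conditions = names(ct$conditions),
                      contrast_name = ct$name)
  })
}

#' Viterbi-decoded motif sites
#'
#' Decodes the maximum-probability state path of each sequence and reports
#' maximal runs of motif states as sites (0-based, half-open coordinates on
#' the scanned sequence). Sites never span the strand separator, since
#' inference splits sequences there.
#'
#' @param hmm A fitted `binding_hmm`.
#' @param x A [sequence_set()] or character vector.
#' @param ids Sequence identifiers (defaults to the set's ids).
#' @return data.frame with columns `seq_id`, `start`, `end`, `motif`.
#' @export
viterbi_sites <- function(hmm, x, ids = NULL) {
  seqs <- as_seqs(x)
  ids <- ids %||% (if (inherits(x, "sequence_set")) x$ids
                   else paste0("seq", seq_along(seqs)))
  pi <- hmm_pi(hmm)
  state_motif <- hmm$states$motif
  first_states <- vapply(hmm$motifs, function(m) m$states[1L], 0L)
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    pieces <- strsplit(seqs[i], "$", fixed = TRUE)[[1L]]
    offset <- 0L
    rows <- list()
    for (pc in pieces) {
      L <- nchar(pc)
      if (L > 0L) {
        path <- hmm_viterbi_c(encode_dna_c(pc)[[1L]], hmm$trans, hmm$emis,
                              pi, hmm_end_weights(hmm))
        mt <- state_motif[path]
        r <- rle(ifelse(is.na(mt), "", mt))
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (k in which(nzchar(r$values))) {
          # split tandem occurrences at interior first-state positions
          span <- starts[k]:ends[k]
          cut <- span[path[span] %in% first_states]
          if (length(cut) == 0L) cut <- starts[k]
          if (cut[1L] != starts[k]) cut <- c(starts[k], cut)
          bounds <- c(cut, ends[k] + 1L)
          for (j in seq_along(cut)) {
            rows[[length(rows) + 1L]] <- data.frame(
              seq_id = ids[i],
              start = offset + bounds[j] - 1L,
              end = offset + bounds[j + 1L] - 1L,
              motif = r$values[k], stringsAsFactors = FALSE)
          }
        }
      }
      offset <- offset + L + 1L  # account for the separator
    }
    out[[i]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), motif = character(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Extract a motif's emission matrix as a PWM
#'
#' @param hmm A `binding_hmm`.
#' @param motif Motif name (default: the first motif).
#' @return Matrix (positions x A,C,G,T) of match-state emissions.
#' @export
motif_pwm <- function(hmm, motif = NULL) {
  motif <- motif %||% names(hmm$motifs)[1L]
  m <- hmm$motifs[[motif]]
  if (is.null(m)) stop("unknown motif: ", motif)
  pwm <- hmm$emis[m$states, , drop = FALSE]
  rownames(pwm) <- seq_len(nrow(pwm))
  pwm
}

#' Serialize a binding-site HMM to JSON
#'
#' Writes topology, transitions, emissions and motif metadata; the model
#' can be restored with [read_hmm_json()].
#'
#' @param hmm A `binding_hmm`.
#' @param path Output file.
#' @export
write_hmm_json <- function(hmm, path) {
  obj <- list(states = hmm$states, trans = hmm$trans, emis = hmm$emis,
              motifs = lapply(hmm$motifs, function(m)
                m[c("name", "seed", "length", "states", "insert_states")]),
              avg_len = hmm$avg_len)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_hmm_json
#' @export
read_hmm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  states <- as.data.frame(obj$states, stringsAsFactors = FALSE)
  to_mat <- function(x, dn) {
    m <- if (is.matrix(x)) x
         else matrix(unlist(x), nrow = length(dn[[1L]]), byrow = TRUE)
    dimnames(m) <- dn
    m
  }
  trans <- to_mat(obj$trans, list(states$name, states$name))
  emis <- to_mat(obj$emis, list(states$name, NUCS))
  motifs <- lapply(obj$motifs, function(m) {
    m$states <- as.integer(m$states)
    m$insert_states <- as.integer(m$insert_states)
    m
  })
  new_binding_hmm(trans, emis, states, motifs, obj$avg_len)
}
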