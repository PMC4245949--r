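# IUPAC degenerate words: each position is a non-empty subset of {A,C,G,T},
# encoded as a bitmask with A=1, C=2, G=4, T=8.

IUPAC_MASKS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L
)
# letter for each mask value 1..15
IUPAC_LETTERS <- character(15L)
IUPAC_LETTERS[IUPAC_MASKS] <- names(IUPAC_MASKS)

#' Construct an IUPAC word
#'
#' An IUPAC word is a degenerate motif: an ordered list of non-empty subsets
#' of `{A,C,G,T}`, one per position, written with the IUPAC nucleotide codes
#' (e.g. `W` = A or T, `N` = any). Its degeneracy is the sum over positions
#' of (number of allowed nucleotides - 1).
#'
#' @param x A string of IUPAC codes (e.g. `"TGTAHATA"`), or an integer
#'   vector of per-position bitmasks (A=1, C=2, G=4, T=8).
#' @return An object of class `iupac_word`.
#' @examples
#' w <- iupac_word("TGTAW")
#' iupac_degeneracy(w)
#' @export
iupac_word <- function(x) {
  if (inherits(x, "iupac_word")) return(x)
  if (is.character(x)) {
    stopifnot(length(x) == 1L, nzchar(x))
    letters <- strsplit(toupper(x), "")[[1]]
    masks <- unname(IUPAC_MASKS[letters])
    if (anyNA(masks))
      stop("not an IUPAC nucleotide code: ",
           paste(unique(letters[is.na(masks)]), collapse = ", "))
  } else {
    masks <- as.integer(x)
    if (length(masks) < 1L || any(masks < 1L) || any(masks > 15L))
      stop("position masks must be integers in 1..15")
  }
  structure(list(masks = as.integer(masks)), class = "iupac_word")
}

#' @export
as.character.iupac_word <- function(x, ...) {
  paste(IUPAC_LETTERS[x$masks], collapse = "")
}

#' @export
print.iupac_word <- function(x, ...) {
  cat("<iupac_word> ", as.character(x),
      " (degeneracy ", iupac_degeneracy(x), ")\n", sep = "")
  invisible(x)
}

#' @export
length.iupac_word <- function(x) length(x$masks)

popcount4 <- function(m) {
  (m %% 2L) + (m %/% 2L %% 2L) + (m %/% 4L %% 2L) + (m %/% 8L %% 2L)
}

#' Degeneracy of an IUPAC word
#'
#' @param w An [iupac_word()] (or string coercible to one).
#' @return Integer: sum over positions of (allowed nucleotides - 1);
#'   0 for a plain A/C/G/T word, `3 * length` for all-N.
#' @export
iupac_degeneracy <- function(w) {
  w <- iupac_word(w)
  sum(popcount4(w$masks) - 1L)
}

#' Single-step generalizations of an IUPAC word
#'
#' Generates all IUPAC words that differ from `w` by allowing exactly one
#' additional nucleotide at exactly one position. A fully degenerate word
#' has no generalizations.
#'
#' @param w An [iupac_word()] (or string coercible to one).
#' @return A list of `iupac_word` objects (possibly empty), ordered by
#'   position and then by added nucleotide.
#' @examples
#' vapply(generalize("ACG"), as.character, "")
#' @export
generalize <- function(w) {
  w <- iupac_word(w)
  out <- list()
  for (p in seq_along(w$masks)) {
    m <- w$masks[p]
    for (bit in c(1L, 2L, 4L, 8L)) {
      if (bitwAnd(m, bit) == 0L) {
        masks <- w$masks
        masks[p] <- bitwOr(m, bit)
        out[[length(out) + 1L]] <- iupac_word(masks)
      }
    }
  }
  out
}

# vectorized string -> bitmask matrix for equal-length IUPAC strings
iupac_mask_matrix_str <- function(words) {
  L <- nchar(words[1L])
  stopifnot(all(nchar(words) == L))
  masks <- IUPAC_MASKS[unlist(strsplit(words, ""), use.names = FALSE)]
  if (anyNA(masks)) stop("not an IUPAC nucleotide code")
  matrix(unname(masks), ncol = L, byrow = TRUE)
}

# IUPAC letter strings for the rows of a bitmask matrix
mask_row_strings <- function(masks) {
  m <- matrix(IUPAC_LETTERS[masks], nrow = nrow(masks))
  do.call(paste0, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

# all single-step generalizations of every row of a bitmask matrix,
# vectorized over rows; returns the generalization masks plus the row index
# of the generating specialization
generalize_all <- function(M) {
  out_masks <- list(); out_parent <- list()
  for (p in seq_len(ncol(M))) {
    for (b in c(1L, 2L, 4L, 8L)) {
      rows <- which(bitwAnd(M[, p], b) == 0L)
      if (length(rows)) {
        Mp <- M[rows, , drop = FALSE]
        Mp[, p] <- bitwOr(Mp[, p], b)
        out_masks[[length(out_masks) + 1L]] <- Mp
        out_parent[[length(out_parent) + 1L]] <- rows
      }
    }
  }
  if (length(out_masks) == 0L)
    return(list(masks = NULL, parent = integer(0)))
  list(masks = do.call(rbind, out_masks), parent = unlist(out_parent))
}

# bitmask matrix (n_words x L) for the C++ scanners
iupac_mask_matrix <- function(words) {
  words <- lapply(words, iupac_word)
  L <- length(words[[1L]]$masks)
  stopifnot(all(vapply(words, function(w) length(w$masks), 0L) == L))
  matrix(unlist(lapply(words, `[[`, "masks")), ncol = L, byrow = TRUE)
}
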