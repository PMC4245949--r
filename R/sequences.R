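# Sequence sets, contrasts, FASTA input and strand transformations.
#
# Sequences are plain uppercase character strings over {A,C,G,T,N}; U is
# mapped to T on input. The double-stranded mode appends "$" and the reverse
# complement; "$" acts as a hard boundary that no motif occurrence and no
# HMM path may span (sequences are split at "$" for inference, and the
# scanners treat it as a never-matching symbol).

#' Construct a sequence set
#'
#' @param seqs Character vector of sequences over `{A,C,G,T,N}` (lowercase
#'   and `U` are normalized; other characters are replaced by `N` with a
#'   warning).
#' @param ids Sequence identifiers; unique within the set. Defaults to
#'   `seq1`, `seq2`, ...
#' @param name Name of the set (the condition label inside a contrast).
#' @return An object of class `sequence_set`.
#' @export
sequence_set <- function(seqs, ids = NULL, name = "set") {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  seqs <- sanitize_residues(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  if (anyDuplicated(ids)) stop("sequence ids must be unique within a set")
  if (any(!nzchar(seqs))) stop("sequences must have length >= 1")
  structure(list(name = name, ids = as.character(ids), seqs = unname(seqs)),
            class = "sequence_set")
}

sanitize_residues <- function(seqs) {
  seqs <- chartr("U", "T", toupper(seqs))
  bad <- grepl("[^ACGTN$]", seqs)
  if (any(bad)) {
    warning(sum(bad), " sequence(s) contained non-ACGTUN characters; ",
            "replaced by N")
    seqs[bad] <- gsub("[^ACGTN$]", "N", seqs[bad])
  }
  seqs
}

#' @export
length.sequence_set <- function(x) length(x$seqs)

#' @export
print.sequence_set <- function(x, ...) {
  cat("<sequence_set> ", x$name, ": ", length(x$seqs), " sequences, ",
      "mean length ", round(mean(nchar(x$seqs)), 1), " nt\n", sep = "")
  invisible(x)
}

#' Read a FASTA file into a sequence set
#'
#' Records are returned in file order; `U` is mapped to `T`, lowercase to
#' uppercase, and any character outside `{A,C,G,T,U,N}` is replaced by `N`
#' with a warning.
#'
#' @param path Path to a FASTA file.
#' @param name Name for the resulting set; defaults to the file name.
#' @return A [sequence_set()].
#' @export
read_fasta <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L)
    stop("FASTA parse error in ", path, ": file is empty")
  if (!startsWith(trimws(lines[nonblank[1L]]), ">"))
    stop("FASTA parse error in ", path, " at line ", nonblank[1L],
         ": expected a '>' header, got: ", lines[nonblank[1L]])
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("FASTA parse error in ", path, ": no records")
  ids <- vapply(strsplit(names(x), "\\s+"), `[`, "", 1L)
  sequence_set(as.character(x), ids = ids,
               name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Reverse complement
#'
#' Standard reverse complement; `N` maps to `N`. Accepts and returns plain
#' character vectors.
#'
#' @param s Character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(s) {
  s <- chartr("ACGTUacgtu", "TGCAATGCAA", s)
  vapply(s, function(x) rawToChar(rev(charToRaw(x))), "", USE.NAMES = FALSE)
}

#' Extend sequences to double-stranded form
#'
#' Concatenates each sequence, the separator `$` and the reverse complement,
#' so motif discovery on the forward strand of the extended sequence covers
#' both strands. No motif occurrence may span the separator.
#'
#' @param s Character vector of sequences (length L each).
#' @return Character vector of extended sequences (length 2L + 1 each).
#' @export
extend_double_stranded <- function(s) {
  paste0(s, "$", reverse_complement(s))
}

# apply strand mode to a sequence_set
apply_strand <- function(set, strand = c("single", "double")) {
  strand <- match.arg(strand)
  if (strand == "double") set$seqs <- extend_double_stranded(set$seqs)
  set
}

#' Mask motif occurrences in a sequence set
#'
#' Every substring matching the IUPAC word (all overlapping matches) is
#' replaced by `N`s. Since an `N` never matches any IUPAC letter, masked
#' regions cannot re-match, making the operation idempotent.
#'
#' @param set A [sequence_set()].
#' @param w An [iupac_word()] or IUPAC string.
#' @param both_strands Also mask matches of the reverse complement pattern
#'   (used by the double-stranded mode).
#' @return The masked [sequence_set()].
#' @export
mask_occurrences <- function(set, w, both_strands = FALSE) {
  words <- list(iupac_word(w))
  if (both_strands) {
    rc <- rc_word(words[[1L]])
    if (as.character(rc) != as.character(words[[1L]]))
      words <- c(words, list(rc))
  }
  for (word in words) {
    len <- length(word$masks)
    hits <- match_positions_c(set$seqs, word$masks)
    for (i in seq_along(set$seqs)) {
      if (length(hits[[i]]) == 0L) next
      ch <- strsplit(set$seqs[i], "")[[1L]]
      for (p in hits[[i]]) ch[(p + 1L):(p + len)] <- "N"
      set$seqs[i] <- paste(ch, collapse = "")
    }
  }
  set
}

# reverse complement of an IUPAC word (bit reversal of masks)
rc_word <- function(w) {
  w <- iupac_word(w)
  comp <- vapply(w$masks, function(m) {
    bitwOr(bitwOr(ifelse(bitwAnd(m, 1L) > 0L, 8L, 0L),
                  ifelse(bitwAnd(m, 2L) > 0L, 4L, 0L)),
           bitwOr(ifelse(bitwAnd(m, 4L) > 0L, 2L, 0L),
                  ifelse(bitwAnd(m, 8L) > 0L, 1L, 0L)))
  }, 0L)
  iupac_word(rev(comp))
}

#' Construct a contrast
#'
#' A contrast is an ordered, named collection of two or more sequence sets
#' (conditions) across which differential motif occurrence is sought, e.g.
#' signal vs. control, rank groups, or repeat experiments. The first listed
#' condition is treated as the signal condition by directional filters.
#'
#' @param ... Two or more [sequence_set()] objects (or one list of them).
#' @param name Name of the contrast.
#' @return An object of class `contrast`.
#' @export
contrast <- function(..., name = "contrast") {
  conds <- list(...)
  if (length(conds) == 1L && !inherits(conds[[1L]], "sequence_set"))
    conds <- conds[[1L]]
  stopifnot(length(conds) >= 2L,
            all(vapply(conds, inherits, TRUE, "sequence_set")))
  nm <- vapply(conds, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("condition names must be unique in a contrast")
  names(conds) <- nm
  structure(list(name = name, conditions = conds), class = "contrast")
}

#' @export
print.contrast <- function(x, ...) {
  cat("<contrast> ", x$name, ": ",
      paste(sprintf("%s (n=%d)", names(x$conditions),
                    vapply(x$conditions, length, 0L)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Construct a collection of contrasts for joint analysis
#'
#' @param ... One or more [contrast()] objects (or one list of them).
#' @return An object of class `contrast_collection`.
#' @export
contrast_collection <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1L]], "contrast")) xs <- xs[[1L]]
  stopifnot(length(xs) >= 1L, all(vapply(xs, inherits, TRUE, "contrast")))
  nm <- vapply(xs, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("contrast names must be unique")
  names(xs) <- nm
  structure(xs, class = "contrast_collection")
}

as_contrast_collection <- function(x) {
  if (inherits(x, "contrast_collection")) return(x)
  if (inherits(x, "contrast")) return(contrast_collection(x))
  stop("expected a contrast or contrast_collection")
}

# flat view of a collection: sets in condition order plus index bookkeeping
collection_layout <- function(cc, strand = "single") {
  cc <- as_contrast_collection(cc)
  sets <- list(); map <- list(); k <- 0L
  for (ct in cc) {
    idx <- integer(0)
    for (cond in ct$conditions) {
      k <- k + 1L
      sets[[k]] <- apply_strand(cond, strand)
      idx <- c(idx, k)
    }
    map[[ct$name]] <- idx
  }
  list(sets = sets, map = map,
       n = vapply(sets, length, 0L),
       seqs = lapply(sets, `[[`, "seqs"))
}
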