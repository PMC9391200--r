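# Dual-end position indexing, position-specific frequency matrices,
# residue-class proportions, and WT-vs-mutant frequency differences.

# The labelled dual-end position set: five N-anchored and four C-anchored.
PC_LABELS <- c("p1", "p2", "p3", "p4", "p5",
               "pOmega", "pOmega-1", "pOmega-2", "pOmega-3")

#' Resolve a dual-end position label to a 0-based index
#'
#' Peptide positions are labelled from both termini: `p1`..`p5` count from
#' the N-terminus, `pOmega`..`pOmega-3` count inward from the C-terminus.
#' For 8-mers `p5` and `pOmega-3` denote the same residue; labels are views,
#' not a partition, so the residue is counted under each label.
#'
#' @param label One of `p1`..`p5`, `pOmega`, `pOmega-1`..`pOmega-3`.
#' @param length Peptide length, 8--13.
#' @return 0-based index into the peptide.
#' @export
resolve_position <- function(label, length) {
  length <- as.integer(length)
  if (any(length < 8L | length > 13L)) {
    stop("peptide length must be in 8..13, got ", paste(length, collapse = ","),
         call. = FALSE)
  }
  if (!label %in% PC_LABELS) {
    stop("unknown position label '", label, "'", call. = FALSE)
  }
  k <- match(label, PC_LABELS)
  if (k <= 5L) {
    rep.int(k - 1L, base::length(length))
  } else {
    length - 1L - (k - 6L)
  }
}

#' Position labels
#' @return Character vector of the nine dual-end labels.
#' @export
position_labels <- function() PC_LABELS

#' Position-specific frequency matrix
#'
#' Counts the residue at each dual-end position label over all peptides of a
#' repertoire. Every peptide contributes exactly one residue to every label,
#' so the per-label denominator equals the repertoire size.
#'
#' @param rep A `pc_repertoire` (or character vector of peptides).
#' @param labels Position labels (default all nine).
#' @return Object of class `pc_freqmat`: `labels`, `counts` (label x residue
#'   integer matrix), `n`, `freq` (counts/n; `NaN` when `n = 0`).
#' @export
frequency_matrix <- function(rep, labels = position_labels()) {
  peptides <- if (inherits(rep, "pc_repertoire")) rep$peptides else
    as.character(rep)
  stopifnot(all(labels %in% PC_LABELS))
  n <- length(peptides)
  counts <- matrix(0L, nrow = length(labels), ncol = 20L,
                   dimnames = list(labels, AA_ALPHABET))
  if (n > 0) {
    len <- nchar(peptides)
    if (any(len < 8L | len > 13L)) {
      stop("all peptides must have length 8..13", call. = FALSE)
    }
    for (lab in labels) {
      idx <- resolve_position(lab, len) + 1L
      res <- substring(peptides, idx, idx)
      tab <- table(factor(res, levels = AA_ALPHABET))
      counts[lab, ] <- as.integer(tab)
    }
  }
  structure(list(labels = labels, counts = counts, n = n,
                 freq = if (n > 0) counts / n else counts * NaN),
            class = "pc_freqmat")
}

#' @export
print.pc_freqmat <- function(x, ...) {
  cat("<pc_freqmat> ", length(x$labels), " labels x 20 residues, n = ",
      x$n, "\n", sep = "")
  invisible(x)
}

#' Residue class
#'
#' A named, non-empty set of residues treated as one feature at a position,
#' e.g. the acidic class \{D, E\} at p4 or the basic class \{K, R\} at p1.
#'
#' @param name Class label.
#' @param members Character vector of canonical residues.
#' @return Object of class `pc_residue_class`.
#' @export
residue_class <- function(name, members) {
  members <- unique(toupper(members))
  if (length(members) == 0 || !all(members %in% AA_ALPHABET)) {
    stop("class members must be a non-empty subset of the 20 residues",
         call. = FALSE)
  }
  structure(list(name = name, members = members), class = "pc_residue_class")
}

#' The acidic D/E class and basic K/R class
#' @rdname residue_class
#' @export
class_DE <- function() residue_class("D/E", c("D", "E"))

#' @rdname residue_class
#' @export
class_KR <- function() residue_class("K/R", c("K", "R"))

#' Class frequency at a position
#'
#' Proportion of peptides whose residue at the given dual-end position
#' belongs to the residue class.
#'
#' @param rep Repertoire or character vector of peptides.
#' @param label Position label.
#' @param cls A [residue_class()].
#' @return List `x` (count), `n` (repertoire size), `proportion` (`NaN` and
#'   `degenerate = TRUE` for an empty repertoire).
#' @export
class_frequency <- function(rep, label, cls) {
  peptides <- if (inherits(rep, "pc_repertoire")) rep$peptides else
    as.character(rep)
  stopifnot(inherits(cls, "pc_residue_class"))
  n <- length(peptides)
  if (n == 0) {
    return(list(x = 0L, n = 0L, proportion = NaN, degenerate = TRUE))
  }
  len <- nchar(peptides)
  idx <- resolve_position(label, len) + 1L
  res <- substring(peptides, idx, idx)
  x <- sum(res %in% cls$members)
  list(x = x, n = n, proportion = x / n, degenerate = FALSE)
}

#' Frequency difference matrix (variant minus reference)
#'
#' Elementwise difference of two position-frequency matrices over identical
#' label sets, as used for mutant-versus-wild-type motif-change heat maps.
#' Per-label rows of the difference sum to zero.
#'
#' @param a,b `pc_freqmat` objects with identical labels.
#' @return Numeric matrix (label x residue) of `freq(a) - freq(b)`.
#' @export
frequency_difference <- function(a, b) {
  stopifnot(inherits(a, "pc_freqmat"), inherits(b, "pc_freqmat"))
  if (!identical(a$labels, b$labels)) {
    stop("frequency matrices have different label sets", call. = FALSE)
  }
  if (a$n == 0 || b$n == 0) {
    stop("frequency difference undefined for an empty repertoire",
         call. = FALSE)
  }
  a$freq - b$freq
}

#' Per-cell two-proportion Z tests for a frequency-difference heat map
#'
#' For each (label, residue) cell, tests equality of the residue proportion
#' between two repertoires with the two-proportion Z test (no continuity
#' correction). No multiplicity correction is applied.
#'
#' @param a,b `pc_freqmat` objects with identical labels.
#' @return List of matrices `z` and `p` (label x residue).
#' @export
frequency_difference_tests <- function(a, b) {
  stopifnot(identical(a$labels, b$labels), a$n > 0, b$n > 0)
  z <- p <- matrix(NA_real_, nrow = length(a$labels), ncol = 20L,
                   dimnames = dimnames(a$counts))
  for (i in seq_along(a$labels)) {
    for (j in seq_len(20L)) {
      t <- two_proportion_z(a$counts[i, j], a$n, b$counts[i, j], b$n)
      z[i, j] <- t$statistic
      p[i, j] <- t$p_value
    }
  }
  list(z = z, p = p)
}

#' Serialize a frequency (or difference) matrix to TSV
#'
#' @param m A `pc_freqmat` or plain label x residue matrix.
#' @param path Output path.
#' @param what For `pc_freqmat`: `"freq"` or `"counts"`.
#' @export
write_matrix_tsv <- function(m, path, what = c("freq", "counts")) {
  what <- match.arg(what)
  mat <- if (inherits(m, "pc_freqmat")) m[[what]] else m
  df <- data.frame(label = rownames(mat),
                   apply(mat, 2, fmt_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
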