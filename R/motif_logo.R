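# Position weight matrices, Kullback-Leibler logo matrices, and motif-based
# allotype assignment of eluted peptides.

#' Build a position weight matrix
#'
#' Log2-odds of pseudocount-regularized positional frequencies over a
#' background composition:
#' `log2((count + pseudocount * q) / (n + pseudocount) / q)`.
#' The default total pseudocount of 1, distributed by background, keeps
#' sparse mutant matrices finite and stable.
#'
#' @param fm A `pc_freqmat` with `n > 0`.
#' @param background A background composition (default
#'   [default_background()]).
#' @param pseudocount Total pseudocount mass, > 0.
#' @return Object of class `pc_pwm`: `labels`, `log_odds` (label x residue).
#' @export
build_pwm <- function(fm, background = default_background(),
                      pseudocount = 1.0) {
  stopifnot(inherits(fm, "pc_freqmat"), pseudocount > 0)
  if (fm$n == 0) stop("cannot build a PWM from an empty repertoire",
                      call. = FALSE)
  background <- validate_background(background)
  q <- matrix(rep(as.numeric(background), each = nrow(fm$counts)),
              nrow = nrow(fm$counts), dimnames = dimnames(fm$counts))
  reg <- (fm$counts + pseudocount * q) / (fm$n + pseudocount)
  structure(list(labels = fm$labels, log_odds = log2(reg / q)),
            class = "pc_pwm")
}

#' @export
print.pc_pwm <- function(x, ...) {
  cat("<pc_pwm> ", length(x$labels), " labels x 20 residues\n", sep = "")
  invisible(x)
}

#' Kullback-Leibler sequence-logo matrix
#'
#' Letter scores are per-residue Kullback-Leibler contributions
#' `p * log2(p/q)` (bits) relative to a background composition, with
#' `0 * log(0) = 0`. Depleted residues receive negative scores and are
#' retained (drawn below the axis by logo tools). The per-position
#' information content is the sum over residues, i.e. the KL divergence of
#' the positional composition from background, and is always >= 0.
#'
#' @param fm A `pc_freqmat` with `n > 0`.
#' @param background Background composition; must be strictly positive at
#'   every residue that occurs.
#' @return Object of class `pc_logo`: `labels`, `letter_score` (label x
#'   residue, bits), `position_ic` (named numeric, bits).
#' @export
kl_logo <- function(fm, background = default_background()) {
  stopifnot(inherits(fm, "pc_freqmat"))
  if (fm$n == 0) stop("cannot build a logo from an empty repertoire",
                      call. = FALSE)
  background <- validate_background(background)
  q <- as.numeric(background)
  p <- fm$freq
  bad <- which(q == 0 & colSums(p) > 0)
  if (length(bad) > 0) {
    stop("background is zero for observed residue(s): ",
         paste(AA_ALPHABET[bad], collapse = ", "), call. = FALSE)
  }
  ls <- p * log2(sweep(p, 2, q, "/"))
  ls[p == 0] <- 0
  ic <- rowSums(ls)
  structure(list(labels = fm$labels, letter_score = ls,
                 position_ic = stats::setNames(ic, fm$labels)),
            class = "pc_logo")
}

#' @export
print.pc_logo <- function(x, ...) {
  cat("<pc_logo> position IC (bits): ",
      paste(names(x$position_ic), fmt_num(x$position_ic), sep = "=",
            collapse = " "), "\n", sep = "")
  invisible(x)
}

# Score every peptide against one PWM: sum of log-odds at each label.
score_peptides_pwm <- function(peptides, pwm) {
  len <- nchar(peptides)
  total <- numeric(length(peptides))
  for (lab in pwm$labels) {
    idx <- resolve_position(lab, len) + 1L
    res <- substring(peptides, idx, idx)
    total <- total + pwm$log_odds[lab, ][match(res, AA_ALPHABET)]
  }
  total
}

#' Motif-based allotype assignment
#'
#' Scores each peptide against every PWM (sum of per-position log-odds) and
#' assigns it to the top-scoring allotype when the margin between the best
#' and second-best score is at least `min_margin` bits; otherwise the
#' peptide is reported as unassigned (ties are never force-assigned).
#' Cell lines co-express endogenous allotypes, so an explicit unassigned
#' pool is part of the contract.
#'
#' @param peptides A `pc_repertoire` or character vector.
#' @param pwms Named list of `pc_pwm` objects (>= 2) sharing a label set.
#' @param min_margin Assignment margin in bits (default 1).
#' @return data.frame: `peptide`, `best`, `second`, `margin`, `assigned`
#'   (the allotype name, or `NA` for unassigned).
#' @export
assign_allotype <- function(peptides, pwms, min_margin = 1.0) {
  pepv <- if (inherits(peptides, "pc_repertoire")) peptides$peptides else
    as.character(peptides)
  stopifnot(length(pwms) >= 2, min_margin >= 0)
  labs <- pwms[[1]]$labels
  for (p in pwms) {
    if (!identical(p$labels, labs)) {
      stop("all PWMs must share one label set", call. = FALSE)
    }
  }
  if (is.null(names(pwms))) {
    stop("pwms must be a named list", call. = FALSE)
  }
  scores <- vapply(pwms, function(p) score_peptides_pwm(pepv, p),
                   numeric(length(pepv)))
  if (length(pepv) == 1L) scores <- matrix(scores, nrow = 1,
                                           dimnames = list(NULL, names(pwms)))
  ord <- t(apply(scores, 1, order, decreasing = TRUE))
  best_i <- ord[, 1]; second_i <- ord[, 2]
  best_s <- scores[cbind(seq_along(pepv), best_i)]
  second_s <- scores[cbind(seq_along(pepv), second_i)]
  margin <- best_s - second_s
  assigned <- ifelse(margin >= min_margin & margin > 0,
                     names(pwms)[best_i], NA_character_)
  data.frame(peptide = pepv, best = names(pwms)[best_i],
             second = names(pwms)[second_i], margin = margin,
             assigned = assigned, stringsAsFactors = FALSE)
}

#' Serialize a logo matrix to TSV
#'
#' Rows are position labels, columns the 20 residues, values letter scores
#' in bits, consumable by standard logo-drawing tools.
#'
#' @param logo A `pc_logo`.
#' @param path Output path.
#' @export
write_logo_tsv <- function(logo, path) {
  write_matrix_tsv(logo$letter_score, path)
}
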