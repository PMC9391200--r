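# Within-repertoire association between residue classes at two positions
# (basic p1 x acidic p4) and cross-allotype correlation of class frequencies.

#' Two-position residue-class contingency table
#'
#' Partitions a repertoire into the four cells of a 2x2 table according to
#' membership of classes at two distinct dual-end positions: `a` = both,
#' `b` = class A only, `c` = class B only, `d` = neither.
#'
#' @param rep Repertoire or character vector of peptides.
#' @param labelA,labelB Distinct position labels.
#' @param clsA,clsB Residue classes ([residue_class()]).
#' @return Object of class `pc_contingency` with integer fields a, b, c, d.
#' @export
contingency <- function(rep, labelA, clsA, labelB, clsB) {
  if (identical(labelA, labelB)) {
    stop("self-association at one position is undefined", call. = FALSE)
  }
  peptides <- if (inherits(rep, "pc_repertoire")) rep$peptides else
    as.character(rep)
  if (length(peptides) == 0) {
    return(structure(list(a = 0L, b = 0L, c = 0L, d = 0L),
                     class = "pc_contingency"))
  }
  len <- nchar(peptides)
  iA <- resolve_position(labelA, len) + 1L
  iB <- resolve_position(labelB, len) + 1L
  inA <- substring(peptides, iA, iA) %in% clsA$members
  inB <- substring(peptides, iB, iB) %in% clsB$members
  structure(list(a = sum(inA & inB), b = sum(inA & !inB),
                 c = sum(!inA & inB), d = sum(!inA & !inB)),
            class = "pc_contingency")
}

#' @export
print.pc_contingency <- function(x, ...) {
  cat("<pc_contingency> a=", x$a, " b=", x$b, " c=", x$c, " d=", x$d,
      " (n=", x$a + x$b + x$c + x$d, ")\n", sep = "")
  invisible(x)
}

#' Association of two residue classes
#'
#' Odds ratio `ad/bc` (Haldane-Anscombe 0.5 correction when any cell is
#' zero, flagged), Wald 95% confidence interval on the log odds ratio, and
#' a p value from the two-proportion Z test comparing P(class B | class A)
#' with P(class B | not class A) -- the same test family used for all
#' proportion comparisons in the pipeline.
#'
#' @param t A `pc_contingency`.
#' @param conf_level Confidence level for the Wald interval.
#' @return A `pc_test` with `estimate` = odds ratio, `ci` = Wald interval.
#' @export
association <- function(t, conf_level = 0.95) {
  stopifnot(inherits(t, "pc_contingency"))
  n <- t$a + t$b + t$c + t$d
  if (n == 0) {
    return(pc_test_result("odds-ratio association", NA_real_, 1,
                          estimate = NA_real_, degenerate = TRUE))
  }
  cells <- c(t$a, t$b, t$c, t$d)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- cells[1] * cells[4] / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(or) + c(-1, 1) * zq * se)
  # conditional proportions: P(B | A) vs P(B | not A)
  zt <- if ((t$a + t$b) >= 1 && (t$c + t$d) >= 1) {
    two_proportion_z(t$a, t$a + t$b, t$c, t$c + t$d)
  } else {
    pc_test_result("two-proportion Z", 0, 1, degenerate = TRUE)
  }
  pc_test_result("odds-ratio association", zt$statistic, zt$p_value,
                 estimate = c(odds_ratio = or), ci = ci,
                 degenerate = corrected || isTRUE(zt$degenerate))
}

#' Cross-allotype correlation of class frequencies
#'
#' Pearson (t-transform p value) and Spearman (rank Pearson with average
#' ranks) correlation between two class frequencies measured across a panel
#' of allotype repertoires, each allotype weighted equally.
#'
#' @param points Two-column matrix or data.frame of (freqA, freqB) per
#'   allotype, >= 3 rows.
#' @return List of two `pc_test` objects, `pearson` and `spearman`, each
#'   with `estimate` = the coefficient.
#' @export
cross_allotype_correlation <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2)
  n <- nrow(points)
  if (n < 3) stop("need >= 3 allotype points", call. = FALSE)
  x <- points[, 1]; y <- points[, 2]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    deg <- pc_test_result("correlation", NA_real_, 1, estimate = NA_real_,
                          degenerate = TRUE)
    return(list(pearson = deg, spearman = deg))
  }
  pear <- function(u, v, method) {
    r <- stats::cor(u, v)
    if (abs(r) >= 1) {
      return(pc_test_result(method, Inf * sign(r), 0, estimate = c(r = r),
                            df = n - 2))
    }
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    pc_test_result(method, tstat, 2 * stats::pt(-abs(tstat), n - 2),
                   estimate = c(r = r), df = n - 2)
  }
  list(pearson = pear(x, y, "Pearson correlation"),
       spearman = pear(rank(x), rank(y), "Spearman correlation"))
}

#' Serialize a contingency/association analysis to TSV
#'
#' @param t A `pc_contingency`.
#' @param assoc Result of [association()] on `t`.
#' @param path Output path.
#' @export
write_association_tsv <- function(t, assoc, path) {
  df <- data.frame(a = t$a, b = t$b, c = t$c, d = t$d,
                   odds_ratio = fmt_num(assoc$estimate[[1]]),
                   ci_low = fmt_num(assoc$ci[1]),
                   ci_high = fmt_num(assoc$ci[2]),
                   z = fmt_num(assoc$statistic),
                   p = fmt_num(assoc$p_value),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
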