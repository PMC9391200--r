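# Grouping of allotypes by binding-cleft residue configurations and
# comparison of grouped ligand class frequencies.

#' Count basic residues at cleft positions 65 and 66
#'
#' Counts arginine/lysine at mature positions 65 and 66 of the alpha-1
#' helix. Histidine is not counted: the charge argument concerns R/K
#' specifically, and His protonation is context-dependent.
#'
#' @param record A `pc_allotype`.
#' @return Integer 0, 1, or 2.
#' @export
basic_count_65_66 <- function(record) {
  res <- cleft_residues(record, c(65L, 66L))
  sum(res %in% c("R", "K"))
}

#' Cleft-residue configuration key
#'
#' Builds a deterministic configuration key from the residues at a set of
#' mature cleft positions (default 62/66/163, the positions flanking the
#' peptide N-terminus), plus derived flags used for grouping: the basic
#' count at 65/66 and presence of R62, K66, R163.
#'
#' @param record A `pc_allotype`.
#' @param positions Mature positions included in the key string.
#' @return Object of class `pc_configuration`: `key` (e.g. "62G/66K/163T"),
#'   `residues`, `basic_count_65_66`, `has_R62`, `has_K66`, `has_R163`.
#' @export
configuration_key <- function(record, positions = c(62L, 66L, 163L)) {
  res <- cleft_residues(record, positions)
  key <- paste0(positions, res, collapse = "/")
  flag <- function(pos, letter) {
    pos <- as.character(pos)
    pos %in% names(res) && res[[pos]] == letter
  }
  all_res <- cleft_residues(record, unique(c(positions, 62L, 65L, 66L, 163L)))
  structure(list(
    key = key,
    residues = res,
    basic_count_65_66 = sum(all_res[c("65", "66")] %in% c("R", "K")),
    has_R62 = identical(all_res[["62"]], "R"),
    has_K66 = identical(all_res[["66"]], "K"),
    has_R163 = identical(all_res[["163"]], "R")
  ), class = "pc_configuration")
}

#' Grouped class frequencies across an allotype panel
#'
#' Computes the class frequency (e.g. acidic p4) for each allotype's
#' repertoire, partitions allotypes into groups by a function of their
#' cleft configuration, and compares group means with the Brown-Forsythe
#' omnibus ANOVA and Dunnett-T3 pairwise tests. Allotypes -- not peptides
#' -- are the replicates.
#'
#' @param reps Named list of repertoires (names = allotype names).
#' @param records Named list of `pc_allotype` records covering every
#'   repertoire name.
#' @param grouping Function mapping a `pc_configuration` to a group label.
#'   Default: the basic count at 65/66 as character.
#' @param label Position label (default "p4").
#' @param cls Residue class (default the acidic D/E class).
#' @return List: `table` (data.frame group/allotype/frequency), `groups`
#'   (named list of frequency vectors), `tests` (omnibus + pairwise, when
#'   >= 3 groups of >= 2; otherwise `NULL` with a message attribute).
#' @export
group_class_frequencies <- function(reps, records,
                                    grouping = NULL,
                                    label = "p4", cls = class_DE()) {
  if (is.null(grouping)) {
    grouping <- function(cfg) as.character(cfg$basic_count_65_66)
  }
  nm <- names(reps)
  missing <- setdiff(nm, names(records))
  if (length(missing) > 0) {
    stop("no allotype record for repertoire(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  freq <- vapply(nm, function(a) class_frequency(reps[[a]], label,
                                                 cls)$proportion,
                 numeric(1))
  grp <- vapply(nm, function(a) grouping(configuration_key(records[[a]])),
                character(1))
  tab <- data.frame(group = grp, allotype = nm, frequency = freq,
                    stringsAsFactors = FALSE, row.names = NULL)
  groups <- split(tab$frequency, tab$group)
  if (length(groups) < 2) {
    stop("grouping produced a single group; omnibus comparison undefined",
         call. = FALSE)
  }
  tests <- if (length(groups) >= 3 &&
               all(vapply(groups, length, integer(1)) >= 2)) {
    group_tests(groups)
  } else {
    NULL
  }
  list(table = tab, groups = groups, tests = tests)
}
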