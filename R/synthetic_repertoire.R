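# Synthetic peptide repertoires with known ground truth: anchored motifs,
# tunable acidic-p4 / basic-p1 class frequencies, p1-p4 coupling by odds
# ratio, WT/mutant pairs with planted shifts, and grouped allotype panels.

#' Default A2-like anchor preferences
#'
#' Position 2 dominated by leucine and the C-terminus by leucine/valine,
#' emulating an HLA-A*02:01-like motif.
#' @return Named list of per-label residue distributions.
#' @export
anchor_prefs_a2 <- function() {
  list(
    p2 = c(L = 0.55, V = 0.15, M = 0.10, I = 0.06, A = 0.06, T = 0.04,
           Q = 0.04),
    pOmega = c(L = 0.42, V = 0.36, I = 0.10, A = 0.06, T = 0.03, M = 0.03)
  )
}

#' Default A24-like anchor preferences
#'
#' Position 2 dominated by tyrosine/phenylalanine and the C-terminus by
#' phenylalanine, emulating an HLA-A*24:02-like motif (Y2/F-Omega dominant
#' anchors).
#' @return Named list of per-label residue distributions.
#' @export
anchor_prefs_a24 <- function() {
  list(
    p2 = c(Y = 0.60, F = 0.25, W = 0.05, M = 0.05, L = 0.05),
    pOmega = c(F = 0.50, L = 0.22, I = 0.15, W = 0.08, M = 0.05)
  )
}

#' Specification for a synthetic repertoire
#'
#' @param n Number of unique peptides to generate.
#' @param length_distribution Named probabilities over lengths 8--13
#'   (default: 9-mer-dominant, as in eluted-ligand data).
#' @param background Background composition used for non-anchor positions.
#' @param anchor_prefs Named list of per-label residue distributions
#'   (default A2-like p2/pOmega).
#' @param p4_DE_freq Target frequency of D/E at p4 (default 0.25, the
#'   elevated acidic-p4 level typical of HLA-A repertoires).
#' @param p1_KR_freq Target frequency of K/R at p1 (default 0.25, the
#'   wild-type A2 level).
#' @param coupling_or Odds ratio linking the K/R1 and D/E4 indicators
#'   (default 1 = independent).
#' @param seed RNG seed.
#' @return Object of class `pc_repertoire_spec`.
#' @export
repertoire_spec <- function(n = 5000L,
                            length_distribution = c(`8` = 0.13, `9` = 0.55,
                                                    `10` = 0.14, `11` = 0.09,
                                                    `12` = 0.05, `13` = 0.04),
                            background = default_background(),
                            anchor_prefs = anchor_prefs_a2(),
                            p4_DE_freq = 0.25,
                            p1_KR_freq = 0.25,
                            coupling_or = 1.0,
                            seed = 1L) {
  stopifnot(n >= 1, abs(sum(length_distribution) - 1) < 1e-9,
            all(names(length_distribution) %in% as.character(8:13)),
            p4_DE_freq >= 0, p4_DE_freq <= 1,
            p1_KR_freq >= 0, p1_KR_freq <= 1,
            coupling_or >= 0)
  background <- validate_background(background)
  for (lab in names(anchor_prefs)) {
    stopifnot(lab %in% PC_LABELS,
              abs(sum(anchor_prefs[[lab]]) - 1) < 1e-9,
              all(names(anchor_prefs[[lab]]) %in% AA_ALPHABET))
  }
  structure(list(n = as.integer(n),
                 length_distribution = length_distribution,
                 background = background, anchor_prefs = anchor_prefs,
                 p4_DE_freq = p4_DE_freq, p1_KR_freq = p1_KR_freq,
                 coupling_or = coupling_or, seed = as.integer(seed)),
            class = "pc_repertoire_spec")
}

#' Solve the 2x2 joint distribution for given margins and odds ratio
#'
#' Finds P(both) for two binary features with margins `pA`, `pB` and odds
#' ratio `or` (exact closed-form solve of the quadratic). Errors when no
#' valid table exists.
#'
#' @param pA,pB Marginal probabilities.
#' @param or Odds ratio (>= 0).
#' @return Numeric vector c(p11, p10, p01, p00).
#' @export
solve_joint_2x2 <- function(pA, pB, or) {
  if (or < 0) stop("odds ratio must be >= 0", call. = FALSE)
  p11 <- if (abs(or - 1) < 1e-12) {
    pA * pB
  } else if (or == 0) {
    if (pA + pB > 1) stop("infeasible margins for odds ratio 0",
                          call. = FALSE)
    0
  } else {
    A <- 1 + (pA + pB) * (or - 1)
    disc <- A^2 - 4 * or * (or - 1) * pA * pB
    if (disc < 0) stop("infeasible margin/odds-ratio combination",
                       call. = FALSE)
    (A - sqrt(disc)) / (2 * (or - 1))
  }
  cell <- c(p11 = p11, p10 = pA - p11, p01 = pB - p11,
            p00 = 1 - pA - pB + p11)
  if (any(cell < -1e-12)) {
    stop("infeasible margin/odds-ratio combination", call. = FALSE)
  }
  pmax(cell, 0)
}

sample_from <- function(k, dist) {
  if (k == 0) return(character(0))
  sample(names(dist), k, replace = TRUE, prob = dist)
}

# Generate k raw peptide sequences from a spec (no dedup), RNG already set.
gen_raw_peptides <- function(spec, k) {
  lens <- as.integer(sample(names(spec$length_distribution), k,
                            replace = TRUE,
                            prob = spec$length_distribution))
  bg <- spec$background
  m <- matrix(sample(AA_ALPHABET, k * 13L, replace = TRUE, prob = bg),
              nrow = k)
  # anchor positions (resolved per peptide length)
  for (lab in names(spec$anchor_prefs)) {
    idx <- resolve_position(lab, lens) + 1L
    m[cbind(seq_len(k), idx)] <- sample_from(k, spec$anchor_prefs[[lab]])
  }
  # joint (K/R at p1) x (D/E at p4) indicator pair
  cell <- solve_joint_2x2(spec$p1_KR_freq, spec$p4_DE_freq,
                          spec$coupling_or)
  cc <- sample(4L, k, replace = TRUE, prob = cell)
  in_kr <- cc %in% c(1L, 2L)
  in_de <- cc %in% c(1L, 3L)
  kr_d <- bg[c("K", "R")] / sum(bg[c("K", "R")])
  non_kr <- bg[setdiff(AA_ALPHABET, c("K", "R"))]
  non_kr <- non_kr / sum(non_kr)
  de_d <- bg[c("D", "E")] / sum(bg[c("D", "E")])
  non_de <- bg[setdiff(AA_ALPHABET, c("D", "E"))]
  non_de <- non_de / sum(non_de)
  m[in_kr, 1L] <- sample_from(sum(in_kr), kr_d)
  m[!in_kr, 1L] <- sample_from(sum(!in_kr), non_kr)
  m[in_de, 4L] <- sample_from(sum(in_de), de_d)
  m[!in_de, 4L] <- sample_from(sum(!in_de), non_de)
  # assemble strings per length
  seqs <- character(k)
  for (L in unique(lens)) {
    rows <- which(lens == L)
    seqs[rows] <- do.call(paste0, asplit(m[rows, seq_len(L), drop = FALSE],
                                         2))
  }
  seqs
}

#' Generate a synthetic peptide repertoire
#'
#' Samples peptides position by position: length from the length
#' distribution, non-anchor positions from the background, anchors from
#' the anchor preference distributions, and the (K/R at p1, D/E at p4)
#' indicator pair jointly from the exact 2x2 distribution with the
#' requested margins and odds ratio. Duplicates are resampled until `n`
#' unique peptides are obtained (cap: 100 n draws). Pure function of
#' (spec, seed).
#'
#' @param spec A [repertoire_spec()].
#' @param name Name of the resulting repertoire.
#' @return List: `repertoire` (a `pc_repertoire` of exactly `n` unique
#'   peptides) and `truth` (the spec echoed with the realized seed).
#' @export
generate_repertoire <- function(spec, name = "synthetic") {
  stopifnot(inherits(spec, "pc_repertoire_spec"))
  with_seed(spec$seed, {
    seqs <- unique(gen_raw_peptides(spec, spec$n))
    drawn <- spec$n
    while (length(seqs) < spec$n) {
      need <- spec$n - length(seqs)
      extra <- gen_raw_peptides(spec, max(need * 2L, 16L))
      drawn <- drawn + length(extra)
      if (drawn > 100L * spec$n) {
        stop("resample cap exceeded while deduplicating; the spec's ",
             "sequence space is too small for n = ", spec$n, call. = FALSE)
      }
      seqs <- unique(c(seqs, extra))
    }
    seqs <- seqs[seq_len(spec$n)]
    list(repertoire = repertoire(seqs, name = name),
         truth = structure(c(unclass(spec), list(realized_seed = spec$seed)),
                           class = "pc_truth"))
  })
}

#' Generate a wild-type / mutant repertoire pair with planted shifts
#'
#' The mutant spec applies additive shifts to the K/R1 and/or D/E4 class
#' frequencies and scales the repertoire size by `size_ratio` (the
#' repertoire-contraction phenotype of cleft mutants). Both repertoires
#' use sub-seeds derived from the base seed. Defaults plant the
#' double-mutant world: D/E4 down 0.10, K/R1 up 0.45 (25% to 70%), and a
#' 70% loss of unique peptides.
#'
#' @param base A [repertoire_spec()] for the wild type.
#' @param shifts Named numeric vector with any of `p4_DE`, `p1_KR`.
#' @param size_ratio Mutant-to-WT repertoire size ratio (> 0).
#' @return List: `wt`, `mut` (repertoires), `truth`.
#' @export
generate_wt_mutant_pair <- function(base,
                                    shifts = c(p4_DE = -0.10,
                                               p1_KR = 0.45),
                                    size_ratio = 0.3) {
  stopifnot(inherits(base, "pc_repertoire_spec"), size_ratio > 0)
  bad <- setdiff(names(shifts), c("p4_DE", "p1_KR"))
  if (length(bad) > 0) stop("unknown shift(s): ", paste(bad, collapse = ","),
                            call. = FALSE)
  mut <- base
  if ("p4_DE" %in% names(shifts)) {
    mut$p4_DE_freq <- base$p4_DE_freq + shifts[["p4_DE"]]
  }
  if ("p1_KR" %in% names(shifts)) {
    mut$p1_KR_freq <- base$p1_KR_freq + shifts[["p1_KR"]]
  }
  if (mut$p4_DE_freq < 0 || mut$p4_DE_freq > 1 ||
      mut$p1_KR_freq < 0 || mut$p1_KR_freq > 1) {
    stop("shifted class frequency outside [0, 1]", call. = FALSE)
  }
  mut$n <- max(1L, as.integer(round(base$n * size_ratio)))
  wt_spec <- base
  wt_spec$seed <- derive_seed(base$seed, 1L)
  mut$seed <- derive_seed(base$seed, 2L)
  wt <- generate_repertoire(wt_spec, name = "WT")
  mu <- generate_repertoire(mut, name = "mutant")
  list(wt = wt$repertoire, mut = mu$repertoire,
       truth = structure(list(base = unclass(base), shifts = shifts,
                              size_ratio = size_ratio,
                              wt_seed = wt_spec$seed, mut_seed = mut$seed),
                         class = "pc_truth"))
}

# scaffold mature HLA heavy-chain-like sequence (length 200), deterministic
synthetic_mature_scaffold <- function() {
  paste(rep("GSHSMRYFETSAVQWLRKDA", 10L), collapse = "")
}

#' Construct a synthetic allotype record with given cleft residues
#'
#' Builds a deterministic mature-length scaffold sequence and patches the
#' requested mature positions, so that panels carry defined residues at
#' the grouping positions (62/65/66/163).
#'
#' @param name Allele-like name.
#' @param cleft Named character vector, names = mature positions.
#' @return A `pc_allotype`.
#' @export
synthetic_allotype <- function(name, cleft) {
  s <- synthetic_mature_scaffold()
  for (pos in names(cleft)) {
    p <- as.integer(pos)
    substr(s, p, p) <- cleft[[pos]]
  }
  allotype_record(name, s, signal_peptide_length = 0L)
}

basic_cleft_for_count <- function(count) {
  switch(as.character(count),
         "2" = c(`62` = "G", `65` = "R", `66` = "K", `163` = "T"),
         "1" = c(`62` = "G", `65` = "G", `66` = "K", `163` = "T"),
         "0" = c(`62` = "G", `65` = "G", `66` = "N", `163` = "T"),
         stop("group label must be '0', '1' or '2' (basic count) ",
              "or supply cleft residues explicitly", call. = FALSE))
}

#' Generate a grouped synthetic allotype panel
#'
#' Each group draws per-allotype D/E4 class frequencies from a truncated
#' normal and generates one repertoire per allotype; synthetic allele
#' sequences carry the group's defining cleft residues at 62/65/66/163.
#' Group labels "0"/"1"/"2" map to the basic-count configurations
#' G65/N66, G65/K66 and R65/K66.
#'
#' @param groups Named list: each element a list with `count` (allotypes),
#'   `mean`, `sd` (class-frequency distribution), and optionally `cleft`
#'   (named residue vector overriding the label-derived configuration).
#' @param peptides_per_allotype Repertoire size per allotype.
#' @param seed RNG seed.
#' @param base_spec Template [repertoire_spec()] for per-allotype
#'   repertoires.
#' @return List: `reps` (named repertoires), `records` (named
#'   `pc_allotype`s), `truth` (planted frequencies per allotype).
#' @export
generate_allotype_panel <- function(groups, peptides_per_allotype = 2000L,
                                    seed = 1L,
                                    base_spec = repertoire_spec()) {
  reps <- list(); records <- list(); planted <- list()
  stream <- 0L
  for (g in names(groups)) {
    spec_g <- groups[[g]]
    if (spec_g$count < 2) {
      warning("group '", g, "' has < 2 allotypes; group tests need >= 2",
              call. = FALSE)
    }
    cleft <- if (!is.null(spec_g$cleft)) spec_g$cleft else
      basic_cleft_for_count(g)
    for (i in seq_len(spec_g$count)) {
      stream <- stream + 1L
      aname <- paste0("SYN-", g, "-", sprintf("%02d", i))
      sd_seed <- derive_seed(seed, stream)
      f <- with_seed(sd_seed, {
        repeat {
          v <- stats::rnorm(1, spec_g$mean, spec_g$sd)
          if (v >= 0 && v <= 1) break
        }
        v
      })
      sp <- base_spec
      sp$n <- as.integer(peptides_per_allotype)
      sp$p4_DE_freq <- f
      sp$seed <- derive_seed(seed, stream + 100000L)
      reps[[aname]] <- generate_repertoire(sp, name = aname)$repertoire
      records[[aname]] <- synthetic_allotype(aname, cleft)
      planted[[aname]] <- list(group = g, p4_DE_freq = f)
    }
  }
  list(reps = reps, records = records,
       truth = structure(list(groups = groups, planted = planted,
                              seed = seed), class = "pc_truth"))
}

#' Write a generated repertoire and its truth record as fixtures
#'
#' @param gen Result of [generate_repertoire()].
#' @param tsv_path Peptide TSV path.
#' @param truth_path Truth JSON path.
#' @export
write_repertoire_fixture <- function(gen, tsv_path, truth_path) {
  df <- data.frame(sequence = gen$repertoire$peptides,
                   allotype = gen$repertoire$name,
                   stringsAsFactors = FALSE)
  utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- unclass(gen$truth)
  truth$background <- as.list(truth$background)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(tsv_path)
}
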