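# Synthetic coordinate ensembles with planted interactions for testing the
# contact-detection and prevalence machinery.

# template residues for planted contacts; partner A goes to chain A,
# partner B to chain P. Geometries satisfy the default criteria with
# >= 0.2 A margin.
plant_template <- function(kind, criteria) {
  ring <- function(center, r = 1.39) {
    ang <- seq(0, 2 * pi, length.out = 7L)[1:6]
    cbind(center[1] + r * cos(ang), center[2] + r * sin(ang), center[3])
  }
  switch(kind,
    salt_bridge = {
      d <- criteria$salt_bridge_cutoff - 0.3
      list(
        A = data.frame(resname = "ARG",
                       atom = c("CZ", "NH1", "NH2", "NE"),
                       element = c("C", "N", "N", "N"),
                       x = c(0, 1.2, -0.6, -0.6), y = c(0, 0, 1.0, -1.0),
                       z = 0, stringsAsFactors = FALSE),
        B = data.frame(resname = "GLU",
                       atom = c("CD", "OE1", "OE2"),
                       element = c("C", "O", "O"),
                       x = c(1.2 + d + 1.0, 1.2 + d, 1.2 + d + 1.0),
                       y = c(-0.8, 0, 0.9), z = 0, stringsAsFactors = FALSE)
      )
    },
    hbond = {
      d <- criteria$hbond_da_cutoff - 0.3
      list(
        A = data.frame(resname = "SER", atom = c("CB", "OG"),
                       element = c("C", "O"),
                       x = c(0, 1.4), y = 0, z = 0,
                       stringsAsFactors = FALSE),
        B = data.frame(resname = "GLY",
                       atom = c("O", "C", "CA", "N"),
                       element = c("O", "C", "C", "N"),
                       x = c(1.4 + d, 1.4 + d + 1.2, 1.4 + d + 2.4,
                             1.4 + d + 3.8),
                       y = c(0, 0.5, 0, 0), z = 0, stringsAsFactors = FALSE)
      )
    },
    pi_cation = {
      d <- criteria$pi_cation_cutoff - 0.5
      rg <- ring(c(0, 0, 0))
      list(
        A = data.frame(resname = "LYS", atom = c("CE", "NZ"),
                       element = c("C", "N"),
                       x = c(0, 0), y = c(0, 0), z = c(d + 1.4, d),
                       stringsAsFactors = FALSE),
        B = data.frame(resname = "PHE",
                       atom = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
                       element = "C",
                       x = rg[, 1], y = rg[, 2], z = rg[, 3],
                       stringsAsFactors = FALSE)
      )
    },
    pi_stack = {
      d <- criteria$pi_stack_cutoff - 1.0
      rg1 <- ring(c(0, 0, 0)); rg2 <- ring(c(0, 0, d))
      list(
        A = data.frame(resname = "PHE",
                       atom = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
                       element = "C",
                       x = rg1[, 1], y = rg1[, 2], z = rg1[, 3],
                       stringsAsFactors = FALSE),
        B = data.frame(resname = "TYR",
                       atom = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
                       element = "C",
                       x = rg2[, 1], y = rg2[, 2], z = rg2[, 3],
                       stringsAsFactors = FALSE)
      )
    },
    stop("unknown plant kind: ", kind, call. = FALSE)
  )
}

DECOY_TYPES <- data.frame(
  resname = c("ARG", "GLU", "LYS", "SER"),
  atom = c("NH1", "OE1", "NZ", "OG"),
  element = c("N", "O", "N", "O"),
  stringsAsFactors = FALSE
)

#' Generate a synthetic conformational ensemble with planted contacts
#'
#' Builds `n_frames` conformations sharing one topology. Each plant is a
#' pair of template residues (chain A / chain P) whose geometry satisfies
#' its interaction criteria with margin; the chain-P partner is displaced
#' far beyond the cutoff in frames where the plant is absent. Decoy atoms
#' of participating types (Arg/Glu/Lys/Ser side-chain atoms) are placed on
#' a 10-A grid, guaranteeing no accidental contact. Per-frame Gaussian
#' jitter of `jitter_sd` A is added to every coordinate; at the default
#' margins, jitter up to ~0.05 A never flips a contact.
#'
#' @param n_frames Number of frames.
#' @param decoy_atoms Number of decoy atoms (split between chains).
#' @param plants List of plants: each a list with `kind` (one of
#'   `salt_bridge`, `hbond`, `pi_cation`, `pi_stack`) and `frames`
#'   (integer vector of frames where the contact is present).
#' @param jitter_sd Gaussian coordinate noise per frame, A (default 0).
#' @param seed RNG seed.
#' @param criteria A [contact_criteria()].
#' @return List: `ensemble` (a `pc_ensemble`), `truth` (plants, with the
#'   chain-A/chain-P residue ids, frames present, and seed).
#' @export
generate_ensemble <- function(n_frames, decoy_atoms = 200L, plants = list(),
                              jitter_sd = 0, seed = 1L,
                              criteria = contact_criteria()) {
  stopifnot(n_frames >= 1)
  rows <- list()
  truth_plants <- list()
  for (i in seq_along(plants)) {
    p <- plants[[i]]
    if (any(p$frames < 1 | p$frames > n_frames)) {
      stop("plant ", i, " lists frames outside 1..", n_frames,
           call. = FALSE)
    }
    tmpl <- plant_template(p$kind, criteria)
    offset <- c(0, 0, 60 * i)  # plants well separated from each other
    for (side in c("A", "B")) {
      df <- tmpl[[side]]
      df$chain <- if (side == "A") "A" else "P"
      df$resnum <- i
      df$icode <- ""
      df$x <- df$x + offset[1]; df$y <- df$y + offset[2]
      df$z <- df$z + offset[3]
      df$plant <- i
      df$movable <- side == "B"
      rows[[length(rows) + 1L]] <- df
    }
    truth_plants[[i]] <- list(kind = p$kind, frames = sort(unique(p$frames)),
                              residueA = paste0("A:", i),
                              residueB = paste0("P:", i))
  }
  if (decoy_atoms > 0) {
    side_len <- ceiling(decoy_atoms^(1 / 2))
    gx <- rep(seq_len(side_len), each = side_len)[seq_len(decoy_atoms)]
    gy <- rep(seq_len(side_len), times = side_len)[seq_len(decoy_atoms)]
    ty <- DECOY_TYPES[(seq_len(decoy_atoms) - 1L) %% nrow(DECOY_TYPES) + 1L, ]
    rows[[length(rows) + 1L]] <- data.frame(
      resname = ty$resname, atom = ty$atom, element = ty$element,
      x = 1000 + 10 * gx, y = 10 * gy, z = 0,
      chain = rep_len(c("A", "P"), decoy_atoms),
      resnum = 1000L + seq_len(decoy_atoms), icode = "",
      plant = NA_integer_, movable = FALSE, stringsAsFactors = FALSE
    )
  }
  base <- do.call(rbind, rows)
  cols <- c("chain", "resnum", "icode", "resname", "atom", "element",
            "x", "y", "z")
  confs <- with_seed(seed, {
    lapply(seq_len(n_frames), function(f) {
      df <- base
      for (i in seq_along(plants)) {
        if (!f %in% plants[[i]]$frames) {
          mv <- which(df$plant == i & df$movable)
          df$x[mv] <- df$x[mv] + 500  # far beyond every cutoff
        }
      }
      if (jitter_sd > 0) {
        df$x <- df$x + stats::rnorm(nrow(df), 0, jitter_sd)
        df$y <- df$y + stats::rnorm(nrow(df), 0, jitter_sd)
        df$z <- df$z + stats::rnorm(nrow(df), 0, jitter_sd)
      }
      conformation(df[cols])
    })
  })
  list(ensemble = ensemble(confs),
       truth = structure(list(plants = truth_plants, n_frames = n_frames,
                              decoy_atoms = decoy_atoms,
                              jitter_sd = jitter_sd, seed = seed),
                         class = "pc_truth"))
}
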