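# Independent oracles and small fixture builders shared across tests.
# These re-derive expected values from first principles and must stay
# independent of the package code paths they check.

# peptide sequences used in the published structures; handy hand-countable
# fixtures
PEP_A2 <- "GLKEGIPAL"   # E4, L2/L-Omega
PEP_A24 <- "QFKDNVILL"  # D4, F2/L-Omega
PEP_A24B <- "VYGFVRACL" # F4

# --- quaternion-method rigid superposition oracle (Horn 1987) ---------------
quaternion_rmsd <- function(P, Q) {
  # P = mobile, Q = reference, both n x 3; returns minimal RMSD
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  M <- t(P0) %*% Q0
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(P0^2) + sum(Q0^2) - 2 * lam) / nrow(P)
  sqrt(max(0, msd))
}

# --- brute-force all-pairs contact oracle -----------------------------------
# re-derives the geometric criteria directly from the atom table
oracle_contacts <- function(conf, criteria, chainA = "A", chainB = "P") {
  df <- as.data.frame(conf)
  d3 <- function(i, j) {
    sqrt((df$x[i] - df$x[j])^2 + (df$y[i] - df$y[j])^2 +
           (df$z[i] - df$z[j])^2)
  }
  rid <- paste0(df$chain, ":", df$resnum, df$icode)
  out <- list()
  add <- function(kind, i, j) {
    out[[length(out) + 1L]] <<- paste(kind, rid[i], rid[j], sep = "|")
  }
  basic <- (df$resname == "ARG" & df$atom %in% c("NH1", "NH2", "NE")) |
    (df$resname == "LYS" & df$atom == "NZ")
  acid <- (df$resname == "ASP" & df$atom %in% c("OD1", "OD2")) |
    (df$resname == "GLU" & df$atom %in% c("OE1", "OE2"))
  donor <- (df$resname == "ARG" & df$atom %in% c("NE", "NH1", "NH2")) |
    (df$resname == "LYS" & df$atom == "NZ") |
    (df$resname == "HIS" & df$atom %in% c("ND1", "NE2")) |
    (df$resname == "SER" & df$atom == "OG") |
    (df$resname == "THR" & df$atom == "OG1") |
    (df$resname == "TYR" & df$atom == "OH") |
    (df$resname == "ASN" & df$atom == "ND2") |
    (df$resname == "GLN" & df$atom == "NE2") |
    (df$resname == "TRP" & df$atom == "NE1") |
    df$atom == "N"
  accept <- (df$resname == "ASP" & df$atom %in% c("OD1", "OD2")) |
    (df$resname == "GLU" & df$atom %in% c("OE1", "OE2")) |
    (df$resname == "ASN" & df$atom == "OD1") |
    (df$resname == "GLN" & df$atom == "OE1") |
    (df$resname == "SER" & df$atom == "OG") |
    (df$resname == "THR" & df$atom == "OG1") |
    (df$resname == "TYR" & df$atom == "OH") |
    (df$resname == "HIS" & df$atom %in% c("ND1", "NE2")) |
    df$atom == "O"
  inA <- df$chain == chainA
  inB <- df$chain == chainB
  idxA <- which(inA); idxB <- which(inB)
  # all-pairs distance matrix (brute force, vectorized for test runtime)
  A <- cbind(df$x[idxA], df$y[idxA], df$z[idxA])
  B <- cbind(df$x[idxB], df$y[idxB], df$z[idxB])
  D <- sqrt(pmax(0, outer(rowSums(A^2), rowSums(B^2), "+") -
                   2 * A %*% t(B)))
  sb <- which(D <= criteria$salt_bridge_cutoff &
                (outer(basic[idxA], acid[idxB], "&") |
                   outer(acid[idxA], basic[idxB], "&")), arr.ind = TRUE)
  for (h in seq_len(nrow(sb))) {
    add("salt_bridge", idxA[sb[h, 1]], idxB[sb[h, 2]])
  }
  # synthetic fixtures carry no explicit hydrogens -> no angle test
  hb <- which(D <= criteria$hbond_da_cutoff &
                (outer(donor[idxA], accept[idxB], "&") |
                   outer(accept[idxA], donor[idxB], "&")), arr.ind = TRUE)
  for (h in seq_len(nrow(hb))) {
    add("hbond", idxA[hb[h, 1]], idxB[hb[h, 2]])
  }
  # group centroids
  cent <- function(rows) c(mean(df$x[rows]), mean(df$y[rows]),
                           mean(df$z[rows]))
  rings <- list(); cations <- list()
  for (u in unique(rid)) {
    rows <- which(rid == u)
    rn <- df$resname[rows[1]]
    ring_atoms <- switch(rn,
                         PHE = , TYR = c("CG", "CD1", "CD2", "CE1", "CE2",
                                         "CZ"),
                         TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
                         NULL)
    if (!is.null(ring_atoms)) {
      rr <- rows[df$atom[rows] %in% ring_atoms]
      if (length(rr) == 6) {
        rings[[u]] <- list(chain = df$chain[rows[1]], xyz = cent(rr))
      }
    }
    if (rn == "LYS") {
      nz <- rows[df$atom[rows] == "NZ"]
      if (length(nz) == 1) {
        cations[[u]] <- list(chain = df$chain[rows[1]],
                             xyz = c(df$x[nz], df$y[nz], df$z[nz]))
      }
    }
    if (rn == "ARG") {
      gg <- rows[df$atom[rows] %in% c("CZ", "NE", "NH1", "NH2")]
      if (length(gg) == 4) {
        cations[[u]] <- list(chain = df$chain[rows[1]], xyz = cent(gg))
      }
    }
  }
  dd <- function(a, b) sqrt(sum((a - b)^2))
  for (cu in names(cations)) {
    for (ru in names(rings)) {
      if (cations[[cu]]$chain == rings[[ru]]$chain) next
      if (!((cations[[cu]]$chain == chainA && rings[[ru]]$chain == chainB) ||
            (cations[[cu]]$chain == chainB && rings[[ru]]$chain == chainA)))
        next
      if (dd(cations[[cu]]$xyz, rings[[ru]]$xyz) <=
          criteria$pi_cation_cutoff) {
        out[[length(out) + 1L]] <- paste("pi_cation", cu, ru, sep = "|")
      }
    }
  }
  rn_ <- names(rings)
  for (u in rn_) {
    for (v in rn_) {
      if (rings[[u]]$chain == chainA && rings[[v]]$chain == chainB &&
          dd(rings[[u]]$xyz, rings[[v]]$xyz) <= criteria$pi_stack_cutoff) {
        out[[length(out) + 1L]] <- paste("pi_stack", u, v, sep = "|")
      }
    }
  }
  sort(unique(unlist(out)))
}

# normalize package contact output to the oracle's identity strings,
# with both orientations mapped to (chain A residue, chain P residue)
contact_ids <- function(ct) {
  if (nrow(ct) == 0) return(character(0))
  a_first <- startsWith(ct$residueA, "A")
  ra <- ifelse(a_first, ct$residueA, ct$residueB)
  rb <- ifelse(a_first, ct$residueB, ct$residueA)
  sort(unique(paste(ct$kind, ra, rb, sep = "|")))
}

# random rigid motion applied to a conformation
apply_rigid <- function(conf, angle, axis, shift) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  xyz <- as.matrix(as.data.frame(conf)[, c("x", "y", "z")]) %*% t(R)
  df <- as.data.frame(conf)
  df$x <- xyz[, 1] + shift[1]
  df$y <- xyz[, 2] + shift[2]
  df$z <- xyz[, 3] + shift[3]
  conformation(df)
}

# write a small peptide TSV and return its path
write_peptide_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

bundled_alleles <- function() {
  system.file("extdata", "hla_alleles_synthetic.fasta",
              package = "pepcleft")
}
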