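# Interaction detection (salt bridges, hydrogen bonds, pi-cation,
# pi-stacking), contact prevalence across conformational ensembles,
# pairwise coulombic energies, Kabsch superposition/RMSD, and distance
# metrics.

# Side-chain atom roles. Numeric criteria follow common structural-biology
# practice; all cutoffs are configurable through contact_criteria().
SB_BASIC <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ")
SB_BASIC_HIS <- list(HIS = c("ND1", "NE2"))
SB_ACID <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

HB_DONOR <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2", GLN = "NE2",
  TRP = "NE1"
)
HB_ACCEPT <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2")
)
BACKBONE_DONOR <- "N"    # amide nitrogen of every residue
BACKBONE_ACCEPT <- "O"   # carbonyl oxygen of every residue

RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")
)
ARG_GUANIDINIUM <- c("CZ", "NE", "NH1", "NH2")

#' Interaction criteria
#'
#' Distance (and hydrogen-bond angle) criteria for contact detection.
#' The published analyses used an external contact tool whose thresholds
#' are not stated; these defaults follow common practice and every value
#' is configurable and recorded in output provenance.
#'
#' @param salt_bridge_cutoff Basic N to acidic O distance, A (default 4.0).
#' @param hbond_da_cutoff Donor-acceptor heavy-atom distance, A (default
#'   3.5).
#' @param hbond_angle_min D-H...A angle in degrees, applied only when an
#'   explicit hydrogen is present (default 120).
#' @param pi_cation_cutoff Cation to ring-centroid distance, A (default
#'   6.0).
#' @param pi_stack_cutoff Ring centroid-centroid distance, A (default 5.5).
#' @param his_charged Treat histidine as protonated/basic (default FALSE).
#' @return Object of class `pc_contact_criteria`.
#' @export
contact_criteria <- function(salt_bridge_cutoff = 4.0,
                             hbond_da_cutoff = 3.5,
                             hbond_angle_min = 120,
                             pi_cation_cutoff = 6.0,
                             pi_stack_cutoff = 5.5,
                             his_charged = FALSE) {
  vals <- c(salt_bridge_cutoff, hbond_da_cutoff, pi_cation_cutoff,
            pi_stack_cutoff)
  if (any(vals <= 0)) stop("all cutoffs must be > 0", call. = FALSE)
  structure(list(salt_bridge_cutoff = salt_bridge_cutoff,
                 hbond_da_cutoff = hbond_da_cutoff,
                 hbond_angle_min = hbond_angle_min,
                 pi_cation_cutoff = pi_cation_cutoff,
                 pi_stack_cutoff = pi_stack_cutoff,
                 his_charged = his_charged),
            class = "pc_contact_criteria")
}

coords_of <- function(conf, idx) {
  cbind(conf$x[idx], conf$y[idx], conf$z[idx])
}

dist_pair <- function(a, b) sqrt(sum((a - b)^2))

# rows of conf matching a (resname -> atom names) role table
role_rows <- function(conf, idx, roles) {
  keep <- logical(length(idx))
  for (rn in names(roles)) {
    keep <- keep | (conf$resname[idx] == rn & conf$atom[idx] %in% roles[[rn]])
  }
  idx[keep]
}

# group descriptors (centroids) per residue for ring / guanidinium groups
group_centroids <- function(conf, idx, atom_table) {
  out <- list()
  rid <- residue_ids(conf, idx)
  for (u in unique(rid)) {
    rows <- idx[rid == u]
    rn <- conf$resname[rows[1]]
    if (!rn %in% names(atom_table)) next
    want <- atom_table[[rn]]
    rows <- rows[conf$atom[rows] %in% want]
    if (length(rows) == length(want)) {
      out[[u]] <- list(residue = u, resname = rn,
                       xyz = colMeans(coords_of(conf, rows)))
    }
  }
  out
}

# explicit hydrogens bonded to a donor heavy atom (within 1.3 A, same residue)
donor_hydrogens <- function(conf, donor_row) {
  same <- which(conf$chain == conf$chain[donor_row] &
                  conf$resnum == conf$resnum[donor_row] &
                  conf$icode == conf$icode[donor_row] &
                  toupper(conf$element) == "H")
  if (length(same) == 0) return(integer(0))
  d <- sqrt((conf$x[same] - conf$x[donor_row])^2 +
              (conf$y[same] - conf$y[donor_row])^2 +
              (conf$z[same] - conf$z[donor_row])^2)
  same[d <= 1.3]
}

contact_row <- function(kind, conf, i, j, distance, frame,
                        atomA = NULL, atomB = NULL,
                        residueA = NULL, residueB = NULL) {
  data.frame(
    kind = kind,
    residueA = if (is.null(residueA)) residue_ids(conf, i) else residueA,
    residueB = if (is.null(residueB)) residue_ids(conf, j) else residueB,
    atomA = if (is.null(atomA)) conf$atom[i] else atomA,
    atomB = if (is.null(atomB)) conf$atom[j] else atomB,
    distance = distance, frame = frame, stringsAsFactors = FALSE
  )
}

#' Detect contacts between two selections of a conformation
#'
#' Finds salt bridges (basic side-chain N of Arg/Lys vs acidic side-chain O
#' of Asp/Glu), hydrogen bonds (donor-acceptor heavy atoms, with a D-H...A
#' angle check only when explicit hydrogens exist), pi-cation contacts
#' (Lys NZ or Arg guanidinium centroid vs Phe/Tyr/Trp ring centroid) and
#' pi-stacking contacts (ring centroid pairs), between two disjoint atom
#' selections. Each qualifying atom (or centroid) pair is reported once per
#' kind. Histidine participates as a cation only when
#' `criteria$his_charged` is set.
#'
#' @param conf A `pc_conformation`.
#' @param criteria A [contact_criteria()].
#' @param selA,selB Residue selections (see [select_atoms()]); must be
#'   non-empty and disjoint.
#' @param frame Frame index recorded in the output (default 1).
#' @return data.frame: kind, residueA, residueB, atomA, atomB, distance,
#'   frame. Zero rows when no contact qualifies.
#' @export
detect_contacts <- function(conf, criteria = contact_criteria(),
                            selA, selB, frame = 1L) {
  ia <- select_atoms(conf, selA)
  ib <- select_atoms(conf, selB)
  if (length(intersect(ia, ib)) > 0) {
    stop("selections must be disjoint", call. = FALSE)
  }
  out <- list()

  basic_tab <- SB_BASIC
  if (isTRUE(criteria$his_charged)) basic_tab <- c(basic_tab, SB_BASIC_HIS)

  cross_dist <- function(ra, rb) {
    # ra x rb distance matrix
    A <- coords_of(conf, ra); B <- coords_of(conf, rb)
    outer(seq_along(ra), seq_along(rb), Vectorize(function(p, q) {
      sqrt(sum((A[p, ] - B[q, ])^2))
    }))
  }

  emit_pairs <- function(kind, ra, rb, cutoff, flip = FALSE) {
    if (length(ra) == 0 || length(rb) == 0) return()
    D <- cross_dist(ra, rb)
    hit <- which(D <= cutoff, arr.ind = TRUE)
    for (h in seq_len(nrow(hit))) {
      i <- ra[hit[h, 1]]; j <- rb[hit[h, 2]]
      # residueA is always reported from selA, residueB from selB
      out[[length(out) + 1L]] <<- if (flip) {
        contact_row(kind, conf, j, i, D[hit[h, 1], hit[h, 2]], frame)
      } else {
        contact_row(kind, conf, i, j, D[hit[h, 1], hit[h, 2]], frame)
      }
    }
  }

  # salt bridges: both orientations (basic in A vs acid in B and vice versa)
  emit_pairs("salt_bridge", role_rows(conf, ia, basic_tab),
             role_rows(conf, ib, SB_ACID), criteria$salt_bridge_cutoff)
  emit_pairs("salt_bridge", role_rows(conf, ib, basic_tab),
             role_rows(conf, ia, SB_ACID), criteria$salt_bridge_cutoff,
             flip = TRUE)

  # hydrogen bonds (donor in one selection, acceptor in the other)
  donors_of <- function(idx) {
    union(role_rows(conf, idx, HB_DONOR),
          idx[conf$atom[idx] == BACKBONE_DONOR])
  }
  accept_of <- function(idx) {
    union(role_rows(conf, idx, HB_ACCEPT),
          idx[conf$atom[idx] == BACKBONE_ACCEPT])
  }
  hb_check <- function(dn, ac, flipAB) {
    for (i in dn) {
      for (j in ac) {
        d <- dist_pair(coords_of(conf, i)[1, ], coords_of(conf, j)[1, ])
        if (d > criteria$hbond_da_cutoff) next
        hyd <- donor_hydrogens(conf, i)
        if (length(hyd) > 0) {
          angles <- vapply(hyd, function(h) {
            v1 <- coords_of(conf, i)[1, ] - coords_of(conf, h)[1, ]
            v2 <- coords_of(conf, j)[1, ] - coords_of(conf, h)[1, ]
            ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                       (sqrt(sum(v1^2)) * sqrt(sum(v2^2))))))
            ang * 180 / pi
          }, numeric(1))
          if (max(angles) < criteria$hbond_angle_min) next
        }
        if (flipAB) {
          out[[length(out) + 1L]] <<- contact_row("hbond", conf, j, i, d,
                                                  frame)
        } else {
          out[[length(out) + 1L]] <<- contact_row("hbond", conf, i, j, d,
                                                  frame)
        }
      }
    }
  }
  hb_check(donors_of(ia), accept_of(ib), flipAB = FALSE)
  hb_check(donors_of(ib), accept_of(ia), flipAB = TRUE)

  # pi-cation and pi-stacking via group centroids
  cations_of <- function(idx) {
    pts <- list()
    lys <- idx[conf$resname[idx] == "LYS" & conf$atom[idx] == "NZ"]
    for (r in lys) {
      pts[[length(pts) + 1L]] <- list(residue = residue_ids(conf, r),
                                      label = "NZ",
                                      xyz = coords_of(conf, r)[1, ])
    }
    gua <- group_centroids(conf, idx,
                           list(ARG = ARG_GUANIDINIUM))
    for (g in gua) {
      pts[[length(pts) + 1L]] <- list(residue = g$residue,
                                      label = "guanidinium",
                                      xyz = g$xyz)
    }
    if (isTRUE(criteria$his_charged)) {
      his <- group_centroids(conf, idx,
                             list(HIS = c("CG", "ND1", "CD2", "CE1", "NE2")))
      for (g in his) {
        pts[[length(pts) + 1L]] <- list(residue = g$residue,
                                        label = "imidazolium", xyz = g$xyz)
      }
    }
    pts
  }
  rings_a <- group_centroids(conf, ia, RING_ATOMS)
  rings_b <- group_centroids(conf, ib, RING_ATOMS)
  pi_cat <- function(cats, rings, flipAB) {
    for (ct in cats) {
      for (rg in rings) {
        d <- dist_pair(ct$xyz, rg$xyz)
        if (d <= criteria$pi_cation_cutoff) {
          if (flipAB) {
            out[[length(out) + 1L]] <<- contact_row(
              "pi_cation", conf, NA, NA, d, frame,
              atomA = "ring", atomB = ct$label,
              residueA = rg$residue, residueB = ct$residue)
          } else {
            out[[length(out) + 1L]] <<- contact_row(
              "pi_cation", conf, NA, NA, d, frame,
              atomA = ct$label, atomB = "ring",
              residueA = ct$residue, residueB = rg$residue)
          }
        }
      }
    }
  }
  pi_cat(cations_of(ia), rings_b, flipAB = FALSE)
  pi_cat(cations_of(ib), rings_a, flipAB = TRUE)
  for (ra in rings_a) {
    for (rb in rings_b) {
      d <- dist_pair(ra$xyz, rb$xyz)
      if (d <= criteria$pi_stack_cutoff) {
        out[[length(out) + 1L]] <- contact_row(
          "pi_stack", conf, NA, NA, d, frame,
          atomA = "ring", atomB = "ring",
          residueA = ra$residue, residueB = rb$residue)
      }
    }
  }

  if (length(out) == 0) {
    return(data.frame(kind = character(0), residueA = character(0),
                      residueB = character(0), atomA = character(0),
                      atomB = character(0), distance = numeric(0),
                      frame = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Contact prevalence across an ensemble
#'
#' For each contact identity (kind + residue pair), the fraction of frames
#' in which at least one qualifying atom pair exists.
#'
#' @param ens A `pc_ensemble`.
#' @param criteria A [contact_criteria()].
#' @param selA,selB Selections as in [detect_contacts()].
#' @return data.frame: kind, residueA, residueB, n_frames, prevalence.
#' @export
contact_prevalence <- function(ens, criteria = contact_criteria(),
                               selA, selB) {
  nf <- length(ens$conformations)
  ids <- list()
  for (f in seq_len(nf)) {
    ct <- detect_contacts(ens$conformations[[f]], criteria, selA, selB,
                          frame = f)
    if (nrow(ct) == 0) next
    key <- unique(paste(ct$kind, ct$residueA, ct$residueB, sep = "\t"))
    for (k in key) ids[[k]] <- c(ids[[k]], f)
  }
  if (length(ids) == 0) {
    return(data.frame(kind = character(0), residueA = character(0),
                      residueB = character(0), n_frames = integer(0),
                      prevalence = numeric(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(names(ids), "\t", fixed = TRUE)
  data.frame(
    kind = vapply(parts, `[`, character(1), 1),
    residueA = vapply(parts, `[`, character(1), 2),
    residueB = vapply(parts, `[`, character(1), 3),
    n_frames = vapply(ids, function(v) length(unique(v)), integer(1)),
    prevalence = vapply(ids, function(v) length(unique(v)) / nf, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Charge set for coulombic pair energies
#'
#' The default charge set places unit formal charges on one representative
#' atom of each charged side-chain group (Arg CZ +1, Lys NZ +1, Asp CG -1,
#' Glu CD -1); all other atoms carry zero charge by design
#' (`complete = FALSE`). A full per-atom table may be supplied with
#' `complete = TRUE`, in which case atoms without an entry trigger the
#' `on_missing` policy.
#'
#' @param charges Named numeric vector, names `"RESNAME:ATOM"`.
#' @param dielectric Relative dielectric constant (> 0, default 1).
#' @param complete Whether the table is meant to cover every atom.
#' @param on_missing `"skip"` (warn once) or `"error"` for uncovered atoms
#'   when `complete = TRUE`.
#' @return Object of class `pc_charge_set`; the coulomb constant is
#'   332.0636 kcal A / (mol e^2).
#' @export
charge_set <- function(charges = c("ARG:CZ" = 1, "LYS:NZ" = 1,
                                   "ASP:CG" = -1, "GLU:CD" = -1),
                       dielectric = 1, complete = FALSE,
                       on_missing = c("skip", "error")) {
  stopifnot(dielectric > 0, all(is.finite(charges)))
  structure(list(charges = charges, dielectric = dielectric,
                 complete = complete, on_missing = match.arg(on_missing),
                 k = 332.0636),
            class = "pc_charge_set")
}

#' Coulombic interaction energy of two residues
#'
#' `E = (k / dielectric) * sum_{i in A, j in B} q_i q_j / r_ij` in
#' kcal/mol; negative values are attractive.
#'
#' @param conf A `pc_conformation`.
#' @param resA,resB Residue specs (`"chain:resnum"`), distinct residues.
#' @param charges A [charge_set()].
#' @return Energy in kcal/mol.
#' @export
coulomb_pair <- function(conf, resA, resB, charges = charge_set()) {
  stopifnot(inherits(charges, "pc_charge_set"))
  ia <- select_atoms(conf, resA)
  ib <- select_atoms(conf, resB)
  if (length(intersect(ia, ib)) > 0) {
    stop("resA and resB must be distinct residues", call. = FALSE)
  }
  qa <- atom_charges(conf, ia, charges)
  qb <- atom_charges(conf, ib, charges)
  A <- coords_of(conf, ia); B <- coords_of(conf, ib)
  e <- 0
  for (p in seq_along(ia)) {
    if (qa[p] == 0) next
    for (q in seq_along(ib)) {
      if (qb[q] == 0) next
      r <- dist_pair(A[p, ], B[q, ])
      if (r == 0) stop("coincident atoms (r = 0) between residues",
                       call. = FALSE)
      e <- e + qa[p] * qb[q] / r
    }
  }
  charges$k / charges$dielectric * e
}

atom_charges <- function(conf, idx, charges) {
  key <- paste0(conf$resname[idx], ":", conf$atom[idx])
  q <- unname(charges$charges[key])
  miss <- is.na(q)
  if (any(miss) && isTRUE(charges$complete)) {
    msg <- paste0("atoms without charge entries: ",
                  paste(utils::head(unique(key[miss]), 5), collapse = ", "))
    if (charges$on_missing == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  q[miss] <- 0
  q
}

#' Kabsch least-squares superposition
#'
#' Rigid-body superposition of `mobile` onto `ref` over a matched atom
#' selection, with the proper-rotation (det = +1) correction. Returns the
#' rotation, translation and fitted RMSD.
#'
#' @param ref,mobile `pc_conformation` objects.
#' @param selection Residue selection applied to both (atoms matched by
#'   chain/residue/atom name); >= 3 non-collinear atoms.
#' @param atoms Optional atom-name restriction.
#' @return List: `rotation` (3x3), `translation` (length 3; the transform
#'   is `x %*% R + t`), `rmsd` (over the selection after fitting).
#' @export
superpose <- function(ref, mobile, selection = unique(ref$chain),
                      atoms = NULL) {
  ir <- select_atoms(ref, selection, atoms)
  im <- select_atoms(mobile, selection, atoms)
  idr <- paste(ref$chain[ir], ref$resnum[ir], ref$icode[ir], ref$atom[ir])
  idm <- paste(mobile$chain[im], mobile$resnum[im], mobile$icode[im],
               mobile$atom[im])
  common <- intersect(idr, idm)
  if (length(common) < 3) {
    stop("selection must match >= 3 atoms in both conformations",
         call. = FALSE)
  }
  P <- coords_of(mobile, im[match(common, idm)])  # mobile
  Q <- coords_of(ref, ir[match(common, idr)])     # reference
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  if (qr(P0)$rank < 2 || qr(Q0)$rank < 2) {
    stop("degenerate (collinear) selection", call. = FALSE)
  }
  H <- t(P0) %*% Q0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  Dm <- diag(c(1, 1, d))
  R <- sv$u %*% Dm %*% t(sv$v)  # x %*% R maps mobile frame to ref frame
  t_vec <- qc - pc %*% R
  fitted <- P %*% R + matrix(t_vec, nrow(P), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = as.numeric(t_vec), rmsd = rmsd)
}

apply_transform <- function(xyz, fit) {
  xyz %*% fit$rotation + matrix(fit$translation, nrow(xyz), 3, byrow = TRUE)
}

#' Per-frame RMSD of a target residue after cleft superposition
#'
#' Superposes each frame of an ensemble onto a reference via a fit
#' selection (e.g. the cleft backbone), then computes the RMSD over the
#' target residue's atoms without refitting -- the measure used to compare
#' side-chain mobility across variants.
#'
#' @param ens A `pc_ensemble`.
#' @param fit_selection Residue selection used for the superposition.
#' @param target_residue Residue spec whose atoms are measured.
#' @param reference Frame index (default 1) or an external
#'   `pc_conformation`.
#' @param fit_atoms Optional atom-name restriction for the fit (e.g.
#'   backbone `c("N","CA","C","O")`).
#' @return Numeric vector of per-frame RMSDs (A).
#' @export
residue_rmsd <- function(ens, fit_selection, target_residue, reference = 1L,
                         fit_atoms = NULL) {
  ref <- if (inherits(reference, "pc_conformation")) reference else
    ens$conformations[[reference]]
  it_ref <- select_atoms(ref, target_residue)
  id_ref <- paste(ref$chain[it_ref], ref$resnum[it_ref], ref$icode[it_ref],
                  ref$atom[it_ref])
  vapply(ens$conformations, function(conf) {
    fit <- superpose(ref, conf, fit_selection, atoms = fit_atoms)
    it <- select_atoms(conf, target_residue)
    id <- paste(conf$chain[it], conf$resnum[it], conf$icode[it],
                conf$atom[it])
    common <- intersect(id_ref, id)
    A <- apply_transform(coords_of(conf, it[match(common, id)]), fit)
    B <- coords_of(ref, it_ref[match(common, id_ref)])
    sqrt(mean(rowSums((A - B)^2)))
  }, numeric(1))
}

#' Minimum distance between two selections
#'
#' @param conf A `pc_conformation`.
#' @param selA,selB Non-overlapping residue selections.
#' @return List: `distance` (A), `atomA`, `atomB` (deterministic tie-break
#'   by atom order).
#' @export
min_distance <- function(conf, selA, selB) {
  ia <- select_atoms(conf, selA)
  ib <- select_atoms(conf, selB)
  if (length(intersect(ia, ib)) > 0) {
    stop("selections must not overlap", call. = FALSE)
  }
  A <- coords_of(conf, ia); B <- coords_of(conf, ib)
  best <- Inf; bi <- bj <- NA_integer_
  for (p in seq_along(ia)) {
    d2 <- (B[, 1] - A[p, 1])^2 + (B[, 2] - A[p, 2])^2 + (B[, 3] - A[p, 3])^2
    q <- which.min(d2)
    if (d2[q] < best) {
      best <- d2[q]; bi <- ia[p]; bj <- ib[q]
    }
  }
  list(distance = sqrt(best),
       atomA = paste(residue_ids(conf, bi), conf$atom[bi]),
       atomB = paste(residue_ids(conf, bj), conf$atom[bj]))
}
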