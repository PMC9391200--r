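simple_conf <- function(df) {
  defaults <- data.frame(chain = "A", resnum = 1L, icode = "",
                         resname = "GLY", atom = "CA", element = "C",
                         x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
  for (nm in names(defaults)) if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  conformation(df)
}

test_that("PDB round trip: single model, multi model, altloc policy", {
  g <- generate_ensemble(3, decoy_atoms = 12,
                         plants = list(list(kind = "salt_bridge",
                                            frames = 1:3)), seed = 2)
  f <- tempfile(fileext = ".pdb")
  write_structure(g$ensemble, f)
  ens <- read_structure(f)
  expect_equal(length(ens), 3)
  expect_equal(nrow(ens$conformations[[1]]),
               nrow(g$ensemble$conformations[[1]]))
  expect_equal(ens$conformations[[2]]$x, g$ensemble$conformations[[2]]$x,
               tolerance = 1e-3)
  # single model
  f1 <- tempfile(fileext = ".pdb")
  write_structure(g$ensemble$conformations[[1]], f1)
  expect_equal(length(read_structure(f1)), 1)
  # altloc: highest occupancy kept (A 0.6 vs B 0.4)
  lines <- c(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BGLY A   1       5.000   0.000   0.000  0.40  0.00           C",
    "END")
  fa <- tempfile(fileext = ".pdb")
  writeLines(lines, fa)
  conf <- read_structure(fa)$conformations[[1]]
  expect_equal(nrow(conf), 1)
  expect_equal(conf$x, 0)
})

test_that("salt-bridge cutoff rule at the boundary", {
  mk <- function(d) simple_conf(data.frame(
    chain = c("A", "P"), resnum = c(1L, 1L), icode = "",
    resname = c("ARG", "GLU"), atom = c("NH1", "OE1"),
    element = c("N", "O"), x = c(0, d), y = 0, z = 0))
  ct <- detect_contacts(mk(3.9), contact_criteria(), "A", "P")
  expect_equal(nrow(ct), 1)
  expect_equal(ct$kind, "salt_bridge")
  expect_equal(ct$distance, 3.9)
  expect_equal(nrow(detect_contacts(mk(4.1), contact_criteria(), "A", "P")),
               0)
  # histidine participates only when flagged
  his <- simple_conf(data.frame(
    chain = c("A", "P"), resnum = c(1L, 1L), icode = "",
    resname = c("HIS", "GLU"), atom = c("NE2", "OE1"),
    element = c("N", "O"), x = c(0, 3.5), y = 0, z = 0))
  # neutral His may hydrogen-bond but never salt-bridge
  ct0 <- detect_contacts(his, contact_criteria(), "A", "P")
  expect_false("salt_bridge" %in% ct0$kind)
  cth <- detect_contacts(his, contact_criteria(his_charged = TRUE),
                         "A", "P")
  expect_true("salt_bridge" %in% cth$kind)
})

test_that("hydrogen-bond angle is applied only with explicit hydrogens", {
  base <- data.frame(
    chain = c("A", "P"), resnum = c(1L, 1L), icode = "",
    resname = c("SER", "GLY"), atom = c("OG", "O"),
    element = c("O", "O"), x = c(0, 3.0), y = 0, z = 0,
    stringsAsFactors = FALSE)
  ct <- detect_contacts(simple_conf(base), contact_criteria(), "A", "P")
  expect_true("hbond" %in% ct$kind)
  # explicit hydrogen pointing away -> angle < 120 -> rejected
  withH <- rbind(base, data.frame(
    chain = "A", resnum = 1L, icode = "", resname = "SER", atom = "HG",
    element = "H", x = -0.95, y = 0, z = 0, stringsAsFactors = FALSE))
  ct2 <- detect_contacts(simple_conf(withH), contact_criteria(), "A", "P")
  expect_false("hbond" %in% ct2$kind)
  # hydrogen pointing toward the acceptor -> angle ~180 -> accepted
  withH$x[3] <- 0.95
  ct3 <- detect_contacts(simple_conf(withH), contact_criteria(), "A", "P")
  expect_true("hbond" %in% ct3$kind)
})

test_that("detect_contacts equals the brute-force oracle on planted scenes", {
  kinds <- c("salt_bridge", "hbond", "pi_cation", "pi_stack")
  crit <- contact_criteria()
  for (s in 1:25) {
    set.seed(s)
    plants <- lapply(sample(kinds, sample(2:4, 1)), function(k) {
      list(kind = k, frames = 1L)
    })
    g <- generate_ensemble(1, decoy_atoms = 220, plants = plants,
                           jitter_sd = 0.03, seed = 1000 + s)
    conf <- g$ensemble$conformations[[1]]
    got <- contact_ids(detect_contacts(conf, crit, "A", "P"))
    want <- oracle_contacts(conf, crit)
    expect_identical(got, want)
    # every plant recovered
    for (i in seq_along(plants)) {
      expect_true(any(grepl(paste0("^", plants[[i]]$kind, "\\|A:", i, "\\|"),
                            got)))
    }
  }
})

test_that("detectors are invariant under global rigid motion", {
  g <- generate_ensemble(1, decoy_atoms = 60,
                         plants = list(list(kind = "salt_bridge",
                                            frames = 1),
                                       list(kind = "pi_stack", frames = 1)),
                         seed = 4)
  conf <- g$ensemble$conformations[[1]]
  ids0 <- contact_ids(detect_contacts(conf, contact_criteria(), "A", "P"))
  set.seed(10)
  for (i in 1:5) {
    moved <- apply_rigid(conf, runif(1, 0, pi), rnorm(3), rnorm(3, 0, 50))
    ids <- contact_ids(detect_contacts(moved, contact_criteria(), "A", "P"))
    expect_identical(ids, ids0)
  }
})

test_that("contact_prevalence is exactly k/n for planted frames", {
  g <- generate_ensemble(20, decoy_atoms = 40,
                         plants = list(list(kind = "salt_bridge",
                                            frames = 1:13),
                                       list(kind = "hbond",
                                            frames = c(1, 5, 20))),
                         seed = 6)
  prev <- contact_prevalence(g$ensemble, contact_criteria(), "A", "P")
  expect_equal(prev$prevalence[prev$kind == "salt_bridge"], 0.65)
  expect_equal(prev$prevalence[prev$kind == "hbond"], 0.15)
})

test_that("coulomb_pair: worked value, scaling, symmetry, bilinearity", {
  conf <- simple_conf(data.frame(
    chain = c("A", "P"), resnum = c(1L, 1L), icode = "",
    resname = c("LYS", "GLU"), atom = c("NZ", "CD"),
    element = c("N", "C"), x = c(0, 4), y = 0, z = 0))
  e <- coulomb_pair(conf, "A:1", "P:1")
  expect_equal(e, -332.0636 / 4, tolerance = 1e-9)
  # doubling the dielectric halves |E|
  e2 <- coulomb_pair(conf, "A:1", "P:1", charge_set(dielectric = 2))
  expect_equal(e2, e / 2)
  # symmetry
  expect_equal(coulomb_pair(conf, "P:1", "A:1"), e)
  # bilinearity in the charge vectors
  cs <- charge_set(charges = c("LYS:NZ" = 2, "GLU:CD" = -1))
  expect_equal(coulomb_pair(conf, "A:1", "P:1", cs), 2 * e)
  # missing-charge policy on complete tables
  cs_err <- charge_set(charges = c("LYS:NZ" = 1), complete = TRUE,
                       on_missing = "error")
  expect_error(coulomb_pair(conf, "A:1", "P:1", cs_err), "without charge")
})

test_that("superpose: rigid-motion invariance and quaternion oracle", {
  set.seed(42)
  mk <- function(xyz) simple_conf(data.frame(
    chain = "A", resnum = seq_len(nrow(xyz)), icode = "", resname = "GLY",
    atom = "CA", element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
  for (i in 1:20) {
    P <- matrix(rnorm(30), 10, 3)
    ref <- mk(P)
    moved <- apply_rigid(ref, runif(1, 0, pi), rnorm(3), rnorm(3, 0, 10))
    fit <- superpose(ref, moved, "A")
    expect_lt(fit$rmsd, 1e-9)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    # random (non-congruent) pairs match the quaternion oracle
    Q <- matrix(rnorm(30), 10, 3)
    fit2 <- superpose(mk(Q), mk(P), "A")
    expect_equal(fit2$rmsd, quaternion_rmsd(P, Q), tolerance = 1e-8)
  }
  # collinear selection errors
  line <- mk(cbind(1:5, 0, 0))
  expect_error(superpose(line, line, "A"), "collinear|degenerate")
})

test_that("residue_rmsd: zero for reference/rigid copies, jitter expectation", {
  g <- generate_ensemble(1, decoy_atoms = 30,
                         plants = list(list(kind = "salt_bridge",
                                            frames = 1)), seed = 12)
  ref <- g$ensemble$conformations[[1]]
  # rigid copies -> rmsd 0 everywhere
  set.seed(3)
  frames <- c(list(ref), lapply(1:4, function(i) {
    apply_rigid(ref, runif(1, 0, pi), rnorm(3), rnorm(3, 0, 20))
  }))
  rr <- residue_rmsd(ensemble(frames), "A", "P:1", reference = 1)
  expect_true(all(rr < 1e-9))
  # jitter only the target residue: E[rmsd] ~ sqrt(3)*sigma (chi mean corr.)
  sigma <- 0.3
  set.seed(8)
  frames2 <- lapply(1:200, function(i) {
    df <- as.data.frame(ref)
    tgt <- df$chain == "P"
    df$x[tgt] <- df$x[tgt] + rnorm(sum(tgt), 0, sigma)
    df$y[tgt] <- df$y[tgt] + rnorm(sum(tgt), 0, sigma)
    df$z[tgt] <- df$z[tgt] + rnorm(sum(tgt), 0, sigma)
    conformation(df)
  })
  rr2 <- residue_rmsd(ensemble(frames2), "A", "P:1", reference = ref)
  # rmsd over k atoms of N(0, sigma^2) displacements: E[rmsd] ~= sigma*sqrt(3)
  # up to the chi correction; 10% tolerance at 200 frames
  expect_lt(abs(mean(rr2) - sigma * sqrt(3)) / (sigma * sqrt(3)), 0.1)
})

test_that("min_distance matches a brute-force oracle and validates input", {
  set.seed(21)
  n <- 250
  df <- data.frame(chain = rep(c("A", "P"), each = n),
                   resnum = rep(1:2, each = n), icode = "",
                   resname = "GLY", atom = paste0("C", rep(1:n, 2)),
                   element = "C", x = rnorm(2 * n, 0, 20),
                   y = rnorm(2 * n, 0, 20), z = rnorm(2 * n, 0, 20),
                   stringsAsFactors = FALSE)
  conf <- conformation(df)
  md <- min_distance(conf, "A", "P")
  A <- as.matrix(df[df$chain == "A", c("x", "y", "z")])
  B <- as.matrix(df[df$chain == "P", c("x", "y", "z")])
  brute <- min(sqrt(outer(rowSums(A^2), rowSums(B^2), "+") -
                      2 * A %*% t(B)))
  expect_equal(md$distance, brute, tolerance = 1e-9)
  expect_error(min_distance(conf, "A", "A"), "overlap")
})

test_that("ensemble construction validates topology", {
  g <- generate_ensemble(2, decoy_atoms = 10, seed = 1)
  c1 <- g$ensemble$conformations[[1]]
  df <- as.data.frame(c1)[-1, ]
  expect_error(ensemble(list(c1, conformation(df))), "topology")
})
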