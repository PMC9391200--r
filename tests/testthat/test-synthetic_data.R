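test_that("solve_joint_2x2: closed-form cells for margins and OR", {
  # independence
  expect_equal(unname(solve_joint_2x2(0.25, 0.25, 1)["p11"]), 0.0625)
  # realized OR of the solved table equals the request
  for (or in c(0.5, 2, 4, 10)) {
    cell <- solve_joint_2x2(0.3, 0.2, or)
    expect_equal(sum(cell), 1, tolerance = 1e-12)
    expect_equal(unname(cell["p11"] + cell["p10"]), 0.3, tolerance = 1e-12)
    expect_equal(unname(cell["p11"] + cell["p01"]), 0.2, tolerance = 1e-12)
    expect_equal(unname(cell["p11"] * cell["p00"] /
                          (cell["p10"] * cell["p01"])), or,
                 tolerance = 1e-9)
  }
  expect_error(solve_joint_2x2(0.9, 0.9, 0), "infeasible")
})

test_that("generators are pure functions of spec + seed", {
  sp <- repertoire_spec(n = 300, seed = 77)
  r1 <- generate_repertoire(sp)$repertoire
  r2 <- generate_repertoire(sp)$repertoire
  expect_identical(r1$peptides, r2$peptides)
  g1 <- generate_ensemble(4, decoy_atoms = 30,
                          plants = list(list(kind = "hbond", frames = 1:2)),
                          jitter_sd = 0.05, seed = 5)
  g2 <- generate_ensemble(4, decoy_atoms = 30,
                          plants = list(list(kind = "hbond", frames = 1:2)),
                          jitter_sd = 0.05, seed = 5)
  for (f in 1:4) {
    expect_identical(g1$ensemble$conformations[[f]]$x,
                     g2$ensemble$conformations[[f]]$x)
  }
  p1 <- generate_allotype_panel(list(`2` = list(count = 2, mean = 0.3,
                                                sd = 0.02)),
                                peptides_per_allotype = 100, seed = 4)
  p2 <- generate_allotype_panel(list(`2` = list(count = 2, mean = 0.3,
                                                sd = 0.02)),
                                peptides_per_allotype = 100, seed = 4)
  expect_identical(lapply(p1$reps, `[[`, "peptides"),
                   lapply(p2$reps, `[[`, "peptides"))
})

test_that("realized class frequencies track the spec at binomial rates", {
  for (n in c(100, 1000, 10000)) {
    r <- generate_repertoire(repertoire_spec(n = n, p4_DE_freq = 0.25,
                                             seed = n))$repertoire
    f <- class_frequency(r, "p4", class_DE())$proportion
    # 4-sigma binomial envelope
    expect_lt(abs(f - 0.25), 4 * sqrt(0.25 * 0.75 / n) + 1e-9)
  }
  r <- generate_repertoire(repertoire_spec(n = 10000, seed = 1))$repertoire
  expect_lt(abs(class_frequency(r, "p4", class_DE())$proportion - 0.25),
            0.015)
  # OR near 1 under independence
  t <- contingency(r, "p1", class_KR(), "p4", class_DE())
  or <- (t$a * t$d) / (t$b * t$c)
  expect_gt(or, 0.85); expect_lt(or, 1.18)
})

test_that("generated repertoires are unique, sized, and length-valid", {
  sp <- repertoire_spec(n = 2000, seed = 15)
  r <- generate_repertoire(sp)$repertoire
  expect_equal(length(r), 2000)
  expect_false(anyDuplicated(r$peptides) > 0)
  expect_true(all(nchar(r$peptides) %in% 8:13))
  # resample cap triggers on an impossibly small sequence space:
  # 8-mers, fixed anchors, two-letter background -> 2^6 = 64 < n
  bg <- setNames(rep(0, 20), pepcleft:::AA_ALPHABET)
  bg[c("G", "A")] <- 0.5
  tiny <- repertoire_spec(
    n = 200, length_distribution = c(`8` = 1),
    anchor_prefs = list(p2 = c(L = 1), pOmega = c(V = 1)),
    background = validate_background(bg),
    p4_DE_freq = 0, p1_KR_freq = 0, seed = 1)
  expect_error(generate_repertoire(tiny), "cap")
})

test_that("anchor preferences shape p2 and the C-terminus", {
  r <- generate_repertoire(repertoire_spec(n = 3000, seed = 8))$repertoire
  fm <- frequency_matrix(r)
  expect_gt(fm$freq["p2", "L"], 0.45)
  expect_gt(fm$freq["pOmega", "L"] + fm$freq["pOmega", "V"], 0.6)
  r24 <- generate_repertoire(repertoire_spec(
    n = 3000, anchor_prefs = anchor_prefs_a24(), seed = 8))$repertoire
  fm24 <- frequency_matrix(r24)
  expect_gt(fm24$freq["p2", "Y"], 0.5)
  expect_gt(fm24$freq["pOmega", "F"], 0.4)
})

test_that("wt/mutant pair: shifts validated, null case unbiased", {
  base <- repertoire_spec(n = 1000, seed = 2)
  expect_error(generate_wt_mutant_pair(base, shifts = c(p1_KR = 0.9)),
               "outside")
  expect_error(generate_wt_mutant_pair(base, shifts = c(bogus = 0.1)),
               "unknown shift")
  nul <- generate_wt_mutant_pair(base, shifts = c(p4_DE = 0), size_ratio = 1)
  expect_equal(length(nul$wt), length(nul$mut))
  d <- frequency_difference(frequency_matrix(nul$mut),
                            frequency_matrix(nul$wt))
  expect_lt(max(abs(d)), 0.08)  # sampling noise only at n = 1000
})

test_that("allotype panel plants cleft residues and recovers group means", {
  pan <- generate_allotype_panel(
    list(`0` = list(count = 10, mean = 0.12, sd = 0.02),
         `1` = list(count = 10, mean = 0.20, sd = 0.02),
         `2` = list(count = 10, mean = 0.30, sd = 0.02)),
    peptides_per_allotype = 2000, seed = 19)
  rec2 <- pan$records[[grep("^SYN-2", names(pan$records))[1]]]
  expect_equal(unname(cleft_residues(rec2, c(65, 66))), c("R", "K"))
  rec0 <- pan$records[[grep("^SYN-0", names(pan$records))[1]]]
  expect_equal(unname(cleft_residues(rec0, c(65, 66))), c("G", "N"))
  g <- group_class_frequencies(pan$reps, pan$records)
  means <- vapply(g$groups[c("0", "1", "2")], mean, numeric(1))
  expect_lt(max(abs(means - c(0.12, 0.20, 0.30))), 0.03)
  expect_warning(generate_allotype_panel(
    list(`2` = list(count = 1, mean = 0.3, sd = 0.01)),
    peptides_per_allotype = 50, seed = 1), "need >= 2")
})

test_that("ensemble plants appear exactly in their frames, with jitter", {
  for (s in 1:5) {
    g <- generate_ensemble(20, decoy_atoms = 100,
                           plants = list(list(kind = "salt_bridge",
                                              frames = 1:13),
                                         list(kind = "pi_cation",
                                              frames = c(3, 7, 9))),
                           jitter_sd = 0.05, seed = 100 + s)
    prev <- contact_prevalence(g$ensemble, contact_criteria(), "A", "P")
    expect_equal(prev$prevalence[prev$kind == "salt_bridge"], 0.65)
    expect_equal(prev$prevalence[prev$kind == "pi_cation"], 0.15)
  }
})

test_that("repertoire fixtures round-trip through the readers", {
  gen <- generate_repertoire(repertoire_spec(n = 120, seed = 33),
                             name = "SIM")
  tsv <- tempfile(fileext = ".tsv")
  js <- tempfile(fileext = ".json")
  write_repertoire_fixture(gen, tsv, js)
  tab <- read_peptide_table(tsv)
  qc <- qc_filter(tab, qc_thresholds(), name = "SIM")
  expect_identical(sort(qc$repertoire$peptides),
                   sort(gen$repertoire$peptides))
  truth <- jsonlite::read_json(js)
  expect_equal(truth$n, 120)
  expect_equal(truth$realized_seed, 33)
})
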