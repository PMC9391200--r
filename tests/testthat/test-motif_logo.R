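uniform_bg <- function() {
  validate_background(setNames(rep(0.05, 20), pepcleft:::AA_ALPHABET))
}

test_that("build_pwm: background-matching counts give zero log-odds", {
  bg <- default_background()
  # counts exactly proportional to background at every label
  n <- 1000
  fm <- frequency_matrix(generate_repertoire(
    repertoire_spec(n = 50, seed = 1))$repertoire)
  fm$counts <- matrix(rep(as.numeric(bg) * n, each = length(fm$labels)),
                      nrow = length(fm$labels),
                      dimnames = dimnames(fm$counts))
  fm$n <- n
  fm$freq <- fm$counts / n
  pwm <- build_pwm(fm, bg, pseudocount = 1)
  expect_true(all(abs(pwm$log_odds) < 1e-12))
})

test_that("build_pwm: sign property for a single peptide", {
  fm <- frequency_matrix(PEP_A2)
  pwm <- build_pwm(fm, default_background(), pseudocount = 1)
  expect_gt(pwm$log_odds["p4", "E"], 0)   # present residue
  expect_lt(pwm$log_odds["p4", "A"], 0)   # absent residue
  expect_true(all(is.finite(pwm$log_odds)))
  empty <- frequency_matrix(character(0))
  expect_error(build_pwm(empty), "empty")
})

test_that("build_pwm recovers the generator's dominant anchor", {
  r <- generate_repertoire(repertoire_spec(n = 1000, seed = 21))$repertoire
  pwm <- build_pwm(frequency_matrix(r))
  expect_equal(names(which.max(pwm$log_odds["p2", ])), "L")
})

test_that("kl_logo: identity, point mass, and depletion handling", {
  bg <- uniform_bg()
  fm <- frequency_matrix(PEP_A2)
  # point mass on one residue, uniform background -> IC = log2(20)
  logo <- kl_logo(fm, bg)
  expect_equal(unname(logo$position_ic["p4"]), log2(20), tolerance = 1e-12)
  # p = q -> IC = 0
  fm$freq <- matrix(rep(0.05, 20 * length(fm$labels)),
                    nrow = length(fm$labels),
                    dimnames = dimnames(fm$counts))
  logo0 <- kl_logo(fm, bg)
  expect_true(all(abs(logo0$position_ic) < 1e-12))
  # negative letter scores retained for depleted residues (0 < p < q)
  fm2 <- frequency_matrix(generate_repertoire(
    repertoire_spec(n = 400, seed = 2))$repertoire)
  logo2 <- kl_logo(fm2, default_background())
  expect_true(any(logo2$letter_score < 0))
  expect_true(all(logo2$position_ic >= -1e-12))
})

test_that("kl_logo errors when background is zero for an observed residue", {
  bg <- setNames(rep(1 / 19, 20), pepcleft:::AA_ALPHABET)
  bg["E"] <- 0
  fm <- frequency_matrix(PEP_A2)  # contains E at p4
  expect_error(kl_logo(fm, validate_background(bg)), "zero")
})

test_that("position IC increases along the acidic-p4 enrichment family", {
  ics <- vapply(c(0.117, 0.25, 0.42), function(f) {
    r <- generate_repertoire(repertoire_spec(n = 4000, p4_DE_freq = f,
                                             seed = 11))$repertoire
    kl_logo(frequency_matrix(r))$position_ic[["p4"]]
  }, numeric(1))
  expect_true(all(diff(ics) > 0))
})

test_that("IC is invariant under consistent residue relabeling", {
  r <- generate_repertoire(repertoire_spec(n = 500, seed = 13))$repertoire
  fm <- frequency_matrix(r)
  bg <- default_background()
  logo <- kl_logo(fm, bg)
  perm <- sample(20)
  fm2 <- fm
  fm2$counts <- fm$counts[, perm]
  colnames(fm2$counts) <- pepcleft:::AA_ALPHABET
  fm2$freq <- fm2$counts / fm2$n
  bg2 <- setNames(as.numeric(bg)[perm], pepcleft:::AA_ALPHABET)
  logo2 <- kl_logo(fm2, validate_background(bg2))
  expect_equal(logo$position_ic, logo2$position_ic, tolerance = 1e-12)
})

a2_a24_pwms <- function(n = 1000, seed = 5) {
  ra2 <- generate_repertoire(repertoire_spec(n = n, seed = seed))$repertoire
  ra24 <- generate_repertoire(repertoire_spec(
    n = n, anchor_prefs = anchor_prefs_a24(),
    seed = seed + 1))$repertoire
  list(A2 = build_pwm(frequency_matrix(ra2)),
       A24 = build_pwm(frequency_matrix(ra24)))
}

test_that("assign_allotype separates disjoint-anchor motifs", {
  pwms <- a2_a24_pwms()
  res <- assign_allotype(c("QYKDNVILF", "GLKEGIPAV"), pwms)
  expect_equal(res$assigned, c("A24", "A2"))
  # infinite margin -> everything unassigned
  res_inf <- assign_allotype(c("QYKDNVILF", "GLKEGIPAV"), pwms,
                             min_margin = Inf)
  expect_true(all(is.na(res_inf$assigned)))
})

test_that("assignment accuracy >= 95% on a 50:50 synthetic mixture", {
  pwms <- a2_a24_pwms(n = 2000, seed = 30)
  accs <- vapply(1:5, function(s) {
    r1 <- generate_repertoire(repertoire_spec(n = 500, seed = 100 + s)
                              )$repertoire
    r2 <- generate_repertoire(repertoire_spec(
      n = 500, anchor_prefs = anchor_prefs_a24(),
      seed = 200 + s))$repertoire
    res <- assign_allotype(c(r1$peptides, r2$peptides), pwms)
    truth <- rep(c("A2", "A24"), each = 500)
    mean(!is.na(res$assigned) & res$assigned == truth)
  }, numeric(1))
  expect_true(all(accs >= 0.95))
})

test_that("PWM consensus peptide is assigned to its own motif", {
  pwms <- a2_a24_pwms()
  consensus <- function(pwm) {
    # build a 9-mer from the argmax residue at each resolvable label
    res <- vapply(c("p1", "p2", "p3", "p4", "p5", "pOmega-3", "pOmega-2",
                    "pOmega-1", "pOmega"), function(lab) {
      names(which.max(pwm$log_odds[lab, ]))
    }, character(1))
    paste(res, collapse = "")
  }
  for (nm in names(pwms)) {
    res <- assign_allotype(consensus(pwms[[nm]]), pwms, min_margin = 0)
    expect_equal(res$assigned, nm)
  }
})
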