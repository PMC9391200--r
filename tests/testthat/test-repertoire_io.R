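test_that("read_peptide_table parses, normalizes case, and rejects bad rows", {
  path <- write_peptide_tsv(data.frame(
    sequence = c("GLKEGIPAL", "glkegipal", "GLKBGIPAL", "QFKDNVILL"),
    ion_score = c("31.2", "28", "40", "oops"),
    stringsAsFactors = FALSE))
  tab <- read_peptide_table(path)
  expect_equal(tab$sequence, c("GLKEGIPAL", "GLKEGIPAL"))
  expect_equal(tab$ion_score, c(31.2, 28))
  rej <- attr(tab, "rejected")
  expect_equal(nrow(rej), 2)
  expect_match(rej$reason[rej$row == 3], "non-canonical residue B")
  expect_match(rej$reason[rej$row == 4], "unparseable ion_score")
})

test_that("read_peptide_table respects column_map and missing column errors", {
  path <- write_peptide_tsv(data.frame(pep = "GLKEGIPAL", score = "30"))
  tab <- read_peptide_table(path, column_map = c(sequence = "pep",
                                                 ion_score = "score"))
  expect_equal(tab$ion_score, 30)
  expect_error(read_peptide_table(path), "sequence column")
})

test_that("qc_filter applies inclusive thresholds and deduplicates", {
  recs <- data.frame(
    sequence = c("GLKEGIPAL", "GLKEGIPAL", "QFKDNVILL", "VYGFVRACL",
                 "KLKEGIPAL", "AAAAAAA"),
    allotype = NA_character_,
    ion_score = c(30, 99, 24, 25, NA, 50),
    delta_mass_ppm = NA_real_,
    source_tpm = c(1, 1, 5, 0.3, 0.29, 1),
    row = 1:6, stringsAsFactors = FALSE)
  qc <- qc_filter(recs, qc_thresholds())
  # 24 < 25 rejected; score 25 / tpm 0.3 pass at the minimum; NA score passes
  # by default but tpm 0.29 fails; 7-mer fails length; one duplicate
  expect_setequal(qc$repertoire$peptides, c("GLKEGIPAL", "VYGFVRACL"))
  expect_equal(unname(qc$report["ion_score"]), 1L)
  expect_equal(unname(qc$report["tpm"]), 1L)
  expect_equal(unname(qc$report["length"]), 1L)
  expect_equal(unname(qc$report["duplicate"]), 1L)
  # accounting identity: rejections + duplicates + retained = records
  expect_equal(sum(qc$report), nrow(recs))
})

test_that("qc_filter is idempotent and require_* flags tighten", {
  recs <- c("GLKEGIPAL", "QFKDNVILL", "GLKEGIPAL")
  qc1 <- qc_filter(recs)
  qc2 <- qc_filter(qc1$repertoire$peptides)
  expect_identical(qc1$repertoire$peptides, qc2$repertoire$peptides)
  expect_equal(unname(qc2$report["duplicate"]), 0L)
  strict <- qc_filter(data.frame(sequence = "GLKEGIPAL",
                                 allotype = NA, ion_score = NA_real_,
                                 delta_mass_ppm = NA_real_,
                                 source_tpm = NA_real_, row = 1),
                      qc_thresholds(require_ion_score = TRUE))
  expect_equal(length(strict$repertoire), 0)
  expect_equal(unname(strict$report["ion_score"]), 1L)
})

test_that("composition_from_fasta counts and excludes non-canonical letters", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">s1", "DDEE"), f)
  comp <- composition_from_fasta(f)
  expect_equal(unname(comp["D"]), 0.5)
  expect_equal(unname(comp["E"]), 0.5)
  expect_equal(sum(comp), 1)
  writeLines(c(">s1", "DXE"), f)
  comp <- composition_from_fasta(f)
  expect_equal(unname(comp["D"]), 0.5)
  writeLines(c(">s1", "XXXX"), f)
  expect_error(composition_from_fasta(f), "no canonical residues")
})

test_that("composition of concatenated FASTAs is the count-weighted mean", {
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  f12 <- tempfile(fileext = ".fasta")
  s1 <- "MKLVDDEEGGHHII"; s2 <- "AAAACDEFGHIKLMNPQRSTVWYY"
  writeLines(c(">a", s1), f1)
  writeLines(c(">b", s2), f2)
  writeLines(c(">a", s1, ">b", s2), f12)
  c1 <- composition_from_fasta(f1); c2 <- composition_from_fasta(f2)
  c12 <- composition_from_fasta(f12)
  n1 <- nchar(s1); n2 <- nchar(s2)
  expect_equal(as.numeric(c12),
               as.numeric((n1 * c1 + n2 * c2) / (n1 + n2)),
               tolerance = 1e-12)
})

test_that("composition estimate converges on sampled proteomes", {
  truth <- default_background()
  f <- tempfile(fileext = ".fasta")
  set.seed(99)
  seqs <- vapply(1:1000, function(i) {
    paste(sample(names(truth), 100, replace = TRUE, prob = truth),
          collapse = "")
  }, character(1))
  writeLines(as.vector(rbind(paste0(">s", 1:1000), seqs)), f)
  est <- composition_from_fasta(f)
  expect_true(all(abs(est - truth) < 0.01))
})

test_that("allele sequences: mature numbering and cleft residues", {
  alleles <- read_allele_sequences(bundled_alleles(),
                                   signal_peptide_length = 24)
  names(alleles) <- vapply(alleles, `[[`, character(1), "name")
  a2 <- alleles[["A*02:01"]]
  a24 <- alleles[["A*24:02"]]
  # the wild-type charge configuration: R65/K66 in A2, G65/K66 in A24
  expect_equal(unname(cleft_residues(a2, c(65, 66))), c("R", "K"))
  expect_equal(unname(cleft_residues(a24, c(65, 66))), c("G", "K"))
  # the alpha-1 helix segment 57-73 carries the documented residues
  seg <- paste(cleft_residues(a2, 57:73), collapse = "")
  expect_equal(seg, "PEYWDGETRKVKAHSQT")
  seg24 <- paste(cleft_residues(a24, 57:73), collapse = "")
  expect_equal(seg24, "PEYWDEETGKVKAHSQT")
  expect_error(cleft_residues(a2, 9999), "out of range")
})

test_that("signal peptide handling and length validation", {
  f <- tempfile(fileext = ".fasta")
  mature <- paste(rep("GSHSMRYFET", 19), collapse = "")
  writeLines(c(">X*00:01", mature), f)
  rec <- read_allele_sequences(f, signal_peptide_length = 0)[[1]]
  expect_equal(rec$mature_sequence, mature)
  expect_error(read_allele_sequences(f, signal_peptide_length = 24),
               "X\\*00:01")
})

test_that("repertoire constructor enforces invariants", {
  expect_error(repertoire("GLKBGIPAL"), "non-canonical")
  expect_error(repertoire("GLKEG"), "length")
  r <- repertoire(c("GLKEGIPAL", "GLKEGIPAL"))
  expect_equal(length(r), 1)
})
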