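test_that("sequence validation normalises case and rejects bad input", {
  expect_equal(validate_sequence("ATKPAN")$sequence, "ATKPAN")
  expect_equal(validate_sequence("atkpan")$sequence, "ATKPAN")
  expect_equal(validate_sequence("  sagvlpwk \n")$sequence, "SAGVLPWK")
  expect_error(validate_sequence(""), "empty")
  expect_error(validate_sequence("   "), "empty")
  expect_error(validate_sequence("ATXPAN"), "'X' at position 3")
  for (bad in c("B", "J", "O", "U", "X", "Z")) {
    expect_error(validate_sequence(paste0("AA", bad)), "illegal residue")
  }
})

test_that("modifications are parsed, bounded, and residue-restricted", {
  p <- peptide("INNNKIITNL", modifications = "Deamidated (N)@2")
  expect_equal(p$modifications$kind, "deamidation")
  expect_equal(p$modifications$position, 2L)
  # deamidation is only meaningful on N or Q
  expect_error(peptide("INNNKIITNL", modifications = "Deamidated (N)@1"),
               "not annotatable")
  expect_silent(peptide("QAA", modifications = "Deamidated (Q)@1"))
  expect_error(peptide("AAA",
                       modifications = data.frame(position = 9, kind = "deamidation")),
               "outside sequence")
  expect_error(peptide("AAN",
                       modifications = data.frame(position = 3, kind = "oxidation")),
               "unregistered")
})

test_that("FASTA I/O round-trips and accepts wrapped sequence lines", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  peps <- random_peptides(12, seed = 11)
  write_fasta(peps, tmp)
  back <- read_fasta(tmp)
  expect_equal(vapply(back, function(p) p$sequence, ""),
               vapply(peps, function(p) p$sequence, ""))
  expect_equal(vapply(back, function(p) p$id, ""),
               vapply(peps, function(p) p$id, ""))

  # wrapped and unwrapped layouts of the same record are equivalent
  wrapped <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">w1", "ATKP", "AN", ">w2", "SGAASASGAA"), wrapped)
  recs <- read_fasta(wrapped)
  expect_equal(vapply(recs, function(p) p$sequence, ""),
               c("ATKPAN", "SGAASASGAA"))
})

test_that("FASTA parser flags malformed files and tolerates empty ones", {
  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("ATKPAN", ">p1", "SGAA"), bad)
  expect_error(read_fasta(bad), "line 1")
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_length(read_fasta(empty), 0)
})

test_that("bundled fixtures satisfy their cardinality invariants", {
  fx <- load_fixtures()
  expect_equal(nrow(fx$identified_peptides), 48L)
  expect_equal(nrow(fx$bioactive_reference), 16L)
  expect_equal(nrow(fx$fragment_truth), 70L)
  expect_equal(sum(fx$fragment_truth$allergen == "allergen"), 28L)
  expect_equal(sum(fx$fragment_truth$allergen == "non_allergen"), 42L)
  expect_length(fx$intact_truth, 7L)
  expect_true(all(fx$intact_truth %in% fx$identified_peptides$sequence))
  # every fixture sequence passes validation (errors would abort the load)
  expect_length(fx$peptides, 48L)
  # the deamidated record carries its parsed modification
  deam <- fx$peptides[[which(fx$identified_peptides$sequence == "INNNKIITNL")]]
  expect_equal(deam$modifications$kind, "deamidation")
  # fixture FASTA round-trip preserves the identified set
  tmp <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(fx$peptides, tmp)
  expect_setequal(vapply(read_fasta(tmp), function(p) p$sequence, ""),
                  fx$identified_peptides$sequence)
})
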