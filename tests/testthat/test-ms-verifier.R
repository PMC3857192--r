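test_that("apply_mutations substitutes with a reference guard", {
  base <- paste(rep("A", 400), collapse = "")
  seq <- paste0(substr(base, 1, 357), "E", substr(base, 359, 400))
  mut <- apply_mutations(seq, "E358C")
  expect_identical(substr(mut, 358, 358), "C")
  expect_identical(nchar(mut), nchar(seq))
  # only position 358 differs
  expect_identical(which(strsplit(mut, "")[[1]] != strsplit(seq, "")[[1]]), 358L)

  expect_identical(apply_mutations(seq, character(0)), seq)
  expect_error(apply_mutations(seq, "K321C"), "expected K at position 321")
  expect_error(apply_mutations("AAA", "A5C"), "outside")
})

test_that("parse_mutation reads chain-qualified from/position/to notation", {
  m <- parse_mutation("B:R360C")
  expect_identical(m[c("chain", "pos", "from", "to")],
                   list(chain = "B", pos = 360L, from = "R", to = "C"))
  expect_true(is.na(parse_mutation("K321C")$chain))
  expect_error(parse_mutation("K32"), "cannot parse")
})

test_that("tryptic digestion follows the Keil rule", {
  d0 <- digest("AKRPGK", protease("trypsin"), 0)
  expect_identical(d0$sequence, c("AK", "RPGK"))
  expect_identical(d0$start, c(1L, 3L))
  expect_identical(d0$end, c(2L, 6L))

  d_nop <- digest("AKRPGK", protease("trypsin", proline_rule = FALSE), 0)
  expect_identical(d_nop$sequence, c("AK", "R", "PGK"))

  nosite <- digest("AGGHWMV", protease("trypsin"), 2)
  expect_identical(nosite$sequence, "AGGHWMV")
  expect_identical(nosite$missed, 0L)
})

test_that("sequential digestion unions the cut sites", {
  got <- sequential_digest("EVCDCLA", list(protease("trypsin"), protease("aspn_d")), 0)
  expect_identical(got$sequence, c("EVC", "DCLA"))
  # single rule reduces to digest()
  s <- "MKAEVRDLKPR"
  expect_identical(sequential_digest(s, list(protease("trypsin")), 2),
                   digest(s, protease("trypsin"), 2))
})

test_that("digestion matches the brute-force oracle on random sequences", {
  set.seed(101)
  rule_sets <- list(
    list(protease("trypsin")),
    list(protease("trypsin"), protease("aspn_d")),
    list(protease("trypsin"), protease("aspn_de"))
  )
  for (k in 1:30) {
    s <- random_peptide(sample(10:80, 1))
    mm <- sample(0:2, 1)
    rules <- rule_sets[[sample(length(rule_sets), 1)]]
    got <- sequential_digest(s, rules, mm)
    exp <- oracle_digest(s, rules, mm)
    expect_identical(got$sequence, exp$sequence)
    expect_identical(got$start, exp$start)
    expect_identical(got$end, exp$end)
    expect_identical(got$missed, exp$missed)
  }
})

test_that("zero-missed fragments tile the sequence exactly", {
  set.seed(7)
  for (k in 1:10) {
    s <- random_peptide(60)
    f <- sequential_digest(s, list(protease("trypsin"), protease("aspn_de")), 0)
    expect_identical(paste(f$sequence, collapse = ""), s)
    expect_identical(f$end - f$start + 1L, nchar(f$sequence))
  }
})

test_that("mutating a cleavage-site residue removes exactly that site", {
  s <- "GAKVLRTPWKDE"   # tryptic sites after K3, R6 is followed by T, K10
  tr <- protease("trypsin")
  before <- cleavage_sites(s, tr)
  mut <- apply_mutations(s, "K10C")
  after <- cleavage_sites(mut, tr)
  expect_identical(setdiff(before, after), 10L)
  expect_identical(setdiff(after, before), integer(0))
})

test_that("monoisotopic peptide masses match the residue-table sums", {
  expect_equal(peptide_monoisotopic_mass("VELCVR"), 717.3843, tolerance = 1e-4)
  expect_equal(peptide_monoisotopic_mass("CLAEVGR"), 746.3745, tolerance = 1e-4)
  expect_equal(peptide_monoisotopic_mass("G"), 75.0320, tolerance = 1e-4)
  expect_error(peptide_monoisotopic_mass("AXZ"), "non-standard")
  # fixed modification: carbamidomethyl adds 57.021464 per cysteine
  expect_equal(peptide_monoisotopic_mass("CC", fixed_mods = c(C = 57.021464)),
               peptide_monoisotopic_mass("CC") + 2 * 57.021464)
})

test_that("mass additivity holds for random peptides", {
  set.seed(13)
  for (k in 1:50) {
    a <- random_peptide(sample(1:25, 1))
    b <- random_peptide(sample(1:25, 1))
    expect_equal(peptide_monoisotopic_mass(paste0(a, b)),
                 peptide_monoisotopic_mass(a) + peptide_monoisotopic_mass(b) -
                   mass_constants$water,
                 tolerance = 1e-6)
  }
})

test_that("disulfide crosslink mass loses exactly two hydrogens", {
  expect_equal(disulfide_crosslink_mass("VELCVR", "CLAEVGR"), 1461.7432,
               tolerance = 1e-4)
  expect_equal(disulfide_crosslink_mass("EVC", "CLA"), 652.2560, tolerance = 1e-4)
  set.seed(3)
  for (k in 1:20) {
    a <- paste0(random_peptide(sample(1:10, 1)), "C")
    b <- paste0("C", random_peptide(sample(1:10, 1)))
    expect_equal(peptide_monoisotopic_mass(a) + peptide_monoisotopic_mass(b) -
                   disulfide_crosslink_mass(a, b), 2.01565, tolerance = 1e-6)
  }
  expect_error(disulfide_crosslink_mass("AAA", "CCC"), "cysteine")
})

test_that("m/z arithmetic: closed form, monotone in z, invertible", {
  expect_equal(mz_for_charge(652.2560342, 1), 653.2633, tolerance = 1e-4)
  expect_equal(mz_for_charge(1461.7432052, 3), 488.2550, tolerance = 1e-4)
  set.seed(9)
  for (M in stats::runif(10, 100, 5000)) {
    expect_equal(mz_for_charge(M, 1), M + 1.0072765)
    mz <- mz_for_charge(M, 1:6)
    expect_true(all(diff(mz) < 0))
    for (z in 1:6) {
      expect_equal(mz_for_charge(M, z) * z - z * mass_constants$proton, M,
                   tolerance = 1e-6)
    }
  }
  expect_error(mz_for_charge(100, 0), "positive integer")
})

# engineered-mutant mini-chains whose digests yield the diagnostic peptides
# EVC (alphaIIb-like chain, R->C kills the tryptic site) and CLA (beta3-like
# chain, E->C); wild-type counterparts digest to EVR / ELA instead
wt_a <- "GKAEVRDLK"; mut_a <- apply_mutations(wt_a, "R6C")
wt_b <- "AKELAEGR";  mut_b <- apply_mutations(wt_b, "E3C")

test_that("diagnostic crosslink enumeration finds the engineered-only species", {
  enz <- list(protease("trypsin"), protease("aspn_de"))
  da <- sequential_digest(mut_a, enz, 0)
  db <- sequential_digest(mut_b, enz, 0)
  wa <- sequential_digest(wt_a, enz, 2)
  wb <- sequential_digest(wt_b, enz, 2)
  sp <- enumerate_diagnostic_crosslinks(da, db, 6L, 3L, charges = 1:4,
                                        wildtype_a = wa, wildtype_b = wb)
  hit <- sp[sp$pep_a == "EVC" & sp$pep_b == "CLA", ]
  expect_identical(nrow(hit), 1L)
  expect_true(hit$diagnostic)
  expect_equal(hit$neutral_mass, 652.2560, tolerance = 1e-4)
  expect_equal(hit$mz_z1, 653.2633, tolerance = 1e-4)
  expect_true(all(diff(sp$neutral_mass) >= 0))

  # hand-enumerable pair set: with 0 missed cleavages each digest holds exactly
  # one Cys-covering peptide, so exactly one species exists
  expect_identical(nrow(sp), 1L)

  # no peptide covering the engineered position -> empty
  none <- enumerate_diagnostic_crosslinks(da, db, 999L, 999L)
  expect_identical(nrow(none), 0L)
})

test_that("observed-peak matching respects ppm tolerance and is monotone in it", {
  enz <- list(protease("trypsin"), protease("aspn_de"))
  sp <- enumerate_diagnostic_crosslinks(
    sequential_digest(mut_a, enz, 0), sequential_digest(mut_b, enz, 0),
    6L, 3L, charges = 1:4
  )
  obs <- data.frame(mz = 653.2630, z = 1)
  got <- match_observed_peaks(sp, obs, tol_ppm = 10)
  expect_identical(nrow(got), 1L)
  expect_lt(abs(got$ppm_error), 1)

  far <- data.frame(mz = 653.2630 * (1 + 50e-6), z = 1)
  expect_identical(nrow(match_observed_peaks(sp, far, tol_ppm = 10)), 0L)
  # widening the tolerance can only add matches
  n10 <- nrow(match_observed_peaks(sp, rbind(obs, far), tol_ppm = 10))
  n100 <- nrow(match_observed_peaks(sp, rbind(obs, far), tol_ppm = 100))
  expect_gte(n100, n10)
  # wrong charge never matches
  expect_identical(nrow(match_observed_peaks(sp, data.frame(mz = 653.2630, z = 2))), 0L)
})
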