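test_that("unmodified peptide masses match the atomic-composition oracle", {
  for (seq in c("GGGGG", "MKTAYIAKQR", ELA_CORE)) {
    expect_equal(sequence_mass(seq, "average"),
                 oracle_peptide_mass(seq, "average"), tolerance = 1e-6)
    expect_equal(sequence_mass(seq, "monoisotopic"),
                 oracle_peptide_mass(seq, "monoisotopic"), tolerance = 1e-6)
  }
})

test_that("each dehydration removes exactly one water", {
  base <- sequence_mass("ASTKA")
  m1 <- apply_maturation("ASTKA", modification_set(dehydrated = 2L))
  m2 <- apply_maturation("ASTKA", modification_set(dehydrated = c(2L, 3L)))
  water <- 2 * 1.008 + 15.999 # first principles: 2 H + 1 O
  expect_equal(base - m1$average, water, tolerance = 1e-9)
  expect_equal(base - m2$average, 2 * water, tolerance = 1e-9)
})

test_that("ring formation adds no mass beyond the prior dehydration", {
  dehydrated_only <- apply_maturation("ASAKC", modification_set(dehydrated = 2L))
  with_ring <- apply_maturation("ASAKC", modification_set(
    dehydrated = 2L, rings = list(c(2, 5))))
  expect_equal(with_ring$average, dehydrated_only$average)
  expect_identical(with_ring$residues[2], "Lan-donor")
  expect_identical(with_ring$residues[5], "Lan-acceptor")
})

test_that("lactate, Abu and methylation deltas follow their net formulas", {
  # lactate on a dehydrated N-terminal Ser: net -N +H +O vs the Dha form
  dha <- apply_maturation("SAKC", modification_set(dehydrated = 1L))
  lac <- apply_maturation("SAKC", modification_set(dehydrated = 1L, lactate = TRUE))
  expect_equal(lac$average - dha$average, -14.007 + 1.008 + 15.999,
               tolerance = 1e-9)
  # Abu: Thr net -O
  abu <- apply_maturation("ATKC", modification_set(abu = 2L))
  expect_equal(sequence_mass("ATKC") - abu$average, 15.999, tolerance = 1e-9)
  # methylation: +CH2 each
  me <- apply_maturation("ATKC", modification_set(methylations = 2L))
  expect_equal(me$average - sequence_mass("ATKC"), 2 * (12.011 + 2 * 1.008),
               tolerance = 1e-9)
})

test_that("the bundled core's ring topology segments sum to the core length", {
  m <- apply_maturation(ELA_CORE, ela_modifications())
  segs <- m$segments
  expect_identical(unname(segs), c(11L, 5L, 3L, 5L, 6L))
  expect_identical(names(segs), c("n_terminal", "ring_system_1", "hinge_1",
                                  "ring_system_2", "c_terminal"))
  expect_identical(sum(segs), nchar(ELA_CORE))
  # the intertwined B/C rings merge into one system spanning 20..24
  expect_identical(unname(segs["ring_system_2"]), 5L)
})

test_that("the mature bundled core matches an independently assembled mass", {
  m <- apply_maturation(ELA_CORE, ela_modifications())
  # oracle: unmodified mass - 6 dehydrations + lactate + Abu deltas
  water <- 2 * 1.008 + 15.999
  expected <- oracle_peptide_mass(ELA_CORE, "average") - 6 * water +
    (-14.007 + 1.008 + 15.999) + (-15.999)
  expect_equal(m$average, expected, tolerance = 1e-6)
  # +CH2 variant sits one methylene above
  m_ch2 <- apply_maturation(ELA_CORE, modification_set(
    dehydrated = c(1L, 3L, 8L, 12L, 20L, 21L),
    rings = list(c(12, 16), c(20, 23), c(21, 24)),
    lactate = TRUE, abu = 27L, methylations = 1L))
  expect_equal(m_ch2$average - m$average, 12.011 + 2 * 1.008, tolerance = 1e-9)
})

test_that("leader cleavage splits by position or motif", {
  prec <- paste0(ELA_LEADER, ELA_CORE)
  by_pos <- cleave_leader(prec, nchar(ELA_LEADER))
  expect_identical(by_pos$core, ELA_CORE)
  by_motif <- cleave_leader(prec, "AASSPQ")
  expect_identical(by_motif$core, ELA_CORE)
  expect_identical(by_motif$cleavage_pos, nchar(ELA_LEADER))
  expect_error(cleave_leader(prec, "AAWSPQ"), "closest candidates")
  expect_error(cleave_leader(prec, 0), "cleavage position")
})

test_that("invalid modification sets are rejected with the failing rule", {
  expect_error(apply_maturation("AAKC", modification_set(dehydrated = 1L)),
               "must be Ser or Thr")
  expect_error(apply_maturation("SAKA", modification_set(
    dehydrated = 1L, rings = list(c(1, 4)))), "must be a core Cys")
  expect_error(apply_maturation("SAKC", modification_set(
    rings = list(c(1, 4)))), "must be a dehydrated")
  expect_error(apply_maturation("TAKC", modification_set(
    dehydrated = 1L, lactate = TRUE)), "lactate requires")
  expect_error(apply_maturation("SSCC", modification_set(
    dehydrated = c(1L, 2L), rings = list(c(1, 3), c(2, 3)))),
    "more than one ring")
  expect_error(apply_maturation("SACC", modification_set(
    dehydrated = 1L, rings = list(c(4, 3)))), "donor must precede")
  expect_error(apply_maturation("SAKC", modification_set(abu = 1L)),
               "Abu positions must be core Thr")
})
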