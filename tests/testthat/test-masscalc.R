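test_that("formula parsing and monoisotopic masses match an independent elemental-mass table", {
  expect_equal(formulaMass("C6H10O5"), 162.052824, tolerance = 1e-6)
  expect_equal(formulaMass("H2O"), 18.010565, tolerance = 1e-6)
  expect_equal(formulaMass("H2O"), oracleFormulaMass("H2O"),
               tolerance = 1e-7)
  expect_equal(formulaMass(parseFormula("C15H11O5")),
               oracleFormulaMass("C15H11O5"), tolerance = 1e-6)
  expect_identical(hillFormula(parseFormula("O5H10C6")), "C6H10O5")
  # repeated element tokens accumulate
  expect_identical(parseFormula("CH3CH3")[["C"]], 2L)

  expect_error(formulaMass("Zr2O"), "unknown element")
  expect_error(parseFormula(""), "empty")
  expect_error(formulaMass(c(C = 0L, H = 0L)), "zero total atoms")
  expect_error(parseFormula("C6H10O5!"), "malformed")

  lib <- defaultBlockLibrary()
  b <- blocks(lib)
  for (i in seq_len(nrow(b)))
    expect_equal(b$residueMass[i], oracleFormulaMass(b$formula[i]),
                 tolerance = 1e-5, label = b$id[i])
})

test_that("cation masses are electron-corrected flavylium [M]+ values", {
  # pelargonidin flavylium: published experimental m/z 271.06008
  expect_lt(abs(cationMass("C15H11O5") - 271.06008), 5e-4)
  # pelargonidin 3,5-O-diglucoside precursor: published 595.16516
  expect_lt(abs(cationMass("C27H31O15") - 595.16516) / 595.16516 * 1e6, 5)
  # definition: cation m/z is always one electron mass light
  for (f in c("C15H11O5", "C27H31O15", "C6H10O5", "H2O"))
    expect_equal(formulaMass(f) - cationMass(f), electronMass(),
                 tolerance = 1e-6)
})

test_that("compositions assemble decoration multisets order-independently", {
  lib <- defaultBlockLibrary()
  digluc <- composeBlocks("pelargonidin", c("hexose", "hexose"), lib)
  expect_identical(hillFormula(totalFormula(digluc)), "C27H31O15")
  rut <- composeBlocks("pelargonidin", c("hexose", "deoxyhexose"), lib)
  rut2 <- composeBlocks("pelargonidin", c("deoxyhexose", "hexose"), lib)
  expect_identical(hillFormula(totalFormula(rut)), "C27H31O14")
  expect_equal(cationMz(rut), cationMz(rut2))
  expect_identical(decorations(rut), decorations(rut2))

  bare <- composeBlocks("pelargonidin", character(0), lib)
  expect_equal(cationMz(bare),
               residueMass(lib, "pelargonidin")[[1]] - electronMass(),
               tolerance = 1e-9)

  expect_error(composeBlocks("nosuch", character(0), lib), "unknown block")
  expect_error(composeBlocks("hexose", character(0), lib), "not an aglycone")
  expect_error(composeBlocks("pelargonidin", "cyanidin", lib), "not aglycones")
})

test_that("neutral-loss masses reproduce published losses and are additive", {
  lib <- defaultBlockLibrary()
  # published: malonylhexose 248.05321, caffeoylhexose 324.08451,
  # rhamnose residue 146.05790
  expect_lt(abs(lossMass(c("malonyl", "hexose"), lib) - 248.05321), 1e-3)
  expect_lt(abs(lossMass(c("caffeoyl", "hexose"), lib) - 324.08451), 1e-3)
  expect_lt(abs(residueMass(lib, "deoxyhexose")[[1]] - 146.05790), 1e-3)
  expect_identical(lossMass(character(0), lib), 0.0)
  expect_error(lossMass("pelargonidin", lib), "glycosyl/acyl")

  set.seed(42)
  decs <- c("hexose", "deoxyhexose", "malonyl", "coumaroyl", "caffeoyl",
            "feruloyl")
  for (k in 1:20) {
    a <- sample(decs, sample(0:4, 1), replace = TRUE)
    b <- sample(decs, sample(0:4, 1), replace = TRUE)
    expect_equal(lossMass(c(a, b), lib),
                 lossMass(a, lib) + lossMass(b, lib), tolerance = 1e-9)
  }
})
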