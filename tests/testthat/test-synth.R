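lib <- defaultBlockLibrary()

test_that("structure sampling is deterministic, distinct and within bounds", {
  s1 <- sampleStructures(50, lib, seed = 101)
  s2 <- sampleStructures(50, lib, seed = 101)
  k1 <- vapply(s1, function(x) paste(aglycone(x),
                                     paste(decorations(x), collapse = ","),
                                     sep = "|"), character(1))
  k2 <- vapply(s2, function(x) paste(aglycone(x),
                                     paste(decorations(x), collapse = ","),
                                     sep = "|"), character(1))
  expect_identical(k1, k2)
  expect_false(anyDuplicated(k1) > 0)
  for (x in s1) {
    expect_true(validObject(x))
    b <- blocks(lib)
    dec <- decorations(x)
    expect_lte(sum(dec %in% b$id[b$class == "glycosyl"]), 4)
    expect_lte(sum(dec %in% b$id[b$class == "acyl"]), 3)
  }

  bare <- sampleStructures(1, lib, seed = 1, maxGlycosyl = 0, maxAcyl = 0)
  expect_length(decorations(bare[[1]]), 0)

  expect_error(sampleStructures(10, lib, seed = 1, maxGlycosyl = 0,
                                maxAcyl = 0),
               "distinct compositions")
})

test_that("simulated spectra carry the designed loss series", {
  mono <- composeBlocks("pelargonidin", "hexose", lib)
  sp <- simulateSpectrum(mono, lib, mzSigmaPpm = 0, nDecoys = 0)
  expect_equal(precursorMz(sp), cationMz(mono), tolerance = 1e-9)
  expect_equal(unname(fragments(sp)[, "mz"]), cationMass("C15H11O5"),
               tolerance = 1e-9)

  bare <- composeBlocks("pelargonidin", character(0), lib)
  spb <- simulateSpectrum(bare, lib, mzSigmaPpm = 0)
  expect_identical(nrow(fragments(spb)), 0L)

  # simulated spectra always satisfy the Spectrum invariants
  for (x in sampleStructures(20, lib, seed = 7))
    expect_true(validObject(simulateSpectrum(x, lib, mzSigmaPpm = 2,
                                             nDecoys = 3)))

  # free glycosyl ions are optional extras
  rut <- composeBlocks("pelargonidin", c("hexose", "deoxyhexose"), lib)
  spr <- simulateSpectrum(rut, lib, mzSigmaPpm = 0, freeGlycosylIons = TRUE)
  expect_true(any(abs(fragments(spr)[, "mz"] - 146.05791) < 1e-4))
})

test_that("simulated tables are reproducible and satisfy the table invariants", {
  t1 <- simulateTables(synthDesign(), seed = 5)
  t2 <- simulateTables(synthDesign(), seed = 5)
  expect_identical(t1$areas, t2$areas)
  expect_identical(t1$ct, t2$ct)

  a <- t1$areas
  isRows <- a[a$compound_id == "formononetin", ]
  expect_identical(sort(unique(isRows$sample_id)), sort(unique(a$sample_id)))
  expect_true(all(isRows$area > 0))
  expect_true(all(a$area >= 0))
  expect_identical(as.integer(table(unique(a[, c("sample_id",
                                                 "stage")])$stage)),
                   rep(3L, 3))
  expect_true(all(t1$ct$ct > 0))
  expect_true("UBQ" %in% t1$ct$gene)
})

test_that("the latent factor drives correlations toward the design limit", {
  # all features ride one factor: as noise vanishes, pairwise rho -> 1
  d <- synthDesign(targetRho = 1 - 1e-12, lognormalSigma = 0, ctSigma = 0,
                   nMetabolites = 5)
  tabs <- simulateTables(d, seed = 11)
  ab <- log(assay(normalizeToIS(tabs$areas)))
  rho <- cor(t(ab))
  expect_true(all(rho > 1 - 1e-6))

  badSigma <- matrix(-0.9, 16, 16); diag(badSigma) <- 1
  expect_error(simulateTables(synthDesign(targetMatrix = badSigma), seed = 1),
               "positive semidefinite")
})
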