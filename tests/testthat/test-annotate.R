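lib <- defaultBlockLibrary()

test_that("precursor decomposition equals the brute-force lattice oracle", {
  set.seed(7)
  masses <- c(runif(200, 250, 1200), 595.16516, 271.06008, 741.22180)
  for (mz in masses) {
    got <- decompositionKeys(decomposePrecursor(mz, lib))
    expect_identical(got, oracleDecompose(mz), label = sprintf("m/z %.5f", mz))
  }
})

test_that("decomposition reproduces the published identifications and is sound", {
  cands <- decomposePrecursor(595.16516, lib)
  pel <- Filter(function(x) aglycone(x) == "pelargonidin", cands)
  expect_length(pel, 1)
  expect_identical(decorations(pel[[1]]), c("hexose", "hexose"))

  cands <- decomposePrecursor(271.06008, lib)
  expect_length(cands, 1)
  expect_identical(aglycone(cands[[1]]), "pelargonidin")
  expect_length(decorations(cands[[1]]), 0)

  expect_length(decomposePrecursor(100.0, lib), 0)

  # soundness: every emitted candidate is within tolerance of the query
  set.seed(11)
  for (mz in runif(50, 400, 1100)) {
    for (cc in decomposePrecursor(mz, lib))
      expect_lte(abs(cationMz(cc) - mz) / mz * 1e6, 5)
  }
})

test_that("widening the precursor tolerance never removes a candidate", {
  set.seed(13)
  for (mz in runif(30, 300, 1100)) {
    narrow <- decompositionKeys(
      decomposePrecursor(mz, lib, annotationParams(precursorTolPpm = 3)))
    wide <- decompositionKeys(
      decomposePrecursor(mz, lib, annotationParams(precursorTolPpm = 12)))
    expect_true(all(narrow %in% wide))
  }
})

test_that("fragments are explained as residue losses and free glycosyl ions", {
  # published peak 1 walk-through: rutinoside-glucoside of pelargonidin
  comp <- composeBlocks("pelargonidin",
                        c("hexose", "hexose", "deoxyhexose"), lib)
  expl <- explainFragments(comp, c(579.16992, 433.11237, 271.05966), lib)
  expect_true(all(expl$explained))
  expect_identical(expl$loss,
                   c("-[hexose]", "-[deoxyhexose+hexose]",
                     "-[deoxyhexose+hexose+hexose]"))

  # published peak 3: free rhamnose residue ion at 146.05790
  rut <- composeBlocks("pelargonidin", c("hexose", "deoxyhexose"), lib)
  expl <- explainFragments(rut, c(146.05790), lib)
  expect_identical(expl$type, "residue")
  expect_true(expl$explained)

  # a bare aglycone explains nothing but its own ion
  bare <- composeBlocks("pelargonidin", character(0), lib)
  expl <- explainFragments(bare, c(271.06010, 180.0, 350.0), lib)
  expect_identical(expl$explained, c(TRUE, FALSE, FALSE))
  expect_identical(expl$loss[1], "[M]+")
})

test_that("the aglycone diagnostic picks the closest flavylium ion", {
  expect_identical(detectAglycone(c(433.11273, 271.05972), lib),
                   "pelargonidin")
  expect_identical(detectAglycone(287.0550, lib), "cyanidin")
  expect_true(is.na(detectAglycone(c(100.0, 200.0), lib)))
  expect_true(is.na(detectAglycone(numeric(0), lib)))
})

test_that("the E440/Emax rule separates 3- from 3,5-glycosides", {
  expect_identical(classifyUV(list(e440OverEmax = 52)), "3-glycoside")
  expect_identical(classifyUV(list(e440OverEmax = 25)), "3,5-glycoside")
  expect_identical(classifyUV(list(e440OverEmax = 35)), "ambiguous")
  expect_error(classifyUV(list(e440OverEmax = 101)), "0, 100")
  expect_error(classifyUV(list()), "no e440OverEmax")
})

test_that("spectrum annotation ranks by fragment explanation then mass error", {
  sp2 <- spectrum("peak2", 595.16516, c(433.11273, 271.05972),
                  uv = list(lambdaMax = c(282, 497), e440OverEmax = 25))
  ann <- annotateSpectrum(sp2, lib)
  top <- bestCandidate(ann)
  expect_identical(aglycone(top$composition), "pelargonidin")
  expect_identical(decorations(top$composition), c("hexose", "hexose"))
  expect_equal(top$fragFraction, 1)
  expect_identical(ann@aglycone, "pelargonidin")
  expect_identical(ann@uvClass, "3,5-glycoside")

  # published peak 5: precursor inconsistent with any composition at 5 ppm,
  # but the fragment series still pins the aglycone (class-only fallback)
  sp5 <- spectrum("peak5", 1094.29358,
                  c(932.23883, 771.21368, 433.11273, 271.06000))
  ann5 <- annotateSpectrum(sp5, lib)
  expect_length(candidates(ann5), 0)
  expect_identical(ann5@aglycone, "pelargonidin")

  # bare aglycone precursor with no fragments: fraction defined as 1
  spb <- spectrum("bare", cationMass("C15H11O5"))
  annb <- annotateSpectrum(spb, lib)
  expect_identical(aglycone(bestCandidate(annb)$composition), "pelargonidin")
  expect_equal(bestCandidate(annb)$fragFraction, 1)
  expect_identical(annb@aglycone, "pelargonidin")
})

test_that("dataset annotation counts aglycone classes and rejects duplicate ids", {
  mgf <- readMGF(system.file("extdata", "gentian_petal_anthocyanins.mgf",
                             package = "anthoNet"))
  res <- annotateDataset(mgf, lib)
  expect_identical(res$summary$nSpectra, 11L)
  expect_identical(unname(res$summary$perAglycone[["pelargonidin"]]), 11L)

  expect_error(annotateDataset(list(mgf[[1]], mgf[[1]]), lib), "duplicate")

  empty <- annotateDataset(list(), lib)
  expect_identical(empty$summary$nSpectra, 0L)
  expect_length(empty$annotations, 0)
})

test_that("noiseless simulated spectra are recovered up to exact mass degeneracy", {
  structures <- sampleStructures(50, lib, seed = 5)
  for (i in seq_along(structures)) {
    truth <- structures[[i]]
    sp <- simulateSpectrum(truth, lib, mzSigmaPpm = 0,
                           freeGlycosylIons = TRUE,
                           spectrumId = paste0("s", i))
    top <- bestCandidate(annotateSpectrum(sp, lib))
    hit <- identical(aglycone(top$composition), aglycone(truth)) &&
      identical(decorations(top$composition), decorations(truth))
    if (hit) {
      succeed()
    } else {
      # the only admissible misses are elemental twins whose predicted
      # fragment set coincides exactly with the truth's: same exact cation
      # m/z, every fragment explained, and every decoration residue
      # evidenced -- information-theoretically indistinguishable
      expect_equal(cationMz(top$composition), cationMz(truth),
                   tolerance = 1e-9)
      expect_identical(top$fragFraction, 1)
      expl <- explainFragments(top$composition, fragments(sp)[, "mz"],
                               lib, annotationParams())
      expect_identical(anthoNet:::decorationCoverage(top$composition, expl),
                       1)
    }
  }
})
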