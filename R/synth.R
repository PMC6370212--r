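#' @include AllClasses.R blockLibrary.R annotate.R
NULL

#' Synthetic study design
#'
#' Describes the simulated experiment: three petal developmental stages
#' (S1 budlet, S3 mature bud, S5 open flower) with three biological
#' replicates each, eleven decorated-anthocyanin metabolites and five
#' biosynthesis transcripts whose log levels are driven by one shared
#' latent factor (a stage trend plus sample noise). The latent pairwise
#' correlation between any two features equals \code{targetRho}; lognormal
#' noise on peak areas and Gaussian noise on Ct values sit on top as
#' measurement layers.
#'
#' @param stages stage labels, in developmental order.
#' @param nReps biological replicates per stage.
#' @param nMetabolites number of simulated metabolites.
#' @param genes transcript ids (the housekeeping gene is added separately).
#' @param targetRho latent pairwise correlation between feature log levels
#'   (scalar, default 0.76), or alternatively supply \code{targetMatrix}.
#' @param targetMatrix optional full positive-semidefinite target
#'   correlation matrix (features = metabolites then genes); overrides
#'   \code{targetRho}. With a full matrix the stage trend enters as
#'   per-feature mean shifts instead of through the shared factor.
#' @param latentSd standard deviation of feature log levels (natural log);
#'   1.2 spans roughly a 30-fold abundance range across samples.
#' @param trendNoiseSd sample-level noise of the latent factor around the
#'   stage trend.
#' @param lognormalSigma multiplicative (natural-log) noise on peak areas.
#' @param ctSigma additive Gaussian noise on Ct values (cycles).
#' @param mzSigmaPpm m/z error for simulated spectra (ppm).
#' @param isArea internal-standard base peak area.
#' @param techReps qPCR technical replicates.
#' @param curveSlope,curveIntercept standard-curve truth shared by all
#'   genes (slope -3.3219 is a perfect doubling).
#' @return a list of class \code{synthDesign}.
#' @export
synthDesign <- function(stages = c("S1", "S3", "S5"), nReps = 3,
                        nMetabolites = 11,
                        genes = c("DFR", "ANS", "GT3", "GT5", "AT5"),
                        targetRho = 0.76, targetMatrix = NULL,
                        latentSd = 1.2, trendNoiseSd = 0.5,
                        lognormalSigma = 0.25, ctSigma = 0.2,
                        mzSigmaPpm = 2, isArea = 1e6, techReps = 3,
                        curveSlope = -3.3219, curveIntercept = 21) {
  d <- list(stages = stages, nReps = nReps, nMetabolites = nMetabolites,
            genes = genes, targetRho = targetRho,
            targetMatrix = targetMatrix, latentSd = latentSd,
            trendNoiseSd = trendNoiseSd, lognormalSigma = lognormalSigma,
            ctSigma = ctSigma, mzSigmaPpm = mzSigmaPpm, isArea = isArea,
            techReps = techReps, curveSlope = curveSlope,
            curveIntercept = curveIntercept)
  class(d) <- "synthDesign"
  d
}

#' Sample distinct anthocyanin compositions
#'
#' Draws \code{n} distinct compositions uniformly from the bounded
#' decoration lattice (aglycone uniform over \code{aglycones}; by default
#' pelargonidin only, mirroring an orange-petal pigment profile).
#'
#' @param n number of structures.
#' @param library a [BuildingBlockLibrary-class].
#' @param seed RNG seed (integer); reproducible draws.
#' @param maxGlycosyl,maxAcyl decoration-count bounds.
#' @param aglycones aglycone ids to draw from.
#' @return list of [Composition-class] with unique multisets.
#' @export
sampleStructures <- function(n, library = defaultBlockLibrary(), seed = NULL,
                             maxGlycosyl = 4L, maxAcyl = 3L,
                             aglycones = "pelargonidin") {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  lattice <- decorationLattice(library, maxGlycosyl, maxAcyl)
  combos <- expand.grid(ag = aglycones, row = seq_len(nrow(lattice)),
                        stringsAsFactors = FALSE)
  if (n > nrow(combos))
    stop("bounds admit only ", nrow(combos), " distinct compositions, ",
         n, " requested")
  pick <- sample(nrow(combos), n)
  lapply(pick, function(i)
    composeBlocks(combos$ag[i],
                  countsToMultiset(lattice[combos$row[i], ]), library))
}

#' Simulate an MS/MS spectrum for a composition
#'
#' Ground-truth fragments are one ion per single-residue loss plus the
#' full-decoration loss (the bare aglycone ion), optionally the free
#' glycosyl residue ions, plus \code{nDecoys} uniform random decoy peaks.
#' All m/z values carry multiplicative Gaussian error of
#' \code{mzSigmaPpm} ppm; intensities follow a decreasing lognormal
#' profile. Note the generator's fragmentation model is narrower than the
#' annotator's (which admits any loss sub-multiset) — deliberately, so
#' recovery tests do not test the engine against itself.
#'
#' @param composition a [Composition-class].
#' @param library a [BuildingBlockLibrary-class].
#' @param mzSigmaPpm m/z error (ppm); 0 for noiseless spectra.
#' @param nDecoys number of random decoy peaks.
#' @param freeGlycosylIons also emit free glycosyl residue ions.
#' @param seed RNG seed.
#' @param spectrumId id for the spectrum.
#' @return a [Spectrum-class].
#' @export
simulateSpectrum <- function(composition, library = defaultBlockLibrary(),
                             mzSigmaPpm = 2, nDecoys = 0,
                             freeGlycosylIons = FALSE, seed = NULL,
                             spectrumId = "synthetic") {
  if (!is.null(seed)) set.seed(seed)
  dec <- composition@decorations
  mz <- numeric(0)
  for (id in unique(dec))
    mz <- c(mz, composition@cationMz - residueMass(library, id))
  if (length(dec))
    mz <- c(mz, composition@cationMz - lossMass(dec, library))
  if (freeGlycosylIons) {
    b <- blocks(library)
    glyc <- unique(dec[dec %in% b$id[b$class == "glycosyl"]])
    if (length(glyc)) mz <- c(mz, unname(residueMass(library, glyc)))
  }
  mz <- sort(unique(round(mz, 9)), decreasing = TRUE)
  if (nDecoys > 0)
    mz <- c(mz, stats::runif(nDecoys, 150,
                             max(composition@cationMz - 50, 160)))
  prec <- composition@cationMz *
    (1 + stats::rnorm(1, 0, mzSigmaPpm * 1e-6))
  mz <- mz * (1 + stats::rnorm(length(mz), 0, mzSigmaPpm * 1e-6))
  inten <- if (length(mz))
    1000 * 0.5^(seq_along(mz) - 1) * exp(stats::rnorm(length(mz), 0, 0.3))
  else numeric(0)
  spectrum(spectrumId, prec, mz, inten)
}

#' Simulate stage-structured peak-area and Ct tables with known truth
#'
#' One shared latent factor (stage trend plus sample noise, standardized)
#' drives both metabolite log abundances and transcript log quantities
#' with loading \code{sqrt(targetRho)}, so any two feature log levels have
#' latent correlation \code{targetRho}. Peak areas split each metabolite's
#' signal over two quantifier fragments (60/40) with lognormal noise; the
#' internal standard is constant up to the same noise. Ct values come from
#' the per-gene standard curve with Gaussian cycle noise; the housekeeping
#' gene UBQ sits at constant quantity 1.
#'
#' @param design a [synthDesign()] list.
#' @param seed RNG seed.
#' @return list with \code{areas} (long peak-area data.frame),
#'   \code{ct} (long Ct data.frame), \code{curves} (named list of
#'   [StandardCurve-class] truth), \code{dilutionData} (simulated dilution
#'   series per gene) and \code{truth} (latent factor, true abundances,
#'   true expression, seed, design).
#' @export
simulateTables <- function(design = synthDesign(), seed = 1) {
  set.seed(seed)
  st <- design$stages
  nR <- design$nReps
  samples <- paste(rep(st, each = nR), seq_len(nR), sep = "_")
  stage <- rep(st, each = nR)
  repl <- rep(seq_len(nR), length(st))
  nS <- length(samples)
  mets <- sprintf("met%02d", seq_len(design$nMetabolites))
  genes <- design$genes
  feats <- c(mets, genes)
  nF <- length(feats)

  if (!is.null(design$targetMatrix)) {
    Sg <- design$targetMatrix
    if (nrow(Sg) != nF || ncol(Sg) != nF)
      stop("targetMatrix must be ", nF, " x ", nF)
    ev <- eigen(Sg, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop("target correlation matrix is not positive semidefinite")
    L <- chol(Sg + diag(1e-10, nF))
    Z <- t(L) %*% matrix(stats::rnorm(nF * nS), nF, nS)
    trendShift <- outer(rep(0, nF),
                        as.numeric(factor(stage, levels = st)) - 2)
    X <- Z + trendShift
    f <- rep(NA_real_, nS)
  } else {
    rho <- design$targetRho
    if (rho < 0 || rho >= 1) stop("targetRho must lie in [0, 1)")
    trend <- as.numeric(factor(stage, levels = st)) - 2  # -1, 0, 1
    f <- trend + stats::rnorm(nS, 0, design$trendNoiseSd)
    f <- (f - mean(f)) / stats::sd(f)
    E <- matrix(stats::rnorm(nF * nS), nF, nS)
    X <- sqrt(rho) * matrix(f, nF, nS, byrow = TRUE) + sqrt(1 - rho) * E
  }
  dimnames(X) <- list(feats, samples)

  logLevel <- design$latentSd * X
  trueAbund <- exp(logLevel[mets, , drop = FALSE])
  trueExpr <- exp(logLevel[genes, , drop = FALSE])

  # peak-area table: two quantifier fragments per compound plus the IS
  split <- c(0.6, 0.4)
  rows <- list()
  for (s in seq_len(nS)) {
    for (m in mets) {
      for (r in 1:2) {
        a <- trueAbund[m, s] * design$isArea * split[r] *
          exp(stats::rnorm(1, 0, design$lognormalSigma))
        rows[[length(rows) + 1L]] <- data.frame(
          compound_id = m, sample_id = samples[s], stage = stage[s],
          replicate = repl[s], fragment_rank = r, area = a)
      }
    }
    for (r in 1:2) {
      a <- design$isArea * split[r] *
        exp(stats::rnorm(1, 0, design$lognormalSigma))
      rows[[length(rows) + 1L]] <- data.frame(
        compound_id = "formononetin", sample_id = samples[s],
        stage = stage[s], replicate = repl[s], fragment_rank = r, area = a)
    }
  }
  areas <- do.call(rbind, rows)

  # Ct table: standard-curve truth shared across genes, UBQ at quantity 1
  ctRows <- list()
  for (s in seq_len(nS)) {
    for (g in c(genes, "UBQ")) {
      q <- if (g == "UBQ") 1 else trueExpr[g, s]
      baseCt <- design$curveIntercept + design$curveSlope * log10(q)
      for (tr in seq_len(design$techReps)) {
        ctRows[[length(ctRows) + 1L]] <- data.frame(
          gene = g, sample = paste(samples[s], tr, sep = "."),
          tissue = stage[s], bio_rep = repl[s], tech_rep = tr,
          ct = baseCt + stats::rnorm(1, 0, design$ctSigma))
      }
    }
  }
  ct <- do.call(rbind, ctRows)

  dil <- c(100, 20, 4, 0.8, 0.16)
  curves <- list()
  dilutionData <- list()
  for (g in c(genes, "UBQ")) {
    curves[[g]] <- new("StandardCurve", gene = g, slope = design$curveSlope,
                       intercept = design$curveIntercept, rSquared = 1,
                       efficiency = 10^(-1 / design$curveSlope) - 1)
    dilutionData[[g]] <- data.frame(
      gene = g, dilution_ng = dil,
      ct = design$curveIntercept + design$curveSlope * log10(dil) +
        stats::rnorm(length(dil), 0, design$ctSigma))
  }

  list(areas = areas, ct = ct, curves = curves,
       dilutionData = do.call(rbind, dilutionData),
       truth = list(seed = seed, design = design, latentFactor = f,
                    trueAbundances = trueAbund, trueExpression = trueExpr))
}

#' Write a full synthetic bundle to disk
#'
#' Emits spectra (MGF), peak areas, Ct values and dilution series (CSV),
#' and a truth manifest (JSON) for a simulated study.
#'
#' @param dir output directory.
#' @param design a [synthDesign()].
#' @param nStructures number of decorated structures to simulate spectra
#'   for.
#' @param seed RNG seed governing every stochastic step.
#' @param library a [BuildingBlockLibrary-class].
#' @return invisibly, the list of paths written.
#' @export
writeSyntheticBundle <- function(dir, design = synthDesign(),
                                 nStructures = 20, seed = 1,
                                 library = defaultBlockLibrary()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  structures <- sampleStructures(nStructures, library, seed = seed)
  spectra <- lapply(seq_along(structures), function(i)
    simulateSpectrum(structures[[i]], library,
                     mzSigmaPpm = design$mzSigmaPpm, nDecoys = 3,
                     spectrumId = sprintf("synth%03d", i)))
  tabs <- simulateTables(design, seed = seed + 1L)
  pM <- file.path(dir, "spectra.mgf"); writeMGF(spectra, pM)
  pA <- file.path(dir, "areas.csv")
  utils::write.csv(tabs$areas, pA, row.names = FALSE)
  pC <- file.path(dir, "ct.csv")
  utils::write.csv(tabs$ct, pC, row.names = FALSE)
  pD <- file.path(dir, "dilutions.csv")
  utils::write.csv(tabs$dilutionData, pD, row.names = FALSE)
  pT <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(seed = seed,
         structures = lapply(structures, function(x) list(
           aglycone = x@aglycone, decorations = as.list(x@decorations),
           formula = hillFormula(x@totalFormula), cation_mz = x@cationMz)),
         true_abundances = as.data.frame(tabs$truth$trueAbundances),
         true_expression = as.data.frame(tabs$truth$trueExpression)),
    pT, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(mgf = pM, areas = pA, ct = pC, dilutions = pD, truth = pT))
}
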