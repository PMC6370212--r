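#' @import methods
NULL

#' Building-block library for decorated anthocyanins
#'
#' Holds the aglycone, glycosyl and acyl blocks from which candidate
#' anthocyanin compositions are assembled. For glycosyl and acyl blocks the
#' stored formula is the residue: the free molecule minus the water lost on
#' glycosidic/ester condensation. For aglycones it is the full flavylium
#' cation formula.
#'
#' @slot blocks data.frame with columns \code{id}, \code{class} (one of
#'   aglycone/glycosyl/acyl), \code{formula} (Hill notation) and
#'   \code{residueMass} (monoisotopic Da, recomputed on construction).
#' @slot version character, free-form library version tag.
#' @export
setClass("BuildingBlockLibrary",
  representation(blocks = "data.frame", version = "character"))

setValidity("BuildingBlockLibrary", function(object) {
  b <- object@blocks
  need <- c("id", "class", "formula", "residueMass")
  if (!all(need %in% names(b)))
    return(paste("blocks must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(b$id)) return("duplicate block ids")
  if (!all(b$class %in% c("aglycone", "glycosyl", "acyl")))
    return("block class must be aglycone, glycosyl or acyl")
  if (!any(b$class == "aglycone")) return("library needs at least one aglycone")
  recomputed <- vapply(b$formula, formulaMass, numeric(1))
  if (any(abs(recomputed - b$residueMass) > 1e-6))
    return("residueMass inconsistent with formula (tolerance 1e-6 Da)")
  # near-identical residue masses are only tolerated across classes
  for (cl in unique(b$class)) {
    m <- sort(b$residueMass[b$class == cl])
    if (length(m) > 1 && any(diff(m) < 0.001))
      return(paste("two", cl, "blocks share a residue mass within 0.001 Da"))
  }
  TRUE
})

#' Anthocyanin composition (aglycone plus decoration multiset)
#'
#' A composition is a multiset, not a structure: positional isomers and
#' linkage topology are deliberately collapsed, because exact mass cannot
#' distinguish them.
#'
#' @slot aglycone id of the aglycone block.
#' @slot decorations sorted character vector of glycosyl/acyl block ids
#'   (multiset; repeats allowed).
#' @slot totalFormula named integer vector of element counts.
#' @slot cationMz theoretical \eqn{[M]^+} m/z (electron-corrected).
#' @export
setClass("Composition",
  representation(aglycone = "character", decorations = "character",
                 totalFormula = "integer", cationMz = "numeric"))

setValidity("Composition", function(object) {
  if (length(object@aglycone) != 1L) return("exactly one aglycone")
  if (is.unsorted(object@decorations)) return("decorations must be sorted")
  mz <- formulaMass(object@totalFormula) - .ELECTRON_MASS
  if (abs(mz - object@cationMz) > 1e-6)
    return("cationMz inconsistent with totalFormula")
  TRUE
})

#' Tandem mass spectrum of a singly charged positive ion
#'
#' @slot spectrumId character identifier.
#' @slot precursorMz precursor m/z (Da), charge 1+.
#' @slot retentionTime minutes; \code{NA} if unknown.
#' @slot fragments two-column numeric matrix (\code{mz}, \code{intensity}).
#' @slot uv list with \code{lambdaMax} (nm) and \code{e440OverEmax}
#'   (percent), or an empty list when no UV/DAD record is attached.
#' @export
setClass("Spectrum",
  representation(spectrumId = "character", precursorMz = "numeric",
                 retentionTime = "numeric", fragments = "matrix",
                 uv = "list"))

setValidity("Spectrum", function(object) {
  if (object@precursorMz <= 0) return("precursorMz must be > 0")
  fr <- object@fragments
  if (ncol(fr) != 2L) return("fragments must have columns mz, intensity")
  if (nrow(fr)) {
    if (any(fr[, 1] >= object@precursorMz + 0.5))
      return("fragment m/z must be < precursorMz + 0.5")
    if (any(fr[, 2] < 0)) return("fragment intensities must be >= 0")
  }
  if (length(object@uv)) {
    r <- object@uv$e440OverEmax
    if (!is.null(r) && (r < 0 || r > 100))
      return("e440OverEmax must lie in [0, 100]")
    lm <- object@uv$lambdaMax
    if (!is.null(lm) && length(lm) && any(lm < 200 | lm > 600))
      return("lambdaMax must lie in [200, 600] nm")
  }
  TRUE
})

#' Annotation parameters
#'
#' @slot precursorTolPpm precursor match tolerance (ppm, default 5).
#' @slot fragmentTolPpm fragment match tolerance (ppm, default 10).
#' @slot maxGlycosyl maximum number of glycosyl residues per candidate.
#' @slot maxAcyl maximum number of acyl residues per candidate.
#' @slot aglyconeWindowDa absolute window (Da) for the aglycone diagnostic
#'   ion, default 0.01.
#' @export
setClass("AnnotationParams",
  representation(precursorTolPpm = "numeric", fragmentTolPpm = "numeric",
                 maxGlycosyl = "integer", maxAcyl = "integer",
                 aglyconeWindowDa = "numeric"))

setValidity("AnnotationParams", function(object) {
  if (object@precursorTolPpm <= 0 || object@fragmentTolPpm <= 0 ||
      object@aglyconeWindowDa <= 0)
    return("tolerances must be > 0")
  if (object@maxGlycosyl < 0 || object@maxAcyl < 0)
    return("decoration bounds must be >= 0")
  TRUE
})

#' Spectrum annotation result
#'
#' @slot spectrumId id of the annotated spectrum.
#' @slot candidates list of candidate records, each a list with elements
#'   \code{composition} (a [Composition]), \code{ppmError},
#'   \code{fragFraction} and \code{coverage}; ranked best-first.
#' @slot fragmentExplanations data.frame, one row per fragment, with the
#'   matched loss multiset (or free-residue ion), theoretical m/z, ppm error
#'   and an \code{explained} flag, for the top candidate.
#' @slot aglycone detected aglycone id, or \code{NA_character_}.
#' @slot uvClass one of 3-glycoside / 3,5-glycoside / ambiguous / absent.
#' @slot displayName conventional label for the top candidate (cosmetic).
#' @export
setClass("Annotation",
  representation(spectrumId = "character", candidates = "list",
                 fragmentExplanations = "data.frame", aglycone = "character",
                 uvClass = "character", displayName = "character"))

#' qRT-PCR standard curve
#'
#' Least-squares line of Ct on log10(template ng); amplification efficiency
#' is \eqn{10^{-1/slope} - 1}.
#'
#' @slot gene gene id.
#' @slot slope Ct per log10 ng (negative for a valid dilution series).
#' @slot intercept Ct at 1 ng.
#' @slot rSquared coefficient of determination of the fit.
#' @slot efficiency amplification efficiency (1 = perfect doubling).
#' @export
setClass("StandardCurve",
  representation(gene = "character", slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", efficiency = "numeric"))

#' Pairwise Pearson correlation result with significance mask
#'
#' @slot rho symmetric matrix of Pearson coefficients.
#' @slot pval symmetric matrix of two-sided p-values from the t statistic
#'   \eqn{\rho\sqrt{(n-2)/(1-\rho^2)}} on n-2 df.
#' @slot significant logical mask, \code{p <= alpha}, diagonal FALSE.
#' @slot alpha significance level used for the mask.
#' @slot nSamples number of samples the correlations were computed over.
#' @slot featureType named character vector tagging each feature (e.g.
#'   transcript / metabolite); may be empty.
#' @export
setClass("CorrelationResult",
  representation(rho = "matrix", pval = "matrix", significant = "matrix",
                 alpha = "numeric", nSamples = "integer",
                 featureType = "character"))

setValidity("CorrelationResult", function(object) {
  r <- object@rho
  if (nrow(r) != ncol(r)) return("rho must be square")
  if (max(abs(r - t(r))) > 1e-12) return("rho must be symmetric")
  if (any(abs(diag(r) - 1) > 1e-12)) return("rho diagonal must be 1")
  if (!identical(dim(object@pval), dim(r)) ||
      !identical(dim(object@significant), dim(r)))
    return("pval/significant dimensions must match rho")
  if (any(object@significant != t(object@significant)))
    return("significance mask must be symmetric")
  TRUE
})

#' Correlation-network summary (edges, node strength, network strength)
#'
#' @slot edges data.frame with columns source, target, rho: significant
#'   pairs whose |rho| passes the display threshold.
#' @slot ns named numeric: per-node strength (mean |rho| over the node's
#'   significant pairs; 0 when a node has none).
#' @slot NS network strength: the mean of the node strengths.
#' @slot displayThreshold the |rho| display cutoff used for \code{edges}.
#' @export
setClass("NetworkSummary",
  representation(edges = "data.frame", ns = "numeric", NS = "numeric",
                 displayThreshold = "numeric"))
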