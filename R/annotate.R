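#' @include AllClasses.R AllGenerics.R blockLibrary.R spectrum.R
NULL

#' Construct annotation parameters
#'
#' Defaults (5 ppm precursor, 10 ppm fragment) reflect the sub-3 ppm mass
#' accuracy typical of high-resolution ESI instruments; decoration bounds
#' cap the combinatorial search at four glycosyl and three acyl residues,
#' generous for petal anthocyanins.
#'
#' @param precursorTolPpm precursor tolerance, ppm.
#' @param fragmentTolPpm fragment tolerance, ppm.
#' @param maxGlycosyl,maxAcyl decoration-count bounds for the search.
#' @param aglyconeWindowDa absolute window for the aglycone diagnostic ion.
#' @return an [AnnotationParams-class].
#' @export
annotationParams <- function(precursorTolPpm = 5, fragmentTolPpm = 10,
                             maxGlycosyl = 4L, maxAcyl = 3L,
                             aglyconeWindowDa = 0.01) {
  new("AnnotationParams", precursorTolPpm = precursorTolPpm,
      fragmentTolPpm = fragmentTolPpm, maxGlycosyl = as.integer(maxGlycosyl),
      maxAcyl = as.integer(maxAcyl), aglyconeWindowDa = aglyconeWindowDa)
}

# All decoration count vectors (one entry per block id) with class-wise
# totals within bounds, enumerated by depth-first descent. Returns a matrix
# with one column per block id.
decorationLattice <- function(library, maxGlycosyl, maxAcyl) {
  b <- blocks(library)
  dec <- b[b$class != "aglycone", , drop = FALSE]
  caps <- ifelse(dec$class == "glycosyl", maxGlycosyl, maxAcyl)
  out <- list()
  rec <- function(i, counts, gUsed, aUsed) {
    if (i > nrow(dec)) {
      out[[length(out) + 1L]] <<- counts
      return(invisible(NULL))
    }
    cap <- if (dec$class[i] == "glycosyl") maxGlycosyl - gUsed
           else maxAcyl - aUsed
    for (k in 0:cap) {
      counts[i] <- k
      rec(i + 1L, counts,
          gUsed + if (dec$class[i] == "glycosyl") k else 0L,
          aUsed + if (dec$class[i] == "acyl") k else 0L)
    }
  }
  rec(1L, integer(nrow(dec)), 0L, 0L)
  m <- do.call(rbind, out)
  colnames(m) <- dec$id
  m
}

# counts (named) -> sorted multiset character vector
countsToMultiset <- function(counts) {
  sort(rep(names(counts), counts))
}

#' Enumerate compositions matching a precursor m/z
#'
#' Exhaustively searches aglycone + decoration multisets (within the
#' decoration bounds of \code{params}) whose theoretical electron-corrected
#' cation m/z lies within \code{precursorTolPpm} of the query. The result is
#' deterministic: sorted by absolute ppm error, then by total block count,
#' then lexicographically by aglycone and decoration ids.
#'
#' @param mz query precursor m/z.
#' @param library a [BuildingBlockLibrary-class].
#' @param params an [AnnotationParams-class].
#' @return list of [Composition-class] candidates (possibly empty).
#' @export
decomposePrecursor <- function(mz, library, params = annotationParams()) {
  stopifnot(is.numeric(mz), length(mz) == 1L, mz > 0)
  b <- blocks(library)
  ags <- b[b$class == "aglycone", , drop = FALSE]
  lattice <- decorationLattice(library, params@maxGlycosyl, params@maxAcyl)
  decMass <- as.numeric(lattice %*% b[colnames(lattice), "residueMass"])
  tol <- mz * params@precursorTolPpm * 1e-6
  cand <- list()
  for (i in seq_len(nrow(ags))) {
    agMz <- cationMass(ags$formula[i])
    hit <- which(abs(agMz + decMass - mz) <= tol)
    for (j in hit) {
      cand[[length(cand) + 1L]] <- composeBlocks(
        ags$id[i], countsToMultiset(lattice[j, ]), library)
    }
  }
  if (!length(cand)) return(list())
  ppm <- vapply(cand, function(x) (x@cationMz - mz) / mz * 1e6, numeric(1))
  nblk <- vapply(cand, function(x) length(x@decorations) + 1L, integer(1))
  key <- vapply(cand, compositionKey, character(1))
  cand[order(abs(ppm), nblk, key)]
}

# every sub-multiset of a decoration multiset, as a list of count vectors
subMultisets <- function(decorations) {
  if (!length(decorations)) {
    m <- matrix(integer(0), nrow = 1, ncol = 0)
    return(m)
  }
  tab <- table(decorations)
  grid <- do.call(expand.grid, lapply(as.integer(tab), function(k) 0:k))
  m <- as.matrix(grid)
  colnames(m) <- names(tab)
  m
}

#' Explain fragment ions of a spectrum given a candidate composition
#'
#' Each fragment is matched against (a) the theoretical precursor minus
#' every sub-multiset of the decoration multiset — any combination of
#' residue losses is admitted, because linkage topology is unknown — and
#' (b) the free-residue ion of each glycosyl in the composition (e.g.
#' rhamnose at 146.058). The smallest-|ppm| match within
#' \code{fragmentTolPpm} wins; anything else is labelled unexplained.
#'
#' @param composition a [Composition-class].
#' @param fragmentMz numeric vector of fragment m/z values.
#' @param library the [BuildingBlockLibrary-class] the composition was built
#'   from.
#' @param params an [AnnotationParams-class].
#' @return data.frame with columns \code{fragmentMz}, \code{type} (loss /
#'   residue / unexplained), \code{loss} (multiset label), \code{theoreticalMz},
#'   \code{ppmError}, \code{explained}.
#' @export
explainFragments <- function(composition, fragmentMz, library,
                             params = annotationParams()) {
  if (!length(fragmentMz))
    return(data.frame(fragmentMz = numeric(0), type = character(0),
                      loss = character(0), theoreticalMz = numeric(0),
                      ppmError = numeric(0), explained = logical(0),
                      stringsAsFactors = FALSE))
  losses <- subMultisets(composition@decorations)
  lossMz <- composition@cationMz -
    as.numeric(if (ncol(losses)) losses %*% residueMass(library, colnames(losses))
               else rep(0, nrow(losses)))
  lossLabel <- apply(losses, 1, function(ct) {
    ms <- countsToMultiset(ct)
    if (!length(ms)) "[M]+" else paste0("-[", paste(ms, collapse = "+"), "]")
  })
  if (!nrow(losses)) { lossMz <- composition@cationMz; lossLabel <- "[M]+" }
  glyc <- unique(composition@decorations[
    composition@decorations %in%
      blocks(library)$id[blocks(library)$class == "glycosyl"]])
  resMz <- if (length(glyc)) residueMass(library, glyc) else numeric(0)
  candMz <- c(lossMz, resMz)
  candLabel <- c(lossLabel, if (length(glyc)) paste0(glyc, " residue ion"))
  candType <- c(rep("loss", length(lossMz)), rep("residue", length(resMz)))
  out <- lapply(fragmentMz, function(fz) {
    ppm <- (fz - candMz) / candMz * 1e6
    best <- which.min(abs(ppm))
    if (length(best) && abs(ppm[best]) <= params@fragmentTolPpm)
      data.frame(fragmentMz = fz, type = candType[best],
                 loss = candLabel[best], theoreticalMz = candMz[best],
                 ppmError = ppm[best], explained = TRUE,
                 stringsAsFactors = FALSE)
    else
      data.frame(fragmentMz = fz, type = "unexplained", loss = NA_character_,
                 theoreticalMz = NA_real_, ppmError = NA_real_,
                 explained = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Detect the aglycone diagnostic ion
#'
#' Anthocyanin MS/MS spectra terminate in the bare flavylium aglycone ion
#' (m/z 271.06 for pelargonidin). Any fragment within
#' \code{aglyconeWindowDa} of a library aglycone's cation mass triggers the
#' diagnostic; with several matches the smallest absolute error wins.
#'
#' @param fragmentMz numeric vector of fragment m/z values.
#' @param library a [BuildingBlockLibrary-class].
#' @param params an [AnnotationParams-class].
#' @return aglycone id, or \code{NA_character_} when none matches.
#' @export
detectAglycone <- function(fragmentMz, library, params = annotationParams()) {
  b <- blocks(library)
  ags <- b[b$class == "aglycone", , drop = FALSE]
  if (!length(fragmentMz)) return(NA_character_)
  agMz <- vapply(ags$formula, cationMass, numeric(1))
  err <- vapply(seq_len(nrow(ags)),
                function(i) min(abs(fragmentMz - agMz[i])), numeric(1))
  hit <- which(err <= params@aglyconeWindowDa)
  if (!length(hit)) return(NA_character_)
  ags$id[hit[which.min(err[hit])]]
}

#' Classify the glycosylation pattern from the E440/Emax ratio
#'
#' 3-O-glycosides absorb relatively more at 440 nm than 3,5-di-O-glycosides:
#' the E440/Emax ratio is roughly twice as large. The decision thresholds
#' (>= 40 percent: 3-glycoside; <= 30 percent: 3,5-glycoside; otherwise
#' ambiguous) bracket the canonical exemplars of 52 and 25 percent.
#'
#' @param uv list with element \code{e440OverEmax} (percent in [0, 100]).
#' @return one of \code{"3-glycoside"}, \code{"3,5-glycoside"},
#'   \code{"ambiguous"}.
#' @export
classifyUV <- function(uv) {
  r <- uv$e440OverEmax
  if (is.null(r) || is.na(r)) stop("uv record has no e440OverEmax")
  if (r < 0 || r > 100) stop("e440OverEmax must lie in [0, 100], got ", r)
  if (r >= 40) "3-glycoside" else if (r <= 30) "3,5-glycoside" else "ambiguous"
}

# fraction of a candidate's distinct decoration residues that appear in an
# explained proper-subset loss or free-residue ion; the full-decoration
# loss (the aglycone ion) is excluded because it carries no residue-level
# evidence
decorationCoverage <- function(composition, expl) {
  decTypes <- unique(composition@decorations)
  if (!length(decTypes)) return(1)
  covered <- character(0)
  nFull <- length(composition@decorations)
  for (i in seq_len(nrow(expl))) {
    if (!expl$explained[i]) next
    if (expl$type[i] == "residue") {
      covered <- c(covered, sub(" residue ion$", "", expl$loss[i]))
    } else if (expl$type[i] == "loss" && expl$loss[i] != "[M]+") {
      ids <- strsplit(sub("^-\\[(.*)\\]$", "\\1", expl$loss[i]), "\\+")[[1]]
      if (length(ids) < nFull) covered <- c(covered, ids)
    }
  }
  mean(decTypes %in% covered)
}

# conventional label table; purely cosmetic, never used in computation
.LABELS <- c(
  "hexose" = "3-O-glucoside",
  "hexose,hexose" = "3,5-O-diglucoside",
  "deoxyhexose,hexose" = "3-O-rutinoside",
  "deoxyhexose,hexose,hexose" = "3-O-rutinoside-5-O-glucoside",
  "hexose,malonyl" = "3-O-(6-O-malonylglucoside)",
  "hexose,hexose,malonyl" = "3-O-(6-O-malonylglucoside)-5-O-glucoside",
  "coumaroyl,hexose" = "3-O-(6-p-coumaroyl)glucoside",
  "coumaroyl,hexose,hexose,malonyl" =
    "3-O-(6-p-coumaroylglucoside)-5-O-(malonylglucoside)",
  "caffeoyl,hexose,hexose,malonyl" =
    "3-O-(6-O-caffeoylglucoside)-5-O-(malonylglucoside)",
  "coumaroyl,feruloyl,hexose,hexose,hexose" =
    "3-O-(feruloylglucosyl-coumaroylglucoside)-5-O-glucoside",
  "caffeoyl,feruloyl,hexose,hexose,hexose" =
    "3-O-(feruloylglucosyl-caffeoylglucoside)-5-O-glucoside"
)

#' Conventional display name for a composition
#'
#' Known decoration multisets get literature-style glycoside names (a
#' rutinoside, for instance, is mass-indistinguishable from separate hexose
#' and deoxyhexose attachments, so the label presumes the conventional
#' disaccharide); anything else falls back to an explicit block sum.
#'
#' @param composition a [Composition-class].
#' @return character scalar.
#' @export
displayName <- function(composition) {
  ag <- composition@aglycone
  agCap <- paste0(toupper(substring(ag, 1, 1)), substring(ag, 2))
  key <- paste(composition@decorations, collapse = ",")
  if (!nzchar(key)) {
    agCap
  } else if (key %in% names(.LABELS)) {
    paste(agCap, .LABELS[[key]])
  } else {
    tab <- table(composition@decorations)
    paste(agCap, "+", paste(tab, names(tab), collapse = " + "))
  }
}

#' Annotate a single spectrum
#'
#' Candidates from [decomposePrecursor()] are re-ranked by (1) descending
#' fraction of fragments explained, (2) descending decoration coverage —
#' the fraction of the candidate's distinct decoration residues evidenced
#' by an explained proper-subset loss or free-residue ion (the bare
#' aglycone ion evidences nothing, since every candidate predicts it at
#' the same m/z) — then (3) ascending absolute precursor ppm error, (4)
#' ascending block count, (5) lexicographic block ids. The coverage term
#' separates elemental-composition twins (e.g. caffeoyl+deoxyhexose
#' versus coumaroyl+hexose, both C15H16O7) whenever the fragment series
#' carries residue-level evidence; twins whose predicted fragment sets
#' coincide exactly remain genuinely indistinguishable. When no
#' composition passes the precursor tolerance but the aglycone diagnostic
#' fires, a class-only annotation (empty candidate list, aglycone set) is
#' emitted — the paper-world analogue of a peak whose printed precursor is
#' internally inconsistent but whose fragment series still pins the
#' aglycone.
#'
#' @param sp a [Spectrum-class].
#' @param library a [BuildingBlockLibrary-class].
#' @param params an [AnnotationParams-class].
#' @return an [Annotation-class].
#' @export
annotateSpectrum <- function(sp, library, params = annotationParams()) {
  fragMz <- fragments(sp)[, 1]
  cands <- decomposePrecursor(precursorMz(sp), library, params)
  recs <- lapply(cands, function(cc) {
    expl <- explainFragments(cc, fragMz, library, params)
    frac <- if (!length(fragMz)) 1 else mean(expl$explained)
    list(composition = cc,
         ppmError = (cc@cationMz - precursorMz(sp)) / precursorMz(sp) * 1e6,
         fragFraction = frac,
         coverage = decorationCoverage(cc, expl))
  })
  if (length(recs)) {
    ord <- order(-vapply(recs, `[[`, numeric(1), "fragFraction"),
                 -vapply(recs, `[[`, numeric(1), "coverage"),
                 abs(vapply(recs, `[[`, numeric(1), "ppmError")),
                 vapply(recs, function(r) length(r$composition@decorations),
                        integer(1)),
                 vapply(recs, function(r) compositionKey(r$composition),
                        character(1)))
    recs <- recs[ord]
  }
  expl <- if (length(recs))
    explainFragments(recs[[1]]$composition, fragMz, library, params)
  else
    data.frame(fragmentMz = fragMz, type = "unexplained",
               loss = NA_character_, theoreticalMz = NA_real_,
               ppmError = NA_real_, explained = FALSE,
               stringsAsFactors = FALSE)
  ag <- detectAglycone(fragMz, library, params)
  # a bare-aglycone precursor is itself diagnostic
  if (is.na(ag) && length(recs) &&
      !length(recs[[1]]$composition@decorations))
    ag <- recs[[1]]$composition@aglycone
  uvClass <- if (!length(sp@uv)) "absent" else classifyUV(sp@uv)
  name <- if (length(recs)) displayName(recs[[1]]$composition)
          else if (!is.na(ag)) paste0(ag, "-type (class-only)")
          else "unidentified"
  new("Annotation", spectrumId = spectrumId(sp), candidates = recs,
      fragmentExplanations = expl, aglycone = ag, uvClass = uvClass,
      displayName = name)
}

#' @rdname Annotation-class
#' @export
setMethod("candidates", "Annotation", function(x) x@candidates)

#' @describeIn Annotation-class top-ranked candidate record (or NULL).
#' @export
setMethod("bestCandidate", "Annotation", function(x) {
  if (length(x@candidates)) x@candidates[[1]] else NULL
})

setMethod("show", "Annotation", function(object) {
  cat("Annotation for spectrum ", object@spectrumId, "\n", sep = "")
  cat("  ", object@displayName, "\n", sep = "")
  cat("  candidates: ", length(object@candidates),
      "; aglycone: ", ifelse(is.na(object@aglycone), "none", object@aglycone),
      "; UV class: ", object@uvClass, "\n", sep = "")
  if (length(object@candidates)) {
    top <- object@candidates[[1]]
    cat(sprintf("  top: %s, %.2f ppm, %.0f%% fragments explained\n",
                hillFormula(top$composition@totalFormula), top$ppmError,
                100 * top$fragFraction))
  }
})

#' Annotate a set of spectra
#'
#' @param spectra list of [Spectrum-class] objects with unique ids.
#' @param library a [BuildingBlockLibrary-class].
#' @param params an [AnnotationParams-class].
#' @return list with \code{annotations} (list of [Annotation-class]) and
#'   \code{summary}: spectra per detected aglycone, and counts of
#'   full-composition, class-only and unidentified spectra.
#' @export
annotateDataset <- function(spectra, library, params = annotationParams()) {
  ids <- vapply(spectra, spectrumId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate spectrum id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  anns <- lapply(spectra, annotateSpectrum, library = library, params = params)
  ag <- vapply(anns, function(a) a@aglycone, character(1))
  full <- vapply(anns, function(a) length(a@candidates) > 0, logical(1))
  list(annotations = anns,
       summary = list(
         nSpectra = length(anns),
         perAglycone = table(ag[!is.na(ag)]),
         nFullComposition = sum(full),
         nClassOnly = sum(!full & !is.na(ag)),
         nUnidentified = sum(!full & is.na(ag))))
}

#' Flatten annotations into a report table
#'
#' One row per spectrum, mirroring the conventional identification-table
#' layout: id, retention time, experimental m/z, explained fragment m/z,
#' Hill formula, assignment label, precursor ppm error, UV class.
#'
#' @param annotations list of [Annotation-class] (or the result of
#'   [annotateDataset()]).
#' @param spectra the matching list of [Spectrum-class] (for rt and m/z).
#' @return data.frame.
#' @export
annotationTable <- function(annotations, spectra) {
  if (is.list(annotations) && !is.null(annotations$annotations))
    annotations <- annotations$annotations
  rows <- mapply(function(a, sp) {
    top <- bestCandidate(a)
    expl <- a@fragmentExplanations
    data.frame(
      spectrum_id = a@spectrumId,
      rt_min = sp@retentionTime,
      precursor_mz = precursorMz(sp),
      msms_explained = paste(
        sprintf("%.5f", expl$fragmentMz[expl$explained]), collapse = "/"),
      formula = if (is.null(top)) NA_character_
                else hillFormula(top$composition@totalFormula),
      assignment = a@displayName,
      ppm_error = if (is.null(top)) NA_real_ else top$ppmError,
      uv_class = a@uvClass,
      stringsAsFactors = FALSE)
  }, annotations, spectra, SIMPLIFY = FALSE)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write annotation outputs (TSV table plus JSON candidate report)
#'
#' @param annotations result of [annotateDataset()].
#' @param spectra the annotated spectra.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeAnnotationReport <- function(annotations, spectra, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "annotations.tsv")
  utils::write.table(annotationTable(annotations, spectra), tsv,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  js <- file.path(dir, "annotations.json")
  payload <- lapply(annotations$annotations, function(a) {
    list(spectrum_id = a@spectrumId,
         aglycone = if (is.na(a@aglycone)) NULL else a@aglycone,
         uv_class = a@uvClass,
         display_name = a@displayName,
         candidates = lapply(a@candidates, function(r) list(
           aglycone = r$composition@aglycone,
           decorations = as.list(r$composition@decorations),
           formula = hillFormula(r$composition@totalFormula),
           cation_mz = r$composition@cationMz,
           ppm_error = r$ppmError,
           fragments_explained_fraction = r$fragFraction)))
  })
  jsonlite::write_json(
    list(summary = annotations$summary[c("nSpectra", "nFullComposition",
                                         "nClassOnly", "nUnidentified")],
         annotations = payload),
    js, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(tsv, js))
}
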