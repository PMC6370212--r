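#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a Spectrum
#'
#' @param spectrumId identifier, unique within a dataset.
#' @param precursorMz precursor m/z (singly charged positive ion).
#' @param fragmentMz numeric vector of fragment m/z values.
#' @param fragmentIntensity matching intensities (arbitrary units); defaults
#'   to 100 for each fragment when not recorded.
#' @param retentionTime minutes, optional.
#' @param uv optional list with \code{lambdaMax} (nm vector) and
#'   \code{e440OverEmax} (percent).
#' @return a [Spectrum-class].
#' @export
spectrum <- function(spectrumId, precursorMz, fragmentMz = numeric(0),
                     fragmentIntensity = NULL, retentionTime = NA_real_,
                     uv = list()) {
  if (is.null(fragmentIntensity))
    fragmentIntensity <- rep(100, length(fragmentMz))
  fr <- cbind(mz = as.numeric(fragmentMz),
              intensity = as.numeric(fragmentIntensity))
  new("Spectrum", spectrumId = as.character(spectrumId),
      precursorMz = as.numeric(precursorMz),
      retentionTime = as.numeric(retentionTime),
      fragments = fr, uv = uv)
}

#' @rdname Spectrum-class
#' @export
setMethod("spectrumId", "Spectrum", function(x) x@spectrumId)
#' @rdname Spectrum-class
#' @export
setMethod("precursorMz", "Spectrum", function(x) x@precursorMz)
#' @rdname Spectrum-class
#' @export
setMethod("fragments", "Spectrum", function(x) x@fragments)

setMethod("show", "Spectrum", function(object) {
  cat("Spectrum ", object@spectrumId, ": [M]+ ",
      sprintf("%.5f", object@precursorMz), ", ",
      nrow(object@fragments), " fragment(s)", sep = "")
  if (!is.na(object@retentionTime))
    cat(", rt ", object@retentionTime, " min", sep = "")
  cat("\n")
})

#' Read spectra from a Mascot Generic Format (MGF) file
#'
#' Only singly charged positive ions are in the model: a \code{CHARGE} line
#' other than \code{1+} is rejected. \code{TITLE} carries the spectrum id,
#' \code{PEPMASS} the precursor m/z, \code{RTINSECONDS} (optional) the
#' retention time.
#'
#' @param path MGF file.
#' @return list of [Spectrum-class] objects.
#' @export
readMGF <- function(path) {
  lines <- readLines(path)
  spectra <- list()
  inBlock <- FALSE
  title <- NA_character_; pep <- NA_real_; rt <- NA_real_
  frag <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (ln == "BEGIN IONS") {
      if (inBlock) stop("malformed MGF: nested BEGIN IONS at line ", i)
      inBlock <- TRUE
      title <- NA_character_; pep <- NA_real_; rt <- NA_real_
      frag <- matrix(numeric(0), ncol = 2)
    } else if (ln == "END IONS") {
      if (!inBlock) stop("malformed MGF: END IONS without BEGIN at line ", i)
      if (is.na(pep)) stop("malformed MGF: block ending at line ", i,
                           " has no PEPMASS")
      if (is.na(title)) title <- paste0("spectrum_", length(spectra) + 1L)
      spectra[[length(spectra) + 1L]] <- spectrum(
        title, pep, frag[, 1], frag[, 2],
        retentionTime = rt / 60)
      inBlock <- FALSE
    } else if (inBlock) {
      if (grepl("^[A-Z]+=", ln)) {
        key <- sub("=.*$", "", ln)
        val <- sub("^[A-Z]+=", "", ln)
        if (key == "TITLE") title <- val
        else if (key == "PEPMASS")
          pep <- as.numeric(strsplit(val, "\\s+")[[1]][1])
        else if (key == "RTINSECONDS") rt <- as.numeric(val)
        else if (key == "CHARGE" && !val %in% c("1+", "+1"))
          stop("only singly charged positive ions are supported ",
               "(CHARGE=", val, " at line ", i, ")")
      } else {
        xs <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
        if (length(xs) < 1 || anyNA(xs))
          stop("malformed MGF peak line at line ", i, ": '", ln, "'")
        if (length(xs) == 1) xs <- c(xs, 100)
        frag <- rbind(frag, xs[1:2])
      }
    } else {
      stop("malformed MGF: content outside BEGIN/END IONS at line ", i)
    }
  }
  if (inBlock) stop("malformed MGF: unterminated final block")
  spectra
}

#' Write spectra to MGF
#'
#' m/z values are serialized with six decimals to preserve ppm-level
#' information.
#'
#' @param spectra list of [Spectrum-class] objects.
#' @param path output file.
#' @export
writeMGF <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", sp@spectrumId),
                 paste0("PEPMASS=", sprintf("%.6f", sp@precursorMz)),
                 "CHARGE=1+"), con)
    if (!is.na(sp@retentionTime))
      writeLines(paste0("RTINSECONDS=", sprintf("%.3f",
                                                sp@retentionTime * 60)), con)
    fr <- sp@fragments
    if (nrow(fr))
      writeLines(sprintf("%.6f %.6f", fr[, 1], fr[, 2]), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Read spectra from the long CSV dialect
#'
#' Columns: \code{spectrum_id}, \code{precursor_mz}, \code{fragment_mz},
#' \code{fragment_intensity} — one row per fragment. A spectrum with no
#' fragments is encoded by a single row with empty fragment fields.
#'
#' @param path CSV file.
#' @return list of [Spectrum-class] objects.
#' @export
readSpectraCSV <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("spectrum_id", "precursor_mz", "fragment_mz", "fragment_intensity")
  if (!all(need %in% names(d)))
    stop("spectra CSV needs columns ", paste(need, collapse = ", "))
  lapply(split(d, factor(d$spectrum_id, levels = unique(d$spectrum_id))),
         function(g) {
    keep <- !is.na(g$fragment_mz)
    spectrum(g$spectrum_id[1], g$precursor_mz[1],
             g$fragment_mz[keep], g$fragment_intensity[keep])
  })
}
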