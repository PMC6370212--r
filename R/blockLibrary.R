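#' @include AllClasses.R AllGenerics.R
NULL

.DEFAULT_BLOCKS <- data.frame(
  id = c("pelargonidin", "cyanidin", "delphinidin",
         "hexose", "deoxyhexose",
         "malonyl", "coumaroyl", "caffeoyl", "feruloyl"),
  class = c(rep("aglycone", 3), rep("glycosyl", 2), rep("acyl", 4)),
  formula = c("C15H11O5", "C15H11O6", "C15H11O7",
              "C6H10O5", "C6H10O4",
              "C3H2O3", "C9H6O2", "C9H6O3", "C10H8O3"),
  stringsAsFactors = FALSE
)

#' Construct a building-block library
#'
#' @param blocks data.frame with columns \code{id}, \code{class}
#'   (aglycone/glycosyl/acyl) and \code{formula} (Hill notation). Residue
#'   masses are always recomputed from the formulas, never taken on trust.
#' @param version version tag stored with the library.
#' @return a [BuildingBlockLibrary-class] object.
#' @export
buildingBlockLibrary <- function(blocks, version = "1") {
  blocks <- as.data.frame(blocks, stringsAsFactors = FALSE)
  blocks$residueMass <- vapply(blocks$formula, formulaMass, numeric(1))
  rownames(blocks) <- blocks$id
  new("BuildingBlockLibrary", blocks = blocks, version = as.character(version))
}

#' Default anthocyanin building-block library
#'
#' Aglycones: pelargonidin, cyanidin, delphinidin (flavylium cation
#' formulas). Glycosyl residues: hexose and deoxyhexose (free sugar minus
#' one water). Acyl residues: malonyl, coumaroyl, caffeoyl, feruloyl (free
#' acid minus one water).
#'
#' @return a [BuildingBlockLibrary-class] with the nine default blocks.
#' @examples
#' lib <- defaultBlockLibrary()
#' blocks(lib)
#' @export
defaultBlockLibrary <- function() buildingBlockLibrary(.DEFAULT_BLOCKS)

#' @rdname BuildingBlockLibrary-class
#' @export
setMethod("blocks", "BuildingBlockLibrary", function(x) x@blocks)

#' Look up block rows by id, with a clear error for unknown ids
#' @noRd
getBlocks <- function(library, ids) {
  b <- blocks(library)
  missing <- setdiff(unique(ids), b$id)
  if (length(missing))
    stop("unknown block id(s): ", paste(missing, collapse = ", "))
  b[ids, , drop = FALSE]
}

#' @describeIn BuildingBlockLibrary-class monoisotopic residue masses for a
#'   vector of block ids.
#' @param library a [BuildingBlockLibrary-class].
#' @param ids character vector of block ids.
#' @export
residueMass <- function(library, ids) {
  m <- getBlocks(library, ids)$residueMass
  names(m) <- ids
  m
}

setMethod("show", "BuildingBlockLibrary", function(object) {
  b <- blocks(object)
  cat("BuildingBlockLibrary (version ", object@version, ") with ",
      nrow(b), " blocks\n", sep = "")
  print(b[, c("id", "class", "formula", "residueMass")], row.names = FALSE)
})

#' Assemble a composition from an aglycone and decoration residues
#'
#' Decorations are a multiset: order never matters and repeats are allowed.
#' The total formula is the element-wise sum of the aglycone cation formula
#' and the residue formulas; the theoretical m/z subtracts one electron mass.
#'
#' @param aglyconeId id of an aglycone block.
#' @param decorationIds character vector (multiset) of glycosyl/acyl ids;
#'   may be empty for the bare aglycone.
#' @param library a [BuildingBlockLibrary-class].
#' @return a [Composition-class].
#' @examples
#' lib <- defaultBlockLibrary()
#' composeBlocks("pelargonidin", c("hexose", "hexose"), lib)  # C27H31O15
#' @export
composeBlocks <- function(aglyconeId, decorationIds = character(0), library) {
  ag <- getBlocks(library, aglyconeId)
  if (ag$class != "aglycone")
    stop("'", aglyconeId, "' is not an aglycone block")
  if (length(decorationIds)) {
    dec <- getBlocks(library, decorationIds)
    if (any(dec$class == "aglycone"))
      stop("decoration ids must name glycosyl/acyl blocks, not aglycones")
  }
  total <- parseFormula(ag$formula)
  for (f in if (length(decorationIds)) getBlocks(library, decorationIds)$formula
            else character(0))
    total <- addFormulas(total, parseFormula(f))
  new("Composition",
      aglycone = aglyconeId,
      decorations = sort(as.character(decorationIds)),
      totalFormula = total,
      cationMz = formulaMass(total) - .ELECTRON_MASS)
}

#' Theoretical neutral-loss mass of a residue multiset
#'
#' The mass removed from a decorated cation when the named residues depart,
#' e.g. \code{c("malonyl", "hexose")} is the malonylhexose loss.
#'
#' @param ids character vector (multiset) of glycosyl/acyl block ids; an
#'   empty vector is the identity loss, mass 0.
#' @param library a [BuildingBlockLibrary-class].
#' @return summed residue mass in Da.
#' @export
lossMass <- function(ids, library) {
  if (!length(ids)) return(0.0)
  b <- getBlocks(library, ids)
  if (any(b$class == "aglycone"))
    stop("loss multisets contain glycosyl/acyl blocks only")
  sum(b$residueMass)
}

#' @rdname Composition-class
#' @export
setMethod("aglycone", "Composition", function(x) x@aglycone)
#' @rdname Composition-class
#' @export
setMethod("decorations", "Composition", function(x) x@decorations)
#' @rdname Composition-class
#' @export
setMethod("cationMz", "Composition", function(x) x@cationMz)
#' @rdname Composition-class
#' @export
setMethod("totalFormula", "Composition", function(x) x@totalFormula)

setMethod("show", "Composition", function(object) {
  dec <- if (length(object@decorations)) {
    tab <- table(object@decorations)
    paste(ifelse(tab > 1, paste0(tab, "x ", names(tab)), names(tab)),
          collapse = " + ")
  } else "(none)"
  cat("Composition: ", object@aglycone, " + ", dec, "\n",
      "  formula ", hillFormula(object@totalFormula),
      ", [M]+ m/z ", sprintf("%.5f", object@cationMz), "\n", sep = "")
})

# canonical multiset key used for equality / deduplication
compositionKey <- function(x) {
  paste(x@aglycone, paste(x@decorations, collapse = ","), sep = "|")
}

#' Write a building-block library to versioned JSON
#'
#' Residue masses are not serialized: they are recomputed from the formulas
#' on load so that a hand-edited file can never carry stale masses.
#'
#' @param library a [BuildingBlockLibrary-class].
#' @param path output file.
#' @export
writeBlockLibrary <- function(library, path) {
  b <- blocks(library)
  jsonlite::write_json(
    list(version = library@version,
         blocks = b[, c("id", "class", "formula")]),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a building-block library from JSON
#'
#' @param path file written by [writeBlockLibrary()] or hand-authored in the
#'   same schema.
#' @return a [BuildingBlockLibrary-class].
#' @export
readBlockLibrary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  buildingBlockLibrary(x$blocks, version = x$version)
}
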