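# IUPAC/CODATA monoisotopic atomic masses (Da), most abundant isotope.
# C is exactly 12 by definition of the unified atomic mass unit.
.ATOMIC_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  O = 15.9949146196,
  N = 14.0030740048,
  S = 31.97207100
)

# rest mass of the electron (Da); subtracted for the flavylium [M]+ cation
.ELECTRON_MASS <- 0.00054858

#' Parse a Hill-notation elemental formula
#'
#' Converts a formula string such as \code{"C27H31O15"} into a named integer
#' vector of element counts, the representation used throughout the package.
#'
#' @param x character scalar, e.g. \code{"C6H10O5"}. An omitted count means 1.
#' @return named integer vector of element counts (names are element symbols).
#' @examples
#' parseFormula("C6H10O5")
#' @export
parseFormula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  x <- gsub("\\s", "", x)
  if (!nzchar(x)) stop("empty formula string")
  if (nzchar(gsub("[A-Z][a-z]?[0-9]*", "", x)))
    stop("malformed formula string: '", x, "'")
  m <- gregexpr("[A-Z][a-z]?[0-9]*", x)[[1]]
  toks <- regmatches(x, list(m))[[1]]
  toks <- toks[nzchar(toks)]
  counts <- integer(0)
  for (tok in toks) {
    sym <- gsub("[0-9]", "", tok)
    num <- gsub("[A-Za-z]", "", tok)
    n <- if (nzchar(num)) as.integer(num) else 1L
    counts[sym] <- if (sym %in% names(counts)) counts[[sym]] + n else n
  }
  validFormula(counts)
  counts
}

# invariant checks shared by every formula consumer
validFormula <- function(counts, allowEmpty = FALSE) {
  if (!length(counts) || is.null(names(counts)))
    stop("formula must be a named vector of element counts")
  if (anyNA(counts) || any(counts != as.integer(counts)) || any(counts < 0))
    stop("element counts must be non-negative integers")
  if (!allowEmpty && sum(counts) == 0)
    stop("formula has zero total atoms")
  invisible(TRUE)
}

#' Format element counts in Hill notation
#'
#' @param counts named integer vector as returned by [parseFormula()].
#' @return character scalar: C first, then H, then remaining elements
#'   alphabetically; zero counts are dropped.
#' @export
hillFormula <- function(counts) {
  validFormula(counts)
  counts <- counts[counts > 0]
  els <- names(counts)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(ord, function(e) {
    if (counts[[e]] == 1L) e else paste0(e, counts[[e]])
  }, character(1)), collapse = "")
}

# element-wise sum of two formulas
addFormulas <- function(a, b) {
  validFormula(a, allowEmpty = TRUE)
  validFormula(b, allowEmpty = TRUE)
  els <- union(names(a), names(b))
  out <- vapply(els, function(e) {
    (if (e %in% names(a)) a[[e]] else 0L) +
      (if (e %in% names(b)) b[[e]] else 0L)
  }, integer(1))
  names(out) <- els
  out
}

# element-wise difference; negative counts are a hard error
subtractFormulas <- function(a, b) {
  validFormula(a)
  validFormula(b, allowEmpty = TRUE)
  els <- union(names(a), names(b))
  out <- vapply(els, function(e) {
    (if (e %in% names(a)) a[[e]] else 0L) -
      (if (e %in% names(b)) b[[e]] else 0L)
  }, integer(1))
  if (any(out < 0))
    stop("formula subtraction produced a negative count for ",
         paste(els[out < 0], collapse = ", "))
  names(out) <- els
  out
}

#' Monoisotopic mass of an elemental formula
#'
#' @param formula either a Hill-notation string or a named integer count
#'   vector. Supported elements: C, H, O, N, S.
#' @return monoisotopic mass in Da.
#' @examples
#' formulaMass("C6H10O5")  # hexose residue, 162.052824
#' formulaMass("H2O")
#' @export
formulaMass <- function(formula) {
  if (is.character(formula)) formula <- parseFormula(formula)
  validFormula(formula)
  unknown <- setdiff(names(formula)[formula > 0], names(.ATOMIC_MASS))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  sum(formula[formula > 0] * .ATOMIC_MASS[names(formula)[formula > 0]])
}

#' Theoretical m/z of a singly charged cation
#'
#' Anthocyanins carry a permanent positive charge on the flavylium core and
#' are detected as the intact molecular ion \eqn{[M]^+}. The theoretical m/z
#' is therefore the monoisotopic mass of the cation's atom inventory minus
#' one electron mass (0.00054858 Da).
#'
#' @inheritParams formulaMass
#' @return theoretical \eqn{[M]^+} m/z at charge 1.
#' @examples
#' cationMass("C15H11O5")  # pelargonidin flavylium cation, 271.06010
#' @export
cationMass <- function(formula) {
  formulaMass(formula) - .ELECTRON_MASS
}

#' Electron rest mass used in cation m/z arithmetic
#'
#' @return the electron mass in Da.
#' @export
electronMass <- function() .ELECTRON_MASS
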