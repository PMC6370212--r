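#' @include AllClasses.R
NULL

#' Fit a qRT-PCR standard curve
#'
#' Least-squares line of Ct on log10(template ng), fitted per gene from a
#' serial dilution (e.g. 100 to 0.16 ng). The amplification efficiency is
#' \eqn{10^{-1/slope} - 1}; a perfect doubling gives slope -3.3219 and
#' efficiency 1.
#'
#' @param dilutionNg template amounts (ng), at least 3 points spanning at
#'   least 2 log10 units.
#' @param ct matching Ct values.
#' @param gene gene id stored with the curve.
#' @return a [StandardCurve-class].
#' @export
fitStandardCurve <- function(dilutionNg, ct, gene = NA_character_) {
  if (length(dilutionNg) != length(ct))
    stop("dilutionNg and ct must have equal length")
  if (length(dilutionNg) < 3) stop("need at least 3 dilution points")
  if (diff(range(log10(dilutionNg))) < 2)
    stop("dilution series must span at least 2 log10 units")
  fit <- stats::lm(ct ~ log10(dilutionNg))
  slope <- unname(stats::coef(fit)[2])
  # a zero-residual fit (synthetic or idealized dilutions) is a legitimate
  # input here; only summary.lm's "perfect fit" caveat is silenced
  r2 <- withCallingHandlers(summary(fit)$r.squared,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (slope >= 0)
    warning("non-negative slope: Ct does not decrease with template amount")
  else if (r2 < 0.9)
    warning("standard curve r-squared below 0.9; check for non-monotone Cts")
  new("StandardCurve", gene = as.character(gene), slope = slope,
      intercept = unname(stats::coef(fit)[1]),
      rSquared = r2,
      efficiency = 10^(-1 / slope) - 1)
}

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf(
    "StandardCurve %s: Ct = %.4f %+.4f x log10(ng), r2 = %.4f, E = %.3f\n",
    object@gene, object@intercept, object@slope, object@rSquared,
    object@efficiency))
})

#' Read a Ct table (long CSV)
#'
#' Columns: \code{gene}, \code{sample}, \code{tissue}, \code{bio_rep},
#' \code{tech_rep}, \code{ct}.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
readCtCSV <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "sample", "tissue", "bio_rep", "tech_rep", "ct")
  if (!all(need %in% names(d)))
    stop("Ct CSV needs columns ", paste(need, collapse = ", "))
  if (any(d$ct <= 0)) stop("Ct values must be > 0")
  d
}

#' Standard-curve quantification with housekeeping normalization
#'
#' Each Ct is interpolated on its gene's standard curve,
#' \eqn{q = 10^{(Ct - intercept)/slope}}; technical replicates are averaged
#' on the quantity scale; each gene's quantity is divided by the
#' housekeeping gene's quantity in the same biological sample. The
#' housekeeping gene's own normalized level is exactly 1 everywhere.
#' Normalized levels below \code{floor} times the gene's maximum are
#' reported as 0 (expression below the practical detection limit, e.g. in
#' non-pigmented leaves).
#'
#' @param ct long data.frame as from [readCtCSV()].
#' @param curves named list of [StandardCurve-class], one per gene in
#'   \code{ct}.
#' @param housekeeping housekeeping gene id (default "UBQ").
#' @param floor detection floor as a fraction of each gene's maximum
#'   normalized level (default 1e-6); set to 0 to disable.
#' @return a [SummarizedExperiment::SummarizedExperiment] (assay
#'   \code{level}, genes x biological samples, housekeeping row removed)
#'   with \code{tissue} and \code{bio_rep} in colData.
#' @export
relativeExpression <- function(ct, curves, housekeeping = "UBQ",
                               floor = 1e-6) {
  genes <- unique(ct$gene)
  if (!housekeeping %in% genes)
    stop("housekeeping gene '", housekeeping, "' absent from Ct table")
  missing <- setdiff(genes, names(curves))
  if (length(missing))
    stop("no standard curve for gene(s): ", paste(missing, collapse = ", "))
  ct$q <- vapply(seq_len(nrow(ct)), function(i) {
    cv <- curves[[ct$gene[i]]]
    10^((ct$ct[i] - cv@intercept) / cv@slope)
  }, numeric(1))
  # average technical replicates on the quantity scale
  ct$bioSample <- paste(ct$tissue, ct$bio_rep, sep = ".")
  agg <- stats::aggregate(q ~ gene + bioSample + tissue + bio_rep,
                          data = ct, mean)
  hk <- agg[agg$gene == housekeeping, ]
  if (!all(unique(agg$bioSample) %in% hk$bioSample))
    stop("housekeeping gene '", housekeeping,
         "' missing from some biological sample(s)")
  hkLookup <- stats::setNames(hk$q, hk$bioSample)
  agg$level <- agg$q / hkLookup[agg$bioSample]
  agg <- agg[agg$gene != housekeeping, ]
  samples <- unique(agg$bioSample)
  outGenes <- setdiff(genes, housekeeping)
  mat <- matrix(NA_real_, length(outGenes), length(samples),
                dimnames = list(outGenes, samples))
  mat[cbind(agg$gene, agg$bioSample)] <- agg$level
  if (floor > 0) {
    mx <- apply(mat, 1, max, na.rm = TRUE)
    mat[mat < floor * mx] <- 0
  }
  meta <- agg[!duplicated(agg$bioSample), c("bioSample", "tissue", "bio_rep")]
  rownames(meta) <- meta$bioSample
  SummarizedExperiment(
    assays = list(level = mat),
    colData = DataFrame(tissue = meta[samples, "tissue"],
                        bio_rep = meta[samples, "bio_rep"],
                        row.names = samples))
}

#' Per-tissue mean and standard deviation of expression levels
#'
#' @param ex SummarizedExperiment from [relativeExpression()].
#' @return list with matrices \code{mean} and \code{sd} (genes x tissues).
#' @export
expressionSummary <- function(ex) {
  mat <- assay(ex)
  tissue <- as.character(colData(ex)$tissue)
  tissues <- unique(tissue)
  mn <- sapply(tissues, function(s)
    rowMeans(mat[, tissue == s, drop = FALSE]))
  sd <- sapply(tissues, function(s)
    apply(mat[, tissue == s, drop = FALSE], 1, stats::sd))
  mn <- matrix(mn, nrow = nrow(mat), dimnames = list(rownames(mat), tissues))
  sd <- matrix(sd, nrow = nrow(mat), dimnames = list(rownames(mat), tissues))
  list(mean = mn, sd = sd)
}
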