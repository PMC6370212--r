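#' @include annotate.R quantify.R expression.R netstat.R
NULL

#' Read per-gene standard curves from CSV
#'
#' Columns: \code{gene}, \code{slope}, \code{intercept}. Efficiency and
#' the [StandardCurve-class] objects are rebuilt from those two numbers.
#'
#' @param path CSV file.
#' @return named list of [StandardCurve-class].
#' @export
readCurvesCSV <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "slope", "intercept") %in% names(d)))
    stop("curves CSV needs columns gene, slope, intercept")
  out <- lapply(seq_len(nrow(d)), function(i)
    new("StandardCurve", gene = d$gene[i], slope = d$slope[i],
        intercept = d$intercept[i], rSquared = NA_real_,
        efficiency = 10^(-1 / d$slope[i]) - 1))
  stats::setNames(out, d$gene)
}

#' Pipeline configuration
#'
#' @param spectra path to an MGF file of spectra (or NULL to skip
#'   annotation).
#' @param areas path to a long peak-area CSV (or NULL to skip
#'   quantification).
#' @param ct path to a long Ct CSV (or NULL to skip expression).
#' @param curves path to a curves CSV, or a named list of
#'   [StandardCurve-class].
#' @param library path to a block-library JSON; NULL for the default
#'   library.
#' @param isName internal-standard compound id.
#' @param housekeeping housekeeping gene id.
#' @param network run the correlation-network stage (needs both areas and
#'   ct).
#' @param alpha significance level for correlations.
#' @param edgeThreshold |rho| display threshold for network edges.
#' @param out output directory.
#' @param seed seed recorded in the report (the pipeline itself is
#'   deterministic).
#' @return a list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(spectra = NULL, areas = NULL, ct = NULL,
                           curves = NULL, library = NULL,
                           isName = "formononetin", housekeeping = "UBQ",
                           network = TRUE, alpha = 0.05,
                           edgeThreshold = 0.65, out = "anthonet_out",
                           seed = 1L) {
  cfg <- list(spectra = spectra, areas = areas, ct = ct, curves = curves,
              library = library, isName = isName,
              housekeeping = housekeeping, network = network, alpha = alpha,
              edgeThreshold = edgeThreshold, out = out, seed = seed)
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file whose fields mirror the arguments of
#'   [pipelineConfig()].
#' @return a \code{pipelineConfig} list.
#' @export
readPipelineConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipelineConfig, x)
}

#' Run the full identify / quantify / express / integrate pipeline
#'
#' Stages run in order: spectrum annotation, internal-standard
#' quantification (with stage composition and metabolite clustering),
#' qRT-PCR expression, and transcript-metabolite correlation network. Each
#' stage writes its artifacts under \code{config$out}; a MANIFEST file
#' records per-stage completion, and a single JSON report collects the
#' headline results (annotation summary, stage percent composition,
#' ns/NS).
#'
#' @param config a [pipelineConfig()] (or path to a JSON config).
#' @return invisibly, the report list; \code{$success} is TRUE iff no
#'   stage errored.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  lib <- if (is.null(config$library)) defaultBlockLibrary()
         else readBlockLibrary(config$library)
  report <- list(seed = config$seed, library_version = lib@version)
  manifest <- character(0)
  ok <- TRUE
  runStage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      ok <<- FALSE
      manifest <<- c(manifest,
                     paste0(name, ": FAILED (", conditionMessage(res), ")"))
      message("stage '", name, "' failed: ", conditionMessage(res))
      NULL
    } else {
      manifest <<- c(manifest, paste0(name, ": ok"))
      res
    }
  }

  ab <- NULL; ex <- NULL

  if (!is.null(config$spectra)) {
    annRes <- runStage("annotate", function() {
      spectra <- readMGF(config$spectra)
      if (!length(spectra)) stop("spectra file contains no spectra")
      ann <- annotateDataset(spectra, lib)
      writeAnnotationReport(ann, spectra, file.path(out, "annotate"))
      ann$summary
    })
    report$annotation <- annRes
  }

  if (!is.null(config$areas)) {
    quantRes <- runStage("quantify", function() {
      areas <- readPeakAreaCSV(config$areas)
      abLocal <- normalizeToIS(areas, isName = config$isName)
      writeQuantification(abLocal, file.path(out, "quantify"))
      ss <- stageSummary(abLocal)
      hc <- tryCatch(hclRows(abLocal),
                     error = function(e) hclRows(abLocal, "euclidean"))
      hclToNewick(hc, file.path(out, "quantify", "hcl.nwk"))
      ab <<- abLocal
      list(stage_percent = as.data.frame(ss$percent))
    })
    report$quantification <- quantRes
  }

  if (!is.null(config$ct)) {
    exprRes <- runStage("expression", function() {
      ctTab <- readCtCSV(config$ct)
      curves <- if (is.character(config$curves)) readCurvesCSV(config$curves)
                else config$curves
      if (is.null(curves)) stop("expression stage needs standard curves")
      exLocal <- relativeExpression(ctTab, curves,
                                    housekeeping = config$housekeeping)
      dir.create(file.path(out, "expression"), showWarnings = FALSE)
      utils::write.csv(as.data.frame(assay(exLocal)),
                       file.path(out, "expression", "levels.csv"))
      ex <<- exLocal
      es <- expressionSummary(exLocal)
      list(mean = as.data.frame(es$mean))
    })
    report$expression <- exprRes
  }

  if (isTRUE(config$network)) {
    netRes <- runStage("network", function() {
      if (is.null(ab) || is.null(ex))
        stop("network stage needs both quantification and expression")
      keyAb <- paste(colData(ab)$stage, colData(ab)$replicate, sep = ".")
      keyEx <- paste(colData(ex)$tissue, colData(ex)$bio_rep, sep = ".")
      shared <- intersect(keyAb, keyEx)
      if (length(shared) < 3)
        stop("fewer than 3 samples shared between metabolite and ",
             "transcript tables")
      m1 <- assay(ab)[, match(shared, keyAb), drop = FALSE]
      m2 <- assay(ex)[, match(shared, keyEx), drop = FALSE]
      colnames(m1) <- colnames(m2) <- shared
      if (any(m1 <= 0) || any(m2 <= 0))
        stop("non-positive abundance or expression value; cannot ",
             "log-transform for correlation")
      # fold-over-IS abundances and relative expression are multiplicative
      # (approximately log-normal), so Pearson correlation is computed on
      # the log scale
      merged <- rbind(log(m1), log(m2))
      ftype <- stats::setNames(
        c(rep("metabolite", nrow(m1)), rep("transcript", nrow(m2))),
        rownames(merged))
      cr <- correlationMatrix(merged, alpha = config$alpha,
                              featureType = ftype)
      net <- buildNetwork(cr, displayThreshold = config$edgeThreshold)
      writeNetwork(net, cr, file.path(out, "network"))
      list(NS = net@NS, ns = as.list(net@ns),
           n_edges = nrow(net@edges), n_samples = cr@nSamples)
    })
    report$network <- netRes
  }

  report$success <- ok
  writeLines(manifest, file.path(out, "MANIFEST"))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(report)
}
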