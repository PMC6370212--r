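#' @include AllClasses.R
NULL

#' Pairwise Pearson correlations with significance mask
#'
#' Correlations are computed across samples for every feature pair
#' (transcript-transcript, metabolite-metabolite, transcript-metabolite
#' alike). Two-sided p-values come from the t statistic
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on n-2 degrees of freedom. Pairs
#' with \code{p <= alpha} form the significance mask that all downstream
#' network statistics use; no multiple-testing correction is applied by
#' default (set \code{adjust = "BH"} to switch it on).
#'
#' @param data numeric matrix, features x samples (at least 3 samples).
#' @param alpha significance level (default 0.05).
#' @param featureType optional named character vector tagging features.
#' @param adjust \code{"none"} (default) or a method for
#'   [stats::p.adjust()] applied to the upper-triangle p-values.
#' @return a [CorrelationResult-class].
#' @export
correlationMatrix <- function(data, alpha = 0.05, featureType = character(0),
                              adjust = "none") {
  data <- as.matrix(data)
  n <- ncol(data)
  if (n < 3) stop("need at least 3 samples")
  sds <- apply(data, 1, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant feature(s): ",
            paste(rownames(data)[sds == 0], collapse = ", "))
    data <- data[sds > 0, , drop = FALSE]
  }
  rho <- stats::cor(t(data))
  rho <- (rho + t(rho)) / 2
  tstat <- abs(rho) * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  pval <- 2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  diag(pval) <- 0
  if (adjust != "none") {
    up <- upper.tri(pval)
    pval[up] <- stats::p.adjust(pval[up], method = adjust)
    pval[lower.tri(pval)] <- t(pval)[lower.tri(pval)]
  }
  sig <- pval <= alpha
  diag(sig) <- FALSE
  new("CorrelationResult", rho = rho, pval = pval, significant = sig,
      alpha = alpha, nSamples = as.integer(n),
      featureType = if (length(featureType)) featureType[rownames(rho)]
                    else character(0))
}

setMethod("show", "CorrelationResult", function(object) {
  k <- nrow(object@rho)
  up <- upper.tri(object@rho)
  cat("CorrelationResult: ", k, " features, ", object@nSamples,
      " samples\n  ", sum(object@significant[up]), "/", sum(up),
      " pairs significant at alpha = ", object@alpha, "\n", sep = "")
})

#' Node strength
#'
#' For each node, the mean of |rho| over its significant off-diagonal
#' pairs. A node with no significant pair gets strength 0. The absolute
#' value makes node strength a coupling magnitude in [0, 1] regardless of
#' correlation sign; \code{useAbs = FALSE} switches to signed averaging.
#'
#' @param cr a [CorrelationResult-class].
#' @param useAbs average |rho| (default) rather than signed rho.
#' @param significantOnly restrict to the significance mask (default);
#'   otherwise average over all off-diagonal pairs.
#' @return named numeric vector of per-node strengths.
#' @export
nodeStrength <- function(cr, useAbs = TRUE, significantOnly = TRUE) {
  r <- if (useAbs) abs(cr@rho) else cr@rho
  mask <- if (significantOnly) cr@significant else
    !diag(TRUE, nrow(r))
  ns <- vapply(seq_len(nrow(r)), function(i) {
    s <- mask[i, ]
    s[i] <- FALSE
    if (!any(s)) 0 else mean(r[i, s])
  }, numeric(1))
  stats::setNames(ns, rownames(r))
}

#' Network strength
#'
#' The arithmetic mean of the node strengths: a single [0, 1] summary of
#' how tightly the transcript-metabolite network is coupled.
#'
#' @param ns numeric vector of node strengths (from [nodeStrength()]).
#' @return scalar network strength.
#' @export
networkStrength <- function(ns) {
  if (!length(ns)) stop("network strength of an empty node set is undefined")
  mean(ns)
}

#' Build the correlation network summary
#'
#' Edges are the significant pairs whose |rho| passes the display
#' threshold (default 0.65), each carrying its signed rho. Node strength
#' and network strength are computed from ALL significant pairs, not just
#' the displayed edges: the display threshold is a drawing choice, not a
#' statistical one. Edge order is deterministic (row-major over the sorted
#' feature ids).
#'
#' @param cr a [CorrelationResult-class].
#' @param displayThreshold minimum |rho| for an edge to be listed.
#' @return a [NetworkSummary-class].
#' @export
buildNetwork <- function(cr, displayThreshold = 0.65) {
  r <- cr@rho
  ids <- rownames(r)
  keep <- which(upper.tri(r) & cr@significant & abs(r) >= displayThreshold,
                arr.ind = TRUE)
  keep <- keep[order(keep[, 1], keep[, 2]), , drop = FALSE]
  edges <- data.frame(source = ids[keep[, 1]], target = ids[keep[, 2]],
                      rho = r[keep], stringsAsFactors = FALSE)
  ns <- nodeStrength(cr)
  new("NetworkSummary", edges = edges, ns = ns, NS = networkStrength(ns),
      displayThreshold = displayThreshold)
}

setMethod("show", "NetworkSummary", function(object) {
  cat("NetworkSummary: ", nrow(object@edges), " edge(s) at |rho| >= ",
      object@displayThreshold, "\n  NS = ", sprintf("%.3f", object@NS),
      " over ", length(object@ns), " nodes\n", sep = "")
})

#' Write network artifacts (edge list CSV, GraphML, ns/NS JSON)
#'
#' The GraphML carries \code{feature_type} (when known) and \code{ns} as
#' node attributes and signed \code{rho} as an edge attribute, ready for
#' Cytoscape-style viewers.
#'
#' @param net a [NetworkSummary-class].
#' @param cr the [CorrelationResult-class] it was built from.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
writeNetwork <- function(net, cr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pEdges <- file.path(dir, "edges.csv")
  utils::write.csv(net@edges, pEdges, row.names = FALSE)
  pRho <- file.path(dir, "correlation.csv")
  utils::write.csv(as.data.frame(cr@rho), pRho)
  pP <- file.path(dir, "pvalues.csv")
  utils::write.csv(as.data.frame(cr@pval), pP)
  g <- igraph::graph_from_data_frame(
    net@edges, directed = FALSE,
    vertices = data.frame(name = names(net@ns), ns = unname(net@ns),
                          feature_type = if (length(cr@featureType))
                            unname(cr@featureType[names(net@ns)])
                          else NA_character_))
  pG <- file.path(dir, "network.graphml")
  igraph::write_graph(g, pG, format = "graphml")
  pJ <- file.path(dir, "network_strength.json")
  jsonlite::write_json(
    list(NS = net@NS, ns = as.list(net@ns),
         display_threshold = net@displayThreshold,
         alpha = cr@alpha, n_samples = cr@nSamples),
    pJ, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(pEdges, pRho, pP, pG, pJ))
}
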