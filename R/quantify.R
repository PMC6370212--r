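#' @include AllClasses.R
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame
NULL

#' Read a long-format peak-area table
#'
#' Columns: \code{compound_id}, \code{sample_id}, \code{stage},
#' \code{replicate}, \code{fragment_rank} (1 or 2), \code{area}. Each
#' compound is quantified from the integrated areas of its two most
#' abundant fragment ions; the internal standard appears as a compound row
#' under its configured name.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
readPeakAreaCSV <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "sample_id", "stage", "replicate",
            "fragment_rank", "area")
  if (!all(need %in% names(d)))
    stop("peak-area CSV needs columns ", paste(need, collapse = ", "))
  if (any(d$area < 0)) stop("peak areas must be >= 0")
  d
}

#' Normalize peak areas to the internal standard
#'
#' Per compound and sample, the quantifier is the sum of its two
#' most-abundant-fragment areas, divided by the internal-standard area of
#' the same sample ("fold over IS"). Compounds absent from a sample get 0.
#' The result is scale-free: multiplying all areas of a sample (IS
#' included) by any constant leaves it unchanged.
#'
#' @param areas long data.frame as from [readPeakAreaCSV()].
#' @param isName compound id of the internal standard (default
#'   "formononetin").
#' @return a [SummarizedExperiment::SummarizedExperiment] (assay
#'   \code{abundance}, compounds x samples) with \code{stage} and
#'   \code{replicate} in \code{colData}. The IS row is removed.
#' @export
normalizeToIS <- function(areas, isName = "formononetin") {
  samples <- unique(areas$sample_id)
  meta <- areas[!duplicated(areas$sample_id),
                c("sample_id", "stage", "replicate")]
  rownames(meta) <- meta$sample_id
  # per-sample summed quantifier area per compound
  agg <- stats::aggregate(area ~ compound_id + sample_id, data = areas, sum)
  isArea <- agg[agg$compound_id == isName, ]
  missingIS <- setdiff(samples, isArea$sample_id)
  if (length(missingIS) || any(isArea$area <= 0)) {
    bad <- c(missingIS, isArea$sample_id[isArea$area <= 0])
    stop("internal standard '", isName, "' missing or non-positive in ",
         "sample(s): ", paste(bad, collapse = ", "))
  }
  isLookup <- stats::setNames(isArea$area, isArea$sample_id)
  compounds <- sort(setdiff(unique(areas$compound_id), isName))
  mat <- matrix(0, length(compounds), length(samples),
                dimnames = list(compounds, samples))
  agg <- agg[agg$compound_id != isName, ]
  mat[cbind(agg$compound_id, agg$sample_id)] <-
    agg$area / isLookup[agg$sample_id]
  SummarizedExperiment(
    assays = list(abundance = mat),
    colData = DataFrame(stage = meta[samples, "stage"],
                        replicate = meta[samples, "replicate"],
                        row.names = samples))
}

#' Per-stage abundance summary and percent composition
#'
#' Means and sample standard deviations are taken across biological
#' replicates within a stage; percent composition is computed from the
#' stage means (each stage column sums to 100 unless all compounds are
#' zero).
#'
#' @param ab SummarizedExperiment from [normalizeToIS()] (or any assay
#'   matrix with a \code{stage} column in colData).
#' @return list with matrices \code{mean}, \code{sd} and \code{percent}
#'   (compounds x stages).
#' @export
stageSummary <- function(ab) {
  mat <- assay(ab)
  stage <- as.character(colData(ab)$stage)
  stages <- unique(stage)
  if (any(!table(factor(stage, levels = stages))))
    stop("every stage needs at least one replicate")
  mn <- sapply(stages, function(s)
    rowMeans(mat[, stage == s, drop = FALSE]))
  sd <- sapply(stages, function(s)
    apply(mat[, stage == s, drop = FALSE], 1, stats::sd))
  mn <- matrix(mn, nrow = nrow(mat), dimnames = list(rownames(mat), stages))
  sd <- matrix(sd, nrow = nrow(mat), dimnames = list(rownames(mat), stages))
  tot <- colSums(mn)
  pct <- sweep(mn, 2, ifelse(tot > 0, tot, 1), "/") * 100
  pct[, tot == 0] <- 0
  list(mean = mn, sd = sd, percent = pct)
}

#' Hierarchical clustering of metabolite rows
#'
#' Agglomerative clustering of compound profiles across samples. The
#' default distance is correlation-based (1 - Pearson rho between row
#' profiles) with average linkage, the common choice for metabolite
#' abundance heatmaps; both are configurable. Rows are ordered by id before
#' clustering so that ties resolve deterministically.
#'
#' @param ab SummarizedExperiment or numeric matrix (rows = compounds).
#' @param distance \code{"correlation"} (1 - Pearson) or
#'   \code{"euclidean"}.
#' @param linkage linkage method passed to [stats::hclust()] (default
#'   \code{"average"}).
#' @return an object of class \code{hclust}.
#' @export
hclRows <- function(ab, distance = c("correlation", "euclidean"),
                    linkage = "average") {
  distance <- match.arg(distance)
  mat <- if (is(ab, "SummarizedExperiment")) assay(ab) else as.matrix(ab)
  if (nrow(mat) < 2) stop("need at least two rows to cluster")
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  if (distance == "correlation") {
    sds <- apply(mat, 1, stats::sd)
    if (any(sds == 0))
      stop("constant row(s) under correlation distance (",
           paste(rownames(mat)[sds == 0], collapse = ", "),
           "); use distance = \"euclidean\"")
    d <- stats::as.dist(1 - stats::cor(t(mat)))
  } else {
    d <- stats::dist(mat)
  }
  stats::hclust(d, method = linkage)
}

#' Serialize a dendrogram as a Newick string
#'
#' @param hc an \code{hclust} object, e.g. from [hclRows()].
#' @param path optional file to write to.
#' @return the Newick string, invisibly if written to file.
#' @export
hclToNewick <- function(hc, path = NULL) {
  tree <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(ape::write.tree(tree))
}

#' Write abundance and stage-summary CSVs
#'
#' @param ab SummarizedExperiment from [normalizeToIS()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
writeQuantification <- function(ab, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "abundance.csv")
  utils::write.csv(as.data.frame(assay(ab)), p1)
  ss <- stageSummary(ab)
  p2 <- file.path(dir, "stage_summary.csv")
  long <- do.call(rbind, lapply(colnames(ss$mean), function(s)
    data.frame(stage = s, compound_id = rownames(ss$mean),
               mean = ss$mean[, s], sd = ss$sd[, s],
               percent = ss$percent[, s], row.names = NULL)))
  utils::write.csv(long, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
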