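#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' BetaPatternSet: odor-by-run beta pattern vectors for one ROI
#'
#' Container for the currency of all pattern analyses: the 36 beta pattern
#' vectors (6 odors x 6 runs under the default design) of one subject,
#' session and bilateral ROI. Extends
#' [SummarizedExperiment::SummarizedExperiment]: rows are voxels (with a
#' hemisphere label in `rowData`), columns are odor-by-run patterns (odor,
#' category and run in `colData`); `metadata` carries subject, session,
#' group and ROI labels. After assembly every hemisphere sub-vector of
#' every pattern has mean 0 and standard deviation 1.
#'
#' @slot normalized logical; TRUE once hemisphere-wise z-scaling has been
#'   applied
#' @export
setClass("BetaPatternSet",
         contains = "SummarizedExperiment",
         representation(normalized = "logical"),
         prototype(normalized = FALSE))

setValidity("BetaPatternSet", function(object) {
  msg <- character(0L)
  if (!"beta" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'beta' is required")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("odor", "category", "run") %in% colnames(cd))) {
    msg <- c(msg, "colData must have odor, category and run")
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!"hemisphere" %in% colnames(rd)) {
    msg <- c(msg, "rowData must have a hemisphere column")
  } else if (!all(rd$hemisphere %in% c("L", "R"))) {
    msg <- c(msg, "hemisphere labels must be 'L' or 'R'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a BetaPatternSet
#'
#' @param beta voxel x pattern matrix
#' @param odor,category,run per-pattern labels
#' @param hemisphere per-voxel "L"/"R" labels
#' @param subject,session,group,roi metadata labels
#' @param normalized whether hemisphere scaling has been applied
#' @return a [BetaPatternSet-class] object
#' @export
BetaPatternSet <- function(beta, odor, category, run, hemisphere,
                           subject = "s01", session = "pre",
                           group = "placebo", roi = "PPC",
                           normalized = FALSE) {
  beta <- as.matrix(beta)
  stopifnot(length(odor) == ncol(beta), length(run) == ncol(beta),
            length(category) == ncol(beta),
            length(hemisphere) == nrow(beta))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(beta = beta),
    colData = S4Vectors::DataFrame(odor = odor, category = category,
                                   run = run),
    rowData = S4Vectors::DataFrame(hemisphere = hemisphere))
  obj <- methods::new("BetaPatternSet", se, normalized = isTRUE(normalized))
  S4Vectors::metadata(obj) <- list(subject = subject, session = session,
                                   group = group, roi = roi)
  obj
}

#' @describeIn BetaPatternSet-class voxel x pattern beta matrix
#' @param x a `BetaPatternSet`
#' @export
betaMatrix <- function(x) SummarizedExperiment::assay(x, "beta")

#' @describeIn BetaPatternSet-class per-pattern labels (odor, category,
#'   run) as a data.frame
#' @export
patternInfo <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
}

#' @describeIn BetaPatternSet-class per-voxel hemisphere labels
#' @export
hemisphereLabels <- function(x) {
  SummarizedExperiment::rowData(x)$hemisphere
}

setMethod("show", "BetaPatternSet", function(object) {
  md <- S4Vectors::metadata(object)
  cat("BetaPatternSet:", nrow(object), "voxels x", ncol(object),
      "patterns\n")
  cat("  subject:", md$subject, " session:", md$session,
      " group:", md$group, " roi:", md$roi, "\n")
  cat("  odors:", paste(unique(patternInfo(object)$odor), collapse = " "),
      "| runs:", length(unique(patternInfo(object)$run)), "\n")
  cat("  hemisphere-normalized:", object@normalized, "\n")
})
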