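#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
NULL

#' Expression cohort container
#'
#' An \code{ImmunoExperiment} is a \linkS4class{SummarizedExperiment} holding a
#' genes x samples expression matrix in an assay named \code{"exprs"}, plus a
#' \code{scaleTag} recording whether values are log2 intensities or linear.
#' Every consumer in the package declares which scale it requires and converts
#' explicitly; nothing guesses the scale from value ranges.
#'
#' @slot scaleTag either \code{"log2"} or \code{"linear"}.
#' @export
setClass("ImmunoExperiment",
  contains = "SummarizedExperiment",
  representation(scaleTag = "character"),
  prototype(scaleTag = "log2")
)

setValidity("ImmunoExperiment", function(object) {
  msg <- character()
  if (!"exprs" %in% names(assays(object)))
    msg <- c(msg, "assay 'exprs' is required")
  if (length(object@scaleTag) != 1L || !object@scaleTag %in% c("log2", "linear"))
    msg <- c(msg, "scaleTag must be one of 'log2', 'linear'")
  if (nrow(object) < 2L || ncol(object) < 2L)
    msg <- c(msg, "at least 2 genes and 2 samples are required")
  gn <- rownames(object); sn <- colnames(object)
  if (is.null(gn) || anyNA(gn) || any(!nzchar(gn)))
    msg <- c(msg, "gene ids must be present and non-empty")
  if (is.null(sn) || anyNA(sn) || any(!nzchar(sn)))
    msg <- c(msg, "sample ids must be present and non-empty")
  if (!is.null(gn) && anyDuplicated(gn))
    msg <- c(msg, "duplicate gene ids")
  if (!is.null(sn) && anyDuplicated(sn))
    msg <- c(msg, "duplicate sample ids")
  if ("exprs" %in% names(assays(object)) && anyNA(assay(object, "exprs")))
    msg <- c(msg, "missing values in expression matrix")
  if (length(msg)) msg else TRUE
})

#' Construct an ImmunoExperiment from a matrix
#'
#' @param exprs numeric genes x samples matrix with row and column names.
#' @param scaleTag \code{"log2"} (default) or \code{"linear"}.
#' @param colData optional per-sample \code{DataFrame}.
#' @param metadata optional list stored as object metadata.
#' @return a validated \code{ImmunoExperiment}.
#' @examples
#' m <- matrix(rnorm(6, 7), 3, 2,
#'             dimnames = list(c("GZMA", "PRF1", "CD8A"), c("s1", "s2")))
#' ie <- ImmunoExperiment(m)
#' scaleTag(ie)
#' @export
ImmunoExperiment <- function(exprs, scaleTag = "log2", colData = NULL,
                             metadata = list()) {
  exprs <- as.matrix(exprs)
  if (is.null(colData))
    colData <- S4Vectors::DataFrame(row.names = colnames(exprs))
  se <- SummarizedExperiment(assays = list(exprs = exprs), colData = colData,
                             metadata = metadata)
  new("ImmunoExperiment", se, scaleTag = scaleTag)
}

#' Named collection of gene sets
#'
#' Holds deduplicated gene symbol lists, typically read from a GMT file with
#' \code{\link{readGeneSetsGMT}}.
#'
#' @slot sets named list of character vectors (unique symbols per set).
#' @slot descriptions per-set description strings, parallel to \code{sets}.
#' @export
setClass("SignatureSets",
  representation(sets = "list", descriptions = "character")
)

setValidity("SignatureSets", function(object) {
  msg <- character()
  nm <- names(object@sets)
  if (length(object@sets)) {
    if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
      msg <- c(msg, "set names must be unique and non-empty")
    if (any(lengths(object@sets) == 0L))
      msg <- c(msg, "gene lists must be non-empty")
    if (any(vapply(object@sets, anyDuplicated, 0L) > 0L))
      msg <- c(msg, "duplicate genes within a set")
  }
  if (length(object@descriptions) != length(object@sets))
    msg <- c(msg, "descriptions must be parallel to sets")
  if (length(msg)) msg else TRUE
})

#' @rdname SignatureSets-class
#' @param sets named list of gene symbol vectors; duplicates within a set are
#'   removed on construction.
#' @param descriptions optional per-set descriptions.
#' @export
SignatureSets <- function(sets, descriptions = NULL) {
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  new("SignatureSets", sets = sets,
      descriptions = as.character(descriptions))
}

#' Per-sample immune signature scores
#'
#' One row per sample; columns hold CYT, TIS, aggressive, IMS, ssGSEA
#' enrichment scores, ESTIMATE-style scores, tumor purity and the
#' immunophenoscore, as computed by \code{\link{scorePanel}}. The invariant
#' \code{ims == cyt * tis - aggressive} is enforced exactly.
#'
#' @slot scores a \code{DataFrame} keyed by sample id.
#' @export
setClass("SignaturePanel", representation(scores = "DataFrame"))

setValidity("SignaturePanel", function(object) {
  sc <- object@scores
  msg <- character()
  if (is.null(rownames(sc)) || anyDuplicated(rownames(sc)))
    msg <- c(msg, "scores must have unique sample-id row names")
  if (all(c("cyt", "tis", "aggressive", "ims") %in% colnames(sc))) {
    d <- abs(sc$ims - (sc$cyt * sc$tis - sc$aggressive))
    if (any(d > 1e-12, na.rm = TRUE))
      msg <- c(msg, "ims must equal cyt * tis - aggressive exactly")
  }
  if ("purity" %in% colnames(sc)) {
    p <- sc$purity
    if (any(p < 0 | p > 1, na.rm = TRUE))
      msg <- c(msg, "purity must lie in [0, 1] where defined")
  }
  if (length(msg)) msg else TRUE
})

#' Nonnegative matrix factorization fit
#'
#' @slot W genes x rank nonnegative basis, columns scaled to unit L2 norm.
#' @slot H rank x samples nonnegative coefficients.
#' @slot rank factorization rank.
#' @slot objective squared-Euclidean objective trace, one value per iteration.
#' @slot nIter iterations run.
#' @slot converged whether the relative-change tolerance was met.
#' @slot seed RNG seed used for the random initialization.
#' @export
setClass("NMFModel",
  representation(W = "matrix", H = "matrix", rank = "integer",
                 objective = "numeric", nIter = "integer",
                 converged = "logical", seed = "integer")
)

setValidity("NMFModel", function(object) {
  msg <- character()
  if (any(object@W < 0) || any(object@H < 0))
    msg <- c(msg, "W and H must be nonnegative")
  if (ncol(object@W) != object@rank || nrow(object@H) != object@rank)
    msg <- c(msg, "W/H dimensions inconsistent with rank")
  if (length(msg)) msg else TRUE
})

#' Consensus clustering result
#'
#' @slot consensus samples x samples co-assignment frequency matrix in [0,1],
#'   symmetric with unit diagonal.
#' @slot nRuns number of NMF runs aggregated.
#' @slot rank factorization rank used.
#' @slot cophenetic cophenetic correlation coefficient of the consensus
#'   distances (stability of the clustering at this rank).
#' @slot labels initial per-sample cluster labels derived from the consensus
#'   matrix (average-linkage cut at \code{rank} groups).
#' @export
setClass("ConsensusResult",
  representation(consensus = "matrix", nRuns = "integer", rank = "integer",
                 cophenetic = "numeric", labels = "integer")
)

setValidity("ConsensusResult", function(object) {
  cm <- object@consensus
  msg <- character()
  if (nrow(cm) != ncol(cm) || !isTRUE(all.equal(cm, t(cm), tolerance = 1e-12)))
    msg <- c(msg, "consensus matrix must be symmetric")
  if (any(cm < -1e-12) || any(cm > 1 + 1e-12))
    msg <- c(msg, "consensus entries must lie in [0, 1]")
  if (any(abs(diag(cm) - 1) > 1e-12))
    msg <- c(msg, "consensus diagonal must be 1")
  if (length(msg)) msg else TRUE
})

#' Refined cluster assignment
#'
#' Final labels after small-cluster exclusion and correlation-driven merging,
#' optionally renamed ImA/ImB/ImC by descending immune score.
#'
#' @slot labels named factor of final cluster labels (excluded samples absent).
#' @slot refinementLog list recording excluded clusters (id, size, samples)
#'   and merged pairs (ids, Pearson r).
#' @slot excludedSamples sample ids dropped with excluded clusters.
#' @export
setClass("ClusterAssignment",
  representation(labels = "factor", refinementLog = "list",
                 excludedSamples = "character")
)

setValidity("ClusterAssignment", function(object) {
  msg <- character()
  if (is.null(names(object@labels)))
    msg <- c(msg, "labels must be named by sample id")
  if (any(object@excludedSamples %in% names(object@labels)))
    msg <- c(msg, "excluded samples must not appear in final labels")
  if (length(msg)) msg else TRUE
})

#' Deconvolution result
#'
#' Per-sample immune-cell composition estimated by nu-support-vector
#' regression against a reference signature matrix.
#'
#' @slot fractions samples x cell-types matrix; rows sum to 1.
#' @slot rmse per-sample root-mean-square reconstruction error.
#' @slot pearsonR per-sample Pearson correlation between reconstruction and
#'   observed mixture.
#' @slot permP per-sample permutation p-value (plus-one corrected, in (0,1]).
#' @export
setClass("DeconvolutionResult",
  representation(fractions = "matrix", rmse = "numeric",
                 pearsonR = "numeric", permP = "numeric")
)

setValidity("DeconvolutionResult", function(object) {
  fr <- object@fractions
  msg <- character()
  ok <- rowSums(fr) == 0 | abs(rowSums(fr) - 1) < 1e-9
  if (any(fr < -1e-12) || !all(ok))
    msg <- c(msg, "fractions must be nonnegative and sum to 1 per sample")
  if (any(object@permP <= 0 | object@permP > 1, na.rm = TRUE))
    msg <- c(msg, "permutation p-values must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})
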