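#' @rdname ImmunoExperiment-class
#' @param x an \code{ImmunoExperiment}.
#' @export
setGeneric("scaleTag", function(x) standardGeneric("scaleTag"))

#' @rdname ImmunoExperiment-class
#' @export
setMethod("scaleTag", "ImmunoExperiment", function(x) x@scaleTag)

#' Expression values on a requested scale
#'
#' Returns the assay matrix, converting explicitly between log2 and linear
#' scales according to the object's \code{scaleTag} (linear values are
#' \code{2^log2}; log2 of linear values requires strictly positive input).
#'
#' @param x an \code{ImmunoExperiment}.
#' @param scale scale required by the caller, \code{"log2"} or \code{"linear"}.
#' @return numeric genes x samples matrix on the requested scale.
#' @export
setGeneric("exprsOn", function(x, scale = "log2") standardGeneric("exprsOn"))

#' @rdname exprsOn
#' @export
setMethod("exprsOn", "ImmunoExperiment", function(x, scale = "log2") {
  scale <- match.arg(scale, c("log2", "linear"))
  m <- assay(x, "exprs")
  if (scaleTag(x) == scale) return(m)
  if (scale == "linear") return(2^m)
  if (any(m <= 0)) stop("cannot take log2 of nonpositive linear values")
  log2(m)
})

#' @rdname SignatureSets-class
#' @param x a \code{SignatureSets}.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname SignatureSets-class
#' @export
setMethod("geneSets", "SignatureSets", function(x) x@sets)

#' @rdname SignaturePanel-class
#' @param x a \code{SignaturePanel}.
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

#' @rdname SignaturePanel-class
#' @export
setMethod("scoreTable", "SignaturePanel", function(x) x@scores)

#' @rdname NMFModel-class
#' @param x an \code{NMFModel}.
#' @export
setGeneric("basisMatrix", function(x) standardGeneric("basisMatrix"))

#' @rdname NMFModel-class
#' @export
setMethod("basisMatrix", "NMFModel", function(x) x@W)

#' @rdname NMFModel-class
#' @export
setGeneric("coefMatrix", function(x) standardGeneric("coefMatrix"))

#' @rdname NMFModel-class
#' @export
setMethod("coefMatrix", "NMFModel", function(x) x@H)

#' @rdname ConsensusResult-class
#' @param x a \code{ConsensusResult}.
#' @export
setGeneric("consensusMatrix", function(x) standardGeneric("consensusMatrix"))

#' @rdname ConsensusResult-class
#' @export
setMethod("consensusMatrix", "ConsensusResult", function(x) x@consensus)

#' @rdname ConsensusResult-class
#' @export
setGeneric("copheneticCoef", function(x) standardGeneric("copheneticCoef"))

#' @rdname ConsensusResult-class
#' @export
setMethod("copheneticCoef", "ConsensusResult", function(x) x@cophenetic)

#' @rdname ClusterAssignment-class
#' @param x a \code{ClusterAssignment} or \code{ConsensusResult}.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname ClusterAssignment-class
#' @export
setMethod("clusterLabels", "ClusterAssignment", function(x) x@labels)

#' @rdname ConsensusResult-class
#' @export
setMethod("clusterLabels", "ConsensusResult", function(x) {
  structure(x@labels, names = rownames(x@consensus))
})

#' @rdname ClusterAssignment-class
#' @export
setGeneric("refinementLog", function(x) standardGeneric("refinementLog"))

#' @rdname ClusterAssignment-class
#' @export
setMethod("refinementLog", "ClusterAssignment", function(x) x@refinementLog)

#' @rdname ClusterAssignment-class
#' @export
setGeneric("excludedSamples", function(x) standardGeneric("excludedSamples"))

#' @rdname ClusterAssignment-class
#' @export
setMethod("excludedSamples", "ClusterAssignment", function(x) x@excludedSamples)

#' @rdname DeconvolutionResult-class
#' @param x a \code{DeconvolutionResult}.
#' @export
setGeneric("cellFractions", function(x) standardGeneric("cellFractions"))

#' @rdname DeconvolutionResult-class
#' @export
setMethod("cellFractions", "DeconvolutionResult", function(x) x@fractions)

setMethod("show", "ImmunoExperiment", function(object) {
  cat("ImmunoExperiment:", nrow(object), "genes x", ncol(object),
      "samples (", object@scaleTag, "scale )\n")
  callNextMethod()
})

setMethod("show", "SignatureSets", function(object) {
  cat("SignatureSets with", length(object@sets), "sets\n")
  for (nm in utils::head(names(object@sets), 6))
    cat("  ", nm, ": ", length(object@sets[[nm]]), " genes\n", sep = "")
  if (length(object@sets) > 6) cat("  ...\n")
})

setMethod("show", "SignaturePanel", function(object) {
  cat("SignaturePanel:", nrow(object@scores), "samples x",
      ncol(object@scores), "scores\n")
  cat("  columns:", paste(colnames(object@scores), collapse = ", "), "\n")
})

setMethod("show", "NMFModel", function(object) {
  cat("NMFModel: rank", object@rank, "|", nrow(object@W), "genes x",
      ncol(object@H), "samples\n")
  cat("  objective:", format(utils::tail(object@objective, 1)),
      "after", object@nIter, "iterations",
      if (object@converged) "(converged)" else "(max iterations)", "\n")
})

setMethod("show", "ConsensusResult", function(object) {
  cat("ConsensusResult: rank", object@rank, "|", object@nRuns, "runs |",
      "cophenetic", format(object@cophenetic, digits = 4), "\n")
})

setMethod("show", "ClusterAssignment", function(object) {
  cat("ClusterAssignment:", length(object@labels), "samples in",
      nlevels(object@labels), "clusters\n")
  print(table(object@labels))
  if (length(object@excludedSamples))
    cat("  excluded:", paste(object@excludedSamples, collapse = ", "), "\n")
})

setMethod("show", "DeconvolutionResult", function(object) {
  cat("DeconvolutionResult:", nrow(object@fractions), "samples x",
      ncol(object@fractions), "cell types\n")
})
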