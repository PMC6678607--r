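#' Read a cell-type signature matrix
#'
#' TSV with a header row of cell-type names and gene symbols in the first
#' column; the published 22-type matrix is one such file (not bundled here),
#' any genes x types reference works.
#'
#' @param path TSV path.
#' @return numeric genes x cell-types matrix.
#' @export
readSignatureMatrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  if (anyNA(m)) stop("missing values in signature matrix")
  if (ncol(m) < 2L) stop("signature matrix needs at least 2 cell types")
  m
}

.zscore <- function(v) (v - mean(v)) / stats::sd(v)

.svrFractions <- function(mixZ, sigZ, nu) {
  fit <- e1071::svm(x = sigZ, y = mixZ, type = "nu-regression",
                    kernel = "linear", nu = nu, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  pred <- drop(sigZ %*% w) - fit$rho  # svm decision value is x.w - rho
  list(w = w, pred = pred,
       rmse = sqrt(mean((pred - mixZ)^2)),
       r = suppressWarnings(stats::cor(pred, mixZ)))
}

#' Deconvolve one bulk mixture by nu-support-vector regression
#'
#' Linear nu-SVR of the (z-scored) mixture on the (z-scored) signature
#' columns over a small nu grid; the nu with the lowest reconstruction RMSE
#' wins. Negative cell-type coefficients are set to zero and the survivors
#' normalized to sum to one. Significance comes from a permutation null:
#' random mixtures resampled from the pooled mixture distribution, p =
#' (1 + #\{r* >= r\}) / (1 + nPerm).
#'
#' @param mixture named per-gene vector of linear-scale expression.
#' @param sig genes x cell-types signature matrix (linear scale).
#' @param nuGrid nu values tried (default 0.25, 0.5, 0.75).
#' @param nPerm permutation count (default 1000; the study convention).
#' @param seed RNG seed for the permutation null.
#' @return list with \code{fractions} (named, sums to 1), \code{rmse},
#'   \code{pearsonR}, \code{permP}, \code{nu}, and \code{degenerate} flag
#'   (all coefficients nonpositive).
#' @export
deconvolveSample <- function(mixture, sig, nuGrid = c(0.25, 0.5, 0.75),
                             nPerm = 1000L, seed = 1L) {
  shared <- intersect(names(mixture), rownames(sig))
  if (length(shared) < 50L)
    stop("fewer than 50 genes shared between mixture and signature matrix")
  mix <- mixture[shared]
  S <- sig[shared, , drop = FALSE]
  sigZ <- (S - mean(S)) / stats::sd(S)
  mixZ <- .zscore(mix)
  fits <- lapply(nuGrid, function(nu) .svrFractions(mixZ, sigZ, nu))
  best <- fits[[which.min(vapply(fits, `[[`, 0, "rmse"))]]
  w <- pmax(best$w, 0)
  degenerate <- sum(w) == 0
  fr <- if (degenerate) w else w / sum(w)
  old <- .saveRNG(); on.exit(.restoreRNG(old), add = TRUE)
  set.seed(as.integer(seed))
  nu <- nuGrid[which.min(vapply(fits, `[[`, 0, "rmse"))]
  rstar <- vapply(seq_len(nPerm), function(i) {
    permZ <- .zscore(sample(mix, length(mix), replace = TRUE))
    .svrFractions(permZ, sigZ, nu)$r
  }, 0)
  permP <- (1 + sum(rstar >= best$r)) / (1 + nPerm)
  list(fractions = fr, rmse = best$rmse, pearsonR = best$r,
       permP = permP, nu = nu, degenerate = degenerate)
}

#' Deconvolve every sample of a cohort
#'
#' Applies \code{\link{deconvolveSample}} per sample. Expression is taken on
#' the linear scale (log2 cohorts are converted by \code{2^x}, the cited
#' method's convention).
#'
#' @param x an \code{ImmunoExperiment} or linear-scale matrix.
#' @param sig genes x cell-types signature matrix.
#' @param nuGrid,nPerm,seed forwarded per sample (seeds derived per sample).
#' @return a \code{\linkS4class{DeconvolutionResult}}.
#' @export
deconvolveCohort <- function(x, sig, nuGrid = c(0.25, 0.5, 0.75),
                             nPerm = 100L, seed = 1L) {
  m <- if (is(x, "ImmunoExperiment")) exprsOn(x, "linear") else as.matrix(x)
  res <- lapply(seq_len(ncol(m)), function(j)
    deconvolveSample(m[, j], sig, nuGrid = nuGrid, nPerm = nPerm,
                     seed = .deriveSeed(seed, j)))
  fr <- do.call(rbind, lapply(res, `[[`, "fractions"))
  rownames(fr) <- colnames(m)
  new("DeconvolutionResult",
      fractions = fr,
      rmse = vapply(res, `[[`, 0, "rmse"),
      pearsonR = vapply(res, `[[`, 0, "pearsonR"),
      permP = vapply(res, `[[`, 0, "permP"))
}

#' Per-cluster presence percentage of a cell type
#'
#' Percent of samples in each cluster whose estimated fraction of the given
#' cell type is positive.
#'
#' @param result a \code{DeconvolutionResult}.
#' @param labels per-sample cluster labels (named), or a
#'   \code{ClusterAssignment}.
#' @param cellType cell-type column name.
#' @return named numeric vector of percentages per cluster.
#' @export
presenceFraction <- function(result, labels, cellType) {
  if (is(labels, "ClusterAssignment")) labels <- clusterLabels(labels)
  fr <- cellFractions(result)
  if (!cellType %in% colnames(fr))
    stop("unknown cell type: ", cellType)
  common <- intersect(names(labels), rownames(fr))
  tapply(fr[common, cellType] > 0, factor(labels[common]),
         function(z) 100 * mean(z))
}
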