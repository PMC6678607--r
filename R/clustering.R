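#' @importFrom stats hclust cutree as.dist cor cophenetic median
NULL

# deterministic derivation of per-run seeds from one master seed (kept < 2^31)
.deriveSeed <- function(master, i) {
  as.integer((as.double(master %% 100003L) * 10007 + i * 7919 + 1) %% 2147483647)
}

#' Shift a log2 submatrix to nonnegative values
#'
#' NMF requires nonnegative input; log2 expression can be negative, so the
#' global minimum is subtracted and recorded.
#'
#' @param m numeric matrix.
#' @return matrix with attribute \code{"shift"} holding the subtracted value.
#' @export
nonnegativeShift <- function(m) {
  s <- min(m)
  out <- m - min(s, 0)
  attr(out, "shift") <- min(s, 0)
  out
}

#' Nonnegative matrix factorization (multiplicative updates)
#'
#' Factorizes a nonnegative matrix V ~ W H under the squared-Euclidean
#' objective with the classical multiplicative update rules, which keep the
#' objective non-increasing. Stops when the relative objective change drops
#' below \code{tol} or after \code{maxIter} iterations. W columns are scaled
#' to unit L2 norm with compensation in H.
#'
#' @param V nonnegative numeric matrix (use \code{\link{nonnegativeShift}}
#'   on log2 data first).
#' @param rank factorization rank, \code{2 <= rank < min(dim(V))}.
#' @param seed RNG seed for the uniform random initialization.
#' @param maxIter iteration cap (default 2000).
#' @param tol relative objective-change tolerance (default 1e-6).
#' @return an \code{\linkS4class{NMFModel}}.
#' @export
nmfFactorize <- function(V, rank, seed = 1L, maxIter = 2000L, tol = 1e-6) {
  V <- as.matrix(V)
  if (any(V < 0))
    stop("V has negative entries; shift log2 data with nonnegativeShift() first")
  if (rank < 1L || rank >= min(dim(V)))
    stop("rank must satisfy 1 <= rank < min(dim(V))")
  eps <- .Machine$double.eps
  n <- nrow(V); p <- ncol(V)
  old <- .saveRNG()
  on.exit(.restoreRNG(old), add = TRUE)
  set.seed(as.integer(seed))
  W <- matrix(stats::runif(n * rank, 0, max(V)), n, rank)
  H <- matrix(stats::runif(rank * p, 0, 1), rank, p)
  obj <- numeric(maxIter)
  converged <- FALSE
  it <- 0L
  prev <- Inf
  while (it < maxIter) {
    it <- it + 1L
    H <- H * crossprod(W, V) / (crossprod(W) %*% H + eps)
    W <- W * tcrossprod(V, H) / (W %*% tcrossprod(H) + eps)
    obj[it] <- sum((V - W %*% H)^2)
    if (is.finite(prev) && prev > 0 &&
        abs(prev - obj[it]) / prev < tol) {
      converged <- TRUE
      break
    }
    prev <- obj[it]
  }
  scl <- sqrt(colSums(W^2))
  scl[scl == 0] <- 1
  W <- sweep(W, 2, scl, "/")
  H <- sweep(H, 1, scl, "*")
  rownames(W) <- rownames(V); colnames(H) <- colnames(V)
  new("NMFModel", W = W, H = H, rank = as.integer(rank),
      objective = obj[seq_len(it)], nIter = it, converged = converged,
      seed = as.integer(seed))
}

.saveRNG <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restoreRNG <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' NMF consensus clustering at a fixed rank
#'
#' Runs \code{nRuns} random-restart factorizations; each run assigns every
#' sample to the argmax row of H (ties to the lowest row index). The
#' consensus matrix holds the fraction of runs in which two samples were
#' co-assigned; stability is summarized by the cophenetic correlation
#' between the consensus distances (1 - consensus) and the cophenetic
#' distances of their average-linkage dendrogram. Initial cluster labels are
#' the \code{rank}-group cut of that dendrogram.
#'
#' @param V nonnegative matrix, genes x samples.
#' @param rank number of clusters / factorization rank.
#' @param nRuns number of NMF runs (default 50, minimum 2).
#' @param seed master seed; per-run seeds are derived deterministically.
#' @param maxIter,tol per-run NMF controls.
#' @return a \code{\linkS4class{ConsensusResult}}.
#' @export
consensusCluster <- function(V, rank, nRuns = 50L, seed = 1L,
                             maxIter = 2000L, tol = 1e-6) {
  V <- as.matrix(V)
  p <- ncol(V)
  if (rank >= p) stop("rank must be smaller than the number of samples")
  if (nRuns < 2L) stop("nRuns must be at least 2")
  co <- matrix(0, p, p)
  for (r in seq_len(nRuns)) {
    fit <- nmfFactorize(V, rank, seed = .deriveSeed(seed, r),
                        maxIter = maxIter, tol = tol)
    a <- apply(coefMatrix(fit), 2, which.max)
    co <- co + outer(a, a, "==")
  }
  co <- co / nRuns
  dimnames(co) <- list(colnames(V), colnames(V))
  d <- stats::as.dist(1 - co)
  hc <- stats::hclust(d, method = "average")
  cd <- stats::cophenetic(hc)
  coph <- if (stats::sd(d) == 0 || stats::sd(cd) == 0) 1.0 else
    stats::cor(d, cd)
  labels <- stats::cutree(hc, k = rank)
  new("ConsensusResult", consensus = co, nRuns = as.integer(nRuns),
      rank = as.integer(rank), cophenetic = coph,
      labels = as.integer(labels))
}

#' Select the factorization rank by cophenetic correlation
#'
#' Runs consensus clustering over a grid of ranks and returns the rank with
#' the highest cophenetic correlation coefficient, plus the full per-rank
#' table for audit. Ties go to the smallest rank; because the consensus
#' matrix is estimated from finitely many runs, its cophenetic coefficient
#' carries Monte-Carlo error of order 1/sqrt(nRuns), so values within
#' \code{tieTol} of the maximum are treated as tied rather than ranked by
#' meaningless digits.
#'
#' @param V nonnegative matrix.
#' @param rankGrid integer vector of candidate ranks (default 2:7).
#' @param nRuns runs per rank.
#' @param seed master seed.
#' @param maxIter,tol per-run NMF controls.
#' @param tieTol cophenetic differences below this are ties (default 0.003).
#' @return list with \code{rank} (chosen), \code{table} (data.frame of rank
#'   and cophenetic), and \code{results} (per-rank
#'   \code{ConsensusResult}s, named by rank).
#' @export
selectRank <- function(V, rankGrid = 2:7, nRuns = 50L, seed = 1L,
                       maxIter = 2000L, tol = 1e-6, tieTol = 0.003) {
  if (!length(rankGrid)) stop("empty rank grid")
  results <- lapply(rankGrid, function(k)
    consensusCluster(V, k, nRuns = nRuns, seed = .deriveSeed(seed, 1000L + k),
                     maxIter = maxIter, tol = tol))
  names(results) <- as.character(rankGrid)
  tab <- data.frame(rank = rankGrid,
                    cophenetic = vapply(results, copheneticCoef, 0))
  chosen <- min(tab$rank[tab$cophenetic >= max(tab$cophenetic) - tieTol])
  list(rank = chosen, table = tab, results = results)
}

#' Mean-expression centroids per cluster
#'
#' @param V genes x samples matrix (the clustering gene set).
#' @param labels per-sample cluster labels, named by sample id.
#' @return genes x clusters matrix of centroid profiles.
#' @export
clusterCentroids <- function(V, labels) {
  labels <- labels[colnames(V)]
  sapply(sort(unique(as.character(labels))), function(cl)
    rowMeans(V[, labels == cl, drop = FALSE]))
}

#' Refine an initial consensus clustering
#'
#' Two-step biological refinement of the mathematical clusters: (1) clusters
#' smaller than \code{minSize} are excluded outright, their samples flagged
#' and dropped from all downstream statistics; (2) while more than
#' \code{targetK} clusters remain, the pair whose mean-expression centroids
#' are most Pearson-correlated is merged (the merged centroid is the
#' size-weighted mean). Every action is recorded in the refinement log, and
#' the procedure is deterministic given labels and centroids.
#'
#' @param labels initial per-sample cluster labels (named by sample id), or
#'   a \code{ConsensusResult}.
#' @param centroids genes x clusters centroid matrix
#'   (\code{\link{clusterCentroids}}); column names must match label values.
#' @param minSize exclusion threshold; default \code{max(4, ceiling(0.1 n))}.
#' @param targetK final number of clusters (default 3).
#' @return a \code{\linkS4class{ClusterAssignment}} with cluster ids
#'   \code{C<k>}.
#' @export
refineClusters <- function(labels, centroids, minSize = NULL, targetK = 3L) {
  if (is(labels, "ConsensusResult")) labels <- clusterLabels(labels)
  if (is.null(names(labels))) stop("labels must be named by sample id")
  lab <- as.character(labels)
  names(lab) <- names(labels)
  if (is.null(minSize)) minSize <- max(4L, ceiling(0.1 * length(lab)))
  log <- list(excluded = list(), merged = list())
  sizes <- table(lab)
  small <- names(sizes)[sizes < minSize]
  excluded <- character()
  for (cl in small) {
    smp <- names(lab)[lab == cl]
    log$excluded[[length(log$excluded) + 1L]] <-
      list(cluster = cl, size = length(smp), samples = smp)
    excluded <- c(excluded, smp)
    lab <- lab[lab != cl]
  }
  cents <- centroids[, setdiff(colnames(centroids), small), drop = FALSE]
  if (length(unique(lab)) < targetK)
    stop("cannot reach targetK = ", targetK, ": only ",
         length(unique(lab)), " clusters remain after exclusion")
  csize <- table(lab)
  while (length(unique(lab)) > targetK) {
    cls <- sort(unique(lab))
    cc <- stats::cor(cents[, cls, drop = FALSE])
    diag(cc) <- -Inf
    ij <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
    a <- cls[min(ij)]; b <- cls[max(ij)]
    log$merged[[length(log$merged) + 1L]] <-
      list(clusters = c(a, b), pearson_r = max(cc))
    na <- sum(lab == a); nb <- sum(lab == b)
    cents[, a] <- (na * cents[, a] + nb * cents[, b]) / (na + nb)
    cents <- cents[, colnames(cents) != b, drop = FALSE]
    lab[lab == b] <- a
  }
  final <- factor(paste0("C", match(lab, sort(unique(lab)))))
  names(final) <- names(lab)
  new("ClusterAssignment", labels = final, refinementLog = log,
      excludedSamples = excluded)
}

#' Rename clusters ImA/ImB/ImC by descending immune score
#'
#' The inflamed cluster (highest mean immune score) becomes ImA, the next
#' ImB, and so on.
#'
#' @param assignment a \code{ClusterAssignment}.
#' @param immuneScore per-sample immune score, named by sample id.
#' @return a \code{ClusterAssignment} with relabelled clusters.
#' @export
relabelByImmuneScore <- function(assignment, immuneScore) {
  lab <- clusterLabels(assignment)
  if (is.null(names(immuneScore)) || !all(names(lab) %in% names(immuneScore)))
    stop("immuneScore must be named and cover every labelled sample")
  means <- tapply(immuneScore[names(lab)], lab, mean)
  means <- means[!is.na(means)]
  ord <- names(sort(means, decreasing = TRUE))
  newNames <- stats::setNames(paste0("Im", LETTERS[seq_along(ord)]), ord)
  relab <- factor(unname(newNames[as.character(lab)]),
                  levels = paste0("Im", LETTERS[seq_along(ord)]))
  names(relab) <- names(lab)
  new("ClusterAssignment", labels = relab,
      refinementLog = refinementLog(assignment),
      excludedSamples = excludedSamples(assignment))
}

#' Per-cluster characterization table
#'
#' Summarizes every cluster: median of each signature score, mean
#' deconvolved cell fractions and per-type presence percentages (fraction of
#' samples with a nonzero fraction), percent TILs-high and median PLR.
#'
#' @param labels per-sample cluster labels (named), or a
#'   \code{ClusterAssignment}.
#' @param panel a \code{SignaturePanel}.
#' @param deconv optional \code{DeconvolutionResult}.
#' @param clinical optional clinical data.frame (needs \code{sample_id},
#'   \code{tils_percent}).
#' @param cbc optional CBC data.frame; PLR is computed per sample.
#' @return data.frame, one row per cluster.
#' @export
characterizeClusters <- function(labels, panel, deconv = NULL,
                                 clinical = NULL, cbc = NULL) {
  if (is(labels, "ClusterAssignment")) labels <- clusterLabels(labels)
  if (!length(labels)) stop("no labels")
  sc <- as.data.frame(scoreTable(panel))[names(labels), , drop = FALSE]
  cls <- if (is.factor(labels)) levels(labels) else sort(unique(labels))
  if (any(table(factor(labels, levels = cls)) == 0))
    stop("empty cluster: ",
         paste(cls[table(factor(labels, levels = cls)) == 0],
               collapse = ", "))
  rows <- lapply(cls, function(cl) {
    idx <- names(labels)[labels == cl]
    row <- data.frame(cluster = cl, n = length(idx))
    for (col in colnames(sc)) {
      if (is.numeric(sc[[col]]))
        row[[paste0("median_", col)]] <- stats::median(sc[idx, col])
    }
    if (!is.null(deconv)) {
      fr <- cellFractions(deconv)[idx, , drop = FALSE]
      for (ct in colnames(fr)) {
        row[[paste0("mean_frac_", ct)]] <- mean(fr[, ct])
        row[[paste0("present_pct_", ct)]] <- 100 * mean(fr[, ct] > 0)
      }
    }
    if (!is.null(clinical)) {
      tt <- clinical$tils_percent[match(idx, clinical$sample_id)]
      row$pct_tils_high <- 100 * mean(tilsHighFlag(tt))
    }
    if (!is.null(cbc)) {
      m <- cbc[match(idx, cbc$sample_id), ]
      row$median_plr <- stats::median(m$platelets / m$lymphocytes)
    }
    row
  })
  do.call(rbind, rows)
}
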