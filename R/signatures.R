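#' Signature scoring configuration
#'
#' Bundles every tunable of the scoring surface: the CYT gene pair, the
#' 18-gene tumor inflammation signature (TIS) list, the aggressive-score
#' coefficients (fixed published values), ssGSEA parameters, the
#' ESTIMATE-style stromal/immune marker sets, the purity cosine constants
#' and the immunophenoscore weight table. All gene lists are editable text
#' shipped under \code{inst/extdata}; pass replacements to use other panels.
#'
#' @param tisGenes character vector of TIS gene symbols (default: shipped
#'   18-symbol list).
#' @param aggressiveCoeffs named coefficients of the three-gene aggressive
#'   score; defaults are the published values and there is rarely a reason
#'   to touch them.
#' @param ssgseaAlpha rank-weight exponent for ssGSEA (default 0.25).
#' @param ssgseaMinSetSize minimum gene-set size (default 5).
#' @param ssgseaNormalize cohort-range rescaling of ssGSEA scores (default
#'   TRUE).
#' @param estimateStromal,estimateImmune marker gene vectors for the
#'   stromal/immune ssGSEA scores (defaults: shipped panels).
#' @param purityConstants the two constants of the purity cosine
#'   \code{purity = cos(c0 + c1 * estimate_score)}.
#' @param ipsWeights data.frame with columns \code{gene}, \code{category}
#'   (MHC / immunomodulator / effector / suppressor) and \code{weight}.
#' @return list of class \code{signatureConfig}.
#' @export
signatureConfig <- function(tisGenes = NULL,
                            aggressiveCoeffs = c(CCL5 = -0.393,
                                                 DDIT4 = 0.443,
                                                 POLR1C = 0.490),
                            ssgseaAlpha = 0.25,
                            ssgseaMinSetSize = 5,
                            ssgseaNormalize = TRUE,
                            estimateStromal = NULL,
                            estimateImmune = NULL,
                            purityConstants = c(0.6049872018, 0.0001467884),
                            ipsWeights = NULL) {
  ext <- function(f) system.file("extdata", f, package = "immunoCohort",
                                 mustWork = TRUE)
  if (is.null(tisGenes)) tisGenes <- readLines(ext("tis_genes.txt"))
  if (is.null(estimateStromal) || is.null(estimateImmune)) {
    gmt <- geneSets(readGeneSetsGMT(ext("signature_sets.gmt")))
    if (is.null(estimateStromal)) estimateStromal <- gmt$ESTIMATE_STROMAL
    if (is.null(estimateImmune)) estimateImmune <- gmt$ESTIMATE_IMMUNE
  }
  if (is.null(ipsWeights))
    ipsWeights <- utils::read.csv(ext("ips_weights.csv"),
                                  stringsAsFactors = FALSE)
  stopifnot(setequal(names(aggressiveCoeffs), c("CCL5", "DDIT4", "POLR1C")),
            ssgseaMinSetSize >= 2,
            all(c("gene", "category", "weight") %in% colnames(ipsWeights)))
  structure(list(cytGenes = c("GZMA", "PRF1"),
                 tisGenes = tisGenes,
                 aggressiveCoeffs = aggressiveCoeffs,
                 ssgseaAlpha = ssgseaAlpha,
                 ssgseaMinSetSize = ssgseaMinSetSize,
                 ssgseaNormalize = ssgseaNormalize,
                 estimateStromal = estimateStromal,
                 estimateImmune = estimateImmune,
                 purityConstants = purityConstants,
                 ipsWeights = ipsWeights),
            class = "signatureConfig")
}

.log2Rows <- function(x, genes, context) {
  m <- if (is(x, "ImmunoExperiment")) exprsOn(x, "log2") else as.matrix(x)
  miss <- setdiff(genes, rownames(m))
  if (length(miss))
    stop(context, ": gene(s) missing from expression matrix: ",
         paste(miss, collapse = ", "))
  m[genes, , drop = FALSE]
}

#' Cytolytic activity (CYT)
#'
#' Geometric mean of GZMA and PRF1 expression, computed on the log2 scale as
#' the arithmetic mean of the two log2 values (identical to log2 of the
#' geometric mean of linear intensities) and reported in log2 units.
#'
#' @param x an \code{ImmunoExperiment} or log2 matrix.
#' @param config a \code{\link{signatureConfig}}.
#' @return named per-sample numeric vector.
#' @export
cytScore <- function(x, config = signatureConfig()) {
  colMeans(.log2Rows(x, config$cytGenes, "cytScore"))
}

#' Tumor inflammation signature (TIS)
#'
#' Unweighted mean of log2 expression over the configured TIS genes present
#' in the matrix. Absent genes are reported in a warning; scoring with none
#' present is an error.
#'
#' @inheritParams cytScore
#' @return named per-sample numeric vector (log2 units).
#' @export
tisScore <- function(x, config = signatureConfig()) {
  m <- if (is(x, "ImmunoExperiment")) exprsOn(x, "log2") else as.matrix(x)
  present <- intersect(config$tisGenes, rownames(m))
  if (!length(present)) stop("tisScore: no TIS genes present")
  absent <- setdiff(config$tisGenes, present)
  if (length(absent))
    warning("tisScore: absent TIS genes: ", paste(absent, collapse = ", "))
  colMeans(m[present, , drop = FALSE])
}

#' Three-gene aggressive score
#'
#' The published linear combination of normalized (log2) expression:
#' \code{-0.393 * CCL5 + 0.443 * DDIT4 + 0.490 * POLR1C}.
#'
#' @inheritParams cytScore
#' @return named per-sample numeric vector.
#' @export
aggressiveScore <- function(x, config = signatureConfig()) {
  co <- config$aggressiveCoeffs
  m <- .log2Rows(x, names(co), "aggressiveScore")
  drop(crossprod(m, unname(co)))
}

#' Integrative immune score (IMS)
#'
#' \code{IMS = CYT * TIS - aggressive}, elementwise.
#'
#' @param cyt,tis,aggressive per-sample numeric vectors of equal length.
#' @return per-sample numeric vector.
#' @export
imsScore <- function(cyt, tis, aggressive) {
  if (length(cyt) != length(tis) || length(cyt) != length(aggressive))
    stop("imsScore: input lengths differ")
  cyt * tis - aggressive
}

#' ESTIMATE-style stromal, immune and purity scores
#'
#' Stromal and immune scores are unnormalized ssGSEA enrichment of the two
#' configured marker panels; their sum is the combined score, and tumor
#' purity is \code{cos(c0 + c1 * estimate_score)}. Purity is reported only
#' while the cosine argument stays in [0, pi/2]; outside that domain it is
#' NA (flagged undefined) rather than clamped to a fabricated fraction.
#'
#' @inheritParams cytScore
#' @return data.frame with columns \code{stromal_score, immune_score,
#'   estimate_score, purity}, one row per sample.
#' @export
estimateScores <- function(x, config = signatureConfig()) {
  sets <- list(stromal = config$estimateStromal,
               immune = config$estimateImmune)
  es <- ssgseaScores(x, sets, alpha = config$ssgseaAlpha,
                     minSize = config$ssgseaMinSetSize, normalize = FALSE)
  if (nrow(es) < 2L) stop("estimateScores: stromal/immune sets missing or too small")
  est <- es["stromal", ] + es["immune", ]
  arg <- config$purityConstants[1] + config$purityConstants[2] * est
  purity <- ifelse(arg >= 0 & arg <= pi / 2, cos(arg), NA_real_)
  data.frame(stromal_score = es["stromal", ], immune_score = es["immune", ],
             estimate_score = est, purity = purity,
             row.names = colnames(es))
}

#' Immunophenoscore (IPS)
#'
#' Genes are z-scored across samples; each of the four categories (MHC,
#' immunomodulator, effector, suppressor) contributes the weighted mean of
#' its gene z-scores (weights normalized by their absolute sum); the raw
#' score is the mean of the four category scores and is discretized to the
#' 0-10 scale as 0 when raw <= 0, otherwise \code{ceiling(10 * raw / 3)}
#' capped at 10.
#'
#' @inheritParams cytScore
#' @return list with \code{ips} (integer 0-10 per sample), \code{raw} and
#'   \code{categories} (samples x 4 matrix of category z means).
#' @export
immunophenoscore <- function(x, config = signatureConfig()) {
  m <- if (is(x, "ImmunoExperiment")) exprsOn(x, "log2") else as.matrix(x)
  wt <- config$ipsWeights
  wt <- wt[wt$gene %in% rownames(m), , drop = FALSE]
  cats <- c("MHC", "immunomodulator", "effector", "suppressor")
  if (!all(cats %in% wt$category)) {
    stop("immunophenoscore: empty category: ",
         paste(setdiff(cats, wt$category), collapse = ", "))
  }
  mu <- rowMeans(m); sdv <- apply(m, 1, stats::sd)
  catScore <- sapply(cats, function(cc) {
    sub <- wt[wt$category == cc, ]
    z <- (m[sub$gene, , drop = FALSE] - mu[sub$gene]) /
      ifelse(sdv[sub$gene] > 0, sdv[sub$gene], 1)
    drop(crossprod(z, sub$weight)) / sum(abs(sub$weight))
  })
  raw <- rowMeans(catScore)
  ips <- ifelse(raw <= 0, 0L, pmin(10L, as.integer(ceiling(10 * raw / 3))))
  list(ips = stats::setNames(ips, colnames(m)), raw = raw,
       categories = catScore)
}

#' Median dichotomization
#'
#' Splits values at their median; ties at the median go to the low group
#' (the "<= median" row convention of the association tables).
#'
#' @param values numeric vector, length >= 2.
#' @return factor with levels \code{low}, \code{high}, named like the input.
#' @export
dichotomizeByMedian <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  med <- stats::median(values)
  if (all(values == values[1L]))
    warning("all values identical; everything is 'low'")
  f <- factor(ifelse(values <= med, "low", "high"), levels = c("low", "high"))
  names(f) <- names(values)
  f
}

#' TILs-high flag
#'
#' TRUE for samples whose stromal TILs density is at or above the threshold
#' (inclusive at the boundary, default 20 percent).
#'
#' @param tilsPercent numeric vector in [0, 100].
#' @param threshold inclusion threshold (default 20).
#' @return logical vector.
#' @export
tilsHighFlag <- function(tilsPercent, threshold = 20) {
  if (any(tilsPercent < 0 | tilsPercent > 100, na.rm = TRUE))
    stop("tilsPercent outside [0, 100]")
  tilsPercent >= threshold
}

#' Compute the full signature panel
#'
#' Runs every per-sample score over a cohort: CYT, TIS, aggressive, IMS,
#' ssGSEA enrichment for each supplied gene set, the ESTIMATE-style scores
#' with purity, and the immunophenoscore.
#'
#' @param x an \code{ImmunoExperiment}.
#' @param sets optional \code{SignatureSets} (or named list) scored by
#'   ssGSEA; defaults to the shipped sets (CD8 activated program and the
#'   ESTIMATE panels).
#' @param config a \code{\link{signatureConfig}}.
#' @return a \code{\linkS4class{SignaturePanel}}.
#' @export
scorePanel <- function(x, sets = NULL, config = signatureConfig()) {
  if (is.null(sets)) {
    sets <- readGeneSetsGMT(system.file("extdata", "signature_sets.gmt",
                                        package = "immunoCohort",
                                        mustWork = TRUE))
  }
  cyt <- cytScore(x, config)
  tis <- tisScore(x, config)
  agg <- aggressiveScore(x, config)
  est <- estimateScores(x, config)
  ips <- immunophenoscore(x, config)
  es <- ssgseaScores(x, sets, alpha = config$ssgseaAlpha,
                     minSize = config$ssgseaMinSetSize,
                     normalize = config$ssgseaNormalize)
  df <- S4Vectors::DataFrame(
    cyt = cyt, tis = tis, aggressive = agg,
    ims = imsScore(cyt, tis, agg),
    stromal_score = est$stromal_score, immune_score = est$immune_score,
    estimate_score = est$estimate_score, purity = est$purity,
    ips = ips$ips, ips_raw = ips$raw,
    row.names = colnames(x))
  if (nrow(es)) {
    esdf <- S4Vectors::DataFrame(t(es))
    colnames(esdf) <- paste0("ssgsea_", rownames(es))
    df <- cbind(df, esdf)
  }
  new("SignaturePanel", scores = df)
}
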