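#' End-to-end pipeline run
#'
#' Orchestrates simulate/load, signature scoring, consensus clustering with
#' refinement, optional deconvolution, and the association stage, from one
#' declarative configuration list. Stage order is prerequisite-safe and a
#' partial failure stops with a stage-named error. One master seed
#' deterministically derives per-stage seeds, so identical configurations
#' give identical outputs.
#'
#' Configuration entries: exactly one of \code{simulate} (a
#' \code{\link{syntheticConfig}} or TRUE for defaults) or \code{input}
#' (list with paths \code{expression}, \code{cbc}, \code{clinical});
#' \code{seed} (mandatory); optional \code{cluster} block (\code{rankGrid},
#' \code{nRuns}, \code{targetK}, \code{topVarGenes}, \code{maxIter},
#' \code{tol}), \code{deconvolve} block (\code{signature} path or matrix,
#' \code{nPerm}), and \code{outDir} to write the results bundle.
#'
#' @param config named list as described above.
#' @return list (the results bundle): \code{cohort}, \code{panel},
#'   \code{clusters}, \code{rankTable}, \code{associations},
#'   \code{deconvolution} (or NULL), \code{summary}, and \code{manifest}
#'   when \code{outDir} was set.
#' @export
runPipeline <- function(config) {
  if (is.null(config$seed)) stop("preflight: config$seed is mandatory")
  hasSim <- !is.null(config$simulate)
  hasInput <- !is.null(config$input)
  if (hasSim == hasInput)
    stop("preflight: exactly one of 'simulate' or 'input' must be given")
  seed <- as.integer(config$seed)

  if (hasSim) {
    sc <- config$simulate
    if (isTRUE(sc)) sc <- syntheticConfig(seed = .deriveSeed(seed, 1L))
    cohort <- simulateCohort(sc)
    cbc <- cbcTable(cohort)
    clinical <- clinicalTable(cohort)
    immuneGenes <- rownames(cohort)[rowData(cohort)$immune_program]
  } else {
    inp <- config$input
    cohort <- readExpressionMatrix(inp$expression,
                                   format = inp$format %||% "tsv")
    cbc <- if (!is.null(inp$cbc)) readCBCTable(inp$cbc) else NULL
    clinical <- if (!is.null(inp$clinical)) readClinicalTable(inp$clinical)
      else NULL
    immuneGenes <- config$cluster$genes %||% rownames(cohort)
    for (tab in list(cbc, clinical)) {
      if (!is.null(tab)) {
        bad <- setdiff(colnames(cohort), tab$sample_id)
        if (length(bad))
          stop("preflight: sample ids missing from a clinical/CBC table: ",
               paste(bad, collapse = ", "))
      }
    }
  }
  if (!is.null(config$deconvolve) && is.null(config$deconvolve$signature))
    stop("preflight: deconvolution requested without a signature matrix")

  panel <- scorePanel(cohort, config = config$score %||% signatureConfig())

  cl <- config$cluster %||% list()
  V <- nonnegativeShift(exprsOn(cohort, "log2")[
    intersect(immuneGenes, rownames(cohort)), , drop = FALSE])
  topVar <- cl$topVarGenes %||% 250L
  if (nrow(V) > topVar) {
    v <- apply(V, 1, stats::var)
    V <- V[order(v, decreasing = TRUE)[seq_len(topVar)], , drop = FALSE]
  }
  sel <- selectRank(V, rankGrid = cl$rankGrid %||% 2:5,
                    nRuns = cl$nRuns %||% 20L,
                    seed = .deriveSeed(seed, 2L),
                    maxIter = cl$maxIter %||% 800L, tol = cl$tol %||% 1e-6)
  targetK <- cl$targetK %||% 3L
  # refinement can only merge down, so use the most stable rank >= targetK
  eligible <- sel$table[sel$table$rank >= targetK, , drop = FALSE]
  if (!nrow(eligible))
    stop("cluster stage: no rank in the grid reaches targetK = ", targetK)
  useRank <- eligible$rank[which.max(eligible$cophenetic)]
  cons <- sel$results[[as.character(useRank)]]
  cents <- clusterCentroids(V, clusterLabels(cons))
  refined <- refineClusters(cons, cents, minSize = cl$minSize,
                            targetK = targetK)
  immScore <- stats::setNames(scoreTable(panel)$immune_score,
                              rownames(scoreTable(panel)))
  clusters <- relabelByImmuneScore(refined, immScore)

  deconv <- NULL
  if (!is.null(config$deconvolve)) {
    sig <- config$deconvolve$signature
    if (is.character(sig)) sig <- readSignatureMatrix(sig)
    deconv <- deconvolveCohort(cohort, sig,
                               nPerm = config$deconvolve$nPerm %||% 100L,
                               seed = .deriveSeed(seed, 3L))
  }

  associations <- NULL
  if (!is.null(cbc)) {
    associations <- associateStage(panel, clusters, cbc, clinical)
  }

  keep <- names(clusterLabels(clusters))
  summaryTab <- characterizeClusters(
    clusterLabels(clusters), panel, deconv = deconv,
    clinical = if (!is.null(clinical))
      clinical[clinical$sample_id %in% keep, ] else NULL,
    cbc = if (!is.null(cbc)) cbc[cbc$sample_id %in% keep, ] else NULL)

  bundle <- list(cohort = cohort, panel = panel, clusters = clusters,
                 rankTable = sel$table, associations = associations,
                 deconvolution = deconv, summary = summaryTab)
  if (!is.null(config$outDir)) {
    bundle$manifest <- writeResultsBundle(panel, clusters, associations,
                                          config$outDir, seed = seed,
                                          config = config[setdiff(
                                            names(config), "score")])
  }
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Association stage: local immunity vs systemic inflammation
#'
#' Runs the statistics linking blood-count markers to the immuno-clusters
#' and signatures: Kruskal-Wallis of PLR across clusters, multinomial
#' odds ratios per 10 PLR units (crude and age-adjusted when age is
#' available), Spearman correlations (TIS vs PLR, TILs vs CD8 enrichment
#' when present), and the dichotomized PLR x aggressive-score odds ratio.
#'
#' @param panel a \code{SignaturePanel}.
#' @param clusters a \code{ClusterAssignment} (or named labels).
#' @param cbc CBC data.frame.
#' @param clinical optional clinical data.frame.
#' @return tidy data.frame of association results.
#' @export
associateStage <- function(panel, clusters, cbc, clinical = NULL) {
  labels <- if (is(clusters, "ClusterAssignment")) clusterLabels(clusters)
    else clusters
  ids <- names(labels)
  cbc <- computeRatios(cbc[match(ids, cbc$sample_id), ])
  sc <- as.data.frame(scoreTable(panel))[ids, ]
  age <- if (!is.null(clinical)) clinical$age_years[match(ids,
                                                          clinical$sample_id)]
  rows <- list()
  kw <- kruskalWallis(cbc$plr, labels)
  rows$kw <- data.frame(marker = "plr", contrast = "kruskal-wallis",
                        estimate = kw$H, ci_low = NA, ci_high = NA,
                        p_value = kw$p, scaling = "", adjustment = "")
  if (nlevels(factor(labels)) >= 3L) {
    mn <- multinomialLogistic(cbc$plr, labels, ref = levels(labels)[1L],
                              unitScale = 10, age = age)
    mn$marker <- "plr"
    rows$mn <- mn
  }
  sp <- spearmanRho(sc$tis, cbc$plr)
  rows$sp <- data.frame(marker = "tis_vs_plr", contrast = "spearman",
                        estimate = sp$rho, ci_low = NA, ci_high = NA,
                        p_value = sp$p, scaling = "", adjustment = "")
  cd8col <- grep("^ssgsea_CD8", colnames(sc), value = TRUE)
  if (!is.null(clinical) && length(cd8col)) {
    tils <- clinical$tils_percent[match(ids, clinical$sample_id)]
    sp2 <- spearmanRho(tils, sc[[cd8col[1L]]])
    rows$sp2 <- data.frame(marker = "tils_vs_cd8", contrast = "spearman",
                           estimate = sp2$rho, ci_low = NA, ci_high = NA,
                           p_value = sp2$p, scaling = "", adjustment = "")
  }
  plrHigh <- dichotomizeByMedian(cbc$plr) == "high"
  aggHigh <- dichotomizeByMedian(sc$aggressive) == "high"
  tab <- table(factor(plrHigh, c(TRUE, FALSE)),
               factor(aggHigh, c(TRUE, FALSE)))
  if (all(tab > 0)) {
    or <- oddsRatio2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    or$marker <- "plr_high_vs_aggressive_high"
    rows$or <- or
  }
  do.call(rbind, rows)
}

#' Human-readable run summary
#'
#' Markdown summary of a pipeline bundle: the per-cluster characterization
#' table and the association table; notes the omission when no CBC table
#' was available.
#'
#' @param bundle result of \code{\link{runPipeline}}.
#' @return character vector of markdown lines (also printable with
#'   \code{cat}).
#' @export
reportSummary <- function(bundle) {
  lines <- c("# Immuno-cluster run summary", "")
  s <- bundle$summary
  cols <- intersect(c("cluster", "n", "median_cyt", "median_tis",
                      "median_aggressive", "median_ims", "median_plr",
                      "pct_tils_high"), colnames(s))
  tab <- s[, cols, drop = FALSE]
  num <- vapply(tab, is.numeric, NA)
  tab[num] <- lapply(tab[num], function(v) signif(v, 4))
  lines <- c(lines, "## Clusters", "",
             paste(colnames(tab), collapse = " | "),
             paste(rep("---", ncol(tab)), collapse = " | "),
             apply(tab, 1, paste, collapse = " | "), "")
  if (is.null(bundle$associations)) {
    lines <- c(lines, "## Associations", "",
               "No CBC table available; association stage omitted.", "")
  } else {
    a <- bundle$associations
    a$estimate <- signif(a$estimate, 4)
    a$p_value <- signif(a$p_value, 3)
    lines <- c(lines, "## Associations", "",
               paste(colnames(a), collapse = " | "),
               paste(rep("---", ncol(a)), collapse = " | "),
               apply(a, 1, function(r) paste(r, collapse = " | ")), "")
  }
  lines
}
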