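#' Synthetic cohort configuration
#'
#' Defaults encode the cohort structure the analysis assumes: 54 samples in
#' three latent immuno-clusters of sizes 15/18/21 with graded activation of
#' an immune gene program (log2 shifts +1.5 / 0 / +0.5 for the inflamed,
#' excluded and intermediate clusters), TILs density linearly linked to the
#' per-sample CD8-program mean, per-cluster lognormal PLR medians 132/162/176
#' (the signal carried by platelets, not NLR), and exponential recurrence
#' times with a higher hazard in the non-inflamed clusters, administratively
#' censored at five years.
#'
#' @param nSamples cohort size (default 54).
#' @param clusterSizes per-cluster sizes, must sum to \code{nSamples}
#'   (default 15, 18, 21 for ImA/ImB/ImC).
#' @param nImmuneGenes size of the immune gene program (default 708); real
#'   HGNC symbols are used for every signature gene, filler symbols for the
#'   rest.
#' @param nBackgroundGenes cluster-independent genes (default 2000).
#' @param immuneShift per-cluster log2 activation shift on immune-program
#'   genes (default +1.5, 0, +0.5).
#' @param nClusterModuleGenes size of each cluster-identity gene module
#'   (default 60). Real cohorts separate because every cluster carries its
#'   own expression program, not just a graded level of one shared program
#'   (default 100); each cluster gets a disjoint module (drawn from the
#'   unnamed immune filler genes) elevated by \code{clusterModuleShift} in
#'   that cluster only. Set to 0 (or \code{clusterModuleShift = 0}) for a
#'   null cohort with no recoverable structure.
#' @param clusterModuleShift log2 elevation of a cluster's own module
#'   (default 2).
#' @param noiseSd per-gene Gaussian log2 noise (default 0.6).
#' @param tilsLink list(intercept, slope, noiseSd) linking the per-sample
#'   CD8-program mean (log2) to TILs percent, clamped to [0, 100].
#' @param plrLink list(medians, sdlog, lymphMedian, lymphSdlog): per-cluster
#'   lognormal PLR medians and dispersions; platelets are drawn as
#'   PLR-median x lymphocyte-median lognormals so the ratio has the target
#'   median.
#' @param neutrophilMedian,neutrophilSdlog,monocyteMedian,monocyteSdlog
#'   lognormal parameters of the cluster-independent counts (10^9 cells/L).
#' @param hazardRatioNoninflamed recurrence hazard of the non-inflamed
#'   clusters relative to the inflamed one (default 3).
#' @param fiveYearEventInflamed five-year event probability in the inflamed
#'   cluster (default 0.10) fixing the baseline exponential hazard.
#' @param horizonDays administrative censoring horizon (default 1826, five
#'   years).
#' @param seed integer RNG seed.
#' @return list of class \code{syntheticConfig}.
#' @export
syntheticConfig <- function(nSamples = 54L,
                            clusterSizes = c(ImA = 15L, ImB = 18L, ImC = 21L),
                            nImmuneGenes = 708L,
                            nBackgroundGenes = 2000L,
                            immuneShift = c(ImA = 1.5, ImB = 0, ImC = 0.5),
                            nClusterModuleGenes = 100L,
                            clusterModuleShift = 2,
                            noiseSd = 0.6,
                            tilsLink = list(intercept = -70, slope = 12,
                                            noiseSd = 10),
                            plrLink = list(medians = c(ImA = 132, ImB = 162,
                                                       ImC = 176),
                                           sdlog = 0.18,
                                           lymphMedian = 1.85,
                                           lymphSdlog = 0.2),
                            neutrophilMedian = 4.4, neutrophilSdlog = 0.25,
                            monocyteMedian = 0.5, monocyteSdlog = 0.3,
                            hazardRatioNoninflamed = 3,
                            fiveYearEventInflamed = 0.10,
                            horizonDays = 1826L,
                            seed = 1L) {
  cfg <- list(nSamples = as.integer(nSamples),
              clusterSizes = clusterSizes,
              nImmuneGenes = as.integer(nImmuneGenes),
              nBackgroundGenes = as.integer(nBackgroundGenes),
              immuneShift = immuneShift,
              nClusterModuleGenes = as.integer(nClusterModuleGenes),
              clusterModuleShift = clusterModuleShift,
              noiseSd = noiseSd,
              tilsLink = tilsLink, plrLink = plrLink,
              neutrophilMedian = neutrophilMedian,
              neutrophilSdlog = neutrophilSdlog,
              monocyteMedian = monocyteMedian,
              monocyteSdlog = monocyteSdlog,
              hazardRatioNoninflamed = hazardRatioNoninflamed,
              fiveYearEventInflamed = fiveYearEventInflamed,
              horizonDays = as.integer(horizonDays),
              seed = as.integer(seed))
  if (sum(cfg$clusterSizes) != cfg$nSamples)
    stop("cluster sizes must sum to nSamples")
  if (any(cfg$clusterSizes <= 0L))
    stop("degenerate config: zero-size cluster")
  if (cfg$noiseSd <= 0 || cfg$plrLink$sdlog <= 0 || cfg$plrLink$lymphSdlog <= 0)
    stop("all standard deviations must be positive")
  if (any(cfg$plrLink$medians <= 0))
    stop("PLR medians must be positive")
  structure(cfg, class = "syntheticConfig")
}

# signature genes guaranteed present so every scoring operation runs unmodified
.signatureGenes <- function() {
  ext <- function(f) system.file("extdata", f, package = "immunoCohort",
                                 mustWork = TRUE)
  tis <- readLines(ext("tis_genes.txt"))
  gmt <- geneSets(readGeneSetsGMT(ext("signature_sets.gmt")))
  ips <- utils::read.csv(ext("ips_weights.csv"), stringsAsFactors = FALSE)
  immuneProgram <- unique(c("GZMA", "PRF1", "CCL5", tis, gmt$CD8_ACTIVATED,
                            gmt$ESTIMATE_IMMUNE,
                            ips$gene[ips$category != "suppressor"]))
  background <- unique(c("DDIT4", "POLR1C", gmt$ESTIMATE_STROMAL,
                         ips$gene[ips$category == "suppressor"]))
  background <- setdiff(background, immuneProgram)
  list(immune = immuneProgram, background = background,
       cd8 = gmt$CD8_ACTIVATED)
}

#' Simulate a cohort with known ground truth
#'
#' Draws a full cohort under \code{\link{syntheticConfig}}: expression
#' (baseline + cluster activation shift + Gaussian log2 noise on
#' immune-program genes; background genes cluster-independent), a CBC table
#' whose platelet/lymphocyte draws give the configured per-cluster PLR
#' medians, TILs linked linearly to the per-sample CD8-program mean, and
#' exponential recurrence times with cluster-dependent hazard censored at
#' the horizon. Ground-truth labels and the generating config travel with
#' the object.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return an \code{\linkS4class{ImmunoExperiment}} whose \code{colData}
#'   carries \code{true_cluster}, the CBC columns, and the clinical columns;
#'   \code{rowData} flags the immune and CD8 programs;
#'   \code{metadata(x)$truthParams} stores the config.
#' @export
simulateCohort <- function(config = syntheticConfig()) {
  old <- .saveRNG()
  on.exit(.restoreRNG(old), add = TRUE)
  set.seed(config$seed)
  sig <- .signatureGenes()
  nIm <- config$nImmuneGenes
  nBg <- config$nBackgroundGenes
  if (length(sig$immune) > nIm)
    stop("nImmuneGenes smaller than the named signature program")
  immuneGenes <- c(sig$immune,
                   sprintf("IMM%04d", seq_len(nIm - length(sig$immune))))
  bgFill <- nBg - length(sig$background)
  backgroundGenes <- c(sig$background,
                       if (bgFill > 0) sprintf("BG%04d", seq_len(bgFill)))
  genes <- c(immuneGenes, backgroundGenes)
  n <- config$nSamples
  sampleIds <- sprintf("TN%02d", seq_len(n))
  clusters <- rep(names(config$clusterSizes), config$clusterSizes)
  names(clusters) <- sampleIds

  base <- c(stats::rnorm(length(immuneGenes), 7, 0.5),
            stats::rnorm(length(backgroundGenes), 7, 1))
  shift <- config$immuneShift[clusters]
  m <- matrix(base, length(genes), n,
              dimnames = list(genes, sampleIds))
  m[immuneGenes, ] <- m[immuneGenes, ] +
    matrix(shift, length(immuneGenes), n, byrow = TRUE)
  # disjoint cluster-identity modules carved out of the immune filler genes
  moduleAssign <- rep(NA_character_, length(genes))
  names(moduleAssign) <- genes
  nMod <- config$nClusterModuleGenes
  if (nMod > 0L && config$clusterModuleShift != 0) {
    filler <- grep("^IMM", immuneGenes, value = TRUE)
    if (length(filler) < nMod * length(config$clusterSizes))
      stop("not enough immune filler genes for the cluster-identity modules")
    for (k in seq_along(config$clusterSizes)) {
      cl <- names(config$clusterSizes)[k]
      mod <- filler[seq.int((k - 1L) * nMod + 1L, k * nMod)]
      moduleAssign[mod] <- cl
      m[mod, clusters == cl] <- m[mod, clusters == cl] +
        config$clusterModuleShift
    }
  }
  m <- m + matrix(stats::rnorm(length(m), 0, config$noiseSd), nrow(m))

  cd8mean <- colMeans(m[intersect(sig$cd8, genes), , drop = FALSE])
  tl <- config$tilsLink
  tils <- pmin(100, pmax(0, tl$intercept + tl$slope * cd8mean +
                           stats::rnorm(n, 0, tl$noiseSd)))

  pl <- config$plrLink
  lymph <- stats::rlnorm(n, log(pl$lymphMedian), pl$lymphSdlog)
  plat <- stats::rlnorm(n, log(pl$medians[clusters] * pl$lymphMedian),
                        pl$sdlog)
  neut <- stats::rlnorm(n, log(config$neutrophilMedian),
                        config$neutrophilSdlog)
  mono <- stats::rlnorm(n, log(config$monocyteMedian), config$monocyteSdlog)

  lambdaA <- -log(1 - config$fiveYearEventInflamed) / config$horizonDays
  hr <- ifelse(clusters == names(config$clusterSizes)[1L], 1,
               config$hazardRatioNoninflamed)
  tEvent <- stats::rexp(n, rate = lambdaA * hr)
  eventFlag <- as.integer(tEvent <= config$horizonDays)
  tObs <- pmin(tEvent, config$horizonDays)

  age <- round(pmin(85, pmax(28, stats::rnorm(n, 55, 10))))

  cd <- S4Vectors::DataFrame(
    true_cluster = clusters,
    neutrophils = neut, lymphocytes = lymph, platelets = plat,
    monocytes = mono,
    age_years = age, tils_percent = tils,
    time_to_event_days = tObs, event_flag = eventFlag,
    row.names = sampleIds)
  x <- ImmunoExperiment(m, scaleTag = "log2", colData = cd,
                        metadata = list(truthParams = config))
  SummarizedExperiment::rowData(x)$immune_program <- genes %in% immuneGenes
  SummarizedExperiment::rowData(x)$cd8_program <- genes %in% sig$cd8
  SummarizedExperiment::rowData(x)$cluster_module <- unname(moduleAssign)
  x
}

#' Ground-truth cluster labels of a simulated cohort
#' @param cohort a cohort from \code{\link{simulateCohort}}.
#' @return named character vector of true cluster ids.
#' @export
truthLabels <- function(cohort) {
  stats::setNames(colData(cohort)$true_cluster, colnames(cohort))
}

#' CBC table of a cohort
#' @param cohort an \code{ImmunoExperiment} with CBC columns in colData.
#' @return data.frame with sample_id and the four counts.
#' @export
cbcTable <- function(cohort) {
  cd <- colData(cohort)
  data.frame(sample_id = colnames(cohort),
             neutrophils = cd$neutrophils, lymphocytes = cd$lymphocytes,
             platelets = cd$platelets, monocytes = cd$monocytes)
}

#' Clinical table of a cohort
#' @param cohort an \code{ImmunoExperiment} with clinical columns in colData.
#' @return data.frame with sample_id, age, TILs and follow-up columns.
#' @export
clinicalTable <- function(cohort) {
  cd <- colData(cohort)
  data.frame(sample_id = colnames(cohort),
             age_years = cd$age_years, tils_percent = cd$tils_percent,
             time_to_event_days = cd$time_to_event_days,
             event_flag = cd$event_flag)
}

#' Generating parameters vs empirical cohort summaries
#'
#' Deterministic per-cluster comparison of what the generator targeted and
#' what the drawn cohort shows: activation shift vs mean immune-program
#' expression, target vs empirical median PLR, mean TILs, empirical vs
#' closed-form expected censoring fraction.
#'
#' @param cohort a cohort from \code{\link{simulateCohort}}.
#' @return data.frame, one row per true cluster.
#' @export
truthReport <- function(cohort) {
  cfg <- metadata(cohort)$truthParams
  if (is.null(cfg)) stop("cohort carries no truthParams; not a simulated cohort")
  lab <- truthLabels(cohort)
  m <- exprsOn(cohort, "log2")
  im <- rowData(cohort)$immune_program
  cbc <- cbcTable(cohort); cli <- clinicalTable(cohort)
  lambdaA <- -log(1 - cfg$fiveYearEventInflamed) / cfg$horizonDays
  do.call(rbind, lapply(names(cfg$clusterSizes), function(cl) {
    idx <- names(lab)[lab == cl]
    hr <- if (cl == names(cfg$clusterSizes)[1L]) 1 else
      cfg$hazardRatioNoninflamed
    data.frame(
      cluster = cl,
      n = length(idx),
      shift_target = unname(cfg$immuneShift[cl]),
      immune_mean_emp = mean(m[im, idx]),
      plr_target = unname(cfg$plrLink$medians[cl]),
      plr_median_emp = stats::median(
        cbc$platelets[cbc$sample_id %in% idx] /
          cbc$lymphocytes[cbc$sample_id %in% idx]),
      tils_mean_emp = mean(cli$tils_percent[cli$sample_id %in% idx]),
      censor_frac_expected = exp(-lambdaA * hr * cfg$horizonDays),
      censor_frac_emp = mean(cli$event_flag[cli$sample_id %in% idx] == 0))
  }))
}

#' Write cohort tables to disk
#'
#' Emits the same TSV/CSV artifacts the readers consume: expression TSV,
#' CBC CSV and clinical CSV.
#'
#' @param cohort a cohort \code{ImmunoExperiment}.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
writeCohortTables <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "expression.tsv")
  writeExpressionMatrix(cohort, p1)
  p2 <- file.path(dir, "cbc.csv")
  utils::write.csv(cbcTable(cohort), p2, row.names = FALSE, quote = FALSE)
  p3 <- file.path(dir, "clinical.csv")
  utils::write.csv(clinicalTable(cohort), p3, row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2, p3))
}
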