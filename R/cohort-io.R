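#' Read a genes x samples expression matrix
#'
#' Reads plain TSV (first column gene symbols, header row of sample ids) or
#' GCT 1.2 (version line \code{#1.2}, dimensions line, \code{Name} and
#' \code{Description} columns). Duplicate gene symbols are collapsed by
#' per-gene maximum; collapsed symbols are recorded in the load report
#' (\code{metadata(x)$loadReport}).
#'
#' @param path path to the expression file.
#' @param format \code{"tsv"} or \code{"gct"}.
#' @param scaleTag scale of the stored values, \code{"log2"} (default) or
#'   \code{"linear"}; files are assumed log2 unless declared otherwise.
#' @return an \code{\linkS4class{ImmunoExperiment}}.
#' @export
readExpressionMatrix <- function(path, format = c("tsv", "gct"),
                                 scaleTag = "log2") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "gct") {
    if (length(lines) < 3L || !startsWith(trimws(lines[1L]), "#1.2"))
      stop("malformed GCT header at line 1: expected version line '#1.2'")
    hdr <- strsplit(lines[3L], "\t", fixed = TRUE)[[1L]]
    if (length(hdr) < 3L || hdr[1L] != "Name" || hdr[2L] != "Description")
      stop("malformed GCT header at line 3: expected 'Name' and 'Description' columns")
    body <- lines[-(1:2)]
    idCol <- 1L; dropCols <- 2L
  } else {
    if (length(lines) < 2L) stop("malformed TSV: need header plus data rows")
    body <- lines
    idCol <- 1L; dropCols <- integer()
  }
  tab <- utils::read.delim(text = body, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  sampleIds <- colnames(tab)[-c(idCol, dropCols)]
  if (anyDuplicated(sampleIds))
    stop("duplicate sample ids: ",
         paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
  genes <- as.character(tab[[idCol]])
  vals <- as.matrix(tab[, sampleIds, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression values in ", path)
  collapsed <- character()
  if (anyDuplicated(genes)) {
    collapsed <- unique(genes[duplicated(genes)])
    # max-collapse duplicated symbols (deterministic, scale-robust)
    vals <- do.call(rbind, lapply(split(seq_along(genes), genes), function(i) {
      apply(vals[i, , drop = FALSE], 2, max)
    }))
    vals <- vals[unique(genes), , drop = FALSE]
  } else {
    rownames(vals) <- genes
  }
  ImmunoExperiment(vals, scaleTag = scaleTag,
                   metadata = list(loadReport = list(
                     path = path, format = format,
                     collapsedGenes = collapsed)))
}

#' Write an expression matrix as TSV
#'
#' Inverse of \code{\link{readExpressionMatrix}}'s TSV dialect; full stored
#' precision so a write/read round trip is exact.
#'
#' @param x an \code{ImmunoExperiment}.
#' @param path output path.
#' @export
writeExpressionMatrix <- function(x, path) {
  m <- assay(x, "exprs")
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then gene symbols, tab-separated.
#' Duplicate symbols within a set are removed; sets with fewer than two
#' distinct genes are rejected with a warning.
#'
#' @param path GMT file path.
#' @return a \code{\linkS4class{SignatureSets}}.
#' @export
readGeneSetsGMT <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(SignatureSets(list()))
  }
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, ": fewer than 3 fields")
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) < 2L) {
      warning("set '", f[1L], "' has fewer than 2 genes; rejected")
      next
    }
    sets[[f[1L]]] <- genes
    desc[f[1L]] <- f[2L]
  }
  SignatureSets(sets, descriptions = unname(desc[names(sets)]))
}

#' Write gene sets to GMT
#' @param x a \code{SignatureSets}.
#' @param path output path.
#' @export
writeGeneSetsGMT <- function(x, path) {
  sets <- geneSets(x)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], x@descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

.readSampleTable <- function(path, required, optional = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% colnames(tab))
    stop("mandatory column 'sample_id' missing in ", path)
  miss <- setdiff(required, colnames(tab))
  if (length(miss))
    stop("mandatory columns missing in ", path, ": ", paste(miss, collapse = ", "))
  keep <- stats::complete.cases(tab[, c("sample_id", required), drop = FALSE]) &
    nzchar(as.character(tab$sample_id))
  dropped <- as.character(tab$sample_id[!keep])
  tab <- tab[keep, , drop = FALSE]
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample ids in ", path)
  rownames(tab) <- NULL
  attr(tab, "dropped") <- dropped
  tab
}

#' Read a complete-blood-count table
#'
#' CSV with columns \code{sample_id, neutrophils, lymphocytes, platelets} and
#' optionally \code{monocytes}, all in 10^9 cells/L. Rows missing a mandatory
#' field are dropped (and listed in the \code{"dropped"} attribute);
#' nonpositive counts are a validation error since the lymphocyte ratios
#' PLR and NLR would be undefined.
#'
#' @param path CSV file path.
#' @return data.frame of validated CBC records.
#' @export
readCBCTable <- function(path) {
  tab <- .readSampleTable(path, c("neutrophils", "lymphocytes", "platelets"),
                          optional = "monocytes")
  for (col in intersect(c("neutrophils", "lymphocytes", "platelets", "monocytes"),
                        colnames(tab))) {
    v <- tab[[col]]
    if (any(!is.na(v) & v <= 0))
      stop("nonpositive ", col, " count in ", path,
           " (ratios would be undefined)")
  }
  tab
}

#' Read a clinical table
#'
#' CSV with columns \code{sample_id, age_years, tils_percent,
#' time_to_event_days, event_flag}. TILs density must lie in [0, 100],
#' event flags must be 0/1 and event times nonnegative.
#'
#' @param path CSV file path.
#' @return data.frame of validated clinical records.
#' @export
readClinicalTable <- function(path) {
  tab <- .readSampleTable(path, c("age_years", "tils_percent",
                                  "time_to_event_days", "event_flag"))
  if (any(tab$tils_percent < 0 | tab$tils_percent > 100))
    stop("tils_percent outside [0, 100] in ", path)
  if (!all(tab$event_flag %in% c(0, 1)))
    stop("event_flag must be 0/1 in ", path)
  if (any(tab$time_to_event_days < 0))
    stop("negative time_to_event_days in ", path)
  if (any(tab$age_years <= 0))
    stop("nonpositive age_years in ", path)
  tab
}

#' Write the results bundle of a run
#'
#' Deterministic CSV outputs (signature scores, cluster labels, association
#' tables) plus a JSON manifest recording the seed, a configuration hash and
#' the file list.
#'
#' @param panel a \code{SignaturePanel}.
#' @param clusters a \code{ClusterAssignment}.
#' @param associations data.frame of association results (tidy: marker,
#'   contrast, estimate, ci_low, ci_high, p, adjustment), or NULL.
#' @param outDir output directory, created if needed.
#' @param seed master seed recorded in the manifest.
#' @param config optional configuration list; its serialized hash lands in the
#'   manifest.
#' @return invisibly, the manifest list (with a \code{files} entry).
#' @export
writeResultsBundle <- function(panel, clusters, associations, outDir,
                               seed = NA_integer_, config = list()) {
  sc <- as.data.frame(scoreTable(panel))
  lab <- clusterLabels(clusters)
  scored <- rownames(sc)
  labelled <- c(names(lab), excludedSamples(clusters))
  if (!setequal(scored, labelled) && !all(scored %in% labelled))
    stop("cluster labels missing for samples: ",
         paste(setdiff(scored, labelled), collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) stop("cannot create output directory ", outDir)

  scoresPath <- file.path(outDir, "signature_scores.csv")
  utils::write.csv(data.frame(sample_id = rownames(sc), sc,
                              check.names = FALSE),
                   scoresPath, row.names = FALSE, quote = FALSE)
  labPath <- file.path(outDir, "cluster_labels.csv")
  labDf <- data.frame(
    sample_id = c(names(lab), excludedSamples(clusters)),
    im_cluster = c(as.character(lab),
                   rep(NA_character_, length(excludedSamples(clusters)))),
    excluded = c(rep(FALSE, length(lab)),
                 rep(TRUE, length(excludedSamples(clusters)))))
  utils::write.csv(labDf, labPath, row.names = FALSE, quote = FALSE)
  files <- c(scoresPath, labPath)
  if (!is.null(associations)) {
    assocPath <- file.path(outDir, "associations.csv")
    utils::write.csv(associations, assocPath, row.names = FALSE, quote = FALSE)
    files <- c(files, assocPath)
  }
  manifest <- list(
    seed = seed,
    config_hash = .configHash(config),
    files = basename(files),
    n_samples = nrow(sc),
    n_excluded = length(excludedSamples(clusters)))
  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, digits = NA)
  manifest$files <- c(manifest$files, basename(manifestPath))
  invisible(manifest)
}

.configHash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  # small deterministic polynomial hash; avoids a digest dependency
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
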