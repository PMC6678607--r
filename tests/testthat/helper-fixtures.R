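# Shared fixtures, all built in code at test time.

suppressPackageStartupMessages(library(SummarizedExperiment))

# small log2 expression matrix with named genes
makeExprs <- function(nGenes = 10, nSamples = 4, seed = 1,
                      genes = sprintf("G%02d", seq_len(nGenes))) {
  set.seed(seed)
  matrix(rnorm(nGenes * nSamples, 7, 1), nGenes, nSamples,
         dimnames = list(genes, sprintf("S%02d", seq_len(nSamples))))
}

writeTsvFixture <- function(m, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

writeGctFixture <- function(m, path = tempfile(fileext = ".gct")) {
  con <- file(path, "w")
  writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
  df <- data.frame(Name = rownames(m), Description = "na", m,
                   check.names = FALSE)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  close(con)
  path
}

# independent brute-force transcription of the ssGSEA running-sum
# definition: explicit walk, recomputing both CDFs step by step
ssgseaOracle <- function(m, set, alpha = 0.25) {
  vapply(seq_len(ncol(m)), function(j) {
    e <- m[, j]
    genes <- rownames(m)
    r <- rank(e, ties.method = "average")
    names(r) <- genes
    walk <- genes[order(-e, genes)]
    inset <- walk %in% set
    denom <- sum(r[walk[inset]]^alpha)
    nOut <- sum(!inset)
    pin <- 0; pout <- 0; es <- 0
    for (i in seq_along(walk)) {
      if (inset[i]) pin <- pin + r[walk[i]]^alpha / denom
      else pout <- pout + 1 / nOut
      es <- es + (pin - pout)
    }
    es
  }, 0)
}

# block-marker signature matrix for deconvolution tests
makeSignatureMatrix <- function(nGenes = 200, nTypes = 5, seed = 42) {
  set.seed(seed)
  sig <- matrix(rlnorm(nGenes * nTypes, 3, 0.4), nGenes, nTypes,
                dimnames = list(sprintf("G%03d", seq_len(nGenes)),
                                paste0("T", seq_len(nTypes))))
  per <- nGenes %/% nTypes
  for (k in seq_len(nTypes))
    sig[((k - 1) * per + 1):(k * per), k] <-
      sig[((k - 1) * per + 1):(k * per), k] * 8
  sig
}
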