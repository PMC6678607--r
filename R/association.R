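#' Systemic inflammation ratios from a CBC table
#'
#' PLR = platelets / lymphocytes, NLR = neutrophils / lymphocytes; raw
#' counts are carried through.
#'
#' @param cbc data.frame from \code{\link{readCBCTable}}.
#' @return data.frame with \code{plr} and \code{nlr} columns added.
#' @export
computeRatios <- function(cbc) {
  if (any(cbc$lymphocytes <= 0))
    stop("nonpositive lymphocyte count: PLR/NLR undefined")
  cbc$plr <- cbc$platelets / cbc$lymphocytes
  cbc$nlr <- cbc$neutrophils / cbc$lymphocytes
  cbc
}

.assocRow <- function(estimate, se, marker = NA, contrast = NA,
                      scaling = "per-unit", adjustment = "crude") {
  z <- log(estimate) / se
  data.frame(marker = marker, contrast = contrast,
             estimate = estimate,
             ci_low = exp(log(estimate) - 1.96 * se),
             ci_high = exp(log(estimate) + 1.96 * se),
             p_value = 2 * stats::pnorm(-abs(z)),
             scaling = scaling, adjustment = adjustment,
             stringsAsFactors = FALSE)
}

#' Crude odds ratio of a 2x2 table
#'
#' OR = (a d) / (b c) with the 95 percent Wald interval
#' \code{exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))} and a two-sided
#' Wald p-value. Rows are exposure, columns outcome. A zero cell makes the
#' OR undefined; the optional Haldane-Anscombe +0.5 correction (off by
#' default) can be switched on instead.
#'
#' @param a,b,c,d cell counts, or pass a 2x2 matrix as \code{a}.
#' @param haldane add 0.5 to every cell when any cell is zero.
#' @return one-row data.frame (estimate, ci_low, ci_high, p_value, ...).
#' @export
oddsRatio2x2 <- function(a, b = NULL, c = NULL, d = NULL, haldane = FALSE) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2L))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("negative cell count")
  if (any(cells == 0)) {
    if (!haldane)
      stop("zero cell: OR undefined (set haldane = TRUE for the +0.5 correction)")
    cells <- cells + 0.5
  }
  orhat <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  .assocRow(orhat, se, contrast = "2x2")
}

#' Binomial logistic regression with Wald odds ratios
#'
#' Maximum-likelihood fit (iteratively reweighted least squares via
#' \code{glm}); returns exp(coefficient) odds ratios with 95 percent Wald
#' intervals per covariate. Supports the crude (single covariate) and
#' age-adjusted modes; age enters as a binary \code{>= 50} indicator by
#' default, continuous age behind \code{ageBinary = FALSE}.
#'
#' @param X covariate matrix or data.frame (numeric columns).
#' @param y binary outcome (0/1 or logical).
#' @param age optional age vector for adjustment.
#' @param ageBinary dichotomize age at 50 (default TRUE).
#' @param maxit IRLS iteration cap (default 100).
#' @return data.frame, one row per covariate (intercept and age term
#'   excluded).
#' @export
binomialLogistic <- function(X, y, age = NULL, ageBinary = TRUE,
                             maxit = 100L) {
  X <- as.data.frame(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("outcome is constant; model degenerate")
  if (nrow(X) <= ncol(X) + 1L) stop("more covariates than observations")
  dat <- cbind(X, .y = y)
  adjustment <- "crude"
  if (!is.null(age)) {
    dat$.age <- if (ageBinary) as.integer(age >= 50) else age
    adjustment <- "age-adjusted"
  }
  fml <- stats::as.formula(paste(".y ~",
                                 paste(setdiff(colnames(dat), ".y"),
                                       collapse = " + ")))
  fit <- stats::glm(fml, family = stats::binomial(), data = dat,
                    control = stats::glm.control(maxit = maxit,
                                                 epsilon = 1e-10))
  if (!fit$converged)
    stop("logistic fit did not converge after ", maxit,
         " iterations; last deviance ", format(fit$deviance))
  co <- summary(fit)$coefficients
  keep <- setdiff(rownames(co), c("(Intercept)", ".age"))
  if (any(abs(co[keep, "Estimate"]) > 15))
    stop("perfect separation suspected for covariate(s): ",
         paste(keep[abs(co[keep, "Estimate"]) > 15], collapse = ", "))
  do.call(rbind, lapply(keep, function(k)
    .assocRow(exp(co[k, "Estimate"]), co[k, "Std. Error"], marker = k,
              contrast = "binomial", adjustment = adjustment)))
}

#' Multinomial logistic regression against a reference cluster
#'
#' Baseline-category logit fit of cluster membership on a continuous
#' marker, ImA (or any chosen cluster) as the referent. Returns the odds
#' ratio per \code{unitScale} marker units for every non-reference cluster
#' with Wald 95 percent intervals; PLR is conventionally scaled per 10
#' units, other markers per unit.
#'
#' @param x continuous marker, one value per sample.
#' @param labels cluster labels (factor or character).
#' @param ref reference cluster (default \code{"ImA"}).
#' @param unitScale marker units per OR step (1 or 10).
#' @param age optional age vector; adjustment as in
#'   \code{\link{binomialLogistic}}.
#' @param ageBinary dichotomize age at 50 (default TRUE).
#' @return data.frame, one row per non-reference cluster.
#' @export
multinomialLogistic <- function(x, labels, ref = "ImA", unitScale = 1,
                                age = NULL, ageBinary = TRUE) {
  labels <- factor(labels)
  if (!ref %in% levels(labels) || !sum(labels == ref))
    stop("reference class '", ref, "' is empty")
  if (nlevels(labels) < 3L) stop("need at least 3 classes")
  labels <- stats::relevel(labels, ref = ref)
  dat <- data.frame(.y = labels, .x = x / unitScale)
  fml <- .y ~ .x
  if (!is.null(age)) {
    dat$.age <- if (ageBinary) as.integer(age >= 50) else age
    fml <- .y ~ .x + .age
  }
  fit <- nnet::multinom(fml, data = dat, trace = FALSE, maxit = 500)
  co <- stats::coef(fit)
  vc <- stats::vcov(fit)
  scaling <- if (unitScale == 10) "per-10-units" else "per-unit"
  adjustment <- if (is.null(age)) "crude" else "age-adjusted"
  do.call(rbind, lapply(rownames(co), function(cl) {
    nm <- paste0(cl, ":.x")
    .assocRow(exp(co[cl, ".x"]), sqrt(vc[nm, nm]), marker = "marker",
              contrast = paste(cl, "vs", ref), scaling = scaling,
              adjustment = adjustment)
  }))
}

#' Spearman rank correlation
#' @param x,y numeric vectors.
#' @return list(rho, p) from the two-sided asymptotic test.
#' @export
spearmanRho <- function(x, y) {
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Kruskal-Wallis rank test
#' @param values numeric vector, or list of group vectors.
#' @param groups group labels when \code{values} is a vector.
#' @return list(H, p) with the tie-corrected statistic.
#' @export
kruskalWallis <- function(values, groups = NULL) {
  if (is.list(values)) {
    if (any(lengths(values) == 0L)) stop("empty group")
    kt <- stats::kruskal.test(values)
  } else {
    if (any(table(groups) == 0L)) stop("empty group")
    kt <- stats::kruskal.test(values, factor(groups))
  }
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Fisher's exact test for a k x 2 table
#' @param tab integer matrix, k rows x 2 columns.
#' @return two-sided p-value.
#' @export
fisherExactKx2 <- function(tab) {
  if (any(rowSums(tab) == 0)) stop("empty group (zero row) in table")
  stats::fisher.test(tab)$p.value
}

#' Kaplan-Meier five-year disease-free survival with log-rank test
#'
#' Product-limit estimate of DFS (time from surgery to first event),
#' truncated at the horizon, with a log-rank comparison across groups.
#'
#' @param times event/censoring times (days), nonnegative.
#' @param events 0/1 event flags.
#' @param groups group labels (e.g. the immuno-clusters).
#' @param horizonDays truncation horizon (default 1826 = 5 years).
#' @return list with the \code{survfit} object, \code{logrank_chisq},
#'   \code{logrank_p} (NA when only one group) and \code{surv_at_horizon}
#'   per group.
#' @export
kmDfs <- function(times, events, groups = NULL, horizonDays = 1826) {
  stopifnot(all(times >= 0), all(events %in% c(0, 1)))
  events <- ifelse(times > horizonDays, 0, events)
  times <- pmin(times, horizonDays)
  if (is.null(groups)) groups <- rep("all", length(times))
  groups <- factor(groups)
  dat <- data.frame(t = times, e = events, g = groups)
  fit <- survival::survfit(survival::Surv(t, e) ~ g, data = dat)
  if (nlevels(groups) > 1L) {
    sd <- survival::survdiff(survival::Surv(t, e) ~ g, data = dat)
    chisq <- sd$chisq
    p <- stats::pchisq(chisq, df = nlevels(groups) - 1L, lower.tail = FALSE)
  } else {
    chisq <- NA_real_; p <- NA_real_
  }
  sm <- summary(fit, times = horizonDays, extend = TRUE)
  list(fit = fit, logrank_chisq = chisq, logrank_p = p,
       surv_at_horizon = stats::setNames(sm$surv, sm$strata))
}

#' Quadrant classification of a marker vs time scatter
#'
#' Q2 = high-x/high-y, Q4 = high-x/low-y, Q1 = low-x/high-y, Q3 =
#' low-x/low-y; values on a boundary go to the low side.
#'
#' @param x,y numeric vectors (e.g. IMS or PLR vs time to event).
#' @param xCut,yCut finite cut points (e.g. means, or the inflamed-cluster
#'   median for PLR).
#' @return character vector of \code{"Q1"}..\code{"Q4"}.
#' @export
quadrantClassify <- function(x, y, xCut, yCut) {
  stopifnot(is.finite(xCut), is.finite(yCut))
  hx <- x > xCut; hy <- y > yCut
  ifelse(hx & hy, "Q2",
         ifelse(hx & !hy, "Q4",
                ifelse(!hx & hy, "Q1", "Q3")))
}
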