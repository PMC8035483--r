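#' Classify cognitive status from a MoCA score
#'
#' Patients with a Montreal Cognitive Assessment total score below 26 are
#' classified as cognitively impaired (CI); 26 or above as not impaired
#' (NCI).
#'
#' @param moca integer score(s) in 0..30.
#' @return character vector of "CI"/"NCI".
#' @export
classify_cognitive_status <- function(moca) {
  if (any(moca < 0 | moca > 30)) stop("MoCA scores must lie in 0..30")
  ifelse(moca < 26, "CI", "NCI")
}

#' Pearson chi-square test on a contingency table
#'
#' No continuity correction (matching the usual R x C group-composition
#' test); degrees of freedom (R-1)(C-1).
#'
#' @param tab R x C matrix of counts.
#' @return list with `statistic`, `df`, `p`.
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("table has an all-zero margin")
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Two-sample t test from group summary statistics
#'
#' Reconstructs the independent two-sample t test from per-group n, mean
#' and standard deviation, either with the classical pooled-variance
#' formula or with the Welch (Satterthwaite) unequal-variance formula.
#' Two-sided p value.
#'
#' @param n1,mean1,sd1 first group's summaries.
#' @param n2,mean2,sd2 second group's summaries.
#' @param variant "pooled" or "welch".
#' @return list with `statistic`, `df`, `p`.
#' @export
two_sample_t_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2,
                                      variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive")
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    tval <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    tval <- (mean1 - mean2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  list(statistic = tval, df = df, p = 2 * pt(-abs(tval), df))
}

#' One-way ANOVA from group summary statistics
#'
#' Reconstructs the F test from per-group n, mean and standard deviation by
#' rebuilding the between- and within-group sums of squares.
#'
#' @param groups list of numeric vectors `c(n, mean, sd)` (or a 3-column
#'   matrix, one row per group).
#' @return list with `statistic` (F), `df` (length 2), `p`.
#' @export
one_way_anova_from_summary <- function(groups) {
  g <- if (is.matrix(groups)) groups else do.call(rbind, groups)
  if (nrow(g) < 2) stop("need at least 2 groups")
  n <- g[, 1]; m <- g[, 2]; s <- g[, 3]
  if (any(n < 2)) stop("each group needs n >= 2")
  k <- nrow(g); big_n <- sum(n)
  gm <- sum(n * m) / big_n
  ssb <- sum(n * (m - gm)^2)
  ssw <- sum((n - 1) * s^2)
  fval <- (ssb / (k - 1)) / (ssw / (big_n - k))
  list(statistic = fval, df = c(k - 1, big_n - k),
       p = pf(fval, k - 1, big_n - k, lower.tail = FALSE))
}

#' ANCOVA group comparison with Bonferroni post hoc tests
#'
#' Fits the linear model `y ~ covariates + group` and tests the group
#' factor by the extra sum of squares against the covariate-only model.
#' Post hoc comparisons are pairwise t tests on the adjusted (model-based)
#' group contrasts, with p values multiplied by the number of pairs and
#' capped at 1 (Bonferroni). With a zero-column covariate matrix this
#' reduces exactly to one-way ANOVA.
#'
#' @param y numeric response (e.g. a metric AUC).
#' @param group factor (or coercible) with >= 2 levels.
#' @param covariates numeric matrix of nuisance covariates (may have zero
#'   columns); a sex indicator should be coded 0/1 by the caller.
#' @return list with `statistic` (F), `df`, `p`, `posthoc` (data.frame of
#'   pairwise contrasts with Bonferroni-adjusted p), `adjusted_means`.
#' @export
ancova_group_test <- function(y, group, covariates = NULL) {
  group <- droplevels(as.factor(group))
  k <- nlevels(group)
  if (k < 2) stop("need at least 2 groups")
  if (is.null(covariates)) covariates <- matrix(numeric(0), length(y), 0)
  covariates <- as.matrix(covariates)
  if (anyNA(y) || anyNA(covariates)) stop("missing values are not supported")
  if (nrow(covariates) != length(y)) stop("covariate rows must match y")
  dat <- data.frame(y = y, group = group)
  if (ncol(covariates)) {
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("c", seq_len(ncol(covariates)))
    }
    dat <- cbind(dat, as.data.frame(covariates))
    full <- lm(stats::reformulate(c(colnames(covariates), "group"), "y"), dat)
    red <- lm(stats::reformulate(colnames(covariates), "y"), dat)
  } else {
    full <- lm(y ~ group, dat)
    red <- lm(y ~ 1, dat)
  }
  if (any(is.na(coef(full)))) {
    stop("design matrix is rank deficient; collinear columns: ",
         paste(names(coef(full))[is.na(coef(full))], collapse = ", "))
  }
  an <- anova(red, full)
  fval <- an$F[2]
  df <- c(an$Df[2], an$Res.Df[2])
  pval <- an$`Pr(>F)`[2]

  # adjusted means: model prediction at covariate means for each group
  beta <- coef(full)
  v <- vcov(full)
  lv <- levels(group)
  cov_means <- if (ncol(covariates)) colMeans(covariates) else numeric(0)
  design_row <- function(g) {
    r <- setNames(numeric(length(beta)), names(beta))
    r["(Intercept)"] <- 1
    if (length(cov_means)) r[names(cov_means)] <- cov_means
    dummy <- paste0("group", g)
    if (dummy %in% names(r)) r[dummy] <- 1
    r
  }
  rows <- vapply(lv, design_row, numeric(length(beta)))
  adj_means <- setNames(as.numeric(crossprod(rows, beta)), lv)

  pairs <- utils::combn(lv, 2)
  n_pairs <- ncol(pairs)
  posthoc <- do.call(rbind, lapply(seq_len(n_pairs), function(j) {
    cvec <- rows[, pairs[1, j]] - rows[, pairs[2, j]]
    est <- sum(cvec * beta)
    se <- sqrt(drop(t(cvec) %*% v %*% cvec))
    tval <- est / se
    p_raw <- 2 * pt(-abs(tval), df[2])
    data.frame(contrast = paste(pairs[1, j], "vs", pairs[2, j]),
               estimate = est, t = tval, p = p_raw,
               p_adjusted = min(1, n_pairs * p_raw),
               stringsAsFactors = FALSE)
  }))
  list(statistic = fval, df = df, p = pval, posthoc = posthoc,
       adjusted_means = adj_means)
}

#' Partial correlation between two variables given covariates
#'
#' Residualises `x` and `y` on the covariates (with intercept) and returns
#' the Pearson correlation of the residuals; the p value comes from the t
#' transform with n - k - 2 degrees of freedom (k = number of covariates).
#' With no covariates this is the ordinary Pearson correlation test.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix (may be NULL / zero columns).
#' @return list with `r`, `p`, `df`.
#' @export
partial_correlation_test <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (is.null(covariates)) covariates <- matrix(numeric(0), n, 0)
  covariates <- as.matrix(covariates)
  k <- ncol(covariates)
  if (n < k + 3) stop("need at least k + 3 observations")
  design <- cbind(1, covariates)
  qrd <- qr(design)
  rx <- qr.resid(qrd, x)
  ry <- qr.resid(qrd, y)
  if (sd(rx) < 1e-14 || sd(ry) < 1e-14) {
    stop("residuals are constant; partial correlation undefined")
  }
  r <- cor(rx, ry)
  df <- n - k - 2
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tval), df), df = df)
}

#' Benjamini-Hochberg step-up false-discovery-rate adjustment
#'
#' @param pvalues numeric vector of p values in \[0, 1\].
#' @return vector of q values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1)) stop("p values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
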