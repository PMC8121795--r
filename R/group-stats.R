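# Group-comparison statistics: normality testing, rank-sum tests, boxplot
# outlier flagging, ANCOVA with demographic covariates, Cohen's d, and the
# clinician-rating (TLC) score arithmetic.

#' Total score from the 18 clinician-rated items
#'
#' Total = 2 * (sum of items 1-11) + (sum of items 12-18), the published
#' summation formula for the 18-item thought/language/communication scale.
#'
#' @param items Integer vector of length 18, each in 0..4.
#' @return Integer total.
#' @export
tlc_total <- function(items) {
  items <- as.numeric(items)
  if (length(items) != 18L) stop("expected exactly 18 items, got ", length(items))
  if (anyNA(items) || any(items < 0 | items > 4 | items != round(items)))
    stop("items must be integers in 0..4")
  as.integer(2 * sum(items[1:11]) + sum(items[12:18]))
}

#' Shapiro-Wilk normality check
#'
#' Downstream rule: features with p < 0.05 are compared with the rank-sum
#' test instead of a parametric model. A constant vector (the test is
#' undefined) is reported as non-normal with `NA` statistics.
#'
#' @param values Numeric vector, n >= 3.
#' @return List `statistic`, `p_value`, `normal` (logical).
#' @export
shapiro_normality <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3L) stop("need at least 3 values")
  res <- tryCatch(stats::shapiro.test(values), error = function(e) NULL)
  if (is.null(res))
    return(list(statistic = NA_real_, p_value = NA_real_, normal = FALSE))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       normal = res$p.value >= 0.05)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration p-value when the smaller sample has at most 8
#' observations and the pooled data are tie-free; tie-corrected normal
#' approximation otherwise.
#'
#' @param a,b Non-empty numeric vectors.
#' @return List `statistic` (Mann-Whitney U for the first sample),
#'   `p_value`, `exact` (logical).
#' @export
wilcoxon_rank_sum <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- min(length(a), length(b)) <= 8L && !ties
  res <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = !exact))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       exact = exact)
}

#' Boxplot-rule outlier indices
#'
#' Flags values outside [Q1 - 1.5 IQR, Q3 + 1.5 IQR] with quartiles from
#' linear interpolation (type 7, R's default).
#'
#' @param values Numeric vector.
#' @return Integer indices of flagged values (empty, with a warning, when
#'   n < 4).
#' @export
boxplot_outliers <- function(values) {
  ok <- which(!is.na(values))
  if (length(ok) < 4L) {
    warning("fewer than 4 values; no outliers flagged")
    return(integer())
  }
  q <- stats::quantile(values[ok], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  fence <- c(q[1] - 1.5 * iqr, q[2] + 1.5 * iqr)
  ok[values[ok] < fence[1] | values[ok] > fence[2]]
}

#' Cohen's d (pooled standard deviation)
#'
#' `(mean(a) - mean(b)) / s_pooled` with the pooled SD using n-1 weights.
#' Sign convention: first argument minus second.
#'
#' @param a,b Numeric vectors with at least 2 values each.
#' @return Numeric scalar.
#' @export
cohens_d <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) stop("need at least 2 values per group")
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) stop("pooled standard deviation is zero")
  (mean(a) - mean(b)) / sqrt(sp2)
}

# Shared linear-model engine for ANCOVA / covariate-adjusted regression.
# Returns the group coefficient's t-test p (equivalent to the ANCOVA F for a
# two-level group factor). Zero-variance covariates are dropped with a
# message; a rank-deficient design among the remaining columns is an error
# naming the collinear terms.
.group_lm <- function(values, group, covariates, test_name) {
  stopifnot(length(values) == length(group))
  g <- factor(group)
  if (nlevels(g) != 2L) stop("group must have exactly two levels")
  if (any(table(g) < 2L)) stop("need at least 2 participants per group")
  df <- data.frame(.y = values, .group = g)
  cov_names <- character()
  if (!is.null(covariates) && length(covariates)) {
    covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
    stopifnot(nrow(covariates) == length(values))
    for (nm in names(covariates)) {
      col <- covariates[[nm]]
      if (length(unique(col[!is.na(col)])) < 2L) {
        message(sprintf("covariate '%s' has no variance; dropped", nm))
        next
      }
      df[[nm]] <- if (is.character(col) || is.logical(col)) factor(col) else col
      cov_names <- c(cov_names, nm)
    }
  }
  if (stats::var(values) == 0) {
    return(list(statistic = 0, p_value = 1, covariates = cov_names, fit = NULL))
  }
  form <- stats::as.formula(paste(
    ".y ~ .group", if (length(cov_names))
      paste("+", paste(cov_names, collapse = " + ")) else ""))
  fit <- stats::lm(form, data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("rank-deficient design; collinear terms: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  sm <- stats::summary.lm(fit)$coefficients
  row <- grep("^\\.group", rownames(sm))
  list(statistic = sm[row, "t value"], p_value = sm[row, "Pr(>|t|)"],
       covariates = cov_names, fit = fit)
}

#' ANCOVA group effect with demographic covariates
#'
#' Linear model of the feature on group plus covariates (typically age, sex,
#' race, education years and study cohort); the reported p-value is for the
#' group term after adjustment. Cohen's d is computed from the raw
#' (unadjusted) group means and pooled SD, matching the convention of
#' reporting raw descriptives alongside adjusted p-values.
#'
#' @param values Numeric feature vector (one per participant).
#' @param group Two-level group labels.
#' @param covariates data.frame (or list) of covariate columns; categorical
#'   columns are one-hot encoded by the model with the first observed level
#'   as reference. `NULL` for none.
#' @param feature Feature name carried into the result.
#' @return A `group_test_result`: list with `feature`, `test`, `statistic`,
#'   `p_value`, `cohens_d`, `covariates`.
#' @export
ancova_group_effect <- function(values, group, covariates = NULL,
                                feature = "feature") {
  res <- .group_lm(values, group, covariates, "ancova")
  g <- factor(group)
  d <- tryCatch(cohens_d(values[g == levels(g)[1]], values[g == levels(g)[2]]),
                error = function(e) NA_real_)
  structure(list(feature = feature, test = "ancova",
                 statistic = res$statistic, p_value = res$p_value,
                 cohens_d = d, covariates = res$covariates),
            class = "group_test_result")
}

#' Covariate-adjusted linear model for a continuous outcome
#'
#' Same engine as [ancova_group_effect()] but framed for continuous outcomes
#' such as a participant's mean next-sentence probability: returns the group
#' coefficient (on the second group level), its p-value, and raw Cohen's d.
#' A constant outcome reports coefficient 0 and p = 1.
#'
#' @inheritParams ancova_group_effect
#' @return A `group_test_result` with an extra `coefficient` field.
#' @export
group_linear_model <- function(values, group, covariates = NULL,
                               feature = "outcome") {
  res <- .group_lm(values, group, covariates, "linear_model")
  coefficient <- if (is.null(res$fit)) 0 else {
    cf <- stats::coef(res$fit)
    unname(cf[grep("^\\.group", names(cf))])
  }
  g <- factor(group)
  d <- tryCatch(cohens_d(values[g == levels(g)[1]], values[g == levels(g)[2]]),
                error = function(e) NA_real_)
  structure(list(feature = feature, test = "linear_model",
                 statistic = res$statistic, p_value = res$p_value,
                 coefficient = coefficient, cohens_d = d,
                 covariates = res$covariates),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("%s [%s]: statistic %.3f, p = %.4g, d = %.3f\n",
              x$feature, x$test, x$statistic, x$p_value, x$cohens_d))
  invisible(x)
}
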