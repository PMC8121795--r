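# Discrimination harness: feature-matrix assembly, leakage-free
# preprocessing, Gaussian naive Bayes with leave-one-out / stratified k-fold
# cross-validation, and ROC AUC via the Mann-Whitney identity.

#' Assemble a feature matrix for classification
#'
#' Feature sets:
#' * `clinical` — the 18 rating items, the global score and the total score
#'   (20 columns);
#' * `nlp` — word-usage score, mean next-sentence probability, per-participant
#'   trajectory intercept and slope, the ten POS rates, and the incomplete-word
#'   count (15 columns);
#' * `combined` — the union (no duplication).
#' With `education = TRUE`, education years are appended as one more
#' predictor.
#'
#' @param nlp_features data.frame keyed by `participant_id` with columns
#'   `word_score`, `mean_nsp`, `traj_intercept`, `traj_slope`, the ten
#'   `pos_*` rates and `incomplete_count` (as produced by the pipeline's
#'   featurize step). May be `NULL` for the clinical set.
#' @param ratings data.frame keyed by `participant_id` with `tlc_item_1` ..
#'   `tlc_item_18`, `tlc_global`, `tlc_total`. May be `NULL` for the nlp set.
#' @param labels Named vector (names = participant ids) of group labels with
#'   two levels; the second level is treated as the positive class.
#' @param feature_set `"clinical"`, `"nlp"` or `"combined"`.
#' @param education Optional named numeric vector of education years to
#'   append; `NULL` to omit.
#' @return A `feature_matrix`: list with `x` (numeric matrix, rownames =
#'   participant ids), `y` (factor), `feature_set`.
#' @export
build_features <- function(nlp_features = NULL, ratings = NULL, labels,
                           feature_set = c("clinical", "nlp", "combined"),
                           education = NULL) {
  feature_set <- match.arg(feature_set)
  ids <- names(labels)
  if (is.null(ids)) stop("labels must be named by participant id")
  cols <- list()
  take <- function(df, wanted) {
    if (is.null(df)) stop("feature set '", feature_set,
                          "' requires inputs that were not supplied")
    miss <- setdiff(wanted, names(df))
    if (length(miss)) stop("missing feature columns: ",
                           paste(miss, collapse = ", "))
    m <- as.matrix(df[match(ids, df$participant_id), wanted, drop = FALSE])
    rownames(m) <- ids
    m
  }
  clinical_cols <- c(paste0("tlc_item_", 1:18), "tlc_global", "tlc_total")
  nlp_cols <- c("word_score", "mean_nsp", "traj_intercept", "traj_slope",
                paste0("pos_", POS_CATEGORIES), "incomplete_count")
  if (feature_set %in% c("clinical", "combined"))
    cols$clinical <- take(ratings, clinical_cols)
  if (feature_set %in% c("nlp", "combined"))
    cols$nlp <- take(nlp_features, nlp_cols)
  x <- do.call(cbind, cols)
  colnames(x) <- unlist(lapply(cols, colnames), use.names = FALSE)
  if (!is.null(education)) {
    x <- cbind(x, education_years = as.numeric(education[ids]))
  }
  y <- factor(labels)
  if (nlevels(y) != 2L) stop("labels must have exactly two levels")
  structure(list(x = x, y = y, feature_set = feature_set),
            class = "feature_matrix")
}

#' Impute and standardize features using training-fold statistics
#'
#' Missing values are replaced by the training-fold column mean, then every
#' column is z-scored by the training-fold mean and SD. Constant columns
#' become all zeros. Columns that are entirely missing in the training fold
#' are dropped (from both folds) with a message — no test-fold value ever
#' enters the statistics.
#'
#' @param train Numeric training matrix.
#' @param test Optional numeric matrix to transform with the training
#'   statistics.
#' @return List `train`, `test` (or `NULL`), `center`, `scale`.
#' @export
preprocess_features <- function(train, test = NULL) {
  train <- as.matrix(train)
  keep <- colSums(!is.na(train)) > 0L
  if (!all(keep)) {
    message("dropping all-missing feature(s): ",
            paste(colnames(train)[!keep], collapse = ", "))
    train <- train[, keep, drop = FALSE]
    if (!is.null(test)) test <- test[, keep, drop = FALSE]
  }
  center <- colMeans(train, na.rm = TRUE)
  apply_center <- function(m) {
    for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- center[j]
    m
  }
  train <- apply_center(train)
  scale_ <- apply(train, 2L, stats::sd)
  scale_[scale_ == 0] <- 1  # constant columns -> all zeros after centering
  std <- function(m) sweep(sweep(m, 2L, center), 2L, scale_, "/")
  list(train = std(train),
       test = if (is.null(test)) NULL else std(apply_center(as.matrix(test))),
       center = center, scale = scale_)
}

# Gaussian naive Bayes. Class priors from training frequencies; per-class
# feature variances floored at 1e-9 times the largest overall feature
# variance (plus an absolute floor) so constant features stay finite.
.nb_fit <- function(x, y) {
  y <- factor(y)
  if (any(table(y) < 1L)) stop("a training fold is missing a class")
  eps <- 1e-9 * max(apply(x, 2L, stats::var), 0) + 1e-12
  stats_by_class <- lapply(levels(y), function(lv) {
    xm <- x[y == lv, , drop = FALSE]
    list(mean = colMeans(xm),
         var = apply(xm, 2L, function(v)
           if (length(v) > 1L) stats::var(v) else 0) + eps)
  })
  names(stats_by_class) <- levels(y)
  list(levels = levels(y),
       prior = as.numeric(table(y)) / length(y),
       stats = stats_by_class)
}

.nb_predict_prob <- function(model, x) {
  x <- as.matrix(x)
  loglik <- vapply(seq_along(model$levels), function(k) {
    st <- model$stats[[k]]
    rowSums(-0.5 * log(2 * pi * rep(st$var, each = nrow(x))) -
              0.5 * sweep(x, 2L, st$mean)^2 /
              rep(st$var, each = nrow(x))) + log(model$prior[k])
  }, numeric(nrow(x)))
  if (is.null(dim(loglik))) loglik <- matrix(loglik, nrow = 1L)
  # positive class = second level; normalize via log-sum-exp
  m <- apply(loglik, 1L, max)
  p <- exp(loglik - m)
  p[, 2] / rowSums(p)
}

#' ROC area under the curve (Mann-Whitney identity)
#'
#' The probability that a uniformly random positive outscores a uniformly
#' random negative, with ties counted 1/2.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Two-level labels; second factor level (or `1` for 0/1
#'   input) is positive.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  y <- factor(labels)
  if (nlevels(y) != 2L) stop("both classes must be present")
  pos <- scores[y == levels(y)[2]]
  neg <- scores[y == levels(y)[1]]
  r <- rank(c(pos, neg), ties.method = "average")
  u <- sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2
  u / (length(pos) * length(neg))
}

.fold_assignments <- function(y, scheme, k, seed) {
  n <- length(y)
  if (scheme == "loo") return(seq_len(n))
  folds <- integer(n)
  rng <- .local_rng(seed)
  for (lv in levels(y)) {
    idx <- which(y == lv)
    idx <- idx[rng$sample_order(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Cross-validated Gaussian naive Bayes discrimination
#'
#' Preprocessing (imputation + standardization) is refit inside every
#' training fold; each participant receives exactly one out-of-fold
#' predicted probability. Accuracy uses a 0.5 probability threshold; AUC is
#' computed over the pooled out-of-fold probabilities (the only coherent
#' choice under leave-one-out, applied uniformly).
#'
#' @param fm A `feature_matrix` from [build_features()], or a list with
#'   numeric matrix `x` and two-level factor `y`.
#' @param scheme `"loo"` (default) or `"kfold"`.
#' @param k Number of folds for `"kfold"` (default 5, stratified by class).
#' @param seed Integer seed controlling the k-fold shuffle.
#' @return A `classification_result`: list with `feature_set`, `cv_scheme`,
#'   `probabilities` (out-of-fold, named by participant), `auc`, `accuracy`.
#' @export
cross_validate_nb <- function(fm, scheme = c("loo", "kfold"), k = 5,
                              seed = 1L) {
  scheme <- match.arg(scheme)
  x <- as.matrix(fm$x); y <- factor(fm$y)
  if (nlevels(y) != 2L || any(table(y) < 2L))
    stop("need at least 2 participants per class")
  folds <- .fold_assignments(y, scheme, k, seed)
  probs <- rep(NA_real_, length(y))
  for (f in unique(folds)) {
    test_i <- which(folds == f)
    train_i <- setdiff(seq_along(y), test_i)
    if (length(unique(y[train_i])) < 2L)
      stop("a training fold is missing a class")
    pp <- preprocess_features(x[train_i, , drop = FALSE],
                              x[test_i, , drop = FALSE])
    model <- .nb_fit(pp$train, y[train_i])
    probs[test_i] <- .nb_predict_prob(model, pp$test)
  }
  names(probs) <- rownames(x)
  pred <- ifelse(probs >= 0.5, levels(y)[2], levels(y)[1])
  structure(list(
    feature_set = fm$feature_set %||% "custom",
    cv_scheme = if (scheme == "loo") "loo" else sprintf("kfold(%d)", k),
    probabilities = probs,
    auc = roc_auc(probs, y),
    accuracy = mean(pred == as.character(y))
  ), class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("naive Bayes [%s, %s]: AUC = %.3f, accuracy = %.1f%%\n",
              x$feature_set, x$cv_scheme, x$auc, 100 * x$accuracy))
  invisible(x)
}
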