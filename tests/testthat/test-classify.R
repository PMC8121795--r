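test_that("build_features assembles the documented column sets", {
  ids <- paste0("p", 1:5)
  ratings <- data.frame(participant_id = ids,
                        matrix(0L, 5, 18,
                               dimnames = list(NULL, paste0("tlc_item_", 1:18))),
                        tlc_global = 0L, tlc_total = 0L)
  nlp <- data.frame(participant_id = ids, word_score = rnorm(5),
                    mean_nsp = runif(5), traj_intercept = rnorm(5),
                    traj_slope = rnorm(5), incomplete_count = 0:4)
  for (cat in speechmarkers:::POS_CATEGORIES)
    nlp[[paste0("pos_", cat)]] <- runif(5, 0, 20)
  labels <- stats::setNames(rep(c("HC", "SSD"), length.out = 5), ids)

  cl <- build_features(ratings = ratings, labels = labels,
                       feature_set = "clinical")
  expect_equal(dim(cl$x), c(5L, 20L))
  np <- build_features(nlp_features = nlp, labels = labels,
                       feature_set = "nlp")
  expect_equal(ncol(np$x), 15L)
  cb <- build_features(nlp_features = nlp, ratings = ratings,
                       labels = labels, feature_set = "combined")
  expect_equal(ncol(cb$x), 35L)  # union, no duplication
  expect_false(anyDuplicated(colnames(cb$x)) > 0)

  edu <- stats::setNames(10:14, ids)
  withedu <- build_features(nlp_features = nlp, labels = labels,
                            feature_set = "nlp", education = edu)
  expect_equal(ncol(withedu$x), 16L)
  expect_equal(unname(withedu$x[, "education_years"]), 10:14)

  # missing cells retained (imputed later), rows kept
  nlp$mean_nsp[2] <- NA
  m <- build_features(nlp_features = nlp, labels = labels, feature_set = "nlp")
  expect_equal(nrow(m$x), 5L)
  expect_true(is.na(m$x[2, "mean_nsp"]))

  expect_error(build_features(labels = labels, feature_set = "clinical"),
               "requires inputs")
})

test_that("preprocess imputes and standardizes with training statistics", {
  train <- matrix(c(1, NA, 3), ncol = 1, dimnames = list(NULL, "f"))
  pp <- preprocess_features(train)
  expect_equal(as.numeric(pp$train), c(-1, 0, 1))

  const <- matrix(5, 4, 1, dimnames = list(NULL, "c"))
  expect_equal(as.numeric(preprocess_features(const)$train), rep(0, 4))

  # leakage: a sentinel in the test fold never shifts the statistics
  test <- matrix(1e9, 1, 1, dimnames = list(NULL, "f"))
  pp2 <- preprocess_features(train, test)
  expect_equal(pp2$center, c(f = 2))
  expect_equal(pp2$train, pp$train)

  allna <- cbind(train, g = NA_real_)
  expect_message(pp3 <- preprocess_features(allna, cbind(test, g = 1)),
                 "all-missing")
  expect_equal(colnames(pp3$train), "f")
  expect_equal(colnames(pp3$test), "f")
})

test_that("roc_auc equals Mann-Whitney pair counting", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.5, 6), rep(c(0, 1), 3)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")

  set.seed(14)
  for (i in 1:200) {
    n <- sample(4:20, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force ties
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(roc_auc(scores, labels), auc_bruteforce(scores, labels))
  }
})

test_that("LOO naive Bayes separates a separable problem", {
  x <- matrix(c(rnorm(10, -3, 0.1), rnorm(10, 3, 0.1)), ncol = 1,
              dimnames = list(paste0("p", 1:20), "f"))
  y <- factor(rep(c("HC", "SSD"), each = 10))
  res <- cross_validate_nb(list(x = x, y = y))
  expect_equal(res$auc, 1.0)
  expect_equal(res$accuracy, 1.0)
  expect_length(res$probabilities, 20L)
})

test_that("LOO results are invariant to participant order", {
  set.seed(2)
  x <- matrix(rnorm(60), ncol = 3,
              dimnames = list(paste0("p", 1:20), paste0("f", 1:3)))
  y <- factor(rep(c("HC", "SSD"), 10))
  r1 <- cross_validate_nb(list(x = x, y = y))
  perm <- sample(20)
  r2 <- cross_validate_nb(list(x = x[perm, ], y = y[perm]))
  expect_equal(r2$probabilities[rownames(x)], r1$probabilities)
  expect_equal(r2$auc, r1$auc)
})

test_that("null features give chance-level AUC on average", {
  set.seed(77)
  aucs <- replicate(200, {
    x <- matrix(rnorm(100), ncol = 5)
    rownames(x) <- paste0("p", 1:20)
    y <- factor(rep(c("HC", "SSD"), each = 10))
    cross_validate_nb(list(x = x, y = y))$auc
  })
  expect_gte(mean(aucs), 0.4)
  expect_lte(mean(aucs), 0.6)
})

test_that("stratified k-fold is seeded and reproducible", {
  set.seed(4)
  x <- matrix(rnorm(80), ncol = 4, dimnames = list(paste0("p", 1:20), NULL))
  colnames(x) <- paste0("f", 1:4)
  y <- factor(rep(c("HC", "SSD"), each = 10))
  r1 <- cross_validate_nb(list(x = x, y = y), scheme = "kfold", k = 5,
                          seed = 9)
  r2 <- cross_validate_nb(list(x = x, y = y), scheme = "kfold", k = 5,
                          seed = 9)
  expect_identical(r1$probabilities, r2$probabilities)
  expect_equal(r1$cv_scheme, "kfold(5)")
  expect_error(cross_validate_nb(list(x = x[1:3, ], y = factor(c("a", "a", "b")))),
               "at least 2")
})

test_that("nlp features dominate near-degenerate clinical ratings", {
  # the headline pattern: with mostly-zero ratings (subclinical disturbance)
  # the clinical-only model is far weaker than the linguistic one
  cls <- preset_report()$classification
  expect_gte(cls$nlp$auc, 0.9)
  expect_lte(cls$clinical$auc, cls$nlp$auc - 0.1)
})

test_that("6-row fixture AUC equals pair counting through the NB path", {
  # single feature: out-of-fold NB probabilities are monotone in the
  # feature, so AUC must equal the direct Mann-Whitney value on the scores
  x <- matrix(c(0.1, 0.4, 0.35, 0.8, 0.75, 0.9), ncol = 1,
              dimnames = list(paste0("p", 1:6), "f"))
  y <- factor(c("HC", "HC", "HC", "SSD", "SSD", "SSD"))
  res <- cross_validate_nb(list(x = x, y = y))
  expect_equal(res$auc, auc_bruteforce(res$probabilities, y))
})
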