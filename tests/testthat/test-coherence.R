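test_that("sentence_pairs pairs each participant sentence with its predecessor", {
  tr <- make_transcript(list(
    list(speaker = "I", text = "How are you?"),
    list(speaker = "P", text = "Fine. Really fine.")))
  pairs <- sentence_pairs(tr)
  expect_length(pairs, 2L)
  expect_equal(pairs[[1]]$first$speaker, "interviewer")
  expect_equal(pairs[[2]]$first$tokens$text, c("Fine"))

  only_i <- make_transcript(list(list(speaker = "I", text = "Hello. There.")))
  expect_length(sentence_pairs(only_i), 0L)

  # participant-opening sentence yields no pair
  p_first <- make_transcript(list(list(speaker = "P", text = "Start. Next.")))
  expect_length(sentence_pairs(p_first), 1L)
})

test_that("mean_nsp filters, weights and flags all-filtered sets", {
  pairs <- lapply(c(6, 3), function(n)
    list(first = stub_sentence(4), second = stub_sentence(n)))
  be <- stub_nsp_backend(list(`6` = 1.0, `3` = 0.0))
  expect_equal(mean_nsp(pairs, be)$mean_nsp, 0.5)
  expect_equal(mean_nsp(pairs, be, min_words = 5)$mean_nsp, 1.0)
  expect_warning(res <- mean_nsp(pairs, be, min_words = 50), "filtered")
  expect_true(is.na(res$mean_nsp))

  # hand-computed weighted mean: (0.9*0.5 + 0.6*1.0 + 0.3*1.5) / 3 = 0.5
  pairs3 <- lapply(c(5, 10, 15), function(n)
    list(first = stub_sentence(4), second = stub_sentence(n)))
  be3 <- stub_nsp_backend(list(`5` = 0.9, `10` = 0.6, `15` = 0.3))
  expect_equal(mean_nsp(pairs3, be3, length_weighting = TRUE)$mean_nsp, 0.5)
  expect_equal(mean_nsp(pairs3, be3)$mean_nsp, 0.6)
})

test_that("prompt_embedding mean-pools word vectors", {
  vecs <- list(a = c(1, 0, 2), b = c(-1, 0, -2), c = c(3, 3, 3))
  be <- list(name = "fixed", embed_words = function(words)
    t(vapply(words, function(w) vecs[[w]], numeric(3))))
  turn1 <- list(speaker = "interviewer",
                sentences = list(list(tokens = data.frame(
                  text = "a", kind = "word", pronoun_class = "none"),
                  speaker = "interviewer", terminal = ".")))
  expect_equal(prompt_embedding(turn1, be), c(1, 0, 2),
               ignore_attr = TRUE)
  mk <- function(words) list(tokens = data.frame(
    text = words, kind = "word", pronoun_class = "none"),
    speaker = "interviewer", terminal = ".")
  turn2 <- list(speaker = "interviewer", sentences = list(mk(c("a", "b"))))
  expect_equal(prompt_embedding(turn2, be), c(0, 0, 0), ignore_attr = TRUE)
  turn3 <- list(speaker = "interviewer",
                sentences = list(mk(c("a", "b")), mk("c")))
  expect_equal(prompt_embedding(turn3, be), c(1, 1, 1), ignore_attr = TRUE)

  empty <- list(speaker = "interviewer", sentences = list(list(
    tokens = data.frame(text = "[name]", kind = "redaction",
                        pronoun_class = "none"),
    speaker = "interviewer", terminal = ".")))
  expect_error(prompt_embedding(empty, be), "no embeddable")
})

test_that("distance metrics satisfy identity and symmetry", {
  dist <- speechmarkers:::.embedding_distance
  x <- c(1, 2, 3); y <- c(-1, 0.5, 2)
  for (m in c("cosine", "euclidean", "mean_abs")) {
    expect_equal(dist(x, x, m), 0, tolerance = 1e-12)
    expect_equal(dist(x, y, m), dist(y, x, m), tolerance = 1e-12)
  }
  expect_equal(dist(c(1, 0), c(0, 1), "cosine"), 1)
  expect_lte(dist(c(1, 0), c(-1, 0), "cosine"), 2)
})

test_that("trajectory points: identical and orthogonal responses", {
  be <- toy_backend(jitter = 0)
  tr <- make_transcript(list(
    list(speaker = "I", text = "house garden street?"),
    list(speaker = "P", text = "house garden street. factory engine wire.")))
  ex <- extract_exchanges(tr)[[1]]
  pts <- trajectory_points(ex, be)
  expect_equal(pts$position, 1:2)
  expect_equal(pts$distance[1], 0, tolerance = 1e-12)
  expect_equal(pts$distance[2], 1, tolerance = 1e-12)  # pure A vs pure B

  # unembeddable response sentence skipped with a message
  tr2 <- make_transcript(list(
    list(speaker = "I", text = "house?"),
    list(speaker = "P", text = "[name] [name]. garden.")))
  ex2 <- extract_exchanges(tr2)[[1]]
  expect_message(pts2 <- trajectory_points(ex2, be), "unembeddable")
  expect_equal(pts2$position, 2L)
})

test_that("drifting responses give increasing distances", {
  be <- toy_backend(jitter = 0)
  # responses move from pure topic A through mixtures to pure topic B
  tr <- make_transcript(list(
    list(speaker = "I", text = "house garden street home family?"),
    list(speaker = "P", text = paste(
      "house garden street home.",
      "house garden factory engine.",
      "house factory engine wire.",
      "factory engine wire metal."))))
  pts <- trajectory_points(extract_exchanges(tr)[[1]], be)
  expect_equal(pts$position, 1:4)
  expect_true(all(diff(pts$distance) > 0))
})

test_that("fit_trajectory equals the closed-form OLS solution", {
  pts <- data.frame(position = c(1, 2, 3), distance = c(0.2, 0.3, 0.4))
  fit <- suppressWarnings(fit_trajectory(pts))  # zero-residual fixture
  expect_equal(fit$slope, 0.1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-12)

  flat <- data.frame(position = 1:5, distance = rep(0.25, 5))
  fitf <- suppressWarnings(fit_trajectory(flat))
  expect_equal(fitf$slope, 0, tolerance = 1e-12)
  expect_equal(fitf$intercept, 0.25, tolerance = 1e-12)

  set.seed(42)
  x <- sample(1:10, 40, replace = TRUE)
  y <- 0.2 + 0.03 * x + rnorm(40, 0, 0.01)
  fit2 <- fit_trajectory(data.frame(position = x, distance = y))
  # independent closed-form least squares
  beta <- cov(x, y) / var(x)
  alpha <- mean(y) - beta * mean(x)
  expect_equal(fit2$slope, beta, tolerance = 1e-10)
  expect_equal(fit2$intercept, alpha, tolerance = 1e-10)
  # point estimates inside their CIs
  expect_true(fit2$ci95_slope[1] <= fit2$slope &&
                fit2$slope <= fit2$ci95_slope[2])

  expect_error(fit_trajectory(pts[1:2, ]), "at least 3")
  expect_error(fit_trajectory(data.frame(position = c(2, 2, 2),
                                         distance = c(1, 2, 3))),
               "identical")
})

test_that("simulated slope is recovered within its CI", {
  set.seed(7)
  pts <- data.frame(position = rep(1:10, 5))
  pts$distance <- 0.25 + 0.01 * pts$position + rnorm(50, 0, 0.005)
  fit <- fit_trajectory(pts)
  expect_true(fit$ci95_slope[1] <= 0.01 && 0.01 <= fit$ci95_slope[2])
})

test_that("group-level recovery: drifting group slopes up, starts farther", {
  fits <- preset_report()$trajectory_fits
  expect_gt(fits$SSD$ci95_slope[1], 0)
  expect_true(fits$HC$ci95_slope[1] <= 0 && 0 <= fits$HC$ci95_slope[2])
  expect_gt(fits$SSD$intercept, fits$HC$intercept)
})

test_that("toy backend NSP: same-topic high, cross-topic low", {
  be <- toy_backend(jitter = 0.02)
  a1 <- c("house", "garden", "street"); a2 <- c("home", "family", "dog")
  b1 <- c("factory", "engine", "wire")
  expect_gt(be$nsp(a1, a2), 0.9)
  expect_lt(be$nsp(a1, b1), 0.2)
  # deterministic
  expect_identical(be$nsp(a1, b1), toy_backend(jitter = 0.02)$nsp(a1, b1))
})
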