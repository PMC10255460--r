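test_that("error metrics match brute-force summation on random vectors", {
  set.seed(2)
  for (i in 1:1000) {
    n <- sample(3:12, 1)
    y <- rnorm(n); p <- rnorm(n)
    m <- sync_metrics(y, p)
    # independent brute-force evaluation of the three formulas
    mae <- 0; mse <- 0
    for (j in seq_len(n)) {
      mae <- mae + abs(p[j] - y[j]) / n
      mse <- mse + (y[j] - p[j])^2 / n
    }
    ybar <- sum(y) / n
    sst <- 0; ssr <- 0
    for (j in seq_len(n)) {
      sst <- sst + (y[j] - ybar)^2
      ssr <- ssr + (y[j] - p[j])^2
    }
    expect_equal(m$mae, mae, tolerance = 1e-12)
    expect_equal(m$mse, mse, tolerance = 1e-12)
    expect_equal(m$r2, 1 - ssr / sst, tolerance = 1e-12)
  }
})

test_that("hand-worked metric examples hold exactly", {
  m <- sync_metrics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(m$mae, 1 / 3)
  expect_equal(m$mse, 1 / 3)
  expect_equal(m$r2, 0.5)   # 1 - (1/3)/(2/3)
  # prediction == mean gives R2 = 0; zero-variance truth is undefined
  y <- c(1, 2, 3, 4)
  expect_equal(sync_metrics(y, rep(mean(y), 4))$r2, 0)
  expect_true(is.na(sync_metrics(rep(1, 4), rep(1, 4))$r2))
})

test_that("window splits follow 7:3 floor arithmetic and determinism", {
  pairs <- tibble::tibble(x = rnorm(121), y = rnorm(121))
  sp <- split_windows(pairs, 0.7, "chronological")
  expect_equal(nrow(sp$train), 84)
  expect_equal(nrow(sp$test), 37)
  expect_equal(sp$train$x, pairs$x[1:84])  # chronological order kept

  p10 <- tibble::tibble(x = rnorm(10), y = rnorm(10))
  sp10 <- split_windows(p10, 0.7, "chronological")
  expect_equal(c(nrow(sp10$train), nrow(sp10$test)), c(7, 3))

  r1 <- split_windows(pairs, 0.7, "random", seed = 42)
  r2 <- split_windows(pairs, 0.7, "random", seed = 42)
  expect_equal(r1$train, r2$train)
  # disjoint and exhaustive
  expect_equal(nrow(r1$train) + nrow(r1$test), 121)
  expect_equal(length(intersect(
    paste(r1$train$x, r1$train$y), paste(r1$test$x, r1$test$y))), 0)
  expect_error(split_windows(pairs[1:5, ]), "at least 10")
})

test_that("identity mapping is fit perfectly by the linear model", {
  x <- seq(0, 1, length.out = 50)
  fit <- fit_sync(tibble::tibble(x = x, y = x),
                  spec = regression_spec("linear"))
  expect_equal(fit$metrics$r2, 1, tolerance = 1e-9)
  expect_equal(fit$metrics$mae, 0, tolerance = 1e-9)
  expect_equal(fit$metrics$mse, 0, tolerance = 1e-9)
  expect_equal(fit$n_train + fit$n_test, 50)
})

test_that("every model family fits a noisy linear relation sensibly", {
  set.seed(3)
  x <- runif(200)
  y <- 0.2 + 0.5 * x + rnorm(200, sd = 0.02)
  pairs <- tibble::tibble(x = x, y = y)
  for (m in c("bayesian_ridge", "linear", "svr", "gbr")) {
    fit <- fit_sync(pairs, spec = regression_spec(m))
    expect_gt(fit$metrics$r2, 0.85)
  }
  # elastic net at penalty weight 1 shrinks the slope to zero here,
  # so it predicts near the mean: R2 near zero, never above the others
  fe <- fit_sync(pairs, spec = regression_spec("elastic_net"))
  expect_lt(fe$metrics$r2, 0.1)
})

test_that("univariate elastic net matches scikit-learn's solution", {
  set.seed(8)
  x <- rnorm(40, sd = 2)
  y <- 1 + 2 * x + rnorm(40, sd = 0.5)
  spec <- regression_spec("elastic_net")
  predict_fn <- eyesync:::fit_model(x, y, spec)
  script <- paste(
    "import sys, json",
    "import numpy as np",
    "from sklearn.linear_model import ElasticNet",
    "d = json.load(open(sys.argv[1]))",
    "m = ElasticNet(alpha=1.0, l1_ratio=0.5)",
    "m.fit(np.array(d['x']).reshape(-1, 1), d['y'])",
    "print(float(m.coef_[0]), float(m.intercept_))",
    sep = "\n")
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(x = x, y = y), f, digits = NA)
  out <- system2("python", c("-c", shQuote(script), shQuote(f)),
                 stdout = TRUE, stderr = FALSE)
  ref <- as.numeric(strsplit(out[length(out)], " ")[[1]])
  # compare on predictions over a grid
  grid <- seq(min(x), max(x), length.out = 9)
  expect_equal(predict_fn(grid), ref[2] + ref[1] * grid, tolerance = 1e-6)
})

test_that("Bayesian ridge behaves like heavily-regularized least squares", {
  set.seed(4)
  x <- rnorm(100)
  y <- 3 * x + rnorm(100, sd = 0.1)
  cf <- eyesync:::bayesian_ridge_fit(matrix(x, ncol = 1), y,
                                     regression_spec("bayesian_ridge")$hyperparameters)
  ols <- unname(coef(lm(y ~ x)))
  # with strong signal the evidence maximization converges near OLS
  expect_equal(cf$coef, ols[2], tolerance = 0.01)
  expect_equal(cf$intercept, ols[1], tolerance = 0.01)
})

test_that("zero-variance test response is flagged, not crashed", {
  pairs <- tibble::tibble(x = c(rnorm(14), rnorm(6)),
                          y = c(rnorm(14), rep(0.5, 6)))
  expect_warning(fit <- fit_sync(pairs, spec = regression_spec("linear")),
                 "zero-variance")
  expect_true(is.na(fit$metrics$r2))
})

test_that("model comparison table has the expected shape and tie rules", {
  set.seed(6)
  x <- runif(60)
  pairs <- tibble::tibble(x = x, y = 0.3 + 0.4 * x + rnorm(60, sd = 0.05))
  tab <- evaluate_models(pairs, n_repeats = 2)
  expect_equal(nrow(tab), 5)
  expect_setequal(names(tab), c("model", "ev", "mae", "mse", "r2_score"))

  pick <- select_best_model(tab)
  expect_equal(pick$model, tab$model[which.max(tab$r2_score)])

  tie <- tibble::tibble(model = c("gbr", "linear"),
                        ev = c(0.5, 0.5), mae = c(0.1, 0.1),
                        mse = c(0.2, 0.1), r2_score = c(0.5, 0.5))
  expect_equal(select_best_model(tie)$model, "linear")  # lower MSE wins
  single <- tie[1, ]
  expect_equal(select_best_model(single)$model, "gbr")
  expect_error(select_best_model(tie[0, ]), "empty")
})

test_that("fits are deterministic under a fixed seed", {
  set.seed(10)
  pairs <- tibble::tibble(x = runif(50), y = runif(50))
  for (m in c("gbr", "svr", "bayesian_ridge")) {
    f1 <- fit_sync(pairs, spec = regression_spec(m, seed = 7))
    f2 <- fit_sync(pairs, spec = regression_spec(m, seed = 7))
    expect_identical(f1$metrics, f2$metrics)
  }
})

test_that("tidy and glance summarize a fit the broom way", {
  x <- seq(0, 1, length.out = 40)
  fit <- fit_sync(tibble::tibble(x = x, y = 2 * x),
                  spec = regression_spec("linear"))
  td <- tidy(fit)
  expect_setequal(td$metric, c("mae", "mse", "r2", "ev"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$model, "linear")
  expect_equal(gl$n_train, 28)
})

test_that("the sync matrix covers every feature-channel-band triple", {
  cfg <- tiny_coupled_config(seed = 3)
  ses <- generate_session(cfg, 1, 1)
  rc <- run_config(synth = cfg, window_s = 20)
  sbr <- suppressMessages(session_band_ratios(ses$eeg, ses$gaze, rc))
  m <- run_sync_matrix(sbr$eye_ratios, sbr$eeg_ratios,
                       regression_spec("gbr"))
  expect_equal(nrow(m), 4 * 18 * 4)
  expect_equal(nrow(dplyr::distinct(m[, c("eye_feature", "channel",
                                          "band")])), 288)
  # the planted triple ranks in the top 5% of the session's R2 values
  planted <- m$r2[m$eye_feature == "pupil_right" & m$channel == "F3" &
                    m$band == "delta"]
  expect_gte(planted, quantile(m$r2, 0.95, na.rm = TRUE))
})
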