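#' Regression model specification
#'
#' The five regression families used to score synchronization, each with
#' fixed, conventional hyperparameters: Bayesian ridge (evidence
#' maximization, gamma hyperpriors alpha_1 = alpha_2 = lambda_1 =
#' lambda_2 = 1e-6, 300 iterations, tol 1e-3), ordinary least squares,
#' elastic net (penalty weight 1.0, mixing 0.5), epsilon-SVR (RBF
#' kernel, C = 1, epsilon = 0.1, gamma = 1/n_features) and gradient
#' boosting regression (100 stages, learning rate 0.1, max depth 3,
#' squared-error loss, subsample 1).
#'
#' @param model One of `"bayesian_ridge"`, `"linear"`, `"elastic_net"`,
#'   `"svr"`, `"gbr"`.
#' @param split_fraction Training fraction of the 7:3 chronological or
#'   random split (default 0.7).
#' @param split_mode `"chronological"` (default) or `"random"`. With
#'   180 s windows sliding by 1 s, adjacent windows overlap almost
#'   completely, so a random split leaks training information into the
#'   test set; the chronological split is the validity-preserving
#'   default and the random mode is retained for fidelity comparisons.
#' @param seed Seed for the random split and any model randomness.
#' @param hyperparameters Named list overriding individual defaults.
#' @return A `regression_spec` list.
#' @export
regression_spec <- function(model = c("gbr", "bayesian_ridge", "linear",
                                      "elastic_net", "svr"),
                            split_fraction = 0.7,
                            split_mode = c("chronological", "random"),
                            seed = 1, hyperparameters = list()) {
  model <- match.arg(model)
  split_mode <- match.arg(split_mode)
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("split_fraction must lie in (0, 1)", call. = FALSE)
  }
  defaults <- switch(model,
    bayesian_ridge = list(alpha_1 = 1e-6, alpha_2 = 1e-6, lambda_1 = 1e-6,
                          lambda_2 = 1e-6, n_iter = 300, tol = 1e-3),
    linear = list(),
    elastic_net = list(alpha = 1.0, l1_ratio = 0.5),
    svr = list(C = 1.0, epsilon = 0.1, gamma = "auto", tol = 1e-3),
    gbr = list(n_estimators = 100, learning_rate = 0.1, max_depth = 3,
               subsample = 1.0)
  )
  defaults[names(hyperparameters)] <- hyperparameters
  structure(list(model = model, split_fraction = split_fraction,
                 split_mode = split_mode, seed = seed,
                 hyperparameters = defaults),
            class = "regression_spec")
}

#' Split paired windows into training and test sets
#'
#' @param pairs Tibble of paired windows (e.g. from
#'   [align_ratio_series()]).
#' @param fraction Training fraction (default 0.7, a 7:3 split).
#' @param mode `"chronological"`: the first `floor(fraction * n)` rows
#'   train; `"random"`: a seeded shuffle.
#' @param seed Seed for random mode.
#' @return List with disjoint, exhaustive tibbles `train` and `test`.
#' @export
split_windows <- function(pairs, fraction = 0.7,
                          mode = c("chronological", "random"), seed = 1) {
  mode <- match.arg(mode)
  n <- nrow(pairs)
  if (n < 10) stop("need at least 10 paired windows to split", call. = FALSE)
  n_train <- floor(fraction * n)
  idx <- if (mode == "chronological") {
    seq_len(n_train)
  } else {
    withr::with_seed(as.integer(seed), sample.int(n, n_train))
  }
  list(train = pairs[idx, ], test = pairs[-idx, ])
}

# ---- model fitting --------------------------------------------------------

fit_model <- function(x, y, spec) {
  hp <- spec$hyperparameters
  switch(spec$model,
    linear = {
      fit <- stats::lm.fit(cbind(1, x), y)
      cf <- fit$coefficients
      function(x_new) cf[1] + cf[2] * x_new
    },
    bayesian_ridge = {
      cf <- bayesian_ridge_fit(matrix(x, ncol = 1), y, hp)
      function(x_new) cf$intercept + cf$coef * x_new
    },
    elastic_net = {
      # univariate elastic net has a closed-form coordinate solution:
      # minimize 1/(2n) sum (y - b - w x)^2 + a*l1*|w| + a*(1-l1)/2 w^2
      xm <- mean(x); ym <- mean(y)
      xc <- x - xm; yc <- y - ym
      n <- length(x)
      rho <- sum(xc * yc) / n
      z <- sum(xc^2) / n
      lam <- hp$alpha
      w <- sign(rho) * max(abs(rho) - lam * hp$l1_ratio, 0) /
        (z + lam * (1 - hp$l1_ratio))
      function(x_new) ym + w * (x_new - xm)
    },
    svr = {
      gamma <- if (identical(hp$gamma, "auto")) 1 else hp$gamma
      fit <- e1071::svm(matrix(x, ncol = 1), y, type = "eps-regression",
                        kernel = "radial", cost = hp$C,
                        epsilon = hp$epsilon, gamma = gamma,
                        tolerance = hp$tol, scale = FALSE, fitted = FALSE)
      if (fit$tot.nSV == 0) {
        # every training point lies inside the epsilon tube; the flat
        # solution f(x) = b is optimal and any b within the tube is
        # feasible -- predict the response mean
        b <- mean(y)
        function(x_new) rep(b, length(x_new))
      } else {
        function(x_new) {
          as.numeric(stats::predict(fit, matrix(x_new, ncol = 1)))
        }
      }
    },
    gbr = {
      dtrain <- xgboost::xgb.DMatrix(matrix(x, ncol = 1), label = y,
                                     nthread = 1)
      fit <- xgboost::xgb.train(
        params = list(eta = hp$learning_rate, max_depth = hp$max_depth,
                      subsample = hp$subsample, lambda = 0, alpha = 0,
                      objective = "reg:squarederror",
                      base_score = mean(y), nthread = 1,
                      seed = as.integer(spec$seed)),
        dtrain, nrounds = hp$n_estimators, verbose = 0)
      function(x_new) as.numeric(stats::predict(fit,
                                                matrix(x_new, ncol = 1)))
    }
  )
}

# Evidence-maximization Bayesian ridge (Gaussian likelihood precision
# `alpha`, isotropic Gaussian weight prior precision `lambda`, gamma
# hyperpriors on both), iterated to convergence of the weights.
bayesian_ridge_fit <- function(X, y, hp) {
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  XtX <- crossprod(Xc); Xty <- crossprod(Xc, yc)
  alpha <- 1 / max(stats::var(yc), 1e-12)
  lambda <- 1
  w <- rep(0, p)
  eig <- eigen(XtX, symmetric = TRUE, only.values = TRUE)$values
  for (it in seq_len(hp$n_iter)) {
    w_old <- w
    A <- alpha * XtX + lambda * diag(p)
    w <- drop(solve(A, alpha * Xty))
    gamma_eff <- sum(alpha * eig / (alpha * eig + lambda))
    rss <- sum((yc - Xc %*% w)^2)
    lambda <- (gamma_eff + 2 * hp$lambda_1) /
      (sum(w^2) + 2 * hp$lambda_2)
    alpha <- (n - gamma_eff + 2 * hp$alpha_1) /
      (rss + 2 * hp$alpha_2)
    if (sum(abs(w - w_old)) < hp$tol) break
  }
  list(coef = w, intercept = ym - sum(w * xm))
}

#' Regression error metrics
#'
#' The three evaluation measures used to score a fit on held-out data:
#' mean absolute error `MAE = (1/m) sum |h(x_i) - y_i|`, mean squared
#' error `MSE = (1/n) sum (y_i - yhat_i)^2`, and the coefficient of
#' determination `R2 = 1 - sum (y_i - yhat_i)^2 / sum (y_i - ybar)^2`
#' (negative values are reported, not clipped). Explained variance
#' `EV = 1 - Var(y - yhat) / Var(y)` is included for model comparison
#' tables.
#'
#' @param y_true,y_pred Numeric vectors of equal length.
#' @return One-row tibble `mae, mse, r2, ev`; `r2` is `NA` when the true
#'   values have zero variance.
#' @examples
#' sync_metrics(c(1, 2, 3), c(1, 2, 4))  # mae 1/3, mse 1/3, r2 0.5
#' @export
sync_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  resid <- y_true - y_pred
  sst <- sum((y_true - mean(y_true))^2)
  tibble::tibble(
    mae = mean(abs(resid)),
    mse = mean(resid^2),
    r2 = if (sst > 0) 1 - sum(resid^2) / sst else NA_real_,
    ev = {
      vy <- mean((y_true - mean(y_true))^2)
      if (vy > 0) 1 - mean((resid - mean(resid))^2) / vy else NA_real_
    }
  )
}

#' Fit one synchronization regression
#'
#' Predicts an EEG channel's band-ratio trajectory from an eye feature's
#' band-ratio trajectory in the same-named band: fits `y = f(x)` on the
#' training windows of a 7:3 split and evaluates MAE, MSE and R-squared
#' on the held-out windows. The held-out R-squared is the
#' synchronization score: the fraction of EEG band-ratio variance
#' predictable from the eye series.
#'
#' @param pairs Tibble with columns `x` and `y` (one band's aligned
#'   windows, from [align_ratio_series()]), or numeric `x` with `y`
#'   supplied separately.
#' @param y Optional numeric response if `pairs` is a numeric vector.
#' @param spec A [regression_spec()].
#' @return A `sync_fit` object; see [tidy.sync_fit()] and
#'   [glance.sync_fit()].
#' @export
fit_sync <- function(pairs, y = NULL, spec = regression_spec()) {
  if (is.numeric(pairs)) {
    pairs <- tibble::tibble(x = pairs, y = y)
  }
  split <- split_windows(pairs, spec$split_fraction, spec$split_mode,
                         spec$seed)
  predict_fn <- fit_model(split$train$x, split$train$y, spec)
  y_pred <- predict_fn(split$test$x)
  metrics <- sync_metrics(split$test$y, y_pred)
  if (is.na(metrics$r2)) {
    warning("zero-variance response on the test windows; R2 undefined")
  }
  structure(list(
    spec = spec, metrics = metrics,
    n_train = nrow(split$train), n_test = nrow(split$test),
    predictions = tibble::tibble(
      window_start_s = if ("window_start_s" %in% names(split$test))
        split$test$window_start_s else seq_len(nrow(split$test)),
      x = split$test$x, y = split$test$y, y_pred = y_pred)
  ), class = "sync_fit")
}

#' @export
print.sync_fit <- function(x, ...) {
  cat("<sync_fit> model:", x$spec$model,
      sprintf("(train %d / test %d windows)\n", x$n_train, x$n_test))
  cat(sprintf("  R2 = %.4f, MAE = %.5f, MSE = %.6f\n",
              x$metrics$r2, x$metrics$mae, x$metrics$mse))
  invisible(x)
}

#' Tidy a synchronization fit
#'
#' @param x A `sync_fit` object.
#' @param ... Unused.
#' @return Tibble of held-out metrics, one row per metric.
#' @method tidy sync_fit
#' @export
tidy.sync_fit <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' One-row summary of a synchronization fit
#'
#' @param x A `sync_fit` object.
#' @param ... Unused.
#' @method glance sync_fit
#' @export
glance.sync_fit <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(model = x$spec$model), x$metrics,
                   tibble::tibble(n_train = x$n_train, n_test = x$n_test))
}

#' Compare the five regression families on one window pairing
#'
#' Fits each specified model over `n_repeats` random-split repeats with
#' distinct seeds and averages explained variance, MAE, MSE and the
#' R-squared score, mirroring a model-selection table with columns
#' EV / MAE / MSE / R2-Score.
#'
#' @param pairs Aligned window tibble with `x`, `y`.
#' @param models Model names (default: all five).
#' @param n_repeats Number of split repeats (default 5).
#' @param split_mode Split mode for the repeats (default random, so the
#'   repeats differ; seeds are `seed + 0:(n_repeats-1)`).
#' @param seed Base seed.
#' @return Tibble `model, ev, mae, mse, r2_score` (means over repeats).
#' @export
evaluate_models <- function(pairs,
                            models = c("bayesian_ridge", "linear",
                                       "elastic_net", "svr", "gbr"),
                            n_repeats = 5,
                            split_mode = "random", seed = 1) {
  if (length(models) < 1) stop("need at least one model", call. = FALSE)
  purrr::map_dfr(models, function(m) {
    reps <- purrr::map_dfr(seq_len(n_repeats) - 1, function(r) {
      spec <- regression_spec(m, split_mode = split_mode, seed = seed + r)
      fit_sync(pairs, spec = spec)$metrics
    })
    tibble::tibble(model = m, ev = mean(reps$ev), mae = mean(reps$mae),
                   mse = mean(reps$mse), r2_score = mean(reps$r2))
  })
}

#' Select the best model from a comparison table
#'
#' Maximum mean R-squared score; ties broken by lower MSE, then by a
#' fixed model-name order.
#'
#' @param table Output of [evaluate_models()].
#' @return A [regression_spec()] for the winning model.
#' @export
select_best_model <- function(table) {
  if (nrow(table) == 0) stop("empty model table", call. = FALSE)
  if (all(is.na(table$r2_score))) stop("all model metrics undefined",
                                       call. = FALSE)
  order_names <- c("bayesian_ridge", "linear", "elastic_net", "svr", "gbr")
  tb <- table[order(-table$r2_score, table$mse,
                    match(table$model, order_names)), ]
  regression_spec(tb$model[1])
}

#' Synchronization matrix for one session
#'
#' Scores every (eye feature, EEG channel, band) triple of one session:
#' eye and EEG band-ratio series are paired within like-named bands,
#' split 7:3, and the held-out R-squared, MAE and MSE recorded. With the
#' full montage and all four features this is 4 x 18 x 4 = 288 triples.
#'
#' @param eye_ratios Tidy eye band-ratio tibble ([eye_band_ratios()]).
#' @param eeg_ratios Tidy EEG band-ratio tibble ([eeg_band_ratios()]).
#' @param spec A [regression_spec()].
#' @param features,channels,bands Optional subsets to score.
#' @return Tibble `eye_feature, channel, band, model, r2, mae, mse,
#'   n_train, n_test`.
#' @export
run_sync_matrix <- function(eye_ratios, eeg_ratios,
                            spec = regression_spec(),
                            features = NULL, channels = NULL, bands = NULL) {
  if (is.null(features)) features <- unique(eye_ratios$source)
  if (is.null(channels)) channels <- unique(eeg_ratios$source)
  if (is.null(bands)) bands <- intersect(band_names(),
                                         unique(eeg_ratios$band))
  grid <- tidyr::crossing(eye_feature = features, channel = channels,
                          band = bands)
  purrr::pmap_dfr(grid, function(eye_feature, channel, band) {
    a <- eye_ratios[eye_ratios$source == eye_feature &
                      eye_ratios$band == band, ]
    b <- eeg_ratios[eeg_ratios$source == channel &
                      eeg_ratios$band == band, ]
    pairs <- suppressMessages(align_ratio_series(a, b))
    res <- tryCatch({
      fit <- suppressWarnings(fit_sync(pairs, spec = spec))
      tibble::tibble(r2 = fit$metrics$r2, mae = fit$metrics$mae,
                     mse = fit$metrics$mse, n_train = fit$n_train,
                     n_test = fit$n_test)
    }, error = function(e) {
      tibble::tibble(r2 = NA_real_, mae = NA_real_, mse = NA_real_,
                     n_train = NA_integer_, n_test = NA_integer_)
    })
    dplyr::bind_cols(
      tibble::tibble(eye_feature = eye_feature, channel = channel,
                     band = band, model = spec$model), res)
  })
}
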