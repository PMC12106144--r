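#' Fit the mean baseline
#'
#' Predicts, for every input, the per-activity mean of the training labels —
#' the simplest way to assign a dedication to each activity, and the floor
#' every other model is expected to beat.
#'
#' @param train a non-empty `windowed_dataset`.
#' @return A `mean_baseline` predictor.
#' @export
fit_mean_baseline <- function(train) {
  if (n_samples(train) == 0) stop("empty training set")
  structure(list(mu = colMeans(train$y), t = ncol(train$y)),
            class = "mean_baseline")
}

#' @export
predict.mean_baseline <- function(object, newdata, ...) {
  n <- if (inherits(newdata, "windowed_dataset")) n_samples(newdata)
       else dim(newdata)[1]
  matrix(object$mu, n, object$t, byrow = TRUE,
         dimnames = list(NULL, names(object$mu)))
}

## AdaBoost.R2 over regression trees (linear loss, weighted-median combiner).
.adaboost_r2_fit <- function(X, y, n_estimators = 20, maxdepth = 3) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  d <- as.data.frame(X); d$.y <- y
  members <- list(); betas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(.y ~ ., data = d, weights = w * n,
                        control = rpart::rpart.control(maxdepth = maxdepth,
                                                       cp = 0, xval = 0))
    pred <- stats::predict(fit, d)
    err <- abs(pred - y)
    emax <- max(err)
    if (emax <= 0) { members <- c(members, list(fit)); betas <- c(betas, 1e-10); break }
    L <- err / emax
    Lbar <- sum(w * L)
    if (Lbar >= 0.5) { if (m == 1) { members <- list(fit); betas <- 1e-10 }; break }
    beta <- Lbar / (1 - Lbar)
    members <- c(members, list(fit)); betas <- c(betas, beta)
    w <- w * beta^(1 - L)
    w <- w / sum(w)
  }
  list(members = members, log_inv_beta = log(1 / betas))
}

.adaboost_r2_predict <- function(model, X) {
  d <- as.data.frame(X)
  P <- vapply(model$members, function(f) stats::predict(f, d),
              numeric(nrow(d)))
  P <- matrix(P, nrow = nrow(d))
  wts <- model$log_inv_beta
  apply(P, 1, function(p) {
    o <- order(p)
    cw <- cumsum(wts[o])
    p[o][which(cw >= 0.5 * sum(wts))[1]]
  })
}

## Gaussian Bayesian ridge regression (closed-form posterior mean) per label.
.bayes_ridge_fit <- function(X, y, lambda = 1) {
  mu_x <- colMeans(X); sd_x <- apply(X, 2, stats::sd); sd_x[sd_x == 0] <- 1
  Z <- scale(X, center = mu_x, scale = sd_x)
  mu_y <- mean(y)
  A <- crossprod(Z) + lambda * diag(ncol(Z))
  beta <- solve(A, crossprod(Z, y - mu_y))
  list(beta = beta, mu_x = mu_x, sd_x = sd_x, mu_y = mu_y)
}

.bayes_ridge_predict <- function(model, X) {
  Z <- scale(X, center = model$mu_x, scale = model$sd_x)
  as.numeric(Z %*% model$beta) + model$mu_y
}

#' Fit per-activity single-day ("window = 1") regressors
#'
#' Classic regressors cannot consume a multi-day sequence, so they see only
#' the previous day's dedication vector. One independent single-output model
#' is fitted per activity and predictions are assembled into the full
#' t-vector, with negatives clipped to zero.
#'
#' @param train a `windowed_dataset` with exactly 1 input day (`w = 2`).
#' @param kind one of `"knn"`, `"svm"`, `"naive_bayes_style"` (a Gaussian
#'   Bayesian ridge per label), `"adaboost"` (AdaBoost.R2 over regression
#'   trees), `"random_forest"`, `"feedforward_net"`.
#' @param k,ntree,size,lambda,n_estimators,maxit,decay tuning knobs of the
#'   respective underlying fitters.
#' @return A `window1_predictor`.
#' @details An activity whose training labels are constant (commonly all
#'   zero) gets a constant predictor for any kind: several of the underlying
#'   fitters reject zero-variance targets, and the constant is their exact
#'   optimum anyway.
#' @export
fit_window1_regressors <- function(train,
                                   kind = c("knn", "svm", "naive_bayes_style",
                                            "adaboost", "random_forest",
                                            "feedforward_net"),
                                   k = 5L, ntree = 100, size = 16, lambda = 1,
                                   n_estimators = 20, maxit = 200,
                                   decay = 1e-3) {
  kind <- match.arg(kind)
  if (dim(train$x)[2] != 1L) {
    stop("window-1 regressors need exactly 1 input day (w = 2), got ",
         dim(train$x)[2])
  }
  X <- matrix(train$x[, 1, ], nrow = dim(train$x)[1])
  colnames(X) <- train$activity_names
  Y <- train$y
  fits <- lapply(seq_len(ncol(Y)), function(j) {
    y <- Y[, j]
    if (stats::var(y) == 0) {
      return(structure(list(value = y[1]), class = "constant_fit"))
    }
    switch(kind,
      knn = list(X = X, y = y, k = k),
      svm = e1071::svm(x = X, y = y),
      naive_bayes_style = .bayes_ridge_fit(X, y, lambda = lambda),
      adaboost = .adaboost_r2_fit(X, y, n_estimators = n_estimators),
      random_forest = randomForest::randomForest(X, y, ntree = ntree),
      feedforward_net = nnet::nnet(X / 100, y, size = size,
                                   linout = TRUE, trace = FALSE,
                                   maxit = maxit, decay = decay,
                                   MaxNWts = 1e5))
  })
  structure(list(kind = kind, fits = fits, t = ncol(Y),
                 activity_names = train$activity_names),
            class = "window1_predictor")
}

#' @export
predict.window1_predictor <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "windowed_dataset")) newdata$x else newdata
  stopifnot(dim(x)[2] == 1L)
  X <- matrix(x[, 1, ], nrow = dim(x)[1])
  colnames(X) <- object$activity_names
  preds <- vapply(object$fits, function(f) {
    if (inherits(f, "constant_fit")) return(rep(f$value, nrow(X)))
    switch(object$kind,
      knn = FNN::knn.reg(train = f$X, test = X, y = f$y, k = f$k)$pred,
      svm = as.numeric(stats::predict(f, X)),
      naive_bayes_style = .bayes_ridge_predict(f, X),
      adaboost = .adaboost_r2_predict(f, X),
      random_forest = as.numeric(stats::predict(f, X)),
      feedforward_net = as.numeric(stats::predict(f, X / 100)))
  }, numeric(nrow(X)))
  preds <- matrix(preds, nrow = nrow(X),
                  dimnames = list(NULL, object$activity_names))
  pmax(preds, 0)
}

#' Evaluate a predictor on a windowed dataset
#'
#' Per-day MAE is the mean over the t activities of the absolute error and
#' per-day MSE the mean of the squared error; dataset scores average over
#' days. Everything is on the percentage scale.
#'
#' @param predictor any fitted predictor with a `predict` method.
#' @param data a non-empty `windowed_dataset`.
#' @return list with `mse`, `mae`, per-day vectors `mse_per_day`,
#'   `mae_per_day`, and wall-clock `seconds` for the predict call.
#' @export
evaluate <- function(predictor, data) {
  if (n_samples(data) == 0) stop("empty evaluation set")
  t0 <- proc.time()["elapsed"]
  pred <- stats::predict(predictor, data)
  secs <- as.numeric(proc.time()["elapsed"] - t0)
  if (!all(dim(pred) == dim(data$y))) stop("prediction shape mismatch")
  err <- pred - data$y
  mae_day <- rowMeans(abs(err))
  mse_day <- rowMeans(err^2)
  list(mse = mean(mse_day), mae = mean(mae_day),
       mse_per_day = mse_day, mae_per_day = mae_day, seconds = secs)
}

# Per-user chronologically contiguous k folds over window samples.
.fold_ids <- function(data, k, mode = c("chronological", "shuffled"),
                      seed = NULL) {
  mode <- match.arg(mode)
  n <- n_samples(data)
  fold <- integer(n)
  if (mode == "shuffled") {
    if (!is.null(seed)) set.seed(seed)
    return(sample(rep_len(seq_len(k), n)))
  }
  for (idx in split(seq_len(n), data$user)) {
    idx <- idx[order(data$label_day[idx])]
    fold[idx] <- ceiling(seq_along(idx) / (length(idx) / k))
  }
  pmin(fold, k)
}

#' k-fold cross-validation of a model factory
#'
#' Folds partition the window samples into chronologically contiguous blocks
#' per user (default), so each fold preserves within-user time order; a
#' shuffled mode is available for comparison but mixes past and future days
#' of the same user across folds (leakage-prone).
#'
#' @param model_factory function(train_dataset) returning a fitted predictor.
#' @param data a `windowed_dataset`.
#' @param k number of folds (default 3).
#' @param seed seed for the shuffled mode.
#' @param mode `"chronological"` (default) or `"shuffled"`.
#' @return An `eval_result`: per-fold scores plus mean and population-form
#'   standard deviation of MSE, MAE and seconds.
#' @export
cross_validate <- function(model_factory, data, k = 3, seed = 1L,
                           mode = c("chronological", "shuffled")) {
  if (k < 2) stop("k must be >= 2")
  mode <- match.arg(mode)
  fold <- .fold_ids(data, k, mode, seed)
  if (length(unique(fold)) < k) stop("not enough samples for ", k, " folds")
  rows <- lapply(seq_len(k), function(f) {
    tr <- subset_windows(data, which(fold != f))
    te <- subset_windows(data, which(fold == f))
    t0 <- proc.time()["elapsed"]
    fit <- model_factory(tr)
    ev <- evaluate(fit, te)
    data.frame(fold = f, mse = ev$mse, mae = ev$mae,
               seconds = as.numeric(proc.time()["elapsed"] - t0))
  })
  folds <- do.call(rbind, rows)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  structure(list(
    folds = folds,
    mse_mean = mean(folds$mse), mse_sd = pop_sd(folds$mse),
    mae_mean = mean(folds$mae), mae_sd = pop_sd(folds$mae),
    seconds_mean = mean(folds$seconds), seconds_sd = pop_sd(folds$seconds)),
    class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("MSE %.2f (+/-%.2f)  MAE %.2f (+/-%.2f)  time %.2fs (+/-%.2f) over %d folds\n",
              x$mse_mean, x$mse_sd, x$mae_mean, x$mae_sd,
              x$seconds_mean, x$seconds_sd, nrow(x$folds)))
  invisible(x)
}

#' Two-sided paired t-test on per-fold scores
#'
#' Conventions for the degenerate cases that arise with k = 3 folds: if every
#' per-fold difference is zero the models are indistinguishable (p = 1); if
#' the differences are nonzero but have zero variance the direction is
#' unambiguous (p = 0).
#'
#' @param scores_a,scores_b equal-length numeric vectors (length >= 2) of
#'   per-fold scores.
#' @return The two-sided p-value.
#' @export
paired_t_test <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) stop("length mismatch")
  if (length(scores_a) < 2) stop("need at least 2 paired scores")
  d <- scores_a - scores_b
  if (all(d == 0)) return(1)
  if (stats::sd(d) == 0) return(0)
  stats::t.test(scores_a, scores_b, paired = TRUE)$p.value
}

#' Hyperparameter search space for the recurrent families
#'
#' @param n_layers_range recurrent/feed-forward layer counts considered.
#' @param conv_range filters and kernel sizes for the convolutional block.
#' @param units_range hidden-unit counts for recurrent and feed-forward
#'   layers.
#' @param dropout_range dropout-rate interval.
#' @param n_trials number of sampled configurations.
#' @return A `search_space` list.
#' @export
search_space <- function(n_layers_range = 1:4, conv_range = 2:64,
                         units_range = 8:256, dropout_range = c(0, 0.4),
                         n_trials = 25) {
  stopifnot(n_trials >= 1, length(units_range) >= 1)
  structure(list(n_layers_range = n_layers_range, conv_range = conv_range,
                 units_range = units_range, dropout_range = dropout_range,
                 n_trials = as.integer(n_trials)),
            class = "search_space")
}

#' Random hyperparameter search over a recurrent family
#'
#' Draws `space$n_trials` architecture configurations with a seeded
#' independent random sampler, scores each by k-fold cross-validated MSE, and
#' returns the argmin together with the full trial log.
#'
#' @param family recurrent family name (see [model_spec()]).
#' @param space a [search_space()].
#' @param data a `windowed_dataset` (its `w` fixes the model window).
#' @param seed seed for the sampler.
#' @param config a [train_config()] used for every trial.
#' @param k cross-validation folds per trial.
#' @return list with `best_spec`, `best_score` (MSE), and `trials`
#'   (data.frame log).
#' @export
hyperparameter_search <- function(family, space, data, seed = 1L,
                                  config = train_config(), k = 3) {
  stopifnot(inherits(space, "search_space"))
  set.seed(seed)
  w <- data$w
  pick <- function(v) if (length(v) == 1) v else sample(v, 1)  # no 1:n trap
  draws <- lapply(seq_len(space$n_trials), function(i) {
    kern <- pick(space$conv_range)
    model_spec(family = family, w = w,
               units = pick(space$units_range),
               n_layers = pick(space$n_layers_range),
               dropout = stats::runif(1, space$dropout_range[1],
                                      space$dropout_range[2]),
               filters = pick(space$conv_range),
               kernel = min(kern, w - 1))
  })
  t_act <- length(data$activity_names)
  rows <- vector("list", length(draws))
  for (i in seq_along(draws)) {
    spec <- draws[[i]]
    cv <- cross_validate(function(tr) {
      train_predictor(build_recurrent_predictor(spec, t_act), tr, config)
    }, data, k = k)
    rows[[i]] <- data.frame(trial = i, units = spec$units,
                            n_layers = spec$n_layers, dropout = spec$dropout,
                            filters = spec$filters, kernel = spec$kernel,
                            mse = cv$mse_mean, mae = cv$mae_mean)
  }
  trials <- do.call(rbind, rows)
  best <- which.min(trials$mse)
  list(best_spec = draws[[best]], best_score = trials$mse[best],
       trials = trials)
}
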