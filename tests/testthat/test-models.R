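make_structured_windows <- function(n_days = 30, t = 3, w = 2, seed = 5,
                                    n_users = 2) {
  set.seed(seed)
  vals <- matrix(pmax(matrix(rnorm(n_days * t, 10, 3), n_days, t), 0),
                 n_days, t)
  make_windows(tiny_table(vals, activities = paste0("A", seq_len(t)),
                          n_users = n_users), w)
}

test_that("mean baseline predicts the training-label column mean, always", {
  tab <- tiny_table(matrix(c(0, 10, 0, 30), 2, 2, byrow = TRUE),
                    activities = c("A", "B"))
  win <- make_windows(dedication_table(
    rbind(data.frame(user = "u", day = as.Date("2020-01-01") + 0:2,
                     A = c(5, 0, 0), B = c(5, 10, 30))), c("A", "B")), 2)
  bl <- fit_mean_baseline(win)
  pred <- predict(bl, win)
  expect_equal(unname(pred[1, ]), unname(colMeans(win$y)))
  # invariant to the input window contents
  alt <- win; alt$x[] <- 99
  expect_equal(predict(bl, alt), pred)
  # brute-force oracle: explicit per-column loop
  brute <- vapply(seq_len(ncol(win$y)), function(j) sum(win$y[, j]) / nrow(win$y), 0)
  expect_equal(unname(pred[1, ]), brute)
  # single training sample: returns that label verbatim
  one <- subset_idx <- win
  one$x <- win$x[1, , , drop = FALSE]; one$y <- win$y[1, , drop = FALSE]
  one$user <- win$user[1]; one$label_day <- win$label_day[1]
  expect_equal(unname(predict(fit_mean_baseline(one), one)[1, ]),
               unname(win$y[1, ]))
  expect_error(fit_mean_baseline(make_windows(tiny_table(matrix(1, 1, 2),
    activities = c("A", "B")), 2)), "empty")
})

test_that("every window-1 regressor kind recovers a constant routine", {
  win <- constant_windows(n = 20, w = 2, t = 3, value = 12)
  for (kind in c("knn", "svm", "naive_bayes_style", "adaboost",
                 "random_forest", "feedforward_net")) {
    fit <- fit_window1_regressors(win, kind)
    pred <- predict(fit, win)
    expect_equal(dim(pred), dim(win$y))
    expect_true(all(abs(pred - 12) < 1), info = kind)
    expect_true(all(pred >= 0), info = kind)
  }
  expect_error(fit_window1_regressors(win, "boosting"))
  win3 <- constant_windows(n = 10, w = 3)
  expect_error(fit_window1_regressors(win3, "knn"), "exactly 1 input day")
})

test_that("1-nearest-neighbour memorizes distinct training inputs", {
  win <- make_structured_windows(n_days = 15, w = 2, n_users = 1)
  fit <- fit_window1_regressors(win, "knn", k = 1)
  expect_equal(unname(predict(fit, win)), unname(pmax(win$y, 0)),
               tolerance = 1e-9)
})

test_that("recurrent builders give t outputs and normalized attention", {
  for (fam in c("rnn", "bi_rnn", "conv_lstm", "attention_rnn")) {
    spec <- model_spec(fam, w = 6, units = 8, kernel = 2, filters = 4)
    model <- build_recurrent_predictor(spec, t = 5)
    win <- constant_windows(n = 10, w = 6, t = 5, value = 8)
    fit <- train_predictor(model, win, train_config(epochs = 2, seed = 3))
    pred <- predict(fit, win)
    expect_equal(dim(pred), c(n_samples(win), 5))
    expect_true(all(pred >= 0), info = fam)  # ReLU head
  }
  fit_att <- train_predictor(
    build_recurrent_predictor(model_spec("attention_rnn", w = 6, units = 8), 5),
    constant_windows(n = 10, w = 6, t = 5), train_config(epochs = 2, seed = 3))
  alpha <- attention_weights(fit_att, constant_windows(n = 10, w = 6, t = 5))
  expect_equal(dim(alpha), c(5, 5))  # 5 samples, w - 1 = 5 steps
  expect_true(all(alpha >= 0))
  expect_equal(unname(rowSums(alpha)), rep(1, 5), tolerance = 1e-12)
  expect_error(model_spec("rnn", w = 1), "w >= 2")
  expect_error(model_spec("rnn", w = 5, n_layers = 9), "n_layers")
})

test_that("parameter count grows monotonically with units", {
  count <- function(units) {
    plan <- adlmonitor:::.net_plan(model_spec("rnn", w = 5, units = units), 7)
    set.seed(1)
    length(unlist(adlmonitor:::.net_init(plan)))
  }
  # analytic count for 1 LSTM layer + dense head:
  # 4u(t + u + 1) + (u + 1)t with t = 7
  expect_equal(count(8), 4 * 8 * (7 + 8 + 1) + 9 * 7)
  expect_true(count(8) < count(16) && count(16) < count(64))
})

test_that("analytic gradients match numerical differentiation", {
  for (fam in c("rnn", "bi_rnn", "conv_lstm", "attention_rnn")) {
    spec <- model_spec(fam, w = 5, units = 4,
                       n_layers = if (fam == "rnn") 2 else 1,
                       filters = 3, kernel = 2, n_ff_layers = 1, ff_units = 5)
    plan <- adlmonitor:::.net_plan(spec, 3)
    set.seed(20)
    params <- adlmonitor:::.net_init(plan)
    # keep every ReLU strictly active so the loss is differentiable
    for (li in seq_along(plan)) {
      if (plan[[li]]$type %in% c("conv", "dense")) {
        params[[li]]$b <- params[[li]]$b + 1
      }
    }
    x <- array(runif(6 * 4 * 3, 0.1, 0.9), c(6, 4, 3))
    y <- matrix(runif(6 * 3, 1, 3), 6, 3)
    xs <- adlmonitor:::.as_step_list(x)
    loss_fn <- function(p) {
      mean((adlmonitor:::.net_forward(p, plan, xs)$pred - y)^2)
    }
    fw <- adlmonitor:::.net_forward(params, plan, xs)
    d_pred <- 2 * (fw$pred - y) / length(y)
    analytic <- unlist(adlmonitor:::.net_backward(params, plan, fw$caches,
                                                  d_pred))
    flat <- unlist(params)
    relist_tpl <- params
    eps <- 1e-5
    numeric_g <- vapply(seq_along(flat), function(i) {
      up <- flat; up[i] <- up[i] + eps
      dn <- flat; dn[i] <- dn[i] - eps
      (loss_fn(utils::relist(up, relist_tpl)) -
         loss_fn(utils::relist(dn, relist_tpl))) / (2 * eps)
    }, 0)
    scale <- max(abs(numeric_g), 1e-8)
    expect_lt(max(abs(analytic - numeric_g)) / scale, 1e-5)
  }
})

test_that("training is seeded-deterministic and fits a realizable optimum", {
  win <- constant_windows(n = 16, w = 4, t = 3, value = 10)
  cfg <- train_config(epochs = 3, seed = 9)
  m <- build_recurrent_predictor(model_spec("rnn", w = 4, units = 6), 3)
  f1 <- train_predictor(m, win, cfg)
  f2 <- train_predictor(m, win, cfg)
  expect_identical(f1$final_loss, f2$final_loss)
  expect_identical(predict(f1, win), predict(f2, win))
  # constant routine is exactly representable: the loss approaches zero
  f3 <- train_predictor(m, win, train_config(learning_rate = 0.02,
                                             epochs = 60, seed = 9))
  expect_lt(f3$final_loss, 1e-4)
  expect_lt(f3$final_loss, f3$loss_history[1])
  expect_error(train_predictor(m, constant_windows(n = 10, w = 3), cfg),
               "does not match")
})

test_that("checkpoints reload to bit-identical predictions", {
  win <- make_structured_windows(n_days = 12, w = 3, t = 3)
  fit <- train_predictor(
    build_recurrent_predictor(model_spec("attention_rnn", w = 3, units = 5), 3),
    win, train_config(epochs = 2, seed = 4))
  dir <- tempfile("ckpt")
  save_predictor(fit, dir, activity_names = paste0("A", 1:3))
  back <- load_predictor(dir)
  expect_identical(predict(back, win), predict(fit, win))
})

test_that("evaluation scores follow the per-day MAE/MSE definitions", {
  win <- constant_windows(n = 10, w = 2, t = 2, value = 0)
  perfect <- fit_mean_baseline(win)  # labels constant 0 -> predicts 0
  ev <- evaluate(perfect, win)
  expect_equal(ev$mse, 0)
  expect_equal(ev$mae, 0)

  # hand-checked day scores
  fake <- structure(list(value = c(3, 3)), class = "fixed_pred")
  assign("predict.fixed_pred",
         function(object, newdata, ...) {
           matrix(object$value, n_samples(newdata), 2, byrow = TRUE)
         }, envir = globalenv())
  on.exit(rm("predict.fixed_pred", envir = globalenv()), add = TRUE)
  ev2 <- evaluate(fake, win)                      # truth 0, prediction 3
  expect_equal(ev2$mae, 3)
  expect_equal(ev2$mse, 9)

  fake2 <- structure(list(value = c(0, 0)), class = "fixed_pred")
  win04 <- win; win04$y <- matrix(c(0, 4), 10, 2, byrow = TRUE)
  ev3 <- evaluate(fake2, win04)                   # truth (0,4), prediction 0
  expect_equal(ev3$mae, 2)
  expect_equal(ev3$mse, 8)
})

test_that("per-day MSE dominates squared MAE (Jensen)", {
  set.seed(1)
  for (i in 1:20) {
    a <- runif(41, 0, 50); b <- runif(41, 0, 50)
    expect_gte(mean((a - b)^2), mean(abs(a - b))^2)
  }
})

test_that("cross-validation folds are chronologically contiguous per user", {
  win <- make_structured_windows(n_days = 20, w = 2, n_users = 3)
  fold <- adlmonitor:::.fold_ids(win, 3)
  for (u in unique(win$user)) {
    f <- fold[win$user == u][order(win$label_day[win$user == u])]
    expect_true(all(diff(f) >= 0))  # non-decreasing in time
    expect_equal(sort(unique(f)), 1:3)
  }
  cv <- cross_validate(fit_mean_baseline, win, k = 3)
  expect_equal(nrow(cv$folds), 3)
  # population-form spread convention, e.g. sd([4,5,6]) -> sqrt(2/3)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  expect_equal(cv$mse_sd, pop_sd(cv$folds$mse))
  expect_equal(pop_sd(c(4, 5, 6)), 0.8164966, tolerance = 1e-6)
  expect_error(cross_validate(fit_mean_baseline, win, k = 1), "k must be")
})

test_that("paired t-test matches the textbook formula and conventions", {
  a <- c(5.0, 4.5, 4.7); b <- c(4.4, 4.3, 4.5)
  d <- a - b
  t_stat <- mean(d) / (sd(d) / sqrt(length(d)))
  p_oracle <- 2 * pt(-abs(t_stat), df = length(d) - 1)
  expect_equal(paired_t_test(a, b), p_oracle, tolerance = 1e-12)
  expect_equal(paired_t_test(a, b), paired_t_test(b, a))  # two-sided symmetry
  expect_equal(paired_t_test(a, a), 1)
  expect_equal(paired_t_test(c(2, 3, 4), c(1, 2, 3)), 0)  # zero-variance diff
  expect_error(paired_t_test(1:3, 1:2), "length")
})

test_that("random search stays in range, is seeded, and handles collapse", {
  win <- make_structured_windows(n_days = 12, w = 3, t = 2, n_users = 2)
  cfg <- train_config(epochs = 1, batch_size = 16, seed = 2)
  point <- search_space(n_layers_range = 1, conv_range = 2, units_range = 8,
                        dropout_range = c(0, 0), n_trials = 25)
  res <- suppressWarnings(
    hyperparameter_search("rnn", point, win, seed = 1, config = cfg, k = 2))
  expect_equal(nrow(res$trials), 25)
  expect_true(all(res$trials$units == 8))
  expect_equal(res$best_spec$units, 8L)

  space <- search_space(units_range = 8:16, n_trials = 4,
                        dropout_range = c(0, 0.4))
  r1 <- suppressWarnings(
    hyperparameter_search("rnn", space, win, seed = 3, config = cfg, k = 2))
  r2 <- suppressWarnings(
    hyperparameter_search("rnn", space, win, seed = 3, config = cfg, k = 2))
  expect_true(all(r1$trials$units %in% 8:16))
  expect_true(all(r1$trials$dropout >= 0 & r1$trials$dropout <= 0.4))
  expect_true(all(r1$trials$n_layers %in% 1:4))
  expect_identical(r1$trials, r2$trials)  # reproducible trial sequence
})
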