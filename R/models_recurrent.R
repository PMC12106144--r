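#' Training configuration for the recurrent predictors
#'
#' Defaults follow the reference recipe used throughout the package: Adam
#' (learning rate 0.1, beta1 0.9, beta2 0.999), mean-squared-error loss,
#' batch size 128, 80 epochs, and a ReLU final activation so predicted
#' dedications are never negative.
#'
#' @param learning_rate Adam step size.
#' @param beta1,beta2 Adam exponential decay rates for the first and second
#'   moment estimates.
#' @param batch_size minibatch size.
#' @param epochs full passes over the training data.
#' @param seed integer seed controlling initialization and batch order.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.1, beta1 = 0.9, beta2 = 0.999,
                         batch_size = 128, epochs = 80, seed = 1L) {
  stopifnot(learning_rate > 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            batch_size >= 1, epochs >= 1)
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

#' Architecture specification for a next-day predictor
#'
#' @param family one of `"rnn"` (stacked LSTM), `"bi_rnn"` (bidirectional
#'   LSTM), `"conv_lstm"` (1-D convolution over time, then LSTM), or
#'   `"attention_rnn"` (LSTM, additive attention over time steps, LSTM).
#' @param w window size: the first `w - 1` days are the input, day `w` the
#'   label. Recurrent families require `w >= 2`.
#' @param units hidden units per recurrent layer.
#' @param n_layers number of recurrent layers (1-4; attention_rnn always uses
#'   two with the attention block in between).
#' @param dropout dropout rate on hidden activations during training, in
#'   \[0, 0.4\].
#' @param filters,kernel convolution filters and kernel width (conv_lstm only).
#' @param n_ff_layers,ff_units optional ReLU feed-forward layers between the
#'   recurrent stack and the output layer.
#' @return A `model_spec`.
#' @export
model_spec <- function(family = c("rnn", "bi_rnn", "conv_lstm",
                                  "attention_rnn"),
                       w = 15, units = 32, n_layers = 1, dropout = 0,
                       filters = 16, kernel = 3, n_ff_layers = 0,
                       ff_units = 64) {
  family <- match.arg(family)
  if (w < 2) stop("recurrent families require w >= 2")
  if (n_layers < 1 || n_layers > 4) stop("n_layers must be in 1..4")
  if (dropout < 0 || dropout > 0.4) stop("dropout must be in [0, 0.4]")
  if (family == "conv_lstm" && kernel > w - 1) {
    stop("conv kernel must not exceed the ", w - 1, " input days")
  }
  structure(list(family = family, w = as.integer(w), units = as.integer(units),
                 n_layers = as.integer(n_layers), dropout = dropout,
                 filters = as.integer(filters), kernel = as.integer(kernel),
                 n_ff_layers = as.integer(n_ff_layers),
                 ff_units = as.integer(ff_units)),
            class = "model_spec")
}

# Layer plan: ordered layer descriptors with input/output dims resolved.
.net_plan <- function(spec, t) {
  plan <- list(); d <- t
  add <- function(l) plan[[length(plan) + 1]] <<- l
  if (spec$family == "conv_lstm") {
    add(list(type = "conv", d_in = d, filters = spec$filters,
             kernel = spec$kernel))
    d <- spec$filters
  }
  n_rec <- if (spec$family == "attention_rnn") 2L else spec$n_layers
  for (j in seq_len(n_rec)) {
    last_rec <- j == n_rec
    if (spec$family == "bi_rnn") {
      add(list(type = "bilstm", d_in = d, units = spec$units,
               return_seq = !last_rec, drop = spec$dropout))
      d <- 2L * spec$units
    } else {
      add(list(type = "lstm", d_in = d, units = spec$units,
               return_seq = !last_rec, drop = spec$dropout))
      d <- spec$units
    }
    if (spec$family == "attention_rnn" && j == 1L) {
      add(list(type = "attn", d_in = d, attn_units = spec$units))
    }
  }
  for (j in seq_len(spec$n_ff_layers)) {
    add(list(type = "dense", d_in = d, d_out = spec$ff_units, relu = TRUE,
             drop = spec$dropout))
    d <- spec$ff_units
  }
  add(list(type = "dense", d_in = d, d_out = t, relu = TRUE, drop = 0))
  plan
}

.net_init <- function(plan) {
  lapply(plan, function(l) switch(
    l$type,
    conv = .conv_init(l$d_in, l$filters, l$kernel),
    lstm = .lstm_init(l$d_in, l$units),
    bilstm = list(fwd = .lstm_init(l$d_in, l$units),
                  bwd = .lstm_init(l$d_in, l$units)),
    attn = .attn_init(l$d_in, l$attn_units),
    dense = .dense_init(l$d_in, l$d_out)))
}

# Forward pass. `xs` is a list of per-step (B x d) matrices already on the
# [0, 1] scale. Returns predictions on the percent scale plus caches.
.net_forward <- function(params, plan, xs, train = FALSE) {
  caches <- vector("list", length(plan))
  cur <- xs  # sequence until a non-return_seq recurrent layer collapses it
  for (li in seq_along(plan)) {
    l <- plan[[li]]; p <- params[[li]]
    if (l$type == "conv") {
      f <- .conv_forward(p, cur)
      caches[[li]] <- list(fwd = f$cache); cur <- f$out
    } else if (l$type == "lstm") {
      f <- .lstm_forward(p, cur, l$units, return_seq = l$return_seq)
      caches[[li]] <- list(fwd = f)
      cur <- f$out
    } else if (l$type == "bilstm") {
      ff <- .lstm_forward(p$fwd, cur, l$units, reverse = FALSE,
                          return_seq = l$return_seq)
      fb <- .lstm_forward(p$bwd, cur, l$units, reverse = TRUE,
                          return_seq = l$return_seq)
      caches[[li]] <- list(fwd = ff, bwd = fb)
      cur <- if (l$return_seq) {
        mapply(cbind, ff$out, fb$out, SIMPLIFY = FALSE)
      } else cbind(ff$out, fb$out)
    } else if (l$type == "attn") {
      f <- .attn_forward(p, cur)
      caches[[li]] <- list(fwd = f$cache, alpha = f$cache$alpha)
      cur <- f$out
    } else if (l$type == "dense") {
      f <- .dense_forward(p, cur, relu = l$relu)
      caches[[li]] <- list(fwd = f$cache); cur <- f$out
    }
    # inverted dropout on hidden activations
    if (train && !is.null(l$drop) && l$drop > 0) {
      if (is.list(cur)) {
        masks <- lapply(cur, function(m) .dropout_mask(dim(m), l$drop))
        cur <- mapply(`*`, cur, masks, SIMPLIFY = FALSE)
      } else {
        masks <- .dropout_mask(dim(cur), l$drop)
        cur <- cur * masks
      }
      caches[[li]]$masks <- masks
    }
  }
  list(pred = cur, caches = caches)
}

.net_backward <- function(params, plan, caches, d_pred) {
  grads <- vector("list", length(plan))
  d_cur <- d_pred
  for (li in rev(seq_along(plan))) {
    l <- plan[[li]]; p <- params[[li]]; cc <- caches[[li]]
    if (!is.null(cc$masks)) {
      d_cur <- if (is.list(d_cur)) mapply(`*`, d_cur, cc$masks, SIMPLIFY = FALSE)
               else d_cur * cc$masks
    }
    if (l$type == "conv") {
      b <- .conv_backward(p, cc$fwd, d_cur)
      grads[[li]] <- b$grads; d_cur <- b$dxs
    } else if (l$type == "lstm") {
      b <- .lstm_backward(p, cc$fwd, d_cur, l$units, return_seq = l$return_seq)
      grads[[li]] <- b$grads; d_cur <- b$dxs
    } else if (l$type == "bilstm") {
      u <- l$units
      if (l$return_seq) {
        d_f <- lapply(d_cur, function(m) m[, 1:u, drop = FALSE])
        d_b <- lapply(d_cur, function(m) m[, (u + 1):(2 * u), drop = FALSE])
      } else {
        d_f <- d_cur[, 1:u, drop = FALSE]
        d_b <- d_cur[, (u + 1):(2 * u), drop = FALSE]
      }
      bf <- .lstm_backward(p$fwd, cc$fwd, d_f, u, return_seq = l$return_seq)
      bb <- .lstm_backward(p$bwd, cc$bwd, d_b, u, return_seq = l$return_seq)
      grads[[li]] <- list(fwd = bf$grads, bwd = bb$grads)
      d_cur <- mapply(`+`, bf$dxs, bb$dxs, SIMPLIFY = FALSE)
    } else if (l$type == "attn") {
      b <- .attn_backward(p, cc$fwd, d_cur)
      grads[[li]] <- b$grads; d_cur <- b$dxs
    } else if (l$type == "dense") {
      b <- .dense_backward(p, cc$fwd, d_cur, relu = l$relu)
      grads[[li]] <- b$grads; d_cur <- b$dx
    }
  }
  grads
}

# elementwise map over two identically-shaped nested lists of numerics
.tree_map2 <- function(f, a, b) {
  if (is.list(a)) return(mapply(.tree_map2, a, b, MoreArgs = list(f = f),
                                SIMPLIFY = FALSE))
  f(a, b)
}
.tree_map <- function(f, a) {
  if (is.list(a)) return(lapply(a, .tree_map, f = f))
  f(a)
}

#' Build an untrained recurrent next-day predictor
#'
#' Maps a `(w - 1) x t` block of daily dedications to the predicted t-vector
#' for the next day. Parameters are initialized (seeded) by
#' [train_predictor()].
#'
#' @param spec a [model_spec()].
#' @param t number of activities.
#' @return An `rnn_predictor` (untrained until passed to [train_predictor()]).
#' @export
build_recurrent_predictor <- function(spec, t) {
  stopifnot(inherits(spec, "model_spec"), t >= 1)
  structure(list(spec = spec, t = as.integer(t),
                 plan = .net_plan(spec, as.integer(t)),
                 params = NULL, trained = FALSE),
            class = "rnn_predictor")
}

.as_step_list <- function(x, idx = NULL) {
  if (!is.null(idx)) x <- x[idx, , , drop = FALSE]
  lapply(seq_len(dim(x)[2]), function(s) x[, s, , drop = TRUE] |>
           matrix(nrow = dim(x)[1]))
}

#' Train a recurrent predictor
#'
#' Minimizes mean squared error with Adam for exactly `config$epochs` epochs
#' at the configured batch size. Fully seeded: identical seed, data and
#' configuration reproduce the same parameters and loss.
#'
#' @param model an `rnn_predictor` from [build_recurrent_predictor()].
#' @param train a `windowed_dataset` whose `w` matches the model spec.
#' @param config a [train_config()].
#' @return The trained predictor, with `final_loss` and `loss_history`
#'   attached.
#' @export
train_predictor <- function(model, train, config = train_config()) {
  stopifnot(inherits(model, "rnn_predictor"),
            inherits(train, "windowed_dataset"))
  if (train$w != model$spec$w) {
    stop("dataset window ", train$w, " does not match model spec w ",
         model$spec$w)
  }
  n <- n_samples(train)
  if (n == 0) stop("empty training set")
  set.seed(config$seed)
  params <- .net_init(model$plan)
  # start the output layer at the per-activity training mean: optimization
  # then only has to learn structure on top of the baseline predictor
  params[[length(params)]]$b <- colMeans(train$y)
  m_state <- .tree_map(function(x) x * 0, params)
  v_state <- .tree_map(function(x) x * 0, params)
  b1 <- config$beta1; b2 <- config$beta2; lr <- config$learning_rate
  eps <- 1e-8; step <- 0L
  t_act <- model$t
  losses <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    batch_losses <- c()
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- perm[start:min(start + config$batch_size - 1L, n)]
      xs <- .as_step_list(train$x, idx)
      xs <- lapply(xs, function(m) m / 100)
      y <- train$y[idx, , drop = FALSE]
      fw <- .net_forward(params, model$plan, xs, train = TRUE)
      err <- fw$pred - y
      loss <- mean(err^2)
      if (!is.finite(loss)) {
        stop("training diverged to non-finite loss at epoch ", epoch,
             "; lower the learning rate")
      }
      batch_losses <- c(batch_losses, loss)
      d_pred <- 2 * err / length(err)
      grads <- .net_backward(params, model$plan, fw$caches, d_pred)
      step <- step + 1L
      m_state <- .tree_map2(function(m, g) b1 * m + (1 - b1) * g, m_state, grads)
      v_state <- .tree_map2(function(v, g) b2 * v + (1 - b2) * g^2, v_state, grads)
      corr <- lr * sqrt(1 - b2^step) / (1 - b1^step)
      upd <- .tree_map2(function(m, v) corr * m / (sqrt(v) + eps),
                        m_state, v_state)
      params <- .tree_map2(`-`, params, upd)
    }
    losses[epoch] <- mean(batch_losses)
  }
  model$params <- params
  model$trained <- TRUE
  model$final_loss <- losses[length(losses)]
  model$loss_history <- losses
  model$config <- config
  model
}

#' @export
predict.rnn_predictor <- function(object, newdata, ...) {
  if (!object$trained) stop("predictor has not been trained")
  x <- if (inherits(newdata, "windowed_dataset")) newdata$x else newdata
  stopifnot(length(dim(x)) == 3, dim(x)[2] == object$spec$w - 1L,
            dim(x)[3] == object$t)
  xs <- lapply(.as_step_list(x), function(m) m / 100)
  .net_forward(object$params, object$plan, xs, train = FALSE)$pred
}

#' Attention weights for a batch of windows
#'
#' Only meaningful for `attention_rnn` models: returns the softmax weights
#' ("alpha values") the attention block assigns to each of the `w - 1` input
#' days; rows are samples and sum to 1.
#'
#' @param model a trained `attention_rnn` predictor.
#' @param newdata a `windowed_dataset` or input array.
#' @return Matrix n x (w - 1) of non-negative weights.
#' @export
attention_weights <- function(model, newdata) {
  if (model$spec$family != "attention_rnn") {
    stop("attention weights exist only for attention_rnn models")
  }
  if (!model$trained) stop("predictor has not been trained")
  x <- if (inherits(newdata, "windowed_dataset")) newdata$x else newdata
  xs <- lapply(.as_step_list(x), function(m) m / 100)
  fw <- .net_forward(model$params, model$plan, xs, train = FALSE)
  ai <- which(vapply(model$plan, function(l) l$type, "") == "attn")
  fw$caches[[ai]]$alpha
}

#' Save a trained predictor as a plain-text checkpoint
#'
#' Writes `manifest.yaml` (family, architecture, window, seed, activity
#' vocabulary) and `weights.txt` (hex-exact parameter dump) into `dir`.
#' Reloading reproduces predictions bit-identically on the same platform.
#'
#' @param model a trained `rnn_predictor`.
#' @param dir checkpoint directory (created if absent).
#' @param activity_names optional activity vocabulary recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
save_predictor <- function(model, dir, activity_names = NULL) {
  if (!model$trained) stop("refusing to checkpoint an untrained predictor")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(spec = unclass(model$spec), t = model$t,
                   seed = model$config$seed,
                   epochs = model$config$epochs,
                   activity_names = activity_names)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  dput(model$params, file = file.path(dir, "weights.txt"),
       control = c("all", "hexNumeric"))
  invisible(dir)
}

#' Load a predictor checkpoint written by [save_predictor()]
#' @param dir checkpoint directory.
#' @return A trained `rnn_predictor`.
#' @export
load_predictor <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  spec <- do.call(model_spec, manifest$spec[c("family", "w", "units",
                                              "n_layers", "dropout", "filters",
                                              "kernel", "n_ff_layers",
                                              "ff_units")])
  model <- build_recurrent_predictor(spec, manifest$t)
  model$params <- dget(file.path(dir, "weights.txt"))
  model$trained <- TRUE
  model$config <- train_config(seed = manifest$seed %||% 1L,
                               epochs = manifest$epochs %||% 80L)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
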