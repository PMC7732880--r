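# Feed-forward neural network classifier: fully connected hidden layers with
# tanh activations and batch normalization, sigmoid output, binary
# cross-entropy loss, Adam updates on shuffled mini-batches. Written in
# plain matrix algebra: at the post-selection widths this package works with
# (tens of features, a few thousand rows) that is fast and keeps training
# bit-reproducible under a seed.

#' Neural network configuration
#'
#' @param hidden_layers number of hidden layers (default 4).
#' @param hidden_width units per hidden layer (default 64).
#' @param activation only `"tanh"` is supported.
#' @param batch_norm apply batch normalization before each activation.
#' @param epochs training epochs (default 100).
#' @param batch_size mini-batch size (default 100).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed integer seed for initialization and batch shuffling.
#' @return an object of class `nn_config`.
#' @export
nn_config <- function(hidden_layers = 4L, hidden_width = 64L,
                      activation = "tanh", batch_norm = TRUE,
                      epochs = 100L, batch_size = 100L,
                      learning_rate = 1e-3, seed = 1L) {
  if (!is_count(hidden_layers, 1L)) stop_ts("hidden_layers must be >= 1")
  if (!is_count(hidden_width, 1L)) stop_ts("hidden_width must be >= 1")
  if (!identical(activation, "tanh")) stop_ts("only tanh activation is supported")
  if (!is_count(epochs, 1L)) stop_ts("epochs must be >= 1")
  if (!is_count(batch_size, 1L)) stop_ts("batch_size must be >= 1")
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    stop_ts("learning_rate must be positive")
  structure(list(hidden_layers = as.integer(hidden_layers),
                 hidden_width = as.integer(hidden_width),
                 activation = activation, batch_norm = isTRUE(batch_norm),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = seed),
            class = "nn_config")
}

nn_init <- function(d_in, cfg) {
  widths <- c(d_in, rep(cfg$hidden_width, cfg$hidden_layers))
  layers <- vector("list", cfg$hidden_layers)
  for (l in seq_len(cfg$hidden_layers)) {
    fan_in <- widths[l]; fan_out <- widths[l + 1]
    lim <- sqrt(6 / (fan_in + fan_out))  # Xavier uniform, suits tanh
    layers[[l]] <- list(
      W = matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
      b = numeric(fan_out),                       # used when batch_norm off
      gamma = rep(1, fan_out), beta = numeric(fan_out),
      run_mean = numeric(fan_out), run_var = rep(1, fan_out))
  }
  lim <- sqrt(6 / (cfg$hidden_width + 1))
  list(layers = layers,
       W_out = matrix(runif(cfg$hidden_width, -lim, lim), cfg$hidden_width, 1),
       b_out = 0)
}

nn_forward <- function(params, X, cfg, training = FALSE, eps = 1e-5) {
  m <- nrow(X)
  cache <- list(A = list(X))
  A <- X
  for (l in seq_along(params$layers)) {
    L <- params$layers[[l]]
    Z <- A %*% L$W
    if (cfg$batch_norm) {
      if (training) {
        mu <- colMeans(Z)
        v <- colMeans(Z^2) - mu^2                 # population variance
      } else {
        mu <- L$run_mean; v <- L$run_var
      }
      inv_sd <- 1 / sqrt(v + eps)
      Xhat <- sweep(sweep(Z, 2, mu, "-"), 2, inv_sd, "*")
      Y <- sweep(sweep(Xhat, 2, L$gamma, "*"), 2, L$beta, "+")
      cache[[paste0("bn", l)]] <- list(Xhat = Xhat, inv_sd = inv_sd,
                                       mu = mu, v = v)
    } else {
      Y <- sweep(Z, 2, L$b, "+")
    }
    H <- tanh(Y)
    cache$A[[l + 1]] <- H
    A <- H
  }
  logits <- as.vector(A %*% params$W_out + params$b_out)
  cache$probs <- plogis(logits)
  cache
}

#' Fit the feed-forward neural network
#'
#' Trains the network on the training rows of the split, typically on the
#' lasso-selected feature subset. Architecture, activation, normalization,
#' epochs and batch size follow the supplied `nn_config`. Training is fully
#' deterministic given the config seed (single-threaded R matrix algebra).
#' Mini-batches of size 1 at the epoch tail are skipped because batch
#' statistics are undefined there.
#'
#' @param fm a `feature_matrix` (restrict with `features` for the
#'   lasso-selected subset).
#' @param split a `split_plan`.
#' @param cfg an `nn_config`.
#' @param features optional feature subset.
#' @return a `fit_result` with `model_kind = "neural_net"` (no coefficient
#'   map; prediction uses batch-norm running statistics).
#' @export
fit_neural_network <- function(fm, split, cfg = nn_config(),
                               features = NULL) {
  stopifnot(inherits(cfg, "nn_config"))
  if (!is.null(features)) {
    if (!length(features)) stop_ts("neural network feature subset is empty")
    fm <- subset_features(fm, features)
  }
  d <- train_xy(fm, split)
  X <- d$x; y <- as.double(d$y)
  n <- nrow(X); momentum <- 0.1; eps <- 1e-5
  lr <- cfg$learning_rate; b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8

  withr::with_seed(cfg$seed, {
    params <- nn_init(ncol(X), cfg)
    adam <- list(); adam_t <- 0
    get_state <- function(key, dims) {
      if (is.null(adam[[key]]))
        adam[[key]] <<- list(m = array(0, dims), v = array(0, dims))
      adam[[key]]
    }
    upd <- function(key, theta, grad) {
      st <- get_state(key, dim(as.array(theta)) %||% length(theta))
      st$m <- b1 * st$m + (1 - b1) * grad
      st$v <- b2 * st$v + (1 - b2) * grad^2
      adam[[key]] <<- st
      mhat <- st$m / (1 - b1^adam_t)
      vhat <- st$v / (1 - b2^adam_t)
      out <- theta - lr * mhat / (sqrt(vhat) + adam_eps)
      dim(out) <- dim(theta)  # keep matrices as matrices, scalars bare
      out
    }

    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(n)
      starts <- seq(1, n, by = cfg$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1, n)]
        if (length(idx) < 2L) next
        Xb <- X[idx, , drop = FALSE]; yb <- y[idx]
        m <- length(idx)
        cache <- nn_forward(params, Xb, cfg, training = TRUE, eps = eps)
        adam_t <- adam_t + 1

        # output layer: BCE gradient wrt logits
        dlogit <- matrix((cache$probs - yb) / m, ncol = 1)
        H_last <- cache$A[[length(cache$A)]]
        gW_out <- crossprod(H_last, dlogit)
        gb_out <- sum(dlogit)
        dA <- dlogit %*% t(params$W_out)

        grads <- vector("list", cfg$hidden_layers)
        for (l in rev(seq_len(cfg$hidden_layers))) {
          L <- params$layers[[l]]
          H <- cache$A[[l + 1]]
          dY <- dA * (1 - H^2)                     # through tanh
          if (cfg$batch_norm) {
            bn <- cache[[paste0("bn", l)]]
            dgamma <- colSums(dY * bn$Xhat)
            dbeta <- colSums(dY)
            dXhat <- sweep(dY, 2, L$gamma, "*")
            sum_dXhat <- colSums(dXhat)
            sum_dXhat_xhat <- colSums(dXhat * bn$Xhat)
            dZ <- sweep(
              m * dXhat -
                matrix(sum_dXhat, m, length(sum_dXhat), byrow = TRUE) -
                bn$Xhat * matrix(sum_dXhat_xhat, m, length(sum_dXhat),
                                 byrow = TRUE),
              2, bn$inv_sd / m, "*")
            grads[[l]] <- list(gamma = dgamma, beta = dbeta)
            # batch-norm running statistics (training-time side effect)
            params$layers[[l]]$run_mean <-
              (1 - momentum) * L$run_mean + momentum * bn$mu
            params$layers[[l]]$run_var <-
              (1 - momentum) * L$run_var + momentum * bn$v
          } else {
            dZ <- dY
            grads[[l]] <- list(b = colSums(dY))
          }
          A_prev <- cache$A[[l]]
          grads[[l]]$W <- crossprod(A_prev, dZ)
          dA <- dZ %*% t(L$W)
        }

        params$W_out <- upd("W_out", params$W_out, gW_out)
        params$b_out <- upd("b_out", params$b_out, gb_out)
        for (l in seq_len(cfg$hidden_layers)) {
          key <- function(nm) paste0("L", l, "_", nm)
          params$layers[[l]]$W <- upd(key("W"), params$layers[[l]]$W,
                                      grads[[l]]$W)
          if (cfg$batch_norm) {
            params$layers[[l]]$gamma <- upd(key("gamma"),
                                            params$layers[[l]]$gamma,
                                            grads[[l]]$gamma)
            params$layers[[l]]$beta <- upd(key("beta"),
                                           params$layers[[l]]$beta,
                                           grads[[l]]$beta)
          } else {
            params$layers[[l]]$b <- upd(key("b"), params$layers[[l]]$b,
                                        grads[[l]]$b)
          }
        }
      }
    }

    feats <- fm$feature_names
    predict_fn <- function(mtx) {
      missing <- setdiff(feats, colnames(mtx))
      if (length(missing))
        stop_ts("prediction matrix lacks feature(s): %s",
                paste(head(missing, 5), collapse = ", "))
      nn_forward(params, mtx[, feats, drop = FALSE], cfg,
                 training = FALSE, eps = eps)$probs
    }
    new_fit_result(
      "neural_net", penalty = NA_real_, intercept = NA_real_,
      coefficients = NULL, predict_fn = predict_fn, features = feats,
      training_meta = list(seed = cfg$seed, epochs = cfg$epochs,
                           batch_size = cfg$batch_size,
                           hidden_layers = cfg$hidden_layers,
                           hidden_width = cfg$hidden_width,
                           weight_checksum = sum(abs(params$W_out)) +
                             sum(vapply(params$layers,
                                        function(L) sum(abs(L$W)), 0))))
  })
}
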