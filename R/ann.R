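#' Min-max feature scaling to [-1, 1]
#'
#' Maps each column affinely onto `[-1, 1]` and stores the per-column
#' minima/maxima for the inverse transform. Constant columns (for example
#' the activity-duration feature, which is constant within a trial) map to 0
#' and are flagged; their inverse transform restores the constant.
#'
#' @param X numeric matrix (rows = observations).
#' @return List with `x` (scaled matrix) and `params` (`min`, `max`,
#'   `constant` logical) usable with [minmax_apply()] / [minmax_invert()].
#' @export
minmax_scale <- function(X) {
  X <- as.matrix(X)
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  const <- (hi - lo) < .Machine$double.eps^0.5
  params <- list(min = lo, max = hi, constant = const)
  list(x = minmax_apply(X, params), params = params)
}

#' @param params scaling parameters from [minmax_scale()].
#' @rdname minmax_scale
#' @export
minmax_apply <- function(X, params) {
  X <- as.matrix(X)
  span <- ifelse(params$constant, 1, params$max - params$min)
  Xs <- sweep(sweep(X, 2, params$min), 2, span, "/") * 2 - 1
  Xs[, params$constant] <- 0
  Xs
}

#' @param Xs scaled matrix to map back to original units.
#' @rdname minmax_scale
#' @export
minmax_invert <- function(Xs, params) {
  Xs <- as.matrix(Xs)
  span <- ifelse(params$constant, 0, params$max - params$min)
  sweep(sweep((Xs + 1) / 2, 2, span, "*"), 2, params$min, "+")
}

#' Nguyen-Widrow layer initialization
#'
#' Hidden-layer weight rows are random directions rescaled to norm
#' `beta = 0.7 * H^(1/n_in)` (H = nodes in the layer, n_in = inputs to the
#' layer) with biases uniform in `[-beta, beta]`, which spreads the tanh
#' units' active regions across the scaled input range. The linear output
#' layer is initialized uniformly in `[-0.5, 0.5]`.
#'
#' @param layer_sizes integer vector, e.g. `c(28, 5, 5, 4)`.
#' @param seed integer seed.
#' @return List of layers, each with matrix `W` (H x n_in) and vector `b`.
#' @export
nguyen_widrow_init <- function(layer_sizes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_layers <- length(layer_sizes) - 1L
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    n_in <- layer_sizes[l]
    H <- layer_sizes[l + 1L]
    if (l < n_layers) {
      beta <- 0.7 * H^(1 / n_in)
      W <- matrix(stats::runif(H * n_in, -1, 1), H, n_in)
      W <- W * beta / sqrt(rowSums(W^2))
      b <- stats::runif(H, -beta, beta)
    } else {
      W <- matrix(stats::runif(H * n_in, -0.5, 0.5), H, n_in)
      b <- stats::runif(H, -0.5, 0.5)
    }
    layers[[l]] <- list(W = W, b = b)
  }
  layers
}

#' Construct the compact feed-forward network
#'
#' Two tanh hidden layers of five nodes each (ten total hidden nodes) and a
#' linear output layer: `y = W3 tanh(W2 tanh(W1 x + b1) + b2) + b3`, with
#' inputs and targets min-max scaled to `[-1, 1]`.
#'
#' @param n_in number of input features (the wearable workflow uses 28: two
#'   13-channel IMUs, the vertical GRF and the activity duration).
#' @param n_out number of outputs (4: sagittal/frontal angle and moment).
#' @param hidden hidden layer sizes.
#' @param seed initialization seed.
#' @return An `ann_model`: layer sizes, weight/bias list, empty scaling
#'   slots and the seed.
#' @export
ann_model <- function(n_in = 28, n_out = 4, hidden = c(5, 5), seed = NULL) {
  sizes <- c(n_in, hidden, n_out)
  structure(list(layer_sizes = sizes,
                 layers = nguyen_widrow_init(sizes, seed),
                 in_scale = NULL, out_scale = NULL, seed = seed,
                 log = NULL),
            class = "ann_model")
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf("<ann_model> %s%s\n",
              paste(x$layer_sizes, collapse = "-"),
              if (is.null(x$log)) " (untrained)"
              else sprintf(" trained: %d epochs, stop=%s",
                           nrow(x$log$trace), x$log$stop_reason)))
  invisible(x)
}

# forward pass on scaled inputs; returns activations for the Jacobian
ann_forward_scaled <- function(layers, Xs, keep = FALSE) {
  A1 <- tanh(tcrossprod(Xs, layers[[1]]$W) +
               matrix(layers[[1]]$b, nrow(Xs), length(layers[[1]]$b),
                      byrow = TRUE))
  A2 <- tanh(tcrossprod(A1, layers[[2]]$W) +
               matrix(layers[[2]]$b, nrow(Xs), length(layers[[2]]$b),
                      byrow = TRUE))
  Y <- tcrossprod(A2, layers[[3]]$W) +
    matrix(layers[[3]]$b, nrow(Xs), length(layers[[3]]$b), byrow = TRUE)
  if (keep) list(A1 = A1, A2 = A2, Y = Y) else Y
}

#' Network prediction in original units
#'
#' Applies the stored input scaling, runs the forward pass and inverts the
#' output scaling. For an untrained model (no scaling fitted yet) the input
#' is assumed already scaled and outputs are returned unscaled.
#'
#' @param model an [ann_model()].
#' @param X feature matrix (rows = observations).
#' @return Matrix of predictions, one column per output.
#' @export
ann_predict <- function(model, X) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
  if (ncol(X) != model$layer_sizes[1])
    stop(sprintf("expected %d features, got %d", model$layer_sizes[1], ncol(X)))
  Xs <- if (is.null(model$in_scale)) X else minmax_apply(X, model$in_scale)
  Ys <- ann_forward_scaled(model$layers, Xs)
  if (is.null(model$out_scale)) Ys else minmax_invert(Ys, model$out_scale)
}

#' Training configuration for Levenberg-Marquardt
#'
#' @param max_epochs maximum number of full-batch LM passes.
#' @param lambda0 initial damping.
#' @param lambda_up,lambda_down damping multipliers on rejected/accepted
#'   steps.
#' @param lambda_max damping ceiling; exceeding it aborts training.
#' @param stall_limit training stops once the error-gradient norm has failed
#'   to improve its running minimum for more than this many consecutive
#'   passes (default 6, i.e. stop on the 7th).
#' @param seed initialization seed used when [train_lm()] re-initializes.
#' @return A `train_config` list.
#' @export
train_config <- function(max_epochs = 100, lambda0 = 1e-3, lambda_up = 10,
                         lambda_down = 0.1, lambda_max = 1e10,
                         stall_limit = 6, seed = NULL) {
  stopifnot(stall_limit >= 1, lambda0 > 0)
  structure(list(max_epochs = max_epochs, lambda0 = lambda0,
                 lambda_up = lambda_up, lambda_down = lambda_down,
                 lambda_max = lambda_max, stall_limit = stall_limit,
                 seed = seed),
            class = "train_config")
}

#' Levenberg-Marquardt training
#'
#' Full-batch damped Gauss-Newton on the min-max-scaled data: each pass
#' solves `(J'J + lambda I) delta = J' e` with the analytic Jacobian of the
#' network residuals, decreasing the damping after accepted steps and
#' increasing it after rejected ones. Training stops at `max_epochs`, when
#' the damping exceeds its ceiling, or when the gradient norm has not
#' improved its running minimum for more than `stall_limit` consecutive
#' passes. The returned model carries the best (lowest-SSE) weights, the
#' fitted input/output scaling, and a training log; the final SSE never
#' exceeds the initial one.
#'
#' @param model an [ann_model()] (re-initialized from `config$seed` when
#'   that is non-NULL).
#' @param X,Y training features and targets in original units (>= 10 rows).
#' @param config a [train_config()].
#' @return The trained `ann_model` with `log = list(trace, stop_reason)`.
#' @export
train_lm <- function(model, X, Y, config = train_config()) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  if (nrow(X) < 10) stop("need at least 10 training rows")
  if (!is.null(config$seed)) {
    model$layers <- nguyen_widrow_init(model$layer_sizes, config$seed)
    model$seed <- config$seed
  }
  sx <- minmax_scale(X); sy <- minmax_scale(Y)
  model$in_scale <- sx$params; model$out_scale <- sy$params
  Xs <- sx$x; Ys <- sy$x

  layers <- model$layers
  pack <- function(l) unlist(lapply(l, function(z) c(t(z$W), z$b)))
  unpack <- function(v) {
    out <- layers
    i <- 0L
    for (l in seq_along(out)) {
      H <- nrow(out[[l]]$W); K <- ncol(out[[l]]$W)
      out[[l]]$W <- matrix(v[i + seq_len(H * K)], H, K, byrow = TRUE)
      i <- i + H * K
      out[[l]]$b <- v[i + seq_len(H)]
      i <- i + H
    }
    out
  }

  theta <- pack(layers)
  p <- length(theta)
  sse_of <- function(l) sum((Ys - ann_forward_scaled(l, Xs))^2)
  sse <- sse_of(layers)
  sse0 <- sse
  lambda <- config$lambda0
  best <- list(theta = theta, sse = sse)
  g_min <- Inf
  stall <- 0L
  trace <- vector("list", config$max_epochs)
  stop_reason <- "max_epochs"

  for (epoch in seq_len(config$max_epochs)) {
    fw <- ann_forward_scaled(layers, Xs, keep = TRUE)
    E <- Ys - fw$Y                       # n x n_out residuals
    J <- ann_jacobian(layers, Xs, fw)    # (n * n_out) x p
    e <- as.numeric(E)                   # column-major: output-by-output
    gvec <- crossprod(J, e)
    JtJ <- crossprod(J)
    gnorm <- sqrt(sum(gvec^2))
    # the gradient has "stopped decreasing" once its running minimum goes
    # unimproved for more than stall_limit consecutive passes; besides
    # ending stalled runs this acts as mild early stopping, which helps the
    # small network generalize across subjects
    if (gnorm < g_min - 1e-12) { g_min <- gnorm; stall <- 0L }
    else stall <- stall + 1L
    if (stall > config$stall_limit) {
      stop_reason <- "gradient_stall"
      trace[[epoch]] <- data.frame(epoch = epoch, sse = sse, grad_norm = gnorm,
                                   lambda = lambda, accepted = NA)
      break
    }
    accepted <- FALSE
    while (!accepted) {
      step <- tryCatch(
        solve(JtJ + diag(lambda, p), gvec),
        error = function(e) NULL)
      if (!is.null(step)) {
        cand <- unpack(theta + as.numeric(step))
        sse_new <- sse_of(cand)
        if (is.finite(sse_new) && sse_new < sse) {
          theta <- theta + as.numeric(step)
          layers <- cand
          sse <- sse_new
          lambda <- max(lambda * config$lambda_down, 1e-12)
          accepted <- TRUE
          if (sse < best$sse) best <- list(theta = theta, sse = sse)
        } else lambda <- lambda * config$lambda_up
      } else lambda <- lambda * config$lambda_up
      if (!accepted && lambda > config$lambda_max) break
    }
    trace[[epoch]] <- data.frame(epoch = epoch, sse = sse, grad_norm = gnorm,
                                 lambda = lambda, accepted = accepted)
    if (!accepted) {
      stop_reason <- "lambda_overflow"
      break
    }
  }
  layers <- unpack(best$theta)
  if (best$sse > sse0 + 1e-12)
    stop("training failure: SSE did not decrease")  # cannot happen by design
  model$layers <- layers
  model$log <- list(trace = do.call(rbind, trace[!vapply(trace, is.null, TRUE)]),
                    stop_reason = stop_reason, sse0 = sse0, sse = best$sse)
  model
}

# Analytic Jacobian of the scaled network outputs w.r.t. all weights/biases,
# stacked output-by-output to match as.numeric(E). Parameter order must agree
# with pack()/unpack() in train_lm: W1 rows (by input), b1, W2, b2, W3, b3.
ann_jacobian <- function(layers, Xs, fw) {
  n <- nrow(Xs)
  n_out <- nrow(layers[[3]]$W)
  D2 <- 1 - fw$A2^2
  D1 <- 1 - fw$A1^2
  H1 <- ncol(fw$A1); H2 <- ncol(fw$A2); d <- ncol(Xs)
  blocks <- vector("list", n_out)
  for (o in seq_len(n_out)) {
    G2 <- D2 * matrix(layers[[3]]$W[o, ], n, H2, byrow = TRUE)   # dY/dZ2
    G1 <- (G2 %*% layers[[2]]$W) * D1                            # dY/dZ1
    JW1 <- G1[, rep(seq_len(H1), each = d)] * Xs[, rep(seq_len(d), H1)]
    JW2 <- G2[, rep(seq_len(H2), each = H1)] * fw$A1[, rep(seq_len(H1), H2)]
    JW3 <- matrix(0, n, H2 * n_out)
    JW3[, (o - 1) * H2 + seq_len(H2)] <- fw$A2
    Jb3 <- matrix(0, n, n_out)
    Jb3[, o] <- 1
    blocks[[o]] <- cbind(JW1, G1, JW2, G2, JW3, Jb3)
  }
  do.call(rbind, blocks)
}

#' Serialize a trained network to structured text
#'
#' Writes layer sizes, scaling parameters, row-major weights/biases, the
#' seed and a digest of the training log as JSON; `read_ann()` restores an
#' equivalent model.
#'
#' @param model an [ann_model()].
#' @param path output file.
#' @return `path` invisibly; `read_ann()` returns the model.
#' @export
write_ann <- function(model, path) {
  obj <- list(
    layer_sizes = model$layer_sizes,
    layers = lapply(model$layers, function(l)
      list(W = as.numeric(t(l$W)), b = l$b)),
    in_scale = model$in_scale, out_scale = model$out_scale,
    seed = model$seed,
    log = if (!is.null(model$log))
      list(stop_reason = model$log$stop_reason,
           epochs = nrow(model$log$trace),
           sse0 = model$log$sse0, sse = model$log$sse))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ann
#' @export
read_ann <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sizes <- as.integer(obj$layer_sizes)
  layers <- vector("list", length(sizes) - 1L)
  for (l in seq_along(layers)) {
    H <- sizes[l + 1L]; K <- sizes[l]
    layers[[l]] <- list(W = matrix(obj$layers$W[[l]], H, K, byrow = TRUE),
                        b = obj$layers$b[[l]])
  }
  fix_scale <- function(s) if (is.null(s)) NULL else
    list(min = s$min, max = s$max, constant = as.logical(s$constant))
  structure(list(layer_sizes = sizes, layers = layers,
                 in_scale = fix_scale(obj$in_scale),
                 out_scale = fix_scale(obj$out_scale),
                 seed = obj$seed, log = obj$log),
            class = "ann_model")
}
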