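#' Echo state network configuration
#'
#' Hyperparameters of the fixed random reservoir used for feature
#' extraction. The reservoir recursion is
#' `x(n) = tanh(W_in u(n) + W_NN x(n-1))` with `x(0) = 0`; only the linear
#' readout is (ridge-)fitted, per trial, and its coefficient matrix is the
#' decoding feature.
#'
#' @param NN reservoir size (number of neurons); the subject-level search
#'   set is `{10, 20, ..., 70}`.
#' @param c sparse degree: fraction of nonzero recurrent connections,
#'   searched over `[0.1, 0.9]` in steps of 0.1.
#' @param rho spectral radius of `W_NN` after rescaling (default 0.98;
#'   `rho < 1` gives the fading-memory echo-state property).
#' @param lambda_r ridge regularization of the readout (default 1e-4).
#' @param seed integer seed freezing the random matrices.
#' @return An object of class `esn_config`.
#' @export
esn_config <- function(NN = 60, c = 0.4, rho = 0.98, lambda_r = 1e-4,
                       seed = 1) {
  stopifnot(NN >= 1, lambda_r >= 0)
  if (!(c > 0 && c <= 1)) stop("sparse degree c must lie in (0, 1]")
  if (!(rho > 0 && rho < 1)) stop("spectral radius rho must lie in (0, 1)")
  structure(list(NN = as.integer(NN), c = c, rho = rho,
                 lambda_r = lambda_r, seed = as.integer(seed)),
            class = "esn_config")
}

#' Initialize a frozen random reservoir
#'
#' Draws `W_in` (NN x C, i.i.d. uniform on `[-1, 1]`) and the sparse
#' recurrent matrix `W_NN` with exactly `round(c * NN^2)` nonzero entries
#' (positions sampled without replacement, values uniform on `[-1, 1]`),
#' then rescales `W_NN` so its spectral radius equals `rho`. Both matrices
#' are immutable thereafter; the same seed always reproduces them. A
#' degenerate draw with zero spectral radius (possible at tiny `NN * c`)
#' is redrawn with an incremented sub-seed and a message.
#'
#' @param config an [esn_config()].
#' @param C number of input channels.
#' @return An object of class `reservoir_model` with elements `W_in`,
#'   `W_NN`, `config`, `C`.
#' @export
init_reservoir <- function(config, C) {
  stopifnot(C >= 1)
  NN <- config$NN
  for (attempt in 0:10) {
    draw <- withr::with_seed(config$seed + attempt, {
      W_in <- matrix(stats::runif(NN * C, -1, 1), NN, C)
      k <- max(1L, round(config$c * NN^2))
      pos <- sample.int(NN^2, k)
      W <- matrix(0, NN, NN)
      W[pos] <- stats::runif(k, -1, 1)
      list(W_in = W_in, W = W)
    })
    sr <- max(abs(eigen(draw$W, only.values = TRUE)$values))
    if (sr > 0) break
    message("degenerate reservoir draw (spectral radius 0); redrawing ",
            "with sub-seed ", config$seed + attempt + 1)
  }
  if (sr == 0) stop("could not draw a reservoir with nonzero spectral radius")
  structure(list(W_in = draw$W_in, W_NN = draw$W * (config$rho / sr),
                 config = config, C = as.integer(C)),
            class = "reservoir_model")
}

#' @export
print.reservoir_model <- function(x, ...) {
  cat(sprintf("<reservoir_model> NN=%d C=%d c=%.2f rho=%.3f seed=%d\n",
              x$config$NN, x$C, x$config$c, x$config$rho, x$config$seed))
  invisible(x)
}

#' Run the reservoir over an epoch
#'
#' Iterates `x(n) = tanh(W_in u(n) + W_NN x(n-1))` from `x0` (zero by
#' default) over the columns of `u`.
#'
#' @param model a [init_reservoir()] model.
#' @param u C x T numeric matrix (one epoch, channels x time).
#' @param x0 initial state (default zero vector).
#' @return NN x T state matrix; all entries in `(-1, 1)`.
#' @export
run_reservoir <- function(model, u, x0 = NULL) {
  if (!is.matrix(u) || nrow(u) != model$C)
    stop("u must be a matrix with ", model$C, " rows (channels)")
  if (!all(is.finite(u))) stop("non-finite values in reservoir input")
  if (is.null(x0)) x0 <- numeric(model$config$NN)
  .reservoir_states(model$W_in, model$W_NN, u, x0)
}

#' Ridge readout of one-step-ahead prediction weights
#'
#' Fits the linear readout mapping the stacked regressor
#' `[x(n); u(n); 1]` to the next input sample `u(n+1)` over
#' `n = 1 .. T-1`, in closed form:
#' `W_out = Y X' (X X' + lambda_r I)^-1`. The flattened `W_out` is the
#' per-trial feature; its length is `C * (NN + C + 1)`.
#'
#' @param states NN x T state matrix from [run_reservoir()].
#' @param u C x T input epoch.
#' @param lambda_r ridge coefficient (>= 0; 0 requires a nonsingular
#'   Gram matrix).
#' @return C x (NN + C + 1) readout matrix.
#' @export
fit_readout <- function(states, u, lambda_r = 1e-4) {
  T_len <- ncol(u)
  if (T_len < 2) stop("need at least 2 time points to fit the readout")
  idx <- seq_len(T_len - 1)
  X <- rbind(states[, idx, drop = FALSE], u[, idx, drop = FALSE],
             rep(1, T_len - 1))
  Y <- u[, idx + 1, drop = FALSE]
  G <- tcrossprod(X) + lambda_r * diag(nrow(X))
  W <- tryCatch(t(solve(G, tcrossprod(X, Y))),
                error = function(e)
                  stop("singular readout system: ", conditionMessage(e),
                       if (lambda_r == 0) " (use lambda_r > 0)" else "",
                       call. = FALSE))
  W
}

#' Feature dimension of the flattened readout
#'
#' The readout regresses C output channels on NN reservoir states, C input
#' channels and one bias, so the flattened feature has length
#' `C * (NN + C + 1)`.
#'
#' @param C channel count.
#' @param NN reservoir size.
#' @return Integer feature dimension.
#' @export
feature_dimension <- function(C, NN) {
  stopifnot(C >= 1, NN >= 1)
  as.integer(C * (NN + C + 1))
}

#' Extract per-trial readout features
#'
#' Runs the same frozen reservoir over every trial of a (z-scored) epoch
#' set and fits one ridge readout per trial; each flattened readout matrix
#' is one feature row.
#'
#' @param epochs an `eeg_epochs` (should be z-scored; feature values are
#'   otherwise dominated by amplitude scale).
#' @param model a [init_reservoir()] whose `C` matches the epoch channels.
#' @return trials x `feature_dimension(C, NN)` matrix with the labels as
#'   attribute `"labels"` and the configuration as attribute `"config"`.
#' @export
extract_features <- function(epochs, model) {
  d <- dim(epochs$data)
  if (d[2] != model$C)
    stop("epoch channel count (", d[2], ") does not match reservoir C (",
         model$C, ")")
  num_f <- feature_dimension(model$C, model$config$NN)
  out <- matrix(0, nrow = d[1], ncol = num_f)
  for (tr in seq_len(d[1])) {
    u <- matrix(epochs$data[tr, , ], nrow = d[2])
    st <- run_reservoir(model, u)
    out[tr, ] <- as.vector(fit_readout(st, u, model$config$lambda_r))
  }
  attr(out, "labels") <- epochs$labels
  attr(out, "config") <- model$config
  out
}
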