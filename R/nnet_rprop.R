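## Feed-forward network (1 hidden layer, hyperbolic tangent in both layers)
## trained with resilient propagation (Rprop).  The output unit is tanh,
## affinely rescaled by (t + 1) / 2 so that scores land in [0, 1]; targets
## are encoded as -1 / +1 and the loss is mean squared error.
##
## Rprop step-size hyperparameters are the canonical Riedmiller-Braun
## defaults: eta+ = 1.2, eta- = 0.5, Delta0 = 0.1, Deltamax = 50,
## Deltamin = 1e-6 (the sign-based variant without weight backtracking).

RPROP_ETA_PLUS <- 1.2
RPROP_ETA_MINUS <- 0.5
RPROP_DELTA0 <- 0.1
RPROP_DELTA_MAX <- 50
RPROP_DELTA_MIN <- 1e-6

nnet_init <- function(d, hidden) {
  list(W1 = matrix(stats::runif(d * hidden, -0.5, 0.5), d, hidden),
       b1 = stats::runif(hidden, -0.5, 0.5),
       W2 = matrix(stats::runif(hidden, -0.5, 0.5), hidden, 1),
       b2 = stats::runif(1, -0.5, 0.5))
}

nnet_forward <- function(net, X) {
  A1 <- tanh(sweep(X %*% net$W1, 2, net$b1, "+"))
  a2 <- tanh(drop(A1 %*% net$W2) + net$b2)
  list(A1 = A1, a2 = a2)
}

nnet_gradient <- function(net, X, t) {
  fw <- nnet_forward(net, X)
  n <- nrow(X)
  dz2 <- ((fw$a2 - t) / n) * (1 - fw$a2^2)
  dA1 <- tcrossprod(dz2, drop(net$W2))
  dZ1 <- dA1 * (1 - fw$A1^2)
  list(W1 = crossprod(X, dZ1),
       b1 = colSums(dZ1),
       W2 = crossprod(fw$A1, matrix(dz2, ncol = 1)),
       b2 = sum(dz2))
}

nnet_mse <- function(net, X, t) {
  mean((nnet_forward(net, X)$a2 - t)^2)
}

#' Train a tanh feed-forward network with resilient propagation
#'
#' Full-batch Rprop on mean squared error with -1/+1 targets.  Training
#' stops when the epoch of minimum validation error has been identified
#' and either `max_epochs` epochs have completed or `max_val_checks`
#' consecutive epochs have failed to improve the validation error (one
#' failed epoch = one validation check).  The returned network carries the
#' weights from the epoch of minimum validation error.
#'
#' @param X_train,y_train Training design matrix and 0/1 labels.
#' @param X_val,y_val Validation set used only for the stopping rule; when
#'   `NULL`, training error is used.
#' @param hidden Hidden units (default 4).
#' @param max_epochs Epoch cap (default 1000).
#' @param max_val_checks Cap on consecutive non-improving epochs (default
#'   500).
#' @return An `rprop_net` with weights, `best_epoch` and error traces.
#' @export
rprop_train <- function(X_train, y_train, X_val = NULL, y_val = NULL,
                        hidden = 4L, max_epochs = 1000L,
                        max_val_checks = 500L) {
  stopifnot(nrow(X_train) == length(y_train))
  t_train <- 2 * y_train - 1
  t_val <- if (!is.null(X_val)) 2 * y_val - 1 else t_train
  Xv <- if (!is.null(X_val)) X_val else X_train

  net <- nnet_init(ncol(X_train), hidden)
  delta <- lapply(net, function(p) array(RPROP_DELTA0, dim = dim(as.matrix(p))))
  prev_sign <- lapply(net, function(p) array(0, dim = dim(as.matrix(p))))

  best <- net
  best_err <- Inf
  best_epoch <- 0L
  checks <- 0L
  trace <- numeric(0)

  for (epoch in seq_len(max_epochs)) {
    g <- nnet_gradient(net, X_train, t_train)
    for (k in names(net)) {
      gk <- as.matrix(g[[k]])
      sg <- sign(gk)
      same <- prev_sign[[k]] * sg
      delta[[k]][same > 0] <- pmin(delta[[k]][same > 0] * RPROP_ETA_PLUS,
                                   RPROP_DELTA_MAX)
      delta[[k]][same < 0] <- pmax(delta[[k]][same < 0] * RPROP_ETA_MINUS,
                                   RPROP_DELTA_MIN)
      sg[same < 0] <- 0  # iRprop-: skip the step after a sign change
      step <- -sg * delta[[k]]
      if (is.matrix(net[[k]])) {
        net[[k]] <- net[[k]] + step
      } else {
        net[[k]] <- net[[k]] + drop(step)
      }
      prev_sign[[k]] <- sg
    }
    err <- nnet_mse(net, Xv, t_val)
    trace <- c(trace, err)
    if (err < best_err) {
      best_err <- err
      best <- net
      best_epoch <- epoch
      checks <- 0L
    } else {
      checks <- checks + 1L
      if (checks >= max_val_checks) break
    }
  }
  structure(list(W1 = best$W1, b1 = best$b1, W2 = best$W2, b2 = best$b2,
                 hidden = hidden, best_epoch = best_epoch,
                 val_error = best_err, trace = trace),
            class = "rprop_net")
}

#' Score inputs with a trained network
#' @param net An `rprop_net`.
#' @param X Design matrix with the training column layout.
#' @return Scores in \[0, 1\] (tanh output rescaled by `(t + 1) / 2`).
#' @export
rprop_predict <- function(net, X) {
  (nnet_forward(net, X)$a2 + 1) / 2
}
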