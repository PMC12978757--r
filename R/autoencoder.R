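# Small fully-connected autoencoder: input -> hidden (tanh) -> latent
# (linear) -> hidden (tanh) -> input (linear). Deliberately minimal: the
# datasets this package targets have at most a few hundred samples, so a
# single hidden layer trained by plain gradient descent is stable and keeps
# the training loop auditable.

#' Initialize an autoencoder model
#'
#' @param input_dim Number of input features.
#' @param hidden_dim Hidden layer width (encoder and mirrored decoder).
#' @param latent_dim Latent code dimension.
#' @param seed Integer seed for Glorot-uniform weight initialization.
#' @return Object of class `autoencoder` holding weight matrices `W1..W4`
#'   and bias vectors `b1..b4`.
#' @export
init_autoencoder <- function(input_dim, hidden_dim = 64L, latent_dim = 10L,
                             seed = 1L) {
  rng <- local_rng(seed)
  glorot <- function(nin, nout) {
    lim <- sqrt(6 / (nin + nout))
    matrix(rng$runif(nin * nout, -lim, lim), nin, nout)
  }
  structure(list(
    W1 = glorot(input_dim, hidden_dim), b1 = numeric(hidden_dim),
    W2 = glorot(hidden_dim, latent_dim), b2 = numeric(latent_dim),
    W3 = glorot(latent_dim, hidden_dim), b3 = numeric(hidden_dim),
    W4 = glorot(hidden_dim, input_dim), b4 = numeric(input_dim),
    input_dim = as.integer(input_dim), hidden_dim = as.integer(hidden_dim),
    latent_dim = as.integer(latent_dim)), class = "autoencoder")
}

# Full forward pass; returns intermediate activations for backprop.
ae_forward <- function(model, X) {
  A1 <- tanh(sweep(X %*% model$W1, 2, model$b1, "+"))
  Z  <- sweep(A1 %*% model$W2, 2, model$b2, "+")
  A2 <- tanh(sweep(Z %*% model$W3, 2, model$b3, "+"))
  Xh <- sweep(A2 %*% model$W4, 2, model$b4, "+")
  list(A1 = A1, Z = Z, A2 = A2, Xh = Xh)
}

#' Encode samples into the latent space
#'
#' @param model An `autoencoder`.
#' @param X Numeric matrix with `input_dim` columns.
#' @return Latent code matrix (rows = samples).
#' @export
encode <- function(model, X) {
  A1 <- tanh(sweep(X %*% model$W1, 2, model$b1, "+"))
  sweep(A1 %*% model$W2, 2, model$b2, "+")
}

#' Autoencoder reconstruction loss
#'
#' Mean squared reconstruction error over the batch plus an L2 weight-decay
#' penalty on the weight matrices (biases excluded):
#' \deqn{L = \frac{1}{b}\sum_x \|R(x) - x\|^2 + \gamma \sum W^2.}
#'
#' @param model An `autoencoder`.
#' @param X Numeric matrix, one sample per row.
#' @param weight_decay Non-negative decay coefficient \eqn{\gamma}.
#' @return Scalar loss, >= 0.
#' @export
reconstruction_loss <- function(model, X, weight_decay = 0) {
  X <- as.matrix(X)
  if (ncol(X) != model$input_dim) {
    stop("dimension mismatch: ", ncol(X), " columns vs input_dim ",
         model$input_dim)
  }
  f <- ae_forward(model, X)
  mean_sq <- sum((f$Xh - X)^2) / nrow(X)
  pen <- sum(model$W1^2) + sum(model$W2^2) + sum(model$W3^2) + sum(model$W4^2)
  mean_sq + weight_decay * pen
}

# Backpropagation. grad_z_extra (b x latent or NULL) is an additive gradient
# on the latent codes coming from losses defined on Z (KL/affinity terms).
# Returns gradients for all weights/biases of the combined objective
# (1/b)*sum||Xh - X||^2 + weight_decay*sum(W^2) + <extra terms via grad_z>.
ae_gradients <- function(model, X, fw, weight_decay = 0, grad_z_extra = NULL) {
  b <- nrow(X)
  d_Xh <- 2 * (fw$Xh - X) / b
  gW4 <- crossprod(fw$A2, d_Xh) + 2 * weight_decay * model$W4
  gb4 <- colSums(d_Xh)
  d_A2 <- d_Xh %*% t(model$W4)
  d_S2 <- d_A2 * (1 - fw$A2^2)            # tanh'
  gW3 <- crossprod(fw$Z, d_S2) + 2 * weight_decay * model$W3
  gb3 <- colSums(d_S2)
  d_Z <- d_S2 %*% t(model$W3)
  if (!is.null(grad_z_extra)) d_Z <- d_Z + grad_z_extra
  gW2 <- crossprod(fw$A1, d_Z) + 2 * weight_decay * model$W2
  gb2 <- colSums(d_Z)
  d_A1 <- d_Z %*% t(model$W2)
  d_S1 <- d_A1 * (1 - fw$A1^2)
  gW1 <- crossprod(X, d_S1) + 2 * weight_decay * model$W1
  gb1 <- colSums(d_S1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
       W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4)
}

ae_step <- function(model, grads, lr) {
  for (nm in c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")) {
    model[[nm]] <- model[[nm]] - lr * grads[[nm]]
  }
  model
}
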