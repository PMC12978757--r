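# Independent brute-force oracles: scalar loops, no shared code with the
# package implementation beyond the guard definitions they must mirror.

oracle_minmax <- function(train, X) {
  out <- X
  for (j in seq_len(ncol(X))) {
    mn <- min(train[, j]); mx <- max(train[, j])
    for (i in seq_len(nrow(X))) {
      out[i, j] <- if (mx > mn) (X[i, j] - mn) / (mx - mn) else 0
      out[i, j] <- min(max(out[i, j], 0), 1)
    }
  }
  out
}

# Fuzzy membership: penalized squared distances with the elementwise
# D = max(d2 - pen, d2/2) guard, scalar loops.
oracle_membership <- function(Z, B, fuz, mu) {
  b <- nrow(Z); C <- nrow(B)
  U <- matrix(0, b, C)
  bbar <- colMeans(B)
  gy <- sapply(seq_len(C), function(y) sum((B[y, ] - bbar)^2))
  pen <- if (mu > 0) mu * sum(gy) / pmax(gy, 1e-12) else rep(0, C)
  for (x in seq_len(b)) {
    d2 <- sapply(seq_len(C), function(y) sum((Z[x, ] - B[y, ])^2))
    if (any(d2 <= .Machine$double.eps * 100)) {
      U[x, which(d2 <= .Machine$double.eps * 100)[1]] <- 1
      next
    }
    D <- if (mu > 0) pmax(pmax(d2 - pen, 0.5 * d2), 1e-12) else pmax(d2, 1e-12)
    w <- D^(-1 / (fuz - 1))
    U[x, ] <- w / sum(w)
  }
  U
}

oracle_target <- function(U) {
  colsum <- colSums(U)
  W <- matrix(0, nrow(U), ncol(U))
  for (x in seq_len(nrow(U))) for (y in seq_len(ncol(U))) {
    W[x, y] <- if (colsum[y] > 0) U[x, y]^2 / colsum[y] else 0
  }
  W / rowSums(W)
}

oracle_kl <- function(T_, U) {
  s <- 0
  for (x in seq_len(nrow(T_))) for (y in seq_len(ncol(T_))) {
    if (T_[x, y] > 0) s <- s + T_[x, y] * log(T_[x, y] / max(U[x, y], 1e-12))
  }
  s
}

oracle_kernel <- function(a, b, alpha, sigma) {
  r <- sqrt(sum((a - b)^2))
  alpha * exp(-r^2 / (2 * sigma^2)) + (1 - alpha) * exp(-r / sigma)
}

oracle_affinity <- function(Z, labels, alpha, sigma, delta) {
  b <- nrow(Z)
  A <- matrix(0, b, b)
  for (x in seq_len(b)) for (u in seq_len(b)) {
    if (labels[x] == labels[u]) {
      A[x, u] <- oracle_kernel(Z[x, ], Z[u, ], alpha, sigma)^delta
    }
  }
  diag(A) <- 1
  A
}

oracle_fisher <- function(X, y) {
  y <- factor(y); d <- ncol(X)
  s <- numeric(d)
  for (a in seq_len(d)) {
    mu_a <- mean(X[, a])
    num <- 0; den <- 0
    for (cl in levels(y)) {
      xi <- X[y == cl, a]; nd <- length(xi)
      num <- num + nd * (mean(xi) - mu_a)^2
      den <- den + nd * mean((xi - mean(xi))^2)   # population variance
    }
    s[a] <- if (den > 0) num / den else 0
  }
  s
}

oracle_mfisher <- function(X, y) {
  y <- factor(y); d <- ncol(X); n <- nrow(X)
  mu0 <- mean(X)
  ms <- numeric(d)
  for (a in seq_len(d)) {
    se <- sd(X[, a]) / sqrt(n)
    if (se == 0) { ms[a] <- 0; next }
    phi <- (mean(X[, a]) - mu0) / se
    num <- 0; den <- 0
    for (cl in levels(y)) {
      xi <- X[y == cl, a]; nd <- length(xi)
      num <- num + nd * (mean(xi) - phi)^2
      den <- den + nd * se
    }
    ms[a] <- if (den > 0) num / den else 0
  }
  ms
}

oracle_wminkowski <- function(a, b, W, rho) {
  s <- 0
  for (i in seq_along(a)) s <- s + W[i] * abs(a[i] - b[i])^rho
  s^(1 / rho)
}

# Classical Euclidean KNN neighbour set (indices of k nearest, ties by
# lower training index).
oracle_knn_neighbors <- function(train, query, k) {
  d <- apply(train, 1, function(r) sqrt(sum((r - query)^2)))
  order(d, seq_len(nrow(train)))[seq_len(k)]
}

oracle_counts <- function(y_true, y_pred, pos) {
  tp <- 0; fp <- 0; tn <- 0; fn <- 0
  for (i in seq_along(y_true)) {
    if (y_true[i] == pos && y_pred[i] == pos) tp <- tp + 1
    if (y_true[i] != pos && y_pred[i] == pos) fp <- fp + 1
    if (y_true[i] != pos && y_pred[i] != pos) tn <- tn + 1
    if (y_true[i] == pos && y_pred[i] != pos) fn <- fn + 1
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# AUC as pairwise concordance probability with ties counted 1/2.
oracle_auc <- function(y_true, scores, pos) {
  p <- which(y_true == pos); n <- which(y_true != pos)
  tot <- 0
  for (i in p) for (j in n) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(p) * length(n))
}

# Random row-stochastic matrix (rows sum to 1).
random_simplex_rows <- function(b, C) {
  M <- matrix(runif(b * C, 0.05, 1), b, C)
  M / rowSums(M)
}
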