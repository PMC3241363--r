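# Independent oracles used to cross-check the package's own implementations.
# These are deliberately written from the textbook definitions and share no
# code with the package.

# one-component PLS1 by NIPALS (single y): w = X'y (normalised), t = Xw,
# p = X't/t't, c = t'y/t't
pls1_oracle <- function(X, y) {
  yc <- y - mean(y)
  w <- drop(crossprod(X, yc))
  w <- w / sqrt(sum(w^2))
  t <- drop(X %*% w)
  p <- drop(crossprod(X, t)) / sum(t^2)
  c <- sum(t * yc) / sum(t^2)
  list(w = w, t = t, p = p, c = c)
}

# pooled-variance two-sample t statistic and two-sided p from the closed form
ttest_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), df = na + nb - 2))
}

# random centred + scaled instance with some y-correlated and some orthogonal
# structure, for exercising the OPLS fit
rand_instance <- function(n = 30, K = 50, seed = 1) {
  set.seed(seed)
  y <- rep(c(1, -1), length.out = n)
  z <- rnorm(n)
  z <- z - mean(z) - y * sum(z * y) / sum(y * y)  # exactly y-orthogonal
  X <- outer(y, rnorm(K, 0, 0.4)) + outer(z, rnorm(K)) +
    matrix(rnorm(n * K), n, K)
  colnames(X) <- sprintf("V%03d", seq_len(K))
  Xs <- scale(X)
  attr(Xs, "scaled:center") <- NULL
  attr(Xs, "scaled:scale") <- NULL
  list(Xs = Xs, y = y)
}
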