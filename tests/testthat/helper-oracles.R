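# Dense generalized-least-squares / BLUP oracle and toy instances used to
# validate the mixed-model-equation solves on small instances.

gls_blup_oracle <- function(X, W, P, R, y) {
  V <- W %*% P %*% t(W) + diag(R)
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  a <- P %*% t(W) %*% Vi %*% (y - X %*% b)
  list(b = drop(b), a = drop(a))
}

make_multitrait_toy <- function(n = 20, m = 30, seed = 42, var_scale = 1) {
  set.seed(seed)
  geno <- matrix(2L * rbinom(n * m, 1, 0.5), n, m)
  ids <- seq_len(n)
  rec <- rbind(
    data.frame(y = rnorm(n), year = 1, stage = "PYT", id = ids,
               var_e = 2 * var_scale),
    data.frame(y = rnorm(12), year = 2, stage = "GIA1", id = ids[1:12],
               var_e = 1.5 * var_scale),
    data.frame(y = rnorm(8), year = 2, stage = "GIA2", id = ids[3:10],
               var_e = 0.8 * var_scale))
  list(geno = geno, ids = ids, rec = rec)
}

multitrait_oracle_parts <- function(toy, G) {
  geno <- toy$geno; rec <- toy$rec; ids <- toy$ids
  m <- ncol(geno)
  Z <- sweep(geno, 2, colMeans(geno))
  p <- colMeans(geno) / 2
  cs <- sum(2 * p * (1 - p))
  Gm <- G / cs
  ri <- match(rec$id, ids)
  is_m <- rec$stage == "PYT"
  W <- matrix(0, nrow(rec), 2 * m)
  W[is_m, 1:m] <- Z[ri[is_m], ]
  W[!is_m, m + 1:m] <- 0.5 * Z[ri[!is_m], ]
  X <- stats::model.matrix(~ 0 + factor(paste(rec$year, rec$stage, sep = ":")))
  P <- rbind(cbind(Gm[1, 1] * diag(m), Gm[1, 2] * diag(m)),
             cbind(Gm[2, 1] * diag(m), Gm[2, 2] * diag(m)))
  list(X = X, W = W, P = P, R = rec$var_e, y = rec$y, m = m)
}
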