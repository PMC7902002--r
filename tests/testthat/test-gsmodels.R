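test_that("multivariate RR-BLUP matches the dense GLS/BLUP oracle", {
  toy <- make_multitrait_toy()
  G <- matrix(c(1, 0.6, 0.6, 1), 2)
  fit <- fit_multitrait_rrblup(training_set(toy$geno, toy$ids, toy$rec), G)
  o <- multitrait_oracle_parts(toy, G)
  sol <- gls_blup_oracle(o$X, o$W, o$P, o$R, o$y)
  expect_equal(unname(fit$b), unname(sol$b), tolerance = 1e-8)
  expect_equal(unname(c(fit$a[, "m"], fit$a[, "ic"])), unname(sol$a),
               tolerance = 1e-8)
})

test_that("with zero genetic covariance a_ic reduces to an intercrop-only ridge fit", {
  toy <- make_multitrait_toy(seed = 7)
  G <- diag(c(1.2, 0.8))
  fit <- fit_multitrait_rrblup(training_set(toy$geno, toy$ids, toy$rec), G)
  # single-trait ridge oracle on the intercrop records alone
  ic <- toy$rec[toy$rec$stage != "PYT", ]
  Z <- sweep(toy$geno, 2, colMeans(toy$geno))
  p <- colMeans(toy$geno) / 2
  lam <- 1 / (0.8 / sum(2 * p * (1 - p)))
  Wic <- 0.5 * Z[match(ic$id, toy$ids), ]
  X <- stats::model.matrix(~ 0 + factor(paste(ic$year, ic$stage, sep = ":")))
  A <- cbind(X, Wic) * sqrt(1 / ic$var_e)
  C <- crossprod(A)
  pp <- ncol(X)
  diag(C)[pp + seq_len(ncol(Z))] <- diag(C)[pp + seq_len(ncol(Z))] + lam
  sol <- solve(C, crossprod(A, ic$y * sqrt(1 / ic$var_e)))
  expect_equal(unname(fit$a[, "ic"]), unname(sol[pp + seq_len(ncol(Z)), 1]),
               tolerance = 1e-8)
})

test_that("the zero-residual limit interpolates the training phenotypes", {
  set.seed(9)
  n <- 12; m <- 5
  geno <- matrix(2L * rbinom(n * m, 1, 0.5), n, m)
  a_true <- rnorm(m)
  Z0 <- sweep(geno, 2, colMeans(geno))
  rec <- data.frame(y = 0.3 + drop(0.5 * Z0 %*% a_true), year = 1,
                    stage = "GIA1", id = seq_len(n), var_e = 1e-9)
  G <- diag(c(1, 1))
  fit <- fit_multitrait_rrblup(training_set(geno, seq_len(n), rec), G)
  Z <- sweep(geno, 2, fit$center)
  yhat <- fit$b[["1:GIA1"]] + drop(0.5 * Z %*% fit$a[, "ic"])
  expect_equal(yhat, rec$y, tolerance = 1e-4)
})

test_that("increasing residual variance shrinks the marker effects", {
  G <- matrix(c(1, 0.5, 0.5, 1), 2)
  toy1 <- make_multitrait_toy(seed = 11, var_scale = 1)
  toy2 <- toy1
  toy2$rec$var_e <- toy2$rec$var_e * 4
  f1 <- fit_multitrait_rrblup(training_set(toy1$geno, toy1$ids, toy1$rec), G)
  f2 <- fit_multitrait_rrblup(training_set(toy2$geno, toy2$ids, toy2$rec), G)
  expect_lt(sum(f2$a^2), sum(f1$a^2))
})

test_that("non-PSD G is rejected and window span is enforced", {
  toy <- make_multitrait_toy(seed = 13)
  Gbad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(fit_multitrait_rrblup(training_set(toy$geno, toy$ids, toy$rec),
                                     Gbad), "positive semi-definite")
  rec_wide <- toy$rec
  rec_wide$year[1] <- 7
  expect_error(training_set(toy$geno, toy$ids, rec_wide), "5 years")
  rec_alien <- toy$rec
  rec_alien$id[1] <- 999L
  expect_error(training_set(toy$geno, toy$ids, rec_alien), "present")
})

test_that("true variance components follow the population definition", {
  gv <- cbind(m = c(1, 3, 5), ic = c(2, 2, 8))
  G <- true_variance_components(gv)
  expect_equal(unname(G["m", "m"]), mean((gv[, 1] - 3)^2))
  expect_equal(G["m", "ic"], G["ic", "m"])
  clones <- cbind(m = rep(1, 4), ic = rep(2, 4))
  expect_equal(unname(true_variance_components(clones)),
               matrix(0, 2, 2), tolerance = 1e-14)
  # perfect correlation: off-diagonal equals the geometric mean of variances
  gperf <- cbind(m = c(1, 2, 4), ic = 2 * c(1, 2, 4))
  Gp <- true_variance_components(gperf)
  expect_equal(unname(Gp["m", "ic"]), sqrt(Gp["m", "m"] * Gp["ic", "ic"]))
  expect_error(true_variance_components(gv[1, , drop = FALSE]), "at least 2")
})

test_that("gGIA predictions are linear in marker effects", {
  set.seed(15)
  geno <- matrix(2L * rbinom(40, 1, 0.5), 8, 5)
  fit <- structure(list(a = cbind(m = rep(0, 5), ic = rep(0, 5)),
                        center = colMeans(geno)), class = "rrblup_fit")
  expect_equal(predict_gGIA(fit, geno), rep(0, 8))
  fit$a[, "ic"] <- c(1, 0, 0, 0, 0)
  gg <- predict_gGIA(fit, geno)
  expect_equal(gg, geno[, 1] - mean(geno[, 1]))
  expect_error(predict_gGIA(fit, geno[, 1:3]), "marker set")
})

# ---- grid model ---------------------------------------------------------

make_grid_toy <- function(nA = 15, nB = 15, m = 40, n_rec = 30, seed = 20) {
  set.seed(seed)
  geno_A <- matrix(2L * rbinom(nA * m, 1, 0.5), nA, m)
  geno_B <- matrix(2L * rbinom(nB * m, 1, 0.5), nB, m)
  rec <- data.frame(y = rnorm(n_rec), year = rep(1:2, length.out = n_rec),
                    stage = sample(c("GRID", "SIA1"), n_rec, TRUE),
                    id_A = sample(seq_len(nA), n_rec, TRUE),
                    id_B = sample(seq_len(nB), n_rec, TRUE),
                    var_e = runif(n_rec, 0.5, 2))
  list(geno_A = geno_A, geno_B = geno_B, rec = rec, nA = nA, nB = nB, m = m)
}

test_that("grid RR-BLUP matches the dense joint ridge oracle", {
  toy <- make_grid_toy()
  ts <- grid_training_set(toy$geno_A, seq_len(toy$nA),
                          toy$geno_B, seq_len(toy$nB), toy$rec)
  fit <- fit_grid_rrblup(ts, 1.3, 0.9)
  ZA <- sweep(toy$geno_A, 2, colMeans(toy$geno_A))
  ZB <- sweep(toy$geno_B, 2, colMeans(toy$geno_B))
  csA <- sum(2 * (colMeans(toy$geno_A) / 2) * (1 - colMeans(toy$geno_A) / 2))
  csB <- sum(2 * (colMeans(toy$geno_B) / 2) * (1 - colMeans(toy$geno_B) / 2))
  W <- cbind(0.5 * ZA[toy$rec$id_A, ], 0.5 * ZB[toy$rec$id_B, ])
  X <- stats::model.matrix(~ 0 + factor(paste(toy$rec$year, toy$rec$stage,
                                              sep = ":")))
  P <- rbind(cbind(1.3 / csA * diag(toy$m), matrix(0, toy$m, toy$m)),
             cbind(matrix(0, toy$m, toy$m), 0.9 / csB * diag(toy$m)))
  sol <- gls_blup_oracle(X, W, P, toy$rec$var_e, toy$rec$y)
  expect_equal(unname(c(fit$a$A, fit$a$B)), unname(sol$a), tolerance = 1e-8)
})

test_that("swapping crop labels swaps the grid marker effects exactly", {
  toy <- make_grid_toy(seed = 21)
  ts <- grid_training_set(toy$geno_A, seq_len(toy$nA),
                          toy$geno_B, seq_len(toy$nB), toy$rec)
  fit <- fit_grid_rrblup(ts, 1.1, 0.7)
  rec_sw <- toy$rec
  rec_sw$id_A <- toy$rec$id_B
  rec_sw$id_B <- toy$rec$id_A
  ts_sw <- grid_training_set(toy$geno_B, seq_len(toy$nB),
                             toy$geno_A, seq_len(toy$nA), rec_sw)
  fit_sw <- fit_grid_rrblup(ts_sw, 0.7, 1.1)
  expect_equal(fit$a$A, fit_sw$a$B, tolerance = 1e-10)
  expect_equal(fit$a$B, fit_sw$a$A, tolerance = 1e-10)
})

test_that("grid fit recovers the active crop and shrinks the silent one", {
  set.seed(22)
  nA <- 120; nB <- 120; m <- 50
  geno_A <- matrix(2L * rbinom(nA * m, 1, 0.5), nA, m)
  geno_B <- matrix(2L * rbinom(nB * m, 1, 0.5), nB, m)
  aA_true <- rnorm(m)
  ZA <- sweep(geno_A, 2, colMeans(geno_A))
  iA <- sample(nA, 400, TRUE)
  iB <- sample(nB, 400, TRUE)
  rec <- data.frame(y = 0.5 * drop(ZA %*% aA_true)[iA], year = 1,
                    stage = "GRID", id_A = iA, id_B = iB, var_e = 1e-4)
  ts <- grid_training_set(geno_A, seq_len(nA), geno_B, seq_len(nB), rec)
  fit <- fit_grid_rrblup(ts, var(drop(ZA %*% aA_true)), 1e-6)
  cosine <- sum(fit$a$A * aA_true) / sqrt(sum(fit$a$A^2) * sum(aA_true^2))
  expect_gt(cosine, 0.95)
  expect_lt(sqrt(sum(fit$a$B^2)), 0.1 * sqrt(sum(fit$a$A^2)))
})

test_that("ungenotyped pair members are excluded with a count", {
  toy <- make_grid_toy(seed = 23)
  rec <- toy$rec
  rec$id_A[1:2] <- 900L
  expect_message(
    ts <- grid_training_set(toy$geno_A, seq_len(toy$nA),
                            toy$geno_B, seq_len(toy$nB), rec),
    "2 record")
  expect_equal(nrow(ts$records), nrow(rec) - 2)
})

test_that("pair gGIA is the component mean and preserves the sum ranking", {
  expect_equal(grid_pair_gGIA(2, 4), 3)
  expect_equal(grid_pair_gGIA(1.7, 1.7), 1.7)
  set.seed(24)
  gA <- rnorm(10); gB <- rnorm(10)
  pg <- outer(gA, gB, grid_pair_gGIA)
  sums <- outer(gA, gB, "+")
  expect_identical(order(-as.vector(pg)), order(-as.vector(sums)))
})

test_that("the multivariate model borrows information from monocrop records", {
  # matched synthetic data, true correlation 0.9: accuracy of a_ic predictions
  # from the joint fit should not fall below the intercrop-only fit
  set.seed(25)
  m <- 40; n <- 60; n_ic <- 15; reps <- 30
  delta <- replicate(reps, {
    rho <- 0.9
    e <- matrix(rnorm(2 * m), m, 2)
    e[, 2] <- rho * e[, 1] + sqrt(1 - rho^2) * e[, 2]
    geno <- matrix(2L * rbinom(n * m, 1, 0.5), n, m)
    Z <- sweep(geno, 2, colMeans(geno))
    gv <- Z %*% e
    G <- crossprod(sweep(gv, 2, colMeans(gv))) / n
    rec_full <- rbind(
      data.frame(y = gv[, 1] + rnorm(n, 0, sqrt(2)), year = 1, stage = "PYT",
                 id = 1:n, var_e = 2),
      data.frame(y = 0.5 * gv[1:n_ic, 2] + rnorm(n_ic), year = 1,
                 stage = "GIA1", id = 1:n_ic, var_e = 1))
    new_geno <- matrix(2L * rbinom(100 * m, 1, 0.5), 100, m)
    gv_new <- sweep(new_geno, 2, colMeans(geno)) %*% e
    f_full <- fit_multitrait_rrblup(training_set(geno, 1:n, rec_full), G)
    f_ic <- fit_multitrait_rrblup(
      training_set(geno, 1:n, rec_full[rec_full$stage != "PYT", ]), G)
    cor(predict_gGIA(f_full, new_geno), gv_new[, 2]) -
      cor(predict_gGIA(f_ic, new_geno), gv_new[, 2])
  })
  expect_gt(mean(delta), 0)
})
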