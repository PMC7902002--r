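# Ridge-regression (RR-BLUP) genomic prediction: the multivariate
# monocrop/intercrop model used by the Conventional programs and the
# two-crop model used by the Grid program. Both are solved exactly through
# the mixed-model equations (direct dense solve; no iterative thresholds).

#' Training set for the multivariate RR-BLUP model
#'
#' Bundles the SNP dosages of the training genotypes of one crop with their
#' stage-tagged phenotypic records. Records reference genotypes by id;
#' `stage` is `"PYT"` (monocrop yield stream) or `"GIA1"`/`"GIA2"` (intercrop
#' yield streams, candidate-level means over probe varieties); `var_e` is the
#' record-level residual variance, i.e. the stage error variance divided by
#' its effective number of replications.
#'
#' @param geno `n x m` SNP dosage matrix (0/2 for DH lines).
#' @param ids Genotype ids, one per row of `geno`.
#' @param records Data frame with columns `y`, `year`, `stage`, `id`, `var_e`.
#' @return An object of class `training_set`.
#' @export
training_set <- function(geno, ids, records) {
  stopifnot(nrow(geno) == length(ids))
  if (nrow(records) > 0) {
    if (!all(records$id %in% ids))
      stop("every record's genotype must be present in the genotype block")
    span <- diff(range(records$year))
    if (span > 4) stop("training window exceeds 5 years (span ", span + 1, ")")
  }
  structure(list(geno = geno, ids = as.integer(ids), records = records),
            class = "training_set")
}

#' Training set for the Grid RR-BLUP model
#'
#' As [training_set()], but every record references one genotype from each
#' crop (`id_A`, `id_B`) and the stages are `"GRID"`, `"SIA1"`, `"SIA2"`.
#' Records whose pair members are not genotyped are excluded with a message.
#'
#' @param geno_A,geno_B SNP dosage matrices for the two crops.
#' @param ids_A,ids_B Genotype ids per row.
#' @param records Data frame with columns `y`, `year`, `stage`, `id_A`,
#'   `id_B`, `var_e`.
#' @return An object of class `grid_training_set`.
#' @export
grid_training_set <- function(geno_A, ids_A, geno_B, ids_B, records) {
  stopifnot(nrow(geno_A) == length(ids_A), nrow(geno_B) == length(ids_B))
  if (nrow(records) > 0) {
    ok <- records$id_A %in% ids_A & records$id_B %in% ids_B
    if (any(!ok)) {
      message(sum(!ok), " record(s) with ungenotyped pair members excluded")
      records <- records[ok, , drop = FALSE]
    }
    span <- diff(range(records$year))
    if (span > 4) stop("training window exceeds 5 years (span ", span + 1, ")")
  }
  structure(list(geno_A = geno_A, ids_A = as.integer(ids_A),
                 geno_B = geno_B, ids_B = as.integer(ids_B),
                 records = records),
            class = "grid_training_set")
}

#' True additive (co)variance components of a population
#'
#' Returns the 2 x 2 additive genetic (co)variance matrix of the true
#' monocrop and intercrop genetic values of a reference population
#' (population covariance, divide by n). In the simulation the variance
#' components supplied to the genomic models are computed each year from the
#' true genetic values rather than estimated, mirroring the study's
#' assumption of known variances.
#'
#' @param gv `N x 2` matrix of true genetic values (columns `m`, `ic`).
#' @return A symmetric 2 x 2 matrix with dimnames `c("m", "ic")`.
#' @export
true_variance_components <- function(gv) {
  if (nrow(gv) < 2) stop("reference population must contain at least 2 genotypes")
  cm <- sweep(gv, 2L, colMeans(gv))
  G <- crossprod(cm) / nrow(gv)
  dimnames(G) <- list(c("m", "ic"), c("m", "ic"))
  G
}

# marker-scaling constant: sum_k 2 p_k q_k in the training genotypes
.marker_scale <- function(geno) {
  p <- colMeans(geno) / 2
  s <- sum(2 * p * (1 - p))
  if (s <= 0) stop("training genotypes are monomorphic at all markers")
  s
}

# invert a small (co)variance matrix, jittering the diagonal if it is
# numerically singular (e.g. perfectly correlated traits late in a program)
.safe_inverse <- function(G) {
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("G must be positive semi-definite")
  if (min(ev) < 1e-10 * max(abs(ev)))
    G <- G + diag(1e-8 * mean(diag(G)) + 1e-12, nrow(G))
  solve(G)
}

# fixed-effect design: one indicator column per (year x stage) combination
.ys_design <- function(records) {
  ys <- factor(paste(records$year, records$stage, sep = ":"))
  X <- matrix(0, nrow(records), nlevels(ys))
  X[cbind(seq_len(nrow(records)), as.integer(ys))] <- 1
  colnames(X) <- levels(ys)
  X
}

# solve the (possibly near-singular) MME system
.solve_mme <- function(C, rhs) {
  sol <- tryCatch(solve(C, rhs), error = function(e) NULL)
  if (is.null(sol)) {
    warning("mixed-model equations are singular; using a pseudo-inverse ",
            "(confounded fixed-effect levels dropped to an estimable set)")
    sol <- MASS::ginv(C) %*% rhs
  }
  sol
}

#' Fit the multivariate RR-BLUP model of one crop
#'
#' Fits, by an exact direct solve of the mixed-model equations, the
#' two-trait ridge-regression model in which monocrop yield records (PYT
#' stage) and intercrop yield records (GIA1 and GIA2 stages) are analysed
#' jointly: fixed effects of year-by-stage per stream, correlated marker
#' effects `(a_m, a_ic)` per SNP with per-marker prior (co)variance
#' `G / sum(2 p q)`, and heterogeneous residual variances `sigma2e / r`
#' taken from each record's `var_e`. Because a GIA record is a
#' candidate-plus-probe pair mean, its design row loads the candidate's
#' centered dosages with coefficient 1/2, keeping `a_ic` on the
#' genetic-value scale.
#'
#' @param ts A [training_set()].
#' @param G 2 x 2 additive (co)variance matrix from
#'   [true_variance_components()].
#' @return An object of class `rrblup_fit` with marker effects `a`
#'   (`m x 2`, columns `m`, `ic`), fixed effects `b`, the marker centering
#'   vector and scaling constant.
#' @export
fit_multitrait_rrblup <- function(ts, G) {
  stopifnot(inherits(ts, "training_set"))
  rec <- ts$records
  if (nrow(rec) < 1) stop("training set has no records")
  m <- ncol(ts$geno)
  if (m < 1) stop("training set has no markers")
  ctr <- colMeans(ts$geno)
  Z <- sweep(ts$geno, 2L, ctr)
  cs <- .marker_scale(ts$geno)
  Kinv <- .safe_inverse(G / cs)

  X <- .ys_design(rec)
  p <- ncol(X)
  row_of <- match(rec$id, ts$ids)
  is_m <- rec$stage == "PYT"
  # intercrop records are candidate-plus-probe means, so they carry half of
  # the candidate's genetic value; the 1/2 lives in the design row (exactly
  # as in the Grid model) and a_ic stays on the genetic-value scale
  W <- matrix(0, nrow(rec), 2L * m)
  W[is_m, seq_len(m)] <- Z[row_of[is_m], , drop = FALSE]
  W[!is_m, m + seq_len(m)] <- 0.5 * Z[row_of[!is_m], , drop = FALSE]

  sw <- sqrt(1 / rec$var_e)
  A <- cbind(X, W) * sw
  yw <- rec$y * sw
  C <- crossprod(A)
  im <- p + seq_len(m)
  iic <- p + m + seq_len(m)
  dg <- diag(C)
  dg[im] <- dg[im] + Kinv[1L, 1L]
  dg[iic] <- dg[iic] + Kinv[2L, 2L]
  diag(C) <- dg
  if (Kinv[1L, 2L] != 0) {
    idx <- cbind(im, iic)
    C[idx] <- C[idx] + Kinv[1L, 2L]
    C[idx[, 2:1, drop = FALSE]] <- C[idx[, 2:1, drop = FALSE]] + Kinv[2L, 1L]
  }
  sol <- .solve_mme(C, crossprod(A, yw))
  a <- cbind(m = sol[im, 1L], ic = sol[iic, 1L])
  structure(list(a = a, b = stats::setNames(sol[seq_len(p), 1L], colnames(X)),
                 center = ctr, scale_const = cs, G = G),
            class = "rrblup_fit")
}

#' Genomic-predicted general intercropping ability
#'
#' gGIA of a genotype is its centered SNP dosage vector times the estimated
#' intercrop marker effects. No intercept is added: all selection steps use
#' ranks, so any constant shift is immaterial.
#'
#' @param fit An `rrblup_fit` or `grid_rrblup_fit`.
#' @param geno SNP dosage matrix of the candidates.
#' @param crop For a grid fit, which crop's marker effects to use.
#' @return Numeric vector of gGIA values, one per candidate.
#' @export
predict_gGIA <- function(fit, geno, crop = NULL) {
  if (inherits(fit, "grid_rrblup_fit")) {
    stopifnot(crop %in% c("A", "B"))
    a <- fit$a[[crop]]
    ctr <- fit$center[[crop]]
  } else {
    a <- fit$a[, "ic"]
    ctr <- fit$center
  }
  if (ncol(geno) != length(a)) stop("marker set does not match the fitted model")
  drop(sweep(geno, 2L, ctr) %*% a)
}

#' Fit the Grid RR-BLUP model for both crops jointly
#'
#' Intercrop yield records indexed by pairs (one genotype per crop) are
#' regressed on both crops' markers simultaneously: each record's design row
#' loads the two centered dosage vectors with coefficient 1/2, so the marker
#' effects `a_A`, `a_B` remain on the genetic-value scale. Fixed effects are
#' year-by-stage (GRID, SIA1, SIA2) and residual variances are the records'
#' `var_e`. Per-crop prior marker variance is
#' `var_ic_crop / sum(2 p q)_crop`.
#'
#' @param ts A [grid_training_set()].
#' @param var_ic_A,var_ic_B True intercrop additive variances of the two
#'   crops' training genotypes.
#' @return An object of class `grid_rrblup_fit` with per-crop marker effect
#'   vectors and centering.
#' @export
fit_grid_rrblup <- function(ts, var_ic_A, var_ic_B) {
  stopifnot(inherits(ts, "grid_training_set"))
  rec <- ts$records
  if (nrow(rec) < 1) stop("training set has no records")
  mA <- ncol(ts$geno_A)
  mB <- ncol(ts$geno_B)
  ctrA <- colMeans(ts$geno_A)
  ctrB <- colMeans(ts$geno_B)
  ZA <- sweep(ts$geno_A, 2L, ctrA)
  ZB <- sweep(ts$geno_B, 2L, ctrB)
  lamA <- 1 / (max(var_ic_A, 1e-12) / .marker_scale(ts$geno_A))
  lamB <- 1 / (max(var_ic_B, 1e-12) / .marker_scale(ts$geno_B))

  X <- .ys_design(rec)
  p <- ncol(X)
  iA <- match(rec$id_A, ts$ids_A)
  iB <- match(rec$id_B, ts$ids_B)
  W <- cbind(0.5 * ZA[iA, , drop = FALSE], 0.5 * ZB[iB, , drop = FALSE])
  sw <- sqrt(1 / rec$var_e)
  A <- cbind(X, W) * sw
  C <- crossprod(A)
  dg <- diag(C)
  dg[p + seq_len(mA)] <- dg[p + seq_len(mA)] + lamA
  dg[p + mA + seq_len(mB)] <- dg[p + mA + seq_len(mB)] + lamB
  diag(C) <- dg
  sol <- .solve_mme(C, crossprod(A, rec$y * sw))
  structure(list(
    a = list(A = sol[p + seq_len(mA), 1L], B = sol[p + mA + seq_len(mB), 1L]),
    b = stats::setNames(sol[seq_len(p), 1L], colnames(X)),
    center = list(A = ctrA, B = ctrB)
  ), class = "grid_rrblup_fit")
}

#' Pair-level gGIA of an intercrop combination
#'
#' The genomic-predicted general intercropping ability of a pair is the
#' arithmetic mean of the two components' gGIA values.
#'
#' @param gGIA_A,gGIA_B gGIA values (vectors are combined elementwise).
#' @return `(gGIA_A + gGIA_B) / 2`.
#' @export
grid_pair_gGIA <- function(gGIA_A, gGIA_B) {
  (gGIA_A + gGIA_B) / 2
}
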