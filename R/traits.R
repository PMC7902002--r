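# Two-trait additive architecture (monocrop yield, intercrop yield) and
# stage-specific phenotype simulation.

# population variance / covariance (divide by n); genetic variances use this
# convention throughout the package
.var_pop <- function(x) mean((x - mean(x))^2)
.cov_pop <- function(x, y) mean((x - mean(x)) * (y - mean(y)))

#' Sample a correlated two-trait QTN architecture
#'
#' For each crop independently, per-QTN additive effects for monocrop yield
#' and intercrop yield are drawn from a bivariate standard normal with the
#' target correlation and then rescaled, trait by trait, so that the additive
#' genetic variance of each trait equals 1 in that crop's founder population
#' (population variance of the founder genetic values). QTN dosages are
#' centered (DH genotypes coded -1/+1), so any affine choice of dosage coding
#' is absorbed by the scaling.
#'
#' @param founders_A,founders_B `founder_set` objects for the two crops.
#' @param target_correlation Genetic correlation between the effect draws for
#'   the two traits (the study uses 0.4, 0.7 and 0.9).
#' @param seed Optional integer seed.
#' @return An object of class `trait_arch`: per crop a QTN-effect matrix
#'   `alpha` (columns `m`, `ic`) plus the realized founder genetic correlation.
#' @export
sample_architecture <- function(founders_A, founders_B, target_correlation,
                                seed = NULL) {
  if (abs(target_correlation) > 1)
    stop("target_correlation must lie in [-1, 1]")
  if (!is.null(seed)) set.seed(seed)
  one_crop <- function(fs) {
    qtn <- fs$gm$qtn
    m <- length(qtn)
    rho <- target_correlation
    e <- matrix(stats::rnorm(2L * m), m, 2L)
    # correlate: [x, rho*x + sqrt(1-rho^2)*y]
    e[, 2L] <- rho * e[, 1L] + sqrt(1 - rho^2) * e[, 2L]
    d <- dosages(fs$pop, qtn) - 1  # centered DH coding
    g <- d %*% e
    s <- apply(g, 2L, function(x) sqrt(.var_pop(x)))
    if (any(s == 0)) stop("founder population has no genetic variance; ",
                          "cannot scale trait effects")
    alpha <- sweep(e, 2L, s, "/")
    gsc <- sweep(g, 2L, s, "/")
    list(alpha = alpha,
         realized_correlation = stats::cor(gsc[, 1L], gsc[, 2L]))
  }
  structure(list(A = one_crop(founders_A), B = one_crop(founders_B),
                 target_correlation = target_correlation,
                 founder_variance = 1),
            class = "trait_arch")
}

#' Genetic values of a population
#'
#' Sums centered QTN dosages times additive effects for both traits.
#'
#' @param pop An `icpop`.
#' @param arch A `trait_arch` from [sample_architecture()].
#' @param gm The `gmap` of the founder set (identifies QTN columns).
#' @return An `N x 2` matrix with columns `m` (monocrop) and `ic` (intercrop).
#' @export
genetic_values <- function(pop, arch, gm) {
  crop_arch <- arch[[pop$crop]]
  d <- dosages(pop, gm$qtn) - 1
  if (ncol(d) != nrow(crop_arch$alpha))
    stop("QTN dosage dimension does not match the trait architecture")
  gv <- d %*% crop_arch$alpha
  colnames(gv) <- c("m", "ic")
  gv
}

# attach genetic values to a population (cached; effects are fixed per run)
.add_gv <- function(pop, arch, gm) {
  pop$gv <- genetic_values(pop, arch, gm)
  pop
}

#' Error variance implied by a target heritability
#'
#' Inverts the entry-mean heritability definition
#' `h2 = sigma2A / (sigma2A + sigma2e / r)`, returning the unique `sigma2e`
#' satisfying it: `r * sigma2A * (1 - h2) / h2`. Per-record (entry-mean)
#' error variance is `sigma2e / r = sigma2A * (1 - h2) / h2`, returned by
#' [record_error_variance()].
#'
#' @param h2 Target narrow-sense heritability, in (0, 1].
#' @param sigma2A Additive genetic variance (1 in the founder population;
#'   stage error variances are fixed from this founder value so that realized
#'   heritability drifts as genetic variance erodes).
#' @param r Effective number of replications.
#' @return The per-plot error variance `sigma2e`.
#' @examples
#' error_variance_for_h2(0.10, 1, 1)  # 9, the DH-stage value
#' @export
error_variance_for_h2 <- function(h2, sigma2A = 1, r = 1) {
  if (!is.numeric(h2) || h2 <= 0 || h2 > 1)
    stop("h2 must lie in (0, 1]")
  if (sigma2A <= 0) stop("sigma2A must be positive")
  if (r < 1) stop("r must be >= 1")
  r * sigma2A * (1 - h2) / h2
}

#' @rdname error_variance_for_h2
#' @export
record_error_variance <- function(h2, sigma2A = 1) {
  error_variance_for_h2(h2, sigma2A, r = 1)
}

#' Simulate monocrop phenotypes
#'
#' Adds a zero-mean normal error with the given variance to the monocrop
#' genetic values.
#'
#' @param a_m Vector of monocrop genetic values.
#' @param sigma2e Error variance of the record (already divided by the
#'   effective number of replications).
#' @return Numeric vector of phenotypes.
#' @export
phenotype_monocrop <- function(a_m, sigma2e) {
  if (sigma2e < 0) stop("error variance must be non-negative")
  a_m + stats::rnorm(length(a_m), 0, sqrt(sigma2e))
}

#' Simulate intercrop phenotypes for genotype pairs
#'
#' The intercrop grain yield of a pair is the mean of the two components'
#' intercrop genetic values plus a zero-mean normal error:
#' `y = (a_ic_A + a_ic_B) / 2 + e`.
#'
#' @param a_ic_A Intercrop genetic values of the crop-A genotypes.
#' @param a_ic_B Intercrop genetic values of the paired crop-B genotypes
#'   (recycled if length 1, e.g. a single probe variety).
#' @param sigma2e Error variance of the record.
#' @return Numeric vector of intercrop phenotypes.
#' @export
phenotype_intercrop <- function(a_ic_A, a_ic_B, sigma2e) {
  if (sigma2e < 0) stop("error variance must be non-negative")
  mu <- (a_ic_A + a_ic_B) / 2
  mu + stats::rnorm(length(mu), 0, sqrt(sigma2e))
}
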