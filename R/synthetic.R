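#' Specification of a synthetic modulator-screen benchmark
#'
#' Describes the in-silico benchmarks used to validate the method: a set of
#' expression profiles split into a "co-regulated" subset — where the TF's
#' target genes are drawn from a multivariate Gaussian with off-diagonal
#' covariance `rho * sigma_ij^2` — and an "independent" subset with diagonal
#' covariance. Effective modulators are highly expressed (mean 1) exactly in
#' the co-regulated profiles and lowly expressed (mean 0) elsewhere; decoy
#' modulators are independent zero-mean noise throughout.
#'
#' Presets reproduce the published benchmark layouts:
#' \describe{
#'   \item{d1}{100 profiles (50 co-regulated), 60 genes: 10 known targets,
#'     10 hidden targets, 50 candidate modulators of which 20 effective.}
#'   \item{d2}{100 profiles (50 co-regulated), 760 genes: 10 known targets,
#'     750 candidates of which 50 effective, no hidden targets.}
#'   \item{noisy30/noisy40/noisy60/noisy70}{As d2 but with 30/40/60/70
#'     co-regulated profiles, so any equal binning mixes dependent and
#'     independent profiles ("noisy bins").}
#' }
#'
#' @param preset One of `"d1"`, `"d2"`, `"noisy30"`, `"noisy40"`,
#'   `"noisy60"`, `"noisy70"`, or `"custom"`.
#' @param n_geps Total number of expression profiles.
#' @param n_dependent_geps Number of profiles in the co-regulated subset.
#' @param n_targets Number of known TF target genes.
#' @param n_hidden_targets Candidate modulators that are secretly targets
#'   (co-regulated with the targets, but labelled as candidates).
#' @param n_potential_modulators Total candidate modulators (effective +
#'   hidden targets + decoys).
#' @param n_effective_modulators Candidates that truly modulate the TF.
#' @param rho Dependence strength of the co-regulated covariance (default 0.6).
#' @param sigma2_range Range the per-element variances are drawn from
#'   (open interval, default (0, 0.5)).
#' @param mod_mean_on,mod_mean_off Effective-modulator mean expression in the
#'   co-regulated / independent subsets (defaults 1 and 0).
#' @param mod_sd Effective-modulator standard deviation (default
#'   `sqrt(0.1)`, i.e. variance 0.1).
#' @param seed Integer seed.
#' @return An object of class `dmi_synth_spec`.
#' @export
#' @examples
#' synthetic_spec("d1", seed = 7)
synthetic_spec <- function(preset = c("d1", "d2", "noisy30", "noisy40",
                                      "noisy60", "noisy70", "custom"),
                           n_geps = 100L, n_dependent_geps = 50L,
                           n_targets = 10L, n_hidden_targets = 0L,
                           n_potential_modulators = 750L,
                           n_effective_modulators = 50L,
                           rho = 0.6, sigma2_range = c(0, 0.5),
                           mod_mean_on = 1, mod_mean_off = 0,
                           mod_sd = sqrt(0.1), seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "d1") {
    n_hidden_targets <- 10L
    n_potential_modulators <- 50L
    n_effective_modulators <- 20L
  } else if (preset %in% c("d2", "noisy30", "noisy40", "noisy60", "noisy70")) {
    n_hidden_targets <- 0L
    n_potential_modulators <- 750L
    n_effective_modulators <- 50L
    n_dependent_geps <- switch(preset, noisy30 = 30L, noisy40 = 40L,
                               noisy60 = 60L, noisy70 = 70L, 50L)
  }
  spec <- list(preset = preset, n_geps = as.integer(n_geps),
               n_dependent_geps = as.integer(n_dependent_geps),
               n_targets = as.integer(n_targets),
               n_hidden_targets = as.integer(n_hidden_targets),
               n_potential_modulators = as.integer(n_potential_modulators),
               n_effective_modulators = as.integer(n_effective_modulators),
               rho = rho, sigma2_range = sigma2_range,
               mod_mean_on = mod_mean_on, mod_mean_off = mod_mean_off,
               mod_sd = mod_sd, seed = as.integer(seed))
  n_decoy <- spec$n_potential_modulators - spec$n_effective_modulators -
    spec$n_hidden_targets
  if (n_decoy < 0L) {
    stop("effective modulators + hidden targets exceed the candidate count",
         call. = FALSE)
  }
  if (spec$n_dependent_geps > spec$n_geps || spec$n_dependent_geps < 0L) {
    stop("'n_dependent_geps' must lie in [0, n_geps]", call. = FALSE)
  }
  if (spec$n_targets < 2L) stop("need at least 2 target genes", call. = FALSE)
  spec$n_decoy_modulators <- as.integer(n_decoy)
  class(spec) <- "dmi_synth_spec"
  spec
}

#' @export
print.dmi_synth_spec <- function(x, ...) {
  cat(sprintf("Synthetic benchmark '%s': %d profiles (%d co-regulated)\n",
              x$preset, x$n_geps, x$n_dependent_geps))
  cat(sprintf("  %d targets + %d hidden targets; %d candidates (%d effective, %d decoys)\n",
              x$n_targets, x$n_hidden_targets, x$n_potential_modulators,
              x$n_effective_modulators, x$n_decoy_modulators))
  cat(sprintf("  rho = %g, sigma2 in (%g, %g), modulator N(%g|%g, sd %g), seed %d\n",
              x$rho, x$sigma2_range[1], x$sigma2_range[2], x$mod_mean_on,
              x$mod_mean_off, x$mod_sd, x$seed))
  invisible(x)
}

# Clip eigenvalues of a symmetric matrix to a small positive floor so the
# literal rho*sigma_ij^2 construction (not guaranteed PD) becomes samplable.
make_positive_definite <- function(sigma, floor = 1e-3) {
  eig <- eigen(sigma, symmetric = TRUE)
  vals <- pmax(eig$values, floor)
  out <- eig$vectors %*% (vals * t(eig$vectors))
  (out + t(out)) / 2
}

#' Generate a synthetic benchmark dataset
#'
#' Draws the expression matrix described by a [synthetic_spec()]: in the
#' co-regulated profiles, target and hidden-target genes come from a
#' zero-mean multivariate Gaussian whose off-diagonal covariance is
#' `rho * sigma_ij^2` (variances and `sigma_ij^2` drawn uniformly from
#' `sigma2_range`, eigenvalues clipped to a small positive floor so the
#' matrix is samplable); in the independent profiles the same genes are
#' independent Gaussians with freshly drawn variances. Effective-modulator
#' profiles are `N(mod_mean_on, mod_sd^2)` in co-regulated profiles and
#' `N(mod_mean_off, mod_sd^2)` otherwise; decoys are independent zero-mean
#' Gaussians throughout. Co-regulated and independent profiles are
#' interleaved at random so that binning by modulator expression, not sample
#' order, drives any separation.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Optional seed overriding `spec$seed`.
#' @return A list with elements:
#' \describe{
#'   \item{expr}{genes x samples matrix with gene/sample ids.}
#'   \item{truth}{list with `target_ids`, `hidden_target_ids`,
#'     `effective_modulator_ids`, `decoy_modulator_ids`,
#'     `modulator_ids` (all candidates) and `dependent_samples`
#'     (indices of the co-regulated profiles).}
#'   \item{sigma_dependent}{the realized (clipped) covariance of the
#'     co-regulated target block.}
#'   \item{spec}{the `dmi_synth_spec` the dataset was generated from.}
#' }
#' @export
#' @examples
#' d1 <- generate_dataset(synthetic_spec("d1", seed = 42))
#' dim(d1$expr)  # 60 x 100
generate_dataset <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "dmi_synth_spec"))
  if (is.null(seed)) seed <- spec$seed
  withr::with_seed(as.integer(seed), {
    m <- spec$n_geps
    k <- spec$n_targets + spec$n_hidden_targets
    lo <- spec$sigma2_range[1]; hi <- spec$sigma2_range[2]
    runif_open <- function(n) {
      u <- stats::runif(n, lo, hi)
      pmin(pmax(u, lo + 1e-12), hi - 1e-12)
    }

    dep_idx <- sort(sample.int(m, spec$n_dependent_geps))
    indep_idx <- setdiff(seq_len(m), dep_idx)

    # covariance of the co-regulated target block: diag sigma_ii^2,
    # off-diagonal rho * sigma_ij^2, clipped to positive-definite
    sigma_dep <- diag(runif_open(k), k)
    off <- matrix(0, k, k)
    off[upper.tri(off)] <- spec$rho * runif_open(k * (k - 1) / 2)
    sigma_dep <- sigma_dep + off + t(off)
    sigma_dep <- make_positive_definite(sigma_dep)

    expr <- matrix(0, nrow = k, ncol = m)
    if (length(dep_idx) > 0L) {
      expr[, dep_idx] <- t(MASS::mvrnorm(length(dep_idx), mu = rep(0, k),
                                         Sigma = sigma_dep))
    }
    if (length(indep_idx) > 0L) {
      sd_indep <- sqrt(runif_open(k))
      expr[, indep_idx] <- matrix(stats::rnorm(k * length(indep_idx),
                                               sd = sd_indep),
                                  nrow = k)
    }

    n_eff <- spec$n_effective_modulators
    eff <- matrix(0, nrow = n_eff, ncol = m)
    eff[, dep_idx] <- stats::rnorm(n_eff * length(dep_idx),
                                   mean = spec$mod_mean_on, sd = spec$mod_sd)
    eff[, indep_idx] <- stats::rnorm(n_eff * length(indep_idx),
                                     mean = spec$mod_mean_off, sd = spec$mod_sd)

    n_dec <- spec$n_decoy_modulators
    dec <- matrix(stats::rnorm(n_dec * m, sd = rep(sqrt(runif_open(n_dec)), m)),
                  nrow = n_dec, ncol = m)

    target_ids <- sprintf("T%02d", seq_len(spec$n_targets))
    hidden_ids <- if (spec$n_hidden_targets > 0L) {
      sprintf("H%02d", seq_len(spec$n_hidden_targets))
    } else character(0)
    eff_ids <- sprintf("M%04d", seq_len(n_eff))
    dec_ids <- sprintf("M%04d", n_eff + seq_len(n_dec))

    full <- rbind(expr, eff, dec)
    rownames(full) <- c(target_ids, hidden_ids, eff_ids, dec_ids)
    colnames(full) <- sprintf("GEP%03d", seq_len(m))

    list(expr = full,
         truth = list(target_ids = target_ids,
                      hidden_target_ids = hidden_ids,
                      effective_modulator_ids = eff_ids,
                      decoy_modulator_ids = dec_ids,
                      modulator_ids = c(eff_ids, hidden_ids, dec_ids),
                      dependent_samples = dep_idx),
         sigma_dependent = sigma_dep,
         spec = spec)
  })
}

#' Closed-form Rényi multi-information of a Gaussian copula
#'
#' For variables whose dependence is a Gaussian copula with correlation
#' matrix R, the order-`alpha` multi-information (the Rényi divergence of
#' the joint from the product of marginals) has the closed form
#' `1 / (2 * (alpha - 1)) * ( -log det(alpha * R^-1 + (1 - alpha) * I)
#'   - alpha * log det(R) )` (natural log). As `alpha -> 1` this tends to
#' the classical Gaussian value `-log(det(R)) / 2`. Marginal transforms do
#' not change the value (copula invariance), so it also applies to, e.g.,
#' Beta-marginal samples coupled through the same Gaussian copula.
#'
#' @param R Correlation matrix (symmetric positive-definite, unit diagonal).
#' @param alpha Rényi order in (0, 1).
#' @return The multi-information in nats.
#' @export
gaussian_copula_rmi <- function(R, alpha = 0.99) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  d <- nrow(R)
  a <- alpha * solve(R) + (1 - alpha) * diag(d)
  (1 / (2 * (alpha - 1))) *
    (-determinant(a, logarithm = TRUE)$modulus[1] -
       alpha * determinant(R, logarithm = TRUE)$modulus[1])
}

# random correlation matrix: normalized Wishart draw, resampled until PD
random_correlation <- function(d) {
  repeat {
    a <- matrix(stats::rnorm(d * d), d, d)
    sigma <- crossprod(a) / d
    r <- stats::cov2cor(sigma)
    if (all(eigen(r, symmetric = TRUE, only.values = TRUE)$values > 1e-8)) {
      return(r)
    }
  }
}

#' Gaussian sample with known multi-information
#'
#' Draws `n` i.i.d. samples from a d-dimensional zero-mean Gaussian — either
#' with identity covariance (independent variables, true multi-information
#' 0) or with a randomly chosen symmetric positive-definite covariance
#' (dependent variables) — and reports the exact multi-information of the
#' generating distribution from the closed form. Used to check estimator
#' convergence.
#'
#' @param d Dimension.
#' @param n Sample size.
#' @param dependent Draw a random dependent covariance?
#' @param alpha Rényi order for the reported true value.
#' @param seed Integer seed.
#' @return A list with `x` (n x d sample), `sigma` (the covariance used),
#'   `correlation`, and `rmi_true` (nats).
#' @export
#' @examples
#' g <- generate_gaussian_convergence_sample(3, 500, dependent = FALSE, seed = 1)
#' g$rmi_true  # 0
generate_gaussian_convergence_sample <- function(d, n, dependent = TRUE,
                                                 alpha = 0.99, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    if (dependent) {
      r <- random_correlation(d)
      sigma <- r
      rmi_true <- gaussian_copula_rmi(r, alpha)
    } else {
      sigma <- diag(d)
      r <- sigma
      rmi_true <- 0
    }
    x <- MASS::mvrnorm(n, mu = rep(0, d), Sigma = sigma)
    list(x = x, sigma = sigma, correlation = r, rmi_true = rmi_true)
  })
}

#' Beta-marginal sample with Gaussian-copula dependence
#'
#' Draws `n` samples whose marginals are Beta(a_j, b_j) with shape
#' parameters drawn from the standard uniform distribution, coupled through
#' a Gaussian copula (random correlation matrix when `dependent`, identity
#' otherwise). Because multi-information is invariant under marginal
#' transforms, the true value equals that of the underlying Gaussian copula.
#'
#' @inheritParams generate_gaussian_convergence_sample
#' @return A list with `x` (n x d sample in (0,1)), `shape1`, `shape2`,
#'   `correlation`, and `rmi_true` (nats).
#' @export
generate_beta_copula_sample <- function(d, n, dependent = TRUE, alpha = 0.99,
                                        seed = 1L) {
  withr::with_seed(as.integer(seed), {
    a <- stats::runif(d); b <- stats::runif(d)
    if (dependent) {
      r <- random_correlation(d)
      z <- MASS::mvrnorm(n, mu = rep(0, d), Sigma = r)
      rmi_true <- gaussian_copula_rmi(r, alpha)
    } else {
      r <- diag(d)
      z <- matrix(stats::rnorm(n * d), n, d)
      rmi_true <- 0
    }
    u <- stats::pnorm(z)
    x <- vapply(seq_len(d), function(j) stats::qbeta(u[, j], a[j], b[j]),
                numeric(n))
    list(x = x, shape1 = a, shape2 = b, correlation = r, rmi_true = rmi_true)
  })
}
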