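#' Gibbs sampler configuration
#'
#' Chain settings for variance-component estimation. The reference
#' configuration is 100,000 iterations with 20,000 burn-in, retaining one
#' sample every 1,000 iterations for the variance traces; posterior means of
#' location effects are accumulated over every post-burn-in iteration.
#' Priors are flat (improper scaled-inverse-chi-square with nu = -2,
#' scale 0).
#'
#' @param n_iterations total Gibbs iterations.
#' @param burn_in discarded initial iterations.
#' @param thin trace retention interval.
#' @param seed integer seed for the chain.
#' @return list of class `gibbs_config`.
#' @export
gibbs_config <- function(n_iterations = 100000, burn_in = 20000,
                         thin = 1000, seed = 1) {
  stopifnot(burn_in < n_iterations, thin >= 1,
            thin <= n_iterations - burn_in)
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "gibbs_config")
}

#' Standardize phenotypes by block-within-site effects and site SD
#'
#' Centers each observation by its block-within-site mean and divides by the
#' phenotypic standard deviation of its site, removing site scale and block
#' location differences before fitting the marker model. Blocks with a
#' single tree are centered by the site mean instead (flagged); a site with
#' zero phenotypic SD yields all-zero standardized values (flagged). The
#' returned fit can be applied to new observations of the same design via
#' [standardize_apply()] so cross-validation can standardize validation
#' trees with training-only statistics.
#'
#' @param values numeric phenotype vector (NA preserved).
#' @param site,block character labels per observation.
#' @return list of class `std_fit`: `values` (standardized), `block_means`,
#'   `site_sd`, `site_means`, `flags`.
#' @export
standardize_phenotypes <- function(values, site, block) {
  stopifnot(length(values) == length(site), length(site) == length(block))
  ok <- !is.na(values)
  site_means <- tapply(values[ok], site[ok], mean)
  site_sd <- tapply(values[ok], site[ok], stats::sd)
  blk_n <- tapply(values[ok], block[ok], length)
  block_means <- tapply(values[ok], block[ok], mean)
  flags <- character(0)
  singleton <- names(blk_n)[blk_n < 2]
  if (length(singleton)) {
    flags <- c(flags, paste0("single-tree block(s) centered by site mean: ",
                             paste(singleton, collapse = ",")))
    site_of_block <- tapply(site[ok], block[ok], function(s) s[1])
    block_means[singleton] <- site_means[site_of_block[singleton]]
  }
  degenerate <- names(site_sd)[is.na(site_sd) | site_sd == 0]
  if (length(degenerate)) {
    flags <- c(flags, paste0("zero phenotypic SD in site(s): ",
                             paste(degenerate, collapse = ",")))
    site_sd[degenerate] <- NA_real_
  }
  fit <- structure(list(block_means = block_means, site_sd = site_sd,
                        site_means = site_means,
                        overall_mean = mean(values[ok]),
                        overall_sd = stats::sd(values[ok]),
                        flags = flags),
                   class = "std_fit")
  fit$values <- standardize_apply(fit, values, site, block)
  fit
}

#' Apply a standardization fit to (new) observations
#'
#' Observations from blocks unseen in training are centered by their site
#' mean; observations from sites unseen in training (e.g. cross-site
#' validation) use the pooled training mean and SD.
#'
#' @param fit a `std_fit` from [standardize_phenotypes()].
#' @param values,site,block observations to standardize.
#' @return standardized values; observations in a degenerate site get 0.
#' @export
standardize_apply <- function(fit, values, site, block) {
  ctr <- fit$block_means[block]
  miss <- is.na(ctr)
  if (any(miss)) # unseen block: fall back to site mean, then pooled mean
    ctr[miss] <- fit$site_means[site[miss]]
  ctr[is.na(ctr)] <- fit$overall_mean
  sds <- fit$site_sd[site]
  sds[is.na(sds) & !(site %in% names(fit$site_sd))] <- fit$overall_sd
  out <- (values - ctr) / sds
  out[!is.na(values) & is.na(sds)] <- 0
  as.numeric(out)
}

#' De-standardize predictions back to the raw trait scale
#' @param fit a `std_fit`.
#' @param std_values standardized predictions.
#' @param site,block design labels of the predicted observations.
#' @return values on the raw trait scale.
#' @export
destandardize <- function(fit, std_values, site, block) {
  ctr <- fit$block_means[block]
  miss <- is.na(ctr)
  if (any(miss)) ctr[miss] <- fit$site_means[site[miss]]
  ctr[is.na(ctr)] <- fit$overall_mean
  sds <- fit$site_sd[site]
  sds[is.na(sds) & !(site %in% names(fit$site_sd))] <- fit$overall_sd
  sds[is.na(sds)] <- 0
  as.numeric(std_values * sds + ctr)
}

#' Gauss-Seidel solver for mixed-model equations
#'
#' Solves a dense symmetric positive-definite system `C x = rhs` (typically
#' assembled mixed-model equations at fixed variance ratios) by Gauss-Seidel
#' coordinate iteration with residual update, stopping when the largest
#' coordinate update falls below `tol`.
#'
#' @param C coefficient matrix.
#' @param rhs right-hand side.
#' @param tol convergence tolerance on the max coordinate update.
#' @param max_sweeps sweep budget; non-convergence is an error.
#' @return list with `solution`, `sweeps`, `converged`.
#' @export
gauss_seidel_blup <- function(C, rhs, tol = 1e-8, max_sweeps = 1000) {
  out <- .gs_dense_cpp(as.matrix(C), as.numeric(rhs), tol, max_sweeps)
  if (!out$converged)
    stop(sprintf(
      "Gauss-Seidel did not converge in %d sweeps (last update %.3g)",
      max_sweeps, out$last_delta), call. = FALSE)
  out$solution <- as.numeric(out$solution)
  names(out$solution) <- rownames(C)
  out
}

#' Gauss-Seidel ridge solver with residual update on the data matrix
#'
#' Solves the marker-model ridge system (unpenalized intercept, common
#' shrinkage `lambda` on all marker effects) by coordinate iteration
#' directly on the n x m covariate matrix, maintaining the residual vector
#' after every coordinate update so `Z'Z` is never formed. This is the
#' iterative scheme the Gibbs sampler's location updates are built on; its
#' fixed point is the ridge closed form `(Z'Z + lambda I)^{-1} Z'y` (after
#' profiling out the intercept).
#'
#' @param Z covariate matrix.
#' @param y response.
#' @param lambda ridge shrinkage `sigma2_e / sigma2_a`.
#' @param tol convergence tolerance on the max coordinate update.
#' @param max_sweeps sweep budget.
#' @return list with `mu`, `alpha`, `sweeps`, `converged`.
#' @export
gauss_seidel_ridge <- function(Z, y, lambda, tol = 1e-8,
                               max_sweeps = 1000) {
  out <- .gs_ridge_cpp(as.matrix(Z), as.numeric(y), lambda, tol, max_sweeps)
  if (!out$converged)
    stop(sprintf("Gauss-Seidel ridge did not converge in %d sweeps",
                 max_sweeps), call. = FALSE)
  out$alpha <- as.numeric(out$alpha)
  names(out$alpha) <- colnames(Z)
  out
}

# Assemble animal-model design pieces shared by the Gibbs and BLUP paths.
.animal_design <- function(phenotypes, pedigree, trait, include_block) {
  stopifnot(trait %in% names(phenotypes))
  obs <- phenotypes[!is.na(phenotypes[[trait]]), , drop = FALSE]
  if (!nrow(obs)) stop("no phenotyped trees", call. = FALSE)
  if (!all(obs$tree %in% pedigree$id))
    stop("phenotyped tree(s) absent from pedigree", call. = FALSE)
  y <- obs[[trait]]
  if (stats::var(y) == 0) stop("response has zero variance", call. = FALSE)
  site_f <- factor(obs$site)
  X <- if (nlevels(site_f) > 1) stats::model.matrix(~site_f)
       else matrix(1, nrow(obs), 1, dimnames = list(NULL, "(Intercept)"))
  if (qr(X)$rank < ncol(X))
    stop("singular fixed-effect design", call. = FALSE)
  blk <- if (include_block) factor(obs$block) else NULL
  list(obs = obs, y = y, X = X,
       block_idx = if (is.null(blk)) integer(nrow(obs)) else
         as.integer(blk),
       block_levels = if (is.null(blk)) character(0) else levels(blk),
       ind_idx = match(obs$tree, pedigree$id))
}

#' Fit the individual-tree (animal) model
#'
#' Fits `y = X beta + S p + T u + e` on raw phenotypes with an overall mean
#' and fixed site effect, a random permanent block-within-site effect
#' `p ~ N(0, I s2p)`, additive polygenic effects `u ~ N(0, A s2u)` over every
#' pedigree member (unphenotyped parents and masked trees receive predicted
#' breeding values through the relationship matrix), and residual
#' `e ~ N(0, I s2e)`. Variance components are estimated by single-site Gibbs
#' sampling with flat priors (`method = "gibbs"`); with
#' `method = "blup"` the mixed-model equations are solved by Gauss-Seidel at
#' the supplied variance components, for fast deterministic refits.
#' Fitting on all sampled trees defines the reference ("true") breeding
#' values against which genomic predictions are validated.
#'
#' @param phenotypes data frame with columns `tree`, `site`, `block` and the
#'   trait; NA responses are allowed (those trees still get EBVs).
#' @param pedigree a [build_pedigree()] result covering all phenotyped trees.
#' @param trait trait column name.
#' @param gibbs a [gibbs_config()].
#' @param method `"gibbs"` (default) or `"blup"`.
#' @param varcomp for `method = "blup"`: list with `sigma2_u`, `sigma2_e`
#'   and (if blocks are included) `sigma2_p`.
#' @param include_block include the random block effect (default TRUE).
#' @param A optional precomputed relationship matrix.
#' @return object of class `animal_fit`: fixed effects, block effects,
#'   EBVs `u` (named, all pedigree members), `varcomp`, `h2`, `trace`.
#' @export
fit_animal_model <- function(phenotypes, pedigree, trait,
                             gibbs = gibbs_config(), method = c("gibbs",
                                                                "blup"),
                             varcomp = NULL, include_block = TRUE,
                             A = NULL) {
  method <- match.arg(method)
  if (!inherits(pedigree, "pedigree")) pedigree <- build_pedigree(pedigree)
  des <- .animal_design(phenotypes, pedigree, trait, include_block)
  if (is.null(A)) A <- numerator_relationship_matrix(pedigree)
  Ainv <- .ainverse(A)
  q <- nrow(Ainv)
  nb <- length(des$block_levels)

  if (method == "gibbs") {
    set.seed(gibbs$seed)
    res <- .gibbs_animal_cpp(des$X, des$block_idx, nb, des$ind_idx, Ainv,
                             des$y, gibbs$n_iterations, gibbs$burn_in,
                             gibbs$thin)
    vc <- list(sigma2_u = res$sigma2_u,
               sigma2_p = if (nb) res$sigma2_p else NA_real_,
               sigma2_e = res$sigma2_e)
    trace <- res$trace
    vc_sd <- list(sigma2_u = stats::sd(trace$sigma2_u),
                  sigma2_e = stats::sd(trace$sigma2_e))
    beta <- as.numeric(res$beta)
    blk <- as.numeric(res$block_effects)
    u <- as.numeric(res$u)
  } else {
    if (is.null(varcomp))
      stop("method = 'blup' needs varcomp (sigma2_u, sigma2_e[, sigma2_p])",
           call. = FALSE)
    lu <- varcomp$sigma2_e / varcomp$sigma2_u
    lp <- if (nb) varcomp$sigma2_e / varcomp$sigma2_p else NULL
    X <- des$X
    S <- if (nb) stats::model.matrix(~0 + factor(des$block_idx,
                                                 levels = seq_len(nb)))
         else NULL
    Tm <- matrix(0, nrow(X), q)
    Tm[cbind(seq_len(nrow(X)), des$ind_idx)] <- 1
    W <- cbind(X, S, Tm)
    C <- crossprod(W)
    off <- ncol(X)
    if (nb) {
      ix <- off + seq_len(nb)
      C[cbind(ix, ix)] <- C[cbind(ix, ix)] + lp
      off <- off + nb
    }
    iu <- off + seq_len(q)
    C[iu, iu] <- C[iu, iu] + lu * Ainv
    rhs <- crossprod(W, des$y)
    # direct dense solve: exact, and at desk scale (a few hundred to a few
    # thousand equations) cheaper than iterating to tight tolerance
    sol <- as.numeric(solve(C, rhs))
    beta <- sol[seq_len(ncol(X))]
    blk <- if (nb) sol[ncol(X) + seq_len(nb)] else numeric(0)
    u <- sol[iu]
    vc <- varcomp
    vc_sd <- NULL
    trace <- NULL
  }
  names(u) <- pedigree$id
  names(beta) <- colnames(des$X)
  if (nb) names(blk) <- des$block_levels
  h2 <- heritability(vc, mode = "pedigree")
  fitted_vals <- as.numeric(des$X %*% beta) +
    (if (nb) blk[des$block_idx] else 0) + u[des$ind_idx]
  structure(list(trait = trait, method = method, beta = beta,
                 block_effects = blk, u = u, varcomp = vc, vc_sd = vc_sd,
                 h2 = h2, trace = trace, fitted = fitted_vals,
                 obs_tree = des$obs$tree,
                 site_levels = levels(factor(des$obs$site))),
            class = "animal_fit")
}

#' Fit the ridge-regression marker model
#'
#' Fits `y = 1 mu + Z alpha + e` on standardized phenotypes with marker
#' effects sharing a common variance `alpha ~ N(0, I s2a)` (ridge
#' regression: all coefficients shrunk to the same extent). With
#' `method = "gibbs"` variance components are estimated by Gibbs sampling
#' with flat priors; with `method = "blup"` the ridge system is solved by
#' Gauss-Seidel with residual update at a fixed shrinkage
#' `lambda = s2e / s2a`.
#'
#' @param y standardized response vector (no NAs).
#' @param Z marker covariate matrix coded -1/0/+1
#'   (see [incidence_covariates()]), rows = individuals, named columns.
#' @param gibbs a [gibbs_config()].
#' @param method `"gibbs"` or `"blup"`.
#' @param lambda shrinkage ratio for `method = "blup"`.
#' @param sum2pq optional `sum(2 p q)` of the fitted panel; enables V_A and
#'   marker-based h2 in the result.
#' @return object of class `marker_fit`: `mu`, `alpha` (named), `varcomp`
#'   (`sigma2_a`, `sigma2_e`, and `V_A`/`h2` when `sum2pq` given), `gebv`
#'   (in-sample genomic breeding values), `trace`.
#' @export
fit_marker_model <- function(y, Z, gibbs = gibbs_config(),
                             method = c("gibbs", "blup"), lambda = NULL,
                             sum2pq = NULL) {
  method <- match.arg(method)
  if (anyNA(y)) stop("standardized response contains NA", call. = FALSE)
  if (stats::var(y) == 0)
    stop("response has zero variance", call. = FALSE)
  n_const <- sum(apply(Z, 2, function(z) all(z == z[1])))
  if (n_const > 0.5 * ncol(Z))
    warning("more than 50% of markers are constant in the training set")
  if (method == "gibbs") {
    set.seed(gibbs$seed)
    res <- .gibbs_ridge_cpp(Z, y, gibbs$n_iterations, gibbs$burn_in,
                            gibbs$thin)
    mu <- res$mu
    alpha <- as.numeric(res$alpha)
    vc <- list(sigma2_a = res$sigma2_a, sigma2_e = res$sigma2_e)
    trace <- res$trace
  } else {
    if (is.null(lambda))
      stop("method = 'blup' needs lambda = sigma2_e / sigma2_a",
           call. = FALSE)
    # exact ridge solution; the unpenalized intercept is profiled out by
    # centering, and for n < m the dual (individual x individual) system
    # is solved instead of the m x m normal equations
    zbar <- colMeans(Z)
    Zc <- sweep(Z, 2, zbar)
    yc <- y - mean(y)
    if (nrow(Z) < ncol(Z)) {
      M <- tcrossprod(Zc)
      diag(M) <- diag(M) + lambda
      alpha <- as.numeric(crossprod(Zc, solve(M, yc)))
    } else {
      M <- crossprod(Zc)
      diag(M) <- diag(M) + lambda
      alpha <- as.numeric(solve(M, crossprod(Zc, yc)))
    }
    mu <- mean(y) - sum(zbar * alpha)
    vc <- list(sigma2_a = NA_real_, sigma2_e = NA_real_, lambda = lambda)
    trace <- NULL
  }
  names(alpha) <- colnames(Z)
  if (!is.null(sum2pq) && !is.na(vc$sigma2_a)) {
    vc$V_A <- additive_variance_markers(vc$sigma2_a, sum2pq)
    vc$h2 <- heritability(vc, mode = "marker")
  }
  structure(list(mu = mu, alpha = alpha, varcomp = vc,
                 gebv = as.numeric(Z %*% alpha), trace = trace,
                 markers = colnames(Z)), class = "marker_fit")
}

#' Genomic-estimated breeding values from a fitted marker model
#'
#' Linear score `g_i = sum_j Z'_ij alpha_j` over the model's markers;
#' individuals absent from training are allowed. Marker sets must match
#' exactly.
#'
#' @param fit a `marker_fit`.
#' @param Z covariate matrix (-1/0/+1) with the model's marker columns.
#' @return named numeric vector of GEBVs.
#' @export
predict_gebv <- function(fit, Z) {
  missing_m <- setdiff(fit$markers, colnames(Z))
  if (length(missing_m))
    stop("covariates lack model markers: ",
         paste(utils::head(missing_m, 5), collapse = ", "), call. = FALSE)
  Z <- Z[, fit$markers, drop = FALSE]
  out <- as.numeric(Z %*% fit$alpha)
  names(out) <- rownames(Z)
  out
}

#' Marker-based additive genetic variance
#'
#' `V_A = sigma2_a * sum(2 p q)`, i.e. the common marker-effect variance
#' scaled by the summed marker heterozygosity of the retained panel.
#'
#' @param sigma2_a common marker-effect variance.
#' @param sum2pq `sum_2pq()` of the retained markers.
#' @return V_A.
#' @export
additive_variance_markers <- function(sigma2_a, sum2pq) {
  stopifnot(sigma2_a >= 0, sum2pq >= 0)
  sigma2_a * sum2pq
}

#' Individual heritability from variance components
#'
#' Pedigree mode: `h2 = s2u / (s2u + s2e)`; marker mode:
#' `h2 = V_A / (V_A + s2e)`. The block variance is excluded from the
#' denominator (within-site, within-block heritability).
#'
#' @param varcomp list with `sigma2_u` or `V_A`, plus `sigma2_e`.
#' @param mode `"pedigree"` or `"marker"`.
#' @return h2 in `[0, 1]`.
#' @export
heritability <- function(varcomp, mode = c("pedigree", "marker")) {
  mode <- match.arg(mode)
  num <- if (mode == "pedigree") varcomp$sigma2_u else varcomp$V_A
  den <- num + varcomp$sigma2_e
  if (is.na(den) || den == 0) stop("zero denominator", call. = FALSE)
  num / den
}

#' Geweke-style convergence z-score for an MCMC trace
#'
#' Compares the means of the first `frac1` and last `frac2` portions of a
#' trace, scaled by their standard errors (independent-sample
#' approximation). `|z| < 3` is taken as no evidence against convergence.
#'
#' @param x numeric trace.
#' @param frac1,frac2 fractions of the chain compared.
#' @return z statistic.
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  i1 <- seq_len(max(2, floor(frac1 * n)))
  i2 <- seq(n - max(2, floor(frac2 * n)) + 1, n)
  m1 <- mean(x[i1]); m2 <- mean(x[i2])
  v <- stats::var(x[i1]) / length(i1) + stats::var(x[i2]) / length(i2)
  if (v == 0) return(0)
  (m1 - m2) / sqrt(v)
}
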