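test_that("standardization removes block means and site scale", {
  set.seed(21)
  n <- 120
  site <- rep(c("S1", "S2"), each = n / 2)
  block <- paste0(site, "_B", rep(1:3, length.out = n))
  y <- ifelse(site == "S1", 100 + rnorm(n, 0, 5), 500 + rnorm(n, 0, 50))
  fit <- standardize_phenotypes(y, site, block)
  for (s in c("S1", "S2")) {
    expect_lt(abs(stats::sd(fit$values[site == s]) - 1), 0.15)
    for (b in unique(block[site == s]))
      expect_lt(abs(mean(fit$values[block == b])), 1e-10)
  }
  # NA preserved
  y2 <- y; y2[5] <- NA
  expect_true(is.na(standardize_phenotypes(y2, site, block)$values[5]))
})

test_that("standardization handles degenerate designs with flags", {
  # constant phenotypes within a site -> zeros, flagged
  y <- c(rep(3, 6), rnorm(6))
  site <- rep(c("A", "B"), each = 6)
  block <- paste0(site, "_b1")
  fit <- standardize_phenotypes(y, site, block)
  expect_true(all(fit$values[site == "A"] == 0))
  expect_match(paste(fit$flags, collapse = " "), "zero phenotypic SD")
  # single-tree block centered by site mean, flagged
  y3 <- rnorm(7)
  site3 <- rep("A", 7)
  block3 <- c(rep("A_b1", 6), "A_b2")
  fit3 <- standardize_phenotypes(y3, site3, block3)
  expect_match(paste(fit3$flags, collapse = " "), "single-tree")
  # centered single-site data keep mean 0
  yc <- scale(rnorm(30), scale = FALSE)[, 1]
  fitc <- standardize_phenotypes(yc, rep("A", 30), rep("A_b1", 30))
  expect_lt(abs(mean(fitc$values)), 1e-10)
})

test_that("Gauss-Seidel solves match direct dense solves", {
  # diagonal system: exact in one sweep
  D <- diag(c(2, 5, 10))
  gs <- gauss_seidel_blup(D, c(4, 10, 30))
  expect_equal(unname(gs$solution), c(2, 2, 3))
  expect_equal(gs$sweeps, 2) # second sweep only confirms convergence

  # random SPD systems, the size of a small mixed-model equation set
  for (s in 1:3) {
    set.seed(s)
    M <- matrix(rnorm(50 * 50), 50)
    C <- crossprod(M) + diag(50)
    rhs <- rnorm(50)
    expect_lt(max(abs(gauss_seidel_blup(C, rhs, tol = 1e-11)$solution -
                        solve(C, rhs))), 1e-8)
  }
})

test_that("Gauss-Seidel ridge equals the ridge closed form", {
  set.seed(31)
  n <- 60; m <- 120
  Z <- matrix(sample(c(-1, 0, 1), n * m, TRUE, c(0.3, 0.4, 0.3)), n)
  y <- rnorm(n)
  lambda <- 15
  gs <- gauss_seidel_ridge(Z, y, lambda, tol = 1e-10, max_sweeps = 5000)
  # closed form with unpenalized intercept via centering
  zbar <- colMeans(Z); Zc <- sweep(Z, 2, zbar); yc <- y - mean(y)
  a_ref <- solve(crossprod(Zc) + diag(lambda, m), crossprod(Zc, yc))
  expect_lt(max(abs(gs$alpha - a_ref)), 1e-6)
  expect_lt(abs(gs$mu - (mean(y) - sum(zbar * a_ref))), 1e-6)
  # and the deterministic marker-model path agrees with both
  fit <- fit_marker_model(y, Z, method = "blup", lambda = lambda)
  expect_lt(max(abs(fit$alpha - gs$alpha)), 1e-6)
})

test_that("ridge GEBVs equal GBLUP predictions on the same data", {
  set.seed(32)
  n <- 80; m <- 300
  Z <- matrix(sample(c(-1, 0, 1), n * m, TRUE), n,
              dimnames = list(sprintf("i%d", 1:n), sprintf("m%d", 1:m)))
  y <- rnorm(n)
  lambda <- 40
  fit <- fit_marker_model(y, Z, method = "blup", lambda = lambda)
  Zc <- sweep(Z, 2, colMeans(Z)); yc <- y - mean(y)
  G <- tcrossprod(Zc)
  u_gblup <- G %*% solve(G + diag(lambda, n), yc)
  expect_gt(stats::cor(fit$gebv, u_gblup), 0.999)
})

test_that("single-record BLUP with identity A shrinks by heritability", {
  set.seed(33)
  n <- 100
  ped <- build_pedigree(data.frame(id = sprintf("i%03d", 1:n), sire = NA,
                                   dam = NA))
  y <- 50 + rnorm(n, 0, 4)
  ph <- data.frame(tree = ped$id, site = "S1", block = "B1", y = y)
  s2u <- 6; s2e <- 2  # h2 = 0.75
  fit <- fit_animal_model(ph, ped, "y", method = "blup",
                          varcomp = list(sigma2_u = s2u, sigma2_e = s2e),
                          include_block = FALSE)
  h2 <- s2u / (s2u + s2e)
  expect_lt(max(abs(fit$u - h2 * (y - fit$beta[1]))), 1e-6)
})

test_that("unphenotyped relatives get the A-projection of progeny EBVs", {
  ped <- toy_diallel_pedigree(n_parents = 6, n_families = 7,
                              progeny_per_family = 5, seed = 3)
  set.seed(34)
  prog <- ped$id[!is.na(ped$sire)]
  ph <- data.frame(tree = prog, site = "S1", block = "B1",
                   y = rnorm(length(prog), 20, 3))
  fit <- fit_animal_model(ph, ped, "y", method = "blup",
                          varcomp = list(sigma2_u = 2, sigma2_e = 1),
                          include_block = FALSE)
  A <- numerator_relationship_matrix(ped)
  par <- ped$id[is.na(ped$sire)]
  proj <- A[par, prog] %*% solve(A[prog, prog], fit$u[prog])
  expect_lt(max(abs(fit$u[par] - proj)), 1e-6)
})

test_that("Gibbs chains are reproducible and agree with deterministic BLUP", {
  pop <- tiny_pop()
  ped <- build_pedigree(pop$pedigree)
  gc1 <- gibbs_config(3000, 500, 50, seed = 9)
  f1 <- fit_animal_model(pop$phenotypes, ped, "height", gibbs = gc1)
  f2 <- fit_animal_model(pop$phenotypes, ped, "height", gibbs = gc1)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$u, f2$u)

  # posterior-mean breeding values track the BLUP solution at the
  # posterior-mean variance components
  fb <- fit_animal_model(pop$phenotypes, ped, "height", method = "blup",
                         varcomp = f1$varcomp)
  expect_gt(stats::cor(f1$u, fb$u), 0.98)

  # marker model determinism and BLUP agreement
  std <- standardize_phenotypes(pop$phenotypes$height, pop$phenotypes$site,
                                pop$phenotypes$block)
  Z <- incidence_covariates(impute_missing(pop$genotypes))
  Zp <- Z[pop$phenotypes$tree, ]
  m1 <- fit_marker_model(std$values, Zp, gibbs = gc1)
  m2 <- fit_marker_model(std$values, Zp, gibbs = gc1)
  expect_identical(m1$trace, m2$trace)
  mb <- fit_marker_model(std$values, Zp, method = "blup",
                         lambda = m1$varcomp$sigma2_e /
                           m1$varcomp$sigma2_a)
  expect_gt(stats::cor(m1$gebv, mb$gebv), 0.98)
})

test_that("Gibbs animal model tracks a direct REML oracle", {
  ped <- toy_diallel_pedigree(n_parents = 12, n_families = 16,
                              progeny_per_family = 12, seed = 6)
  A <- numerator_relationship_matrix(ped)
  set.seed(35)
  L <- t(chol(A))
  u <- as.numeric(L %*% rnorm(nrow(A))) * sqrt(3)
  prog <- ped$id[!is.na(ped$sire)]
  y <- 10 + u[match(prog, ped$id)] + rnorm(length(prog))
  ph <- data.frame(tree = prog, site = "S1", block = "B1", y = y)
  fit <- fit_animal_model(ph, ped, "y", include_block = FALSE, A = A,
                          gibbs = gibbs_config(6000, 1000, 50, seed = 4))
  K <- A[match(prog, ped$id), match(prog, ped$id)]
  h2_reml <- reml_h2_oracle(y, matrix(1, length(y), 1), K)
  expect_lt(abs(fit$h2 - h2_reml), 0.12)
})

test_that("increasing shrinkage strictly decreases the effect norm", {
  set.seed(36)
  Z <- matrix(sample(c(-1, 0, 1), 50 * 80, TRUE), 50)
  y <- rnorm(50)
  norms <- sapply(c(1, 10, 100, 1000), function(l)
    sqrt(sum(fit_marker_model(y, Z, method = "blup", lambda = l)$alpha^2)))
  expect_true(all(diff(norms) < 0))
})

test_that("rescaling the response rescales effects but not heritability", {
  pop <- tiny_pop()
  ped <- build_pedigree(pop$pedigree)
  gc1 <- gibbs_config(2000, 400, 40, seed = 5)
  f1 <- fit_animal_model(pop$phenotypes, ped, "height", gibbs = gc1)
  ph10 <- pop$phenotypes
  ph10$height <- ph10$height * 10
  f10 <- fit_animal_model(ph10, ped, "height", gibbs = gc1)
  # identical RNG stream makes the equivariance exact, not just in law
  expect_equal(f10$u, f1$u * 10, tolerance = 1e-8)
  expect_equal(f10$varcomp$sigma2_u, f1$varcomp$sigma2_u * 100,
               tolerance = 1e-8)
  expect_equal(f10$h2, f1$h2, tolerance = 1e-10)
})

test_that("marker effects respond to signal and its absence", {
  set.seed(37)
  n <- 200; m <- 100
  Z <- matrix(sample(c(-1L, 0L, 1L), n * m, TRUE), n,
              dimnames = list(NULL, sprintf("m%03d", 1:m)))
  y <- 2 * Z[, 17] # single causal marker, no noise
  fit <- fit_marker_model(y, Z, gibbs = gibbs_config(2000, 400, 40,
                                                     seed = 2))
  expect_equal(which.max(abs(fit$alpha)), 17L, ignore_attr = TRUE)

  # GEBV arithmetic
  fit1 <- fit_marker_model(rnorm(3), matrix(c(-1, 0, 1), 3, 1,
                                            dimnames = list(NULL, "m1")),
                           method = "blup", lambda = 5)
  fit1$alpha <- c(m1 = 1)
  Znew <- matrix(c(0, 1, 2) - 1, 3, 1, dimnames = list(letters[1:3], "m1"))
  expect_equal(unname(predict_gebv(fit1, Znew)), c(-1, 0, 1))
  fit1$alpha <- c(m1 = 0)
  expect_equal(unname(predict_gebv(fit1, Znew)), c(0, 0, 0))
  colnames(Znew) <- "other"
  expect_error(predict_gebv(fit1, Znew), "lack model markers")
})

test_that("heritability and marker additive variance follow the printed arithmetic", {
  # pedigree-based: height, combined sites
  expect_equal(round(heritability(list(sigma2_u = 3503.73,
                                       sigma2_e = 1613.54), "pedigree"), 2),
               0.68)
  # marker-based: height, combined sites
  expect_equal(round(heritability(list(V_A = 1851.53, sigma2_e = 2514.81),
                                  "marker"), 2), 0.42)
  expect_equal(heritability(list(sigma2_u = 1, sigma2_e = 0), "pedigree"),
               1)
  expect_error(heritability(list(sigma2_u = 0, sigma2_e = 0)), "zero")

  # V_A round-trip: sigma2_a = 0.97 and V_A = 1851.53 imply
  # sum(2pq) = 1908.8
  s2pq <- 1851.53 / 0.97
  expect_equal(additive_variance_markers(0.97, s2pq), 1851.53)
  expect_equal(additive_variance_markers(0, 1000), 0)
  expect_equal(additive_variance_markers(2 * 0.97, s2pq),
               2 * additive_variance_markers(0.97, s2pq))
})

test_that("Geweke diagnostic is calm on stationary traces", {
  set.seed(38)
  expect_lt(abs(geweke_z(rnorm(500))), 3)
})
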