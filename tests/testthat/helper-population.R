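# Shared simulated fixtures, built once per test run and cached in an
# environment so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small population: quick container / QC / pedigree checks
tiny_pop <- function() {
  fixture("tiny_pop", function() {
    cfg <- sim_config(n_parents = 10, n_families = 12,
                      progeny_per_family = 10, n_progeny_total = 110,
                      n_markers = 400, n_qtl = 50,
                      trait_specs = default_trait_specs()[1, ])
    simulate_population(cfg, seed = 101)
  })
}

# mid-size population with an analysis bundle: validation-scheme checks
mid_data <- function() {
  fixture("mid_data", function() {
    cfg <- sim_config(n_families = 30, progeny_per_family = 14,
                      n_progeny_total = 420, n_markers = 1200, n_qtl = 150,
                      trait_specs = default_trait_specs()[1, ])
    pop <- simulate_population(cfg, seed = 202)
    data <- prepare_gs_data(pop, "height",
                            gibbs = gibbs_config(5000, 1000, 100,
                                                 seed = 17))
    list(pop = pop, data = data)
  })
}

# two-generation diallel pedigree without simulating genotypes
toy_diallel_pedigree <- function(n_parents = 8, n_families = 10,
                                 progeny_per_family = 4, seed = 5) {
  crosses <- partial_diallel_matings(n_parents, n_families, seed = seed)
  prog <- do.call(rbind, lapply(seq_len(n_families), function(f) {
    data.frame(id = sprintf("%s_%02d", crosses$family[f],
                            seq_len(progeny_per_family)),
               sire = crosses$sire[f], dam = crosses$dam[f],
               family = crosses$family[f], provenance = NA,
               stringsAsFactors = FALSE)
  }))
  founders <- data.frame(id = sprintf("P%02d", seq_len(n_parents)),
                         sire = NA, dam = NA, family = NA,
                         provenance = sprintf("PR%d",
                                              rep_len(1:4, n_parents)),
                         stringsAsFactors = FALSE)
  build_pedigree(rbind(founders, prog))
}

# direct REML on the animal model's marginal likelihood: an independent
# oracle for variance-ratio estimation (profile s2e, optimize h2)
reml_h2_oracle <- function(y, X, K) {
  n <- length(y)
  p <- ncol(X)
  obj <- function(logit_h2) {
    h2 <- 1 / (1 + exp(-logit_h2))
    V <- (h2 / (1 - h2)) * K + diag(n)
    cV <- chol(V)
    Vi <- chol2inv(cV)
    XVX <- crossprod(X, Vi %*% X)
    P <- Vi - Vi %*% X %*% solve(XVX, t(X) %*% Vi)
    s2e <- as.numeric(t(y) %*% P %*% y) / (n - p)
    -(-sum(log(diag(cV))) - 0.5 * as.numeric(determinant(XVX)$modulus) -
        0.5 * (n - p) * log(s2e))
  }
  opt <- stats::optimize(obj, c(-5, 5))
  1 / (1 + exp(-opt$minimum))
}
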