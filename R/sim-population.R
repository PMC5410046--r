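#' Simulation configuration for a partial-diallel breeding population
#'
#' Defines the study conditions emulated by the simulator: a two-generation
#' breeding population of interconnected full-sib families produced by a
#' partial diallel among a small set of selected parents, planted on a small
#' number of sites, and genotyped for biallelic gene SNPs spread over the
#' spruce linkage groups.
#'
#' Defaults mirror an advanced-breeding spruce trial: 27 parents, 34 full-sib
#' families of 22 progeny trimmed at random to 734 trees, 2 sites with 4
#' blocks each, 4993 SNPs on 12 linkage groups totalling 1850 cM
#' (about 2.7 markers per cM), 1.8% missing genotype calls.
#'
#' @param n_parents number of diallel parents.
#' @param n_families number of full-sib families (distinct non-self parent
#'   pairs; must not exceed `choose(n_parents, 2)`).
#' @param progeny_per_family progeny generated per family before trimming.
#' @param n_progeny_total total progeny kept after random trimming (`NULL`
#'   keeps all `n_families * progeny_per_family`).
#' @param n_sites,n_blocks_per_site field design dimensions.
#' @param n_linkage_groups,total_map_length genome map: number of linkage
#'   groups and total length in centimorgans.
#' @param n_markers number of biallelic SNPs.
#' @param n_qtl number of markers carrying additive trait effects.
#' @param founder_maf_beta two shape parameters of a symmetric Beta whose
#'   draw, scaled onto (0, 0.5], gives founder minor-allele frequencies.
#' @param missing_rate fraction of genotype calls masked at random.
#' @param n_provenances parental provenances, assigned round-robin.
#' @param trait_specs data frame of trait definitions, see
#'   [default_trait_specs()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_parents = 27, n_families = 34,
                       progeny_per_family = 22, n_progeny_total = 734,
                       n_sites = 2, n_blocks_per_site = 4,
                       n_linkage_groups = 12, total_map_length = 1850,
                       n_markers = 4993, n_qtl = 200,
                       founder_maf_beta = c(2, 2), missing_rate = 0.018,
                       n_provenances = 10,
                       trait_specs = default_trait_specs()) {
  if (n_parents < 2) stop("need at least 2 parents", call. = FALSE)
  if (n_families > choose(n_parents, 2))
    stop("n_families exceeds the number of distinct unordered parent pairs",
         call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  if (length(founder_maf_beta) != 2 || any(!is.finite(founder_maf_beta)) ||
      any(founder_maf_beta <= 0))
    stop("founder_maf_beta must be two positive shape parameters",
         call. = FALSE)
  if (n_qtl > n_markers) stop("n_qtl cannot exceed n_markers", call. = FALSE)
  stopifnot(is.data.frame(trait_specs),
            all(c("name", "mean", "genetic_var", "h2", "site_effect_sd",
                  "block_effect_sd", "direction") %in% names(trait_specs)))
  if (any(trait_specs$h2 <= 0 | trait_specs$h2 > 1))
    stop("trait h2 must be in (0, 1]", call. = FALSE)
  if (!all(trait_specs$direction %in% c("higher_better", "lower_better")))
    stop("trait direction must be higher_better or lower_better",
         call. = FALSE)
  n_total <- n_families * progeny_per_family
  if (is.null(n_progeny_total)) n_progeny_total <- n_total
  if (n_progeny_total > n_total)
    stop("n_progeny_total exceeds generated progeny", call. = FALSE)
  structure(list(
    n_parents = n_parents, n_families = n_families,
    progeny_per_family = progeny_per_family,
    n_progeny_total = n_progeny_total,
    n_sites = n_sites, n_blocks_per_site = n_blocks_per_site,
    n_linkage_groups = n_linkage_groups,
    total_map_length = total_map_length,
    n_markers = n_markers, n_qtl = n_qtl,
    founder_maf_beta = founder_maf_beta, missing_rate = missing_rate,
    n_provenances = n_provenances, trait_specs = trait_specs
  ), class = "sim_config")
}

#' Default trait architecture for the simulator
#'
#' Four growth/wood traits with heritabilities in the 0.4-0.8 range typical
#' of mature conifer trials: height (cm, h2 0.68), wood density (kg/m3,
#' h2 0.41), diameter at breast height (mm, h2 0.57) and microfibril angle
#' (degrees, h2 0.74, lower values favorable). Genetic variances follow the
#' magnitudes of pedigree-based variance components reported for such trials.
#'
#' @return data frame with one row per trait.
#' @export
default_trait_specs <- function() {
  data.frame(
    name = c("height", "density", "dbh", "mfa"),
    mean = c(800, 450, 100, 15),
    genetic_var = c(3500, 598, 126, 0.14),
    h2 = c(0.68, 0.41, 0.57, 0.74),
    site_effect_sd = c(60, 15, 10, 0.4),
    block_effect_sd = c(25, 8, 5, 0.2),
    direction = c("higher_better", "higher_better", "higher_better",
                  "lower_better"),
    stringsAsFactors = FALSE
  )
}

#' Simulate diallel founders: haplotypes, allele frequencies and marker map
#'
#' Marker minor-allele frequencies are drawn from a symmetric Beta scaled to
#' (0, 0.5]; markers are placed uniformly at random on the genetic map
#' (linkage group chosen proportional to its length, position uniform within
#' it) and sorted by position. Each founder receives two haplotypes with
#' independent Bernoulli(p) alleles per marker.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @return list with `haplotypes` (array `n_parents` x 2 x `n_markers` of
#'   0/1 alleles), `freq` (design frequencies), and `map` (data frame
#'   `marker`, `linkage_group`, `position_cM`, sorted within group).
#' @export
simulate_founders <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- config$n_markers
  lg_len <- config$total_map_length / config$n_linkage_groups
  lg <- sample.int(config$n_linkage_groups, m, replace = TRUE)
  pos <- stats::runif(m, 0, lg_len)
  ord <- order(lg, pos)
  lg <- lg[ord]; pos <- pos[ord]
  map <- data.frame(marker = sprintf("M%05d", seq_len(m)),
                    linkage_group = lg, position_cM = pos,
                    stringsAsFactors = FALSE)
  freq <- 0.5 * stats::rbeta(m, config$founder_maf_beta[1],
                             config$founder_maf_beta[2])
  # guard against exactly-zero frequencies (monomorphic by design)
  freq <- pmin(pmax(freq, 1e-4), 0.5)
  hap <- array(0L, dim = c(config$n_parents, 2, m))
  for (h in 1:2)
    hap[, h, ] <- matrix(stats::rbinom(config$n_parents * m, 1,
                                       rep(freq, each = config$n_parents)),
                         nrow = config$n_parents)
  list(haplotypes = hap, freq = freq, map = map)
}

#' Choose the crosses of a partial diallel
#'
#' Selects `n_families` distinct unordered non-self parent pairs. When at
#' least `ceiling(n_parents / 2)` families are requested, a first round of
#' pairs over a shuffled parent order guarantees every parent enters at
#' least one cross; remaining pairs are drawn at random without replacement.
#'
#' @param parents vector of parent ids (or a single integer count).
#' @param n_families number of crosses.
#' @param seed optional integer seed.
#' @return data frame with columns `sire`, `dam`, `family`.
#' @export
partial_diallel_matings <- function(parents, n_families, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(parents) == 1 && is.numeric(parents))
    parents <- sprintf("P%02d", seq_len(parents))
  np <- length(parents)
  max_pairs <- choose(np, 2)
  if (n_families > max_pairs)
    stop("requested more families than distinct parent pairs", call. = FALSE)
  pairs_idx <- utils::combn(np, 2)
  chosen <- integer(0)
  if (n_families >= ceiling(np / 2)) {
    ord <- sample.int(np)
    base <- cbind(ord[seq(1, np - 1, by = 2)], ord[seq(2, np, by = 2)])
    if (np %% 2 == 1) base <- rbind(base, c(ord[np], ord[1]))
    key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    all_keys <- key(pairs_idx[1, ], pairs_idx[2, ])
    chosen <- match(key(base[, 1], base[, 2]), all_keys)
    chosen <- chosen[seq_len(min(length(chosen), n_families))]
  }
  remaining <- setdiff(seq_len(max_pairs), chosen)
  extra <- n_families - length(chosen)
  if (extra > 0)
    chosen <- c(chosen, sample(remaining, extra))
  sel <- pairs_idx[, chosen, drop = FALSE]
  data.frame(sire = parents[sel[1, ]], dam = parents[sel[2, ]],
             family = sprintf("F%02d", seq_len(n_families)),
             stringsAsFactors = FALSE)
}

# Haldane map function: recombination fraction from distance in cM.
haldane_r <- function(d_cM) 0.5 * (1 - exp(-0.02 * d_cM))

# Precompute per-interval switch probabilities for gamete formation:
# the first marker of each linkage group starts from a random haplotype
# (probability 0.5), later markers switch with the Haldane fraction.
.switch_probs <- function(map) {
  m <- nrow(map)
  r <- numeric(m)
  new_lg <- c(TRUE, map$linkage_group[-1] != map$linkage_group[-m])
  d <- c(0, diff(map$position_cM))
  if (any(d[!new_lg] < 0)) stop("map positions not sorted within linkage group",
                                call. = FALSE)
  r[!new_lg] <- haldane_r(d[!new_lg])
  r[new_lg] <- 0.5
  r
}

# One gamete from a 2 x m haplotype pair: crossover indicators per interval,
# cumulative parity picks the transmitted haplotype at each marker.
.make_gamete <- function(hap2, switch_p) {
  switches <- stats::rbinom(length(switch_p), 1, switch_p)
  state <- cumsum(switches) %% 2L
  hap2[cbind(state + 1L, seq_along(state))]
}

#' Drop genes through meioses of one cross
#'
#' Forms progeny genotypes as the sum of one recombinant gamete from each
#' parent. Recombination between adjacent markers follows the Haldane map
#' function (no interference); linkage groups assort independently.
#'
#' @param sire_hap,dam_hap 2 x m matrices of parental haplotypes (0/1).
#' @param map marker map sorted by linkage group and position.
#' @param n_progeny number of progeny to generate.
#' @param seed optional integer seed.
#' @return integer matrix `n_progeny` x m of allele counts 0/1/2.
#' @export
gene_drop <- function(sire_hap, dam_hap, map, n_progeny, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- .switch_probs(map)
  out <- matrix(0L, n_progeny, nrow(map))
  for (i in seq_len(n_progeny))
    out[i, ] <- .make_gamete(sire_hap, sp) + .make_gamete(dam_hap, sp)
  out
}

#' Simulate phenotypes from true breeding values and a field design
#'
#' Generates `y = mean + site + block(site) + TBV + e` per trait, with the
#' residual variance chosen so the within-site individual heritability
#' equals the trait's target: `ve = gv * (1 - h2) / h2` where `gv` is the
#' trait's genetic variance (`h2 = 1` gives a noiseless trait). Site and
#' block effects are fixed realizations drawn once per call unless supplied.
#'
#' @param tbv individuals x traits matrix of true breeding values; column
#'   names must match `trait_specs$name`.
#' @param site,block character labels per individual; blocks are nested in
#'   sites (block labels must be unique across sites).
#' @param trait_specs trait definition table, see [default_trait_specs()].
#' @param seed optional integer seed.
#' @param site_effects,block_effects optional pre-drawn effect matrices
#'   (levels x traits, rownames = labels); drawn from the trait spec SDs
#'   when missing.
#' @return list with `values` (data frame of trait columns), `resid_var`,
#'   `site_effects`, `block_effects`.
#' @export
simulate_phenotypes <- function(tbv, site, block, trait_specs, seed = NULL,
                                site_effects = NULL, block_effects = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ts <- trait_specs
  stopifnot(nrow(tbv) == length(site), length(site) == length(block))
  if (any(ts$h2 <= 0 | ts$h2 > 1))
    stop("target h2 must be in (0, 1]", call. = FALSE)
  n_traits <- nrow(ts)
  site_lev <- sort(unique(site))
  blk_lev <- sort(unique(block))
  if (is.null(site_effects)) {
    site_effects <- matrix(stats::rnorm(length(site_lev) * n_traits),
                           length(site_lev), n_traits,
                           dimnames = list(site_lev, ts$name)) *
      rep(ts$site_effect_sd, each = length(site_lev))
  }
  if (is.null(block_effects)) {
    block_effects <- matrix(stats::rnorm(length(blk_lev) * n_traits),
                            length(blk_lev), n_traits,
                            dimnames = list(blk_lev, ts$name)) *
      rep(ts$block_effect_sd, each = length(blk_lev))
  }
  resid_var <- ts$genetic_var * (1 - ts$h2) / ts$h2
  values <- data.frame(row.names = seq_along(site))
  for (t in seq_len(n_traits)) {
    e <- if (resid_var[t] > 0)
      stats::rnorm(length(site), 0, sqrt(resid_var[t])) else 0
    values[[ts$name[t]]] <- ts$mean[t] +
      site_effects[match(site, rownames(site_effects)), t] +
      block_effects[match(block, rownames(block_effects)), t] +
      tbv[, ts$name[t]] + e
  }
  list(values = values, resid_var = resid_var,
       site_effects = site_effects, block_effects = block_effects)
}

#' Simulate a complete partial-diallel population
#'
#' Runs the full generative model: founder haplotypes, diallel crosses, gene
#' dropping, QTL-based true breeding values, field design and phenotypes.
#' A random subset of `n_qtl` genotyped markers carries additive effects
#' drawn from a normal distribution and rescaled so the realized genetic
#' variance among progeny matches each trait's `genetic_var`; all other
#' markers are neutral. Phenotypes are
#' `y = mean + site + block(site) + TBV + e`, with the residual variance set
#' from the target heritability (`ve = gv * (1 - h2) / h2`), so the
#' within-site individual heritability equals `h2` by construction. Missing
#' genotype calls are masked completely at random.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the whole population is reproducible from it.
#' @return object of class `sim_population`: list with `config`, `pedigree`,
#'   `genotypes` (progeny x markers, 0/1/2/NA), `map`, `tbv` (individuals x
#'   traits, progeny and parents), `phenotypes` (tree/site/block/family +
#'   trait columns), `qtl` (marker effects per trait) and `truth` (variance
#'   components and design effects used).
#' @export
simulate_population <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  fo <- simulate_founders(config)
  parents <- sprintf("P%02d", seq_len(config$n_parents))
  crosses <- partial_diallel_matings(parents, config$n_families)
  m <- config$n_markers
  sp <- .switch_probs(fo$map)

  n_total <- config$n_families * config$progeny_per_family
  G <- matrix(0L, n_total, m)
  fam_of <- character(n_total)
  sire_of <- character(n_total)
  dam_of <- character(n_total)
  row <- 0L
  for (f in seq_len(config$n_families)) {
    si <- match(crosses$sire[f], parents)
    di <- match(crosses$dam[f], parents)
    sh <- rbind(fo$haplotypes[si, 1, ], fo$haplotypes[si, 2, ])
    dh <- rbind(fo$haplotypes[di, 1, ], fo$haplotypes[di, 2, ])
    for (k in seq_len(config$progeny_per_family)) {
      row <- row + 1L
      G[row, ] <- .make_gamete(sh, sp) + .make_gamete(dh, sp)
      fam_of[row] <- crosses$family[f]
      sire_of[row] <- crosses$sire[f]
      dam_of[row] <- crosses$dam[f]
    }
  }
  ids <- sprintf("%s_%02d", fam_of, stats::ave(seq_len(n_total), fam_of,
                                               FUN = seq_along))
  keep <- sort(sample.int(n_total, config$n_progeny_total))
  G <- G[keep, , drop = FALSE]
  ids <- ids[keep]; fam_of <- fam_of[keep]
  sire_of <- sire_of[keep]; dam_of <- dam_of[keep]
  rownames(G) <- ids
  colnames(G) <- fo$map$marker
  n <- nrow(G)

  # parents' genotypes (for TBVs of founders)
  GP <- fo$haplotypes[, 1, ] + fo$haplotypes[, 2, ]
  rownames(GP) <- parents
  colnames(GP) <- fo$map$marker

  provenance <- sprintf("PR%02d",
                        rep_len(seq_len(config$n_provenances),
                                config$n_parents))
  pedigree <- data.frame(
    id = c(parents, ids),
    sire = c(rep(NA_character_, config$n_parents), sire_of),
    dam = c(rep(NA_character_, config$n_parents), dam_of),
    family = c(rep(NA_character_, config$n_parents), fam_of),
    provenance = c(provenance,
                   provenance[match(sire_of, parents)]),
    stringsAsFactors = FALSE
  )

  # QTL architecture: shared positions, independent effects per trait
  qtl_idx <- sort(sample.int(m, config$n_qtl))
  ts <- config$trait_specs
  n_traits <- nrow(ts)
  Wq <- G[, qtl_idx, drop = FALSE] - 1
  WqP <- GP[, qtl_idx, drop = FALSE] - 1
  tbv <- matrix(0, n + config$n_parents, n_traits,
                dimnames = list(c(ids, parents), ts$name))
  qtl_eff <- matrix(0, config$n_qtl, n_traits,
                    dimnames = list(fo$map$marker[qtl_idx], ts$name))
  # scale effects so the base-population additive variance (founder allele
  # frequencies, linkage equilibrium) equals genetic_var; heritability is
  # defined in the founder population, which is what the animal model's
  # polygenic variance estimates
  pq <- colMeans(rbind(fo$haplotypes[, 1, qtl_idx],
                       fo$haplotypes[, 2, qtl_idx]))
  base_scale <- 2 * pq * (1 - pq)
  for (t in seq_len(n_traits)) {
    a <- stats::rnorm(config$n_qtl)
    sc <- sqrt(ts$genetic_var[t] / sum(base_scale * a^2))
    a <- a * sc
    qtl_eff[, t] <- a
    tbv[seq_len(n), t] <- as.numeric(Wq %*% a)
    tbv[n + seq_len(config$n_parents), t] <- as.numeric(WqP %*% a)
  }

  # field design: balanced random split of each family over sites,
  # random block within site
  site <- integer(n)
  for (f in unique(fam_of)) {
    idx <- which(fam_of == f)
    idx <- sample(idx)
    halves <- rep_len(seq_len(config$n_sites), length(idx))
    site[idx] <- halves
  }
  block <- sample.int(config$n_blocks_per_site, n, replace = TRUE)
  site_lab <- sprintf("S%d", site)
  block_lab <- sprintf("S%d_B%d", site, block)

  site_eff <- matrix(stats::rnorm(config$n_sites * n_traits), config$n_sites,
                     n_traits,
                     dimnames = list(sprintf("S%d", seq_len(config$n_sites)),
                                     ts$name)) *
    rep(ts$site_effect_sd, each = config$n_sites)
  blk_labels <- as.vector(outer(seq_len(config$n_blocks_per_site),
                                seq_len(config$n_sites),
                                function(b, s) sprintf("S%d_B%d", s, b)))
  blk_eff <- matrix(stats::rnorm(length(blk_labels) * n_traits),
                    length(blk_labels), n_traits,
                    dimnames = list(blk_labels, ts$name)) *
    rep(ts$block_effect_sd, each = length(blk_labels))

  ph <- simulate_phenotypes(tbv[seq_len(n), , drop = FALSE], site_lab,
                            block_lab, ts,
                            site_effects = site_eff,
                            block_effects = blk_eff)
  pheno <- cbind(data.frame(tree = ids, site = site_lab, block = block_lab,
                            family = fam_of, stringsAsFactors = FALSE),
                 ph$values)
  resid_var <- ph$resid_var

  if (config$missing_rate > 0) {
    nmiss <- round(config$missing_rate * length(G))
    G[sample.int(length(G), nmiss)] <- NA_integer_
  }

  structure(list(
    config = config, seed = seed, pedigree = pedigree, genotypes = G,
    map = fo$map, tbv = tbv, phenotypes = pheno, qtl = qtl_eff,
    truth = list(founder_freq = fo$freq, genetic_var = ts$genetic_var,
                 resid_var = resid_var, site_effects = site_eff,
                 block_effects = blk_eff, trait_means = ts$mean)
  ), class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat("Simulated partial-diallel population\n")
  cat(sprintf("  %d parents, %d families, %d progeny\n",
              x$config$n_parents, x$config$n_families, nrow(x$genotypes)))
  cat(sprintf("  %d markers on %d linkage groups (%.0f cM)\n",
              x$config$n_markers, x$config$n_linkage_groups,
              x$config$total_map_length))
  cat(sprintf("  traits: %s\n",
              paste(x$config$trait_specs$name, collapse = ", ")))
  invisible(x)
}
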