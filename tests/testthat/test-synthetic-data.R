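test_that("partial diallel matings are distinct non-self pairs", {
  # full-scale design
  m <- partial_diallel_matings(27, 34, seed = 1)
  expect_equal(nrow(m), 34)
  expect_true(all(m$sire != m$dam))
  key <- paste(pmin(m$sire, m$dam), pmax(m$sire, m$dam))
  expect_false(anyDuplicated(key) > 0)
  # every parent mated when enough families are requested
  expect_setequal(union(m$sire, m$dam), sprintf("P%02d", 1:27))

  # forced outcomes
  m2 <- partial_diallel_matings(2, 1, seed = 3)
  expect_setequal(c(m2$sire, m2$dam), c("P01", "P02"))
  m6 <- partial_diallel_matings(4, 6, seed = 3)
  key6 <- paste(pmin(m6$sire, m6$dam), pmax(m6$sire, m6$dam))
  expect_equal(sort(key6),
               sort(apply(utils::combn(sprintf("P%02d", 1:4), 2), 2,
                          function(p) paste(p[1], p[2]))))

  expect_error(partial_diallel_matings(4, 7), "more families")
})

test_that("founder simulation respects the MAF distribution and map", {
  cfg <- sim_config(n_parents = 2, n_families = 1, progeny_per_family = 4,
                    n_progeny_total = 4, n_markers = 2000,
                    founder_maf_beta = c(2000, 2000),
                    trait_specs = default_trait_specs()[1, ])
  fo <- simulate_founders(cfg, seed = 4)
  # near-degenerate Beta concentrated at 0.5 * 0.5 = 0.25
  expect_lt(max(abs(fo$freq - 0.25)), 0.02)
  # markers sorted within linkage group, positions within the group length
  expect_true(all(diff(fo$map$position_cM)[diff(fo$map$linkage_group) == 0]
                  >= 0))
  expect_true(all(fo$map$position_cM >= 0 &
                    fo$map$position_cM <= cfg$total_map_length /
                      cfg$n_linkage_groups))
  # determinism
  fo2 <- simulate_founders(cfg, seed = 4)
  expect_identical(fo$haplotypes, fo2$haplotypes)

  expect_error(sim_config(founder_maf_beta = c(-1, 2)), "shape")
})

test_that("realized marker MAF matches the founder Beta mean", {
  pop <- tiny_pop()
  st <- marker_stats(pop$genotypes)
  # symmetric Beta(2,2) on (0, 0.5] has mean 0.25; realized MAF is pulled
  # down slightly because frequencies near 0.5 can only fold downward
  expect_lt(abs(mean(st$maf, na.rm = TRUE) - 0.25), 0.03)
})

test_that("gene drop follows the Haldane map function", {
  two_marker_map <- function(d) data.frame(marker = c("A", "B"),
                                           linkage_group = c(1, 1),
                                           position_cM = c(0, d))
  hap_het <- rbind(c(1, 1), c(0, 0)) # phase-known double heterozygote
  recomb_frac <- function(map, n = 10000, seed = 9) {
    set.seed(seed)
    sp <- sprucegs:::.switch_probs(map)
    g <- replicate(n, sprucegs:::.make_gamete(hap_het, sp))
    mean(g[1, ] != g[2, ])
  }
  # zero distance: always co-inherited
  expect_equal(recomb_frac(two_marker_map(0)), 0)
  # 50 cM: Haldane closed form (1 - exp(-1)) / 2
  expect_lt(abs(recomb_frac(two_marker_map(50)) - 0.5 * (1 - exp(-1))),
            0.02)
  # different linkage groups: independent assortment
  map_lg <- data.frame(marker = c("A", "B"), linkage_group = c(1, 2),
                       position_cM = c(0, 0))
  expect_lt(abs(recomb_frac(map_lg) - 0.5), 0.02)
  # unsorted map rejected
  bad <- data.frame(marker = c("A", "B"), linkage_group = c(1, 1),
                    position_cM = c(5, 2))
  expect_error(gene_drop(hap_het, hap_het, bad, 1), "sorted")
})

test_that("full sibs share ~0.25 more marker-estimated kinship than non-relatives", {
  pop <- tiny_pop()
  Gi <- impute_missing(apply_qc(orient_minor(pop$genotypes)$genotypes,
                                qc_thresholds(min_minor_carriers = 2))$genotypes)
  G <- genomic_relationship_structure(Gi)$G
  ped <- build_pedigree(pop$pedigree)
  cls <- classify_pairs(ped, ids = rownames(Gi))
  gval <- G[cbind(match(cls$id1, rownames(G)), match(cls$id2, colnames(G)))]
  # sample-frequency centering shifts all G entries by the mean sample
  # relatedness, so the identifiable quantity is the full-sib vs unrelated
  # CONTRAST: expected A difference 0.5 (kinship difference 0.25)
  contrast <- mean(gval[cls$class == "full_sib"]) -
    mean(gval[cls$class == "unrelated"])
  expect_lt(abs(contrast - 0.5), 0.1)
})

test_that("phenotype construction honours the target heritability model", {
  # noiseless trait: phenotype rank order equals TBV rank order per block
  ts <- default_trait_specs()[1, ]
  ts$h2 <- 1
  cfg <- sim_config(n_parents = 6, n_families = 6, progeny_per_family = 12,
                    n_progeny_total = 72, n_markers = 300, n_qtl = 40,
                    trait_specs = ts)
  pop <- simulate_population(cfg, seed = 7)
  ph <- pop$phenotypes
  tbv <- pop$tbv[ph$tree, "height"]
  for (b in unique(ph$block)) {
    ix <- ph$block == b
    expect_equal(order(ph$height[ix]), order(tbv[ix]))
  }
  # determinism: identical seed, identical population
  pop2 <- simulate_population(cfg, seed = 7)
  expect_identical(pop$phenotypes, pop2$phenotypes)
  expect_identical(pop$genotypes, pop2$genotypes)

  expect_error(sim_config(trait_specs = transform(ts, h2 = 0)), "h2")
})

test_that("population dimensions and missingness match the configuration", {
  pop <- tiny_pop()
  cfg <- pop$config
  expect_equal(nrow(pop$genotypes), cfg$n_progeny_total)
  expect_equal(ncol(pop$genotypes), cfg$n_markers)
  expect_equal(nrow(pop$pedigree), cfg$n_parents + cfg$n_progeny_total)
  miss <- mean(is.na(pop$genotypes))
  expect_lt(abs(miss - cfg$missing_rate), 0.005)
  # every progeny's parents exist
  prog <- pop$pedigree[!is.na(pop$pedigree$sire), ]
  expect_true(all(prog$sire %in% pop$pedigree$id))
  expect_true(all(prog$dam %in% pop$pedigree$id))
})
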