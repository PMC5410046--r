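test_that("family-stratified folds partition individuals evenly", {
  fam <- rep(sprintf("F%02d", 1:34), each = 20)
  ids <- paste0(fam, "_", 1:20)
  folds <- make_cv_folds(ids, fam, k = 10, seed = 2)
  # partition: every individual in exactly one fold
  expect_setequal(names(folds), ids)
  expect_equal(unname(table(folds)), rep(68, 10), ignore_attr = TRUE)
  # each family contributes 2 members per fold
  per_fam <- table(fam, folds)
  expect_true(all(per_fam == 2))
  # determinism
  expect_identical(folds, make_cv_folds(ids, fam, k = 10, seed = 2))
  expect_false(identical(folds, make_cv_folds(ids, fam, k = 10, seed = 3)))
  # degenerate single fold is flagged
  expect_warning(make_cv_folds(ids[1:5], fam[1:5], k = 1), "coincide")
  # families smaller than k spread over distinct folds
  f2 <- make_cv_folds(ids[1:6], fam[1:6], k = 10, seed = 1)
  expect_equal(anyDuplicated(f2), 0)
})

test_that("accuracy and predictive ability follow the Pearson definitions", {
  pred <- data.frame(tree = letters[1:10], fold = rep(1:2, each = 5),
                     pred = c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3),
                     yhat_raw = c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3))
  ref <- stats::setNames(c(2, 1, 3, 2, 6, 8, 1, 7, 4, 2), letters[1:10])
  ph <- data.frame(tree = letters[1:10],
                   y = c(2.5, 0.5, 3.5, 1.5, 5.5, 8.5, 1.5, 6.5, 4.5, 2.5))
  res <- accuracy_and_predictive_ability(pred, ref, ph, "y")
  # frozen five-point Pearson values, computed by the correlation formula
  r1 <- stats::cor(pred$pred[1:5], ref[letters[1:5]])
  r2 <- stats::cor(pred$pred[6:10], ref[letters[6:10]])
  expect_equal(res$per_fold$accuracy, c(r1, r2))
  expect_equal(res$accuracy, mean(c(r1, r2)))
  expect_equal(res$accuracy_error, stats::sd(c(r1, r2)))

  # identities and sign
  pred_id <- data.frame(tree = letters[1:10], fold = 1,
                        pred = unname(ref), yhat_raw = unname(ref))
  expect_equal(accuracy_and_predictive_ability(pred_id, ref)$accuracy, 1)
  pred_neg <- transform(pred_id, pred = -pred)
  expect_equal(accuracy_and_predictive_ability(pred_neg, ref)$accuracy, -1)
  # zero-variance predictions flagged as NA
  pred0 <- transform(pred_id, pred = 1)
  expect_true(is.na(accuracy_and_predictive_ability(pred0, ref)$accuracy))
})

test_that("out-of-fold marker predictions never see validation phenotypes", {
  md <- mid_data()
  data <- md$data
  ph <- data$phenotypes
  folds <- make_cv_folds(ph$tree, ph$family, k = 5, seed = 3)
  val1 <- names(folds)[folds == 1]
  p1 <- cross_validate(data, "markers", folds, fast = TRUE)
  # permute validation-fold phenotypes: training data unchanged
  data2 <- data
  ix <- match(val1, data2$phenotypes$tree)
  set.seed(1)
  data2$phenotypes[[data2$trait]][ix] <-
    sample(data2$phenotypes[[data2$trait]][ix])
  p2 <- cross_validate(data2, "markers", folds, fast = TRUE)
  g1 <- p1$pred[p1$fold == 1][match(val1, p1$tree[p1$fold == 1])]
  g2 <- p2$pred[p2$fold == 1][match(val1, p2$tree[p2$fold == 1])]
  expect_equal(g1, g2)
  # and every individual is predicted exactly once
  expect_setequal(p1$tree, ph$tree)
  expect_equal(anyDuplicated(p1$tree), 0)
})

test_that("cross-validation recovers strong signal and rejects pure noise", {
  # noiseless trait: genomic prediction close to perfect
  ts <- default_trait_specs()[1, ]
  ts$h2 <- 0.999
  cfg <- sim_config(n_parents = 12, n_families = 20,
                    progeny_per_family = 24, n_progeny_total = 480,
                    n_markers = 300, n_qtl = 100, missing_rate = 0,
                    trait_specs = ts)
  pop <- simulate_population(cfg, seed = 71)
  data <- prepare_gs_data(pop, "height",
                          gibbs = gibbs_config(4000, 800, 80, seed = 3))
  folds <- make_cv_folds(pop$phenotypes$tree, pop$phenotypes$family, 10, 4)
  pr <- cross_validate(data, "markers", folds, fast = TRUE)
  tbv <- pop$tbv[pop$phenotypes$tree, "height"]
  names(tbv) <- pop$phenotypes$tree
  acc_tbv <- accuracy_and_predictive_ability(pr, tbv)
  expect_gt(acc_tbv$pooled_accuracy, 0.95)

  # pure noise: permuted phenotypes give near-zero accuracy
  md <- mid_data()
  data2 <- md$data
  set.seed(9)
  data2$phenotypes[[data2$trait]] <- sample(data2$phenotypes[[data2$trait]])
  data2$ratios$lambda_marker <- md$data$ratios$lambda_marker
  folds2 <- make_cv_folds(data2$phenotypes$tree, data2$phenotypes$family,
                          10, 5)
  pr2 <- cross_validate(data2, "markers", folds2, fast = TRUE)
  tbv2 <- md$pop$tbv[data2$phenotypes$tree, "height"]
  names(tbv2) <- data2$phenotypes$tree
  expect_lt(abs(accuracy_and_predictive_ability(pr2,
                                                tbv2)$pooled_accuracy),
            0.1)
})

test_that("site schemes validate within, across, and on matched subsets", {
  md <- mid_data()
  data <- md$data
  # single-site CV
  a1 <- scenario_sites(data, "single", "markers", site = "S1", k = 5,
                       seed = 2)
  expect_true(is.finite(a1$accuracy))
  # cross-site: trained on S1, validated on every S2 tree
  a2 <- scenario_sites(data, "cross", "markers", site = "S1", seed = 2)
  expect_true(is.finite(a2$pooled_accuracy))
  # the simulator draws no genotype-by-site interaction, so cross-site
  # accuracy stays in the same regime as within-site accuracy
  expect_gt(a2$pooled_accuracy, a1$accuracy - 0.2)
  # site_mean truncates oversized subsets with a flag
  expect_warning(
    scenario_sites(data, "site_mean", "markers", subset_size = 10000,
                   n_rep = 1, k = 5, seed = 2), "exceeds")
  expect_error(scenario_sites(data, "single", site = "nope"), "unknown")
})

test_that("half-sib split yields only half-sib cross-set links", {
  md <- mid_data()
  ped <- md$data$pedigree
  sp <- scenario_half_sib(ped, seed = 4)
  expect_gt(length(sp$train), 0)
  expect_gt(length(sp$validation), 0)
  expect_length(intersect(sp$train, sp$validation), 0)
  # audit with classify_pairs: no full sib spans the two sets
  cls <- classify_pairs(ped, ids = c(sp$train, sp$validation),
                        A = md$data$A)
  cross <- (cls$id1 %in% sp$train) != (cls$id2 %in% sp$train)
  expect_false(any(cls$class[cross] == "full_sib"))
  # the scheme's point: half-sib links across the sets exist
  expect_gt(sum(cls$class[cross] == "half_sib"), 0)
  # determinism
  sp2 <- scenario_half_sib(ped, seed = 4)
  expect_identical(sp, sp2)
})

test_that("unrelated split severs all pedigree relationships", {
  md <- mid_data()
  ped <- md$data$pedigree
  sp <- scenario_unrelated(ped, seed = 6)
  expect_gt(length(sp$validation), 0)
  A <- md$data$A
  cross <- A[sp$validation, sp$train]
  expect_equal(max(abs(cross)), 0)
  # single provenance: impossible
  ped1 <- ped
  ped1$provenance[is.na(ped1$sire)] <- "PR1"
  expect_error(scenario_unrelated(ped1), "provenances")
})

test_that("marker subsets honour modes, determinism and partition", {
  markers <- sprintf("M%04d", 1:500)
  eff <- stats::setNames(stats::rnorm(500), markers)
  # identity
  expect_setequal(marker_subset(markers, "random_k", k = 500), markers)
  # determinism
  s1 <- marker_subset(markers, "random_k", k = 100, seed = 7)
  expect_identical(s1, marker_subset(markers, "random_k", k = 100,
                                     seed = 7))
  # top + complement partition the panel
  top <- marker_subset(markers, "top_abs_k", k = 50, effects = eff)
  rest <- marker_subset(markers, "complement_top_k", k = 50,
                        effects = eff)
  expect_length(intersect(top, rest), 0)
  expect_setequal(c(top, rest), markers)
  expect_true(min(abs(eff[top])) >= max(abs(eff[rest])))
  # linkage-group subset
  map <- data.frame(marker = markers,
                    linkage_group = rep(1:5, each = 100),
                    position_cM = 1:100)
  lg3 <- marker_subset(markers, "linkage_group", map = map, group = 3)
  expect_setequal(lg3, markers[201:300])
  expect_error(marker_subset(markers, "random_k", k = 600), "exceeds")
})

test_that("training-size series runs and small subsets stay evaluable", {
  md <- mid_data()
  res <- training_size_series(md$data, c(420, 120),
                              model_kinds = "markers", k = 5, seed = 11,
                              reestimate = "none")
  expect_equal(nrow(res), 2)
  expect_true(all(is.finite(res$accuracy)))
  expect_error(training_size_series(md$data, 5, k = 5), "2k")
})

test_that("relatedness scenarios order accuracies as expected", {
  md <- mid_data()
  data <- md$data
  ph <- data$phenotypes
  folds <- make_cv_folds(ph$tree, ph$family, 10, 8)
  full <- accuracy_and_predictive_ability(
    cross_validate(data, "markers", folds, fast = TRUE),
    data$reference, ph, data$trait)
  half <- evaluate_split(data, scenario_half_sib(data$pedigree, seed = 8),
                         "markers")
  unrel <- evaluate_split(data, scenario_unrelated(data$pedigree,
                                                   seed = 8), "markers")
  expect_gt(full$accuracy, half$pooled_accuracy)
  expect_gt(half$pooled_accuracy, unrel$pooled_accuracy)
})
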