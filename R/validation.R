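#' Family-stratified cross-validation folds
#'
#' Shuffles members within each family and deals them round-robin into `k`
#' folds, so every fold draws about `1/k` of every family and each
#' individual sits in exactly one validation set. Families smaller than `k`
#' spread over distinct folds. `k = 1` (training = validation) is allowed
#' but flagged with a warning.
#'
#' @param ids individual ids.
#' @param family family label per individual.
#' @param k number of folds.
#' @param seed integer seed.
#' @return named integer vector of fold assignments (1..k).
#' @export
make_cv_folds <- function(ids, family, k = 10, seed = 1) {
  stopifnot(length(ids) == length(family), k >= 1)
  if (k == 1) warning("k = 1: training and validation sets coincide")
  set.seed(seed)
  fold <- integer(length(ids))
  names(fold) <- ids
  for (f in unique(family)) {
    idx <- which(family == f)
    idx <- idx[sample.int(length(idx))]
    start <- sample.int(k, 1)
    fold[idx] <- 1 + (start - 1 + seq_along(idx) - 1) %% k
  }
  fold
}

# Estimate variance ratios for fast (deterministic) refits from one Gibbs
# fit on the supplied data.
.estimate_ratios <- function(data, trait, gibbs) {
  af <- fit_animal_model(data$phenotypes, data$pedigree, trait,
                         gibbs = gibbs, A = data$A)
  std <- standardize_phenotypes(data$phenotypes[[trait]],
                                data$phenotypes$site,
                                data$phenotypes$block)
  Z <- data$Z[data$phenotypes$tree, , drop = FALSE]
  mf <- fit_marker_model(std$values, Z, gibbs = gibbs, sum2pq = data$sum2pq)
  list(animal = af$varcomp,
       lambda_marker = mf$varcomp$sigma2_e / mf$varcomp$sigma2_a,
       animal_fit = af, marker_fit = mf)
}

#' Assemble an analysis dataset for cross-validation and scenarios
#'
#' Bundles the pieces every validation scheme needs: phenotypes, pedigree,
#' imputed marker covariates, the relationship matrix and reference EBVs.
#' Reference breeding values are estimated once from ALL trees with the
#' animal model; cross-validated predictions are correlated against them.
#'
#' @param population a `sim_population` (or a compatible list with
#'   `phenotypes`, `pedigree`, `genotypes`, `map`).
#' @param trait trait column to analyse.
#' @param gibbs chain settings for the reference fit and ratio estimation.
#' @param thresholds QC thresholds applied before imputation.
#' @return list of class `gs_data` with `phenotypes`, `pedigree`, `A`, `Z`
#'   (coded covariates, all progeny), `sum2pq`, `reference` (named EBVs),
#'   `ratios` (variance components / shrinkage for deterministic refits),
#'   `reference_fit`, `marker_fit_full`.
#' @export
prepare_gs_data <- function(population, trait, gibbs = gibbs_config(),
                            thresholds = qc_thresholds()) {
  ped <- build_pedigree(population$pedigree)
  qc <- apply_qc(orient_minor(population$genotypes)$genotypes, thresholds)
  Gi <- impute_missing(qc$genotypes)
  Z <- incidence_covariates(Gi)
  A <- numerator_relationship_matrix(ped)
  data <- list(phenotypes = population$phenotypes, pedigree = ped, A = A,
               Z = Z, sum2pq = sum_2pq(Gi), trait = trait,
               map = population$map, qc_report = qc$report)
  est <- .estimate_ratios(data, trait, gibbs)
  data$ratios <- list(animal = est$animal,
                      lambda_marker = est$lambda_marker)
  data$reference_fit <- est$animal_fit
  data$marker_fit_full <- est$marker_fit
  data$reference <- est$animal_fit$u
  class(data) <- c("gs_data", "list")
  data
}

# Fit on a training subset and predict a validation subset, for one model
# kind. Used by cross_validate and the single-split scenarios.
# Marker kind: standardization fitted on training only; GEBV = Z' alpha.
# Pedigree kind: animal model refit with validation phenotypes masked; the
# masked trees' breeding values are predicted through A (for the
# two-generation diallel this is the parental-average projection).
.fit_predict <- function(data, model_kind, train_ids, pred_ids,
                         gibbs, fast, markers = NULL) {
  ph <- data$phenotypes
  trait <- data$trait
  if (model_kind == "markers") {
    tr <- ph[ph$tree %in% train_ids, , drop = FALSE]
    std <- standardize_phenotypes(tr[[trait]], tr$site, tr$block)
    Z <- data$Z
    if (!is.null(markers)) Z <- Z[, markers, drop = FALSE]
    Ztr <- Z[tr$tree, , drop = FALSE]
    if (fast) {
      fit <- fit_marker_model(std$values, Ztr, method = "blup",
                              lambda = data$ratios$lambda_marker)
    } else {
      fit <- fit_marker_model(std$values, Ztr, gibbs = gibbs)
    }
    pred <- predict_gebv(fit, Z[pred_ids, , drop = FALSE])
    pv <- ph[match(pred_ids, ph$tree), , drop = FALSE]
    yhat_std <- fit$mu + pred
    yhat_raw <- destandardize(std, yhat_std, pv$site, pv$block)
    list(pred = pred, yhat_std = yhat_std, yhat_raw = yhat_raw, fit = fit,
         std = std)
  } else {
    masked <- ph
    masked[[trait]][!(masked$tree %in% train_ids)] <- NA
    if (fast) {
      fit <- fit_animal_model(masked, data$pedigree, trait,
                              method = "blup",
                              varcomp = data$ratios$animal, A = data$A)
    } else {
      fit <- fit_animal_model(masked, data$pedigree, trait, gibbs = gibbs,
                              A = data$A)
    }
    pred <- fit$u[pred_ids]
    pv <- ph[match(pred_ids, ph$tree), , drop = FALSE]
    # fixed-effect part using the fit's own site levels; sites unseen in
    # training fall back to the reference-level (intercept) estimate
    site_f <- factor(pv$site, levels = fit$site_levels)
    Xp <- matrix(0, nrow(pv), length(fit$beta))
    Xp[, 1] <- 1
    if (length(fit$site_levels) > 1) {
      ix <- as.integer(site_f) - 1L
      sel <- !is.na(ix) & ix >= 1L
      Xp[cbind(which(sel), 1L + ix[sel])] <- 1
    }
    blk_eff <- fit$block_effects[pv$block]
    blk_eff[is.na(blk_eff)] <- 0
    yhat_raw <- as.numeric(Xp %*% fit$beta) + blk_eff + pred
    list(pred = pred, yhat_std = pred, yhat_raw = yhat_raw, fit = fit)
  }
}

#' K-fold cross-validation of breeding-value prediction
#'
#' For each fold, the model is trained on the complement and the fold's
#' trees are predicted: the marker model through their coded genotypes
#' (standardization fitted on training trees only), the pedigree model by
#' refitting the animal model with the fold's phenotypes masked so its
#' breeding values flow only through the relationship matrix. Out-of-fold
#' predictions cover every individual exactly once.
#'
#' @param data a [prepare_gs_data()] bundle.
#' @param model_kind `"markers"` or `"pedigree"`.
#' @param folds fold assignment from [make_cv_folds()] (names = tree ids).
#' @param gibbs chain settings for per-fold Gibbs refits.
#' @param fast if TRUE (default) per-fold fits are deterministic BLUP
#'   solves reusing the full-data variance ratios; if FALSE variance
#'   components are re-estimated by Gibbs in every fold.
#' @param markers optional marker-id subset (marker model only).
#' @return data frame `tree`, `fold`, `pred` (breeding value),
#'   `yhat_raw` (predicted phenotype on the trait scale).
#' @export
cross_validate <- function(data, model_kind = c("markers", "pedigree"),
                           folds, gibbs = gibbs_config(), fast = TRUE,
                           markers = NULL) {
  model_kind <- match.arg(model_kind)
  ids <- names(folds)
  stopifnot(all(ids %in% data$phenotypes$tree))
  out <- NULL
  for (k in sort(unique(folds))) {
    val <- ids[folds == k]
    train <- ids[folds != k]
    if (!length(train)) {
      if (length(unique(folds)) == 1) train <- val  # degenerate k = 1
      else stop("fold with zero training data", call. = FALSE)
    }
    fp <- .fit_predict(data, model_kind, train, val, gibbs, fast, markers)
    out <- rbind(out, data.frame(tree = val, fold = k,
                                 pred = as.numeric(fp$pred),
                                 yhat_raw = fp$yhat_raw,
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Accuracy and predictive ability of cross-validated predictions
#'
#' Accuracy is the Pearson correlation between predicted and reference
#' breeding values; predictive ability is the Pearson correlation between
#' predicted and observed phenotypes. Both are computed per fold (mean and
#' SD across folds reported as the error) and pooled over all
#' out-of-fold predictions.
#'
#' @param predictions data frame from [cross_validate()] (columns `tree`,
#'   `fold`, `pred`, optionally `yhat_raw`).
#' @param reference named vector of reference EBVs.
#' @param phenotypes optional data frame with `tree` and the trait column
#'   for predictive ability.
#' @param trait trait column name in `phenotypes`.
#' @return list of class `accuracy_result`: `accuracy`, `accuracy_error`,
#'   `predictive_ability`, `pa_error`, `pooled_accuracy`, `pooled_pa`,
#'   `per_fold`.
#' @export
accuracy_and_predictive_ability <- function(predictions, reference,
                                            phenotypes = NULL,
                                            trait = NULL) {
  stopifnot(all(predictions$tree %in% names(reference)))
  ref <- reference[predictions$tree]
  obs <- if (!is.null(phenotypes) && !is.null(trait))
    phenotypes[[trait]][match(predictions$tree, phenotypes$tree)] else NULL
  safe_cor <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0)
      return(NA_real_)
    stats::cor(a, b)
  }
  per_fold <- do.call(rbind, lapply(split(seq_len(nrow(predictions)),
                                          predictions$fold), function(ix) {
    data.frame(
      fold = predictions$fold[ix[1]],
      accuracy = safe_cor(predictions$pred[ix], ref[ix]),
      predictive_ability = if (is.null(obs)) NA_real_ else
        safe_cor(predictions$yhat_raw[ix], obs[ix]))
  }))
  rownames(per_fold) <- NULL
  structure(list(
    accuracy = mean(per_fold$accuracy, na.rm = TRUE),
    accuracy_error = stats::sd(per_fold$accuracy),
    predictive_ability = mean(per_fold$predictive_ability, na.rm = TRUE),
    pa_error = stats::sd(per_fold$predictive_ability),
    pooled_accuracy = safe_cor(predictions$pred, ref),
    pooled_pa = if (is.null(obs)) NA_real_ else
      safe_cor(predictions$yhat_raw, obs),
    per_fold = per_fold), class = "accuracy_result")
}

#' Site-specific validation schemes
#'
#' `single`: k-fold CV restricted to one site's trees. `cross`: train on
#' all trees of one site, validate on all trees of the other.
#' `site_mean`: mean over `n_rep` replicate models, each a k-fold CV on a
#' random subset of `subset_size` trees (matching the mean per-site sample
#' size); subsets larger than the population are truncated with a flag.
#'
#' @param data a [prepare_gs_data()] bundle.
#' @param mode `"single"`, `"cross"` or `"site_mean"`.
#' @param model_kind `"markers"` or `"pedigree"`.
#' @param site training site label (single / cross).
#' @param validation_site validation site for `cross` (default: the other
#'   site).
#' @param subset_size,n_rep for `site_mean` (defaults 359 and 5).
#' @param k folds for CV-based modes.
#' @param seed integer seed.
#' @param gibbs,fast passed to [cross_validate()].
#' @return an `accuracy_result` (with `per_rep` attached for `site_mean`).
#' @export
scenario_sites <- function(data, mode = c("single", "cross", "site_mean"),
                           model_kind = "markers", site = NULL,
                           validation_site = NULL, subset_size = 359,
                           n_rep = 5, k = 10, seed = 1,
                           gibbs = gibbs_config(), fast = TRUE) {
  mode <- match.arg(mode)
  ph <- data$phenotypes
  sites <- sort(unique(ph$site))
  if (!is.null(site) && !site %in% sites)
    stop("unknown site id: ", site, call. = FALSE)
  if (mode == "single") {
    sub <- ph[ph$site == site, ]
    if (!nrow(sub)) stop("site has no trees", call. = FALSE)
    folds <- make_cv_folds(sub$tree, sub$family, k, seed)
    pred <- cross_validate(data, model_kind, folds, gibbs, fast)
    accuracy_and_predictive_ability(pred, data$reference, ph, data$trait)
  } else if (mode == "cross") {
    if (length(sites) < 2) stop("cross mode needs >= 2 sites", call. = FALSE)
    if (is.null(validation_site))
      validation_site <- setdiff(sites, site)[1]
    train <- ph$tree[ph$site == site]
    val <- ph$tree[ph$site == validation_site]
    if (!length(train) || !length(val))
      stop("site has no trees", call. = FALSE)
    fp <- .fit_predict(data, model_kind, train, val, gibbs, fast)
    pred <- data.frame(tree = val, fold = 1, pred = as.numeric(fp$pred),
                       yhat_raw = fp$yhat_raw, stringsAsFactors = FALSE)
    accuracy_and_predictive_ability(pred, data$reference, ph, data$trait)
  } else {
    n_total <- nrow(ph)
    if (subset_size > n_total) {
      warning("subset_size exceeds population; using all trees")
      subset_size <- n_total
    }
    reps <- lapply(seq_len(n_rep), function(r) {
      set.seed(seed + r)
      take <- .stratified_subsample(ph$tree, ph$family, subset_size)
      sub <- ph[ph$tree %in% take, ]
      folds <- make_cv_folds(sub$tree, sub$family, k, seed + r)
      pred <- cross_validate(data, model_kind, folds, gibbs, fast)
      accuracy_and_predictive_ability(pred, data$reference, ph, data$trait)
    })
    out <- reps[[1]]
    out$accuracy <- mean(vapply(reps, `[[`, 0, "accuracy"))
    out$accuracy_error <- stats::sd(vapply(reps, `[[`, 0, "accuracy"))
    out$predictive_ability <- mean(vapply(reps, `[[`, 0,
                                          "predictive_ability"))
    out$pa_error <- stats::sd(vapply(reps, `[[`, 0, "predictive_ability"))
    attr(out, "per_rep") <- reps
    out
  }
}

# Family-stratified subsample of approximately n ids.
.stratified_subsample <- function(ids, family, n) {
  frac <- n / length(ids)
  take <- unlist(lapply(split(ids, family), function(v) {
    v <- v[sample.int(length(v))]
    v[seq_len(max(1, round(frac * length(v))))]
  }), use.names = FALSE)
  if (length(take) > n) take <- sample(take, n)
  take
}

#' Half-sib train/validation split
#'
#' Partitions full-sib families so training and validation sets share
#' single parents but no full-sib family spans both sets: cross-set pairs
#' related through a shared parent are half-sibs. Families are assigned
#' greedily in seeded random order, each to the side that its parents'
#' current coverage lacks (then to the smaller side); parents present in a
#' single family only cannot support the scheme, their families lean to
#' training (flagged).
#'
#' @param pedigree a [build_pedigree()] result (two-generation diallel).
#' @param seed integer seed.
#' @return list with `train`, `validation` (tree ids), `train_families`,
#'   `validation_families`, `flags`.
#' @export
scenario_half_sib <- function(pedigree, seed = 1) {
  if (!inherits(pedigree, "pedigree")) pedigree <- build_pedigree(pedigree)
  set.seed(seed)
  prog <- pedigree[!is.na(pedigree$family), ]
  fams <- unique(prog[, c("family", "sire", "dam")])
  fams <- fams[sample.int(nrow(fams)), ]
  side <- stats::setNames(rep(NA_character_, nrow(fams)), fams$family)
  parent_sides <- list()
  flags <- character(0)
  fam_count <- table(c(fams$sire, fams$dam))
  for (i in seq_len(nrow(fams))) {
    par <- c(fams$sire[i], fams$dam[i])
    want <- character(0)
    for (p in par) {
      seen <- parent_sides[[p]]
      if (fam_count[p] > 1 && !is.null(seen)) {
        lack <- setdiff(c("train", "validation"), seen)
        want <- c(want, lack)
      }
    }
    pick <- if (length(want)) names(sort(table(want),
                                         decreasing = TRUE))[1]
            else c("train", "validation")[
              1 + (sum(side == "validation", na.rm = TRUE) <
                     sum(side == "train", na.rm = TRUE))]
    side[fams$family[i]] <- pick
    for (p in par)
      parent_sides[[p]] <- union(parent_sides[[p]], pick)
  }
  single <- names(fam_count)[fam_count == 1]
  if (length(single))
    flags <- c(flags, paste0("parent(s) in one family only: ",
                             paste(single, collapse = ",")))
  tf <- names(side)[side == "train"]
  vf <- names(side)[side == "validation"]
  list(train = prog$id[prog$family %in% tf],
       validation = prog$id[prog$family %in% vf],
       train_families = tf, validation_families = vf, flags = flags)
}

#' Unrelated train/validation split
#'
#' Validation families share no parent and no provenance with training
#' families: whole provenances are held out, families both of whose parents
#' sit in held-out provenances validate, families with no parent there
#' train, and straddling families are dropped. Cross-set additive
#' relationships are all zero.
#'
#' @param pedigree a [build_pedigree()] result with provenance labels.
#' @param seed integer seed.
#' @param target_fraction approximate fraction of trees to hold out.
#' @return list with `train`, `validation`, `validation_provenances`,
#'   `dropped_families`.
#' @export
scenario_unrelated <- function(pedigree, seed = 1, target_fraction = 0.15) {
  if (!inherits(pedigree, "pedigree")) pedigree <- build_pedigree(pedigree)
  set.seed(seed)
  founders <- pedigree[is.na(pedigree$sire), ]
  if (all(is.na(founders$provenance)) ||
      length(unique(stats::na.omit(founders$provenance))) < 2)
    stop("need >= 2 parental provenances to form an unrelated split",
         call. = FALSE)
  prog <- pedigree[!is.na(pedigree$family), ]
  fams <- unique(prog[, c("family", "sire", "dam")])
  prov_of <- stats::setNames(founders$provenance, founders$id)
  provs <- sample(unique(stats::na.omit(founders$provenance)))
  n_total <- nrow(prog)
  held <- character(0)
  for (pv in provs) {
    cand <- c(held, pv)
    vf <- fams$family[prov_of[fams$sire] %in% cand &
                        prov_of[fams$dam] %in% cand]
    if (sum(prog$family %in% vf) >= target_fraction * n_total) {
      held <- cand
      break
    }
    held <- cand
  }
  vf <- fams$family[prov_of[fams$sire] %in% held &
                      prov_of[fams$dam] %in% held]
  tf <- fams$family[!(prov_of[fams$sire] %in% held) &
                      !(prov_of[fams$dam] %in% held)]
  dropped <- setdiff(fams$family, c(vf, tf))
  if (!length(vf) || !length(tf))
    stop("could not separate unrelated families and provenances",
         call. = FALSE)
  list(train = prog$id[prog$family %in% tf],
       validation = prog$id[prog$family %in% vf],
       validation_provenances = held, dropped_families = dropped)
}

#' Evaluate a single train/validation split
#'
#' Fits on the training trees, predicts the validation trees, and reports
#' accuracy against the reference EBVs (single split, no folds).
#'
#' @param data a [prepare_gs_data()] bundle.
#' @param split list with `train` and `validation` id vectors.
#' @param model_kind `"markers"` or `"pedigree"`.
#' @param gibbs,fast passed to the underlying fit.
#' @return an `accuracy_result`.
#' @export
evaluate_split <- function(data, split, model_kind = "markers",
                           gibbs = gibbs_config(), fast = TRUE) {
  fp <- .fit_predict(data, model_kind, split$train, split$validation,
                     gibbs, fast)
  pred <- data.frame(tree = split$validation, fold = 1,
                     pred = as.numeric(fp$pred), yhat_raw = fp$yhat_raw,
                     stringsAsFactors = FALSE)
  accuracy_and_predictive_ability(pred, data$reference, data$phenotypes,
                                  data$trait)
}

#' Marker subsets for reduced-panel models
#'
#' `random_k`: k markers drawn at random. `top_abs_k`: the k markers with
#' the largest absolute estimated effects (ties broken by marker id).
#' `complement_top_k`: the full panel minus `top_abs_k`. `linkage_group`:
#' all mapped markers of one linkage group.
#'
#' @param markers full marker id vector.
#' @param mode subset mode.
#' @param k subset size (random / top / complement).
#' @param effects named effect vector (required for top/complement).
#' @param map marker map data frame (required for linkage_group).
#' @param group linkage group id.
#' @param seed integer seed for `random_k`.
#' @return character vector of marker ids.
#' @export
marker_subset <- function(markers, mode = c("random_k", "top_abs_k",
                                            "complement_top_k",
                                            "linkage_group"),
                          k = NULL, effects = NULL, map = NULL,
                          group = NULL, seed = 1) {
  mode <- match.arg(mode)
  if (mode %in% c("random_k", "top_abs_k", "complement_top_k")) {
    stopifnot(!is.null(k))
    if (k > length(markers))
      stop("k exceeds available markers", call. = FALSE)
  }
  if (mode == "random_k") {
    set.seed(seed)
    return(sort(sample(markers, k)))
  }
  if (mode %in% c("top_abs_k", "complement_top_k")) {
    if (is.null(effects)) stop("effects required", call. = FALSE)
    eff <- effects[markers]
    ord <- order(-abs(eff), names(eff))
    top <- markers[ord][seq_len(k)]
    if (mode == "top_abs_k") return(sort(top))
    return(sort(setdiff(markers, top)))
  }
  if (is.null(map) || is.null(group))
    stop("map and group required", call. = FALSE)
  sort(intersect(markers, map$marker[map$linkage_group == group]))
}

#' Training-set size series
#'
#' For each requested size, draws a family-stratified subsample, runs the
#' full k-fold CV pipeline on it for the requested model kinds, and reports
#' accuracy (against the full-data reference EBVs) with its fold error.
#'
#' @param data a [prepare_gs_data()] bundle.
#' @param sizes vector of subset sizes (<= total trees).
#' @param model_kinds model kinds to run.
#' @param k folds.
#' @param seed integer seed.
#' @param gibbs chain settings for variance re-estimation.
#' @param reestimate how variance components are obtained at each size:
#'   `"per_fold"` (default) re-runs the Gibbs sampler in every training
#'   fold, as in the basic validation scheme, so small training sets carry
#'   their full variance-estimation uncertainty into the predictions;
#'   `"per_size"` runs one chain per subset and solves the folds
#'   deterministically at those ratios; `"none"` reuses the full-data
#'   ratios throughout (fastest, but shields small subsets from estimation
#'   noise).
#' @return data frame: `size`, `model_kind`, `accuracy`, `accuracy_error`,
#'   `predictive_ability`, `pa_error`.
#' @export
training_size_series <- function(data, sizes, model_kinds = c("markers",
                                                              "pedigree"),
                                 k = 10, seed = 1,
                                 gibbs = gibbs_config(),
                                 reestimate = c("per_fold", "per_size",
                                                "none")) {
  reestimate <- match.arg(reestimate)
  ph <- data$phenotypes
  stopifnot(all(sizes <= nrow(ph)))
  if (any(sizes < 2 * k))
    stop("smallest size must be at least 2k", call. = FALSE)
  out <- NULL
  for (s in sizes) {
    set.seed(seed + s)
    take <- if (s == nrow(ph)) ph$tree else
      .stratified_subsample(ph$tree, ph$family, s)
    sub <- ph[ph$tree %in% take, ]
    folds <- make_cv_folds(sub$tree, sub$family, k, seed + s)
    dat_s <- data
    if (reestimate == "per_size") {
      std <- standardize_phenotypes(sub[[data$trait]], sub$site, sub$block)
      mf <- fit_marker_model(std$values, data$Z[sub$tree, , drop = FALSE],
                             gibbs = gibbs)
      dat_s$ratios$lambda_marker <- mf$varcomp$sigma2_e /
        mf$varcomp$sigma2_a
      if ("pedigree" %in% model_kinds) {
        masked <- ph
        masked[[data$trait]][!(masked$tree %in% sub$tree)] <- NA
        af <- fit_animal_model(masked, data$pedigree, data$trait,
                               gibbs = gibbs, A = data$A)
        dat_s$ratios$animal <- af$varcomp
      }
    }
    for (mk in model_kinds) {
      pred <- cross_validate(dat_s, mk, folds, gibbs,
                             fast = (reestimate != "per_fold"))
      acc <- accuracy_and_predictive_ability(pred, data$reference, ph,
                                             data$trait)
      out <- rbind(out, data.frame(size = s, model_kind = mk,
                                   accuracy = acc$accuracy,
                                   accuracy_error = acc$accuracy_error,
                                   predictive_ability =
                                     acc$predictive_ability,
                                   pa_error = acc$pa_error))
    }
  }
  rownames(out) <- NULL
  out
}
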