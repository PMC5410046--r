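#!/usr/bin/env Rscript
# Step 4: the factors affecting genomic prediction accuracy: relatedness
# between training and validation sets (full-sib CV vs half-sib split vs
# unrelated provenances), marker subsets (random panels, largest-effect
# panel, per-linkage-group panels), and the training-set size ladder.

library(sprucegs)

seed <- 2026
data <- readRDS("scratch/gs_data.rds")
ph <- data$phenotypes
folds <- make_cv_folds(ph$tree, ph$family, 10, seed)

message("Relatedness scenarios ...")
full <- accuracy_and_predictive_ability(
  cross_validate(data, "markers", folds, fast = TRUE),
  data$reference, ph, data$trait)
half <- evaluate_split(data, scenario_half_sib(data$pedigree, seed = seed),
                       "markers")
unrel <- evaluate_split(data, scenario_unrelated(data$pedigree,
                                                 seed = seed), "markers")
rel <- data.frame(scenario = c("full_sib_cv", "half_sib", "unrelated"),
                  accuracy = c(full$accuracy, half$pooled_accuracy,
                               unrel$pooled_accuracy))
print(rel, digits = 2)
write.table(rel, "results/relatedness.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

message("Marker subsets ...")
mall <- colnames(data$Z)
eff <- data$marker_fit_full$alpha
acc_sub <- function(mk) accuracy_and_predictive_ability(
  cross_validate(data, "markers", folds, fast = TRUE, markers = mk),
  data$reference, ph, data$trait)$accuracy
subsets <- list(
  full = NULL,
  random_1000 = marker_subset(mall, "random_k", k = 1000, seed = seed),
  random_500 = marker_subset(mall, "random_k", k = 500, seed = seed),
  random_250 = marker_subset(mall, "random_k", k = 250, seed = seed),
  top_250 = marker_subset(mall, "top_abs_k", k = 250, effects = eff),
  remaining = marker_subset(mall, "complement_top_k", k = 250,
                            effects = eff))
sub <- data.frame(subset = names(subsets),
                  n_markers = sapply(subsets, function(x)
                    if (is.null(x)) length(mall) else length(x)),
                  accuracy = sapply(subsets, acc_sub))
# per-linkage-group models
lg_acc <- sapply(sort(unique(data$map$linkage_group)), function(g)
  acc_sub(marker_subset(mall, "linkage_group", map = data$map, group = g)))
sub <- rbind(sub, data.frame(subset = sprintf("LG%02d",
                                              sort(unique(
                                                data$map$linkage_group))),
                             n_markers = NA, accuracy = lg_acc))
print(sub, digits = 2)
write.table(sub, "results/marker_subsets.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

message("Training-size ladder (per-fold variance re-estimation) ...")
sizes <- c(nrow(ph), 490, 330, 224, 147, 106)
tss <- training_size_series(data, sizes, model_kinds = c("markers",
                                                         "pedigree"),
                            k = 10, seed = seed,
                            gibbs = gibbs_config(4000, 1000, 100,
                                                 seed = seed),
                            reestimate = "per_fold")
print(tss, digits = 2)
write.table(tss, "results/training_sizes.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message("Wrote results/relatedness.tsv, marker_subsets.tsv, training_sizes.tsv")
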