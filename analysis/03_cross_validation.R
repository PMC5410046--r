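#!/usr/bin/env Rscript
# Step 3: family-stratified 10-fold cross-validation of both model kinds on
# the combined sites, plus the site-specific schemes (within-site models,
# cross-site transfer, matched-size site mean). Writes a tidy accuracy
# table under results/.

library(sprucegs)

seed <- 2026
data <- readRDS("scratch/gs_data.rds")
ph <- data$phenotypes

rows <- list()
add <- function(scenario, model_kind, acc) {
  rows[[length(rows) + 1]] <<- data.frame(
    scenario = scenario, trait = data$trait, model_kind = model_kind,
    accuracy = acc$accuracy, accuracy_error = acc$accuracy_error,
    predictive_ability = acc$predictive_ability, pa_error = acc$pa_error)
}

message("Combined-site 10-fold CV ...")
folds <- make_cv_folds(ph$tree, ph$family, 10, seed)
for (mk in c("pedigree", "markers")) {
  pred <- cross_validate(data, mk, folds, fast = TRUE)
  acc <- accuracy_and_predictive_ability(pred, data$reference, ph,
                                         data$trait)
  add("combined_sites", mk, acc)
  write.table(pred, sprintf("results/cv_%s.tsv", mk), sep = "\t",
              row.names = FALSE, quote = FALSE)
  message(sprintf("  %-8s accuracy %.2f (%.2f), predictive ability %.2f",
                  mk, acc$accuracy, acc$accuracy_error,
                  acc$predictive_ability))
}

message("Site schemes ...")
for (s in sort(unique(ph$site))) {
  for (mk in c("pedigree", "markers")) {
    add(paste0("single_", s), mk,
        scenario_sites(data, "single", mk, site = s, seed = seed))
    add(paste0("cross_from_", s), mk,
        scenario_sites(data, "cross", mk, site = s, seed = seed))
  }
}
for (mk in c("pedigree", "markers"))
  add("site_mean", mk,
      scenario_sites(data, "site_mean", mk, subset_size = 359, n_rep = 5,
                     seed = seed))

out <- do.call(rbind, rows)
write.table(out, "results/accuracy_sites.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message("Wrote results/accuracy_sites.tsv")
print(out, digits = 2)
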