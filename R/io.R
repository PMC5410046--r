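#' Read / write the genotype matrix TSV
#'
#' Tab-separated, rows = individuals (first column `id`), columns =
#' markers, values 0/1/2 with missing encoded as `NA`, `.` or empty.
#'
#' @param path file path.
#' @name genotype_io
#' @export
read_genotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ".", ""))
  ids <- as.character(df[[1]])
  G <- as.matrix(df[, -1, drop = FALSE])
  bad <- !is.na(G) & !(G %in% c(0, 1, 2))
  if (any(bad)) {
    rows <- unique(which(bad, arr.ind = TRUE)[, 1])
    stop("invalid genotype values at data line(s): ",
         paste(utils::head(rows, 5), collapse = ", "), call. = FALSE)
  }
  storage.mode(G) <- "integer"
  rownames(G) <- ids
  G
}

#' @rdname genotype_io
#' @param genotypes matrix to write.
#' @export
write_genotypes <- function(genotypes, path) {
  df <- data.frame(id = rownames(genotypes), genotypes,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Read / write the phenotype CSV
#'
#' Comma-separated with columns `tree,site,block,family` plus one column
#' per trait; `NA` marks missing measurements.
#' @param path file path.
#' @name phenotype_io
#' @export
read_phenotypes <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname phenotype_io
#' @param phenotypes data frame to write.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE)
  invisible(path)
}

#' Read / write the marker map TSV
#'
#' Tab-separated columns `marker`, `linkage_group`, `position_cM`.
#' @param path file path.
#' @name map_io
#' @export
read_marker_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("marker", "linkage_group", "position_cM") %in% names(df)))
  if (any(df$position_cM < 0))
    stop("negative map positions", call. = FALSE)
  df
}

#' @rdname map_io
#' @param map data frame to write.
#' @export
write_marker_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Import genotypes from a VCF file
#'
#' Reads biallelic SNP records through the `vcfR` package and converts the
#' GT field to 0/1/2 counts of the ALT allele (missing `./.` becomes NA).
#' Multiallelic records are rejected.
#'
#' @param path VCF path (plain or gzipped).
#' @return individuals x markers integer matrix.
#' @export
vcf_to_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the vcfR package is required for VCF import", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  if (any(multi))
    stop("multiallelic record(s) not supported: ",
         paste(utils::head(vcfR::getID(v)[multi], 5), collapse = ", "),
         call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    out <- rep(NA_integer_, length(g))
    out[g %in% c("0/0", "0|0")] <- 0L
    out[g %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    out[g %in% c("1/1", "1|1")] <- 2L
    out
  }
  G <- apply(gt, 2, count_alt)
  rownames(G) <- rownames(gt)
  t(G) # individuals x markers
}

#' Write a simulated population to a directory
#'
#' Emits the native text formats: `pedigree.csv`, `phenotypes.csv`,
#' `genotypes.tsv`, `map.tsv`, and `truth.json` (QTL effects, true breeding
#' values, variance components used). Byte-identical for identical
#' config + seed.
#'
#' @param population a `sim_population`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_population <- function(population, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(build_pedigree(population$pedigree),
                 file.path(dir, "pedigree.csv"))
  write_phenotypes(population$phenotypes, file.path(dir, "phenotypes.csv"))
  write_genotypes(population$genotypes, file.path(dir, "genotypes.tsv"))
  write_marker_map(population$map, file.path(dir, "map.tsv"))
  truth <- list(seed = population$seed,
                qtl_effects = as.data.frame(population$qtl),
                qtl_markers = rownames(population$qtl),
                tbv = as.data.frame(population$tbv),
                tbv_ids = rownames(population$tbv),
                genetic_var = population$truth$genetic_var,
                resid_var = population$truth$resid_var,
                trait_means = population$truth$trait_means)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read a population directory back into a `sim_population`-like bundle
#' @param dir directory written by [write_population()].
#' @return list with `pedigree`, `phenotypes`, `genotypes`, `map`, `truth`.
#' @export
read_population <- function(dir) {
  need <- c("pedigree.csv", "phenotypes.csv", "genotypes.tsv", "map.tsv")
  paths <- file.path(dir, need)
  missing <- need[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ",
         paste(file.path(dir, missing), collapse = ", "), call. = FALSE)
  truth_path <- file.path(dir, "truth.json")
  list(pedigree = read_pedigree(paths[1]),
       phenotypes = read_phenotypes(paths[2]),
       genotypes = read_genotypes(paths[3]),
       map = read_marker_map(paths[4]),
       truth = if (file.exists(truth_path))
         jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL)
}

#' Run the full genomic-selection pipeline on a population directory
#'
#' Executes QC, imputation, the reference animal model, family-stratified
#' cross-validation for both model kinds, and the gain report, writing
#' tidy TSV/JSON results plus a manifest (seed, input checksums) to
#' `out_dir`. This is the programmatic equivalent of running the numbered
#' analysis drivers end to end on one trait.
#'
#' @param in_dir population directory (see [write_population()]).
#' @param out_dir output directory.
#' @param trait trait to analyse.
#' @param seed integer seed.
#' @param gibbs chain settings.
#' @param k CV folds.
#' @param intensity,cycle_pedigree,cycle_markers gain settings.
#' @return list with the main results (invisibly also written to disk).
#' @export
run_pipeline <- function(in_dir, out_dir, trait, seed = 1,
                         gibbs = gibbs_config(seed = seed), k = 10,
                         intensity = 0.05, cycle_pedigree = 28,
                         cycle_markers = 9) {
  pop <- read_population(in_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  data <- prepare_gs_data(pop, trait, gibbs = gibbs)
  ph <- data$phenotypes
  folds <- make_cv_folds(ph$tree, ph$family, k, seed)
  res <- list()
  for (mk in c("pedigree", "markers")) {
    pred <- cross_validate(data, mk, folds, gibbs = gibbs, fast = TRUE)
    acc <- accuracy_and_predictive_ability(pred, data$reference, ph, trait)
    utils::write.table(pred, file.path(out_dir,
                                       sprintf("cv_%s.tsv", mk)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    res[[mk]] <- list(predictions = pred, accuracy = acc)
  }
  dirn <- "higher_better"
  pp <- stats::setNames(res$pedigree$predictions$yhat_raw,
                        res$pedigree$predictions$tree)
  pm <- stats::setNames(res$markers$predictions$yhat_raw,
                        res$markers$predictions$tree)
  gains <- gain_report(pp, pm[names(pp)], direction = dirn,
                       intensity = intensity,
                       cycle_pedigree = cycle_pedigree,
                       cycle_markers = cycle_markers, trait = trait)
  utils::write.table(gains, file.path(out_dir, "gains.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  summary_df <- data.frame(
    scenario = "combined_sites", trait = trait,
    model_kind = c("pedigree", "markers"),
    accuracy = c(res$pedigree$accuracy$accuracy,
                 res$markers$accuracy$accuracy),
    accuracy_error = c(res$pedigree$accuracy$accuracy_error,
                       res$markers$accuracy$accuracy_error),
    predictive_ability = c(res$pedigree$accuracy$predictive_ability,
                           res$markers$accuracy$predictive_ability),
    pa_error = c(res$pedigree$accuracy$pa_error,
                 res$markers$accuracy$pa_error))
  utils::write.table(summary_df, file.path(out_dir, "accuracy.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  fitjson <- list(
    trait = trait,
    varcomp_pedigree = data$reference_fit$varcomp,
    h2_pedigree = data$reference_fit$h2,
    varcomp_markers = data$marker_fit_full$varcomp,
    sum_2pq = data$sum2pq,
    qc = data$qc_report[c("n_input", "n_kept", "dropped_by_rule")])
  jsonlite::write_json(fitjson, file.path(out_dir, "fit.json"),
                       digits = NA, auto_unbox = TRUE)
  manifest <- list(
    seed = seed, trait = trait, k = k,
    gibbs = unclass(gibbs),
    inputs = as.list(tools::md5sum(list.files(in_dir, full.names = TRUE))),
    package_version = as.character(utils::packageVersion("sprucegs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(list(accuracy = summary_df, gains = gains, fit = fitjson,
                 data = data))
}
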