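#' QC thresholds for SNP markers
#'
#' Conjunctive retention rules for biallelic gene SNPs: call rate at least
#' `min_call_rate`, absolute within-population fixation index at most
#' `max_abs_fis`, minor allele frequency at least `min_maf`, and the minor
#' allele carried by at least `min_minor_carriers` individuals.
#'
#' @param min_call_rate minimum fraction of non-missing calls.
#' @param max_abs_fis maximum `|F_IS|`, `F_IS = 1 - H_obs / H_exp`.
#' @param min_maf minimum minor allele frequency among observed calls.
#' @param min_minor_carriers minimum individuals carrying >= 1 minor allele.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_call_rate = 0.85, max_abs_fis = 0.50,
                          min_maf = 0.0055, min_minor_carriers = 10) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            max_abs_fis >= 0, max_abs_fis <= 1,
            min_maf >= 0, min_maf <= 0.5, min_minor_carriers >= 0)
  structure(list(min_call_rate = min_call_rate, max_abs_fis = max_abs_fis,
                 min_maf = min_maf, min_minor_carriers = min_minor_carriers),
            class = "qc_thresholds")
}

#' Orient genotype coding to the minor allele
#'
#' Flips markers (`g -> 2 - g`) whose counted-allele frequency among
#' observed calls exceeds 0.5, so values 0/1/2 count copies of the minor
#' allele. Orientation is fixed once from the full reference panel and
#' should not be redone after subsetting, so covariate signs stay stable
#' across scenarios.
#'
#' @param genotypes individuals x markers matrix of 0/1/2/NA.
#' @return list with `genotypes` (oriented) and `flipped` (logical per
#'   marker).
#' @export
orient_minor <- function(genotypes) {
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  flip <- !is.na(p) & p > 0.5
  if (any(flip))
    genotypes[, flip] <- 2L - genotypes[, flip]
  list(genotypes = genotypes, flipped = flip)
}

#' Per-marker quality-control statistics
#'
#' For each marker: call rate (non-missing fraction), counted-allele
#' frequency `p`, minor allele frequency `min(p, 1 - p)`, observed and
#' expected heterozygosity (`H_exp = 2 p (1 - p)`), fixation index
#' `F_IS = 1 - H_obs / H_exp` (NA when `H_exp = 0`), and the number of
#' individuals carrying at least one minor allele.
#'
#' @param genotypes individuals x markers matrix of 0/1/2/NA.
#' @return data frame, one row per marker.
#' @export
marker_stats <- function(genotypes) {
  if (!length(genotypes)) stop("empty genotype matrix", call. = FALSE)
  n_obs <- colSums(!is.na(genotypes))
  call_rate <- n_obs / nrow(genotypes)
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  p[n_obs == 0] <- NA_real_
  maf <- pmin(p, 1 - p)
  h_obs <- colMeans(genotypes == 1, na.rm = TRUE)
  h_obs[n_obs == 0] <- NA_real_
  h_exp <- 2 * p * (1 - p)
  fis <- ifelse(!is.na(h_exp) & h_exp > 0, 1 - h_obs / h_exp, NA_real_)
  minor_is_p <- !is.na(p) & p <= 0.5
  carr_counted <- colSums(genotypes >= 1, na.rm = TRUE)
  carr_other <- colSums(genotypes <= 1, na.rm = TRUE)
  n_minor_carriers <- ifelse(minor_is_p, carr_counted, carr_other)
  n_minor_carriers[n_obs == 0] <- 0L
  data.frame(marker = colnames(genotypes), call_rate = call_rate, p = p,
             maf = maf, h_obs = h_obs, h_exp = h_exp, fis = fis,
             n_minor_carriers = n_minor_carriers,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply marker QC filters
#'
#' Keeps markers passing all thresholds. The report attributes each dropped
#' marker to the first failing rule in the order call rate, MAF, minor-
#' allele carriers, `|F_IS|` (all rules are conjunctive, so the order only
#' affects attribution, not the surviving set). Markers with undefined
#' statistics (all calls missing) fail the call-rate rule.
#'
#' @param genotypes individuals x markers matrix of 0/1/2/NA.
#' @param thresholds a [qc_thresholds()].
#' @return list with `genotypes` (filtered), `stats`, and `report` (per-rule
#'   drop counts plus kept/dropped marker ids).
#' @export
apply_qc <- function(genotypes, thresholds = qc_thresholds()) {
  st <- marker_stats(genotypes)
  fail_cr <- st$call_rate < thresholds$min_call_rate
  fail_maf <- is.na(st$maf) | st$maf < thresholds$min_maf
  fail_car <- st$n_minor_carriers < thresholds$min_minor_carriers
  fail_fis <- !is.na(st$fis) & abs(st$fis) > thresholds$max_abs_fis
  # attribution follows the declared order call_rate > maf > carriers > fis
  first_fail <- rep(NA_character_, nrow(st))
  for (rule in rev(c("call_rate", "maf", "carriers", "fis"))) {
    fl <- switch(rule, call_rate = fail_cr, maf = fail_maf,
                 carriers = fail_car, fis = fail_fis)
    first_fail[fl] <- rule
  }
  keep <- is.na(first_fail)
  report <- list(
    n_input = nrow(st), n_kept = sum(keep),
    dropped_by_rule = c(call_rate = sum(first_fail == "call_rate",
                                        na.rm = TRUE),
                        maf = sum(first_fail == "maf", na.rm = TRUE),
                        carriers = sum(first_fail == "carriers",
                                       na.rm = TRUE),
                        fis = sum(first_fail == "fis", na.rm = TRUE)),
    kept = st$marker[keep],
    dropped = data.frame(marker = st$marker[!keep],
                         rule = first_fail[!keep],
                         stringsAsFactors = FALSE)
  )
  list(genotypes = genotypes[, keep, drop = FALSE], stats = st,
       report = report)
}

#' Impute missing genotypes by the rounded marker mean
#'
#' Missing calls are replaced by the mean of the observed calls of the same
#' marker, rounded to the nearest genotype value with half-up ties (mean
#' 0.5 imputes 1, mean 1.5 imputes 2) and clipped to 0..2.
#'
#' @param genotypes individuals x markers matrix of 0/1/2/NA.
#' @return complete integer matrix; observed entries are never changed.
#' @export
impute_missing <- function(genotypes) {
  mm <- colMeans(genotypes, na.rm = TRUE)
  if (anyNA(mm))
    stop("marker(s) with all calls missing; run apply_qc first",
         call. = FALSE)
  fill <- pmin(pmax(floor(mm + 0.5), 0), 2)
  idx <- which(is.na(genotypes), arr.ind = TRUE)
  if (nrow(idx))
    genotypes[idx] <- fill[idx[, 2]]
  storage.mode(genotypes) <- "integer"
  genotypes
}

#' Marker incidence covariates coded -1 / 0 / +1
#'
#' Recodes a complete 0/1/2 genotype matrix to the indicator covariates of
#' the marker model: major homozygote -1, heterozygote 0, minor homozygote
#' +1 (equivalently, alleles valued -0.5 a_j and +0.5 a_j so the homozygote
#' difference is 2 a_j).
#'
#' @param genotypes complete (imputed) integer matrix of 0/1/2.
#' @return numeric matrix `genotypes - 1`.
#' @export
incidence_covariates <- function(genotypes) {
  if (anyNA(genotypes))
    stop("genotype matrix has missing values; impute first", call. = FALSE)
  if (any(genotypes != round(genotypes)) ||
      any(genotypes < 0 | genotypes > 2))
    stop("genotypes must be integers in 0..2", call. = FALSE)
  genotypes - 1
}

#' Sum of marker heterozygosities, sum(2 p q)
#'
#' Returns the sum over markers of `2 p_k (1 - p_k)`, with allele
#' frequencies computed from non-missing calls. Scales the common marker
#' variance to the marker-based additive genetic variance
#' `V_A = sigma2_a * sum(2 p q)`.
#'
#' @param genotypes individuals x markers matrix of 0/1/2 (NA allowed).
#' @return scalar sum.
#' @export
sum_2pq <- function(genotypes) {
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  sum(2 * p * (1 - p), na.rm = TRUE)
}

#' Spectral structure of the genomic relationship matrix
#'
#' Builds the frequency-centered and -scaled genomic relationship matrix
#' `G = W W' / sum(2 p q)` with `W = genotypes - 2 p`, and returns the
#' fraction of variation captured by the leading eigenvector,
#' `lambda_1 / sum(lambda)`. A small fraction indicates weak population
#' structure (relatedness dominated by the family design, not provenance
#' groups).
#'
#' @param genotypes complete individuals x markers matrix of 0/1/2.
#' @return list with `fraction`, `eigenvalues` and `G`.
#' @export
genomic_relationship_structure <- function(genotypes) {
  if (nrow(genotypes) < 2) stop("need at least 2 individuals", call. = FALSE)
  if (anyNA(genotypes)) stop("impute missing genotypes first", call. = FALSE)
  p <- colMeans(genotypes) / 2
  W <- sweep(genotypes, 2, 2 * p)
  denom <- sum(2 * p * (1 - p))
  G <- tcrossprod(W) / denom
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  list(fraction = ev[1] / sum(ev), eigenvalues = ev, G = G)
}
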