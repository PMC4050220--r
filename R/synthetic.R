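# Published per-group genotype counts for the five MET/AKT1 SNPs
# (codes 1/2/3 per SNP; the two homozygotes and the heterozygote as
# labelled in the dictionary below). HIGH columns sum to 93, LOW to 89.
table1_counts <- function() {
  list(
    snp_names = c("rs1130233", "rs1858830", "rs2237717", "rs41735",
                  "rs42336"),
    high = matrix(c(22, 21, 50,
                    42, 44, 7,
                    25, 18, 50,
                    25, 17, 51,
                    17, 24, 52), nrow = 5, byrow = TRUE),
    low = matrix(c(33, 15, 41,
                   37, 42, 10,
                   28, 23, 38,
                   29, 19, 41,
                   20, 28, 41), nrow = 5, byrow = TRUE),
    dictionary = list(
      rs1130233 = c("1" = "AA", "2" = "GG", "3" = "AG"),
      rs1858830 = c("1" = "GG", "2" = "GC", "3" = "CC"),
      rs2237717 = c("1" = "CC", "2" = "CT", "3" = "TT"),
      rs41735   = c("1" = "GG", "2" = "AA", "3" = "GA"),
      rs42336   = c("1" = "GG", "2" = "AA", "3" = "GA")
    )
  )
}

#' Specification of a synthetic genotype/phenotype dataset
#'
#' Describes a two-group study with an optional planted epistatic barcode:
#' carriers of the planted barcode occur at a different rate in the HIGH
#' group than in the LOW group, while every other genotype is drawn
#' independently from per-SNP background frequencies. Defaults emulate a
#' 182-subject, 5-SNP panel: group sizes 89/93, planted barcode SNPs(1,4)
#' with heterozygous genotypes (codes 3-3), carrier rates 30/89 vs 18/93,
#' and background genotype frequencies equal to the panel's pooled marginal
#' genotype counts.
#'
#' @param n_high,n_low intended group sizes (defaults 89 and 93).
#' @param m number of SNPs (default 5).
#' @param planted_barcode an [snp_barcode()] enriched in the HIGH group, or
#'   `NULL` for pure background data. Default `SNPs(1,4) 3-3`.
#' @param carrier_prob_high,carrier_prob_low carrier probabilities of the
#'   planted barcode in each group (defaults `30/89` and `18/93`).
#' @param background_genotype_freqs `m x 3` matrix of per-SNP genotype
#'   probabilities (rows sum to 1). Default: the pooled five-SNP panel
#'   marginals when `m = 5`, uniform otherwise.
#' @param phenotype_mean_high,phenotype_mean_low,phenotype_sd normal
#'   phenotype model per group. Defaults (100, 80, 3) separate the groups
#'   by more than 6 within-group standard deviations, so splitting at the
#'   sample mean recovers the intended groups with per-subject
#'   misassignment probability below 1e-3.
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_high = 89, n_low = 93, m = 5,
                           planted_barcode = snp_barcode(c(1, 4), c(3, 3)),
                           carrier_prob_high = 30 / 89,
                           carrier_prob_low = 18 / 93,
                           background_genotype_freqs = NULL,
                           phenotype_mean_high = 100,
                           phenotype_mean_low = 80,
                           phenotype_sd = 3,
                           seed = NULL) {
  m <- as.integer(m)
  if (is.null(background_genotype_freqs)) {
    background_genotype_freqs <- if (m == 5) {
      t1 <- table1_counts()
      (t1$high + t1$low) / 182
    } else {
      matrix(1 / 3, nrow = m, ncol = 3)
    }
  }
  background_genotype_freqs <- as.matrix(background_genotype_freqs)
  if (!all(dim(background_genotype_freqs) == c(m, 3)))
    stop("background_genotype_freqs must be an m x 3 matrix")
  if (any(background_genotype_freqs < 0) ||
      any(abs(rowSums(background_genotype_freqs) - 1) > 1e-8))
    stop("each background genotype triple must be a probability vector")
  if (!is.null(planted_barcode)) {
    stopifnot(inherits(planted_barcode, "snp_barcode"))
    if (max(planted_barcode$snp_indices) > m)
      stop("planted barcode refers to SNPs beyond m = ", m)
    if (!(carrier_prob_high >= 0 && carrier_prob_high <= 1 &&
          carrier_prob_low >= 0 && carrier_prob_low <= 1))
      stop("carrier probabilities must lie in [0, 1]")
  }
  if (phenotype_mean_high <= phenotype_mean_low)
    stop("phenotype_mean_high must exceed phenotype_mean_low")
  structure(list(n_high = as.integer(n_high), n_low = as.integer(n_low),
                 m = m, planted_barcode = planted_barcode,
                 carrier_prob_high = carrier_prob_high,
                 carrier_prob_low = carrier_prob_low,
                 background_genotype_freqs = background_genotype_freqs,
                 phenotype_mean_high = phenotype_mean_high,
                 phenotype_mean_low = phenotype_mean_low,
                 phenotype_sd = phenotype_sd,
                 seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic genotype/phenotype dataset
#'
#' For each subject, carrier status of the planted barcode is drawn with the
#' group-specific probability. Carriers receive the planted genotype at each
#' planted SNP; non-carriers draw the planted SNPs from background with the
#' exact planted combination rejected (so the planted carrier probabilities
#' are exact, not lower bounds). All other SNPs are independent background
#' draws. Phenotypes are drawn from the group-specific normal model, so
#' [dichotomize_by_mean()] recovers the intended groups (up to the
#' documented misassignment probability).
#'
#' @param spec a [synthetic_spec()].
#' @return a [genotype_dataset()] (not yet dichotomized). Intended carrier
#'   flags are attached as attribute `"carrier"` and intended groups as
#'   attribute `"intended_group"` for diagnostics.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_high + spec$n_low
  intended <- rep(c("HIGH", "LOW"), c(spec$n_high, spec$n_low))
  bg <- spec$background_genotype_freqs

  geno <- vapply(seq_len(spec$m), function(j) {
    sample.int(3, n, replace = TRUE, prob = bg[j, ])
  }, integer(n))

  carrier <- rep(FALSE, n)
  pb <- spec$planted_barcode
  if (!is.null(pb)) {
    p_combo <- prod(bg[cbind(pb$snp_indices, pb$genotype_codes)])
    if (p_combo > 0.999)
      stop("background places essentially all mass on the planted ",
           "combination; rejection sampling for non-carriers is infeasible")
    p <- ifelse(intended == "HIGH", spec$carrier_prob_high,
                spec$carrier_prob_low)
    carrier <- stats::rbinom(n, 1, p) == 1
    geno[carrier, pb$snp_indices] <-
      matrix(pb$genotype_codes, nrow = sum(carrier),
             ncol = length(pb$snp_indices), byrow = TRUE)
    # reject the planted combination among non-carriers
    repeat {
      sub <- geno[, pb$snp_indices, drop = FALSE]
      is_combo <- rowSums(sub == rep(pb$genotype_codes,
                                     each = n)) == length(pb$snp_indices)
      clash <- which(!carrier & is_combo)
      if (length(clash) == 0) break
      for (j in seq_along(pb$snp_indices)) {
        geno[clash, pb$snp_indices[j]] <-
          sample.int(3, length(clash), replace = TRUE,
                     prob = bg[pb$snp_indices[j], ])
      }
    }
  }

  phen <- stats::rnorm(n,
                       mean = ifelse(intended == "HIGH",
                                     spec$phenotype_mean_high,
                                     spec$phenotype_mean_low),
                       sd = spec$phenotype_sd)
  snp_names <- if (spec$m == 5) table1_counts()$snp_names
               else sprintf("snp%02d", seq_len(spec$m))
  ds <- genotype_dataset(sprintf("S%04d", seq_len(n)), phen, geno,
                         snp_names)
  attr(ds, "carrier") <- carrier
  attr(ds, "intended_group") <- intended
  ds
}

#' Deterministic dataset reproducing the published per-SNP genotype counts
#'
#' Builds a 182-subject, 5-SNP dataset whose per-SNP, per-group genotype
#' counts equal the published single-SNP table exactly (30 cells). Only the
#' marginal counts are constrained: the joint genotype structure is filled
#' in by a seeded within-group shuffle of each SNP column, so multi-SNP
#' carrier counts are not (and cannot be) reproduced from marginals alone.
#' Phenotypes are constant within group (HIGH 100, LOW 80) so the mean
#' split recovers the groups exactly.
#'
#' @param seed seed for the within-group column shuffles (default 1).
#' @return a [genotype_dataset()] with the panel's rs-identifiers and
#'   genotype dictionary.
#' @export
fixture_table1_marginals <- function(seed = 1) {
  t1 <- table1_counts()
  n_high <- sum(t1$high[1, ])  # 93
  n_low <- sum(t1$low[1, ])    # 89
  set.seed(seed)
  col_for <- function(counts) sample(rep(1:3, counts))
  geno <- rbind(
    vapply(1:5, function(j) col_for(t1$high[j, ]), integer(n_high)),
    vapply(1:5, function(j) col_for(t1$low[j, ]), integer(n_low))
  )
  phen <- rep(c(100, 80), c(n_high, n_low))
  genotype_dataset(sprintf("S%04d", seq_len(n_high + n_low)), phen, geno,
                   t1$snp_names, genotype_dictionary = t1$dictionary)
}
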