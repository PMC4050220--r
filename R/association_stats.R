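#' 2x2 contingency table of barcode carriers vs. phenotype group
#'
#' Cells: `a` = HIGH-group carriers, `b` = LOW-group carriers, `c` = HIGH
#' others (non-carriers), `d` = LOW others.
#'
#' @param a,b,c,d non-negative counts.
#' @return an object of class `barcode_contingency`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative counts")
  structure(as.list(cells), class = "barcode_contingency")
}

#' @export
print.barcode_contingency <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), nrow = 2, byrow = TRUE,
              dimnames = list(c("carrier", "other"), c("HIGH", "LOW")))
  print(m)
  invisible(x)
}

#' Build the carriers-vs-others table for a barcode
#'
#' @param ds a dichotomized [genotype_dataset()].
#' @param bc an [snp_barcode()].
#' @return a [contingency_table()] whose margins equal the group sizes.
#' @export
build_contingency <- function(ds, bc) {
  nm <- count_matches(ds, bc)
  gs <- group_sizes(ds)
  contingency_table(nm[["n_high"]], nm[["n_low"]],
                    gs[["n_high"]] - nm[["n_high"]],
                    gs[["n_low"]] - nm[["n_low"]])
}

haldane_adjust <- function(t, haldane) {
  if (haldane) lapply(t[c("a", "b", "c", "d")], `+`, 0.5)
  else t[c("a", "b", "c", "d")]
}

#' Odds ratio of a 2x2 table
#'
#' `OR = (a d) / (b c)`; an OR above 1 means barcode carriers are enriched
#' in the HIGH group.
#'
#' @param t a [contingency_table()].
#' @param haldane add 0.5 to every cell first (Haldane-Anscombe correction
#'   for zero cells); off by default.
#' @return scalar odds ratio.
#' @export
odds_ratio <- function(t, haldane = FALSE) {
  x <- haldane_adjust(t, haldane)
  if (x$b * x$c == 0)
    stop("odds ratio undefined: zero in b*c (enable haldane = TRUE)")
  (x$a * x$d) / (x$b * x$c)
}

#' Woolf confidence interval for the odds ratio
#'
#' Normal approximation on the log odds ratio:
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param t a [contingency_table()] with all cells positive (or `haldane`).
#' @param level confidence level (default 0.95).
#' @param haldane as in [odds_ratio()].
#' @return named numeric vector `c(low, high)`.
#' @export
woolf_ci <- function(t, level = 0.95, haldane = FALSE) {
  x <- haldane_adjust(t, haldane)
  if (any(unlist(x) == 0))
    stop("Woolf CI undefined with a zero cell (enable haldane = TRUE)")
  or <- (x$a * x$d) / (x$b * x$c)
  z <- stats::qnorm((1 + level) / 2)
  se <- sqrt(1 / x$a + 1 / x$b + 1 / x$c + 1 / x$d)
  ci <- exp(log(or) + c(-1, 1) * z * se)
  c(low = ci[1], high = ci[2])
}

#' Pearson chi-square test of a 2x2 table
#'
#' The closed form `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on 1 degree of
#' freedom, without continuity correction by default (Yates correction
#' available via `yates = TRUE`).
#'
#' @param t a [contingency_table()] with no zero margin.
#' @param yates apply the Yates continuity correction.
#' @return list with `statistic` and `p_value`.
#' @export
pearson_chi2 <- function(t, yates = FALSE) {
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0))
    stop("chi-square test undefined: a table margin is zero")
  num <- abs(a * d - b * c)
  if (yates) num <- max(num - n / 2, 0)
  stat <- n * num^2 / prod(margins)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Post-hoc power of the chi-square test
#'
#' Power of the 1-df chi-square test at level `alpha` when the observed
#' statistic is taken as the noncentrality parameter (equivalently, effect
#' size `w = sqrt(chi2 / N)` at the observed total N):
#' `P( chi2_1(lambda) > q_{1, 1-alpha} )` with `lambda` = observed chi2.
#' With `lambda = 0` this reduces to `alpha`, and it increases to 1 as the
#' observed effect grows.
#'
#' @param t a [contingency_table()].
#' @param alpha significance level (default 0.05).
#' @return scalar power in `[alpha, 1)`.
#' @export
posthoc_power <- function(t, alpha = 0.05) {
  lambda <- pearson_chi2(t)$statistic
  crit <- stats::qchisq(1 - alpha, df = 1)
  stats::pchisq(crit, df = 1, ncp = lambda, lower.tail = FALSE)
}

#' Full statistical evaluation of barcodes
#'
#' Builds the carriers-vs-others table for each barcode and reports the
#' group difference, Pearson chi-square P value, odds ratio with Woolf CI,
#' and post-hoc power, one row per barcode. A Bonferroni-adjusted P value
#' across the barcodes actually tested is included as an extension column.
#'
#' @param ds a dichotomized [genotype_dataset()].
#' @param barcodes an [snp_barcode()] or list of them.
#' @param alpha significance level for the power column.
#' @param level confidence level of the odds-ratio CI.
#' @return data frame with columns `k`, `snp_names`, `genotype_codes`,
#'   `n_high_match`, `n_low_match`, `difference`, `chi2`, `p_value`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `power`, `p_bonferroni`.
#' @export
evaluate_barcodes <- function(ds, barcodes, alpha = 0.05, level = 0.95) {
  if (inherits(barcodes, "snp_barcode")) barcodes <- list(barcodes)
  rows <- lapply(barcodes, function(bc) {
    t <- build_contingency(ds, bc)
    chi <- pearson_chi2(t)
    ci <- woolf_ci(t, level = level)
    data.frame(
      k = length(bc$snp_indices),
      snp_names = paste(ds$snp_names[bc$snp_indices], collapse = ","),
      genotype_codes = paste(bc$genotype_codes, collapse = "-"),
      n_high_match = t$a, n_low_match = t$b,
      difference = t$a - t$b,
      chi2 = chi$statistic, p_value = chi$p_value,
      odds_ratio = odds_ratio(t),
      ci_low = ci[["low"]], ci_high = ci[["high"]],
      power = posthoc_power(t, alpha = alpha),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- stats::p.adjust(out$p_value, method = "bonferroni")
  out
}

#' Write a barcode evaluation report
#'
#' Writes the evaluated barcodes as a TSV, sorted by group difference
#' descending (ties broken by SNP names then genotype codes), plus a JSON
#' sidecar (`<path>.json`) recording the swarm configuration and seed.
#'
#' @param results data frame from [evaluate_barcodes()] (non-empty).
#' @param path output TSV path; the sidecar is written to `paste0(path,
#'   ".json")`.
#' @param config optional [swarm_config()] to record in the sidecar.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, config = NULL) {
  if (!is.data.frame(results) || nrow(results) == 0)
    stop("results must be a non-empty data frame of evaluated barcodes")
  ord <- order(-results$difference, results$snp_names,
               results$genotype_codes)
  utils::write.table(results[ord, ], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(generated_by = "snpbarcode",
               n_barcodes = nrow(results))
  if (!is.null(config)) meta$config <- unclass(config)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
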