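#' SNP barcode
#'
#' A barcode is a combination of `k >= 2` distinct SNPs together with one
#' fixed genotype code per SNP. A subject *carries* the barcode if its
#' genotype equals the barcode's code at every selected SNP (exact genotype
#' equality; no dominant/recessive collapsing). Barcodes are stored in
#' canonical form: SNP indices sorted ascending with genotype codes permuted
#' in lockstep, so carrier status is invariant to the order of construction.
#'
#' @param snp_indices integer vector of `k` distinct 1-based SNP indices.
#' @param genotype_codes integer vector of `k` genotype codes in `{1,2,3}`.
#' @return an object of class `snp_barcode`.
#' @examples
#' snp_barcode(c(4, 1), c(3, 3))  # canonicalizes to SNPs(1,4) 3-3
#' @export
snp_barcode <- function(snp_indices, genotype_codes) {
  snp_indices <- as.integer(snp_indices)
  genotype_codes <- as.integer(genotype_codes)
  k <- length(snp_indices)
  if (k < 2)
    stop("a barcode needs at least 2 SNPs, got ", k)
  if (length(genotype_codes) != k)
    stop("lengths differ: ", k, " SNP indices vs ",
         length(genotype_codes), " genotype codes")
  if (anyDuplicated(snp_indices))
    stop("SNP indices must be distinct (SNPs cannot be repeatedly selected)")
  if (any(snp_indices < 1))
    stop("SNP indices are 1-based and must be positive")
  if (!all(genotype_codes %in% 1:3))
    stop("genotype codes must be in {1, 2, 3}")
  ord <- order(snp_indices)
  structure(list(snp_indices = snp_indices[ord],
                 genotype_codes = genotype_codes[ord]),
            class = "snp_barcode")
}

#' @export
format.snp_barcode <- function(x, ...) {
  sprintf("SNPs(%s) %s",
          paste(x$snp_indices, collapse = ","),
          paste(x$genotype_codes, collapse = "-"))
}

#' @export
print.snp_barcode <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Parse a barcode from its "i:g,j:g" string form
#'
#' @param s string such as `"1:3,4:3"` (SNP index : genotype code pairs).
#' @return an `snp_barcode`.
#' @export
parse_barcode <- function(s) {
  parts <- strsplit(trimws(strsplit(s, ",", fixed = TRUE)[[1]]), ":",
                    fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop("barcode string must look like '1:3,4:3'")
  m <- matrix(as.integer(unlist(parts)), nrow = 2)
  snp_barcode(m[1, ], m[2, ])
}

# Logical carrier vector: TRUE where the subject matches the barcode at every
# selected SNP. A missing genotype at any barcode SNP makes the subject a
# non-carrier.
carrier_vector <- function(ds, bc) {
  m <- length(ds$snp_names)
  if (any(bc$snp_indices > m))
    stop("barcode SNP index out of range: dataset has ", m, " SNPs")
  sub <- ds$genotypes[, bc$snp_indices, drop = FALSE]
  hits <- sub == rep(bc$genotype_codes, each = nrow(sub))
  hits[is.na(hits)] <- FALSE
  rowSums(hits) == length(bc$snp_indices)
}

#' Count barcode carriers in the HIGH and LOW groups
#'
#' @param ds a dichotomized `genotype_dataset`.
#' @param bc an `snp_barcode` valid for `ds`.
#' @return named integer vector `c(n_high, n_low)` of carriers per group.
#' @export
count_matches <- function(ds, bc) {
  if (is.null(ds$group)) stop("dataset has not been dichotomized")
  carrier <- carrier_vector(ds, bc)
  c(n_high = sum(carrier & ds$group == "HIGH"),
    n_low  = sum(carrier & ds$group == "LOW"))
}

#' Barcode fitness: difference in carrier counts between groups
#'
#' The objective of the swarm search: the number of HIGH-group carriers
#' minus the number of LOW-group carriers. In `"absolute"` mode the
#' magnitude of the difference is used instead (direction-free search).
#'
#' @param n_high,n_low non-negative carrier counts per group.
#' @param objective `"signed"` (default) or `"absolute"`.
#' @return integer fitness; higher is better.
#' @examples
#' barcode_fitness(30, 18)  # 12
#' @export
barcode_fitness <- function(n_high, n_low,
                            objective = c("signed", "absolute")) {
  objective <- match.arg(objective)
  stopifnot(n_high >= 0, n_low >= 0)
  d <- as.integer(n_high) - as.integer(n_low)
  if (objective == "absolute") abs(d) else d
}
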