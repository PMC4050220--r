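#' Enumerate every barcode of a given size
#'
#' Yields each canonical barcode exactly once: all `choose(m, k)` SNP
#' subsets crossed with all `3^k` genotype assignments. Intended as the
#' ground-truth oracle for small panels; refuses when the space exceeds the
#' cap.
#'
#' @param m number of SNPs in the panel.
#' @param k barcode size, `2 <= k <= m`.
#' @param cap refuse to enumerate more than this many barcodes
#'   (default `1e6`); use the swarm search instead for larger spaces.
#' @return list of [snp_barcode()] objects, length `choose(m, k) * 3^k`.
#' @export
enumerate_barcodes <- function(m, k, cap = 1e6) {
  m <- as.integer(m); k <- as.integer(k)
  if (k > m) stop("k = ", k, " exceeds the number of SNPs (", m, ")")
  total <- choose(m, k) * 3^k
  if (total > cap)
    stop("enumeration would visit ", format(total, big.mark = ","),
         " barcodes (cap ", format(cap, big.mark = ","),
         "); use run_pso() for spaces this large")
  subsets <- utils::combn(m, k, simplify = FALSE)
  codes <- as.matrix(expand.grid(rep(list(1:3), k)))
  out <- vector("list", total)
  i <- 0L
  for (s in subsets) {
    for (r in seq_len(nrow(codes))) {
      i <- i + 1L
      out[[i]] <- snp_barcode(s, codes[r, ])
    }
  }
  out
}

#' Exhaustively rank all barcodes of size k
#'
#' Evaluates every barcode and ranks by the group difference (fitness),
#' descending. Ties are broken by SNP indices then genotype codes,
#' lexicographically, so the ranking is deterministic. The first row is the
#' global optimum -- the upper bound no swarm run can exceed.
#'
#' @param ds a dichotomized [genotype_dataset()].
#' @param k barcode size.
#' @param objective as in [swarm_config()].
#' @param cap enumeration cap, as in [enumerate_barcodes()].
#' @return a data frame with one row per barcode: `barcode` (display
#'   string), `n_high`, `n_low`, `difference`, sorted best-first; the
#'   corresponding `snp_barcode` objects are attached as the `"barcodes"`
#'   attribute, in row order.
#' @export
exhaustive_best <- function(ds, k, objective = c("signed", "absolute"),
                            cap = 1e6) {
  objective <- match.arg(objective)
  if (is.null(ds$group)) stop("dataset has not been dichotomized")
  bcs <- enumerate_barcodes(n_snps(ds), k, cap = cap)
  counts <- vapply(bcs, function(b) count_matches(ds, b), integer(2))
  fit <- mapply(barcode_fitness, counts[1, ], counts[2, ],
                MoreArgs = list(objective = objective))
  snp_key <- vapply(bcs, function(b)
    paste(sprintf("%06d", b$snp_indices), collapse = ","), character(1))
  code_key <- vapply(bcs, function(b)
    paste(b$genotype_codes, collapse = ","), character(1))
  ord <- order(-fit, snp_key, code_key)
  res <- data.frame(
    barcode = vapply(bcs, format, character(1))[ord],
    n_high = counts[1, ord],
    n_low = counts[2, ord],
    difference = fit[ord],
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  attr(res, "barcodes") <- bcs[ord]
  res
}
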