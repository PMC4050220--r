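#' Genotype/phenotype dataset
#'
#' Container for a case-style genotype table: one row per subject with an
#' identifier, a continuous phenotype score, and one categorical genotype
#' code per SNP. Genotype codes follow the common three-state convention:
#' `1` and `2` are the two homozygotes, `3` the heterozygote. Missing
#' genotypes are `NA`. Subjects are assigned to a `HIGH` or `LOW` phenotype
#' group by [dichotomize_by_mean()].
#'
#' @param subject_ids character vector of unique subject identifiers.
#' @param phenotype numeric phenotype score per subject (arbitrary units).
#' @param genotypes integer matrix (subjects x SNPs) of codes in `{1,2,3}`
#'   or `NA` for missing.
#' @param snp_names character vector of unique SNP labels, one per column.
#' @param genotype_dictionary optional named list mapping each SNP name to a
#'   `c("1" = ..., "2" = ..., "3" = ...)` allele-pair labelling.
#'
#' @return An object of class `genotype_dataset`: a list with fields
#'   `subject_ids`, `phenotype`, `genotypes`, `snp_names`,
#'   `genotype_dictionary`, and `group` (factor with levels `HIGH`, `LOW`,
#'   or `NULL` before dichotomization).
#' @seealso [read_genotype_table()], [dichotomize_by_mean()]
#' @export
genotype_dataset <- function(subject_ids, phenotype, genotypes, snp_names,
                             genotype_dictionary = NULL) {
  subject_ids <- as.character(subject_ids)
  phenotype <- as.numeric(phenotype)
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  n <- length(subject_ids)
  if (length(phenotype) != n)
    stop("phenotype length (", length(phenotype),
         ") does not match number of subjects (", n, ")")
  if (nrow(genotypes) != n)
    stop("genotype matrix has ", nrow(genotypes), " rows but there are ",
         n, " subjects")
  if (length(snp_names) != ncol(genotypes))
    stop("found ", length(snp_names), " SNP names for ", ncol(genotypes),
         " genotype columns")
  if (anyDuplicated(snp_names))
    stop("SNP names must be unique")
  if (anyNA(phenotype))
    stop("phenotype must be numeric and non-missing for every subject")
  bad <- which(!is.na(genotypes) & !(genotypes %in% 1:3), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("invalid genotype code ", genotypes[bad[1, 1], bad[1, 2]],
         " at row ", bad[1, 1], ", SNP ", snp_names[bad[1, 2]],
         " (codes must be 1, 2, 3 or missing)")
  }
  dimnames(genotypes) <- list(subject_ids, snp_names)
  structure(
    list(subject_ids = subject_ids,
         phenotype = phenotype,
         genotypes = genotypes,
         snp_names = as.character(snp_names),
         genotype_dictionary = genotype_dictionary,
         group = NULL),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", length(x$subject_ids), "subjects x",
      length(x$snp_names), "SNPs\n")
  cat("  SNPs:", paste(x$snp_names, collapse = ", "), "\n")
  if (is.null(x$group)) {
    cat("  groups: not yet dichotomized\n")
  } else {
    tab <- table(x$group)
    cat("  groups: HIGH =", tab[["HIGH"]], ", LOW =", tab[["LOW"]],
        "(phenotype mean split)\n")
  }
  invisible(x)
}

#' Number of subjects / SNPs in a dataset
#' @param ds a `genotype_dataset`.
#' @return integer count.
#' @export
n_subjects <- function(ds) length(ds$subject_ids)

#' @rdname n_subjects
#' @export
n_snps <- function(ds) length(ds$snp_names)

#' Read a delimited genotype table
#'
#' Expects a header row `id, phenotype, <snp1>, ..., <snpm>` followed by one
#' row per subject. Genotype codes must be 1, 2, 3, or the missing sentinel.
#'
#' @param path path to the file.
#' @param dialect `"csv"` (comma) or `"tsv"` (tab) delimited.
#' @param missing character vector of sentinels parsed as missing genotypes
#'   (empty cells are always treated as missing).
#' @param genotype_dictionary optional dictionary as in [genotype_dataset()].
#' @return a validated [genotype_dataset()].
#' @export
read_genotype_table <- function(path, dialect = c("csv", "tsv"),
                                missing = "NA", genotype_dictionary = NULL) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE)
  if (ncol(raw) < 3)
    stop("malformed header in ", path,
         ": expected columns id, phenotype, then at least one SNP")
  if (!identical(tolower(names(raw)[1:2]), c("id", "phenotype")))
    stop("malformed header in ", path,
         ": first two columns must be 'id' and 'phenotype', found '",
         names(raw)[1], "', '", names(raw)[2], "'")
  phen <- suppressWarnings(as.numeric(raw[[2]]))
  if (anyNA(phen)) {
    i <- which(is.na(phen))[1]
    stop("non-numeric phenotype '", raw[i, 2], "' at row ", i)
  }
  snp_names <- names(raw)[-(1:2)]
  gcols <- as.matrix(raw[, -(1:2), drop = FALSE])
  gcols[gcols %in% c(missing, "")] <- NA_character_
  gnum <- suppressWarnings(matrix(as.integer(gcols), nrow = nrow(gcols)))
  bad <- which((!is.na(gcols) & is.na(gnum)) |
                 (!is.na(gnum) & !(gnum %in% 1:3)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("invalid genotype code '", gcols[bad[1, 1], bad[1, 2]],
         "' at row ", bad[1, 1], ", SNP ", snp_names[bad[1, 2]],
         " (codes must be 1, 2, 3 or missing)")
  }
  genotype_dataset(raw[[1]], phen, gnum, snp_names,
                   genotype_dictionary = genotype_dictionary)
}

#' Write a genotype dataset back to a delimited table
#'
#' Inverse of [read_genotype_table()]: round-trips subject ids, phenotypes,
#' SNP names, and the genotype matrix (missing values written as `NA`).
#'
#' @param ds a `genotype_dataset`.
#' @param path output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @export
write_genotype_table <- function(ds, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  df <- data.frame(id = ds$subject_ids, phenotype = ds$phenotype,
                   check.names = FALSE, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(ds$genotypes, check.names = FALSE))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Split subjects into HIGH and LOW groups at the phenotype mean
#'
#' Subjects scoring strictly above the arithmetic mean of all phenotype
#' scores are labelled `HIGH`; subjects at or below the mean are `LOW`.
#'
#' @param ds a `genotype_dataset`.
#' @return the dataset with `group` populated; attributes `n_high`, `n_low`
#'   carry the group sizes.
#' @export
dichotomize_by_mean <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (n_subjects(ds) == 0) stop("cannot dichotomize an empty dataset")
  mu <- mean(ds$phenotype)
  ds$group <- factor(ifelse(ds$phenotype > mu, "HIGH", "LOW"),
                     levels = c("HIGH", "LOW"))
  attr(ds, "phenotype_mean") <- mu
  attr(ds, "n_high") <- sum(ds$group == "HIGH")
  attr(ds, "n_low") <- sum(ds$group == "LOW")
  ds
}

#' Group sizes of a dichotomized dataset
#' @param ds a dichotomized `genotype_dataset`.
#' @return named integer vector `c(n_high, n_low)`.
#' @export
group_sizes <- function(ds) {
  if (is.null(ds$group)) stop("dataset has not been dichotomized")
  c(n_high = sum(ds$group == "HIGH"), n_low = sum(ds$group == "LOW"))
}
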