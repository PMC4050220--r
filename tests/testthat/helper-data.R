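# Six-subject toy dataset over two SNPs: HIGH genotypes (1,3),(3,3),(3,3);
# LOW genotypes (3,3),(2,1),(3,2). The barcode SNPs(1,2) 3-3 is carried by
# 2 HIGH and 1 LOW subject.
toy_dataset <- function() {
  ds <- genotype_dataset(
    subject_ids = paste0("S", 1:6),
    phenotype = c(100, 100, 100, 80, 80, 80),
    genotypes = rbind(c(1, 3), c(3, 3), c(3, 3),
                      c(3, 3), c(2, 1), c(3, 2)),
    snp_names = c("snpA", "snpB")
  )
  dichotomize_by_mean(ds)
}

# The four published best-barcode 2x2 tables (HIGH carriers, LOW carriers,
# HIGH others, LOW others).
published_tables <- function() {
  list(
    k2 = contingency_table(30, 18, 59, 75),
    k3 = contingency_table(27, 15, 62, 78),
    k4 = contingency_table(25, 14, 64, 79),
    k5 = contingency_table(11, 4, 78, 89)
  )
}

random_contingency <- function() {
  contingency_table(sample(1:40, 1), sample(1:40, 1),
                    sample(1:80, 1), sample(1:80, 1))
}
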