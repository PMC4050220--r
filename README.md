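# snpbarcode

Particle swarm search for **SNP barcodes** — combinations of SNPs with
fixed genotypes whose carrier frequency differs maximally between a
high-phenotype and a low-phenotype group.

## The problem

Case-style genetic association studies often find no significant single-SNP
effects, yet a joint pattern — say, heterozygous at two particular SNPs
simultaneously — can still be clearly enriched in one phenotype group.
`snpbarcode` is for researchers with a small-to-moderate panel of
categorically coded genotypes (codes 1/2/3: the two homozygotes and the
heterozygote) and a continuous phenotype, who want to find and evaluate
such multi-SNP genotype patterns.

Subjects are split at the phenotype mean into `HIGH` (strictly above) and
`LOW` groups. A barcode `X` = `k` distinct SNPs plus one genotype code per
SNP is scored by the signed carrier-count difference

    F(X) = #(HIGH carriers of X) − #(LOW carriers of X)

and the search maximizes `F` with a global-best particle swarm
optimization (population 50, 100 iterations, inertia weight linearly
decreasing 0.9 → 0.4, c1 = c2 = 2) over a continuous encoding with
nearest-integer decoding and duplicate-SNP repair. An exhaustive
enumerator provides the exact optimum on small panels, and selected
barcodes are evaluated with the 2×2 carriers-vs-others table: odds ratio,
Woolf 95% CI, Pearson chi-square (no continuity correction), and
noncentral chi-square post-hoc power. A synthetic-data generator plants an
epistatic barcode at configurable group-specific carrier rates so the
whole pipeline can be validated without any external data.

## Worked example

```r
library(snpbarcode)

spec <- synthetic_spec(seed = 7)           # 89/93 subjects, 5 SNPs,
                                           # planted SNPs(1,4) 3-3
ds <- dichotomize_by_mean(generate_dataset(spec))
ds
#> genotype_dataset: 182 subjects x 5 SNPs
#>   SNPs: rs1130233, rs1858830, rs2237717, rs41735, rs42336
#>   groups: HIGH = 89 , LOW = 93 (phenotype mean split)

res <- run_pso(ds, swarm_config(k = 2, seed = 7))
res
#> PSO best barcode: SNPs(1,3) 3-3
#>   carriers: HIGH 33, LOW 19; difference 14
```

The swarm's answer is the barcode "heterozygous at SNP 1 *and* SNP 3",
carried by 33 of 89 HIGH subjects but only 19 of 93 LOW subjects. On five
SNPs we can confirm it is the global optimum (in this seed's dataset,
sampling noise made this background pattern outscore the planted
`SNPs(1,4) 3-3`, difference 9 — a realistic reminder that the top barcode
and the true signal need not coincide at n = 182):

```r
head(exhaustive_best(ds, k = 2), 3)
#>         barcode n_high n_low difference
#> 1 SNPs(1,3) 3-3     33    19         14
#> 2 SNPs(1,2) 3-1     30    18         12
#> 3 SNPs(1,4) 3-3     26    17          9

evaluate_barcodes(ds, res$barcode)
#>   difference  chi2 p_value odds_ratio ci_low ci_high power
#>           14 6.177   0.013      2.295  1.183   4.452   0.7
```

So carriers of the best barcode have 2.3 times the odds of being in the
HIGH group (95% CI 1.18–4.45, chi-square P = 0.013). Statistics can also
be computed straight from published 2×2 counts:

```r
t <- contingency_table(30, 18, 59, 75)   # HIGH/LOW carriers, HIGH/LOW others
odds_ratio(t); woolf_ci(t); pearson_chi2(t)$p_value; posthoc_power(t)
#> OR 2.119 (1.077 to 4.168), P = 0.028, power = 0.594
```

A thin command-line wrapper ships in `inst/cli/snpbarcode.R`
(`search`, `exhaustive`, `evaluate`, `simulate` subcommands), e.g.

```sh
Rscript inst/cli/snpbarcode.R search --input data.csv --k 2..5 --seed 1 --out report.tsv
```

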