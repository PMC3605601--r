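# ppgwas — privacy-preserving GWAS on secret-shared genotypes

Genome-wide association studies need large case–control cohorts, but genotype
data are an identity code: they cannot be anonymized, and even aggregate
allele frequencies can leak who was in a study. One cryptographic way out is
to keep the data secret-shared across several independent hosts and run the
association tests *obliviously*, releasing nothing but a per-SNP significance
bit. `ppgwas` is a faithful single-process simulation of such a system:
three simulated data hosts plus a trusted dealer, with provable-style
security modeled at the protocol level (honest-but-curious parties,
3-out-of-3 additive sharing), and association testing done entirely with
integer arithmetic on shares.

## What it computes

Genotype calls are encoded as allele-count pairs — AA→(2,0), AB→(1,1),
BB→(0,2), missing NN→(0,0) — and secret-shared over the ring **Z**₂ᵏ
(default k = 128). Case/control membership is a secret-shared 0/1 index
vector, built either from an analyst's member list or evaluated obliviously
from shared phenotypes with an inclusion-criterion language
(`"age >= 50 & has_diabetes"`). Contingency tables are then secure inner
products, e.g. the allele table for one SNP is

    a = x·g_A   c = x·g_B      (cases)
    b = y·g_A   d = y·g_B      (controls)

Four tests are provided, each held as an exact integer fraction m/n on
shares:

| test | statistic |
|---|---|
| `chi2` | Pearson χ² on the 2×2 allele table: m = N(ad−bc)², n = (a+b)(c+d)(a+c)(b+d) |
| `chi2prop` | pooled two-proportion z² (algebraically equal on 2×2 tables; verified, not assumed) |
| `catt` | Cochran–Armitage trend over AA/AB/BB with weights (0,1,2) |
| `tdt` | transmission disequilibrium (u−v)²/(u+v) over double-heterozygous-parent trios |

Significance at level α is decided without floating point: the χ²(1)
critical value t(α) is approximated by a public fraction p/q
(p = ⌊t(α)·q⌋, q = 10⁶ by default) and the hosts open only the secure
comparison bit of `m·q ≥ p·n`. Bonferroni correction rescales the threshold;
false-discovery-rate control is a fully oblivious Benjamini–Hochberg
procedure built on a Batcher odd-even merge sorting network whose only
public outputs are the rejection count and the decision bits.

A synthetic-data module generates Hardy–Weinberg genotype panels (with
planted case/control allele-frequency differences), phenotype tables and
parent–child trios with tunable transmission distortion τ, and an exact
plaintext reference pipeline (big-integer arithmetic in plain R) mirrors the
secure path bit for bit — the test suite requires the two to agree exactly.

## Worked example

```r
library(ppgwas)

g  <- simulate_genotypes(400, 1000, maf = c(0.05, 0.5), seed = 1)
ph <- simulate_phenotypes(400, 0.5, donor_ids = g$donor_ids, seed = 2)
g  <- plant_association(g, snp_index = 7, attr(ph, "case_ids"),
                        f_case = 0.5, f_ctrl = 0.2, seed = 3)

res <- run_secure_gwas(g, test = "chi2",
                       phenotypes = ph, criterion = "has_disease",
                       correction = "bonferroni", alpha = 0.05, seed = 4)
res$n_rejected
#> [1] 1
subset(res$decisions, decision == 1)
#>    snp_id test decision undefined
#> 7    snp7 chi2        1         0
vapply(audit_log(res$session), function(x) x$what, "")
#> [1] "chi2 decision bits"             "chi2 undefined-statistic flags"
```

The planted SNP (case allele frequency 0.5 vs 0.2 in controls) is the single
Bonferroni-significant hit; the audit log confirms that nothing but the
decision bits and the public undefined-statistic flags was ever opened.
`run_plaintext_gwas()` with the same inputs returns identical decisions and
the identical exact (m, n) fractions.

The same pipeline is scriptable from a shell through the thin Rscript
wrapper shipped with the package:

```sh
ppgwas=$(Rscript -e 'cat(system.file("cli", "ppgwas.R", package = "ppgwas"))')
Rscript "$ppgwas" simulate --donors 400 --snps 1000 --seed 1 \
    --out-genotypes g.tsv --out-phenotypes p.csv
Rscript "$ppgwas" encode-share --genotypes g.tsv --seed 2 \
    --out-host0 h0 --out-host1 h1 --out-host2 h2
Rscript "$ppgwas" test --host-dirs h0,h1,h2 --criterion "has_disease" \
    --phenotypes p.csv --test chi2 --correction bonferroni --out decisions.tsv
```

Each host directory holds only uniform-looking shares; deleting any one of
them makes reconstruction fail (3-out-of-3).

Genotypes can also come from a TSV dialect (header `snp_id<TAB>donor...`,
one row of AA/AB/BB/NN calls per SNP) or from biallelic VCF GT fields
(REF→allele A, first ALT→allele B, any call containing `.`→NN;
multi-allelic sites are skipped with a warning).

## Limitations

This is a protocol-level simulation for method development and teaching, not
a hardened deployment: the three hosts live in one process, the dealer is
trusted, parties are honest-but-curious, and no networking, malicious
security or timing-channel hardening is provided. See the methods vignette
(`vignettes/secure-gwas-methods.Rmd`) for the model, parameter choices and
numerical details.
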