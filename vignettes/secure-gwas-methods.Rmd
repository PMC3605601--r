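---
title: "Secure association testing on secret-shared genotypes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Secure association testing on secret-shared genotypes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, the security
model it simulates, the parameters that matter, and the numerical and design
choices behind them. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem and the computation model

A case–control association scan reduces, per SNP, to a small contingency
table and a 1-df χ²-type statistic. The privacy problem is that the genotype
matrix itself must never be visible to any single party. The engine
simulated here keeps every genotype, phenotype and cohort label
*3-out-of-3 additively secret-shared* over the ring $\mathbb{Z}_{2^k}$:
a value $x$ is stored as three uniform-looking summands $x_0+x_1+x_2 \equiv x
\pmod{2^k}$, one per host. Any single share — and any pair of shares — is
marginally uniform, so one or two compromised hosts learn nothing.

The three hosts are in-process actors exchanging messages through a recorded
bus; a trusted dealer supplies correlated randomness. The adversary model is
honest-but-curious, and the simulation is functional: no real networking, no
malicious security, no timing hardening. Within that model the protocol
discipline is real and tested:

* addition, subtraction and public-constant operations are local (zero
  messages);
* multiplication uses a fresh Beaver triple $(\alpha,\beta,\gamma=\alpha\beta)$
  per element and opens only the uniformly masked differences $a-\alpha$,
  $b-\beta$;
* comparison opens only $d+r$ for a uniform dealer mask $r$;
* the number of messages depends only on operand shapes, never on data
  (asserted on the bus counters);
* every deliberate release goes through one audited `open_value()` call, and
  an end-to-end run's audit log contains decision bits, undefined-statistic
  flags and (for FDR) the rejection count — nothing else.

### Secure comparison

The dealer-assisted comparison computes $[a \ge b]$ for non-negative
operands below $2^{k-2}$: with $d = a - b + 2^{k-2} \in [0, 2^{k-1})$, the
answer is bit $k-2$ of $d$. The hosts open $c = d + r \bmod 2^k$ (uniform),
the dealer shares the bits of $r$, and the bits of $d = c - r$ are recovered
by a borrow-propagation chain over the shared mask bits with the public bits
of $c$ — one secure multiplication per bit position, $k-1$ in total. The
operand bound is the caller's obligation and is enforced at configuration
time by `ring_width_check()` (below). Correctness is verified exhaustively
on a $k=8$ ring.

## Genotype encoding and storage layout

Calls are encoded as allele-count pairs AA→(2,0), AB→(1,1), BB→(0,2),
NN→(0,0), so allele counting is arithmetic rather than string matching. The
shared database holds, per SNP, one row of $f_A$ and one of $f_B$ values,
one column per donor. Two redundant 0/1 flag rows $h_{AA}$ and $h_{BB}$ are
shared at import time (a versioned extension of the share-store format):
with them every genotype-class count and every TDT ingredient is a pure
bilinear form —

* heterozygous indicator: $i_{AB} = f_A f_B$;
* homozygous indicators: the flag rows themselves;
* missing: $i_{NN} = 1 - h_{AA} - h_{BB} - f_A f_B$;
* double-heterozygous parents: $z = (f_A^{(m)} f_B^{(m)})(f_A^{(f)} f_B^{(f)})$.

The alternative — deriving $i_{AA} = f_A(f_A-1)/2$ on shares — needs a
division by 2 that has no multiplicative inverse modulo $2^k$; the redundant
rows keep every hot-path operation a dot product, at the cost of one extra
shared row pair per SNP. This choice is verified exhaustively over all valid
encodings and all 16 parent genotype pairs.

A donor with a missing call contributes 0 to every allele and genotype
count, so NN calls silently shrink the effective $N$ for that SNP. This
follows the encoding literally; it is the documented consequence of treating
missingness as (0,0).

## Statistics as exact integer fractions

Every statistic is carried as a shared non-negative fraction $m/n$ equal to
the real-valued statistic exactly:

* Pearson χ² (allele 2×2): $m = N(ad-bc)^2$, $n = (a+b)(c+d)(a+c)(b+d)$;
* two-proportion z² : computed through the pooled-variance route
  $m = N\,(a n_2 - b n_1)^2$, $n = n_1 n_2 (a+b)(c+d)$, where
  $n_1 = a+c,\ n_2 = b+d$. On 2×2 tables this is algebraically the same
  rational number as the Pearson form; the package computes both through
  distinct code paths and the suite asserts their exact cross-multiplied
  equality rather than assuming it;
* Cochran–Armitage trend with public integer weights $(w_0,w_1,w_2)$,
  default $(0,1,2)$:
  $m = N\left(\sum_j w_j (m_2 r_j - m_1 s_j)\right)^2$,
  $n = m_1 m_2 \left(N \sum_j w_j^2 n_j - (\sum_j w_j n_j)^2\right)$;
* TDT: $m = (u-v)^2$, $n = u+v$.

Signed intermediates live in two's complement on the ring and are squared
before comparison. A denominator reconstructing to 0 (monomorphic SNP, empty
group, no informative trios) marks the statistic undefined; the pipeline
maps undefined to "not significant" and reports the flag, so a genome-wide
run never aborts. Agreement with independent floating-point oracles
(`chisq.test`, `prop.trend.test`, `mcnemar.test`) is asserted to 12 digits,
and the χ²(1) null calibration below checks the forms globally.

## Significance without floating point

For level $\alpha$, the critical value $t(\alpha)$ of χ²(1) is public, so it
is approximated once by $p/q$ with $p = \lfloor t(\alpha)\, q\rfloor$. The
decision $m/n \ge p/q$ becomes the integer comparison $m q \ge p n$ on
shares; only the resulting bit is opened (the `>=` convention holds at the
boundary). Flooring $p$ errs toward significance by at most $1/q$: decisions
can disagree with the floating-point rule only for statistics inside
$[p/q,\ t(\alpha))$, a band of width $< 1/q$ that shrinks proportionally
with $q$. The default $q = 10^6$ makes the band ≈ $9\times10^{-7}$ wide at
$\alpha = 0.05$; the suite pins the disagreement set to exactly this band on
dense statistic lattices at $q = 10^3$ and $10^6$.

**Ring width.** With $N$ donors every table entry is at most $2N$, and the
largest compared operands ($mq$, $pn$, and the sorting network's
cross-products $m_i n_j$) are bounded by $16\,(2N)^5 q$. The configuration
guard requires $16\,(2N)^5 q < 2^{k-2}$ (the comparison contract); at
$N = 1080$, $q = 10^6$ this needs $k \ge 82$, comfortably inside the default
$k = 128$, while 32-bit rings are rejected. The check is pure and public and
runs before any sharing.

**Multiple testing.** Bonferroni rescales the threshold to level
$\alpha/\text{(number of tests)}$ — nothing else changes. FDR control is a
fully oblivious Benjamini–Hochberg: the shared fractions are sorted in
descending order by a Batcher odd-even merge network (data-independent
shape, $O(M \log^2 M)$ comparators; comparator = cross-multiplied secure
comparison plus oblivious swap), the rank-$i$ statistic is compared against
the public threshold for level $\alpha i/M$, and a secure suffix-OR yields
the largest qualifying rank $j^\ast$ — which *is* the rejection count, one
of the two things BH legitimately releases. Each SNP's decision is then the
audited comparison of its own statistic against the public rank-$j^\ast$
threshold. That set provably equals the top-$j^\ast$ ranks (if $c$ SNPs
reach the rank-$j^\ast$ threshold, rank $c$ also qualifies, so $c = j^\ast$),
which avoids a second, inverse-permutation sorting pass. Undefined
statistics are obliviously rewritten to $0/1$ first and can never be
rejected. Per-rank thresholds are public because $\alpha$, $M$ and the ranks
are public.

## Cohort formation

Scenario 1 (analyst knows the cohort): the member list becomes a shared 0/1
index vector; the control group defaults to its complement. Scenario 2
(phenotypes are themselves shared): an inclusion criterion such as
`"age >= 50 & has_diabetes"` is parsed into an expression tree (grammar v1:
OR < AND < NOT, parenthesized subexpressions, integer comparisons against
public constants) and evaluated on shares — boolean leaves are the shared
attributes, comparisons use the secure-comparison protocol with the constant
shared trivially, equality is $(a\ge b)(b\ge a)$, AND is a secure
multiplication, OR is $1-(1-a)(1-b)$, NOT is $1-a$. The work depends only on
the criterion shape and donor count. Case/control disjointness is not
enforced (the complement construction gives it for free; explicit control
criteria may overlap, which reconstruction-level tests can flag but the
engine does not forbid).

## The synthetic-data generator

The generator emulates a HapMap-style panel: per SNP an allele-A frequency
drawn uniformly from 0.05–0.5 (a typical minor-allele-frequency range for
genotyping arrays; a fixed value can be given instead), genotypes sampled
under Hardy–Weinberg equilibrium, independent missingness, optional planted
SNPs regenerated with distinct case/control allele frequencies, and
parent–child trios with Mendelian inheritance in which a heterozygous parent
transmits allele A with probability τ (τ = 0.5 is the TDT null). Phenotypes
are a boolean disease flag at a given prevalence plus an integer age uniform
on 30–79, constructed so that the documented criterion `"has_disease"`
recovers the intended case set exactly.

What it does **not** model: linkage disequilibrium, population
stratification, genotyping-error structure, realistic MAF spectra. Passing
tests therefore demonstrate protocol correctness and the statistics'
sampling behaviour under clean HWE nulls and alternatives — not robustness
to confounding in real cohorts, which is out of scope for the engine.

## Problem sizes and study conditions used by the checks

The verification workloads are the package's own choices, sized to the
conditions they probe:

* exhaustive protocol checks on $k=6$ and $k=8$ rings (4096 pairs);
* secure-vs-plaintext equivalence at 270 donors × 1000 SNPs for all four
  tests and both cohort scenarios, plus a 1080-donor run (the donor range of
  typical HapMap panels at reduced SNP count) — agreement must be exact,
  fraction by fraction and bit by bit;
* null calibration on 5000 SNPs: empirical size within 3 Monte-Carlo
  standard errors of α = 0.05 at 200+200 donors, and Kolmogorov–Smirnov
  goodness of fit against χ²(1) at the 1% level. The χ²(1) law is
  asymptotic and a KS test on 5000 samples resolves deviations of
  D ≈ 0.023, while the finite-sample approximation error of the allele
  tests decays as O(1/√N) (measurably ≈ 0.04 at 200+200 donors — a property
  of the statistic, not of the implementation), so the goodness-of-fit check
  runs at 1080+1080 donors, where the approximation error sits below the KS
  resolution; SNPs are processed in blocks of 1000 to bound the shared
  database held in memory. For the TDT the statistic is a lattice with an
  atom at zero of mass ≈ $0.8/\sqrt{u+v}$, so its KS check uses 4000
  informative transmissions per SNP (drawn directly under the null); a full
  trio pipeline (1000 trios × 1000 SNPs) separately checks the TDT rejection
  rate, whose expected size under the mixed informative-count distribution
  is ≈ 0.0498;
* power: a planted SNP with case/control allele frequencies 0.5/0.2 at
  200+200 donors has allele-χ² noncentrality ≈ 79, so at the genome-wide
  Bonferroni threshold for 262,264 tests (t ≈ 27) detection is expected in
  ≳ 99.8% of replicates; 100 replicates are run and the secure decisions
  must match the plaintext oracle replicate by replicate;
* oblivious BH on 500-statistic instances (null χ² draws with 25
  noncentral spikes) against the plaintext step-up, repeated over draws.

## Numerical choices and degenerate inputs

* **Limb arithmetic.** Ring elements are little-endian base-$2^{32}$ limb
  vectors (held exactly in doubles, computed in 64-bit integers in compiled
  code); modulus-$2^k$ reduction is truncation. The exact plaintext
  reference uses an independent base-$10^6$ big-integer module in plain R,
  so secure/plaintext agreement crosses two unrelated arithmetic
  implementations.
* **Randomness.** One root seed per run splits into independent streams for
  sharing, dealer triples and comparison masks; generators never disturb the
  caller's RNG state. Rerunning with the same seed reproduces every share
  byte for byte.
* **Threshold rounding.** $p = \lfloor t\,q\rfloor$ (toward significance by
  $< 1/q$); ties at the threshold are significant.
* **Degenerate inputs.** Empty groups, monomorphic SNPs, all-missing SNPs
  and trio sets with no informative families all flow through as undefined
  statistics → non-significant, flagged, never an error. Constant-weight
  CATT vectors are rejected at the interface.
* **Sorting-network padding.** Instances are padded to a power of two with
  sentinel fractions $0/1$, which sort below every defined statistic and
  cannot be rejected.

## Known limitations

Single-process simulation (the trust separation is a modeling construct);
trusted dealer; honest-but-curious only; statistics limited to the four 1-df
tests (no genotypic 2-df χ², covariate adjustment or exact tests); no
population-structure correction; releasing only decision bits is a design
goal, so nothing in the public output allows effect-size estimation.
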