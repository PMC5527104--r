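---
title: "Detecting significantly mutated positions across a domain family"
author: "smpscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting significantly mutated positions across a domain family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smpscan)
```

## The problem

Somatic mutation catalogs are deep enough that recurrence can be assessed not
only within one gene but across a whole superfamily of homologous domains:
if a position in a shared domain fold matters for function, mutations will
accumulate at the *aligned column* across many family members even when no
single gene shows a hotspot.  `smpscan` pools somatic point mutations
(missense and silent) across the columns of a multiple sequence alignment of
a domain family — the motivating case is the ~500-domain human kinome — and
asks, column by column, whether the pooled mutations look non-random.
Columns that do are called Significantly Mutated Positions (SMPs).

The central design idea is the choice of null: mutations falling in the same
genes but *outside* the aligned domains are produced by the same mutational
processes (the same patients, the same signatures) yet carry no information
about the aligned fold.  All background quantities are estimated from those
unaligned mutations; no neutrality assumption is made about any individual
mutation.

## The background model

From the non-domain records the package estimates:

* `E_r = O_r / N_r` — expected mutations per residue of type `r`, where
  `O_r` counts non-domain mutations at type-`r` residues (silent mutations
  included, since they are part of the same process) and `N_r` counts
  type-`r` residues outside the domains.
* `P_rv` — a 20x20 row-stochastic substitution matrix from the observed
  (reference, variant) pairs; the diagonal carries the silent mass.  Rows
  never observed stay undefined rather than being smoothed (a pseudocount
  option exists for tiny fixtures but defaults to off, because at realistic
  catalog sizes smoothing would only perturb well-estimated rows).
* Patient and cancer-type count tables over the *full* dataset (domain plus
  non-domain) — the two label tests deliberately condition on the whole
  catalog, because the question they ask is whether the column's mutations
  are spread over patients/types the way the catalog as a whole is.

A column's expected count is `E_a = sum_r E_r R_ar`, with `R_ar` the number
of aligned (non-gap) residues of type `r` at the column.  A gene "aligns at"
a column only if it has a non-gap residue there; gapped genes contribute
nothing to `R_ar` and are never drawn in gene-level nulls.

## The seven tests

Recurrent mutations are informative but can be idiosyncratic to one gene, so
the panel works at three collapse levels:

* **Mutation level** (every record counts): *Mutation Number* — upper-tail
  Poisson test of `N_a` against mean `E_a`, in closed form; *Patients* and
  *Cancer Types* — chi-square goodness-of-fit of the column's label
  distribution against `E_ac = N_a N_c / N`, where a label's class `c` is
  its dataset-wide mutation count.  The null redraws `N_a` labels with
  replacement from the catalog's label multiset.
* **Residue level** (identical substitutions collapse): *Reference
  Residues* — chi-square of observed event counts per reference type
  against `E_ar = R_ar E_r`; *Variant Residues* — chi-square of produced
  amino acids against `E_av = sum_r P_rv O_ar`.  Nulls redraw the fixed
  number of events from types weighted by the expectations.
* **Gene level** (one event per gene per column): *Cancer Genes* — mean
  per-gene cancer-likelihood score of mutated genes (smaller = more
  cancer-like; lower-tail); *Gene Relatedness* — mean pairwise patristic
  distance among mutated genes on the family guide tree (lower-tail).
  Nulls draw the same number of genes from those aligned at the column,
  weighted by the `E_r` of each gene's own residue, *without* replacement —
  after gene-level collapse a gene cannot appear twice at one column, so a
  with-replacement draw would put mass on impossible configurations.

Empirical p-values use the add-one estimator
`p = (1 + #extreme) / (B + 1)` with ties counted as extreme: always
positive (so Fisher combination is defined) and valid under exchangeability.
`B` defaults to 10,000 per column per test and is configurable.  Per-(column,
test) RNG streams are derived from one master seed, so a scan is bit-for-bit
reproducible and the result does not depend on evaluation order.

Columns mutated in fewer than two distinct genes are not tested: the
gene-level statistics need at least a pair, and a single-gene column is a
within-gene hotspot question, not a cross-family one.

## Combination, FDR, and reporting

Per column the available p-values (a skipped test is dropped and the degrees
of freedom adjusted — dropping preserves validity where imputing would not)
are combined with Fisher's method, `X^2_{2k} = -2 sum ln p_i`, and BH-adjusted
across tested columns; SMPs are columns with `q < 0.10`.  An unweighted
Z-score (Stouffer) combination is computed alongside as a cross-check;
unweighted, because no test has a prior claim to more reliability — they all
consume the same catalog.  Boundary p-values (exactly 1, from permutation
ties) are clamped to `1 - 1e-4` before the normal quantile; `1e-4` is the
resolution floor `1/(B+1)` of the default permutation grid, so a tie at 1 is
treated symmetrically with a floor value.  A much smaller clamp would send
tied p-values to `|z| ~ 8` and let single ties dominate the combined score.

The per-test contribution summary counts, at raw `p < 0.05` (raw, not
adjusted: the question is which tests support an SMP, not a second round of
discovery), how many SMPs each test detects and how many columns are
supported by two or more tests.

## Group re-analysis

The same pipeline can be re-run inside a subfamily (e.g. one kinase group).
Only groups with more than 20 aligned members and more than 2,000 in-domain
mutations are eligible, and catch-all labels ("atypical", "other") are
excluded — smaller or heterogeneous groups produce calls that swing on
single mutations.  The background is refit from the members' own non-domain
mutations: the null should derive from the same genes whose domains are
being tested, and mutational processes differ between subfamilies.  FDR is
controlled per group.

## The synthetic generator

`simulate_smp_data()` builds a complete input bundle with known truth:

* A random gene tree (`ape::rtree`, depth normalized to 1, scalable) down
  which domain sequences evolve with a per-column substitution process;
  each column has its own Dirichlet-drawn residue profile (concentration
  0.2, giving the strongly conserved columns typical of domain
  alignments).  There is no indel process, so column truth is unambiguous;
  an optional gap mask (per-column occupancy uniform on 0.3–1) emulates the
  very uneven occupancy of real domain alignments, where a typical column
  aligns only a fraction of the family.
* Flanking non-domain sequence on both sides of the domain.  Defaults
  (300 columns, 300 flanking residues per side, 200 genes, 400 patients,
  baseline rate 7e-5 per residue per patient) yield roughly 5,000 mutations
  with about one third inside the domain — the proportions of a
  ~300-residue domain inside a ~900-residue protein, and the domain share
  observed in large kinome catalogs.
* A genetic-code-aware substitution spectrum: each reference amino acid
  reaches only its single-nucleotide codon neighbours (weighted by codon
  paths), with 23% silent mass on the diagonal and a 2% uniform floor for
  rare multi-nucleotide events.  Point-mutation catalogs are sparse in
  exactly this way, and the sparsity matters: a dense uniform spectrum
  would make the Variant Residues expectations far noisier than anything
  the test would meet in practice.
* Patients with lognormal burden weights, each assigned one cancer type;
  mutations inherit their patient's type.
* Planted effects per column: a rate fold enrichment, an optional forced
  variant residue (a spectrum bias at matched counts), an optional gene
  subset, and an optional score shift — enough to exercise each test's
  specificity separately.

What the generator does *not* emulate: trinucleotide signature structure,
DNA-level coordinates, indels, isoform complexity, and correlation between
a gene's conservation and its mutability.  Passing the synthetic checks
therefore demonstrates that the statistical machinery is calibrated and
recovers planted signal under the stated generative model, not that every
assumption holds in a particular real catalog.

## Calibration protocol and numerical choices

Calibration is assessed on a null family (no planted effects) at the default
scale with gap masks on, `B = 2000`, fixed seeds.  Two details matter:

* Permutation p-values are discrete and conservative by construction, with
  large atoms at 1 for conserved columns (a column with one residue type
  can only ever tie its null).  For uniformity diagnostics the package
  offers tie-randomized p-values (`randomized = TRUE`), the standard
  randomized-p construction that is exactly uniform under exchangeability;
  reported pipeline p-values always remain the conservative add-one ones.
* The Mutation Number test is assessed over *all* columns.  The
  two-mutated-genes eligibility filter conditions on the mutation count
  itself, so within the filtered set the count test's null is truncated
  and no count-based test could appear uniform there; the six conditional
  tests are unaffected because they hold `N_a` fixed.

Other numerical choices: entropy is Shannon entropy in nats over non-gap
residue frequencies (base configurable); protein positions are 1-based and
alignment columns are reported 1-based; duplicate records (same gene,
position, substitution, patient and cancer type) are removed whatever their
source; records whose reference residue contradicts the chosen isoform are
dropped after an optional offset-reconciliation step that keeps the offset
conserving the most mutations; missing cancer types become the reserved
`"missing/other"` label and participate in the Cancer Types test as a
category of their own.

Problem sizes used by the test-suite and acceptance checks (chosen so the
whole suite runs comfortably on one CPU): calibration at 200 genes x 300
columns with `B = 2000`; planted-recovery at 100 genes x 150 columns over
20 seeds with `B = 1000`; background recovery at ~50,000 non-domain
mutations; enumeration oracles at up to 4 events and 4 categories with
`B = 10,000`.

## Known limitations

* With very sparse backgrounds (small gene groups), `E_r` can be zero and
  substitution rows undefined; affected tests are recorded as missing at a
  column rather than silently imputed.  The group eligibility thresholds
  exist precisely to keep re-analyses out of this regime.
* The Variant Residues expectations inherit sampling noise from `P_rv`;
  at catalog sizes far below ~5,000 mutations the test runs mildly hot.
* Residue-level events at the same site with different variants share a
  reference residue, a mild dependence the multinomial null ignores; its
  effect is visible only as slight extra mass in the far tail of the
  Reference Residues statistic at small `N_a`.
* The Poisson count test relies on an accurately estimated `E_r`; shared
  estimation error shifts all columns coherently, which matters only when
  the non-domain catalog is small.

## A worked example

```{r example, eval = FALSE}
cfg <- smp_sim_config(n_genes = 100, domain_length = 150,
                      flank_length = 150, n_patients = 300,
                      baseline_rate = 3e-4, seed = 1,
                      planted = list(plant(column = 40, fold = 20)))
sim <- simulate_smp_data(cfg)
fit <- smp_scan(sim$family$alignment, sim$mutations, sim$family$sequences,
                sim$family$scores, sim$family$distances,
                smp_control(B = 1000, seed = 1))
summary(fit)
plot(fit)
report(fit, sim$family$alignment)
```
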