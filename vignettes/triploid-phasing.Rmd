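---
title: "Phasing a triploid individual from SNP fragments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasing a triploid individual from SNP fragments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triphase)
```

## The problem

A triploid organism carries three copies of each chromosome, hence three
haplotypes: three binary strings over its single-nucleotide polymorphism
(SNP) sites, with `0` for the major and `1` for the minor allele.
Sequencing reads observe short stretches of one (unknown) copy; after
alignment and allele-calling each read becomes a *fragment*: a row of an
`m x n` matrix `M` over `{0, 1, -}`, null (`-`) outside the sites the read
covers.  Genotyping gives, per site, the unordered conflation of the three
alleles — equivalently the column allele sum `s_j` in `{0, 1, 2, 3}` — but
not their assignment to chromosome copies.  Sites with `s_j` in `{1, 2}`
are heterozygous; only they carry phase information.

Haplotype assembly under the *minimum error correction with genotype
information* (MEC/GI) model asks for the smallest number of entry flips in
`M` such that the corrected fragments partition into three mutually
compatible classes whose consensus haplotypes match the genotype.  MEC/GI
is a hard combinatorial problem; this package implements a fast greedy
solver for the triploid case plus the machinery needed to study it:
accuracy measures, fragment simulators, and an exhaustive exact solver for
small instances.

## The solver

`ehtld()` (enumeration haplotyping triploid with least difference)
reconstructs the heterozygous sites left to right.

**Preprocessing** (`preprocess()`).  Homozygous columns are removed from
`M` and the genotype (their single allele value is recorded for
re-insertion), rows left with no covered site are dropped, and the
remaining rows are sorted by `l(i)`, the column of their leftmost covered
site (stable sort, so input order breaks ties — the sort only matters for
cache locality, not for results).  For each column `j` the set `r(j)` of
covering rows is computed.

**Column-wise enumeration.**  At a heterozygous column with allele sum
`s_j` exactly three assignments of alleles to the three haplotypes are
genotype-compatible: `(0,0,1), (0,1,0), (1,0,0)` for `s_j = 1` and
`(0,1,1), (1,0,1), (1,1,0)` for `s_j = 2` (`enumerate_column_values()`,
always in this order).  Given the partial haplotypes `h'` over columns
`1..j-1`, each candidate `a` is scored by

```
D(a) = sum over i in r(j) of  min over k in {1,2,3} of
       HD(h'_k + a_k, M[i, ], l(i), j)
```

where `HD(X, Y, s, e)` is the null-aware Hamming distance over the window
`s..e`: positions where either sequence is null never count as mismatches.
Each covering fragment is charged its distance to the *best matching*
haplotype over the window from its own first site up to the current
column; the candidate with the smallest total is kept.  Fragment positions
to the right of `j` are never consulted — the solver has no lookahead, so
a fragment whose gap spans column `j` influences later columns only.
Because each fragment is re-anchored at its own `l(i)`, a wrong decision
at one column does not propagate through the score of unrelated later
columns.

**Numerical and tie-break choices.**

* Column 1 has no left context; all three candidates are equivalent up to
  relabelling of the haplotypes, and every downstream measure is invariant
  to relabelling.  It is fixed canonically to `(1,0,0)` / `(1,1,0)`.
* Ties in `D` are broken towards the first candidate in the enumeration
  order above, making the solver fully deterministic (bit-identical output
  for identical input).
* A heterozygous column covered by no fragment is unconstrained; the first
  candidate is taken and a warning is emitted (suppress with
  `quiet = TRUE`).
* The implementation keeps, per fragment and haplotype, the running
  windowed distance and extends it by one column per step, so the
  enumeration stage costs O(coverage x sites x 3) rather than rescoring
  windows from scratch; `score_assignment()` exposes the direct
  definitional evaluation, and the test suite checks the two agree
  everywhere.

**Augmenting** (`augment()`).  The removed homozygous columns are
re-inserted with their recorded allele in all three haplotypes.  The
output is always compatible with the genotype.

```{r}
M <- snp_matrix(c("001-", "-011", "110-", "-100"))
G <- as_genotype(c(1L, 1L, 2L, 2L))
ehtld(M, G)
```

## Accuracy measures

Three standard measures are implemented, all invariant under relabelling
of the reconstructed haplotypes:

* **Reconstruction rate** (`reconstruction_rate()`): the fraction of
  correctly phased alleles, maximised over the six relabellings:
  `RR = 1 - min_pi sum_k HD(h_k, hhat_pi(k), 1, n) / (3n)`.  The double
  permutation sometimes seen in this definition is redundant — only the
  relative relabelling matters — so a single minimisation over the six
  permutations is used.
* **Vector error** (`vector_error()`): the polyploid generalisation of
  switch error — the minimum number of switch points partitioning the
  heterozygous columns into segments inside which the reconstruction is a
  fixed permutation of the truth.  Computed by a dynamic program over the
  six permutations: a permutation *matches* a column when it maps the true
  column onto the reconstructed one elementwise (repeated alleles within a
  column make several permutations match, and the program minimises over
  all of them).  Homozygous columns carry no phase and are skipped; it is
  reported as a switch count, so a reconstruction that is a global
  relabelling of the truth scores 0.  A column admitting no matching
  permutation can only arise from genotype-incompatible input and signals
  an error rather than guessing a convention.
* **MEC score** (`mec_score()`): the summed minimum per-fragment distance
  to the three reconstructed haplotypes — the number of corrections needed
  for every fragment to agree with its best-matching haplotype.

## The simulators

No public triploid truth sets exist, so evaluation uses simulation.
`generate_haplotypes(n, d)` draws the first haplotype uniformly, flips
exactly `round(d * n)` uniformly chosen sites to obtain the second (`d` is
the divergence *fraction*; settings like `d = 0.3` at `n = 100` make no
sense as absolute distances), and builds the third as a per-site mosaic of
the first two with probability 1/2 each.  The heterozygous sites are then
exactly the `round(d * n)` sites where the first two copies differ.

Two read layouts are emulated, parameterised by `sim_config()`:

* **Shotgun mode** (`simulate_celsim()`): `m1` single fragments with
  lengths uniform on `[f_min, f_max]` SNP sites (defaults 3 and 7, the
  practical range for shotgun data) and `m2` mate-pair fragments of
  nominal length `n/10`.  A mate-pair consists of two reads of
  `floor(n/10)` sites from the same haplotype separated by a
  `floor(n/10)`-site null gap — the same read/gap/read thirds geometry as
  the 454 mode below.  Fragment counts follow the nominal bookkeeping
  `m1 = round((c/2) n / mean(f_min, f_max))`,
  `m2 = round((c/2) n / floor(n/10))`, so each class carries nominal
  coverage `c/2`; since a mate-pair's two reads cover twice its nominal
  length, realized covered entries total about `1.5 c n`.  This geometry
  was chosen over a single contiguous `n/10` block because mate-pairs
  exist precisely to provide long-range linkage: with only short
  contiguous fragments, relabelling two haplotypes inside a run where they
  locally agree is invisible to every fragment, and phasing accuracy would
  *fall* as divergence grows instead of staying flat.
* **454 mode** (`simulate_metasim()`): `m = round(3 n c / ((1+p_m) f_len))`
  fragments of which a fraction `p_m` (default 0.25) are mate-pairs — two
  reads of `f_len` sites around an `f_len`-site gap, total span
  `3 f_len` — and the rest single reads of `f_len` sites, satisfying the
  coverage identity `(m1 + 2 m2) f_len / (3n) = c`.  Read lengths are
  fixed at `f_len` exactly rather than drawn from an empirical
  pyrosequencing length distribution, to keep unmodelled variance out of
  benchmark comparisons.

Start positions and haplotypes of origin are uniform; both reads of a
mate-pair always come from the same haplotype.  `plant_errors()` flips
each covered entry independently with probability `p_s` (`0 <= p_s <
0.5`) and records the flipped positions, so every instance carries its
clean matrix, its corrupted matrix and full provenance.  Everything is
reproducible from the seed.  Fragment counts round half away from zero
with a minimum of one per enabled class.

What the simulators do *not* model: base quality scores, indels,
alignment error, allele-calling error correlated along a read, non-uniform
fragment start distributions, and more than two alleles per site.  Passing
the benchmark suite therefore shows that the solver handles the
*fragment-matrix* abstraction of these platforms well, not that it is
robust to upstream artefacts of real pipelines.

## The exact oracle

`exact_mecgi()` enumerates every genotype-compatible assignment over the
heterozygous columns (three per column, with column 1 fixed canonically to
quotient out relabelling) and returns the minimum-MEC triple, the optimum
value and the number of optima found.  The search space is
`3^(n_het - 1)`, so it is guarded by `max_het` (default 10).  It exists to
bound the greedy solver in tests: the greedy MEC can never beat it, and on
error-free instances whose heterozygous columns are chain-connected by
co-covering fragments both attain MEC 0.

## Validation set-up and known limitations

The package's own benchmark runs (see `run_benchmark()` and the test
suite) use 100 replicate instances per parameter setting at `n = 100`
(plus one grid at `n = 1000`), the scale at which means of RR/VE/MEC are
stable to a few parts per thousand.  Two behaviours are worth knowing:

* With the span of a mate-pair tied to `n/10`, long-range linkage *grows*
  with the haplotype length, so phasing long haplotypes at fixed coverage
  is mildly easier per site than short ones in this emulation.  Published
  shotgun-simulation studies sometimes show the opposite trend; absolute
  read lengths there are fixed by the instrument, not by `n`.
* On error-free instances the greedy solver can commit, at a column where
  the candidates tie, to a phase that a fragment whose *gap* spans the
  column later contradicts; with no lookahead this surfaces as a small
  positive MEC (a correction or two per instance) even at `p_s = 0`,
  and as occasional extra switch points.

The solver targets ploidy 3 only: the enumeration set (three candidates
per column), the canonical initialisation and the six-permutation metrics
are all specific to three haplotypes.  Generalising the enumeration to
higher ploidy would replace "3 candidates" by the compositions of `s_j`
into `k` binary alleles and the permutation group accordingly.
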