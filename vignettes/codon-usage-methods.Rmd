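---
title: "Methods: codon usage bias indices, comparative analyses and the K2P/NJ stage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon usage bias indices, comparative analyses and the K2P/NJ stage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonbias)
```

# Scope and model

`codonbias` quantifies codon usage bias (CUB) in validated coding
sequences. A CDS is accepted only if it starts with ATG, ends with a
stop codon (TAA/TAG/TGA), has length divisible by three, and contains
no bases outside {A,C,G,T} (lowercase and U are normalised on input;
any other IUPAC code rejects the record with a machine-readable
reason). The genetic code is fixed to the standard nuclear table; the
59 codons of the 18 degenerate amino-acid families (Leu/Ser/Arg 6-fold,
Ile 3-fold, five 4-fold, nine 2-fold) are the domain of every
synonymous-usage statistic, with stops, ATG and TGG always excluded.

## Stop-codon handling

Composition tables include the terminal stop codon by default
(`include_stop = TRUE`), because whole-CDS base counts only reconcile
with the sequence length that way (a 1152 bp CDS has 384 codons
including its stop). The synonymous-usage indices (RSCU, ENC, Fop,
RCBS) always exclude it, since a stop codon belongs to no synonymous
family. Both behaviours sit behind the one explicit flag; published
per-position count tables appear to follow the same convention, which
is why the default reproduces them.

## GC3 versus GC3s

Two closely related quantities are deliberately both reported. `GC3` is
the G+C fraction at third positions of *all* counted codons (stop
included under the default flag), which is what whole-CDS composition
tables print. `GC3s` restricts to third positions of codons in
degenerate families (stops, ATG, TGG excluded) and is the quantity the
ENC literature conditions on. They differ by at most a few tenths of a
percent on real genes; since published tables are often ambiguous about
which was used, the package emits both columns rather than guessing.

## Skews

`skew(x, y) = (x − y)/(x + y)` is orientation-sensitive, and published
GC3-skew columns are printed in either orientation (sometimes both
within one study: a text range of 0 to −0.09 next to a positive table
column). The core operation is therefore orientation-agnostic, and the
composition profile reports both `gc3_skew_gc` ((G3−C3)/(G3+C3)) and
`gc3_skew_cg` (its negation), with the orientation in the column name.
A zero denominator returns 0 with a warning rather than NaN.

# The bias indices

## RSCU

`RSCU(c) = g_c · n_i / Σ_family g`: the observed count over the count
expected if the family's `n_i` codons were used equally. Within every
family with at least one occurrence the values sum to `n_i` (a tested
invariant). A family with zero occurrences yields missing values — not
zeros, which would understate usage of the other codons. The
conventional thresholds are kept as flags: preferred (> 1) and
over-represented (> 1.6). For multi-gene tables `rscu_report()` offers
both the mean-of-genes RSCU (the usual presentation alongside pooled
counts) and RSCU recomputed from pooled counts; the two differ in the
second decimal and the choice is the caller's.

## ENC

`ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, where `F_k` averages the codon
homozygosity `F` of the degeneracy-`k` families present in the gene.
The default estimator is the with-replacement form `F = Σ p²`: it is
the only choice under which the two analytic endpoints hold exactly at
any gene length — a gene using one codon per family gives every
`F = 1` and `ENC = 2 + 9 + 1 + 5 + 3 = 20`, and a gene using all
synonymous codons equally gives `F_k = 1/k` and
`ENC = 2 + 18 + 3 + 20 + 18 = 61`. Wright's bias-corrected estimator
`(nΣp² − 1)/(n − 1)` is available via `estimator = "wright"` for users
who prefer the small-sample correction; it skips families observed
fewer than twice. When a gene lacks 3-fold usage entirely (no Ile),
`F3` is imputed as `(F2 + F4)/2` — the conventional fallback — and
flagged in the result's attributes. ENC is clamped at 61 from above;
values below 20 cannot arise under the Σp² estimator. ENC is invariant
under codon-order permutation and synonym relabeling, and decreases
monotonically as usage concentrates (both tested).

## Fop

Fop is the fraction of degenerate-family codon occurrences that use the
family's optimal codon. Absent an organism-specific optimal-codon list,
the optimal codon of each family defaults to its most frequent codon
*in that gene*, with ties broken alphabetically for determinism; an
explicit `optimal_set` overrides this. Published Fop columns that sit
at 0.305–0.306 for every species are numerically ≈ 18/59 and are not
reproducible under any standard definition we know; the package
documents its definition and makes no attempt to match such values.

## RCBS

For codon `c = b1 b2 b3`, the expectation under positional
independence is `E[O_c] = O_tot · f1(b1) f2(b2) f3(b3)` with the `f_p`
estimated from the same gene (stop codon excluded throughout), and
`w_c = (O_c − E[O_c])/E[O_c]`. The gene score is

```
RCBS = exp( (1/O_tot) Σ_c O_c · log(1 + w_c) ) − 1
```

i.e. an observed-count-weighted geometric mean of `O_c / E[O_c]`,
minus one. Some published statements of the formula take `log w_c`
bare, which is undefined whenever a codon is under-represented
(`w_c < 0`); the original definition's `log(1 + w_c)` is implemented
and the deviation noted here. Codons with `O_c = 0` contribute
nothing. RCBS depends only on counts, hence is order-invariant
(tested against a brute-force oracle).

# Comparative layer

Summary tables give the arithmetic mean and n−1 SD per column;
percent-scale columns are summarised with their SD on the proportion
scale, matching the convention of composition tables that print means
in percent with proportion SDs. Per-codon correlations against GC3s
use Pearson's r with the two-sided t-transform p-value on n−2 df;
codons with zero variance across genes are flagged not-computable
rather than dropped silently. No multiple-testing correction is
applied to the 59 per-codon tests in the headline columns — matching
how such heat maps are usually reported — but a Benjamini–Hochberg
column is always emitted alongside. The correlation variable defaults
to RSCU (scale-free across genes of different length), with raw counts
available by flag; the compositional variable defaults to GC3s with
GC3 by flag.

RSCU clustering uses average linkage on Euclidean distances for both
genes and codons: deterministic given the matrix, no random
initialisation, ties resolved by `hclust`'s fixed ordering. Missing
RSCU values (absent families) are zero-filled for the distance
computation and reported in a mask. Cells are banded at the 1 / 1.6
thresholds to mirror the usual three-colour heat-map semantics.

# Phylogenetic stage

The phylo stage consumes an *already aligned*, equal-length input;
multiple sequence alignment is out of scope (for real data, e.g.
`mafft` output is read directly). Complete deletion removes every
column containing a gap or ambiguous base in any row — the
whole-matrix analogue, not pairwise deletion.

The Kimura 2-parameter distance is computed from the closed form
`d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q)` with `P`/`Q` the observed
transition/transversion proportions; `1 − 2P − Q ≤ 0` or `1 − 2Q ≤ 0`
raises a saturation error rather than returning NaN. The in-package
implementation is cross-checked in the tests against
`ape::dist.dna(model = "K80")`, and reduces to the Jukes–Cantor
distance when transitions are one third of all changes (tested
numerically). Tree building is Saitou–Nei neighbor joining via
`ape::nj` — exact on additive matrices (tested on trees with known
path-length matrices) — with negative branch-length estimates clamped
to zero and counted. Bootstrap support resamples columns with
replacement under a single user-visible seed, re-runs K2P + NJ per
replicate, and scores each internal bipartition of the point-estimate
tree with `ape::prop.clades`; saturated replicates are skipped and
counted, with a warning beyond 1%. Newick output (with integer support
labels) round-trips through `ape`'s reader.

# Synthetic data

The generators define the package's test bed and its statistical
assumptions:

- `generate_cds()` draws amino acids i.i.d. — by default uniformly over
  the 18 degenerate families with Met and Trp at weight 0.1 each
  (occasional, as in real proteins, without dominating composition) —
  then draws a synonymous codon per site from per-family probability
  vectors (default uniform). All outputs pass validation, and
  generation is a pure function of its arguments, seed included.
- `make_extreme_cds()` is the deterministic companion used for the ENC
  endpoints: 10 occurrences of one codon per family (ENC exactly 20) or
  10 of every codon (ENC exactly 61).
- `generate_gc3_series()` puts total weight `g` on the G/C-ending
  codons of each family (every degenerate family has at least one
  G/C-ending and one A/T-ending codon, so any `g` in (0,1) is
  feasible); measured GC3s converges to `g` at the binomial 1/√n rate,
  and tests use 3-SE tolerances at fixed seeds.
- `evolve_alignment()` simulates per-site independent evolution under
  the K80 model with exact matrix-exponential transition probabilities
  (transitions at `kappa` times each transversion, branch lengths in
  expected substitutions/site, uniform root), so long branches are
  exact rather than event-approximated. No indels, no rate
  heterogeneity, no codon structure.

What the generators deliberately do not emulate: realistic amino-acid
composition, autocorrelation of codon usage along a gene, context-
dependent mutation, alignment error, or selection at the protein
level. Tests passing on synthetic data therefore validate the
*estimators and pipeline plumbing*, not claims about any particular
genome.

# Problem sizes and numerical choices

The test suite runs at deliberately modest sizes — genes of 80–400
codons for index tests, a 10,000-codon gene for frequency convergence,
alignments of 600–5,000 sites with 15–20 replicates for distance
recovery, bootstrap checks at 30–50 replicates — chosen so the whole
suite completes in seconds while keeping all 3-SE statistical bounds
comfortably powered. Internal values are kept at full double precision
everywhere; rounding (percent to 1 decimal, skews to 2–3) happens only
at the TSV serialisation layer of `run_pipeline()` and can be disabled
(`digits = NULL`). Tie-breaks are alphabetical (optimal codon,
highest-RSCU codon) or input-order (clustering), so every result is
deterministic given input, configuration and seed.

# Known limitations

- Fop without an external optimal-codon list measures within-gene
  concentration, not translational optimality against tRNA pools.
- RCBS expectations use the gene's own positional frequencies; very
  short genes make those frequencies noisy and the score unstable.
- The GC3s/GC3 ambiguity in published tables cannot be resolved
  post hoc; both are reported, and cross-study comparisons should say
  which they use.
- The phylo stage assumes a trustworthy alignment; no model selection
  beyond K2P is offered, and rate heterogeneity is not modelled.
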