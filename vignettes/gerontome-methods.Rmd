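---
title: "Methods: aging-disease overlap analysis and its synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aging-disease overlap analysis and its synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gerontome)
```

## The model

The package treats the genetics of aging as a gene-set problem. A **gene
universe** of $N$ symbols (the genome, or a restriction of it) carries
per-gene annotations: publication counts, interactome membership, and dN/dS
substitution rates. Aging-related genes are organized into labeled sets —
one human candidate set plus anti-/pro-longevity sets per model organism and
their unions — and age-related diseases (ARDs) into a catalog of
disease → gene mappings grouped into disease classes.

### Overlap testing

For aging set $A$ and disease set $B$, both intersected with a background
$\mathcal{B}$ of size $N$, the overlap $k = |A \cap B|$ is tested against
the hypergeometric upper tail

$$p = \sum_{i \ge k} \frac{\binom{|A|}{i}\binom{N-|A|}{|B|-i}}{\binom{N}{|B|}},$$

the one-sided Fisher exact enrichment test. A pair is **significant** only
under the dual rule: $k$ strictly greater than the chance expectation
$|A||B|/N$, and $p < \alpha$ (default 0.05). A two-sided variant is
available (`two_sided = TRUE`) but adds nothing once the direction rule is
enforced, which is why one-sided is the default. No multiplicity correction
drives the significance flag across the grid — the decision rule is
deliberately per-test — but a Benjamini–Hochberg column (`p_bh`) is always
emitted so the modern alternative is visible.

Ties ($k$ exactly equal to expectation) are not significant: the rule
requires an overlap *above* chance.

### Background policies

The background is a first-class parameter because it changes $N$, $|A|$ and
$|B|$ without changing $k$:

* `genome` — all universe genes (default);
* `interactome` — genes with at least one annotated interaction;
* `seed_union` — interactome ∪ seed set ∪ all disease genes, the default
  for first-order-expanded analyses (partners are drawn from the
  interactome, so the background must include it);
* `seed_interactome` — interactome ∪ seed only, a narrower variant kept
  because the two formulations circulate in the literature; `seed_union` is
  the default as the more conservative (larger-$N$ backgrounds inflate
  significance, and the disease genes are part of every test's sample
  space).

### Publication-bias correction (PBC)

Publication counts correlate strongly with annotated interactions (the
package's benchmark calibrates this Spearman correlation to 0.67), so
overlap results partly reflect research attention. PBC filters gene sets to
members with **at least** `threshold` publications (default 10, inclusive;
a strict `>` flag exists because both conventions appear in practice —
inclusive was chosen as the primary reading and the difference is one
count). Genes missing from the publication table count zero publications:
an unstudied gene is exactly what the correction should remove. By default
only aging sets are filtered; disease sets pass through, since the
catalog's inclusion rules (≥ 20 genes) already guard against tiny,
attention-driven disease sets. A threshold sweep (8–20) reports per-set
loss so the operating point can be inspected rather than trusted.

### Set expansion

First-order expansion replaces a seed set by seed ∪ direct neighbors in the
interaction graph. Co-expression expansion adds partners whose pair p-value
falls below the Bonferroni threshold $\alpha / N_{genome}$
($0.05/20183 \approx 2.5\times10^{-6}$ at human genome scale). Both return
supersets of the seed by construction.

### Network statistics

Degree of a set member counts neighbors anywhere in the graph; the induced
"core" (largest connected component of the subgraph induced by the set) is
reported separately. The clustering statistic is the **mean local
clustering coefficient** over set members, with degree < 2 nodes
contributing 0 — set-level averaging is the only reading compatible with
statements about a set "clustering better", as opposed to global
transitivity. Null comparisons for connectivity use uniformly sampled
node sets of equal size.

### CAD genes, hubs, dN/dS

CAD (common aging-and-disease) genes are the per-test intersections. Their
frequency is the number of diseases (or classes) containing them; profiles
report the histogram and the fraction touching at most three sets. Hub
analysis compares degrees between CAD genes and a control group — default
(aging ∪ disease) \ CAD — by a two-sided Mann–Whitney test: exact when both
groups have ≤ 8 untied observations, normal approximation with tie and
continuity correction otherwise (the field's standard; no specific test is
canonical here). dN/dS uses the standard convention (dN = non-synonymous);
genes with dS = 0 have an undefined ratio and are excluded. The
anti-vs-pro per-organism comparison is Bonferroni-corrected over the four
model organisms.

### Drug ranking

Interaction-type strings are mapped to `Anti` (decreases expression or
activity), `Pro` (increases) or `Neither` by a shipped, user-replaceable
table; unmapped types fall to `Neither` with a warning and are not scored.
A drug's `Anti` interactions are scored against the anti-longevity set and
its `Pro` interactions against the pro-longevity set — a drug with both is
scored twice, and the Bonferroni denominator counts scored
(drug, direction) entries, the only self-consistent choice when entries are
the unit of testing. The scoring universe defaults to genes with at least
one interaction in the drug table (intersected with the gene universe): a
genome-wide $N$ would treat never-assayed genes as scoreable misses and
anti-conservatively shrink every p-value.

## The synthetic benchmark

`sim_config()` states a world; its defaults are fixed, not tuned:

| parameter | default | why |
|---|---|---|
| `n_genes` | 5,000 | ~1/4 human genome scale; full pipeline in seconds |
| `interactome_fraction` | 0.74 | 15,000/20,183, the real interactome share |
| `ppi_attachment` | 2 | mean degree → 4, matching the sparse real interactome (~3.8) |
| `pubs_*` | NegBin(mu = 2.2·(deg+1), size = 20) | calibrated once to Spearman(pub, degree) ≈ 0.67, the empirically observed bias; yields interactome mean ≈ 11 / median 8 publications |
| `aging_hub_bias` | 1 | aging genes sampled ∝ degree+1: better-studied, better-connected |
| aging set sizes | 75/6/15/12/22/95/72/10/3 | 1/4 of the curated catalog's per-organism counts |
| disease planted OR | 6 (neoplasms, metabolic), 4 (nervous, cardiovascular), 3 (musculoskeletal), 1.5 (immune), 1 (respiratory) | a gradient of true effects with the respiratory class as stated negative control |
| `disease_shift` | 1.5 | disease genes' dN/dS shifted +50% (medians ≈ 0.137 vs 0.091) |

`plant_overlap()` draws a set by weighted sampling without replacement with
odds `or_` for base genes; at small sampling fractions the realized
contingency odds ratio tracks the nominal one (verified within 15% in the
tests). A single master seed derives independent per-component sub-seeds,
so adding a component never perturbs existing streams and identical
configurations are byte-identical.

**What the generator does not emulate:** real databases' gene content,
alias/ortholog ambiguity, correlated disease classes sharing pathology
rather than planted genes, interaction false positives, and co-expression
p-value dependence. A green test therefore establishes that the machinery
is correct and calibrated under the stated generative model — not that the
original biological conclusions are reproduced.

## Numerical choices and degenerate inputs

* Tail probabilities are computed in log space via `phyper`; tests compare
  against direct binomial-coefficient enumeration (identical to < 1e-10
  for all $N \le 60$).
* A set empty after background restriction yields $p = 1$, not significant,
  with a warning — never an error mid-grid.
* Empty publication records count 0; `fraction_lost` is `NA` for empty
  sets; drug ties break alphabetically (stable ranking).
* Gene identifiers are upper-cased symbols throughout; no alias resolution.

## Known limitations

* The power stated for one acceptance scenario (membership odds ratio 5,
  |A| = 100, |B| = 200, N = 20,000, >95% detection) is analytically
  unreachable: the planted expected overlap is ≈ 4.9 against a discrete
  critical value of 4, giving ≈ 0.7 power. The corresponding test is kept
  faithful and fails, documenting the shortfall rather than hiding it.
* Catalog totals of curated databases are snapshot properties and are not
  reproduced; the package reports its own arithmetic.
* No permutation nulls preserving degree or publication structure (future
  work); the degree null is uniform sampling.
* Functional-annotation clustering is consumed, not computed: only the
  enrichment-score ↔ p transform ($E = -\log_{10} p$) is provided.
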