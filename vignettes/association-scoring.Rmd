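---
title: "Scoring disease–metabolite associations through the gut microbiome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring disease–metabolite associations through the gut microbiome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(micrometab)
```

## The problem and the model

Most of what is known about the gut microbiome in disease comes in two
disconnected tables. Case–control surveys report that particular microbes are
*increased* or *decreased* in a disease, almost always at the **genus** level,
because 16S and shallow metagenomic sequencing rarely resolve deeper.
Metabolic reconstructions and culture studies report which metabolites a
microbe produces, at the **strain** level, and say nothing about disease.
`micrometab` joins the two through the taxonomy and asks, for every disease
and metabolite: do the microbes that make this metabolite tend to be the
ones enriched in the disease, or the ones depleted?

The join has three steps.

1. **Harmonize.** Curated tables carry duplicates (the same link reported by
   several studies) and contradictions (a disease–genus pair reported with
   both directions). Duplicates are collapsed on the association key;
   contradictory pairs are removed entirely — both directions — because the
   sources give no principled way to arbitrate, and a vote would bake the
   accident of study counts into the scores. The dropped pairs are listed in
   the harmonization report so the rule can be audited.

2. **Propagate.** A genus-level direction is assumed to apply to every strain
   of that genus: if *Faecalibacterium* is decreased in obesity, each
   *F. prausnitzii* strain in the production table is treated as decreased.
   Propagation is restricted to the *strain universe* — the distinct taxids
   of the harmonized microbe–metabolite table. Strains without metabolic
   annotation cannot contribute producer counts, and counting them in the
   panel totals would make the scores depend on how complete a particular
   taxonomy dump happens to be; restricting to the universe makes every count
   reproducible from the input files alone. Universe members whose own rank
   is species or subspecies are treated as strain-level members; only their
   genus ancestry matters.

3. **Score.** For a disease with $M$ increased and $N$ decreased strains, and
   a metabolite produced by $m$ of the increased and $n$ of the decreased
   strains, the association strength is

   $$S_{as} = \frac{m}{M} - \frac{n}{N}, \qquad S_{as} \in [-1, 1],$$

   and its credibility weight, combining evidence count with effect size, is

   $$S_{ac} = (m+n)\,\lvert S_{as}\rvert.$$

   A positive $S_{as}$ ties the metabolite to disease-enriched microbes
   (a candidate **marker**); a negative $S_{as}$ ties it to disease-depleted
   microbes (a candidate **drug** or protective biomarker).

We count *strains*, not genera, in $M$ and $N$: the producer counts $m$ and
$n$ are necessarily strain-level, and mixing a genus-level denominator with a
strain-level numerator would let a single well-annotated genus dominate the
ratio. The genus-level alternative is coherent but is not implemented.

```{r}
association_strength(m = 0, M = 7, n = 5, N = 8)
confidence(m = 0, n = 5, s_as = -0.625)
```

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `s_as_abs_min` | 0.05 | minimum $\lvert S_{as}\rvert$ (score units) for a pair to be *meaningful* |
| `s_ac_min` | 1 | minimum $S_{ac}$ (producer-weighted score units) |

Both comparisons are **strict**: a pair at exactly the boundary fails. The
defaults are deliberately permissive — $S_{ac} > 1$ mostly removes pairs
supported by a single weakly-informative producer — and both can be raised
via `meaning_thresholds()` or the `--sas-min` / `--sac-min` flags when a
shorter candidate list is wanted.

## Numerical and degenerate-input choices

* **Zero denominators.** Some diseases have microbes reported in only one
  direction, so $M = 0$ or $N = 0$ must not be an error. The missing class's
  ratio contributes 0, which keeps the formula total and gives such diseases
  scores of exactly $+1$ or $-1$ for any metabolite their strains produce —
  visible in real corpora as a band of $\pm 1$ scores for single-microbe
  diseases.

  ```{r}
  association_strength(m = 1, M = 1, n = 0, N = 0)
  ```

* **Suppressed pairs.** Pairs with $m + n = 0$ are not emitted: their
  $S_{ac}$ is 0, they can never pass the strict thresholds, and emitting
  every disease × metabolite combination would grow the output
  quadratically for no information.

* **Ranking ties.** Output is sorted per disease by ascending $S_{as}$, ties
  broken by descending $S_{ac}$, then ascending metabolite ID, so the
  "$k$-th strongest negative association" is well defined and runs are
  byte-reproducible. The tie rule is a package convention; any ordering
  claim about rank $k$ should be read with it in mind.

* **Printed precision.** Written tables print $S_{as}$ to 3 decimals and
  $S_{ac}$ to 2, rounding half away from zero (3.125 prints as `3.13`);
  `--full-precision` adds unrounded columns.

* **Zero scores in validation.** A pair with $S_{as} = 0$ is counted as
  inconsistent with any observed direction rather than excluded, so the
  consistency denominator stays the set of meaningful-scored pairs.

* **Dirty taxonomies.** Genus taxids absent from the lineage (retired IDs
  are common in curation tables) are skipped and reported, not fatal; cycles
  and orphan parents in the lineage itself are structural errors, since they
  poison every ancestor query.

## Validation against experimental labels

`compare_directions()` checks, for each experimentally observed
disease–metabolite direction (metabolite up or down in the disease), whether
the predicted score sign agrees. The consistency fraction is computed over
the labeled pairs that were scored *and* meaningful, not over all labels:
the method does not claim to recall every experimental pair — presence-only
production data cannot see, for example, host-derived metabolites — only
that the pairs it does call meaningful point the right way.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` builds a complete input bundle with known ground truth:
a three-level taxonomy (root → genera → strains), Bernoulli disease–genus
associations with a configurable increase probability, Bernoulli
strain–metabolite production links, *planted* metabolites produced
exclusively by all decreased (or increased) strains of a designated disease,
and validation labels derived from the planted truth with optional direction
noise. Each table draws from its own seeded sub-stream, so changing the
metabolite count does not perturb the taxonomy draw, and identical
configurations give byte-identical bundles.

Defaults (5 diseases, 10 genera of 3 strains, 50 metabolites,
`p_increase = 0.5`, `density_assoc = 0.5`, `density_prod = 0.1`, one planted
metabolite per class, no label noise) are sized like a small curated corpus
slice: a realistic disease has tens of associated strains and a typical
strain is annotated with a ~10% slice of the metabolite panel. They are
study conditions, not tuning knobs.

The generator reproduces the *structure* the scoring method assumes, which
is exactly what makes planted recovery a fair test of the code. It does not
emulate real-data pathologies: the heavy-tailed distribution of strains per
genus, correlated production profiles within a genus, annotation bias toward
culturable organisms, or curation noise in direction calls. Passing tests
therefore demonstrate that the pipeline computes its defined quantities
correctly, not that those quantities are robust to biased real-world inputs.

Test and experiment problem sizes in this package (up to ~5 diseases, ~20
strains, ~30 metabolites for oracle comparisons; 100 random instances; 1000
random count quadruples) were chosen so that an independent brute-force
enumeration is itself trivially checkable.

## Known limitations

* Directions are binary; effect sizes and abundances are not modeled, and
  two scores are not a significance test. $S_{ac}$ weights evidence count
  but has no null distribution.
* Production links are presence-only: a metabolite *consumed* by a microbe,
  or produced only under particular conditions, is indistinguishable from
  one constitutively produced.
* The genus-to-strain assumption is known to be optimistic — strains within
  a genus differ metabolically; it is the price of joining genus-level
  epidemiology to strain-level metabolism.
* Contradiction removal discards real signal when one direction is backed by
  much stronger evidence; the report makes the discards visible so they can
  be re-curated upstream.
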