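---
title: "Abstraction levels and conditional enrichment for literature-based drug safety signals"
author: "adegea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Abstraction levels and conditional enrichment for literature-based drug safety signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adegea)
```

## The problem

Biomedical articles are indexed with controlled terms (MeSH descriptors),
each optionally qualified by a sub-heading giving its context. When one
descriptor in an article is a drug qualified with *adverse effects* and
another is a disease qualified with *chemically induced*, the pair is a
candidate adverse drug event (ADE). Two questions then arise:

1. **Granularity.** Indexers describe the same clinical event at very
   different depths of the terminology (*Aneurysm, Ruptured* vs
   *Vascular Diseases*). At which level should candidate events be
   aggregated before counting?
2. **Significance.** Given a drug's set of supporting articles, which
   aggregated event terms appear more often than the literature-wide
   background predicts — after discounting terms that only co-occur
   because they are hierarchically or clinically entangled with a
   stronger term?

`adegea` answers both with generalized enrichment analysis (GEA):
over-representation testing of annotation profiles against a large
reference corpus, with an information-content-based choice of term
granularity and a pairwise conditional correction for term dependencies.
A proportional reporting ratio (PRR) baseline is included for comparison.

## Reference statistics

Over a reference annotation corpus (in production use, all of MEDLINE;
here any corpus in the package's TSV dialect), every article indexed with
a term is also attributed to all of the term's ancestors along
tree-number prefixes. With $a(t)$ the aggregated article set of term $t$
and $n$ the number of articles in the corpus,

$$ p(t) = \frac{|a(t)|}{n}, \qquad IC(t) = -\log_2 p(t). $$

IC quantifies specificity in bits: frequently used general terms score
low, rare specific terms score high. The reference size $n$ is the full
article universe, including articles without annotations, so supplying an
explicit universe changes probabilities, not counts. Pairwise
co-frequencies $a_{xy} = |a(x) \cap a(y)|$ are stored sparsely (only
co-occurring pairs, unordered); they quantify the dependencies the
conditional test corrects for. Qualifiers are ignored on the reference
side: background frequencies describe how often terms are discussed at
all, not how often in an ADE context.

## Abstraction levels

An abstraction level is the subset of terms with IC in a half-open range
$[ic_{\min}, ic_{\max})$, plus a mapping of every other term onto it:

* IC in range: the term represents itself;
* IC at or above the upper bound (too specific): the term is aggregated,
  independently along each of its tree-number paths, into the *nearest*
  ancestor with in-range IC; representatives from different paths are all
  kept, so a multi-classified term is counted under several
  representatives and the conditional correction later handles the
  induced correlation;
* IC below the lower bound, or no in-range ancestor on any path: the
  term is excluded and reported in the coverage accounting.

The lower bound is inclusive and the upper exclusive; both are plain
configuration values because the useful range is use-case dependent and
must be chosen empirically. A fixed tree-hierarchy level (for example,
"aggregate everything to its 2nd-level ancestors") is provided as the
conventional alternative via `build_tree_level()`.

Reference-side frequencies for a level need no recounting: ancestor
propagation already makes $a(\text{representative})$ contain every
descendant's articles. On the set-of-interest side, `apply_level()`
rewrites annotations to representatives and deduplicates per article, so
an article indexed with two siblings that share a representative counts
once.

## Signal detection

For a drug (or an ATC4 class, pooling its member ingredients), the *set
of interest* $S$ holds the $s$ articles linking it to qualified events.
For each representative event term $x$ observed $m$ times in $S$, with
$a$ reference articles out of $n$ carrying $x$, the raw p-value is the
inclusive upper tail

$$ P(X \ge m), \quad X \sim \mathrm{Hypergeom}(n, a, s), $$

computed through the survival function (never $1 - \mathrm{CDF}$, which
loses precision at the extreme tails this application lives in; raw
p-values around $10^{-35}$ are routine for well-supported signals).
$m = 0$ yields $p = 1$. The set of interest is deliberately *not*
excluded from the reference: a small specific set against a vastly
larger general background does not require mutual exclusiveness.

Terms passing a first-stage threshold (`alpha1`, default 0.1 — the
loosest reporting threshold) enter the conditional stage. For each
enriched pair $(x, y)$ whose reference co-count $a_{xy}$ is at least 1,
the conditional p-value asks whether $x$'s joint appearances with $y$
exceed what their background co-occurrence predicts:

$$ P(X \ge m_{xy}), \quad X \sim \mathrm{Hypergeom}(a_y, a_{xy}, o), $$

where $o$ is $y$'s count in $S$ and $m_{xy}$ the number of $S$-articles
carrying both. The final adjusted p-value is the maximum of the raw
p-value and all pairwise conditional p-values, which guarantees
`adjusted_p >= raw_p`. A term that rides along with a stronger term as
often as the reference predicts (the extreme case being an ancestor whose
reference co-count with its descendant equals the descendant's count)
saturates at $p = 1$ and drops out, while the driving term survives.

Two readings of the conditional population are possible from the method's
prose; the package uses reference-side counts ($a_y$, $a_{xy}$) with
set-of-interest draws, because the correction is explicitly about
co-occurrence *in the reference*. The choice is isolated inside
`conditional_p()` so the alternative (population $= S$) could be swapped
in one place. Conditioning ranges over first-stage-enriched terms only;
conditioning on never-enriched terms would only add noise from tests with
no power.

No multiple-testing correction is applied by default — decisions are
made by thresholding raw/adjusted p at 0.1, 0.05 or 0.005 (strict
comparisons) — but a per-subject Benjamini–Hochberg option is available
(`p_adjust = "BH"`).

The PRR baseline fills the standard 2×2 table over the candidate-article
universe: $a$ articles with drug and event, $b$ drug without event, $c$
event without drug, $d$ neither, and

$$ PRR = \frac{a/(a+b)}{c/(c+d)}, $$

with 0.5 added to all four cells when any is zero, and a 95% log-scale
Wald interval. For a drug class, $a/b$ count articles mentioning any
member drug and $c/d$ articles mentioning any other drug.

## Evaluation

Gold standards are (subject, outcome, label) tables in the style of the
OMOP drug-safety reference set: few outcomes, many positive and negative
control drugs. Outcomes are mapped onto the active abstraction level
(an excluded outcome is a configuration error, not a silent zero); a
drug-level gold standard can be lifted to ATC4 classes, where a class
containing both positive and negative member drugs for an outcome
becomes positive and leaves the negative controls. Scores are
$-\log_{10}(\text{adjusted } p)$ for GEA and the PRR value for PRR, so
the rank-based AUC (ties count one half) is comparable across methods.
Subjects with no supporting article produce no signal by construction and
are ranked below every scored subject; reported precision/recall/F1 are
rounded half-up to two decimals, matching how such tables are
conventionally printed.

## The synthetic study generator

The generator emulates the four inputs end to end so that every claim
the test suite makes is computed, not assumed. Its defaults are the
package's study conditions:

| parameter | default | rationale |
|---|---|---|
| `n_articles` | 2000 | large enough for stable leaf IC (~80 articles/leaf), small enough for second-scale tests |
| `depth`, `branching` | 3, 3 | 39 disease terms, 27 leaves: the smallest shape with real multi-level aggregation |
| `n_drug_terms` | 20 | drugs are supplementary-concept records: no tree numbers |
| `multi_parent_fraction` | 0.15 | leaf-only grafting, so every placement carries a complete tree-number path and ancestor closures stay consistent across a descriptor's tree numbers |
| `background_rate` | 0.04 | per-leaf annotation probability; internal counts arise only via propagation |
| `drug_rate` | 0.05 | one drug mention per ~20 articles |
| `drug_qualifier_rate` | 0.25 | most background drug mentions are therapeutic-use context, not *adverse effects*; only qualified mentions enter candidate pairs |
| `event_qualifier_rate` | 0.5 | half of disease annotations are *chemically induced* |

Planted associations append `n_supporting` articles mentioning the drug
with the AE qualifier; each such article carries the planted event
(CI-qualified) with probability
$\min(1, \text{multiplier} \times \text{background\_rate} \times
\text{event\_qualifier\_rate})$. The multiplier is a relative risk
against the background qualified-event rate; literature ADE support is
extremely concentrated (an article about a drug's adverse event almost
always indexes that event), so tests and the acceptance script use a
saturating multiplier (100), under which all supporting articles are
co-annotated. At multiplier 1 the "supporting" articles are
indistinguishable from background drug-mention articles, which is how the
null corpora for type-I checks are built.

The analysis-side abstraction range used by the tests and the acceptance
script is IC $[3, 12)$: synthetic leaf IC concentrates around 4.3–4.8
(dipping toward 3.9 for heavily planted leaves), second-level nodes sit
near 3.1 with effectively zero set-of-interest counts, and roots near
1.8 are excluded.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: publication types and dates, abstract text,
indexing-depth variation between journals, correlated comorbidity
structure beyond hierarchy-induced co-frequency, reporting-rate
differences between outcomes, and MEDLINE-scale sparsity (a real
reference set has tens of millions of articles and ~75 million stored
co-frequency pairs; the synthetic one has thousands and hundreds).
Consequently the near-perfect recovery metrics on planted synthetic
associations characterize correctness of the machinery, not expected
performance on MEDLINE.

## Numerical and design choices

* **Tail convention** is the inclusive upper tail everywhere, via
  `phyper(..., lower.tail = FALSE)`; an exhaustive enumeration oracle
  pins every value for populations up to 30 at $10^{-12}$.
* **Half-open IC ranges** `[min, max)` follow from the documented
  boundary behavior (terms at the upper bound aggregate, terms below the
  lower bound are ignored) and are asserted over whole mappings.
* **Nearest in-range ancestor per path**, not the shallowest: a deeper
  in-range ancestor is a strictly better representative, and the
  union across paths preserves multi-classification.
* **Ties and degenerate inputs**: empty sets of interest yield empty
  result tables ("no signal"), not errors; result ordering is
  deterministic (adjusted p, then term id) so reruns are byte-identical;
  an annotated descriptor missing from the terminology is kept as an
  orphan leaf with a warning rather than silently dropped.
* **Zero-cell PRR correction** adds 0.5 to all four cells whenever any
  cell is zero, before both the estimate and its interval.
* **Orphan drugs in gold standards** (no supporting article anywhere)
  are scored as worst-rank rather than dropped, because absence of
  literature support is a real and informative failure mode of
  literature-based detection.

## Known limitations

* The conditional max rule is harsh at small sample sizes: with only a
  handful of set-of-interest articles, a weakly co-enriched noise term
  can inflate a strong term's adjusted p purely through overlap
  granularity. At reference scale the effect vanishes; at toy scale it
  is visible if most of a drug's articles do not carry the true event.
* First-stage eligibility (`alpha1`) interacts with the correction:
  loosening it admits more conditioning partners and can only raise
  adjusted p-values.
* IC ranges are corpus-relative: the same range expresses different
  granularity over corpora of different size or annotation density, so
  ranges must be re-chosen when the reference changes.
* Candidate extraction trusts the qualifier semantics of the indexing;
  it cannot distinguish an article *refuting* an association from one
  reporting it.
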