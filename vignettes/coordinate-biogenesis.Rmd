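---
title: "Coordinate biogenesis of miRNAs: model, pipeline, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinate biogenesis of miRNAs: model, pipeline, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coordbio)
```

## The model

Target mRNAs are not passive substrates of miRNA repression: an mRNA whose
3′UTR carries multiple binding sites for one miRNA enhances the Dicer1-mediated
processing of that miRNA's precursor, and miRNAs whose sites sit in tandem on
the same 3′UTR are swept along. `coordbio` operationalizes this *coordinate
biogenesis* (CB) as a relationship between four molecules — a primary miRNA
(miRNA-1, the CB regulator), a shared target gene A, a secondary miRNA
(miRNA-2), and a secondary effector gene B — called a **triad** when, on
merged 3′UTR site counts,

1. `n₁(A) ≥ 2`, `1 ≤ n₂(A) < n₁(A)` — the regulator dominates the shared
   3′UTR, with the secondary present in tandem; and
2. `n₂(B) ≥ 2`, `n₁(B) = 0` — gene B is a genuine miRNA-2 target out of the
   regulator's direct reach.

Condition 2 is what gives the model its force: a change at gene B cannot be a
direct effect of the regulator, so a consistent expression pattern (regulator
and secondary up, gene A and gene B down, or the fully mirrored pattern) is
evidence for the indirect, biogenesis-mediated route.

Two readings of the verbal conditions are not decidable from the prose alone,
and this package fixes them as its own design choices: "fewer" is strict
(`n₂(A) < n₁(A)`; ties disqualify), and "in tandem" requires at least one
miRNA-2 site on gene A (`n₂(A) ≥ 1`) but imposes no distance or ordering
constraint — co-occurrence on one 3′UTR suffices. An optional `max_gap`
argument restricts tandemness by base distance for users who want a stricter
spatial reading; it is off by default because no distance threshold has a
principled value.

## Site counting

All conditions are evaluated on an index of **merged 3′UTR sites per (miRNA,
gene) pair**. Three choices matter:

* **Coordinates** are 0-based half-open internally; database-style dialects
  declaring 1-based inclusive positions are converted at parse time. This
  makes interval arithmetic unambiguous.
* **Cross-database deduplication**: when catalogs are pooled, two sites of
  the same pair overlapping by ≥ 1 base on the same chromosome and strand
  merge into their union (via `IRanges::reduce`). Pooled databases frequently
  list the same physical site with slightly different boundaries; without a
  merge rule, pooling would inflate counts and manufacture triads. The rule
  can be disabled (`merge_overlaps = FALSE`) to count raw records.
* **Gene-level pooling**: sites on different transcripts of a gene are pooled
  to the gene before merging, because the triad conditions reason about
  "gene A" and "gene B", not isoforms.

Sites outside the 3′UTR are retained in the catalog for reporting but never
indexed — the CB mechanism as modeled is exclusively a 3′UTR phenomenon.
Evidence tiers (strong/weak/direct) are carried through and not filtered by
default; `min_evidence` restricts them.

## Expression contextualization

mRNAs are called with a symmetric linear-scale rule (default: fold change
≥ 1.5 or ≤ 1/1.5 with p ≤ 0.05); miRNAs with a sign rule (logFC > 0 or < 0,
p ≤ 0.05). Raw p-values are used, matching how such screens are typically
reported; an adjusted column can be substituted on input. As the fold-change
threshold tends to 1, the mRNA rule converges to the miRNA sign rule — a
property the tests exercise.

`contextualize()` has two modes. `down_down` reproduces the validation-set
construction: keep triads whose gene A **and** gene B are called down, with
the secondary miRNA required up whenever a miRNA table is supplied. The
regulator is assumed upregulated when unmeasured, because the question the
filter answers is conditioned on an induced regulator (its call is recorded
as `up` in that case, and this assumption is deliberate and documented).
Unmeasured targets drop the triad — conservative, since an unmeasured gene
cannot support the pattern. `full_pattern` filters nothing and instead
assigns tiers: `high_confidence` for the coherent up/up/down/down pattern or
its mirror image ("vice versa" direction included, although the macrophage
use case only exercises the forward one), `low_confidence` when all four
features are significantly changed but incoherently, `unsupported` otherwise.

The **direct-regulation filter** removes triads where gene A is a known
direct regulator (e.g. a transcription factor) of gene B, since such an edge
offers a shorter explanation for gene B's change than coordinate biogenesis.
It is directional — gene A → gene B only — because the confound runs in that
direction; `bidirectional = TRUE` is available for stricter pruning.

All filters are contractive (output ⊆ input) and idempotent; both properties
are asserted in the test suite.

## Over-representation analysis

Effector genes are tested against pathway collections with the inclusive
upper-tail hypergeometric probability P(X ≥ k), the standard ORA convention,
delegated to `stats::phyper` (the tests check it against exact enumeration of
binomial-coefficient ratios for every configuration with N ≤ 60). The
background universe is an explicit argument, never a default: whether it
should be the annotation universe or an expressed-gene universe is a study
decision, and the printed "background ratio" depends directly on it. Query
genes absent from the background are dropped before `n` is computed (and
reported), because a hit ratio over unmappable genes is meaningless. Only
Benjamini–Hochberg adjustment is offered.

## The progressive-dampening model

The layered model gives the CB cascade quantitative form. Its three pieces
are this package's concrete instantiation of a verbally described mechanism —
the underlying study presents the idea through fitted panels whose exact
equations are not printed in its text, so the forms below are our design,
kept behind a small interface so alternates can be swapped:

1. **Response curve**: the secondary miRNA level as a polynomial in the
   primary level, default degree 2 — the smallest nonlinearity consistent
   with a saturating dose response (`fit_response_curve`).
2. **Layer propagation**: multiplicative coupling,
   `level(n) = cₙ · level(n−1)`, with cₙ ∈ [0, 1]; cₙ = 1 is the
   conservation limit, cₙ = 0 decouples a layer (`propagate_layers`).
3. **Dampened repression**: an mRNA in layer t integrates repression from
   all miRNA layers m ≤ t as
   `baseline · exp(−Σₘ β · w^(t−m) · level(m))`, with attenuation base
   w ∈ (0, 1) (default 0.5 in simulations) and strength β ≥ 0. The log-linear
   form keeps predictions in (0, baseline] and makes the repressive effect
   decay geometrically with layer distance — the defining "dampening"
   property, which the tests verify as strict monotonicity in both level and
   distance.

`recover_params()` exploits the structure: for fixed w the model is linear in
β after the `−log(target/baseline)` transform, so β is profiled out in closed
form and w found by 1-D minimization (golden-section pass followed by a local
polish; noiseless recovery is accurate to ~1e−10). A single-layer series is
refused — without at least two distances there is nothing to attenuate, and w
is unidentifiable.

## What the synthetic data emulate — and what they do not

`generate_catalog()` plants triads that share one regulator but use disjoint
(gene A, secondary, gene B) blocks, so the planted set is provably the
complete triad set of the catalog; every triad condition gets a dedicated
decoy class violating exactly that condition (count tie on gene A, single
site on gene B, a regulator site on gene B, no tandem site on gene A). Site
coordinates live on a fictitious genome with one chromosome per gene, and
each pair's sites include one overlapping duplicate so interval merging is
exercised everywhere. `generate_expression()` plants the CB signature
(regulator and secondaries up by `up_lfc`, both targets down by `down_lfc`,
background flat) and derives p-values from a two-group Welch t-test on
simulated 3 + 3 replicates, so the p/logFC joint structure is realistic
rather than invented; replicate noise has a small fixed measurement floor
(sd 0.05 log2 units) so the test statistic is defined even at zero biological
noise, where every planted feature passes the default thresholds and no
background feature reaches the fold-change rule.

What passing on these data shows: the conditions, filters, and estimators
are implemented exactly and recover known truth. What it does not show:
performance on real catalogs, where binding-site evidence is noisy and
biased, site counts depend on database snapshots, miRNA families share seed
sites, and expression changes are confounded — none of which the generator
emulates. Headline relationship counts from any particular database snapshot
are therefore outside what this package (or any desk reimplementation)
can reproduce.

## Numerical choices and problem sizes

Degenerate inputs fail loudly: empty catalogs enumerate to empty (not an
error), an absent regulator warns, duplicate DE feature ids are ambiguous and
rejected, p-values outside [0, 1] and non-finite fold changes are validation
errors, and a constant response series reports R² = 1 with vanishing
higher-order coefficients. Enumeration output order is deterministic
(lexicographic), and identical pipeline configurations byte-reproduce their
written outputs; run summaries store run-relative paths for that reason.

The shipped analyses and checks use deliberately small problem sizes — five
planted triads over ~16 miRNAs × 20 genes, 200 random oracle catalogs of up
to 12 × 12, 20 pipeline seeds, a three-layer dampening network with eight
doses, and exhaustive hypergeometric checks to N = 60 — sizes at which
brute-force oracles are exact and the complete suite runs in well under a
minute, while still covering every code path.

## Known limitations

* Binding-site catalogs are taken as given; no de-novo site prediction,
  conservation scoring, or seed-type analysis.
* Differential expression is an input (`feature_id`, `log2fc`, `pvalue`);
  the package does not model counts.
* Triads are pairwise; chains of three or more miRNAs are only represented
  as compositions of triads, and the dampening model's layers assume a
  single primary driver.
* The direct-regulation filter is only as good as the supplied edge list.
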