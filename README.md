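# coordbio

Predicting **coordinate biogenesis (CB)** relationships between microRNAs
from binding-site catalogs and expression data.

## The scientific problem

miRNAs repress mRNAs through binding sites in the 3′UTR. When a target mRNA
carries several sites for one miRNA, processing of that miRNA's precursor is
enhanced — and this boost can spill over onto *other* miRNAs whose sites sit
in tandem on the same 3′UTR. A "primary" miRNA (miRNA-1, the CB regulator)
with the larger number of sites on a shared target (gene A) thereby drives
the biogenesis of a "secondary" miRNA (miRNA-2) with fewer sites on that
same 3′UTR; the newly made miRNA-2 then represses its own targets (gene B),
which the primary miRNA does not touch directly. In activated macrophages
this coupling lets one anti-inflammatory miRNA (e.g. miR-146a-5p) reshape
the expression of genes it has no binding sites on.

`coordbio` turns that mechanism into a testable prediction pipeline. A
**CB triad** (miRNA-1, gene A, miRNA-2, gene B) is called on merged 3′UTR
site counts when

1. gene A carries ≥ 2 miRNA-1 sites, at least one miRNA-2 site, and strictly
   fewer miRNA-2 than miRNA-1 sites (`n₂(A) < n₁(A)`), and
2. gene B carries ≥ 2 miRNA-2 sites and **no** miRNA-1 sites.

The **prevalence** of a (miRNA-1, miRNA-2) pair is the number of distinct
genes A supporting it, and ranks candidate pairs. Triads are then
contextualized against differential-expression tables (gene A and gene B
down, regulator and secondary miRNA up — or the fully mirrored pattern —
give a high-confidence call), pruned of relationships where gene A directly
regulates gene B (e.g. as a transcription factor), and the effector genes
tested for pathway over-representation with the upper-tail hypergeometric
probability

  P(X ≥ k), X ~ Hypergeometric(N, K, n)

for k hits among n query genes against a K-gene pathway in an N-gene
background. A layered **progressive-dampening model** describes how the
repressive influence of a miRNA decays across regulatory layers: target
level = baseline · exp(−Σₘ β · w^(t−m) · level(m)) with attenuation base
w ∈ (0, 1), so an effect x layers away is scaled by w^x.

## Worked example

The `analysis/` scripts are a complete worked study over a synthetic bundle
with five planted triads and decoy interactions violating each condition:

```sh
Rscript analysis/01_simulate_data.R
Rscript analysis/02_enumerate_triads.R
Rscript analysis/03_contextualize.R
Rscript analysis/04_pathway_enrichment.R
Rscript analysis/05_dampening_model.R
```

which prints

```
catalog: 92 sites, 27 indexed pairs, 5 planted triads
enumerated 5 triads across 5 miRNA pairs; planted set recovered exactly: TRUE
5 enumerated -> 5 down-down -> 4 after direct-regulation filter
confidence tiers: high_confidence=4
top set: effectors (k/n = 4/4, p = 0.00103, padj = 0.00206)
worked example mmu05132: computed p = 9.57e-05 (printed 9.57e-05)
noiseless recovery: w = 0.50000000 (truth 0.5), beta = 1.00000000 (truth 1)
```

Reading it: enumeration found exactly the five planted triads (decoys all
rejected); the expression filter kept all five (their targets were planted
down, secondaries up); the transcription-factor edge planted over one pair
removed exactly that relationship; the four surviving effector genes are
over-represented in their pathway set; and for the published
Salmonella-infection pathway row (gene ratio 15/170, background ratio
253/8900) the computed tail probability reproduces the printed 9.57×10⁻⁵.
The dampening fit recovers the simulation truth (w = 0.5, β = 1) to
machine precision from a noiseless three-layer, eight-dose series.

Interactively:

```r
library(coordbio)
g  <- generate_catalog(seed = 7)
tr <- enumerate_triads(g$catalog)
de <- generate_expression(g$truth, seed = 8)
cx <- contextualize(tr, de$mrna_de, de$mirna_de, mode = "down_down")
pair_prevalence(cx)
```

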