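# tepinkit

Protein complexes assemble and disassemble over the cell cycle, but the
protein–protein interaction networks (PINs) produced by high-throughput
screens are static: every interaction ever observed is present at once,
with no temporal context and a substantial load of false positives.
`tepinkit` builds a **time-evolving PIN** from a static interaction network
and a time-course gene expression matrix, weights its edges with biological
evidence, mines **temporal protein complexes** from the snapshots with a
bundled Markov clustering implementation, and evaluates the predictions
against a reference complex catalogue. It is aimed at computational
biologists studying the dynamic organisation of interactomes (the canonical
setting is yeast: a DIP-style interaction network, a metabolic-cycle
expression course, and a MIPS-style complex catalogue), and at anyone who
needs the standard complex-prediction evaluation metrics on their own
predictions.

## The method

**Activity calling (deviation degree).** For gene *i* with expression
*exp<sub>it</sub>* over time points *t* = 1…*n*,

- *u<sub>i</sub>* = mean of the profile,
- *σ<sub>i</sub>* = sample standard deviation (*n* − 1 denominator),
- active threshold = *u<sub>i</sub>* + *σ<sub>i</sub>*,

and gene *i* is **active** at *t* exactly when *exp<sub>it</sub>* strictly
exceeds its threshold. Each gene is judged against its own curve, so both
constitutively low and constitutively high expressors are handled sensibly
where a single global cutoff fails. Any alternative detector (a function
from an expression row to a set of time points) can be plugged in.

**Network construction.** Snapshot *t* is the subgraph of the static PIN
induced on the proteins active at *t*; the ordered sequence of *n*
snapshots is the time-evolving PIN.

**Edge weighting.** Each snapshot edge (*i*, *j*) receives

&nbsp;&nbsp;&nbsp;&nbsp;*W<sub>ij</sub>* = *CAC<sub>ij</sub>* + *PCC<sub>ij</sub>*

where the *connected affinity coefficient* sums, over every known complex
*k* containing the interaction, the ratio *N<sub>k</sub>* / *R<sub>k</sub>*
of the complex's member count to its induced static-PIN edge count, and
*PCC* is the Pearson correlation of the two genes' full expression
profiles. Edges with *W* ≤ 0 are eliminated as likely false positives.

**Complex mining.** Markov clustering (expansion–inflation iteration on the
column-stochastic transition matrix, inflation 2.0 by default) runs on each
snapshot separately; the *n* result groups are merged, single-protein
clusters are discarded, and a size-ordered redundancy filter removes every
complex whose overlap score with a larger retained complex reaches a
threshold (1.0 by default, i.e. exact-overlap duplicates).

**Evaluation.** Predicted complex *pc* matches known complex *kc* when the
overlap score OS = |*pc* ∩ *kc*|² / (|*pc*| · |*kc*|) reaches 0.2. From the
match counts: Sn = TP / (TP + FN), Sp = TP / (TP + FP), and their harmonic
mean (F-measure). Function enrichment of a complex is the exact
hypergeometric upper-tail probability of its overlap with each annotation
term, computed in log space.

## Worked example

The bundled generator plants complexes with contiguous activation windows,
so the whole pipeline can be exercised without any downloads:

```r
library(tepinkit)

d <- generate_synthetic(synth_config(n_proteins = 100, n_complexes = 8, seed = 42))
sched <- activity_profiles(d$expr)      # per-gene mean, sd, threshold, active set
net   <- build_tepin(d$pin, sched)      # 36 induced snapshots
net
#> Time-evolving PIN: 36 snapshot(s), unweighted
#>   average nodes 14.0, edges 17.9, density 0.194212

wnet <- weight_network(net, d$pin, d$expr, d$known)
pred <- mine_temporal_complexes(wnet)   # MCL per snapshot, merged + filtered
glance(match_complexes(pred, d$known, os_threshold = 0.2))
#> # A tibble: 1 × 12
#>   n_predicted n_known    tp    fp    fn   mkc perfect    sn    sp f_measure
#>         <int>   <int> <int> <int> <int> <int>   <int> <dbl> <dbl>     <dbl>
#> 1          11       8    10     1     0     8       8     1 0.909     0.952
```

All 8 planted complexes are recovered perfectly (`mkc = 8`, `perfect = 8`);
10 of the 11 predictions match a planted complex (Sn = 1.0, Sp = 0.909,
F = 0.952). Enrichment against the generator's annotation map:

```r
enrichment_summary(annotate_complexes(pred, d$annotation))
#> # A tibble: 1 × 3
#>   n_complexes n_significant pct_significant
#>         <int>         <int>           <dbl>
#> 1          11            10            90.9
```

`plot_activity_histogram(sched)`, `autoplot(net)` and
`plot_enrichment_bins()` give the standard graphical views.

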