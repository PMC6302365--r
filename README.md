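# netmark

Discriminative subnetwork biomarker discovery on co-expression-weighted
protein-interaction networks.

Two-class expression studies (the motivating case: two experimental models of
mild traumatic brain injury — a focal and a diffuse injury — profiled in rat
cortex) are usually mined one gene at a time. That discards genes of modest
individual effect that sit at the heart of a coherently perturbed module.
`netmark` instead searches a protein-interaction network, with every edge
weighted by the absolute Pearson correlation of its two genes' expression,
for gene subnetworks scoring high on

&nbsp;&nbsp;&nbsp;&nbsp;**S = βM + |R|**

where

* **M** (modularity) is the mean weighted clustering coefficient of the
  members on the induced subgraph,
  C<sub>i</sub> = Σ<sub>l≠i</sub>Σ<sub>m≠i,m≠l</sub> w<sub>il</sub>w<sub>lm</sub>w<sub>mi</sub> / [(Σ<sub>l≠i</sub> w<sub>il</sub>)² − Σ<sub>l≠i</sub> w<sub>il</sub>²],
  with M = 0 for sets smaller than 3;
* **R** (class relevance) is the two-sample t statistic comparing the
  per-sample mean z-score of the members (the *summarized expression*
  V<sub>Kj</sub> = Σ z<sub>ij</sub>/n) between the two classes;
* **β** trades the two (default 1; β = 0 is the topology-blind baseline).

Candidates are grown greedily from differentially expressed seed genes
(best-neighbor-pair triangle first, then single best neighbors while the
score strictly improves), de-duplicated by subset/superset/50%-overlap
pruning, and assessed against a permutation null that reassigns expression
vectors to gene identifiers — dissociating interaction topology from
expression while keeping the class signal. Marker sets are evaluated as
SVM classification features (summarized expression per gene group,
stratified repeated cross-validation, ROC/AUC and F-score) against
individual-gene and GMT gene-set baselines, with hypergeometric/BH
enrichment for interpretation. A synthetic-data generator with planted,
co-expressed, class-shifted modules makes the whole pipeline testable
without any external download.

## Worked example

Simulate a study with two planted 6-gene modules (within-module correlation
0.7, class shift 1 SD) over 200 background genes, then fit:

```r
library(netmark)
truth <- planted_truth(n_modules = 2, module_size = 6, n_background = 200,
                       delta = 1, rho = 0.7, n_per_class = 50)
net   <- generate_network(truth, seed = 11)
extra <- setdiff(net$nodes, c(unlist(truth$modules), truth$background))
expr  <- generate_expression(truth, extra_genes = extra, seed = 12)

fit <- netmark(net, expr, normalize = FALSE, n_perm = 20, seed = 7)
fit
#> netmark fit
#> network: 212 nodes, 437 edges
#> subnetworks after pruning: 8
#> significant at p < 0.05: 0  (null: 420 scores, 20 permutations)

round(head(coef(fit), 5), 3)
#>          n     M      R      S     p
#> subnet1 38 0.126 13.132 13.258 0.074
#> subnet2 30 0.194 10.727 10.921 0.264
#> subnet3 23 0.271 10.493 10.764 0.269
#> subnet4 21 0.260 10.494 10.755 0.269
#> subnet5 28 0.000 -9.670  9.670 0.348

recovery_report(fit$subnetworks, truth)$jaccard
#>   module1   module2
#> 0.6666667 0.7142857
```

Reading the output: the search found 8 non-redundant subnetworks; the top
one couples 38 genes with modularity 0.126 and a summarized-expression t of
13.1 between the classes (positive: higher in the first class). Both planted
modules are recovered inside the pruned subnetworks (best Jaccard 0.67 and
0.71). None clears the permutation null at p < 0.05 here — at 50 samples
per class the t component dominates the score and the label-preserving null
chains chance-aligned genes almost as well as the real data does; the
methods vignette discusses this regime in detail. `plot(fit)` overlays the
observed scores on the null histogram; `predict(fit, newdata)` encodes the
fitted subnetworks as classification features for new samples.

For shell use, `inst/scripts/netmark.R` exposes `simulate`, `preprocess`,
`build-network`, `find`, `permute`, `select`, `evaluate` and `run`
subcommands over the same functions, and `run_pipeline()` writes every
intermediate table plus a JSON run manifest.

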