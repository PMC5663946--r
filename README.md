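# chromnet

Chromatin interaction networks and the connectivity of cell-specific
regulatory elements.

Broad H3K4me3 domains (cell-identity promoters) and super enhancers are
not just marked differently on the linear genome — they are wired
differently in 3D. chromnet builds annotated chromatin interaction
networks from interaction calls (ChIA-PET, HiChIP or Hi-C style) whose
anchors fall on open-chromatin peaks, and provides the analyses that
make that wiring quantitative, for computational biologists working
with chromatin conformation data:

* **Loop calling** — a hypergeometric peak-pair test for HiChIP-style
  valid pairs and a four-filter (donut / vertical / horizontal /
  lower-left) local-background Poisson test for binned Hi-C contact
  matrices, both under Benjamini–Hochberg control.
* **Network construction and annotation** — peak-defined nodes,
  PET-weighted edges capped at 1 Mb, connected components; one
  regulatory state per node via a priority schema, with broad-domain
  and super-enhancer overlays and a merged-domain network variant.
* **Interaction enrichment** — per annotation pair, the observed edge
  count against the expectation
  `Expected(A,B) = Σ_chrom |E_chrom| · N_AB / N_all` over admissible
  node pairs (same chromosome, midpoints ≤ 1 Mb; within-class pairs
  counted unordered), reported as log2 ratios.
* **Topology** — closeness `1/Σ nd(u,v)`, harmonic `Σ 1/nd(u,v)` and
  betweenness centralities with component-size normalisation, plus the
  full 73-orbit graphlet machinery for 2–5-node subgraphs: catalog
  generation, fast per-node orbit counting (ESU in C++), Spearman
  hierarchical orbit clustering and per-node cluster scores
  `CS_ki = max_{j∈C_k} (O_ij − μ_j)/σ_j`.
* **Classification** — RBF-kernel SVMs over 16 network + 7 genomic
  features with MCC-optimised grid search, greedy forward feature
  selection, ROC/PR/AUC and accuracy at a 0.2 probability threshold,
  for broad-domain-vs-promoter and super-enhancer-vs-enhancer tasks.
* **Targets, specificity and SNPs** — bounded BFS enhancer→promoter
  target assignment, SPM expression specificity (cosine similarity to a
  single-type profile), Wilcoxon group comparisons, and a label-
  permutation test for phenotype-SNP enrichment in enhancers targeting
  broad domains (E-BD) versus regular promoters (E-P).
* **A synthetic-data generator** with recorded ground truth (planted
  enrichment multipliers, hub structure, specific expression, boosted
  SNP rates, planted contact-matrix loops) so the entire pipeline is
  testable without any external download.

## Worked example

Everything below runs from scratch off the synthetic generator:

```r
library(chromnet)

cfg <- generator_config(seed = 42)
gen <- generate_network_inputs(cfg, "demo")

net <- build_network(read_bedpe(gen$files$calls),
                     read_bed(gen$files$peaks), extension = 250)
net <- annotate_network(net,
  states = read_states(gen$files$states),
  tss = read_tss(gen$files$tss),
  broad_domains = read_bed(gen$files$broad_domains),
  super_enhancers = read_bed(gen$files$super_enhancers))
net
#> chromatin interaction network: 1771 nodes, 4532 edges, 3 components
#> annotations: broad_domain=109, enhancer=644, insulator=199, other=265, promoter=374, super_enhancer=180

enrichment_matrix(net)
#> interaction enrichment, log2(observed/expected):
#>                broad_domain enhancer insulator other promoter super_enhancer
#> broad_domain           0.71    -0.31     -0.32  0.01     0.93           1.76
#> enhancer              -0.31    -0.36     -0.13 -0.26    -0.30          -0.27
#> insulator             -0.32    -0.13     -0.39 -0.08    -0.11          -0.11
#> other                  0.01    -0.26     -0.08  0.00    -0.17          -0.35
#> promoter               0.93    -0.30     -0.11 -0.17     0.79          -0.38
#> super_enhancer         1.76    -0.27     -0.11 -0.35    -0.38           1.88
```

The generator planted a 4× broad-domain↔super-enhancer multiplier
(log2 = 2, recovered here as 1.76; see the methods vignette for why the
estimate runs slightly conservative), a 5× within-domain
super-enhancer boost and 2× among promoter-state nodes — visible as the
red corners of the matrix, while unboosted pairs sit near 0.

```r
se_edge_split(net)$within_fraction
#> [1] 0.9056604            # SE-SE edges inside one domain

deg <- igraph::degree(as_igraph(net))
ann <- net$nodes$annotation
mean(deg[ann == "broad_domain"]); mean(deg[ann == "promoter"])
#> [1] 6.9  /  5.7
compare_groups(deg[ann == "broad_domain"], deg[ann == "promoter"])$p_value
#> [1] 9.87e-06             # one-sided Wilcoxon: broad domains are hubs
```

Orbit signatures, cluster scores and the super-enhancer classifier:

```r
sig <- count_orbits(net)                 # 73 orbit counts per node
cl  <- cluster_orbits(sig, k = 7)        # Spearman hierarchical clusters
cs  <- cluster_scores(sig, cl)           # CS1..CS7 per node
ft  <- extract_features(net, centralities(net), cs,
                        read_tss(gen$files$tss),
                        positive = "super_enhancer", negative = "enhancer")
train_svm(ft, folds = 5, seed = 1,
          cost_grid = c(1, 10), gamma_grid = c(0.01, 0.1))
#> SVM report: AUC 0.956, MCC 0.724, accuracy 0.883 at p>=0.20 (C=10, gamma=0.01)
```

An AUC well above chance means network wiring alone carries substantial
information about which enhancers belong to super-enhancer domains;
`forward_select()` ranks which features carry it, and
`ablate_feature_groups()` compares network-only, genomic-only and
combined models.

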