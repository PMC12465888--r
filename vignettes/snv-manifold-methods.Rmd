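---
title: "Methods: a binomial VAE manifold for single-cell SNV analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a binomial VAE manifold for single-cell SNV analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snvae)
```

## The problem

Single-cell SNV data arrive as two cells x SNPs count matrices: `A` (reads
supporting the alternative allele, "AD") and `D` (total reads, "DP"),
typically compiled by cellsnp-lite from a barcoded BAM. The data are extremely
sparse — in nuclear scRNA-seq most SNPs are simply not covered in most cells
(`D = 0`) — and, for mitochondrial SNVs, allele frequencies are continuous
(heteroplasmy), not diploid genotypes. Two tasks dominate: demultiplexing
pooled donors by germline genotype and tracing somatic lineages, where
descendant cells inherit all ancestral mutations and so SNVs of related
lineages strongly co-vary.

`snvae` embeds each cell into a low-dimensional latent manifold with a
binomial variational autoencoder and performs three downstream analyses on
that manifold: genotype clustering, SNP ranking by cluster-vs-bulk F-tests,
and cluster-level phylogeny construction.

## The model

For cell $i$, the input is the logit of the smoothed allele frequency,
$x_{ij} = \mathrm{logit}\!\left(\frac{a_{ij}+c}{d_{ij}+2c}\right)$ with
pseudo-count $c$ (default 1). The smoothing is symmetric, so an unobserved
entry ($d_{ij}=0$) has smoothed AF exactly $1/2$ and logit exactly $0$: it
contributes nothing to the affine encoder.

$$
(\mu_i^{raw}, \log\sigma_i^2) = \mathrm{encoder}_\phi(x_i), \qquad
\mu_i = \mu_i^{raw} / l_i, \qquad l_i = \#\{j : d_{ij} > 0\}
$$

The division by the observed-SNP count $l_i$ ("observed-SNP normalization")
removes per-cell coverage as a latent direction: a cell and its
coverage-doubled copy encode to the same $\mu$ (a property the test suite
checks numerically). Sampling uses one Monte-Carlo draw
$z_i = \mu_i + \sigma_i \odot \varepsilon$, and the decoder maps
$z_i$ through an affine layer and a sigmoid to reconstructed allele
frequencies $\hat{x}_i \in (0,1)$. The likelihood is binomial,
$a_{ij} \sim \mathrm{Binomial}(d_{ij}, \hat{x}_{ij})$, so unobserved entries
carry zero likelihood weight, and the cost is

$$
\sum_i -\mathbb{E}_{z\sim q}\big[\textstyle\sum_j a_{ij}\log\hat{x}_{ij} +
(d_{ij}-a_{ij})\log(1-\hat{x}_{ij})\big] \;+\;
\beta \sum_i \mathrm{KL}\big(\mathcal{N}(\mu_i,\sigma_i^2)\,\|\,
\mathcal{N}(0,I)\big).
$$

Defaults follow the method's published configuration: $\beta = 0$ (the
Monte-Carlo step is kept, which is why the model remains a VAE), latent
dimension $D = \lfloor n_{SNP}/2 \rfloor$, 2000 epochs of full-batch Adam at
learning rate $10^{-4}$, weight decay 0, no dropout. The encoder and decoder
are single affine maps by default — the logit at the input and the sigmoid at
the output are the only nonlinearities; `n_hidden_layers` inserts
leaky-rectifier hidden layers for ablations. Training is implemented directly
on BLAS matrix operations with exact analytic gradients; the binomial term is
evaluated through the decoder logits in softplus form for numerical
stability. All randomness (initialization, Monte-Carlo draws) flows from one
integer seed, and a fixed seed reproduces the fit bit for bit.

Design choices where the model description is open:

* The normalization divides the posterior-mean head only; the log-variance
  head is returned unnormalized. Sampling uses the normalized mean.
* Cells observing zero SNPs get normalizer 1 and are flagged; pre-filtering
  is the intended remedy.
* The smoothing pseudo-count is exposed (`pseudocount`); the symmetric form
  `(a+c)/(d+2c)` was chosen so missing data sit exactly at logit 0.
* Full-batch optimization is the default because the matrices this method
  targets fit comfortably in memory; `batch_size` enables minibatching.

## Pre-filtering

Three diagnostics guide SNP/cell selection: observed SNPs per cell, mean
coverage per SNP (averaged over all cells — averaging over observed cells
only is a config alternative we considered and rejected for its sensitivity
to single-cell outliers), and the logit-variance per SNP computed over
observed cells only, so that pseudo-0.5 missing values do not dilute the
spread. Filtering applies the SNP thresholds first and then re-computes the
per-cell observed-SNP counts on the retained panel, judging cell quality on
the SNPs actually used. Cut-offs are left to the user (knee/elbow points on
the diagnostic plots); the package writes the diagnostics as TSV so the
choice is scriptable.

## Clustering and evaluation

Two clustering routes, as in the published workflow:

* **k-means** on the full-dimensional latent means, with `k = "auto"`
  selecting the number of clusters by maximal mean silhouette over
  `k_range` (2..30 by default; ties go to the smallest k).
* **Leiden** community detection (modularity objective) on an unweighted
  kNN graph (k = 15, Euclidean), built by default on a 3D UMAP of the
  latent space; resolution 1 by default.

A property worth knowing: modularity-based community detection has a
characteristic scale set by the total edge count. On uniform blobs of many
hundreds of cells with a kNN-15 graph, Leiden at resolution 1 splits blobs
into several *pure* sub-communities — we verified the same behavior in an
independent graph-clustering implementation on identical embeddings, so it is
a property of the objective, not of this package. Majority-mapping accuracy
is unaffected (splits stay within a donor/clone), but partition-level metrics
such as the adjusted Rand index are. The published workflow's answer is to
tune the resolution per dataset; `resolution = "auto"` automates exactly that
by maximizing the mean silhouette over a small resolution grid — the
graph-clustering analog of the automatic-k rule — and is what the lineage
analyses here use.

Evaluation against ground-truth labels uses majority mapping (each predicted
cluster maps to its most frequent true label), which tolerates cluster
splitting, matching how the published confusion matrices are read; an
optimal one-to-one assignment is available as an option. Silhouette scores of
label sets are computed in latent space by default (UMAP space optional).

## SNP ranking

For each SNP and each cluster, a two-group one-way ANOVA compares the
smoothed allele frequencies of the cluster's observed cells against the
bulk — taken literally as *all* observed cells, cluster included, following
the method's definition; `exclude_cluster_from_bulk = TRUE` gives the
disjoint variant. The p-value uses the F distribution with
$(1, n_1+n_2-2)$ degrees of freedom. As numerical guards, F is capped at 20
and p floored at $10^{-16}$; with the caps disabled the statistic equals a
textbook sum-of-squares ANOVA exactly (tested against `anova(lm(...))` to
1e-10). Per SNP the minimum p over clusters is reported (the per-cluster
matrix is attached as an attribute), SNPs are ranked by ascending p with ties
broken by descending F and column order, and the heatmap view orders cells by
cluster and SNPs by rank, masking unobserved entries. No multiple-testing
correction is applied, matching the published procedure; the ranking is a
prioritization, not an inference.

## Cluster phylogeny

Distances between clusters are the mean of the shortest
$\min(k_{pairs}, |p|\cdot|q|)$ Euclidean distances between posterior-mean
vectors of cells in the two clusters ($k_{pairs} = 100$ by default). The
multifurcating tree joins cluster pairs greedily in ascending distance order,
skipping joins that would close a cycle, until one acyclic connected graph
remains — exactly a minimum spanning tree of the cluster distance graph, with
deterministic smallest-index tie-breaks. (Classical Saitou–Nei
neighbor-joining, which infers internal nodes, is deliberately not what this
procedure is.) The bifurcating alternative is an average-linkage dendrogram
on the same distances, exportable as Newick; the linkage is a config knob.

**Limitation.** The latent metric of a converged linear autoencoder is not an
isometry of the input space. On simulated clone trees we find that *chain*
topologies (sequential subclonal evolution) are recovered exactly across
seeds, but in *balanced* topologies the two leaf siblings can end up closer
to each other in latent space than to their parent, so the spanning tree
substitutes the sibling-sibling edge for one parent-child edge. Early in
training (when the encoder is still close to a random projection, which
nearly preserves distances) the balanced tree is recovered correctly; the
distortion is a property of the converged embedding. Interpreting an inferred
sibling edge as possibly "two children of a common ancestor" is therefore
prudent.

## Synthetic data

Two generators provide ground truth for every downstream test.

* `simulate_donors()`: each donor's genotype is drawn i.i.d. per SNP from
  allele-frequency levels $\{0.01, 0.5, 0.99\}$ — kept off exact 0/1 to model
  sequencing error, with the distance from 0/1 configurable. Depths are
  Poisson per entry (mean 2 by default, emulating sparse nuclear scRNA-seq;
  zeros are unobserved entries) and alt counts binomial.
* `simulate_lineages()`: clones sit on a rooted tree; each clone acquires
  private SNVs carried by itself and all descendants at one continuous
  heteroplasmic allele frequency per SNV (uniform on 0.1–0.9 by default);
  the root's SNVs are the inherited set shared by all clones; non-carriers
  show the error rate. Depth mean 20 by default, reflecting the higher
  coverage of mitochondrial SNVs; optional doublets mix two clones' expected
  AFs 1:1.

Presets mirror the published dataset shapes (734x1905/4 donors, 13,939x929/8,
9,436x864/18 with donor sizes spanning 67–1519; 1001x56 and 9204x274
mitochondrial designs). What the generators deliberately do *not* emulate:
cell-to-cell coverage correlation with transcriptional state, allelic
expression imbalance, ambient/barcode-swapping contamination, index hopping,
or linkage between SNPs beyond clone structure. Passing tests therefore show
the machinery is correct under the stated statistical model, not that every
real dataset will reach the same accuracy.

## Problem sizes used by the tests and the acceptance script

The donor designs carry enormous genotype signal per cell (donors differ at
roughly two-thirds of SNPs), so accuracy saturates well below the published
matrix sizes. The test suite and the acceptance script keep each design's
donor count, depth model and (for the 18-donor design) the published
smallest-donor size of 67 cells — the smallest donor must stay well above the
kNN neighborhood size of 15 for graph clustering to be able to resolve it —
and reduce the cell totals and SNP panels: 200-SNP panels in the test suite,
150-SNP panels in the acceptance script, with 734 / 800 / ~1870 cells for the
4- / 8- / 18-donor designs. Training always uses the full
2000-epoch defaults. The lineage test uses the 1001-cell cell-line preset
with heteroplasmic allele frequencies drawn from 0.4–0.9 ("strong" private
SNVs) at depth 20.

## Numerical choices

* Binomial NLL computed via softplus of the decoder logits (never forming
  $\log \hat{x}$ at saturated values); `decode_latent()` additionally clamps
  its returned probabilities to $[10^{-15}, 1-10^{-15}]$.
* Encoder/decoder weights initialized uniformly on
  $\pm 1/\sqrt{\mathrm{fan~in}}$; Adam with $\beta_1=0.9$, $\beta_2=0.999$,
  $\epsilon=10^{-8}$.
* Each k-means fit is the better — by total within-cluster sum of squares —
  of ten random restarts and one run initialized from Ward-tree centroids;
  high-dimensional latent spaces give k-means hard local optima that random
  restarts alone hit too often, and the hierarchical start is deterministic.
* Logit-variance uses the $n-1$ sample variance and defines SNPs observed in
  fewer than two cells as variance 0.
* Silhouette-based selections break ties toward the smallest k / coarsest
  resolution; spanning-tree ties break by smallest cluster-index pair.
* Degenerate inputs: all-identical points cluster as one community; a single
  cluster makes silhouette and SNP ranking error out with clear messages;
  empty filter results raise a condition carrying the diagnostic report.
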