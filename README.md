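# hypervne

Vital-node identification in hypergraphs via von Neumann graph entropy,
with the nonlinear contagion and attack experiments used to evaluate such
rankings.

Many real systems — collaboration groups, review platforms, question
threads — are group interactions, naturally modelled as a hypergraph
$H=(V,E)$ whose hyperedges are node sets of arbitrary cardinality $r_j$.
This package ranks the nodes of such a hypergraph by how much structural
complexity they carry, where complexity is measured spectrally: for an
ordinary graph with Laplacian $L$ and $m$ edges, the density operator
$\rho = L/(2m)$ is trace-one and positive semi-definite, and its von
Neumann entropy is $S(\rho) = -\sum_i \lambda_i \ln \lambda_i$.

The core method, **high-order von Neumann entropy centrality (HVC)**,
projects the hypergraph onto its s-line graphs $L_s(H)$ (hyperedges as
vertices, adjacent iff they share at least $s$ nodes, $s = 1..s_{max}$),
measures the entropy change $\Delta\Theta_s(e_j)$ caused by removing each
hyperedge-vertex, maps changes back to nodes with cardinality-discounted
weights and fuses orders harmonically:

$$HVC(v_i) \;=\; \sum_{s=1}^{s_{max}} \frac{1}{s}
  \sum_{j \in \Gamma(v_i)} \frac{\Delta\Theta_s(e_j)}{r_j}.$$

**semi-SAVC** is the fast variant: the quadratic entropy approximation
$S \approx \frac{x\ln x}{x-1}\big(1-\frac{1}{4m^2}\sum_v (d_v^2+d_v)\big)$
replaces the spectral form, and only orders up to
$\lfloor s_{max}/2\rfloor$ are fused.

Also included:

* baselines — hyperdegree (HDC), closeness (CC), vector (VC) and
  sub-hypergraph (SHC) centrality;
* a discrete-time nonlinear SIR model with per-hyperedge kernel
  $\beta(r_j,\eta) = \alpha\,\eta^\kappa$, for spreading-influence
  experiments;
* evaluation instruments — targeted-attack robustness (residual largest
  component), Pearson score correlation, ranking monotonicity, and
  order-saturation sweeps;
* synthetic generators (random, planted-overlap, planted high-order
  noise) and plain-text hypergraph I/O (hyperedge lists, bipartite TSV);
* a command-line interface (`exec/hypervne`) with subcommands
  `project`, `entropy`, `rank`, `sir`, `evaluate`, `generate`.

## Worked example

An 11-node, 4-hyperedge hypergraph whose line graphs are a star ($s=1$), a
path plus isolate ($s=2$) and a single edge ($s=3$):

```r
library(hypervne)
h <- example_hypergraph()
h
#> Hypergraph: 11 nodes, 4 hyperedges, smax = 3
#>   cardinality: min 3 / median 4 / max 6

hvc_scores(h)
#> Centrality scores (HVC), 11 nodes; top 5:
#>  node     score rank
#>    v2 0.3869204    1
#>    v3 0.3869204    2
#>    v5 0.3380540    3
#>    v6 0.3380540    4
#>    v7 0.3380540    5
```

v2 and v3 head the ranking because they sit in both of the two
most-overlapping hyperedges; their score is the sum over incident
hyperedges and orders of entropy changes, e.g. the order-1 star loses all
0.8676 nats of entropy when its centre is removed.  Attacking the network
in this order and measuring the residual largest component:

```r
robustness_curve(h, rank_nodes(hvc_scores(h)))
#>   fraction removed lcc
#> 1      0.1       2   8
#> 2      0.2       3   7
#> 3      0.3       4   6

monotonicity(hvc_scores(h))   # 0.7617: few ties
monotonicity(hdc_scores(h))   # 0.2975: hyperdegree ties heavily
```

Spreading influence of the top 20% seeds under the nonlinear SIR model
(mean prevalence at step 5, 100 runs):

```r
set.seed(1)
influence(h, top_fraction_nodes(hvc_scores(h), 0.2),
          alpha = 0.05, kappa = 1.25, gamma = 0.2,
          steps = 5, n_runs = 100)$mean
#> 0.5245
```

The same pipeline from the shell:

```sh
Rscript -e 'hypervne::hypervne_cli()' rank --input h.txt --method hvc --out rank.csv
Rscript -e 'hypervne::hypervne_cli()' sir  --input h.txt --seeds-from rank.csv \
        --top 0.01 --alpha 1e-4 --kappa 1.25 --gamma 0.2 --steps 5 --runs 100
```

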