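# frailnet

Frailness and resilience of networks under simultaneous multi-node
alterations, via a perturbed master equation — with a cohort layer for
scoring somatic-mutation profiles on pathway subnetworks.

## The problem

Most network-based scoring of molecular alterations follows an
*enrichment paradigm*: more signal on a pathway, more relevance. But
whether a set of co-occurring alterations actually disrupts a network
depends on *where* they sit, not only on how many there are. `frailnet`
models information flow on an undirected network as a master equation on
the random-walk Laplacian, couples the altered (query) nodes to an
external environment node at intensity ε, and asks how strongly the
stationary flow is deformed.

For a network with column-normalized transition matrix Π, Laplacian
L = I − Π, stationary state p_s ∝ degree and Fiedler number λ_F, a query
set S is encoded as the Laplacian perturbation

    ΔL_ε = ε Σ_{q∈S} (e₀ − e_q)(e₀ − e_q)ᵀ

on the system extended by the environment node e₀. The **frailness** of
the configuration is

    ρ = ‖ΔL′_ε‖ / λ_F ,

where ΔL′ is the projection of ΔL onto the spectral basis with the
stationary mode deflated out, and the norm is λ_F-weighted so that ρ is
exactly the convergence boundary of the package's iterative solver: the
perturbative scheme for the stationary state converges iff ρ_ε < 1, and
the **critical intensity** μ = ε/ρ(ε) is also retrievable independently by
bisection. Single alterations always give ρ = 0 (rank-one perturbations
are annihilated exactly); adding an alteration never decreases ρ; and no
configuration can diverge below λ_F. Large ρ = frail, small ρ = resilient.

On top of the core model the package scores mutation cohorts: per-sample
frailness over pathway subnetworks extracted from a protein–protein
interaction network, gene-pair co-occurrence tables, a hypergeometric test
for marginal (degree-one) mutations among the least resilient samples, and
the two-component **Gene Frailness Index** GFI = (σ, ρ′) combining a
gene's co-mutation rate with the normalized median frailness of its
carriers. Seeded generators for networks and long-tailed mutation cohorts
make the whole pipeline testable without external data.

## Worked example

```r
library(frailnet)

net <- make_leafy_network(m_core = 24, n_marginal = 6, seed = 5)
ts  <- transition_system(net)
ts
#> <transition_system> 36 nodes; lambda_F = 0.185571; spectral range [0, 1.82769]

# a central driver co-altered with a marginal (degree-one) gene
frailness(ts, c("n1", "leaf2"))
#> <frailness> Q = 2, epsilon = 1: rho = 1.94963, mu_analytic = 0.512919 (lambda_F = 0.185571)

critical_threshold(ts, c("n1", "leaf2"))
#> <critical_threshold> mu_hat = 0.512887 (bisection), mu_analytic = 0.512919, lambda_F = 0.185571
```

ρ ≈ 1.95 at ε = 1 says this two-alteration configuration is strongly
disruptive: the scheme would diverge beyond μ ≈ 0.51, well below typical
core–core pairs on the same network (ρ ≲ 1.4). The bisection estimate of μ
agrees with the analytic value to four digits.

A synthetic cohort end to end:

```r
spec <- cohort_spec(n_samples = 300, seed = 7, planted_effect = TRUE)
muts <- make_mutation_cohort(spec, net)
sr   <- sample_frailness(net, muts)

gene_frailness_index(sr, n_samples = 300)
#> # A tibble: 5 x 5   (head)
#>   gene   m_star   sigma rho_tilde rho_prime
#> 1 stalk5      1 0.00333      2.55     1
#> 2 stalk3      1 0.00333      2.54     0.993
#> 3 stalk2      1 0.00333      2.52     0.986
#> 4 leaf3      15 0.05         2.37     0.927
#> 5 n23         2 0.00667      2.24     0.877

marginal_enrichment(net, sr)
#>   n_population n_success n_drawn x_top p_value status
#> 1          187        75      10     8  0.0106 ok
```

Reading the GFI: the peripheral genes (`leaf*`, and the linkers `stalk*`
they attach through) carry the highest normalized median frailness ρ′ —
rarely mutated, but destabilizing when co-mutated — while frequent central
genes score through the σ component. The enrichment test confirms that 8
of the 10 least resilient samples carry a degree-one mutation
(p ≈ 0.01).

Plot helpers: `autoplot()` on intensity scans and current fields,
`plot_gfi()`, `plot_frailness_by_mstar()`.

A thin command-line wrapper ships in `inst/cli/frailnet.R` with
subcommands `frailness`, `threshold`, `currents`, `cohort`, `simulate`
over TSV/GMT inputs.

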