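# mdccr — multi-modal dynamic cross-correlation for MD trajectories

`mdccr` finds correlated atomic motions in molecular-dynamics trajectories
that conventional dynamic cross-correlation (DCC) maps miss when motions are
multi-modal — side chains flipping between rotamers, loops transiently
touching a binding partner.  It is aimed at structural biologists analysing
trajectories of protein and protein–nucleic-acid complexes who want residue
interaction networks and candidate communication pathways, not just a
correlation heatmap.

## The method

Conventional DCC measures co-directional motion relative to mean positions:

    DCC(i,j) = <Δr_i · Δr_j> / sqrt(<|Δr_i|²> <|Δr_j|²>),   Δr_i(t) = r_i(t) − <r_i>

When an atom's coordinate distribution has several basins, the mean is a
point the atom barely visits and part-time contacts average away.  `mdccr`
instead fits each heavy atom's coordinate cloud with a Gaussian mixture —
each component is a *mode* (one basin) — and correlates mode pairs:

    mDCC(i,j;k,l) = <w Δr_{i,k} · Δr_{j,l}> / sqrt(<w |Δr_{i,k}|²> <w |Δr_{j,l}|²>)

with deviations `Δr_{i,k}(t) = r_i(t) − μ_k` taken from the mode center and
`w(t) = p_k(r_i(t)) p_l(r_j(t))` the joint mode-membership probability.
Values lie in [−1, 1] and reduce exactly to DCC for uni-modal atoms.
Residue pairs are summarised by the largest mode-pair value (rare mode
pairs, time-averaged joint probability ≤ 0.1, are dropped).  Residue pairs
with mDCC ≥ 0.5 whose mode centers sit within 5 Å become edges of a
contact-correlation network; edges with conventional DCC < 0.5 are flagged
*transient*.  Betweenness centrality ranks residues as network mediators.

## Worked example

A synthetic pair of atoms sharing a two-state switch with anti-aligned mode
geometry — a transient contact that plain DCC cannot see:

```r
library(mdccr)

sys <- generate_two_state_pair(n_frames = 20000, occupancy = 0.5,
                               rho = 0.9, jitter_sigma = 1, seed = 3)
tr <- sys$trajectory

dcc(tr, 1, 2)
#> [1] -0.5267263

m <- mdcc(tr, selection = "all", seed = 3)
print(m)
#> mDCC residue correlation matrix: 2 residues
#>   off-diagonal mDCC: min 0.899, median 0.899, max 0.899 (1 defined)
#>   rare-pair weight floor: 0.1

m$mdcc["A:1:ALA", "B:1:ALA"]
#> [1] 0.8991985
```

The naive correlation is strongly negative (the basin-to-basin geometry
cancels the within-basin coupling), while the mode-resolved value recovers
the planted within-mode correlation of 0.9.  Building the network flags the
pair as a transient interaction.  In this geometry the two in-contact
basins are matched by one mode pair and the two far-apart basins by
another, with near-identical correlations, so the example uses the
`any_mode_pair` rule (any mode pair passing both thresholds qualifies)
rather than insisting that the single best-correlated pair also be the one
in contact:

```r
net <- build_network(m, any_mode_pair = TRUE)
print(net)
#> Contact-correlation network: 2 residues, 1 edges (1 transient)
#>   thresholds: mDCC >= 0.50, center distance < 5.0 A
net$edges[, c("label_a", "label_b", "mdcc", "dcc", "center_distance", "transient")]
#>   label_a label_b      mdcc        dcc center_distance transient
#> 1 A:1:ALA B:1:ALA 0.8978218 -0.5267263        3.998157      TRUE
```

On a real system the steps are the same: `read_topology()` +
`read_trajectory()` (multi-model PDB or DCD), `superpose()`, `mdcc()`,
`build_network()`, `top_betweenness()`.  Descriptors (`rmsd_series()`,
`rmsf()`, `pca_cartesian()`, `distance_series()`, `density_cluster_2d()`)
cover the usual trajectory characterisation, and a thin command-line front
end lives at `inst/cli/mdcc.R`.

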