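# dualcomm

Primal and dual communities in plane flow networks.

Spatial supply networks — leaf venation, power grids, vascular and hydraulic
systems — often owe their robustness to *boundaries*. Classical (primal)
communities are separated by weak connections: a cut-set S of light edges,
whose total weight bounds the algebraic connectivity,

    lambda_2  <=  mu_2  =  (N1 + N2)/(N1 N2) * sum_{l in S} w_l.

But strong connections separate networks just as effectively. On a plane
graph, the faces form a dual graph whose edge weights are the *inverse*
primal weights, `w* = sum_l 1/w_l` over shared edges; a thick vein in the
primal is a weak link in the dual. Communities of the dual graph — **dual
communities** — are bounded by strongly weighted paths (cut-paths p), with

    lambda_2*  <=  mu_2*  =  (N1* + N2*)/(N1* N2*) * sum_{l in p} 1/w_l,

and both bounds become exact as the respective connectivity vanishes. The
package builds weighted duals of plane networks, detects primal and dual
communities and hierarchies by spectral bisection, verifies the bounds, and
quantifies how both boundary types suppress failure spreading:

* **Linear flows**: sensitivity factors (PTDFs) in the primal form
  `eta = w_l l_l' I L^+ I' l_e` and the exactly equivalent dual form based on
  the cycle-space Laplacian `C' W^-1 C`; line-outage flow changes; the
  distance-controlled mean flow ratio R between communities.
* **Threshold cascades**: the weighted fractional-threshold model on lattices
  with an inhomogeneous middle strip — a homogeneous lattice cascades
  globally, while both a weak and a strong strip stop the cascade near half
  coverage.
* **Optimal supply networks**: dissipation minimization
  `D = sum <F^2>/w` under `sum w^gamma <= 1` with fluctuating Dirichlet
  sources; growing source fluctuations drive a transition from primal
  communities (local supply areas) to dual communities (a central vein).
* **Oscillator networks**: phase-locked states of second-order oscillators,
  and the suppression of localized-perturbation responses across community
  boundaries.

Everything runs on deterministic synthetic generators (square, triangular
and honeycomb lattices with tunable boundaries and nested veins), and
graphs round-trip through plain-text edge lists, JSON and GraphML.

## A worked example

A strong vein splits a lattice into two dual communities that primal
community detection cannot see:

```r
library(dualcomm)

pg <- square_lattice(21, 10, mode = "cut_path", contrast = 1e4)
bs <- bisect(pg, side = "dual")
bs
#> bisection (dual): |V1| = 90, |V2| = 90, lambda2* = 1.99886e-05 <= mu2* = 2e-05 (9 boundary edges)
```

The dual Fiedler value and its cut-path bound agree to 0.06% at this
contrast ("exact in the limit of vanishing dual connectivity"); the nine
boundary edges are precisely the vein. The same machinery recovers nested
vein hierarchies exactly (`hierarchical_decompose(graph, 2, side = "dual")`
on `vein_hierarchy_lattice()` fixtures), while the primal decomposition of
the same graph does not align with the veins (adjusted Rand index 0.34).

Failure spreading respects both boundary types. On the cascade lattice:

```r
cascade_scan(c(1e-2, 1, 1e2), reps = 200, seed = 1)
#>       w    median       q25       q75
#> 1 1e-02 0.5487179 0.5384615 0.5596154
#> 2 1e+00 1.0000000 1.0000000 1.0000000
#> 3 1e+02 0.4692308 0.4666667 0.4717949
```

The homogeneous lattice always cascades globally (median final infected
fraction 1); a weak (`10^-2`) or strong (`10^2`) middle strip stops the
cascade at the boundary, leaving roughly half the lattice infected.

The command-line wrapper `inst/cli/dualcomm` exposes the same operations
(`synth`, `dualize`, `communities`, `hierarchy`, `sensitivity`,
`flowratio`, `cascade`, `optimize`, `oscillate`) for shell pipelines; all
stochastic subcommands take `--seed` and write byte-identical outputs on
reruns.

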