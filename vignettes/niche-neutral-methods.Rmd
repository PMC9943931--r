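---
title: "Simulating and diagnosing a niche-neutral metacommunity continuum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and diagnosing a niche-neutral metacommunity continuum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`nnc` simulates an individual-based metacommunity on a two-dimensional
torus: a `width x height` lattice of local communities, each holding
exactly `J` individuals (default 16). Every individual belongs to a
species, every species to a *guild*, and the guild carries the
environmental niche — a Gaussian response to the site environment `E` with
optimum `mu` in [0, 1] and tolerance `sigma` in (0, 10]. Species of the
same guild are ecologically identical; this is what makes the system a
*niche-neutral continuum*: with one guild (or very wide tolerances) the
dynamics are pure neutral drift with speciation and dispersal limitation;
with many narrow guilds, environmental filtering sorts species along the
gradient.

Each synchronous time step replaces all `JM = width * height * J`
individuals:

1. **Speciation.** Each individual founds a new species with probability
   `nu` (default 0.001). The new species inherits its ancestor's guild
   (niche conservatism, point-mutation speciation) and is labelled by the
   ancestor's slot and the time step.
2. **Replacement lottery.** Each remaining slot at site `s` draws a parent
   from the probability vector `m * EF_s + (1 - m) * RA_s`, where `RA_s`
   is the local relative abundance of the non-speciating parent pool
   (local birth), and `EF_s` is the environment-filtered immigration
   field: the eight torus neighbours contribute `w(s, s') = 1/8` times
   their relative abundances, weighted by the habitat association
   `HA(s, guild)` — the Gaussian niche density of the guild at `E_s`,
   rescaled per site by the row maximum — and renormalized. Only
   immigration success is filtered by the environment; birth and death are
   niche-free.
3. **Pruning.** Extinct lineages disappear from the species registry.

The dispersal rate `m` takes the design levels 0.01, 0.09 and 0.81. The
*approximate scale* `floor(sqrt(m / nu))` — 3, 9 and 28 sites at
`nu = 0.001` — is the characteristic distance a lineage diffuses before
speciating, i.e. the radius of an independent biogeographic unit. The
analysed *model communities* are a central window (10 x 10 in the full
designs), so the three dispersal levels place that fixed window either
across several biogeographic units (m = 0.01) or deep inside one
(m = 0.81).

### Parent sampling and the coupling contract

The engine samples parents at the level of individual slots, not species:
each non-speciating local individual has weight `(1 - m) / n_s` and each
non-speciating neighbour individual `m * (1/8) * (1/n_s') * HA(s, g) / Z_s`.
Because conspecific individuals have equal weight, this reproduces the
matrix formulation exactly — and because the weights depend only on sites
and guilds, never on species labels, two runs with identical seeds and
identical (site, guild, founder) configurations make identical choices
regardless of labelling. That is the mechanism behind the convergence
test below. The per-site row-maximum rescaling of `HA` cancels in the
normalization of `EF`; it is kept for fidelity and the invariance is
asserted in tests.

Degenerate sites — all `J` locals speciated, or a zero immigration field —
drop the affected term and renormalize. At design parameters the local
case has probability about `nu^J` (1e-48 at full scale) per site-step; the
engine counts occurrences rather than aborting.

### Convergence by duality

Neutral genealogies are dual to coalescing random walkers with an
annihilation rate: tracing ancestry backwards, two lineages that pick the
same parent merge, and a lineage that hits a speciation event dies. The
package runs the *monodominance* initialization (each guild one species)
and declares convergence at the first step where, for every guild, the
surviving individuals of initial species descend from at most one founder
— all initial lineages per guild have *coalesced* or been *annihilated*.
From that step on the run is indistinguishable, up to a bijection of
species labels, from the paired *infinite-diversity* run (each founder its
own species) with the same seed. `coupled_pair_check()` executes both
chains on shared randomness and verifies the bijection at and after the
convergence time; the acceptance suite does this for 20 seeded pairs.
The guild count is non-increasing (speciation conserves guilds), so the
*stationary guild number* is reached at the last guild extinction;
`run_to_convergence()` reports that step alongside the convergence time,
and their ratio is the quantity whose median falls with `m` in the
reduced-scale trend test.

## The diagnostic battery

All statistics act on the site-by-species abundance table of the central
window at convergence time.

* **Functional diversity.** Species-pair similarity is the overlap of the
  two Gaussian niche densities (`integral of min(phi1, phi2)`; analytic
  crossing points, equal-variance closed form `2 * pnorm(-d / (2 sigma))`).
  Within-guild similarity is exactly 1. From pooled abundances the package
  reports Simpson's `D` and effective number `1 / sum(p^2)`, Rao's
  quadratic entropy `Q = sum p_i p_j d_ij` with effective number
  `1 / (1 - Q)` (the inverse-Simpson analogue; the acceptance values never
  depend on this convention), functional uniqueness `U = Q / D` and
  redundancy `R = 1 - U`. Single-guild communities give `U = 0` exactly;
  a single-species community leaves `U` undefined and is reported as 0
  with a flag. `initial_rao()` evaluates the t0 pool treating each guild
  as one species — the x-axis of the redundancy comparison.
* **Variation partitioning.** Abundances are Hellinger-transformed;
  environmental predictors are the first- and second-order orthogonal
  polynomials of `E` (raw `E` cannot model unimodal responses); spatial
  predictors are classic PCNM eigenfunctions (truncation at the longest
  minimum-spanning-tree edge, distances beyond it set to 4t, positive
  eigenvectors kept). Each set passes the classical alpha-only forward
  selection (global permutation pre-test at alpha = 0.05, then greedy
  admission by added R2 gated on the partial permutation p-value; the
  Blanchet adjusted-R2 stopping rule exists behind `r2_stop` but is off by
  default). Adjusted (Ezekiel) fractions: environmental [a+b], spatial
  [b+c], pure environmental [a], pure spatial [c], shared [b], residual
  [d]. Tests are one-tailed pseudo-F permutation tests (999 permutations
  by default); with conditioning, reduced-model residuals are permuted.
  Because environmental tests are biased when both species and environment
  are spatially structured, species-environment claims rest on the pure
  environmental component.
* **Component classification.** Single-guild windows have no true
  species-environment structure, so a significant pure environmental
  component is *false environmental* and significant spatial structure
  without environmental signal is *true spatial*; multi-guild windows give
  *true environmental* and *spatial*.
* **Hierarchical habitat structure.** When at least two guilds coexist and
  the pure environmental component is significant, sites are clustered by
  k-means on the canonical (linear-combination, scaling 1) scores of the
  environmental RDA, with k chosen by the simple structure index over
  k = 2..k_max (vegan's cascaded k-means). Two package-level choices are
  documented here because the criterion is brittle: axes carrying < 5% of
  the canonical variance are excluded (near-noise axes destabilize SSI),
  and among near-tied SSI values (within 10% of the maximum) the smallest
  k wins — SSI profiles go flat when tight clusters are over-split, and
  argmax alone splits clean two-cluster data into 4-7 groups almost half
  the time. With these guards, planted three-habitat data are recovered
  exactly and two-habitat data give pure (nested) partitions, though exact
  k = 2 remains a majority rather than a guarantee. The habitat partition
  is tested by a permutation RDA of its dummy variables — a circular test,
  since the clusters derive from the response; the output says so.
  The hierarchical spatial model then decomposes residual variation with
  among-habitat PCNMs (of habitat-centroid distances, expanded to member
  sites) and within-habitat block PCNMs (zero outside their block), each
  forward-selected on the residuals of the community given the habitat
  dummies. Habitats with fewer than three sites get no within block and
  are flagged.
* **Autocorrelation analysis.** For a fitted component, the species-pair
  Pearson correlation table is compared (Mantel, lower tail) with the
  table of Euclidean distances between the species' Moran's I
  correlograms — equal-width distance classes, Sturges rule
  `ceiling(1 + log2(n_pairs))` for the overall model, three classes per
  environmental context when the context has at least 45 site pairs and
  two otherwise. Under neutrality the correlation is near zero; niche
  structure makes equivalent species positively correlated with similar
  correlograms, so the Mantel correlation goes negative. The correlogram
  distance metric (Euclidean on the I vectors) is a package choice; the
  method leaves it open.

## Environmental structures

All three gradients are bounded in [0, 1], with each value represented by
(approximately) the same number of sites, and repeat continuously across
the torus seam:

* `random` — an exact uniform ladder of `n_sites` values, randomly
  permuted: no spatial correlation by construction.
* `linear` — a triangle wave along x, constant in y, one period per 20
  columns (one wave on the small system, two on the large), sampled
  half-a-step off-phase so each of the 10 distinct levels occupies exactly
  one tenth of the sites. Anisotropic by design.
* `humps` — the sum-of-cosines field `cos(2 pi x / 5) + cos(2 pi y / 5)`,
  rank-mapped to the uniform ladder: exactly `(width/5) * (height/5)`
  strict 8-neighbour local maxima (16 small, 64 large; four inside the
  10 x 10 window), isotropic. A product-cosine bump field was rejected
  because its tied 2 x 2 plateaus create spurious strict maxima after
  rank tie-breaking. Ties of the periodic field are broken by a smooth
  full-torus secondary field, then at random.

One numerical caveat, also recorded in the tests: exact per-value
uniformity forces a fine rank ladder, and the hump field's exactly tied
level sets then let the seam step deviate from the interior maximum by up
to the tied level's ladder span (one ladder step on 20 x 20, about 0.01
on 40 x 40) — the seam-equality property is exact for the linear wave but
only holds within that bound for humps; uniformity was given priority.

## The experimental design

`enumerate_scenarios(nn_config("paper_full"))` reproduces the full design:
small system 20 x 20 (JM = 6400) with m in {0.01, 0.09}, large system
40 x 40 (JM = 25,600, the small-system pool quadrupled) with m = 0.81;
three environmental structures; guild numbers g in {1, 8, 40, 160, 500}
with optima U(0, 1), tolerances U(0, 10], and guild sizes from g - 1
distinct uniform cutpoints of JM (distinctness guarantees no empty guild —
duplicated cutpoints would contradict g guilds being present). Five niche
draws and five size draws per multi-guild level, 25 single-guild niche
draws, shared across cells as in the design: 825 scenarios, 750 + 75.
Scenarios whose narrowest tolerance falls below 0.0052 (an empirical
property of six draws in the full-scale design) are flagged by
`exclusion_filter()`, not rejected; the threshold is configuration.

## The reduced preset and what a green test establishes

Full-scale scenarios need hours; the `reduced` preset is the package's
test world: an 8 x 8 grid with J = 8 (JM = 512), `nu = 0.01`, a 6 x 6
central window, triangle period 8 and bump period 4, guild levels
{1, 8, 40}, one replicate per stratum (21 scenarios), 199 permutations.
Choices worth defending:

* `nu = 0.01` keeps the dispersal-to-speciation scales (1, 3, 9) in the
  same relation to the window as the full design's (3, 9, 28) to its
  10 x 10 window: the window spans several biogeographic units at low m
  and sits inside one at high m, which is the axis of every comparison.
* The window is 6 x 6, not the ratio-faithful 4 x 4, because a 4 x 4
  window centred on the symmetric triangle wave contains only two distinct
  E values — too few for a degree-2 polynomial model — and 36 sites give
  the ordination usable degrees of freedom.
* Convergence on this world takes a few hundred steps (seconds per run),
  so the coupled-pair criterion runs 20 full pairs and the trend criterion
  runs ~200 simulations inside the suite's budget. Type-I calibrations use
  99 permutations per replicate over 1000 replicates: at alpha = 0.05 the
  rejection probability is exactly 0.05 under the null.

The generator emulates the stated world of the design — it is not a fit to
any empirical system. A green suite establishes that the mechanics,
statistics and classifications behave as specified on that world at
reduced scale; it does not certify the full-scale figures, which are
asserted only as directional trends: the median time-to-stationary-guild
ratio falls with m; the multi-guild relative environmental fraction is
largest at m = 0.81 (conditioned, as in the full-scale comparison, on
windows that kept at least two guilds — unconditioned, high dispersal
usually collapses the reduced window to one guild and the trend is
invisible); and the single-guild pure-environment test over-rejects under
the linear gradient at high m, the known Type-I inflation of
environmentally structured spatial data.

## Numerical choices and edge cases

* Gaussian overlap: analytic crossing points with a quadrature fallback
  (tolerance 1e-9); tested against split-interval quadrature — naive
  single-interval quadrature loses ~1e-7 at the min() kinks.
* RDA uses pivoted QR with tolerance 1e-8; collinear predictors are
  dropped and named. A numerically zero residual maps the pseudo-F to
  +Inf (a tiny negative residual sum would otherwise flip its sign).
* Permutation p-values are `(1 + exceedances) / (1 + n_perm)`; permutation
  schemes: free row permutation without conditioning, reduced-model
  residual permutation with conditioning; both seeded.
* All randomness derives from explicit seeds; scenario stages derive
  31-bit seeds from (master seed, stage, ids) so batches are reproducible
  and parallelizable per scenario.
* Species identifiers are (slot, step) codes, unique within a step and
  stable across coupled runs; founder lineage labels propagate through
  parenthood and survive speciation events only as code prefixes.

## Known limitations

* The birth-death niche variant (environment acting on birth/death rates
  rather than immigration success) is not implemented; `nn_config` carries
  no flag for it and the engine would need a different replacement kernel.
* Constrained (spatially structured) randomizations of environmental
  variables — the remedy for the Type-I inflation the package reproduces —
  are out of scope; the inflation is demonstrated, not corrected.
* The SSI-based habitat count is brittle (see above); treat `k` as an
  order-of-magnitude summary, not an estimator of the guild number. At
  full scale the same holds: habitat types are usually fewer than the
  coexisting guilds.
* Full-scale (20 x 20 / 40 x 40, nu = 0.001) runs are supported but slow
  in pure R (minutes to hours per scenario); the workbench exists to make
  the reduced world routine and the full world possible, not fast.
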