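# cdmstab

Stability analysis and competition inference for discrete-time multispecies
communities with delayed maturity.

## The problem

Communities of competing species with non-trivial life cycles — mosquitoes,
for instance, whose larvae take days to mature while adults compete for
oviposition sites — are naturally described by delay difference equations.
`cdmstab` implements the **competitive delayed multispecies (CDM) model**:
each species $i$ matures after $\delta_i$ time steps, adults survive each
step with probability $1 - z_i$, and per-capita recruitment is
Beverton–Holt/Leslie–Gower,

$$x_i(t+1) = (1 - z_i)\,x_i(t) +
  \frac{\lambda_i\,x_i(t-\delta_i)}
       {1 + q_i^{-1}\sum_k A_{ik}\,x_k(t-\delta_i)}
  \prod_{a=0}^{\delta_i-1}\sigma_{a|i},$$

with $A_{ij} \ge 0$ the competitive pressure of species $j$ on species $i$.
The package provides, for this model:

* **Simulation** in two exactly equivalent forms (age-expanded and
  collapsed delayed), with consistent initialisation between them;
* **Equilibria** in closed form — interior (coexistence), boundary, and the
  recovery of the density-dependence scaling `q` from any observed positive
  equilibrium (`solve_q()`);
* **Local stability**: an analytic Jacobian whose spectrum depends on the
  equilibrium only through relative abundances (so stability of *every*
  possible coexistence equilibrium is a function on the simplex,
  exhaustively scanned by `rho_surface()`), spectral radius and return time
  $T_R = (1-\rho)^{-1}$, Frobenius-normal-form classes, and the
  graph-theoretic (Gershgorin/Brualdi) sufficient conditions including the
  delay-free diagonal-dominance criterion;
* **Competition inference**: the Pianka niche-overlap matrix from
  resource-use tables (`pianka_overlap()`), and `fit_competition()`, which
  estimates $A$ from relative abundances alone by minimising
  $[\rho(J(\bar p, A)) - 1]\sum_{ij}A_{ij}$ — trading the resilience of the
  observed equilibrium against total competition strength;
* A **command-line tool** (`inst/cli/cdmstab`) with subcommands
  `simulate | equilibrium | stability | scan | pianka | optimise | fixture`
  over YAML community configs, and a built-in three-species *Anopheles
  gambiae* s.l. malaria-vector configuration (`anopheles_fixture()`).

It is written for population ecologists and vector-biology modellers who
need to ask: *is the coexistence we observe dynamically stable, how fast
does it recover from perturbation, and what competition structure best
explains it?*

## Worked example

The bundled fixture describes three competing malaria-vector species on a
daily time step (maturation delay 10 days, adult recruitment rate 4.5 per
female per day, adult mortality 0.125 per day) observed at relative
abundances (0.34, 0.42, 0.24). Couple them with a high niche-overlap
competition matrix and ask whether that coexistence is stable:

```r
library(cdmstab)
fx <- anopheles_fixture()
A <- matrix(0.9, 3, 3); diag(A) <- 1          # high-overlap competition
comm <- cdm_community(fx$species, A,
                      q = solve_q(cdm_community(fx$species, A), fx$p_bar * 100))
interior_equilibrium(comm)
#> Interior equilibrium (feasible):
#>   x*: 34, 42, 24
#>   relative abundances p: 0.34, 0.42, 0.24
#>   fixed-point residual: 0
cdm_stability(comm, fx$p_bar)
#> CDM local stability at p = (0.34, 0.42, 0.24)
#>   spectral radius rho = 0.998405 -> stable
#>   asymptotic return time T_R = 627.146 steps
#>   Gershgorin bound on rho: 1.8750 (diagnostic)
#>   diagonal dominance (delay-free sufficient condition): FALSE
#>   class-wise sufficient condition: FALSE (weakly irreducible: TRUE)
```

The equilibrium is locally stable, but barely: perturbations decay by a
factor 0.9984 per day, an asymptotic return time of about 627 days, and
neither sufficient condition can certify the stability (the numerical
spectral radius decides). Estimating the competition matrix from the
observed composition instead:

```r
fit <- fit_competition(fx$p_bar, fx$species, seed = 1, warm_start = A)
fit
#> CDM competition fit (m = 3) at p_bar = (0.34, 0.42, 0.24)
#> A_hat:
#>      [,1] [,2] [,3]
#> [1,]    1    0    0
#> [2,]    0    1    0
#> [3,]    0    0    1
#> objective = -0.340280; rho at p_bar = 0.886573; T_R = 8.816 steps
```

For species with identical life histories the objective's global optimum
turns out to be the competition-free matrix: interspecific pressure erodes
self-regulation so quickly here that no amount of added competition pays
for the lost resilience, and the fitted system recovers from perturbations
in days (T_R ≈ 8.8) rather than years. See the methods vignette
(`vignettes/cdm-stability.Rmd`) for the geometry of this objective and for
every numerical tolerance used above.

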