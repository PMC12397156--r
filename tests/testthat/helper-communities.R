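# Shared builders for test batteries. All randomness is locally seeded so the
# suite is reproducible end to end.

# A random community together with a guaranteed-feasible interior equilibrium:
# pick positive adult abundances first, then recover the q that makes them the
# equilibrium (always positive when lambda_tilde > z > 0 and diag(A) > 0).
make_feasible_community <- function(seed, m = NULL, delta_max = 4,
                                    dominant = FALSE) {
  if (is.null(m)) m <- (seed %% 4L) + 1L
  comm <- random_community(seed, m = m, delta_max = delta_max,
                           dominant = dominant)
  set.seed(seed + 10000L)
  x_star <- runif(m, 0.5, 5)
  comm$q <- solve_q(comm, x_star)
  list(community = comm, x_star = x_star)
}

# positive random initial history matrix for the delayed form
random_history <- function(community, seed) {
  set.seed(seed)
  D <- max(community_delta(community))
  matrix(runif((D + 1L) * community$m, 0.2, 3), ncol = community$m)
}

# uniformly random strictly interior simplex point
random_simplex_point <- function(m, min_p = 0.05) {
  repeat {
    p <- rexp(m)
    p <- p / sum(p)
    if (min(p) >= min_p) return(p)
  }
}

# the high-overlap baseline competition matrix used with the mosquito fixture
overlap_baseline <- function(m = 3, a = 0.9) {
  A <- matrix(a, m, m)
  diag(A) <- 1
  A
}

anopheles_community <- function(A = overlap_baseline(), total = 100) {
  fx <- anopheles_fixture()
  comm <- cdm_community(fx$species, A)
  comm$q <- solve_q(comm, fx$p_bar * total)
  list(community = comm, p_bar = fx$p_bar, x_bar = fx$p_bar * total)
}
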