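# Built-in example configurations: the three-species Anopheles gambiae s.l.
# malaria-vector community, and seeded random communities for test batteries.

#' Three-species Anopheles gambiae s.l. community
#'
#' Life histories and observed relative abundances for the three competing
#' malaria-vector species of the *Anopheles gambiae* sensu lato complex
#' (*An. arabiensis*, *An. coluzzii*, *An. gambiae* s.s.), on a daily time
#' step with females only (1:1 sex ratio assumed). All three species share
#' the same life history: immature period `delta = 10` days with immature
#' survival absorbed into the fecundity (all `sigma_immature = 1`, a latent
#' lagged immature population), adult recruitment rate
#' `lambda_tilde = 9/2` females per female per day, and adult daily
#' mortality `z = 0.125`. The observed relative abundances are
#' `p_bar = (0.34, 0.42, 0.24)`.
#'
#' @return List with `species` (list of three [species_life_history()]
#'   objects, named `Aa`, `Ac`, `Ag`) and `p_bar`.
#' @examples
#' fx <- anopheles_fixture()
#' sapply(fx$species, `[[`, "lambda_tilde")  # all 4.5
#' @export
anopheles_fixture <- function() {
  sp <- species_life_history(delta = 10L, sigma_immature = rep(1, 10),
                             sigma_adult = 1 - 0.125, fecundity = 9 / 2)
  list(species = list(Aa = sp, Ac = sp, Ag = sp),
       p_bar = c(Aa = 0.34, Ac = 0.42, Ag = 0.24))
}

#' Seeded random CDM community
#'
#' Draws a reproducible community with positive net growth
#' (`lambda_tilde > z > 0`) guaranteed by construction; with
#' `dominant = TRUE` the competition matrix is strictly row diagonally
#' dominant (the regime where every coexistence equilibrium is provably
#' stable), otherwise off-diagonal competition is drawn up to `offdiag_max`
#' and may destabilise parts of the simplex.
#'
#' @param seed Integer seed (local to this call).
#' @param m Number of species.
#' @param delta_max Maximum maturation delay (delays drawn uniformly on
#'   `0..delta_max`).
#' @param dominant Force strict row diagonal dominance of `A`.
#' @param z_range,growth_range Ranges for adult mortality `z` and the ratio
#'   `lambda_tilde / z` (drawn uniformly).
#' @param sigma_range Range for immature survival probabilities.
#' @param offdiag_max Upper bound for off-diagonal draws when
#'   `dominant = FALSE`.
#' @param q_range Range for the intraspecific scaling `q`.
#' @return A [cdm_community()] with `q` set.
#' @export
random_community <- function(seed, m = 3, delta_max = 4, dominant = FALSE,
                             z_range = c(0.1, 0.5), growth_range = c(1.5, 8),
                             sigma_range = c(0.6, 1), offdiag_max = 1.5,
                             q_range = c(0.5, 5)) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  species <- lapply(seq_len(m), function(i) {
    delta <- sample.int(delta_max + 1L, 1L) - 1L
    sig <- runif(delta, sigma_range[1], sigma_range[2])
    z <- runif(1, z_range[1], z_range[2])
    lt <- z * runif(1, growth_range[1], growth_range[2])  # lambda_tilde > z
    species_life_history(delta, sig, sigma_adult = 1 - z,
                         fecundity = lt / prod(sig))
  })
  A <- matrix(runif(m * m, 0, if (dominant) 1 else offdiag_max), m, m)
  if (m == 1L) {
    diag(A) <- runif(1, 0.5, 1.5)
  } else if (dominant) {
    diag(A) <- 0
    diag(A) <- rowSums(A) * runif(m, 1.05, 2) + 0.1
  } else {
    diag(A) <- runif(m, 0.5, 1.5)
  }
  cdm_community(species, A, q = runif(m, q_range[1], q_range[2]))
}
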