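#' Per-capita recruitment functions
#'
#' `percap_growth()` evaluates the Beverton-Holt/Leslie-Gower per-capita
#' recruitment `G_i(x) = lambda_i / (1 + (1/q_i) * sum_k A[i,k] x_k)` for
#' every species at adult abundances `x`. `percap_growth_F()` additionally
#' discounts by survival through the immature phase,
#' `F_i(x) = G_i(x) * prod(sigma_immature_i)`, the net per-capita rate at
#' which today's adults contribute adults `delta_i + 1` steps ahead.
#'
#' Both are positive and bounded above by `lambda_i` (respectively
#' `lambda_tilde_i`), and strictly decrease in any `x_k` with `A[i,k] > 0`.
#'
#' @param community A [cdm_community()] with `q` set.
#' @param x Non-negative adult abundance vector of length `m`.
#' @return Numeric vector of length `m`.
#' @examples
#' sp <- species_life_history(0, numeric(0), 0.5, 2)
#' comm <- cdm_community(list(sp), matrix(1), q = 1)
#' percap_growth(comm, 1) # 2 / (1 + 1) = 1
#' @export
percap_growth <- function(community, x) {
  q <- require_q(community, "percap_growth()")
  x <- as.numeric(x)
  if (length(x) != community$m) stop("`x` must have length m")
  if (any(x < 0)) stop("`x` must be non-negative")
  community_lambda(community) / (1 + drop(community$A %*% x) / q)
}

#' @rdname percap_growth
#' @export
percap_growth_F <- function(community, x) {
  percap_growth(community, x) * community_survival_product(community)
}

# expanded (age-structured) one-step map --------------------------------------

#' Advance the age-expanded system one step
#'
#' One step of the age-structured recurrence: recruits of species `i` are
#' `G_i(x) * x_i` (with `x` the current adult abundances); immature class
#' `a` survives into class `a + 1` with probability `sigma_immature[a]`; the
#' adult class receives maturing individuals from the oldest immature class
#' and retains surviving adults. For `delta_i = 0` the single class updates
#' as `sigma_adult * y + G_i(x) * y`.
#'
#' @param community A [cdm_community()] with `q` set.
#' @param y Expanded state vector (see [state_blocks()] for the ordering).
#' @return The expanded state one step ahead (same length, non-negative).
#' @export
step_expanded <- function(community, y) {
  validate_expanded_state(community, y)
  blocks <- state_blocks(community)
  x <- y[adult_indices(community)]
  G <- percap_growth(community, x)
  out <- numeric(length(y))
  for (i in seq_len(community$m)) {
    sp <- community$species[[i]]
    ix <- blocks[[i]]
    yi <- y[ix]
    d <- sp$delta
    if (d == 0L) {
      out[ix] <- sp$sigma_adult * yi + G[i] * yi
    } else {
      new <- numeric(d + 1L)
      new[1L] <- G[i] * yi[d + 1L]                       # age 0 recruits
      if (d > 1L)
        new[2:d] <- sp$sigma_immature[1:(d - 1L)] * yi[1:(d - 1L)]
      new[d + 1L] <- sp$sigma_immature[d] * yi[d] + sp$sigma_adult * yi[d + 1L]
      out[ix] <- new
    }
  }
  out
}

# delayed form ----------------------------------------------------------------

#' Adult-abundance history for the delayed form
#'
#' The delayed recurrence needs, for each species `i`, the full adult
#' abundance vector `delta_i` steps back. The history is stored as a
#' `(max(delta) + 1) x m` matrix of past adult vectors, oldest row first and
#' the current abundances in the last row. `adult_history()` builds one,
#' recycling a single starting vector `x0` into a constant history (the
#' package default when only the present is known) or accepting a full
#' matrix. `history_buffer()` extracts the spec of species `i`'s own past:
#' its last `delta_i + 1` adult abundances. `current_adults()` returns the
#' newest row.
#'
#' @param community A [cdm_community()] object.
#' @param x0 Either a non-negative vector of length `m` (constant-history
#'   fill) or a `(max(delta) + 1) x m` matrix, oldest row first.
#' @return An object of class `"adult_history"`.
#' @export
adult_history <- function(community, x0) {
  D <- max(community_delta(community))
  m <- community$m
  if (is.matrix(x0)) {
    if (nrow(x0) != D + 1L || ncol(x0) != m)
      stop(sprintf("history matrix must be %d x %d (rows oldest first)", D + 1L, m))
    H <- x0
  } else {
    x0 <- as.numeric(x0)
    if (length(x0) != m) stop("`x0` must have length m")
    H <- matrix(rep(x0, each = D + 1L), nrow = D + 1L)
  }
  if (any(H < 0)) stop("history abundances must be non-negative")
  structure(list(H = H, m = m, D = D), class = "adult_history")
}

#' @rdname adult_history
#' @param history An `"adult_history"` object.
#' @param i Species index.
#' @export
history_buffer <- function(history, i, community) {
  d <- community$species[[i]]$delta
  history$H[(history$D + 1L - d):(history$D + 1L), i]
}

#' @rdname adult_history
#' @export
current_adults <- function(history) history$H[history$D + 1L, ]

#' Advance the delayed system one step
#'
#' One step of the collapsed delayed recurrence
#' `x_i(t+1) = sigma_adult_i x_i(t) + x_i(t - delta_i) G_i(x(t - delta_i)) *
#' prod(sigma_immature_i)`: equivalent to [step_expanded()] on a consistent
#' age-structured state, but carrying only adult abundances.
#'
#' @param community A [cdm_community()] with `q` set.
#' @param history An [adult_history()] object with full buffers.
#' @return The updated `"adult_history"`; the new adult vector is
#'   `current_adults()` of the result.
#' @export
step_delayed <- function(community, history) {
  if (!inherits(history, "adult_history")) stop("`history` must be an adult_history")
  require_q(community, "step_delayed()")
  m <- community$m
  if (history$m != m || nrow(history$H) != history$D + 1L)
    stop("under-filled or mismatched history")
  delta <- community_delta(community)
  surv <- community_survival_product(community)
  xt <- current_adults(history)
  xnew <- numeric(m)
  for (i in seq_len(m)) {
    xlag <- history$H[history$D + 1L - delta[i], ]   # full vector at t - delta_i
    G <- percap_growth(community, xlag)[i]
    xnew[i] <- community$species[[i]]$sigma_adult * xt[i] +
      xlag[i] * G * surv[i]
  }
  history$H <- rbind(history$H[-1L, , drop = FALSE], xnew, deparse.level = 0)
  history
}

# trajectories ----------------------------------------------------------------

new_trajectory <- function(time, adults, expanded = NULL) {
  colnames(adults) <- paste0("species_", seq_len(ncol(adults)))
  structure(list(time = time, adults = adults, expanded = expanded),
            class = "cdm_trajectory")
}

#' @export
print.cdm_trajectory <- function(x, ...) {
  cat(sprintf("CDM trajectory: %d species, t = %d..%d%s\n",
              ncol(x$adults), min(x$time), max(x$time),
              if (is.null(x$expanded)) "" else " (expanded state retained)"))
  cat("final adult abundances:", paste(signif(x$adults[nrow(x$adults), ], 6),
                                       collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.cdm_trajectory <- function(x, ...) {
  data.frame(time = x$time, x$adults, check.names = FALSE)
}

#' @export
plot.cdm_trajectory <- function(x, log = "", ...) {
  matplot(x$time, x$adults, type = "l", lty = 1, xlab = "time",
          ylab = "adult abundance", log = log, ...)
  legend("topright", legend = colnames(x$adults), col = seq_len(ncol(x$adults)),
         lty = 1, bty = "n")
  invisible(x)
}

#' Simulate a community forward in time
#'
#' Iterates either the age-expanded recurrence or the equivalent delayed
#' recurrence for `nsim` steps. The two forms produce identical adult
#' trajectories when started consistently; the expanded form carries the
#' immature age classes explicitly, the delayed form only the adults and
#' their history.
#'
#' @param object A [cdm_community()] with `q` set.
#' @param nsim Number of steps `T >= 0`; the trajectory has `T + 1` rows.
#' @param seed Unused (the model is deterministic); kept for the generic.
#' @param init Initial condition. For the expanded form: a full expanded
#'   state vector, or an adult vector of length `m` (immatures are then
#'   filled consistently with a constant adult history). For the delayed
#'   form: an [adult_history()], or an adult vector (constant-history fill).
#' @param form `"delayed"` or `"expanded"`.
#' @param keep_expanded Retain the full age-structured state at every step
#'   (expanded form only).
#' @param ... Ignored.
#' @return A `"cdm_trajectory"`: time index, `(T+1) x m` adult matrix and
#'   optionally the expanded states.
#' @examples
#' fx <- anopheles_fixture()
#' comm <- cdm_community(fx$species, A = diag(3), q = 1)
#' eq <- interior_equilibrium(comm)
#' tr <- simulate(comm, nsim = 10, init = eq$x_star)
#' max(abs(tr$adults[11, ] - eq$x_star)) < 1e-10
#' @export
simulate.cdm_community <- function(object, nsim = 1, seed = NULL, init,
                                   form = c("delayed", "expanded"),
                                   keep_expanded = FALSE, ...) {
  form <- match.arg(form)
  if (nsim < 0) stop("`nsim` must be >= 0")
  nsim <- as.integer(nsim)
  m <- object$m
  if (form == "expanded") {
    y <- if (length(init) == m && !is.matrix(init))
      expanded_state_from_history(object, adult_history(object, init))
    else as.numeric(init)
    validate_expanded_state(object, y)
    n <- length(y)
    adults <- matrix(NA_real_, nsim + 1L, m)
    exp_states <- if (keep_expanded) matrix(NA_real_, nsim + 1L, n) else NULL
    ai <- adult_indices(object)
    adults[1L, ] <- y[ai]
    if (keep_expanded) exp_states[1L, ] <- y
    if (nsim > 0) for (t in seq_len(nsim)) {
      y <- step_expanded(object, y)
      adults[t + 1L, ] <- y[ai]
      if (keep_expanded) exp_states[t + 1L, ] <- y
    }
    new_trajectory(0:nsim, adults, exp_states)
  } else {
    h <- if (inherits(init, "adult_history")) init else adult_history(object, init)
    adults <- matrix(NA_real_, nsim + 1L, m)
    adults[1L, ] <- current_adults(h)
    if (nsim > 0) for (t in seq_len(nsim)) {
      h <- step_delayed(object, h)
      adults[t + 1L, ] <- current_adults(h)
    }
    new_trajectory(0:nsim, adults)
  }
}

# consistency between the two forms -------------------------------------------

#' Expanded state consistent with an adult history
#'
#' Builds the age-structured state implied by a record of past adult
#' abundances: age class `a` of species `i` holds the survivors of the
#' recruits produced `a + 1` steps ago,
#' `y_a = prod(sigma_immature[1..a]) * G_i(x(-a-1)) * x_i(-a-1)`.
#' Starting [step_expanded()] from this state reproduces, in its adult
#' coordinates, exactly the trajectory of [step_delayed()] on the history.
#'
#' @param community A [cdm_community()] with `q` set.
#' @param history An [adult_history()] object.
#' @return An expanded state vector.
#' @export
expanded_state_from_history <- function(community, history) {
  blocks <- state_blocks(community)
  y <- numeric(community$m + sum(community_delta(community)))
  for (i in seq_len(community$m)) {
    sp <- community$species[[i]]
    d <- sp$delta
    ix <- blocks[[i]]
    vals <- numeric(d + 1L)
    vals[d + 1L] <- current_adults(history)[i]
    if (d > 0L) for (a in 0:(d - 1L)) {
      xpast <- history$H[history$D + 1L - (a + 1L), ]     # x(t - a - 1)
      G <- percap_growth(community, xpast)[i]
      s <- if (a == 0L) 1 else prod(sp$sigma_immature[1:a])
      vals[a + 1L] <- s * G * xpast[i]
    }
    y[ix] <- vals
  }
  y
}

#' Expanded state at an interior equilibrium
#'
#' The age-structured state whose adult coordinates equal `x_star` and whose
#' immature classes are at their equilibrium values
#' `y_0 = G_i(x*) x_i*`, `y_a = sigma_immature[a] * y_{a-1}`; a fixed point
#' of [step_expanded()].
#'
#' @param community A [cdm_community()] with `q` set.
#' @param x_star Positive adult equilibrium abundances.
#' @return An expanded state vector.
#' @export
expanded_equilibrium_state <- function(community, x_star) {
  expanded_state_from_history(community, adult_history(community, x_star))
}

#' Proportionally perturb an equilibrium state
#'
#' Scales every age class of species `i`'s block by `1 - fractions[i]`,
#' preserving the equilibrium age structure within each species — the
#' natural discrete analogue of "decrease species i's abundance by f".
#'
#' @param community A [cdm_community()] with `q` set.
#' @param x_star Positive adult equilibrium abundances.
#' @param fractions Per-species reduction fractions in `[0, 1)`.
#' @return A perturbed expanded state vector.
#' @export
perturb_equilibrium <- function(community, x_star, fractions) {
  fractions <- rep_len(as.numeric(fractions), community$m)
  if (any(fractions < 0) || any(fractions >= 1))
    stop("`fractions` must lie in [0, 1)")
  y <- expanded_equilibrium_state(community, x_star)
  blocks <- state_blocks(community)
  for (i in seq_len(community$m))
    y[blocks[[i]]] <- (1 - fractions[i]) * y[blocks[[i]]]
  y
}

#' Non-delayed reduction of the community dynamics
#'
#' Returns the one-step map `x -> (1/z_i) F_i(x) x_i` of the non-delayed
#' system associated with the delayed model. Its fixed points coincide with
#' the equilibria of the delayed system (setting `x(t+1) = x(t)` in either
#' gives `F_i(x) = z_i`), so it gives a delay-free route to the same
#' equilibrium structure. Its stability properties are generally different
#' from the delayed system's; it is the classical multispecies Leslie-Gower
#' map when all `z_i = 1`.
#'
#' @param community A [cdm_community()] with `q` set.
#' @return A function of `x` returning the mapped abundance vector. If the
#'   community has `lambda_tilde == z` for some species, the interior
#'   equilibrium degenerates to the boundary; a warning is issued.
#' @export
reduce_to_nondelayed <- function(community) {
  require_q(community, "reduce_to_nondelayed()")
  lt <- community_lambda_tilde(community)
  z <- community_z(community)
  if (any(abs(lt - z) < 1e-12))
    warning("lambda_tilde == z for some species: only the trivial/boundary fixed point exists for them")
  force(community)
  function(x) percap_growth_F(community, x) * x / z
}
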