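# Estimation of the interspecific competition matrix: descriptive
# (niche overlap) and dynamic (resilience optimisation) routes, plus the
# exhaustive stability scan over the relative-abundance simplex.

#' Pianka niche-overlap matrix
#'
#' Computes the pairwise niche-overlap index
#' `alpha[i,j] = sum_r p_ir p_jr / sqrt(sum_r p_ir^2 * sum_r p_jr^2)` from a
#' species-by-resource table of utilisation proportions: the cosine
#' similarity of the species' resource-use vectors, 1 for identical use, 0
#' for disjoint use. Coercing `A = alpha` gives a symmetric competition
#' matrix with unit diagonal — overlap measures shared resource use, not
#' competition itself, which is the gap the optimisation route addresses.
#'
#' @param table `m x R` matrix (or data frame) of proportions; each row must
#'   sum to 1 (tolerance `1e-9`) with entries in `[0, 1]`.
#' @return Symmetric `m x m` matrix with unit diagonal and entries in
#'   `[0, 1]`; row/column names carried over from `table`.
#' @examples
#' pianka_overlap(rbind(c(0.5, 0.5), c(1, 0)))[1, 2]  # 1 / sqrt(2)
#' @export
pianka_overlap <- function(table) {
  P <- as.matrix(table)
  if (!is.numeric(P)) stop("`table` must be numeric")
  if (any(P < 0) || any(P > 1)) stop("utilisation proportions must lie in [0, 1]")
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-9))
    stop(sprintf("each row must sum to 1; row %d sums to %.6g",
                 which.max(abs(rs - 1)), rs[which.max(abs(rs - 1))]))
  nrm <- sqrt(rowSums(P^2))
  if (any(nrm == 0)) stop("zero-norm resource-use row")
  alpha <- (P %*% t(P)) / tcrossprod(nrm)
  alpha <- (alpha + t(alpha)) / 2          # exact symmetry in floating point
  diag(alpha) <- 1
  dimnames(alpha) <- list(rownames(P), rownames(P))
  alpha
}

#' Regular grid on the interior of the relative-abundance simplex
#'
#' Enumerates all points `p` with components that are multiples of `step`,
#' `sum(p) == 1`, and `min(p) >= margin` (strictly interior), in
#' lexicographic order. These points parameterise, up to total abundance,
#' every possible coexistence equilibrium of a CDM community.
#'
#' @param m Number of species.
#' @param step Lattice resolution; `1/step` must be (near-)integer.
#' @param margin Minimum component, `0 < margin < 1/m`.
#' @return Matrix with one row per point and `m` columns.
#' @examples
#' simplex_grid(2, step = 0.25, margin = 0.25)
#' @export
simplex_grid <- function(m, step = 0.02, margin = 0.01) {
  if (m < 1) stop("`m` must be >= 1")
  if (margin <= 0 || margin >= 1 / m)
    stop("`margin` must lie in (0, 1/m)")
  N <- round(1 / step)
  if (abs(N - 1 / step) > 1e-8) stop("`step` must divide 1")
  kmin <- ceiling(margin * N - 1e-9)
  recurse <- function(parts_left, units_left) {
    if (parts_left == 1L) {
      if (units_left >= kmin) return(matrix(units_left, 1L, 1L))
      return(matrix(integer(0), 0L, 1L))
    }
    hi <- units_left - kmin * (parts_left - 1L)
    if (hi < kmin) return(matrix(integer(0), 0L, parts_left))
    do.call(rbind, lapply(kmin:hi, function(k) {
      rest <- recurse(parts_left - 1L, units_left - k)
      if (nrow(rest) == 0L) return(matrix(integer(0), 0L, parts_left))
      cbind(k, rest, deparse.level = 0)
    }))
  }
  K <- recurse(m, N)
  if (nrow(K) == 0L)
    stop("no interior lattice points: infeasible margin/step combination")
  P <- K / N
  colnames(P) <- paste0("p", seq_len(m))
  P
}

#' Spectral radius over the relative-abundance simplex
#'
#' Evaluates `rho(J)` of the analytic CDM Jacobian at every point of a
#' simplex grid: an exhaustive local-stability assessment of *all* possible
#' coexistence equilibria given only the life histories and `A` — no `q`
#' and no total abundance needed, since the Jacobian spectrum depends on the
#' equilibrium only through relative abundances.
#'
#' @inheritParams jacobian_cdm
#' @param grid Matrix of simplex points ([simplex_grid()] output), or `NULL`
#'   to build one with `step` and `margin`.
#' @param step,margin Grid parameters used when `grid` is `NULL`.
#' @param tol Stability classification tolerance.
#' @return An object of class `"rho_surface"`: data frame with columns
#'   `p1..pm`, `rho`, `stable`; attributes `step` and `margin` when the grid
#'   was built internally.
#' @export
rho_surface <- function(object, A = NULL, grid = NULL, step = 0.02,
                        margin = 0.01, tol = 1e-9) {
  comm <- as_community(object, A = A)
  if (is.null(grid)) {
    grid <- simplex_grid(comm$m, step = step, margin = margin)
  } else {
    grid <- as.matrix(grid)
    if (ncol(grid) != comm$m) stop("grid must have m columns")
    if (any(abs(rowSums(grid) - 1) > 1e-9) || any(grid <= 0))
      stop("grid rows must be strictly positive and sum to 1")
    step <- NA_real_; margin <- min(grid)
  }
  rho <- apply(grid, 1L, function(p) spectral_radius(jacobian_cdm(comm, p)))
  out <- data.frame(grid, rho = rho, stable = rho < 1 - tol)
  structure(out, step = step, margin = margin,
            class = c("rho_surface", "data.frame"))
}

#' @export
print.rho_surface <- function(x, ...) {
  cat(sprintf("Spectral-radius surface: %d simplex points, rho in [%.5f, %.5f], %d%% stable\n",
              nrow(x), min(x$rho), max(x$rho), round(100 * mean(x$stable))))
  NextMethod()
}

#' Resilience-competition objective for a candidate competition matrix
#'
#' The criterion minimised by [fit_competition()]:
#' `(rho(J(p_bar, A)) - 1) * sum(A)` (double sum over all entries, the
#' constant diagonal included). For a stabilising `A` (`rho < 1`) the value
#' is negative, and it decreases both when the system becomes more resilient
#' at the observed composition (smaller `rho`) and when total competition
#' strengthens (larger `sum(A)`); multiplying by a constant such as `1/m^2`
#' (mean competition strength) would not change the minimiser.
#'
#' @param A Candidate competition matrix (unit diagonal expected).
#' @param p_bar Observed relative abundances (positive, sums to 1).
#' @param object A [cdm_community()] or list of life histories.
#' @return Scalar objective value (negative iff `rho < 1`).
#' @export
competition_objective <- function(A, p_bar, object) {
  comm <- as_community(object, A = A)
  p_bar <- as.numeric(p_bar)
  if (any(p_bar <= 0) || abs(sum(p_bar) - 1) > 1e-9)
    stop("`p_bar` must be strictly positive and sum to 1")
  (spectral_radius(jacobian_cdm(comm, p_bar)) - 1) * sum(A)
}

upper_tri_to_A <- function(theta, m) {
  A <- diag(m)
  A[upper.tri(A)] <- theta
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  A
}

#' Estimate the competition matrix from relative abundances
#'
#' Fits the interspecific competition matrix of a CDM community by
#' minimising [competition_objective()] over the candidate set of symmetric
#' non-negative matrices with unit diagonal and off-diagonal entries in
#' `[0, a_max]`. The premise: coexisting species are (i) more likely to be
#' observed near a resilient equilibrium — small spectral radius, fast
#' return after perturbations — and (ii) under pressure to compete as
#' strongly as possible; the objective trades the two off at the observed
#' relative abundances `p_bar`. Only `p_bar`, the recruitment rates and the
#' adult mortalities enter — no absolute abundances and no `q`.
#'
#' The `m (m - 1) / 2` free entries are optimised by multistart bounded
#' quasi-Newton (`stats::optim`, L-BFGS-B): `n_starts` uniform draws over
#' the box (plus `warm_start`, e.g. a Pianka overlap matrix, when given),
#' keeping the best converged candidate; ties broken by lower spectral
#' radius. Fixed `seed` makes the result reproducible bit for bit. A fit
#' whose best value is non-negative (no stabilising candidate found) errors.
#'
#' @param p_bar Observed relative abundances (positive, sums to 1).
#' @param object A [cdm_community()] (its `A` is ignored) or list of
#'   [species_life_history()] objects.
#' @param a_max Upper bound on off-diagonal entries; the default 1 keeps the
#'   estimate on the niche-overlap scale.
#' @param n_starts Number of random starts.
#' @param seed Integer seed for the starts.
#' @param warm_start Optional matrix in the candidate set used as an extra
#'   start.
#' @return An object of class `"cdm_fit"`: `A_hat`, `objective`, `rho`
#'   (at `p_bar` under `A_hat`), `return_time`, `trace` (one row per start),
#'   plus the inputs.
#' @examples
#' fx <- anopheles_fixture()
#' fit <- fit_competition(fx$p_bar, fx$species, n_starts = 4, seed = 1)
#' coef(fit)
#' @export
fit_competition <- function(p_bar, object, a_max = 1, n_starts = 16,
                            seed = NULL, warm_start = NULL) {
  species <- if (inherits(object, "cdm_community")) object$species else object
  m <- if (inherits(species, "species_life_history")) 1L else length(species)
  comm0 <- as_community(species, A = diag(m))
  p_bar <- as.numeric(p_bar)
  if (length(p_bar) != m || any(p_bar <= 0) || abs(sum(p_bar) - 1) > 1e-9)
    stop("`p_bar` must be strictly positive of length m and sum to 1")
  if (a_max <= 0) stop("`a_max` must be positive")
  if (n_starts < 1) stop("`n_starts` must be >= 1")
  k <- (m * (m - 1L)) %/% 2L
  fn <- function(theta) {
    A <- upper_tri_to_A(theta, m)
    (spectral_radius(jacobian_cdm(comm0, p_bar, A = A)) - 1) * sum(A)
  }
  if (k == 0L) {                                 # single species: no free entries
    A_hat <- diag(m)
    obj <- fn(numeric(0))
    rho <- spectral_radius(jacobian_cdm(comm0, p_bar, A = A_hat))
    return(structure(list(A_hat = A_hat, objective = obj, rho = rho,
                          return_time = if (rho < 1) return_time(rho) else NA_real_,
                          trace = data.frame(start = I(list(numeric(0))),
                                             value = obj, convergence = 0L),
                          p_bar = p_bar, species = comm0$species,
                          a_max = a_max, seed = seed), class = "cdm_fit"))
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  starts <- lapply(seq_len(n_starts), function(s) runif(k, 0, a_max))
  if (!is.null(warm_start)) {
    W <- as.matrix(warm_start)
    if (nrow(W) != m || any(abs(diag(W) - 1) > 1e-9) || any(W < 0) ||
        any(abs(W - t(W)) > 1e-9))
      stop("`warm_start` must be symmetric non-negative with unit diagonal")
    starts <- c(starts, list(pmin(W[upper.tri(W)], a_max)))
  }
  fits <- lapply(starts, function(s)
    tryCatch(optim(s, fn, method = "L-BFGS-B", lower = 0, upper = a_max,
                   control = list(factr = 1e4)),
             error = function(e) list(par = s, value = Inf, convergence = 999L,
                                      message = conditionMessage(e))))
  trace <- data.frame(start = I(starts),
                      value = vapply(fits, `[[`, numeric(1), "value"),
                      convergence = vapply(fits, function(f)
                        as.integer(f$convergence), integer(1)))
  ok <- trace$convergence %in% c(0L, 52L) & is.finite(trace$value)
  if (!any(ok))
    stop(paste0("all optimisation starts failed to converge:\n",
                paste(utils::capture.output(print(trace[, c("value", "convergence")])),
                      collapse = "\n")))
  cand <- which(ok)
  vals <- trace$value[cand]
  rhos <- vapply(cand, function(i)
    spectral_radius(jacobian_cdm(comm0, p_bar,
                                 A = upper_tri_to_A(fits[[i]]$par, m))), numeric(1))
  best <- cand[order(vals, rhos)][1L]
  A_hat <- upper_tri_to_A(fits[[best]]$par, m)
  rho <- spectral_radius(jacobian_cdm(comm0, p_bar, A = A_hat))
  if (trace$value[best] >= 0)
    stop("no stabilising competition matrix found: best objective is non-negative (rho >= 1 at p_bar)")
  structure(list(A_hat = A_hat, objective = trace$value[best], rho = rho,
                 return_time = if (rho < 1) return_time(rho) else NA_real_,
                 trace = trace, p_bar = p_bar, species = comm0$species,
                 a_max = a_max, seed = seed),
            class = "cdm_fit")
}

#' @export
print.cdm_fit <- function(x, ...) {
  m <- length(x$p_bar)
  cat(sprintf("CDM competition fit (m = %d) at p_bar = (%s)\n",
              m, paste(signif(x$p_bar, 4), collapse = ", ")))
  cat("A_hat:\n"); print(round(x$A_hat, 4))
  cat(sprintf("objective = %.6f; rho at p_bar = %.6f; T_R = %.3f steps\n",
              x$objective, x$rho, x$return_time))
  invisible(x)
}

#' @export
summary.cdm_fit <- function(object, ...) {
  tr <- object$trace
  res <- list(fit = object,
              n_starts = nrow(tr),
              n_converged = sum(tr$convergence %in% c(0L, 52L)),
              best_value = object$objective,
              value_range = range(tr$value[is.finite(tr$value)]),
              mean_offdiag = if (length(object$p_bar) > 1)
                mean(object$A_hat[upper.tri(object$A_hat)]) else NA_real_)
  class(res) <- "summary.cdm_fit"
  res
}

#' @export
print.summary.cdm_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("starts: %d (%d converged); objective range across starts: [%.6f, %.6f]\n",
              x$n_starts, x$n_converged, x$value_range[1], x$value_range[2]))
  if (!is.na(x$mean_offdiag))
    cat(sprintf("mean estimated interspecific coefficient: %.4f\n", x$mean_offdiag))
  invisible(x)
}

#' @export
coef.cdm_fit <- function(object, ...) object$A_hat

#' Predict the spectral radius at new community compositions
#'
#' Evaluates `rho(J(p, A_hat))` of the fitted system at new simplex points:
#' the predicted per-step dampening of perturbations were the community
#' observed at composition `p`.
#'
#' @param object A `"cdm_fit"`.
#' @param newdata Matrix (rows = simplex points) or single vector; defaults
#'   to the fitted `p_bar`.
#' @param ... Ignored.
#' @return Numeric vector of spectral radii.
#' @export
predict.cdm_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$p_bar
  P <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1L)
  comm <- as_community(object$species, A = object$A_hat)
  apply(P, 1L, function(p) spectral_radius(jacobian_cdm(comm, p)))
}

#' Plot the fitted spectral-radius surface
#'
#' For three-species fits, draws the `rho` surface of the fitted system over
#' the simplex (as a `p1`-`p2` heat map, `p3 = 1 - p1 - p2`) and marks the
#' observed composition and the surface minimum. For two species, plots
#' `rho` against `p1`.
#'
#' @param x A `"cdm_fit"`.
#' @param step,margin Grid resolution for the surface.
#' @param ... Passed to the underlying plot.
#' @return The `"rho_surface"` used, invisibly.
#' @export
plot.cdm_fit <- function(x, step = 0.02, margin = 0.01, ...) {
  m <- length(x$p_bar)
  surf <- rho_surface(x$species, A = x$A_hat, step = step, margin = margin)
  if (m == 2L) {
    plot(surf$p1, surf$rho, type = "l", xlab = "p1", ylab = "spectral radius", ...)
    abline(v = x$p_bar[1], lty = 2)
  } else if (m == 3L) {
    u <- sort(unique(surf$p1)); v <- sort(unique(surf$p2))
    Z <- matrix(NA_real_, length(u), length(v))
    Z[cbind(match(surf$p1, u), match(surf$p2, v))] <- surf$rho
    image(u, v, Z, xlab = "p1", ylab = "p2",
          col = hcl.colors(64, "viridis"), ...)
    points(x$p_bar[1], x$p_bar[2], pch = 4, cex = 1.5)
    amin <- which.min(surf$rho)
    points(surf$p1[amin], surf$p2[amin], pch = 1, cex = 1.5)
  } else {
    plot(surf$rho, type = "h", xlab = "grid index", ylab = "spectral radius", ...)
  }
  invisible(surf)
}
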