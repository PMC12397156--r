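#' Interior (coexistence) equilibrium of the CDM model
#'
#' Solves the closed-form equilibrium condition
#' `A x* = diag(lambda_tilde - z) diag(z)^{-1} q`; for nonsingular `A` the
#' interior equilibrium `x*` is unique. The equilibrium is *feasible* when
#' every entry is strictly positive, in which case the relative abundances
#' `p = x* / sum(x*)` are also returned — the coordinates on the simplex
#' that alone determine local stability (see [jacobian_cdm()]).
#'
#' @param community A [cdm_community()]; `q` may be supplied here instead.
#' @param q Optional override of the community's `q`.
#' @param tol Strict-positivity tolerance for the feasibility flag.
#' @param max_condition Refuse the solve when the estimated condition number
#'   of `A` exceeds this (the closed form assumes exact nonsingularity).
#' @return An object of class `"cdm_equilibrium"`: list with `x_star`,
#'   `feasible`, `q_used`, `p` (or `NULL` if infeasible) and `residual`, the
#'   max-abs defect of the fixed-point condition.
#' @examples
#' sp <- species_life_history(0, numeric(0), 0.5, 2)
#' comm <- cdm_community(list(sp), matrix(1), q = 1)
#' interior_equilibrium(comm)$x_star  # q (lambda_tilde / z - 1) = 3
#' @export
interior_equilibrium <- function(community, q = community$q, tol = 1e-12,
                                 max_condition = 1e12) {
  if (is.null(q)) require_q(community, "interior_equilibrium()")
  q <- rep_len(as.numeric(q), community$m)
  if (any(q <= 0)) stop("`q` must be positive")
  A <- community$A
  rc <- rcond(A)
  if (!is.finite(rc) || rc < 1 / max_condition)
    stop(sprintf("competition matrix is singular or ill-conditioned (reciprocal condition estimate %.3g); the closed-form equilibrium is unreliable", rc))
  lt <- community_lambda_tilde(community)
  z <- community_z(community)
  rhs <- (lt - z) / z * q
  x_star <- drop(solve(A, rhs))
  feasible <- all(x_star > tol)
  # defect of x = sigma_adult x + lambda_tilde x / (1 + q^{-1} A x)
  comm_q <- community; comm_q$q <- q
  residual <- max(abs(x_star - ((1 - z) * x_star +
                                  percap_growth_F(comm_q, pmax(x_star, 0)) * x_star)))
  structure(list(x_star = x_star, feasible = feasible, q_used = q,
                 p = if (feasible) x_star / sum(x_star) else NULL,
                 residual = residual),
            class = "cdm_equilibrium")
}

#' @export
print.cdm_equilibrium <- function(x, ...) {
  cat(sprintf("Interior equilibrium (%sfeasible):\n", if (x$feasible) "" else "in"))
  cat("  x*:", paste(signif(x$x_star, 6), collapse = ", "), "\n")
  if (x$feasible)
    cat("  relative abundances p:", paste(signif(x$p, 4), collapse = ", "), "\n")
  cat(sprintf("  fixed-point residual: %.3g\n", x$residual))
  invisible(x)
}

#' Recover the intraspecific scaling q from an observed equilibrium
#'
#' Inverts the equilibrium condition for `q`:
#' `q_i = z_i * sum_k A[i,k] x*_k / (lambda_tilde_i - z_i)`. Whenever the
#' observed equilibrium is positive, `lambda_tilde > z > 0` and `diag(A) > 0`,
#' the recovered `q` is guaranteed strictly positive, so any observed
#' coexistence point is attainable as an interior equilibrium of the model.
#' Feeding the result back into [interior_equilibrium()] reproduces
#' `x_star`. `q` is homogeneous of degree one in `x_star`: only relative
#' abundances plus one scale parameter are identified.
#'
#' @param community A [cdm_community()] (its `q`, if any, is ignored).
#' @param x_star Strictly positive observed adult equilibrium abundances.
#' @return Positive numeric vector `q` of length `m`.
#' @examples
#' sp <- species_life_history(0, numeric(0), 0.5, 2)
#' comm <- cdm_community(list(sp), matrix(1))
#' solve_q(comm, x_star = 3)  # 1
#' @export
solve_q <- function(community, x_star) {
  x_star <- as.numeric(x_star)
  if (length(x_star) != community$m || any(x_star <= 0))
    stop("`x_star` must be strictly positive of length m")
  lt <- community_lambda_tilde(community)
  z <- community_z(community)
  bad <- which(lt <= z)
  if (length(bad))
    stop(sprintf("no positive equilibrium possible: lambda_tilde <= z for species %s",
                 paste(bad, collapse = ", ")))
  z * drop(community$A %*% x_star) / (lt - z)
}

#' Boundary equilibria
#'
#' Equilibria with a non-empty set of species extinct: the surviving
#' subsystem sits at its own interior equilibrium (solved with the
#' corresponding submatrix of `A` and entries of `q`) and the extinct set is
#' at zero. Passing all species returns the trivial equilibrium.
#'
#' @param community A [cdm_community()] with `q` set.
#' @param extinct Integer indices of the extinct species (non-empty).
#' @return An object of class `"cdm_boundary"`: `extinct_set`, `x_hat`
#'   (full-length vector, zeros on the extinct set), `feasible` flag for the
#'   surviving subsystem.
#' @export
boundary_equilibrium <- function(community, extinct) {
  extinct <- sort(unique(as.integer(extinct)))
  m <- community$m
  if (length(extinct) == 0L || any(extinct < 1L) || any(extinct > m))
    stop("`extinct` must be a non-empty subset of 1..m")
  q <- require_q(community, "boundary_equilibrium()")
  x_hat <- numeric(m)
  surviving <- setdiff(seq_len(m), extinct)
  feasible <- TRUE
  if (length(surviving)) {
    sub <- cdm_community(community$species[surviving],
                         community$A[surviving, surviving, drop = FALSE],
                         q = q[surviving])
    eq <- interior_equilibrium(sub)
    x_hat[surviving] <- eq$x_star
    feasible <- eq$feasible
  }
  structure(list(extinct_set = extinct, x_hat = x_hat, feasible = feasible),
            class = "cdm_boundary")
}

#' @export
print.cdm_boundary <- function(x, ...) {
  cat(sprintf("Boundary equilibrium, extinct species {%s}%s:\n",
              paste(x$extinct_set, collapse = ", "),
              if (x$feasible) "" else " (surviving subsystem infeasible)"))
  cat("  x_hat:", paste(signif(x$x_hat, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Leslie-Gower global-stability inequality for the non-delayed model
#'
#' Per-species check of the sufficient condition for global stability of the
#' positive equilibrium of the non-delayed multispecies Leslie-Gower model:
#' `lambda_i - 1 >= sum_{j != i} lambda_j A[i,j] / A[j,j]`, required
#' together with `lambda > 1` elementwise (and interspecific competition
#' small); this is a global counterpart to the local conditions used for the
#' delayed model and is reported as-is, without any smallness test.
#'
#' @param lambda Positive fecundity vector.
#' @param A Competition matrix with `diag(A) > 0`.
#' @return List with `per_species` logical vector for the inequality,
#'   `lambda_gt_one` logical vector, and `overall` (all inequalities hold
#'   and `lambda > 1`).
#' @export
sacker_condition <- function(lambda, A) {
  lambda <- as.numeric(lambda)
  A <- as.matrix(A)
  m <- length(lambda)
  if (nrow(A) != m || ncol(A) != m) stop("dimension mismatch")
  if (any(diag(A) <= 0)) stop("diag(A) must be strictly positive")
  scaled <- sweep(A, 2L, diag(A), "/") * rep(lambda, each = m)  # lambda_j A_ij / A_jj
  per <- vapply(seq_len(m), function(i)
    lambda[i] - 1 >= sum(scaled[i, -i]), logical(1))
  list(per_species = per, lambda_gt_one = lambda > 1,
       overall = all(per) && all(lambda > 1))
}
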