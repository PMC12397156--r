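# Jacobian assembly and local stability theory for the CDM model.
#
# All matrices follow the package ordering contract (species-major blocks,
# ages ascending, adult last; see state_blocks()).

as_community <- function(object, A = NULL, q = NULL) {
  if (inherits(object, "cdm_community")) {
    if (!is.null(A)) object$A <- as.matrix(A)
    if (!is.null(q)) object$q <- rep_len(as.numeric(q), object$m)
    if (nrow(object$A) != object$m) stop("`A` dimensions must match m")
    return(object)
  }
  if (inherits(object, "species_life_history")) object <- list(object)
  if (is.null(A)) stop("`A` is required when passing bare life histories")
  cdm_community(object, A, q = q)
}

#' Analytic Jacobian of the CDM model at an interior equilibrium
#'
#' Assembles the Jacobian of the age-expanded CDM recurrence evaluated at an
#' interior equilibrium with adult abundances `x` (strictly positive). The
#' intraspecific scaling `q` is *not* needed: at equilibrium the density
#' dependence saturates at `lambda_tilde_i / z_i`, and the equilibrium
#' enters the reproduction row of species `i` only through the ratios
#' `A[i,j] x_i / sum_k A[i,k] x_k`. Consequently `J(c x) == J(x)` for any
#' `c > 0`: stability of a coexistence equilibrium depends only on the
#' relative abundances, so `x` may equally be a point of the simplex.
#'
#' Nonzero entries: per-species immature survival subdiagonals and the
#' adult diagonal/maturation entries, plus the age-0 (reproduction) row of
#' each species at every adult column with `A[i,j] != 0`.
#'
#' @param object A [cdm_community()], or a list of [species_life_history()]
#'   objects (then `A` is required).
#' @param x Strictly positive adult abundances or relative abundances,
#'   length `m`.
#' @param A Optional competition matrix overriding the community's.
#' @return An object of class `"cdm_jacobian"`: the dense `n x n` matrix
#'   (`n = m + sum(delta)`) with attributes `blocks` (per-species index
#'   ranges) and `adult` (adult-class indices).
#' @examples
#' sp <- species_life_history(0, numeric(0), 0.5, 2)
#' jacobian_cdm(list(sp), x = 1, A = matrix(1))  # 1x1 matrix 0.625
#' @export
jacobian_cdm <- function(object, x, A = NULL) {
  comm <- as_community(object, A = A)
  m <- comm$m
  x <- as.numeric(x)
  if (length(x) != m || any(x <= 0))
    stop("`x` must be strictly positive of length m (abundances or relative abundances)")
  lt <- community_lambda_tilde(comm)
  z <- community_z(comm)
  lam <- community_lambda(comm)
  if (any(lt <= z))
    stop("interior equilibrium requires lambda_tilde > z for every species")
  delta <- community_delta(comm)
  blocks <- state_blocks(comm)
  adult <- adult_indices(comm)
  n <- m + sum(delta)
  J <- matrix(0, n, n)
  S <- drop(comm$A %*% x)                     # sum_k A_ik x_k
  for (i in seq_len(m)) {
    sp <- comm$species[[i]]
    ix <- blocks[[i]]
    d <- delta[i]
    r <- comm$A[i, ] * x[i] / S[i]            # A_ij x_i / S_i
    if (d > 0L) {
      for (a in seq_len(d))                   # survival subdiagonal
        J[ix[a + 1L], ix[a]] <- sp$sigma_immature[a]
      J[ix[d + 1L], ix[d + 1L]] <- sp$sigma_adult
      # reproduction row (age 0) at adult columns
      J[ix[1L], adult[i]] <-
        z[i] * (lam[i] / lt[i] - lam[i] * (lt[i] - z[i]) / lt[i]^2 * r[i])
      for (j in seq_len(m)[-i]) if (comm$A[i, j] != 0)
        J[ix[1L], adult[j]] <-
          -z[i] * lam[i] * (lt[i] - z[i]) / lt[i]^2 * r[j]
    } else {
      J[ix[1L], adult[i]] <-
        sp$sigma_adult + z[i] * (1 - (lam[i] - z[i]) / lam[i] * r[i])
      for (j in seq_len(m)[-i]) if (comm$A[i, j] != 0)
        J[ix[1L], adult[j]] <-
          -z[i] * (lam[i] - z[i]) / lam[i] * r[j]
    }
  }
  structure(J, blocks = blocks, adult = adult, class = c("cdm_jacobian", "matrix"))
}

#' Central-difference Jacobian of the expanded one-step map
#'
#' Numerical Jacobian of [step_expanded()] by central differences at an
#' expanded state, used as the independent numerical check on
#' [jacobian_cdm()]. Unlike the analytic route this needs `q`.
#'
#' @param community A [cdm_community()] with `q` set.
#' @param y Expanded state at which to differentiate (typically
#'   [expanded_equilibrium_state()]).
#' @param h Relative step size for the differences.
#' @return A plain `n x n` matrix.
#' @export
jacobian_numeric <- function(community, y, h = 1e-6) {
  validate_expanded_state(community, y)
  if (h <= 0) stop("`h` must be positive")
  n <- length(y)
  J <- matrix(0, n, n)
  for (l in seq_len(n)) {
    hl <- h * max(1, abs(y[l]))
    yp <- y; yp[l] <- y[l] + hl
    ym <- y; ym[l] <- max(y[l] - hl, 0)
    J[, l] <- (step_expanded(community, yp) - step_expanded(community, ym)) /
      (yp[l] - ym[l])
  }
  J
}

#' Spectral radius and asymptotic return time
#'
#' `spectral_radius()` is the maximum modulus of the eigenvalues: the
#' long-run per-step amplification of small deviations from equilibrium,
#' and the local stability criterion (`rho < 1`). `return_time()` converts
#' it into the asymptotic return time after a perturbation,
#' `T_R = 1 / (1 - rho)`; shorter return times mean higher resilience.
#'
#' @param J A square matrix.
#' @return `spectral_radius()`: a scalar `>= 0`; `return_time()`: a scalar
#'   `>= 1` (errors when `rho >= 1`, where no finite return time exists).
#' @export
spectral_radius <- function(J) {
  J <- unclass(J)
  if (!is.matrix(J) || nrow(J) != ncol(J)) stop("`J` must be a square matrix")
  if (nrow(J) == 0L) return(0)
  max(Mod(eigen(J, only.values = TRUE)$values))
}

#' @rdname spectral_radius
#' @param rho A spectral radius, `rho < 1`.
#' @export
return_time <- function(rho) {
  if (any(rho >= 1)) stop("return time is undefined for rho >= 1")
  1 / (1 - rho)
}

# Frobenius normal form ------------------------------------------------------

#' Classes of a matrix: strongly connected components in triangular order
#'
#' Partitions the node set of the digraph of `J` (arc `i -> j` iff
#' `J[i, j] != 0`) into its strongly connected components ("classes"),
#' ordered so that a simultaneous row/column permutation by the
#' concatenated classes puts `J` into lower block-triangular (Frobenius
#' normal) form, with each diagonal block irreducible or a 1x1 zero. When
#' the nodes carry species block structure (a `"cdm_jacobian"`), the species
#' with at least one node in each class are also reported.
#'
#' @param J Square matrix; preferably a [jacobian_cdm()] result so that
#'   species sets can be attached.
#' @return An object of class `"class_partition"`: `classes` (list of
#'   integer node sets, diagonal-block order), `species` (list of species
#'   index sets `D_w`, or `NULL` when `J` has no block metadata), and
#'   `permutation` (the concatenated node order).
#' @export
frobenius_partition <- function(J) {
  blocks <- attr(J, "blocks")
  M <- unclass(J)
  if (!is.matrix(M) || nrow(M) != ncol(M)) stop("`J` must be a square matrix")
  n <- nrow(M)
  g <- igraph::graph_from_adjacency_matrix((M != 0) * 1, mode = "directed")
  memb <- igraph::components(g, mode = "strong")$membership
  r <- max(memb)
  # condensation DAG: edge c(i) -> c(j) for each arc i -> j across classes
  nz <- which(M != 0, arr.ind = TRUE)
  from <- memb[nz[, 1L]]; to <- memb[nz[, 2L]]
  keep <- from != to
  cond <- igraph::graph_from_edgelist(cbind(from[keep], to[keep])) |>
    igraph::simplify()
  if (igraph::vcount(cond) < r) cond <- igraph::add_vertices(cond, r - igraph::vcount(cond))
  # lower triangular form: arcs must run from later classes to earlier ones
  ord <- rev(as.integer(igraph::topo_sort(cond, mode = "out")))
  classes <- lapply(ord, function(w) which(memb == w))
  species <- NULL
  if (!is.null(blocks)) {
    node2sp <- integer(n)
    for (i in seq_along(blocks)) node2sp[blocks[[i]]] <- i
    species <- lapply(classes, function(ix) sort(unique(node2sp[ix])))
  }
  structure(list(classes = classes, species = species,
                 permutation = unlist(classes)),
            class = "class_partition")
}

#' @export
print.class_partition <- function(x, ...) {
  cat(sprintf("Frobenius partition: %d class(es)\n", length(x$classes)))
  for (w in seq_along(x$classes)) {
    cat(sprintf("  class %d: nodes {%s}", w, paste(x$classes[[w]], collapse = ",")))
    if (!is.null(x$species))
      cat(sprintf(" | species {%s}", paste(x$species[[w]], collapse = ",")))
    cat("\n")
  }
  invisible(x)
}

#' Irreducibility and weak irreducibility of a matrix digraph
#'
#' `B` is irreducible iff its digraph is strongly connected, equivalently
#' `(I + |B|)^(n-1) > 0` elementwise. `B` is weakly irreducible iff every
#' node lies on a nontrivial cycle with some other node: row `i` of
#' `C = (I + |B|)^(n-1)` has an off-diagonal `C[i,j] != 0` with `C[j,i] != 0`
#' too. Weak irreducibility is the hypothesis of the cycle-product
#' (Brualdi) eigenvalue bound behind [check_sufficient_stability()]. Powers
#' are evaluated in boolean arithmetic so large `n` cannot overflow.
#'
#' @param B Square matrix.
#' @return List with logicals `irreducible` and `weakly_irreducible`.
#' @export
irreducibility_flags <- function(B) {
  B <- unclass(B)
  if (!is.matrix(B) || nrow(B) != ncol(B)) stop("`B` must be a square matrix")
  n <- nrow(B)
  if (n == 1L)
    return(list(irreducible = B[1L, 1L] != 0, weakly_irreducible = FALSE))
  # boolean (I + |B|)^(n-1) by repeated squaring
  P <- (diag(n) + abs(B)) > 0
  C <- diag(n) > 0
  e <- n - 1L
  while (e > 0L) {
    if (e %% 2L == 1L) C <- (C %*% P) > 0
    P <- (P %*% P) > 0
    e <- e %/% 2L
  }
  offdiag <- C & t(C)
  diag(offdiag) <- FALSE
  list(irreducible = all(C),
       weakly_irreducible = all(rowSums(offdiag) > 0))
}

# sufficient conditions -------------------------------------------------------

#' Class-wise sufficient condition for local stability of coexistence
#'
#' Evaluates, at an interior equilibrium with (relative) abundances `x`, the
#' graph-theoretic sufficient condition for local asymptotic stability: for
#' every class `D_w` of the Frobenius partition of the Jacobian and every
#' species `i` in it,
#' \deqn{\{|G_i + x_i \partial G_i/\partial x_i| + \sum_{j \in D_w
#'   \setminus i} |x_i \partial G_i/\partial x_j|\}\,
#'   \prod_a \sigma_{a|i} < z_i,}
#' with the CDM partial derivatives in closed form (no `q` needed). The
#' condition generalises the classical delay-independent single-species
#' criterion `|d(x F(x))/dx| < z` and, like it, involves the delays only
#' through the immature survival product. It rests on a cycle-product
#' eigenvalue bound that requires the Jacobian to be weakly irreducible;
#' the flag is reported and, when violated, the check is not claimed.
#'
#' A species whose nodes fall in several classes (possible only when a
#' reproduction entry is exactly zero) is conservatively required to pass in
#' every class containing one of its nodes.
#'
#' The condition is sufficient, not necessary: failure says nothing about
#' instability ([spectral_radius()] decides).
#'
#' @inheritParams jacobian_cdm
#' @return List: `per_species` (logical, conjunction over classes),
#'   `per_class` (list of per-species margins and verdicts),
#'   `weakly_irreducible`, and `overall` (all species pass and the
#'   hypothesis holds).
#' @export
check_sufficient_stability <- function(object, x, A = NULL) {
  comm <- as_community(object, A = A)
  J <- jacobian_cdm(comm, x)
  flags <- irreducibility_flags(J)
  part <- frobenius_partition(J)
  m <- comm$m
  lt <- community_lambda_tilde(comm)
  z <- community_z(comm)
  cc <- (lt - z) / lt
  S <- drop(comm$A %*% x)
  pass <- rep(TRUE, m)
  per_class <- vector("list", length(part$classes))
  for (w in seq_along(part$classes)) {
    Dw <- part$species[[w]]
    lhs <- vapply(Dw, function(i) {
      others <- setdiff(Dw, i)
      cross <- if (length(others)) sum(comm$A[i, others]) * x[i] / S[i] else 0
      z[i] * (abs(1 - cc[i] * comm$A[i, i] * x[i] / S[i]) + cc[i] * cross)
    }, numeric(1))
    ok <- lhs < z[Dw]
    per_class[[w]] <- data.frame(species = Dw, lhs = lhs, z = z[Dw], pass = ok)
    pass[Dw] <- pass[Dw] & ok
  }
  list(per_species = pass, per_class = per_class,
       weakly_irreducible = flags$weakly_irreducible,
       overall = all(pass) && flags$weakly_irreducible)
}

#' Diagonal-dominance sufficient condition for stable coexistence
#'
#' Checks strict row diagonal dominance of the competition matrix,
#' `A[i,i] > sum_{j != i} A[i,j]` for every `i`: when intraspecific
#' competition outweighs total interspecific competition (and
#' `lambda_tilde > z > 0`), any interior equilibrium of the CDM model is
#' feasible with a positive `q` and locally asymptotically stable — at
#' *every* point of the relative-abundance simplex and regardless of the
#' maturation delays.
#'
#' @param object A [cdm_community()] or a bare competition matrix.
#' @return List with `per_species`, `overall` (the dominance condition), and
#'   `growth_feasible` (`lambda_tilde > z > 0`; `NA` for a bare matrix).
#' @export
check_diagonal_dominance <- function(object) {
  if (inherits(object, "cdm_community")) {
    A <- object$A
    growth <- all(community_lambda_tilde(object) > community_z(object)) &&
      all(community_z(object) > 0)
  } else {
    A <- as.matrix(object)
    growth <- NA
  }
  per <- vapply(seq_len(nrow(A)), function(i) A[i, i] > sum(A[i, -i]), logical(1))
  list(per_species = per, overall = all(per), growth_feasible = growth)
}

#' Stability of boundary equilibria (invasion condition)
#'
#' A boundary equilibrium is locally asymptotically stable when (i) the
#' surviving subsystem is locally stable at its own interior equilibrium
#' (`rho(J_resident) < 1`) and (ii) each extinct species cannot invade:
#' `(lambda_tilde_i - z_i) / z_i < (1/q_i) sum_k A[i,k] x_hat_k`,
#' equivalently `G_i(x_hat) * prod(sigma_immature_i) < z_i` — the net
#' recruitment of a rare invader into the resident community falls short of
#' its adult mortality. Unlike the interior condition this depends on the
#' actual resident abundances, hence on `q` (the empty sum makes the trivial
#' equilibrium stable iff `lambda_tilde < z` for all species).
#'
#' @param community A [cdm_community()] with `q` set.
#' @param boundary A [boundary_equilibrium()] result (or a set of extinct
#'   indices, from which one is computed).
#' @return List: `rho_resident`, `resident_stable`, per-extinct-species
#'   data frame `invasion` (growth potential vs competitive pressure, and
#'   the condition), and `stable` (both requirements hold).
#' @export
boundary_stability <- function(community, boundary) {
  q <- require_q(community, "boundary_stability()")
  if (!inherits(boundary, "cdm_boundary"))
    boundary <- boundary_equilibrium(community, boundary)
  m <- community$m
  extinct <- boundary$extinct_set
  surviving <- setdiff(seq_len(m), extinct)
  if (length(surviving)) {
    sub <- cdm_community(community$species[surviving],
                         community$A[surviving, surviving, drop = FALSE],
                         q = q[surviving])
    rho_res <- spectral_radius(jacobian_cdm(sub, boundary$x_hat[surviving]))
  } else rho_res <- 0
  resident_stable <- rho_res < 1 - 1e-9
  lt <- community_lambda_tilde(community)
  z <- community_z(community)
  pressure <- drop(community$A[extinct, , drop = FALSE] %*% boundary$x_hat) / q[extinct]
  growth <- (lt[extinct] - z[extinct]) / z[extinct]
  invasion <- data.frame(species = extinct, growth_potential = growth,
                         competitive_pressure = pressure,
                         excluded = growth < pressure)
  list(rho_resident = rho_res, resident_stable = resident_stable,
       invasion = invasion,
       stable = resident_stable && all(invasion$excluded))
}

#' Gershgorin upper bound on the spectral radius
#'
#' `max_i (|B[i,i]| + sum_{j != i} |B[i,j]|)`: the farthest reach of the
#' Gershgorin discs from the origin, an always-valid upper bound on the
#' spectral radius. Diagnostic only — for delayed-model Jacobians the bound
#' routinely exceeds one even when the equilibrium is stable (rows holding
#' the adult survival probability plus a maturation inflow sum past one,
#' e.g. under a simple lag with all immature survivals equal to one), which
#' is what motivates the cycle-based class-wise condition instead.
#'
#' @param B Square matrix.
#' @return Scalar upper bound on `rho(B)`.
#' @export
gersgorin_bound <- function(B) {
  B <- unclass(B)
  if (!is.matrix(B) || nrow(B) != ncol(B)) stop("`B` must be a square matrix")
  max(rowSums(abs(B)))
}

# report ----------------------------------------------------------------------

#' Local stability report at an interior equilibrium
#'
#' One-stop assessment at (relative) abundances `x`: spectral radius of the
#' analytic Jacobian, three-way classification with a tolerance band
#' (`stable` iff `rho < 1 - tol`, `marginal` iff `|rho - 1| <= tol`),
#' asymptotic return time when stable, and the sufficient conditions
#' (diagonal dominance; class-wise bound) plus the Gershgorin diagnostic.
#'
#' @inheritParams jacobian_cdm
#' @param tol Classification tolerance around `rho = 1`.
#' @return An object of class `"cdm_stability"`.
#' @export
cdm_stability <- function(object, x, A = NULL, tol = 1e-9) {
  comm <- as_community(object, A = A)
  J <- jacobian_cdm(comm, x)
  rho <- spectral_radius(J)
  state <- if (rho < 1 - tol) "stable"
  else if (abs(rho - 1) <= tol) "marginal"
  else "unstable"
  structure(list(
    rho = rho, state = state, stable = state == "stable",
    return_time = if (rho < 1) return_time(rho) else NA_real_,
    gersgorin = gersgorin_bound(J),
    diagonal_dominance = check_diagonal_dominance(comm),
    sufficient = check_sufficient_stability(comm, x),
    x = as.numeric(x), tol = tol), class = "cdm_stability")
}

#' @export
print.cdm_stability <- function(x, ...) {
  cat(sprintf("CDM local stability at p = (%s)\n",
              paste(signif(x$x / sum(x$x), 4), collapse = ", ")))
  cat(sprintf("  spectral radius rho = %.6f -> %s\n", x$rho, x$state))
  if (!is.na(x$return_time))
    cat(sprintf("  asymptotic return time T_R = %.3f steps\n", x$return_time))
  cat(sprintf("  Gershgorin bound on rho: %.4f (diagnostic)\n", x$gersgorin))
  cat(sprintf("  diagonal dominance (delay-free sufficient condition): %s\n",
              x$diagonal_dominance$overall))
  cat(sprintf("  class-wise sufficient condition: %s (weakly irreducible: %s)\n",
              x$sufficient$overall, x$sufficient$weakly_irreducible))
  invisible(x)
}
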