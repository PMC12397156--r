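#' Life-history parameters for one species
#'
#' Bundles the stage-structured life history of a single species in a
#' discrete-time (typically daily) model: the maturation delay, per-step
#' survival probabilities of the immature age classes, the adult per-step
#' survival probability, and the density-independent fecundity.
#'
#' Two derived quantities are attached: the adult per-step mortality
#' probability `z = 1 - sigma_adult`, and the density-independent rate of
#' adult recruitment `lambda_tilde = fecundity * prod(sigma_immature)`, the
#' fecundity discounted by survival through the whole immature phase. When
#' `delta = 0` the product is empty and `lambda_tilde == fecundity`.
#'
#' @param delta Non-negative integer maturation delay (number of immature
#'   age classes; `0` means recruits are adult immediately).
#' @param sigma_immature Numeric vector of length `delta` of per-step
#'   survival probabilities for ages `0..delta-1`, each in `(0, 1]`.
#' @param sigma_adult Adult per-step survival probability, in `(0, 1)`.
#' @param fecundity Per-adult production of new recruits per time step,
#'   positive.
#'
#' @return An object of class `"species_life_history"`: a list with the four
#'   arguments plus `z` and `lambda_tilde`.
#' @examples
#' sp <- species_life_history(delta = 10, sigma_immature = rep(1, 10),
#'                            sigma_adult = 0.875, fecundity = 4.5)
#' sp$z            # 0.125
#' sp$lambda_tilde # 4.5
#' @export
species_life_history <- function(delta, sigma_immature = rep(1, delta),
                                 sigma_adult, fecundity) {
  if (length(delta) != 1L || is.na(delta) || delta < 0 || delta != round(delta))
    stop("`delta` must be a single non-negative integer")
  delta <- as.integer(delta)
  sigma_immature <- as.numeric(sigma_immature)
  if (length(sigma_immature) != delta)
    stop(sprintf("`sigma_immature` must have length delta = %d, got %d",
                 delta, length(sigma_immature)))
  if (delta > 0L && (any(sigma_immature <= 0) || any(sigma_immature > 1)))
    stop("immature survival probabilities must lie in (0, 1]")
  if (length(sigma_adult) != 1L || sigma_adult <= 0 || sigma_adult >= 1)
    stop("`sigma_adult` must lie in (0, 1)")
  if (length(fecundity) != 1L || fecundity <= 0)
    stop("`fecundity` must be a positive scalar")
  structure(
    list(delta = delta,
         sigma_immature = sigma_immature,
         sigma_adult = as.numeric(sigma_adult),
         fecundity = as.numeric(fecundity),
         z = 1 - as.numeric(sigma_adult),
         lambda_tilde = as.numeric(fecundity) * prod(sigma_immature)),
    class = "species_life_history")
}

#' @export
print.species_life_history <- function(x, ...) {
  cat(sprintf(
    "Species life history: delta = %d, sigma_adult = %g (z = %g),\n  fecundity = %g, adult recruitment rate lambda_tilde = %g\n",
    x$delta, x$sigma_adult, x$z, x$fecundity, x$lambda_tilde))
  invisible(x)
}

#' Multispecies community under competitive density dependence
#'
#' A community couples `m` species' life histories through an `m x m`
#' competition matrix `A` (non-negative, strictly positive diagonal):
#' `A[i, j]` is the per-capita competitive pressure of species `j` on the
#' recruitment of species `i`, relative to the intraspecific pressure
#' `A[i, i]`. The optional positive vector `q` scales the overall strength of
#' density dependence per species (larger `q` means weaker density
#' dependence and a proportionally larger equilibrium). Per-capita
#' recruitment is Beverton-Holt/Leslie-Gower:
#' `G_i(x) = lambda_i / (1 + (1/q_i) * sum_k A[i,k] x_k)`.
#'
#' `q` is optional because the stability analysis of interior equilibria
#' does not need it (see [jacobian_cdm()]); simulation and equilibrium
#' computation do ([interior_equilibrium()], [simulate.cdm_community()]),
#' and it can be recovered from an observed equilibrium with [solve_q()].
#'
#' @param species List of [species_life_history()] objects (length `m >= 1`).
#' @param A `m x m` numeric competition matrix, `A >= 0` elementwise with
#'   `diag(A) > 0`.
#' @param q Optional positive numeric vector of length `m`.
#' @return An object of class `"cdm_community"`.
#' @examples
#' sp <- species_life_history(0, numeric(0), sigma_adult = 0.5, fecundity = 2)
#' comm <- cdm_community(list(sp), A = matrix(1), q = 1)
#' interior_equilibrium(comm)$x_star # 3
#' @export
cdm_community <- function(species, A, q = NULL) {
  if (inherits(species, "species_life_history")) species <- list(species)
  if (!is.list(species) || length(species) < 1L ||
      !all(vapply(species, inherits, logical(1), "species_life_history")))
    stop("`species` must be a non-empty list of species_life_history objects")
  m <- length(species)
  A <- as.matrix(A)
  if (!is.numeric(A) || nrow(A) != m || ncol(A) != m)
    stop(sprintf("`A` must be a numeric %d x %d matrix", m, m))
  if (any(A < 0)) stop("`A` must be non-negative elementwise")
  if (any(diag(A) <= 0)) stop("diag(A) must be strictly positive")
  if (!is.null(q)) {
    q <- as.numeric(q)
    if (length(q) == 1L) q <- rep(q, m)
    if (length(q) != m || any(q <= 0))
      stop("`q` must be a positive vector of length m")
  }
  structure(list(species = species, A = A, q = q, m = m),
            class = "cdm_community")
}

#' @export
print.cdm_community <- function(x, ...) {
  cat(sprintf("CDM community of %d species (state dimension %d)\n",
              x$m, x$m + sum(community_delta(x))))
  cat(sprintf("  delta: %s | z: %s | lambda_tilde: %s\n",
              paste(community_delta(x), collapse = ", "),
              paste(signif(community_z(x), 4), collapse = ", "),
              paste(signif(community_lambda_tilde(x), 4), collapse = ", ")))
  cat(sprintf("  q: %s\n",
              if (is.null(x$q)) "<unset>" else paste(signif(x$q, 4), collapse = ", ")))
  cat("  A:\n")
  print(unname(x$A))
  invisible(x)
}

#' @export
summary.cdm_community <- function(object, ...) {
  res <- list(
    m = object$m,
    delta = community_delta(object),
    z = community_z(object),
    lambda = community_lambda(object),
    lambda_tilde = community_lambda_tilde(object),
    A = object$A,
    q = object$q,
    diagonally_dominant = check_diagonal_dominance(object$A)$overall,
    growth_feasible = all(community_lambda_tilde(object) > community_z(object)))
  class(res) <- "summary.cdm_community"
  res
}

#' @export
print.summary.cdm_community <- function(x, ...) {
  cat(sprintf("CDM community summary (m = %d)\n", x$m))
  print(data.frame(delta = x$delta, fecundity = x$lambda,
                   lambda_tilde = x$lambda_tilde, z = x$z,
                   row.names = paste0("species_", seq_len(x$m))))
  cat(sprintf("  lambda_tilde > z for all species: %s\n", x$growth_feasible))
  cat(sprintf("  A strictly row diagonally dominant: %s\n", x$diagonally_dominant))
  invisible(x)
}

# per-community parameter accessors -----------------------------------------

#' Community-level parameter vectors
#'
#' Convenience accessors returning per-species vectors: maturation delays,
#' adult mortality `z`, fecundity `lambda`, adult recruitment `lambda_tilde`,
#' and the product of immature survival probabilities.
#'
#' @param community A [cdm_community()] object.
#' @return Numeric (or integer) vector of length `m`.
#' @name community-accessors
NULL

#' @rdname community-accessors
#' @export
community_delta <- function(community)
  unname(vapply(community$species, `[[`, integer(1), "delta"))

#' @rdname community-accessors
#' @export
community_z <- function(community)
  unname(vapply(community$species, `[[`, numeric(1), "z"))

#' @rdname community-accessors
#' @export
community_lambda <- function(community)
  unname(vapply(community$species, `[[`, numeric(1), "fecundity"))

#' @rdname community-accessors
#' @export
community_lambda_tilde <- function(community)
  unname(vapply(community$species, `[[`, numeric(1), "lambda_tilde"))

#' @rdname community-accessors
#' @export
community_survival_product <- function(community)
  unname(vapply(community$species, function(s) prod(s$sigma_immature), numeric(1)))

# state ordering contract ----------------------------------------------------
# Every expanded-state vector and Jacobian in the package uses species-major
# blocks in community order; within a block ages ascend 0..delta_i, so the
# adult class is the last entry of each block.

#' Index layout of the expanded (age-structured) state
#'
#' The expanded state stacks, species by species in community order, the
#' abundances of all age classes of each species, ages ascending so that the
#' adult class is last in each block. `state_blocks()` returns the index
#' ranges of the blocks; `adult_indices()` the positions of the adult
#' classes within the full state vector.
#'
#' @param community A [cdm_community()] object.
#' @return For `state_blocks()`, a list of integer vectors (one per species);
#'   for `adult_indices()`, an integer vector of length `m`.
#' @export
state_blocks <- function(community) {
  delta <- community_delta(community)
  ends <- cumsum(delta + 1L)
  starts <- c(1L, ends[-length(ends)] + 1L)
  mapply(seq.int, starts, ends, SIMPLIFY = FALSE)
}

#' @rdname state_blocks
#' @export
adult_indices <- function(community) {
  vapply(state_blocks(community), function(ix) ix[length(ix)], integer(1))
}

#' Validate an expanded state vector
#'
#' @param community A [cdm_community()] object.
#' @param y Numeric vector of all age-class abundances in the package's
#'   ordering contract (length `m + sum(delta)`), non-negative.
#' @return `y`, invisibly, after validation.
#' @export
validate_expanded_state <- function(community, y) {
  n <- community$m + sum(community_delta(community))
  if (!is.numeric(y) || length(y) != n)
    stop(sprintf("expanded state must be numeric of length %d, got %d",
                 n, length(y)))
  if (any(y < 0)) stop("expanded state must be non-negative")
  invisible(y)
}

require_q <- function(community, what = "this operation") {
  if (is.null(community$q))
    stop(sprintf("q required: %s needs the intraspecific scaling vector `q`; supply it in cdm_community() or recover it with solve_q()", what))
  community$q
}
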