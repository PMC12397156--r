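# Configuration and tabular I/O. Community configs are YAML (JSON-compatible);
# trajectories, rho surfaces and matrices travel as CSV.

community_schema <- list(
  top = c("species", "A", "q"),
  species = c("delta", "sigma_immature", "sigma_adult", "fecundity"))

#' Read and write community configuration files
#'
#' A community config is a YAML (or JSON — YAML 1.2 is a superset) mapping
#' with keys `species` (a list of mappings with keys `delta`,
#' `sigma_immature`, `sigma_adult`, `fecundity`), `A` (row-major list of
#' rows) and optionally `q`. Validation is strict: unknown keys are
#' rejected, and parameter errors name the offending species and field.
#' `write_community()` followed by `read_community()` reproduces the
#' community exactly.
#'
#' @param path File path.
#' @param community A [cdm_community()] object.
#' @return `read_community()`: a [cdm_community()]. `write_community()`:
#'   `path`, invisibly.
#' @export
read_community <- function(path) {
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop(sprintf(
                    "failed to parse %s: %s", path, conditionMessage(e))))
  if (!is.list(cfg)) stop(sprintf("%s: top level must be a mapping", path))
  unknown <- setdiff(names(cfg), community_schema$top)
  if (length(unknown))
    stop(sprintf("%s: unknown top-level key(s): %s", path,
                 paste(unknown, collapse = ", ")))
  if (is.null(cfg$species) || !is.list(cfg$species) || !length(cfg$species))
    stop(sprintf("%s: `species` must be a non-empty list", path))
  species <- lapply(seq_along(cfg$species), function(i) {
    s <- cfg$species[[i]]
    if (!is.list(s)) stop(sprintf("%s: species[%d] must be a mapping", path, i))
    unknown <- setdiff(names(s), community_schema$species)
    if (length(unknown))
      stop(sprintf("%s: species[%d]: unknown key(s): %s", path, i,
                   paste(unknown, collapse = ", ")))
    for (key in c("delta", "sigma_adult", "fecundity"))
      if (is.null(s[[key]]))
        stop(sprintf("%s: species[%d]: missing required key `%s`", path, i, key))
    tryCatch(
      species_life_history(s$delta,
                           if (is.null(s$sigma_immature)) rep(1, s$delta)
                           else unlist(s$sigma_immature),
                           s$sigma_adult, s$fecundity),
      error = function(e) stop(sprintf("%s: species[%d]: %s", path, i,
                                       conditionMessage(e))))
  })
  m <- length(species)
  if (is.null(cfg$A)) stop(sprintf("%s: missing required key `A`", path))
  A <- tryCatch(matrix(unlist(cfg$A), nrow = m, byrow = TRUE),
                error = function(e) stop(sprintf("%s: `A` is not rectangular", path)))
  if (length(unlist(cfg$A)) != m * m)
    stop(sprintf("%s: `A` must be %d x %d (row-major)", path, m, m))
  q <- if (is.null(cfg$q)) NULL else unlist(cfg$q)
  tryCatch(cdm_community(species, A, q = q),
           error = function(e) stop(sprintf("%s: %s", path, conditionMessage(e))))
}

#' @rdname read_community
#' @export
write_community <- function(community, path) {
  if (!inherits(community, "cdm_community")) stop("not a cdm_community")
  cfg <- list(
    species = lapply(community$species, function(s)
      list(delta = s$delta, sigma_immature = as.list(s$sigma_immature),
           sigma_adult = s$sigma_adult, fecundity = s$fecundity)),
    A = apply(community$A, 1L, as.list, simplify = FALSE))
  if (!is.null(community$q)) cfg$q <- as.list(community$q)
  yaml::write_yaml(cfg, path, precision = 17L)
  invisible(path)
}

#' Trajectory and matrix CSV output
#'
#' `write_trajectory()` writes a [simulate.cdm_community()] result as CSV
#' with header `time, species_1..species_m` (adult abundances); with
#' `expanded = TRUE` and a trajectory carrying expanded states, a wide CSV
#' with columns `species_i.age_a` is written instead. `read_resource_table()`
#' reads a species-by-resource CSV of utilisation proportions (first column
#' = species label) for [pianka_overlap()].
#'
#' @param trajectory A `"cdm_trajectory"`.
#' @param path Output path.
#' @param expanded Write all age classes instead of adults.
#' @param community Community (needed to label age-class columns).
#' @return The path, invisibly (writers); a numeric matrix (reader).
#' @export
write_trajectory <- function(trajectory, path, expanded = FALSE,
                             community = NULL) {
  if (!inherits(trajectory, "cdm_trajectory")) stop("not a cdm_trajectory")
  if (expanded) {
    if (is.null(trajectory$expanded))
      stop("trajectory does not carry expanded states (simulate with keep_expanded = TRUE)")
    if (is.null(community)) stop("`community` is required to label age classes")
    labs <- unlist(lapply(seq_len(community$m), function(i)
      paste0("species_", i, ".age_", 0:community_delta(community)[i])))
    df <- data.frame(time = trajectory$time, trajectory$expanded)
    names(df) <- c("time", labs)
  } else {
    df <- as.data.frame(trajectory)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_resource_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L) stop(sprintf("%s: expected species label column plus resources", path))
  first_numeric <- is.numeric(df[[1L]])
  P <- as.matrix(df[, if (first_numeric) seq_len(ncol(df)) else -1L, drop = FALSE])
  if (!first_numeric) rownames(P) <- as.character(df[[1L]])
  if (!is.numeric(P)) stop(sprintf("%s: resource columns must be numeric", path))
  P
}

#' @rdname write_trajectory
#' @param surface A `"rho_surface"`.
#' @export
write_rho_surface <- function(surface, path) {
  utils::write.csv(as.data.frame(surface), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
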