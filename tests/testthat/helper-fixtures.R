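# Shared fixtures. Phantom cases are cached per (seed, scale) so several
# test files can reuse them without regenerating.

.case_cache <- new.env(parent = emptyenv())

# full-resolution phantom (the generator's default study conditions)
default_case <- function(seed = 7) {
  key <- paste0("full", seed)
  if (is.null(.case_cache[[key]]))
    .case_cache[[key]] <- make_case(phantom_spec(rng_seed = seed))
  .case_cache[[key]]
}

# reduced-resolution phantom spec used for registration-heavy tests
small_spec <- function(seed = 1, ...) {
  phantom_spec(fixed_dim = c(32, 32, 20), fixed_spacing = c(2.74, 2.74, 5.4),
               moving_dim = c(44, 44, 24), moving_spacing = c(2, 2, 4.6),
               rng_seed = seed, ...)
}

small_case <- function(seed = 1) {
  key <- paste0("small", seed)
  if (is.null(.case_cache[[key]]))
    .case_cache[[key]] <- make_case(small_spec(seed))
  .case_cache[[key]]
}

# registration settings sized for the reduced-resolution phantoms
small_config <- function(...) {
  registration_config(pyramid_levels = 2, max_iters = 40,
                      outer_iterations = 2, control_spacing_mm = 35,
                      n_surface_points = 250, ...)
}

# random blocky structure mask on a small grid (for metric oracle tests)
random_mask <- function(dim = c(8, 9, 7), spacing = c(1, 1.5, 2),
                        p = 0.4) {
  labs <- array(as.integer(runif(prod(dim)) < p), dim)
  if (!any(labs == 1L)) labs[ceiling(dim[1] / 2), 1, 1] <- 1L
  structure_mask(labs, grid_geometry(dim, spacing), c(structure = 1L))
}

# brute-force directed mean surface distance (all-pairs oracle)
oracle_mda <- function(b, a) {
  sb <- surface_points(b)
  sa <- surface_points(a)
  mean(apply(sb, 1, function(p)
    sqrt(min(colSums((t(sa) - p)^2)))))
}

# brute-force DSC by explicit voxel counting
oracle_dice <- function(a, b) {
  A <- a$labels == 1L; B <- b$labels == 1L
  2 * sum(A & B) / (sum(A) + sum(B))
}

# exact Wilcoxon two-sided p by full enumeration of sign assignments
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  wp_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wp <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(wp <= wp_obs + 1e-9), mean(wp >= wp_obs - 1e-9)))
}
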