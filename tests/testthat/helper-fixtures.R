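# Shared fixtures, memoized across test files (helpers are sourced once per
# session). Everything is generated in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

default_partition <- function() {
  fixture("partition", function() {
    lm <- build_discoid_meniscus(knee_config())
    split_anterior_posterior(partition_rings(lm))
  })
}

default_study <- function() {
  fixture("study", function() {
    suppressMessages(run_study(study_config(), verbose = FALSE))
  })
}

# uniform-thickness circular disc wrapped as a solid region (generic
# partition path: carries no construction metadata)
flat_disc <- function(radius = 12, thickness = 3, rho_in = 0) {
  m <- annulus_mesh(c(0, 0), c(radius, radius), rho_in,
                    function(x, y) rep(0, length(x)),
                    function(x, y) rep(thickness, length(x)),
                    n_rho = 10L, n_theta = 48L, n_zeta = 2L,
                    region = "disc")
  solid_region(m, "disc")
}

# random rotation matrix (deterministic under the caller's seed)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9L), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# symmetric Voigt vector -> 3x3 matrix
voigt_to_mat <- function(s) {
  matrix(c(s[1L], s[6L], s[5L],
           s[6L], s[2L], s[4L],
           s[5L], s[4L], s[3L]), 3L)
}

mat_to_voigt <- function(M) c(M[1L, 1L], M[2L, 2L], M[3L, 3L],
                              M[2L, 3L], M[1L, 3L], M[1L, 2L])
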