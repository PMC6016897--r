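# The default (published) model instance: W = 20.211 mm, h = 14.20 mm,
# three cusps.
paper_cusp <- function() pv_cusp(20.211, 14.20, 3L)

# Random but valid cusp parameter sets for property-style tests.
random_cusps <- function(n, seed = 42L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    pv_cusp(width = runif(1, 5, 40),
            max_height = runif(1, 2, 25),
            n_cusps = sample(2:6, 1L))
  })
}

# Small random triangle mesh for I/O round-trip tests.
random_mesh <- function(n_faces = 10L, seed = 7L) {
  set.seed(seed)
  v <- matrix(runif(9L * n_faces, -10, 10), ncol = 3L)
  f <- matrix(sample(nrow(v), 3L * n_faces, replace = TRUE), ncol = 3L)
  ok <- f[, 1L] != f[, 2L] & f[, 2L] != f[, 3L] & f[, 1L] != f[, 3L]
  valve_mesh(v, f[ok, , drop = FALSE])
}

# Greatest nearest-neighbour distance from each point of `a` to the point
# set `b` (symmetrized Hausdorff-style check for point-set equality).
max_pointset_dist <- function(a, b) {
  one_way <- function(p, q) {
    max(vapply(seq_len(nrow(p)), function(i)
      min(sqrt(colSums((t(q) - p[i, ])^2))), numeric(1L)))
  }
  max(one_way(a, b), one_way(b, a))
}
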