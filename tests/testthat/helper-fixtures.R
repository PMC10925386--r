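# Shared in-code fixtures. All tests generate their data programmatically.

# small band set (7 sparse bands + the 1660 reference) for fast cube tests
tiny_wavenumbers <- function() c(1036, 1102, 1238, 1396, 1545, 1660, 1668, 1746)

# fast phantom: 48 x 48, 8 bands, small blobs
tiny_spec <- function(boundary_smoothness = 2.5, ...) {
  phantom_spec(rows = 48, cols = 48, wavenumbers = tiny_wavenumbers(),
               boundary_smoothness = boundary_smoothness, ...)
}

# deterministic random cube (not a phantom): smooth noise planes
random_cube <- function(nb = 3, rows = 40, cols = 40, seed = 1, dx = 0.5, dy = 0.5,
                        wavenumbers = seq(1000, by = 100, length.out = nb)) {
  set.seed(seed)
  hyper_cube(array(stats::rnorm(nb * rows * cols, mean = 0.5, sd = 0.1),
                   c(nb, rows, cols)),
             wavenumbers, dx, dy)
}

rel_err <- function(a, b) sqrt(sum((a - b)^2)) / max(sqrt(sum(b^2)), 1e-300)
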