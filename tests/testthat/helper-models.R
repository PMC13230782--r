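# Shared fixtures, all built in code.

# Two triangles joined by one bridge edge (3-4): modules A = {1,2,3},
# B = {4,5,6}; 7 edges of which 1 is inter.
toy_two_triangles <- function() {
  modular_network(
    rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6), c(3, 4)),
    labels = c(1, 1, 1, 2, 2, 2))
}

# Small-support symmetric two-community model for exact reference sums.
small_tl_model <- function(z_intra = 3, z_inter = 2) {
  tl_model(poisson_dist(z_intra, 1e-8), poisson_dist(z_inter, 1e-8))
}

# The workhorse study model: symmetric Poisson blocks, total mean degree 15.
study_model <- function(mu) tl_model_poisson(15, mu)

expect_monotone_increasing <- function(x, tol = 0) {
  expect_true(all(diff(x) >= -tol))
}
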