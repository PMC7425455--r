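# Shared fixtures: everything is generated in code at test time.

# desk-scale ground truth on a 16^3 grid (fast; used wherever full images
# are needed but the default 32^3 world would be slow)
small_truth <- function(seed = 101, ...) {
  ground_truth(group_sizes = c(CN = 20, EMCI = 15, LMCI = 13, AD = 12),
               grid_shape = c(16, 16, 16), seed = seed, ...)
}

# noise-free, confound-free world: exact linear construction checks
exact_truth <- function(seed = 7, beta_vrf_gmv = -0.05) {
  small_truth(seed = seed, beta_vrf_gmv = beta_vrf_gmv,
              noise_sd_image = 0, subject_sd_gmv = 0,
              group_atrophy = c(CN = 0, EMCI = 0, LMCI = 0, AD = 0))
}

# tiny deterministic volume for I/O tests
demo_volume <- function(dim3 = c(5, 4, 3), seed = 42) {
  set.seed(seed)
  volume_image(array(round(rnorm(prod(dim3)), 4), dim = dim3),
               voxel_size = c(2, 2, 2), origin = c(-10, -8, -6), id = "demo")
}

# independent per-voxel OLS oracle: plain normal equations, one voxel at a
# time (never uses the package's fitting path)
ols_oracle <- function(X, y) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  se <- unname(sqrt(as.numeric(t(res) %*% res) / df * diag(xtx_inv)))
  list(beta = as.numeric(beta), se = se, t = as.numeric(beta) / se, df = df)
}
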