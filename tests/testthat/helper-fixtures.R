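# Shared fixtures: everything is generated in code at test time.

# small grid keeps CNN unit tests fast
tiny_grid <- function(n = 120L) wavenumber_grid(400, 2000, n)

noiseless_cfg <- function(background_scale = 0.1)
  noise_config(noise_sd = 0, max_shift = 0L,
               background_scale = background_scale)

# a quick two-block architecture for small-input training tests
tiny_arch <- function(head = "classifier")
  cnn_architecture(list(c(4, 5, 2), c(8, 5, 2)), dense_units = 16L,
                   dropout = 0, head = head)

random_spectrum <- function(grid = wavenumber_grid(), seed = 1) {
  set.seed(seed)
  spectrum_1d(abs(stats::rnorm(grid$n_points)) + 0.1, grid, "random")
}

# brute-force geometric-mean threshold search over every achievable call set
brute_force_gm <- function(scores, truth) {
  u <- sort(unique(scores))
  cand <- c(u - 1e-9, u + 1e-9)
  npos <- sum(truth == 1); nneg <- sum(truth == 0)
  best <- -1
  for (thr in cand) {
    call <- scores >= thr
    gm <- sqrt(sum(call & truth == 1) / npos * sum(!call & truth == 0) / nneg)
    if (gm > best) best <- gm
  }
  best
}
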