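# Shared fixtures: the synthetic ground-truth world used across the suite.
# Everything is generated in code; nothing is read from disk.

default_chip <- function() ground_truth_chip(66.4, 46, 7.5, 1.40)

# cached noiseless calibration of the default chip (used by several files)
noiseless_cal <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_calibration(default_chip(), sigma = 0)
    cache
  }
})

# independent analytic three-layer (prism/metal/buffer) reflection
# coefficient, coded directly from the textbook single-film formula
three_layer_r <- function(n1, n2, n3, d_nm, lambda_nm, theta_deg, pol = "p") {
  th <- theta_deg * pi / 180
  k0 <- 2 * pi / lambda_nm
  beta <- n1 * sin(th)
  kz <- lapply(c(n1, n2, n3), function(n) {
    kz <- k0 * sqrt(n^2 - beta^2 + 0i)
    if (Im(kz) < 0 || (Im(kz) == 0 && Re(kz) < 0)) -kz else kz
  })
  q <- lapply(1:3, function(i) {
    n <- c(n1, n2, n3)[i]
    if (pol == "p") kz[[i]] / (k0 * n^2) else kz[[i]] / k0
  })
  r12 <- (q[[1]] - q[[2]]) / (q[[1]] + q[[2]])
  r23 <- (q[[2]] - q[[3]]) / (q[[2]] + q[[3]])
  ph <- exp(2i * kz[[2]] * d_nm)
  (r12 + r23 * ph) / (1 + r12 * r23 * ph)
}

# random passive stack generator for property sweeps
random_stack <- function() {
  n_internal <- sample(1:4, 1)
  layers <- list(optical_layer("in", runif(1, 1.3, 2.0), Inf))
  for (j in seq_len(n_internal)) {
    n <- complex(real = runif(1, 0.1, 4), imaginary = runif(1, 0, 5))
    layers[[length(layers) + 1]] <- optical_layer(paste0("L", j), n, runif(1, 0, 100))
  }
  layers[[length(layers) + 1]] <- optical_layer("out", runif(1, 1.0, 1.6), Inf)
  optical_stack(layers, wavelength_nm = runif(1, 400, 1600))
}
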