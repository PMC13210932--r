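# Shared small fixtures, built in code at load time.

tiny_fixture_config <- function(seed = 7L, noise_sd = 0.05) {
  fixture_config(K = 3L, n_sequences_per_class = c(5L, 3L, 2L),
                 length_range = c(140L, 200L), Ds = 6L,
                 noise_sd = noise_sd, seed = seed)
}

tiny_segments <- function(seed = 7L, Ts = 32L) {
  segment_sequences(generate_toy_dataset(tiny_fixture_config(seed)), Ts = Ts)
}

# hand-built two-class physical segments with known extrema
handmade_segments <- function() {
  cn <- c(sensor_channel_names(3L), moment_channel_names(), "body_weight")
  mk <- function(vals, class, w) {
    m <- cbind(vals, hip = vals[, 1] * 0.5, knee = vals[, 2] * 0.5, w)
    colnames(m) <- cn
    new_segment(m, class, space = "physical")
  }
  list(mk(matrix(c(2, 3, 4, 0, 1, 2, -1, 0, 1), 3), 1L, 70),
       mk(matrix(c(10, 11, 12, 5, 6, 7, 2, 3, 4), 3), 2L, 80))
}

# finite-difference gradient comparison for a scalar loss over named params
check_gradients <- function(model, lossf, grads, n_per_param = 2L,
                            h = 1e-5, seed = 1L) {
  worst <- 0
  set.seed(seed)
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    for (i in sample(length(p), min(n_per_param, length(p)))) {
      m2 <- model; m2$params[[nm]][i] <- p[i] + h
      m3 <- model; m3$params[[nm]][i] <- p[i] - h
      num <- (lossf(m2) - lossf(m3)) / (2 * h)
      ana <- grads[[nm]][i]
      # floor the denominator: exactly-zero gradients (e.g. key biases under
      # softmax shift invariance) only see finite-difference noise
      worst <- max(worst, abs(num - ana) / max(1e-5, abs(num) + abs(ana)))
    }
  }
  worst
}
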