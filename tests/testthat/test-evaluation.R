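test_that("rho = 0 sweep point reproduces the no-augmentation baseline bit-for-bit", {
  segs <- tiny_segments(seed = 61L, Ts = 32L)
  test_segs <- tiny_segments(seed = 62L, Ts = 32L)
  stats <- fit_zscore_stats(segs, fit_minmax_stats(segs))
  cfg <- momentformer_config(Ds = 6L, Tc = 24L, C = 16L, L = 1L, heads = 2L,
                             ffn_mult = 2L, dropout = 0.1)
  sweep <- ratio_sweep(segs, test_segs, diffusion_model = NULL,
                       schedule = NULL, stats = stats, rho_values = 0,
                       seeds = c(3L, 4L), reg_cfg = cfg, epochs = 3L)
  base <- train_regressor(segs, stats, cfg, epochs = 3L, batch_size = 16L,
                          lr = 1e-3, seed = 3L)
  ev <- evaluate_regressor(base, test_segs, stats)
  mt <- compute_metrics(ev$predictions, ev$truths)
  got <- sweep[sweep$seed == 3 & sweep$class == "all", ]
  expect_identical(got$rmse, mt$rmse)
  expect_identical(got$r2, mt$r2)
  # shape: (classes + pooled) x joints rows per (rho, seed)
  expect_equal(nrow(sweep), 2 * (3 + 1) * 2)
  # rho > 0 without a checkpoint errors
  expect_error(ratio_sweep(segs, test_segs, NULL, NULL, stats,
                           rho_values = c(0, 1), seeds = 1L, reg_cfg = cfg),
               "checkpoint")
})

test_that("sensor ablation masks channels and favours informative modalities", {
  # moments depend only on the encoder channels by construction
  segs <- tiny_segments(seed = 71L, Ts = 32L)
  test_segs <- tiny_segments(seed = 72L, Ts = 32L)
  cfg <- momentformer_config(Ds = 6L, Tc = 24L, C = 16L, L = 1L, heads = 2L,
                             ffn_mult = 2L, dropout = 0)
  res <- sensor_ablation(segs, test_segs,
                         subsets = list(b = "encoder", a = "insole",
                                        g = c("insole", "encoder", "imu")),
                         seeds = 1L, reg_cfg = cfg, epochs = 12L,
                         lr = 2e-3)
  pooled <- res[res$class == "all", ]
  enc <- mean(pooled$rmse[pooled$subset == "b"])
  ins <- mean(pooled$rmse[pooled$subset == "a"])
  expect_lt(enc, ins)
  expect_error(sensor_ablation(segs, test_segs,
                               subsets = list(z = "barometer"),
                               seeds = 1L, reg_cfg = cfg), "no channels")
})

test_that("full-subset ablation reduces to the standard pipeline", {
  segs <- tiny_segments(seed = 81L, Ts = 32L)
  test_segs <- tiny_segments(seed = 82L, Ts = 32L)
  cfg <- momentformer_config(Ds = 6L, Tc = 24L, C = 16L, L = 1L, heads = 2L,
                             ffn_mult = 2L, dropout = 0.1)
  res <- sensor_ablation(segs, test_segs,
                         subsets = list(g = c("insole", "encoder", "imu")),
                         seeds = 5L, reg_cfg = cfg, epochs = 2L, lr = 1e-3)
  stats <- fit_zscore_stats(segs, fit_minmax_stats(segs))
  base <- train_regressor(segs, stats, cfg, epochs = 2L, batch_size = 16L,
                          lr = 1e-3, seed = 5L)
  ev <- evaluate_regressor(base, test_segs, stats)
  mt <- compute_metrics(ev$predictions, ev$truths)
  got <- res[res$class == "all", ]
  expect_equal(got$rmse, mt$rmse, tolerance = 1e-12)
})
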