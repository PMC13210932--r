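test_that("equal-split allocation reproduces the reference before/after counts", {
  before <- c(1729000, 420000, 344000)
  plan <- plan_allocation(before, rho = 2)
  expect_equal(plan$synthetic_counts, rep(1662000, 3))
  expect_equal(plan$after_counts, c(3391000, 2082000, 2006000))
  expect_equal(round(plan$percent_before, 1), c(69.4, 16.8, 13.8))
  expect_equal(round(plan$percent_after, 1), c(45.3, 27.8, 26.8))
  expect_equal(round(plan$imbalance_before, 2), 5.03)
  expect_equal(round(plan$imbalance_after, 2), 1.69)
})

test_that("allocation edge cases and conservation properties", {
  expect_equal(plan_allocation(c(10, 20), rho = 0)$synthetic_counts, c(0, 0))
  expect_equal(plan_allocation(c(10, 10), rho = 1)$synthetic_counts, c(10, 10))
  expect_error(plan_allocation(c(0, 0), rho = 2))
  expect_error(plan_allocation(c(-1, 5), rho = 2))
  # remainder goes to the largest classes
  p <- plan_allocation(c(5, 3, 2), rho = 1)   # 10 synthetic over 3 classes
  expect_equal(sum(p$synthetic_counts), 10)
  expect_equal(p$synthetic_counts, c(4, 3, 3))
  # conservation + imbalance strictly decreases for unequal counts, rho > 0
  set.seed(9)
  for (i in 1:20) {
    n <- sample(1:500, 4)
    rho <- stats::runif(1, 0.1, 3)
    p <- plan_allocation(n, rho)
    expect_equal(p$after_counts, n + p$synthetic_counts)
    expect_equal(sum(p$synthetic_counts), round(rho * sum(n)))
    if (max(n) > min(n)) expect_lt(p$imbalance_after, p$imbalance_before)
  }
  # per-class mode preserves proportions
  pc <- plan_allocation(c(100, 50), rho = 2, mode = "per_class")
  expect_equal(pc$synthetic_counts, c(200, 100))
})

test_that("augmented dataset conserves counts, provenance and class ranges", {
  segs <- tiny_segments(seed = 31L, Ts = 16L)
  stats <- fit_minmax_stats(segs)
  counts <- tabulate(vapply(segs, `[[`, integer(1), "class_label"), 3L)
  plan <- plan_allocation(counts, rho = 0.2)
  # a crude stub denoiser is enough for the structural contracts
  stub <- denoiser_fn(function(X, t, labels, B) 0.2 * X)
  sch <- reduced_schedule(20)
  aug <- build_augmented_dataset(segs, stub, sch, plan, stats,
                                 guidance_settings(s = 1), seed = 3L)
  expect_length(aug, length(segs) + sum(plan$synthetic_counts))
  prov <- vapply(aug, `[[`, character(1), "provenance")
  expect_equal(sum(prov == "synthetic"), sum(plan$synthetic_counts))
  D <- ncol(segs[[1]]$values)
  for (sg in aug[prov == "synthetic"]) {
    c <- sg$class_label
    expect_equal(sg$space, "physical")
    # clipping + per-class denormalization keep values inside fitted ranges
    for (d in seq_len(D - 1L))
      expect_true(all(sg$values[, d] >= stats$min[c, d] - 1e-9 &
                        sg$values[, d] <= stats$max[c, d] + 1e-9))
    # weight column constant over time
    expect_equal(stats::sd(sg$values[, D]), 0)
  }
})

test_that("oracle-driven synthetic class means match real means", {
  # two classes of near-Gaussian physical segments; the matched analytic
  # denoiser must reproduce per-class channel means (Table-4-style check)
  set.seed(77)
  Ts <- 8L; D <- 2L
  cn <- c("hip_angle", "body_weight")
  mk <- function(center, c) {
    v <- cbind(stats::rnorm(Ts, center, 1), 70)
    colnames(v) <- cn
    new_segment(v, c, space = "physical")
  }
  segs <- c(lapply(1:60, function(i) mk(10, 1L)),
            lapply(1:60, function(i) mk(-5, 2L)))
  st <- fit_minmax_stats(segs)
  norm <- lapply(segs, normalize_segment, stats = st)
  su_stats <- function(c) {
    m <- do.call(rbind, lapply(norm[vapply(norm, `[[`, integer(1),
                                           "class_label") == c],
                               `[[`, "values"))
    c(mean(m[, 1]), stats::sd(m[, 1]))
  }
  s1 <- su_stats(1L); s2 <- su_stats(2L)
  sch <- build_schedule(400, 1e-4, 0.05)
  orc <- oracle_gaussian_denoiser(c(s1[1], s2[1]), c(s1[2], s2[2]), sch)
  plan <- plan_allocation(c(60L, 60L), rho = 1)
  aug <- build_augmented_dataset(segs, orc, sch, plan, st,
                                 guidance_settings(s = 1), seed = 13L)
  syn <- aug[vapply(aug, `[[`, character(1), "provenance") == "synthetic"]
  for (c in 1:2) {
    real_mu <- mean(do.call(rbind, lapply(segs[vapply(segs, `[[`, integer(1),
                                                      "class_label") == c],
                                          `[[`, "values"))[, 1])
    sv <- do.call(rbind, lapply(syn[vapply(syn, `[[`, integer(1),
                                           "class_label") == c],
                                `[[`, "values"))[, 1]
    se <- stats::sd(sv) / sqrt(length(sv) / Ts)
    expect_lt(abs(mean(sv) - real_mu), 4 * se + 0.05 * abs(real_mu))
  }
})
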