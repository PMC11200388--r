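test_that("quantization maps the two amplitude bands to 1 and 2", {
  flat <- structure(list(sample_rate = 100, voltages = numeric(50),
                         true_steps = data.frame()), class = "optical_trace")
  expect_equal(quantize_trace(flat), integer(50))
  tr <- generate_optical_trace(40, 30)
  lab <- quantize_trace(tr)
  pk <- count_peaks(lab)
  expect_equal(pk$count, nrow(tr$true_steps))
  expect_equal(pk$sides, rep_len(c(1L, 2L), pk$count))
  # single high spike on a zero baseline
  spike <- flat
  spike$voltages[25] <- 3.0
  expect_equal(which(quantize_trace(spike) == 2L), 25L)
  # dead band [0.5, 1) quantizes to 0
  dead <- flat
  dead$voltages[10] <- 0.7
  expect_equal(quantize_trace(dead), integer(50))
  expect_error(quantize_trace(flat, low_cut = 1.5), "low_cut")
})

test_that("moving-mean filter removes spikes and keeps plateaus", {
  expect_equal(smooth_labels(c(0L, 1L, 0L), 3), c(0L, 0L, 0L))
  expect_equal(smooth_labels(c(1L, 1L, 1L), 3), c(0L, 1L, 0L))
  # a 3-sample peak survives window 3 with a shortened plateau
  x <- c(0L, 0L, 2L, 2L, 2L, 0L, 0L)
  expect_equal(smooth_labels(x, 3), c(0L, 0L, 0L, 2L, 0L, 0L, 0L))
  # an even window half-covered by 2s must not fabricate 1-labels
  y <- c(0L, 0L, 2L, 2L, 2L, 2L, 2L, 2L, 0L, 0L)
  expect_false(any(smooth_labels(y, 4) == 1L))
  expect_error(smooth_labels(x, 0), "positive")
  expect_equal(smooth_labels(x, 1), x)
})

test_that("moving-mean filter agrees with the direct window oracle", {
  set.seed(11)
  for (i in 1:25) {
    labels <- sample(0:2, 60, replace = TRUE, prob = c(0.7, 0.15, 0.15))
    w <- sample(3:8, 1)
    expect_equal(smooth_labels(labels, w), oracle_smooth(labels, w))
  }
})

test_that("peak counting and alternation correction", {
  expect_equal(count_peaks(c(0, 1, 1, 0, 2, 2, 0)),
               list(count = 2L, sides = c(1L, 2L)))
  expect_equal(count_peaks(integer(10))$count, 0)
  # adjacent value change splits peaks
  expect_equal(count_peaks(c(1, 1, 2, 2))$count, 2)
  expect_equal(enforce_alternation(c(1, 2, 1, 2))[c("kept_count", "repeats_removed")],
               list(kept_count = 4L, repeats_removed = 0L))
  expect_equal(enforce_alternation(c(1, 1, 2))[c("kept_count", "repeats_removed")],
               list(kept_count = 2L, repeats_removed = 1L))
  expect_equal(enforce_alternation(c(1, 1, 1, 2, 2))$sides_kept, c(1L, 2L))
  expect_equal(enforce_alternation(integer(0))$kept_count, 0L)
})

test_that("window-growing count converges to the generator truth", {
  tr <- generate_optical_trace(52, 60)
  gt <- converged_count(tr)
  expect_s3_class(gt, "ground_truth_count")
  expect_equal(gt$steps, nrow(tr$true_steps))
  expect_equal(gt$window_used, 3)
  expect_equal(gt$iterations, 1)
  expect_equal(gt$repeats_removed, 0)
})

test_that("spike-laden traces converge to the true count", {
  for (seed in 1:8) {
    cad <- 30 + (seed * 11) %% 81
    tr <- generate_optical_trace(cad, 60, noise = noise_spec(spike_rate = 10),
                                 seed = seed)
    expect_equal(converged_count(tr)$steps, nrow(tr$true_steps))
  }
})

test_that("pathological traces fail loudly at the window cap", {
  # peaks of strictly decreasing widths die one by one as the window grows,
  # so successive corrected counts never agree
  v <- numeric(3000)
  pos <- 50
  for (wd in 3:28) {
    v[pos:(pos + wd - 1)] <- if (wd %% 2) 1.5 else 2.5  # alternate sides
    pos <- pos + wd + 60
  }
  tr <- structure(list(sample_rate = 100, voltages = v,
                       true_steps = data.frame()), class = "optical_trace")
  expect_error(converged_count(tr, trial = "width ladder"),
               "did not converge.*width ladder")
})

test_that("signed error is the relative delta with missed steps negative", {
  expect_equal(compute_error(1000, 1000), 0)
  expect_equal(compute_error(900, 1000), -0.10)
  expect_equal(compute_error(1100, 1000), 0.10)
  expect_error(compute_error(5, 0), "> 0")
  # antisymmetric around the truth
  for (d in c(1, 17, 250))
    expect_equal(compute_error(1000 + d, 1000), -compute_error(1000 - d, 1000))
})

test_that("experiment bookkeeping expands settings by cadences", {
  sub <- subsample_settings(2, 4, 5)
  plan <- experiment_plan(sub)
  expect_equal(nrow(plan), 448)
  expect_equal(nrow(unique(plan[, 1:3])), 224)
  # vector form crosses every setting with every cadence
  p2 <- experiment_plan(sub[1:3, ], c(30, 70, 110))
  expect_equal(nrow(p2), 9)
  expect_error(experiment_plan(sub[0, ]), "non-empty")
  expect_error(experiment_plan(sub, matrix(30, nrow = 2, ncol = 2)),
               "one row per setting")
})

test_that("experiment runner is seeded and exact on clean perfect trials", {
  s <- sensor_settings(threshold_grid()[17], 6, 2480)
  clean <- run_experiment(s, cadences = 30, duration = 60,
                          noise = noise_spec(), seed = 3)
  expect_equal(clean$true_steps, 30L)
  expect_equal(clean$sensor_steps, 30L)
  expect_equal(clean$error_frac, 0)
  two <- rbind(s, sensor_settings(32, 1, 80))
  a <- run_experiment(two, cadences = c(35, 100), duration = 30, seed = 9)
  b <- run_experiment(two, cadences = c(35, 100), duration = 30, seed = 9)
  expect_identical(a, b)
  expect_equal(nrow(a), 4)
  expect_equal(a$seed, 9 + 2 * (1:4))
})
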