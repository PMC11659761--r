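test_that("noise-free planted down gene decreases strictly with age", {
  cfg <- sim_config(n_genes = 20, n_samples_per_tissue = 30,
                    tissues = c(t1 = "g1"), frac_down = 0.5, frac_up = 0,
                    slope_down = -0.05, noise_sd = 1e-9, seed = 2)
  sim <- simulate_aging_cohort(cfg)
  dirs <- sim$truth$direction
  down <- dirs$gene[dirs$direction == "down"][1]
  ord <- order(sim$samples$age)
  vals <- unclass(sim$expr$t1)[down, sim$samples$sample_id[ord]]
  expect_true(all(diff(vals) < 0))
})

test_that("zero effect fractions plant an all-null truth", {
  cfg <- sim_config(n_genes = 50, n_samples_per_tissue = 20,
                    tissues = c(t1 = "g1", t2 = "g1"),
                    frac_down = 0, frac_up = 0, seed = 3)
  sim <- simulate_aging_cohort(cfg)
  expect_true(all(sim$truth$direction$direction == "null"))
  expect_true(all(sim$truth$direction$slope == 0))
})

test_that("planted correlation matches the closed-form prediction", {
  # r = a / sqrt(a^2 + sigma^2) with a = slope * sd(age), age ~ U(40,69)
  cfg <- sim_config(n_genes = 2000, n_samples_per_tissue = 150,
                    tissues = c(t1 = "g1"), frac_down = 0.1, frac_up = 0,
                    slope_down = -0.04, noise_sd = 1.0, seed = 1)
  sim <- simulate_aging_cohort(cfg)
  age <- sim$samples$age
  calls <- suppressMessages(
    screen_tissue(sim$expr$t1, sim$samples, age_window = NULL))
  dirs <- sim$truth$direction
  down <- dirs$gene[dirs$direction == "down"]
  emp_r <- mean(calls$r[match(down, calls$gene)])
  a <- -0.04 * sd(age)
  theo_r <- a / sqrt(a^2 + 1.0^2)
  expect_lt(abs(emp_r - theo_r), 0.05)
})

test_that("identical seeds give bit-identical cohorts", {
  cfg <- sim_config(n_genes = 100, n_samples_per_tissue = 15, seed = 7)
  s1 <- simulate_aging_cohort(cfg)
  s2 <- simulate_aging_cohort(cfg)
  expect_identical(s1$expr, s2$expr)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$truth$direction, s2$truth$direction)
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(n_samples_per_tissue = 5), "config error")
  expect_error(sim_config(frac_down = 0.7, frac_up = 0.5), "config error")
  expect_error(sim_config(noise_sd = 0), "config error")
  expect_error(sim_config(age_range = c(69, 40)), "config error")
})

test_that("disease cohort plants same-sign shifts on syntropic genes only", {
  cfg <- sim_config(n_genes = 200, n_samples_per_tissue = 20,
                    tissues = c(t1 = "g1"), frac_down = 0.3, frac_up = 0.1,
                    seed = 4)
  sim <- simulate_aging_cohort(cfg)
  dis <- simulate_disease_cohort(sim$truth, group = "g1",
                                 frac_syntropic = 1, shift = 5,
                                 n_per_arm = 25, noise_sd = 0.3, seed = 5)
  expect_error(simulate_disease_cohort(sim$truth, frac_syntropic = 1.2),
               "config error")
  tr <- dis$truth$disease
  expect_true(all(tr$syntropic == (tr$aging_direction != "null")))
  case <- dis$samples$sample_id[dis$samples$condition == "case"]
  ctrl <- dis$samples$sample_id[dis$samples$condition == "control"]
  vals <- unclass(dis$expr)
  dmean <- rowMeans(vals[, case]) - rowMeans(vals[, ctrl])
  down <- tr$gene[tr$aging_direction == "down"]
  up <- tr$gene[tr$aging_direction == "up"]
  expect_true(all(dmean[down] < 0))
  expect_true(all(dmean[up] > 0))
  # arms share the same drawn ages (age-matched design)
  expect_identical(dis$samples$age[dis$samples$condition == "case"],
                   dis$samples$age[dis$samples$condition == "control"])
})

test_that("intervention cohort offsets rescued genes in the high arm only", {
  cfg <- sim_config(n_genes = 200, n_samples_per_tissue = 20,
                    tissues = c(t1 = "g1"), frac_down = 0.3, frac_up = 0,
                    seed = 6)
  sim <- simulate_aging_cohort(cfg)
  iv <- simulate_intervention_cohort(sim$truth, group = "g1",
                                     frac_rescued = 1, offset = 5,
                                     n_per_arm = 20, noise_sd = 0.3,
                                     seed = 7)
  arm <- stratify_activity(iv$samples)
  expect_equal(unname(table(arm)[c("high", "low", "moderate")]),
               rep(20L, 3), ignore_attr = TRUE)
  vals <- unclass(iv$expr)
  down <- iv$truth$rescue$gene
  hi_mean <- rowMeans(vals[down, names(arm)[arm == "high"]])
  lo_mean <- rowMeans(vals[down, names(arm)[arm == "low"]])
  expect_true(all(hi_mean - lo_mean > 2))
  mo_mean <- rowMeans(vals[down, names(arm)[arm == "moderate"]])
  expect_true(all(abs(mo_mean - lo_mean) < 2))
})

test_that("mixture simulation is an exact matrix product at zero noise", {
  sig <- matrix(c(10, 0, 2, 0, 8, 1), nrow = 3,
                dimnames = list(c("m1", "m2", "m3"),
                                c("neuron", "astro")))
  # unit fraction on neuron reproduces the neuron profile exactly
  f1 <- matrix(c(1, 0), 1, dimnames = list("a", colnames(sig)))
  mix <- simulate_mixture(sig, f1, noise_cv = 0)
  expect_equal(unclass(mix$expr)[, 1], sig[, "neuron"],
               ignore_attr = TRUE)
  # linearity: profiles of (0.6,0.4) and (0.4,0.6) differ by 0.2*(s1-s2)
  f2 <- rbind(a = c(0.6, 0.4), b = c(0.4, 0.6))
  colnames(f2) <- colnames(sig)
  mix2 <- simulate_mixture(sig, f2, noise_cv = 0)
  expect_equal(unclass(mix2$expr)[, "a"] - unclass(mix2$expr)[, "b"],
               0.2 * (sig[, 1] - sig[, 2]), ignore_attr = TRUE,
               tolerance = 1e-12)
  # fraction vectors must lie on the simplex
  expect_error(simulate_mixture(sig, rbind(c(0.6, 0.5))), "sum to 1")
  expect_error(simulate_mixture(sig, rbind(c(-0.2, 1.2))), "non-negative")
})
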