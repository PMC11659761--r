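test_that("control-mean normalization matches a hand computation", {
  vals <- matrix(c(1, 2, 3, 4, 5,
                   3, 4, 5, 6, 7,
                   2, 2, 2, 2, 2,
                   5, 6, 7, 8, 9), nrow = 5,
                 dimnames = list(paste0("G", 1:5), paste0("s", 1:4)))
  em <- expression_matrix(vals, scale = "log2")
  strata <- setNames(c("A", "A", "B", "B"), paste0("s", 1:4))
  out <- normalize_to_control_mean(em, control_ids = paste0("s", 1:4),
                                   strata = strata)
  # stratum A control mean = rowMeans(s1,s2); hand-computed shift
  expect_equal(unclass(out)[, "s1"],
               vals[, "s1"] - rowMeans(vals[, c("s1", "s2")]))
  expect_equal(unclass(out)[, "s3"],
               vals[, "s3"] - rowMeans(vals[, c("s3", "s4")]))
  # all-control strata end with log2 mean 0 for every gene
  expect_equal(max(abs(rowMeans(unclass(out)[, c("s1", "s2")]))), 0)
  # raw scale divides instead of shifting
  em_raw <- expression_matrix(vals + 1, scale = "raw")
  out_raw <- normalize_to_control_mean(em_raw, paste0("s", 1:4), strata)
  expect_equal(unclass(out_raw)[, "s1"],
               (vals[, "s1"] + 1) / rowMeans(vals[, c("s1", "s2")] + 1))
  expect_error(normalize_to_control_mean(em, c("s1"), strata),
               "stratum 'A'")
})

test_that("two-group contrast: exact fold changes and Welch p oracle", {
  em <- tiny_expr(10, 12)
  a <- colnames(em)[1:6]; b <- colnames(em)[7:12]
  d0 <- two_group_diff(
    expression_matrix(cbind(unclass(em)[, a],
                            `colnames<-`(unclass(em)[, a],
                                         paste0("x", 1:6))),
                      scale = "log2"), a, paste0("x", 1:6))
  expect_equal(d0$log2fc, rep(0, 10))
  # group_a = group_b + 1 gives log2FC exactly 1
  shifted <- unclass(em)[, b] + 1
  colnames(shifted) <- paste0("y", 1:6)
  d1 <- two_group_diff(expression_matrix(cbind(unclass(em)[, b], shifted),
                                         scale = "log2"),
                       paste0("y", 1:6), b)
  expect_equal(d1$log2fc, rep(1, 10))
  # per-gene agreement with stats::t.test (Welch)
  d <- two_group_diff(em, a, b)
  for (g in rownames(em)[1:5]) {
    ref <- t.test(unclass(em)[g, a], unclass(em)[g, b])
    expect_equal(d$p[d$gene == g], ref$p.value, tolerance = 1e-12)
  }
  expect_error(two_group_diff(em, a[1:2], b), ">= 3")
})

test_that("swapping groups negates log2FC and preserves p", {
  em <- tiny_expr(30, 14)
  a <- colnames(em)[1:7]; b <- colnames(em)[8:14]
  d_ab <- two_group_diff(em, a, b)
  d_ba <- two_group_diff(em, b, a)
  expect_equal(d_ab$log2fc, -d_ba$log2fc)
  expect_equal(d_ab$p, d_ba$p)
})

test_that("zero-variance genes are flagged, not silently dropped", {
  vals <- matrix(rnorm(40), 4, 10,
                 dimnames = list(paste0("G", 1:4),
                                 paste0("s", 1:10)))
  vals[2, ] <- 3  # flat in both groups
  em <- expression_matrix(vals, scale = "log2")
  d <- two_group_diff(em, paste0("s", 1:5), paste0("s", 6:10))
  expect_true(d$flagged[2])
  expect_true(is.na(d$p[2]))
  expect_false(any(d$flagged[-2]))
})

test_that("activity stratification encodes the documented boundaries", {
  st <- sample_table(data.frame(
    sample_id = c("a", "b", "c", "d", "e"),
    activity = c(2.2e5, 2.1e5, 0.5e5, 1.0e5, NA)))
  expect_message(arm <- stratify_activity(st), "excluded 1")
  expect_equal(unname(arm[c("a", "b", "c", "d")]),
               c("high", "moderate", "low", "low"))
  expect_false("e" %in% names(arm))
})

test_that("syntropy is 1 when every down-aging gene is strongly shifted", {
  cfg <- sim_config(n_genes = 300, n_samples_per_tissue = 40,
                    tissues = c(t1 = "g1"), frac_down = 0.2, frac_up = 0,
                    seed = 15)
  sim <- simulate_aging_cohort(cfg)
  dirs <- sim$truth$direction
  calls <- fake_calls(dirs$gene, ifelse(dirs$direction == "down",
                                        "down", "none"))
  dis <- simulate_disease_cohort(sim$truth, "g1", frac_syntropic = 1,
                                 shift = 4, n_per_arm = 30,
                                 noise_sd = 0.5, seed = 16)
  case <- dis$samples$sample_id[dis$samples$condition == "case"]
  ctrl <- dis$samples$sample_id[dis$samples$condition == "control"]
  diff <- two_group_diff(dis$expr, case, ctrl)
  rep <- syntropy(calls, diff, "down")
  expect_equal(rep$proportion, 1)
  expect_equal(rep$n_syntropic, rep$n_aging_detected)
})

test_that("syntropy and rescue ignore gene order and absent genes", {
  genes <- sprintf("G%02d", 1:30)
  calls <- fake_calls(genes, ifelse(genes %in% genes[1:10], "down",
                                    "none"))
  diff <- data.frame(gene = genes[3:25],
                     log2fc = rep(c(-2, 2), length.out = 23),
                     p = 0.001, n_a = 20, n_b = 20, flagged = FALSE,
                     stringsAsFactors = FALSE)
  class(diff) <- c("DiffTable", "data.frame")
  r1 <- syntropy(calls, diff, "down")
  r2 <- syntropy(calls, diff[sample(nrow(diff)), ], "down")
  expect_equal(r1$n_syntropic, r2$n_syntropic)
  expect_equal(r1$n_aging_detected, 8)  # G03..G10 present
  # absent genes removed from denominator (detection rule)
  diff2 <- diff[diff$gene %in% genes[5:25], ]
  class(diff2) <- c("DiffTable", "data.frame")
  expect_equal(syntropy(calls, diff2, "down")$n_aging_detected, 6)
  res1 <- rescue(calls, diff, "down")
  res2 <- rescue(calls, diff[rev(seq_len(nrow(diff))), ], "down")
  expect_equal(res1$n_rescued, res2$n_rescued)
})

test_that("rescue counts are monotone in fold_min and alpha", {
  set.seed(44)
  genes <- sprintf("G%03d", 1:200)
  calls <- fake_calls(genes, "down")
  diff <- data.frame(gene = genes,
                     log2fc = rnorm(200, 0.15, 0.2),
                     p = runif(200, 0, 0.2), n_a = 20, n_b = 20,
                     flagged = FALSE, stringsAsFactors = FALSE)
  class(diff) <- c("DiffTable", "data.frame")
  r10 <- rescue(calls, diff, "down", fold_min = 1.0)
  r11 <- rescue(calls, diff, "down", fold_min = 1.1)
  expect_lte(r11$n_rescued, r10$n_rescued)
  # exactly the genes with 1.0 < fold <= 1.1 drop out
  dropped <- setdiff(r10$genes, r11$genes)
  expect_true(all(diff$log2fc[match(dropped, diff$gene)] <= log2(1.1)))
  r_strict <- rescue(calls, diff, "down", alpha = 0.01)
  expect_lte(r_strict$n_rescued, r10$n_rescued)
  expect_error(rescue(calls, diff, "down", fold_min = 0.5), ">= 1")
})

test_that("rescue is 1 when all planted offsets are large", {
  cfg <- sim_config(n_genes = 300, n_samples_per_tissue = 40,
                    tissues = c(t1 = "g1"), frac_down = 0.2, frac_up = 0,
                    seed = 17)
  sim <- simulate_aging_cohort(cfg)
  dirs <- sim$truth$direction
  calls <- fake_calls(dirs$gene, ifelse(dirs$direction == "down",
                                        "down", "none"))
  iv <- simulate_intervention_cohort(sim$truth, "g1", frac_rescued = 1,
                                     offset = 4, n_per_arm = 25,
                                     noise_sd = 0.5, seed = 18)
  arm <- stratify_activity(iv$samples)
  diff <- two_group_diff(iv$expr, names(arm)[arm == "high"],
                         names(arm)[arm == "low"])
  rep <- rescue(calls, diff, "down")
  expect_equal(rep$proportion, 1)
})
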