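make_tables <- function(r_vectors, genes = NULL) {
  if (is.null(genes)) genes <- sprintf("G%04d", seq_len(nrow(r_vectors)))
  lapply(as.data.frame(r_vectors), function(r) {
    out <- data.frame(gene = genes, r = r, p = 0.5, n = 100L,
                      call = "none", stringsAsFactors = FALSE)
    class(out) <- c("AgingCallTable", "data.frame")
    out
  })
}

test_that("signature similarity is 1 for identical and -1 for negated", {
  set.seed(41)
  r <- rnorm(150, 0, 0.3)
  tabs <- make_tables(cbind(t1 = r, t2 = r, t3 = -r))
  sim <- tissue_signature_similarity(tabs, k = 2)
  expect_equal(sim$similarity["t1", "t2"], 1)
  expect_equal(sim$similarity["t1", "t3"], -1)
  expect_true(all(diag(sim$similarity) == 1))
  expect_equal(sim$similarity, t(sim$similarity))
})

test_that("too-small common gene sets are rejected", {
  set.seed(42)
  tabs <- make_tables(matrix(rnorm(2 * 50), ncol = 2,
                             dimnames = list(NULL, c("a", "b"))))
  expect_error(tissue_signature_similarity(tabs), "meaningless")
  expect_error(tissue_signature_similarity(tabs[1]), ">= 2 tissues")
})

test_that("clustering recovers 12 planted tissues in 4 groups exactly", {
  cfg <- sim_config(noise_sd = 0.5, seed = 13)
  sim <- simulate_aging_cohort(cfg)
  calls <- lapply(sim$expr, function(e)
    suppressMessages(screen_tissue(e, sim$samples)))
  ts <- tissue_signature_similarity(calls, k = 4)
  planted <- cfg$tissues[names(ts$groups)]
  ari <- mclust::adjustedRandIndex(planted, ts$groups)
  expect_equal(ari, 1)
  # fixed grouping override is honored verbatim
  fixed <- setNames(rep(c("A", "B"), 6), names(calls))
  ts2 <- tissue_signature_similarity(calls, groups = fixed)
  expect_identical(ts2$groups, fixed[names(calls)])
})

test_that("group intersection equals brute-force enumeration", {
  set.seed(43)
  genes <- sprintf("G%03d", 1:60)
  sets <- lapply(1:3, function(i) sample(genes, 30))
  tabs <- lapply(sets, function(s)
    fake_calls(genes, ifelse(genes %in% s, "down", "none")))
  names(tabs) <- c("t1", "t2", "t3")
  gi <- group_intersection(tabs, c(t1 = "g", t2 = "g", t3 = "g"), "down")
  expect_equal(gi$g$genes, sort(Reduce(intersect, sets)))
  # Venn region counts equal exhaustive membership enumeration
  membership <- sapply(sets, function(s) genes %in% s)
  for (region in names(gi$g$venn)) {
    members <- strsplit(region, "&", fixed = TRUE)[[1]]
    idx <- match(members, c("t1", "t2", "t3"))
    exact <- sum(apply(membership, 1, function(m)
      all(m[idx]) && !any(m[-idx])))
    expect_equal(unname(gi$g$venn[region]), exact)
  }
  # the full-overlap region is the intersection count
  expect_equal(unname(gi$g$venn["t1&t2&t3"]), length(gi$g$genes))
})

test_that("intersection handles identical and disjoint called sets", {
  genes <- sprintf("G%02d", 1:20)
  s <- genes[1:8]
  tabs <- replicate(3, fake_calls(genes, ifelse(genes %in% s, "down",
                                                "none")),
                    simplify = FALSE)
  names(tabs) <- paste0("t", 1:3)
  grp <- setNames(rep("g", 3), names(tabs))
  gi <- group_intersection(tabs, grp, "down")
  expect_equal(gi$g$genes, sort(s))
  # order independence and idempotence
  gi_rev <- group_intersection(tabs[3:1], grp, "down")
  expect_equal(gi_rev$g$genes, gi$g$genes)
  # disjoint sets: empty intersection, no error
  tabs2 <- list(t1 = fake_calls(genes, ifelse(genes %in% genes[1:5],
                                              "down", "none")),
                t2 = fake_calls(genes, ifelse(genes %in% genes[6:10],
                                              "down", "none")))
  gi2 <- group_intersection(tabs2, c(t1 = "g", t2 = "g"), "down")
  expect_length(gi2$g$genes, 0)
  expect_error(group_intersection(tabs, character(0), "down"), "empty")
})

test_that("cross-validation requires k_min tissues plus one confirmation", {
  genes <- sprintf("G%02d", 1:10)
  disc <- lapply(1:3, function(i)
    fake_calls(genes, ifelse(genes %in% genes[1:4], "down", "none")))
  names(disc) <- paste0("t", 1:3)
  val_yes <- fake_calls(genes, ifelse(genes %in% genes[1:2], "down",
                                      "none"))
  cv <- cross_validate(disc, list(val_yes), k_min = 3, "down")
  expect_equal(cv$candidates, genes[1:4])
  expect_equal(cv$validated, genes[1:2])
  # no validation support: candidate but not validated
  val_no <- fake_calls(genes, rep("none", 10))
  cv2 <- cross_validate(disc, list(val_no), k_min = 3, "down")
  expect_length(cv2$validated, 0)
  expect_error(cross_validate(disc, list(val_yes), k_min = 4, "down"),
               "exceeds")
})

test_that("validation on shared-truth cohorts retains planted genes", {
  cfg <- sim_config(n_genes = 800, n_samples_per_tissue = 120,
                    tissues = setNames(rep(c("g1", "g2"), each = 3),
                                       paste0("t", 1:6)),
                    frac_down = 0.15, frac_up = 0, seed = 14)
  sim <- simulate_aging_cohort(cfg)
  calls <- lapply(sim$expr, function(e)
    suppressMessages(screen_tissue(e, sim$samples)))
  vcfg <- cfg
  vcfg$tissues <- c(v1 = "g1", v2 = "g2")
  vcfg$seed <- 999L
  vsim <- simulate_aging_cohort(vcfg, truth = sim$truth)
  vcalls <- lapply(vsim$expr, function(e)
    suppressMessages(screen_tissue(e, vsim$samples, log_age = TRUE)))
  cv <- cross_validate(calls, vcalls, k_min = 3, "down")
  dirs <- sim$truth$direction
  true_g1 <- dirs$gene[dirs$group == "g1" & dirs$direction == "down"]
  true_any <- unique(dirs$gene[dirs$direction == "down"])
  # planted genes dominate the validated set and are mostly retained
  expect_gte(mean(cv$validated %in% true_any), 0.95)
  expect_gte(mean(true_g1 %in% cv$validated), 0.9)
})
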