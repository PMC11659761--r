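#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with its conventional
#' default: up-call p < 0.05 and down-call p < 0.01 on raw p-values,
#' cross-cohort support of >= 3 tissues for up genes and >= 6 for down
#' genes, contrast significance 0.05, minimum rescue fold 1.0 (1.1 for
#' cell-resolved contrasts), actigraphy cut-offs 1e5 and 2.1e5
#' counts/day, discovery age window 40-69 years, age split for fraction
#' comparisons at 60 years, four tissue groups and 50 markers per cell
#' type. The synthetic cohort layout is a \code{\link{sim_config}}.
#'
#' @param seed Integer master seed; every stage derives its stream from it.
#' @param sim A \code{\link{sim_config}} describing the synthetic cohorts
#'   (its own seed is overridden by \code{seed}).
#' @param stages Character vector of stages to run, in dependency order;
#'   a subset of \code{c("simulate","screen","group","validate",
#'   "syntropy","rescue","deconvolve","enrich")}.
#' @param alpha_up,alpha_down Screen thresholds.
#' @param k_min_up,k_min_down Cross-validation support thresholds.
#' @param alpha_diff Contrast significance threshold.
#' @param fold_min,fold_min_cell Minimum rescue folds (bulk, cell-level).
#' @param activity_cuts Actigraphy cut-offs (counts/day).
#' @param age_window Discovery age window (years).
#' @param age_split Age boundary for cell-fraction comparisons (years).
#' @param n_groups Number of tissue groups to cut the signature tree into.
#' @param markers_per_type Signature markers per cell type.
#' @param frac_syntropic,frac_rescued Planted effect fractions for the
#'   synthetic disease / intervention cohorts.
#' @param n_per_arm Samples per arm in the synthetic contrast cohorts.
#' @param shift,offset Planted disease shift / rescue offset (log2 units).
#' @return A validated list of class \code{PipelineConfig}.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_config(seed = seed),
                            stages = c("simulate", "screen", "group",
                                       "validate", "syntropy", "rescue",
                                       "deconvolve", "enrich"),
                            alpha_up = 0.05, alpha_down = 0.01,
                            k_min_up = 3, k_min_down = 6,
                            alpha_diff = 0.05,
                            fold_min = 1.0, fold_min_cell = 1.1,
                            activity_cuts = c(1e5, 2.1e5),
                            age_window = c(40, 69), age_split = 60,
                            n_groups = 4, markers_per_type = 50,
                            frac_syntropic = 0.40, frac_rescued = 0.40,
                            n_per_arm = 50, shift = 1.0, offset = 1.0) {
  all_stages <- c("simulate", "screen", "group", "validate", "syntropy",
                  "rescue", "deconvolve", "enrich")
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0)
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  for (v in c(alpha_up, alpha_down, alpha_diff))
    if (v <= 0 || v > 1) stop("alpha thresholds must be in (0,1]",
                              call. = FALSE)
  if (fold_min < 1 || fold_min_cell < 1)
    stop("fold thresholds must be >= 1", call. = FALSE)
  sim$seed <- as.integer(seed)
  structure(list(
    seed = as.integer(seed), sim = sim,
    stages = intersect(all_stages, stages),
    alpha_up = alpha_up, alpha_down = alpha_down,
    k_min_up = k_min_up, k_min_down = k_min_down,
    alpha_diff = alpha_diff, fold_min = fold_min,
    fold_min_cell = fold_min_cell, activity_cuts = activity_cuts,
    age_window = age_window, age_split = age_split,
    n_groups = n_groups, markers_per_type = markers_per_type,
    frac_syntropic = frac_syntropic, frac_rescued = frac_rescued,
    n_per_arm = n_per_arm, shift = shift, offset = offset),
    class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Every key of \code{\link{pipeline_config}} may appear in the file;
#' keys under \code{sim:} are passed to \code{\link{sim_config}}.
#'
#' @param path YAML file path.
#' @return A \code{PipelineConfig}.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  y <- yaml::read_yaml(path)
  sim_args <- y$sim
  y$sim <- NULL
  if (!is.null(sim_args) && !is.null(sim_args$tissues))
    sim_args$tissues <- unlist(sim_args$tissues)
  sim <- if (is.null(sim_args)) NULL else do.call(sim_config, sim_args)
  args <- y
  if (!is.null(sim)) args$sim <- sim
  do.call(pipeline_config, args)
}

stage_seed <- function(config, stage) {
  # distinct, reproducible stream per stage, kept within 32-bit range
  offsets <- c(simulate = 11L, validate = 23L, disease = 37L,
               intervention = 51L, scref = 67L, mixture = 83L)
  (config$seed * 97L + offsets[[stage]]) %% .Machine$integer.max
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic pipeline
#'
#' Executes the enabled stages in dependency order on synthetic cohorts
#' generated from the configured layout, writes every intermediate table
#' under \code{out_dir}, and emits a manifest recording the config hash,
#' seed, per-file checksums and row counts. Re-running with an identical
#' config and seed reproduces byte-identical outputs and manifest.
#'
#' Stage dependencies: screen needs simulate; group, validate, syntropy
#' and rescue need screen; enrich needs group; deconvolve is
#' self-contained (simulates its own reference and mixtures).
#'
#' @param config A \code{\link{pipeline_config}} (or path to a YAML file).
#' @param out_dir Output directory (created if absent).
#' @param quiet Suppress progress messages.
#' @return Invisibly, the manifest list (also written to
#'   \code{out_dir/manifest.json}); its \code{results} element carries the
#'   headline numbers (screen sensitivity, grouping agreement, syntropy
#'   and rescue estimates vs truth, deconvolution error).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stages <- config$stages
  need <- function(stage, dep) {
    if (stage %in% stages && !dep %in% stages)
      stop(sprintf("dependency error: stage '%s' requires stage '%s'",
                   stage, dep), call. = FALSE)
  }
  need("screen", "simulate")
  for (s in c("group", "validate", "syntropy", "rescue"))
    need(s, "screen")
  need("enrich", "group")

  files <- character(0)
  rows <- integer(0)
  results <- list()
  add_file <- function(path, n) {
    files <<- c(files, path)
    rows <<- c(rows, as.integer(n))
  }

  cohort <- NULL; calls <- NULL; sim_grp <- NULL

  if ("simulate" %in% stages) {
    say("stage simulate: %d genes x %d tissues", config$sim$n_genes,
        length(config$sim$tissues))
    cfg <- config$sim
    cfg$seed <- stage_seed(config, "simulate")
    cohort <- simulate_aging_cohort(cfg)
    add_file(write_tsv(as.data.frame(cohort$samples),
                       file.path(out_dir, "samples.tsv")),
             nrow(cohort$samples))
    add_file(write_tsv(cohort$truth$direction,
                       file.path(out_dir, "truth_direction.tsv")),
             nrow(cohort$truth$direction))
    for (tis in names(cohort$expr)) {
      p <- file.path(out_dir, sprintf("expr_%s.tsv", tis))
      write_expression(cohort$expr[[tis]], p)
      add_file(p, nrow(cohort$expr[[tis]]))
    }
  }

  if ("screen" %in% stages) {
    say("stage screen: %d tissues", length(cohort$expr))
    calls <- lapply(cohort$expr, function(e)
      suppressMessages(screen_tissue(
        e, cohort$samples, alpha_up = config$alpha_up,
        alpha_down = config$alpha_down, age_window = config$age_window)))
    for (tis in names(calls))
      add_file(write_tsv(as.data.frame(calls[[tis]]),
                         file.path(out_dir, sprintf("calls_%s.tsv", tis))),
               nrow(calls[[tis]]))
  }

  if ("group" %in% stages) {
    say("stage group: cutting signature tree at k=%d", config$n_groups)
    sim_grp <- tissue_signature_similarity(calls, k = config$n_groups)
    add_file(write_tsv(data.frame(tissue = rownames(sim_grp$similarity),
                                  round(sim_grp$similarity, 10),
                                  check.names = FALSE),
                       file.path(out_dir, "tissue_similarity.tsv")),
             nrow(sim_grp$similarity))
    add_file(write_tsv(data.frame(tissue = names(sim_grp$groups),
                                  group = unname(sim_grp$groups)),
                       file.path(out_dir, "tissue_groups.tsv")),
             length(sim_grp$groups))
    for (direction in c("down", "up")) {
      gi <- group_intersection(calls, sim_grp$groups, direction)
      df <- do.call(rbind, lapply(gi, function(g)
        data.frame(group = g$group, direction = g$direction,
                   n_genes = length(g$genes),
                   genes = paste(g$genes, collapse = ","),
                   stringsAsFactors = FALSE)))
      add_file(write_tsv(df, file.path(
        out_dir, sprintf("group_%s_genes.tsv", direction))), nrow(df))
      results[[paste0("group_", direction, "_counts")]] <-
        stats::setNames(vapply(gi, function(g) length(g$genes), 0L),
                        names(gi))
    }
    # agreement between recovered grouping and the planted tissue layout
    planted <- config$sim$tissues[names(sim_grp$groups)]
    results$grouping_agreement <-
      rand_index_adjusted(as.integer(factor(planted)),
                          as.integer(factor(sim_grp$groups)))
  }

  if ("validate" %in% stages) {
    say("stage validate")
    vcfg <- config$sim
    vcfg$tissues <- stats::setNames(
      unique(unname(config$sim$tissues))[1:2],
      c("validation_01", "validation_02"))
    vcfg$seed <- stage_seed(config, "validate")
    vcohort <- simulate_aging_cohort(vcfg, truth = cohort$truth)
    vcalls <- lapply(vcohort$expr, function(e)
      suppressMessages(screen_tissue(
        e, vcohort$samples, alpha_up = config$alpha_up,
        alpha_down = config$alpha_down, log_age = TRUE,
        age_window = config$age_window)))
    for (direction in c("down", "up")) {
      k_min <- if (direction == "down") config$k_min_down else config$k_min_up
      cv <- cross_validate(calls, vcalls, k_min = k_min, direction)
      df <- data.frame(gene = cv$candidates,
                       validated = cv$candidates %in% cv$validated,
                       stringsAsFactors = FALSE)
      add_file(write_tsv(df, file.path(
        out_dir, sprintf("validated_%s.tsv", direction))), nrow(df))
      results[[paste0("validated_", direction)]] <-
        c(candidates = cv$n_candidates, validated = cv$n_validated)
    }
  }

  if ("syntropy" %in% stages) {
    say("stage syntropy: planted fraction %.2f", config$frac_syntropic)
    dis <- simulate_disease_cohort(
      cohort$truth, group = cohort$truth$groups[1],
      frac_syntropic = config$frac_syntropic, shift = config$shift,
      n_per_arm = config$n_per_arm, noise_sd = config$sim$noise_sd,
      seed = stage_seed(config, "disease"))
    ids_case <- dis$samples$sample_id[dis$samples$condition == "case"]
    ids_ctrl <- dis$samples$sample_id[dis$samples$condition == "control"]
    diff <- two_group_diff(dis$expr, ids_case, ids_ctrl)
    add_file(write_tsv(as.data.frame(diff),
                       file.path(out_dir, "disease_diff.tsv")), nrow(diff))
    tis1 <- names(config$sim$tissues)[
      config$sim$tissues == cohort$truth$groups[1]][1]
    rep <- syntropy(calls[[tis1]], diff, "down", alpha = config$alpha_diff)
    add_file(write_tsv(data.frame(
      tissue = tis1, direction = rep$direction,
      n_aging_detected = rep$n_aging_detected,
      n_syntropic = rep$n_syntropic, proportion = rep$proportion),
      file.path(out_dir, "syntropy_report.tsv")), 1)
    results$syntropy <- c(estimated = rep$proportion,
                          planted = config$frac_syntropic)
  }

  if ("rescue" %in% stages) {
    say("stage rescue: planted fraction %.2f", config$frac_rescued)
    iv <- simulate_intervention_cohort(
      cohort$truth, group = cohort$truth$groups[1],
      frac_rescued = config$frac_rescued, offset = config$offset,
      n_per_arm = config$n_per_arm, noise_sd = config$sim$noise_sd,
      activity_cuts = config$activity_cuts,
      seed = stage_seed(config, "intervention"))
    arm <- suppressMessages(stratify_activity(iv$samples))
    diff <- two_group_diff(iv$expr, names(arm)[arm == "high"],
                           names(arm)[arm == "low"])
    add_file(write_tsv(as.data.frame(diff),
                       file.path(out_dir, "intervention_diff.tsv")),
             nrow(diff))
    tis1 <- names(config$sim$tissues)[
      config$sim$tissues == cohort$truth$groups[1]][1]
    rep <- rescue(calls[[tis1]], diff, "down", alpha = config$alpha_diff,
                  fold_min = config$fold_min)
    add_file(write_tsv(data.frame(
      tissue = tis1, direction = rep$direction,
      n_aging_detected = rep$n_aging_detected,
      n_rescued = rep$n_rescued, proportion = rep$proportion),
      file.path(out_dir, "rescue_report.tsv")), 1)
    results$rescue <- c(estimated = rep$proportion,
                        planted = config$frac_rescued)
  }

  if ("deconvolve" %in% stages) {
    say("stage deconvolve")
    scref <- simulate_sc_reference(seed = stage_seed(config, "scref"))
    sig <- build_signature(scref$expr, scref$labels,
                           markers_per_type = config$markers_per_type)
    add_file(write_tsv(data.frame(gene = rownames(sig), unclass(sig),
                                  check.names = FALSE),
                       file.path(out_dir, "signature_matrix.tsv")),
             nrow(sig))
    k <- ncol(sig)
    frac_true <- with_seed(stage_seed(config, "mixture"), {
      f <- matrix(stats::rexp(50 * k), ncol = k)
      f / rowSums(f)
    })
    colnames(frac_true) <- colnames(sig)
    mix <- simulate_mixture(sig, frac_true, noise_cv = 0.1,
                            seed = stage_seed(config, "mixture"))
    est <- estimate_fractions(mix$expr, sig)
    add_file(write_tsv(data.frame(sample_id = rownames(est), unclass(est),
                                  check.names = FALSE),
                       file.path(out_dir, "cell_fractions.tsv")), nrow(est))
    results$deconvolution_mean_l1 <-
      mean(rowSums(abs(unclass(est) - mix$fractions)))
  }

  if ("enrich" %in% stages) {
    say("stage enrich")
    truth_sets <- lapply(cohort$truth$groups, function(g) {
      d <- cohort$truth$direction
      d$gene[d$group == g & d$direction == "down"]
    })
    names(truth_sets) <- paste0("planted_down_", cohort$truth$groups)
    coll <- gene_set_collection(truth_sets, universe = cohort$truth$genes)
    gi <- group_intersection(calls, sim_grp$groups, "down")
    biggest <- names(which.max(vapply(gi, function(g) length(g$genes), 0L)))
    enr <- hypergeom_enrich(gi[[biggest]]$genes, coll,
                            universe = cohort$truth$genes)
    add_file(write_tsv(enr, file.path(out_dir, "enrichment.tsv")),
             nrow(enr))
    results$enrichment_top_set <- enr$set[1]
  }

  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    stages = stages,
    files = lapply(stats::setNames(seq_along(files), basename(files)),
                   function(i) list(md5 = unname(tools::md5sum(files[i])),
                                    n_rows = rows[i])),
    results = results)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

# Adjusted Rand index between two integer label vectors (Hubert-Arabie).
rand_index_adjusted <- function(a, b) {
  tab <- table(a, b)
  s <- function(x) sum(choose(x, 2))
  sij <- s(tab); si <- s(rowSums(tab)); sj <- s(colSums(tab))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)
  (sij - expected) / denom
}
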