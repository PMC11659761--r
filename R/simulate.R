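#' @title Synthetic cohorts with planted ground truth
#' @description Generators for multi-tissue aging cohorts, age-matched
#'   case/control cohorts, intervention cohorts with an actigraphy
#'   covariate, labeled single-cell reference profiles and bulk cell
#'   mixtures. Every generator returns machine-readable truth tables so
#'   that each downstream stage can be scored against what was planted.
#' @name simulate
NULL

# Run `code` under an isolated RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards: simulations never touch global RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Simulation configuration for aging cohorts
#'
#' Defaults describe the study conditions the rest of the package is
#' calibrated against: 2000 genes, 150 donors per tissue, 12 brain-like
#' tissues in four groups of three, ages uniform on 40-69 years, 10% of
#' genes declining and 5% rising with age at 0.05 log2 units/year, and
#' residual noise of 1 log2 unit. With these values a planted declining
#' gene has expected age correlation |r| of about 0.4.
#'
#' @param n_genes Number of genes.
#' @param n_samples_per_tissue Donors per tissue (>= 10).
#' @param tissues Named character vector mapping tissue label to group
#'   label; tissues in the same group share the planted direction map.
#' @param age_range Two-element numeric, donor age range in years.
#' @param frac_down,frac_up Proportions of genes planted as declining /
#'   rising with age (per group); \code{frac_down + frac_up <= 1}.
#' @param slope_down,slope_up Signed slopes, log2 units per year.
#' @param noise_sd Residual SD, log2 units (> 0).
#' @param baseline_mean,baseline_sd Per-gene baseline expression drawn
#'   from Normal(baseline_mean, baseline_sd^2) log2 units.
#' @param seed Integer seed.
#' @return A validated list of class \code{SimulationConfig}.
#' @export
sim_config <- function(n_genes = 2000,
                       n_samples_per_tissue = 150,
                       tissues = default_tissues(),
                       age_range = c(40, 69),
                       frac_down = 0.10, frac_up = 0.05,
                       slope_down = -0.05, slope_up = 0.05,
                       noise_sd = 1.0,
                       baseline_mean = 5, baseline_sd = 2,
                       seed = 1L) {
  if (n_samples_per_tissue < 10)
    stop("config error: n_samples_per_tissue must be >= 10 ",
         "(correlations are unusable below that)", call. = FALSE)
  if (frac_down < 0 || frac_up < 0 || frac_down + frac_up > 1)
    stop("config error: frac_down/frac_up must be in [0,1] and sum <= 1",
         call. = FALSE)
  if (noise_sd <= 0) stop("config error: noise_sd must be > 0", call. = FALSE)
  if (length(age_range) != 2 || age_range[1] >= age_range[2])
    stop("config error: age_range must be [min, max] with min < max",
         call. = FALSE)
  if (is.null(names(tissues)) || any(names(tissues) == ""))
    stop("config error: tissues must be a named vector tissue -> group",
         call. = FALSE)
  if (slope_down > 0 || slope_up < 0)
    stop("config error: slope_down must be <= 0 and slope_up >= 0",
         call. = FALSE)
  structure(list(
    n_genes = as.integer(n_genes),
    n_samples_per_tissue = as.integer(n_samples_per_tissue),
    tissues = tissues, age_range = as.numeric(age_range),
    frac_down = frac_down, frac_up = frac_up,
    slope_down = slope_down, slope_up = slope_up,
    noise_sd = noise_sd,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    seed = as.integer(seed)), class = "SimulationConfig")
}

#' Default tissue layout: 12 tissues in four groups of three
#' @return Named character vector tissue -> group.
#' @export
default_tissues <- function() {
  stats::setNames(rep(paste0("group_", c("i", "ii", "iii", "iv")), each = 3),
                  paste0("tissue_", sprintf("%02d", 1:12)))
}

#' Simulate a multi-tissue aging cohort
#'
#' For gene g in sample s of a tissue, the log2 expression is
#' \code{baseline_g + slope_[g,group] * (age_s - mid_age) + eps},
#' \code{eps ~ Normal(0, noise_sd^2)}; ages are uniform on the configured
#' range and tissues in the same group share the planted direction map.
#' Null genes have slope exactly zero.
#'
#' @param config A \code{\link{sim_config}}.
#' @param truth Optional truth object from a previous call: reuse its
#'   baselines and direction maps to simulate an independent validation
#'   cohort with the same planted biology.
#' @return List with \code{expr} (named list of log2-scale
#'   \code{ExpressionMatrix}, one per tissue), \code{samples} (a
#'   \code{SampleTable} covering all tissues) and \code{truth} (class
#'   \code{SyntheticTruth}: per-group direction/slope tables, baselines,
#'   and the generating config).
#' @export
simulate_aging_cohort <- function(config, truth = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  with_seed(config$seed, {
    genes <- sprintf("G%05d", seq_len(config$n_genes))
    groups <- unique(unname(config$tissues))
    if (is.null(truth)) {
      baseline <- stats::setNames(
        stats::rnorm(config$n_genes, config$baseline_mean,
                     config$baseline_sd), genes)
      n_down <- floor(config$frac_down * config$n_genes)
      n_up <- floor(config$frac_up * config$n_genes)
      dir_tab <- do.call(rbind, lapply(groups, function(g) {
        pick <- sample(genes, n_down + n_up)
        dir <- rep("null", config$n_genes)
        names(dir) <- genes
        dir[pick[seq_len(n_down)]] <- "down"
        if (n_up > 0) dir[pick[n_down + seq_len(n_up)]] <- "up"
        slope <- ifelse(dir == "down", config$slope_down,
                        ifelse(dir == "up", config$slope_up, 0))
        data.frame(gene = genes, group = g, direction = unname(dir),
                   slope = unname(slope), stringsAsFactors = FALSE)
      }))
      truth <- structure(list(
        genes = genes, groups = groups, direction = dir_tab,
        baseline = baseline, config = config), class = "SyntheticTruth")
    } else {
      stopifnot(inherits(truth, "SyntheticTruth"))
      genes <- truth$genes
      baseline <- truth$baseline
      dir_tab <- truth$direction
      groups <- unique(unname(config$tissues))
      if (!all(groups %in% truth$groups))
        stop("config tissues reference groups absent from supplied truth",
             call. = FALSE)
    }
    mid <- mean(config$age_range)
    n <- config$n_samples_per_tissue
    expr <- list()
    smp <- list()
    for (tis in names(config$tissues)) {
      grp <- config$tissues[[tis]]
      ages <- stats::runif(n, config$age_range[1], config$age_range[2])
      slopes <- dir_tab$slope[dir_tab$group == grp]
      vals <- baseline + outer(slopes, ages - mid) +
        matrix(stats::rnorm(length(genes) * n, 0, config$noise_sd),
               nrow = length(genes))
      ids <- sprintf("%s_s%03d", tis, seq_len(n))
      dimnames(vals) <- list(genes, ids)
      expr[[tis]] <- expression_matrix(vals, scale = "log2")
      smp[[tis]] <- data.frame(sample_id = ids, age = ages, sex = "unknown",
                               tissue = tis, condition = "healthy",
                               activity = NA_real_, cohort = "aging",
                               stringsAsFactors = FALSE)
    }
    list(expr = expr,
         samples = sample_table(do.call(rbind, smp)),
         truth = truth)
  })
}

#' Simulate an age-matched case/control disease cohort
#'
#' A stated fraction of the planted aging genes of one tissue group
#' receives an additional case-arm shift in the same direction as its
#' aging trend ("syntropic" deregulation). The case and control arms share
#' the same drawn ages, so the contrast is net of aging, mirroring an
#' age-matched patient/control design.
#'
#' @param truth \code{SyntheticTruth} from \code{\link{simulate_aging_cohort}}.
#' @param group Which tissue group's direction map to use.
#' @param frac_syntropic Fraction of that group's planted aging genes given
#'   a disease shift, in [0,1].
#' @param shift Magnitude of the case-arm shift, log2 units (applied with
#'   the sign of the gene's aging direction).
#' @param n_per_arm Samples per arm.
#' @param noise_sd Residual SD, log2 units.
#' @param tissue Tissue label recorded in the output metadata.
#' @param seed Integer seed.
#' @return List with \code{expr}, \code{samples} (conditions case/control)
#'   and \code{truth} with a \code{disease} table (gene, aging direction,
#'   syntropic flag, signed shift) appended.
#' @export
simulate_disease_cohort <- function(truth, group = NULL,
                                    frac_syntropic = 0.40, shift = 1.0,
                                    n_per_arm = 50, noise_sd = 1.0,
                                    tissue = NULL, seed = 1L) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  if (frac_syntropic < 0 || frac_syntropic > 1)
    stop("config error: frac_syntropic must be in [0,1]", call. = FALSE)
  if (is.null(group)) group <- truth$groups[1]
  if (is.null(tissue)) tissue <- paste0(group, "_disease")
  dir_tab <- truth$direction[truth$direction$group == group, ]
  with_seed(seed, {
    aging <- dir_tab$gene[dir_tab$direction != "null"]
    n_syn <- round(frac_syntropic * length(aging))
    syn <- if (n_syn > 0) sample(aging, n_syn) else character(0)
    sgn <- ifelse(dir_tab$direction == "down", -1,
                  ifelse(dir_tab$direction == "up", 1, 0))
    shift_vec <- ifelse(dir_tab$gene %in% syn, sgn * shift, 0)
    ages <- stats::runif(n_per_arm, truth$config$age_range[1],
                         truth$config$age_range[2])
    mid <- mean(truth$config$age_range)
    base <- truth$baseline + outer(dir_tab$slope, c(ages, ages) - mid)
    vals <- base + matrix(stats::rnorm(length(truth$genes) * 2 * n_per_arm,
                                       0, noise_sd), nrow = length(truth$genes))
    vals[, seq_len(n_per_arm)] <- vals[, seq_len(n_per_arm)] + shift_vec
    ids <- c(sprintf("case_%03d", seq_len(n_per_arm)),
             sprintf("ctrl_%03d", seq_len(n_per_arm)))
    dimnames(vals) <- list(truth$genes, ids)
    smp <- sample_table(data.frame(
      sample_id = ids, age = c(ages, ages), sex = "unknown",
      tissue = tissue,
      condition = rep(c("case", "control"), each = n_per_arm),
      activity = NA_real_, cohort = "disease", stringsAsFactors = FALSE))
    truth$disease <- data.frame(
      gene = dir_tab$gene, group = group,
      aging_direction = dir_tab$direction,
      syntropic = dir_tab$gene %in% syn, shift = shift_vec,
      stringsAsFactors = FALSE)
    list(expr = expression_matrix(vals, scale = "log2"),
         samples = smp, truth = truth)
  })
}

#' Simulate an intervention cohort with an actigraphy covariate
#'
#' Three equal arms (low / moderate / high physical activity) with
#' activity drawn uniformly within each arm's actigraphy interval
#' (cut-offs 1e5 and 2.1e5 counts/day). A stated fraction of the group's
#' planted down-aging genes gains a positive expression offset in the
#' high-activity arm only — the planted "rescue". Arms share drawn ages.
#'
#' @param truth \code{SyntheticTruth} from \code{\link{simulate_aging_cohort}}.
#' @param group Tissue group whose down-aging genes are eligible for rescue.
#' @param frac_rescued Fraction of planted down genes rescued, in [0,1].
#' @param offset Rescue offset, log2 units (> 0), added in the high arm.
#' @param n_per_arm Samples per arm.
#' @param noise_sd Residual SD, log2 units.
#' @param activity_cuts Actigraphy cut-offs, counts/day: moderate and high
#'   boundaries (default \code{c(1e5, 2.1e5)}), with the high arm drawn up
#'   to \code{activity_max}.
#' @param activity_max Upper bound for high-arm activity draws.
#' @param tissue Tissue label for the output metadata.
#' @param seed Integer seed.
#' @return List with \code{expr}, \code{samples} (carrying \code{activity})
#'   and \code{truth} with a \code{rescue} table appended.
#' @export
simulate_intervention_cohort <- function(truth, group = NULL,
                                         frac_rescued = 0.40, offset = 1.0,
                                         n_per_arm = 50, noise_sd = 1.0,
                                         activity_cuts = c(1e5, 2.1e5),
                                         activity_max = 3.2e5,
                                         tissue = NULL, seed = 1L) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  if (frac_rescued < 0 || frac_rescued > 1)
    stop("config error: frac_rescued must be in [0,1]", call. = FALSE)
  if (is.null(group)) group <- truth$groups[1]
  if (is.null(tissue)) tissue <- paste0(group, "_intervention")
  dir_tab <- truth$direction[truth$direction$group == group, ]
  with_seed(seed, {
    down <- dir_tab$gene[dir_tab$direction == "down"]
    n_res <- round(frac_rescued * length(down))
    rescued <- if (n_res > 0) sample(down, n_res) else character(0)
    ages <- stats::runif(n_per_arm, truth$config$age_range[1],
                         truth$config$age_range[2])
    mid <- mean(truth$config$age_range)
    arms <- rep(c("low", "moderate", "high"), each = n_per_arm)
    activity <- c(stats::runif(n_per_arm, 0, activity_cuts[1]),
                  stats::runif(n_per_arm, activity_cuts[1], activity_cuts[2]),
                  stats::runif(n_per_arm, activity_cuts[2], activity_max))
    all_ages <- rep(ages, times = 3)
    base <- truth$baseline + outer(dir_tab$slope, all_ages - mid)
    vals <- base + matrix(stats::rnorm(length(truth$genes) * 3 * n_per_arm,
                                       0, noise_sd), nrow = length(truth$genes))
    hi <- arms == "high"
    vals[dir_tab$gene %in% rescued, hi] <-
      vals[dir_tab$gene %in% rescued, hi] + offset
    ids <- sprintf("%s_%03d", arms, rep(seq_len(n_per_arm), times = 3))
    dimnames(vals) <- list(truth$genes, ids)
    smp <- sample_table(data.frame(
      sample_id = ids, age = all_ages, sex = "unknown", tissue = tissue,
      condition = "healthy", activity = activity, cohort = "intervention",
      stringsAsFactors = FALSE))
    truth$rescue <- data.frame(
      gene = down, group = group, rescued = down %in% rescued,
      offset = ifelse(down %in% rescued, offset, 0),
      stringsAsFactors = FALSE)
    list(expr = expression_matrix(vals, scale = "log2"),
         samples = smp, truth = truth)
  })
}

#' Simulate labeled single-cell reference profiles
#'
#' Each cell type expresses a dedicated block of marker genes at a high
#' level on top of a shared low background, giving well-separated
#' signatures for deconvolution tests. Expression is returned on the log2
#' scale with per-cell Gaussian noise.
#'
#' @param cell_types Character vector of type labels.
#' @param markers_per_type Exclusive marker genes per type.
#' @param cells_per_type Cells per type (>= 20 for signature building).
#' @param n_background Additional non-marker genes shared by all types.
#' @param marker_level,background_level Mean log2 expression of a type's
#'   own markers and of everything else.
#' @param noise_sd Per-cell residual SD, log2 units.
#' @param seed Integer seed.
#' @return List with \code{expr} (log2 \code{ExpressionMatrix}, cells as
#'   samples) and \code{labels} (character vector of cell-type labels
#'   aligned with columns).
#' @export
simulate_sc_reference <- function(cell_types = c("neuron", "oligodendrocyte",
                                                 "astrocyte", "microglia",
                                                 "vascular", "OPC"),
                                  markers_per_type = 50,
                                  cells_per_type = 40,
                                  n_background = 200,
                                  marker_level = 8, background_level = 2,
                                  noise_sd = 0.5, seed = 1L) {
  with_seed(seed, {
    k <- length(cell_types)
    n_genes <- k * markers_per_type + n_background
    genes <- sprintf("M%05d", seq_len(n_genes))
    mu <- matrix(background_level, nrow = n_genes, ncol = k,
                 dimnames = list(genes, cell_types))
    for (i in seq_len(k)) {
      block <- (i - 1) * markers_per_type + seq_len(markers_per_type)
      mu[block, i] <- marker_level
    }
    n_cells <- k * cells_per_type
    labels <- rep(cell_types, each = cells_per_type)
    vals <- mu[, labels] +
      matrix(stats::rnorm(n_genes * n_cells, 0, noise_sd), nrow = n_genes)
    vals[vals < 0] <- 0
    colnames(vals) <- sprintf("cell_%04d", seq_len(n_cells))
    list(expr = expression_matrix(vals, scale = "log2"), labels = labels)
  })
}

#' Simulate bulk mixtures of known cell-type composition
#'
#' Each bulk sample is the fraction-weighted sum of the cell-type mean
#' profiles on the linear scale, optionally perturbed by multiplicative
#' log-normal noise with the stated coefficient of variation (mean exactly
#' one, so zero CV reproduces the exact matrix product).
#'
#' @param signature Genes x cell-types matrix of mean profiles. A plain
#'   matrix is taken as linear-scale; a \code{CellSignatureMatrix} (log2
#'   means, see \code{\link{build_signature}}) is converted via \code{2^x}.
#' @param fractions Samples x cell-types matrix; rows non-negative and
#'   summing to 1 within 1e-6.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (0 = noise-free).
#' @param seed Integer seed.
#' @return List with \code{expr} (raw-scale bulk \code{ExpressionMatrix})
#'   and \code{fractions} (the true composition, rows matching samples).
#' @export
simulate_mixture <- function(signature, fractions, noise_cv = 0, seed = 1L) {
  sig <- if (inherits(signature, "CellSignatureMatrix"))
    2^unclass(signature) else as.matrix(signature)
  fractions <- as.matrix(fractions)
  if (is.null(colnames(fractions))) colnames(fractions) <- colnames(sig)
  if (!identical(colnames(fractions), colnames(sig)))
    stop("fraction columns must match signature cell types", call. = FALSE)
  if (any(fractions < 0))
    stop("config error: fractions must be non-negative", call. = FALSE)
  if (any(abs(rowSums(fractions) - 1) > 1e-6))
    stop("config error: each fraction vector must sum to 1 within 1e-6",
         call. = FALSE)
  with_seed(seed, {
    bulk <- sig %*% t(fractions)
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      noise <- matrix(stats::rlnorm(length(bulk), meanlog = -sdlog^2 / 2,
                                    sdlog = sdlog), nrow = nrow(bulk))
      bulk <- bulk * noise
    }
    if (is.null(rownames(fractions)))
      rownames(fractions) <- sprintf("mix_%03d", seq_len(nrow(fractions)))
    colnames(bulk) <- rownames(fractions)
    list(expr = expression_matrix(bulk, scale = "raw"),
         fractions = fractions)
  })
}
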