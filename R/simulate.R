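#' Simulation configuration
#'
#' Defines the generative model for the synthetic study: two disease-vs-healthy
#' expression datasets with a shared (attenuated) disease effect, technical
#' replicates in dataset A, a paired TKI-treatment dataset, and Ct-scale qPCR
#' tables. Gene-wise residual variances follow a scaled inverse chi-square law
#' with prior degrees of freedom `d0_true` and prior variance `s0_true`, the
#' same hierarchy assumed by empirical-Bayes variance moderation.
#'
#' Defaults encode the study conditions the pipeline is validated under:
#' 6 vs 6 biological samples per cohort, triplicate technical replicates in
#' dataset A, 10 paired treatment patients, 20% of genes carrying a disease
#' effect of absolute log2 fold-change between 0.7 and 2, and technical noise
#' `tech_rep_sd = 0.18` log2 units (so the 2.5/97.5 percentiles of
#' replicate-vs-replicate fold-changes land near ±0.5). `cross_dataset_rho`
#' defaults to 0.676, calibrated in closed form so the correlation of
#' *estimated* fold-changes between the two datasets targets 0.63 after
#' attenuation by sampling noise (see the methods vignette).
#' `class_probs` defaults to the (rescued, enhanced, independent) mix
#' (0.742, 0.106, 0.152).
#'
#' @param n_genes Number of genes.
#' @param n_per_group_A,n_per_group_B Biological samples per cohort (disease
#'   and control each) in datasets A and B.
#' @param n_tech_reps Technical replicates per biological sample in dataset A.
#' @param n_patients_treatment Paired patients in the treatment dataset.
#' @param frac_de Fraction of genes with a true disease effect.
#' @param effect_low,effect_high Bounds of the absolute disease log2
#'   fold-change (uniform, random sign).
#' @param cross_dataset_rho Correlation of the dataset-B disease effect with
#'   the dataset-A effect (attenuation + independent noise), in `[0, 1]`.
#' @param class_probs Probabilities of the (rescued, enhanced, independent)
#'   treatment classes for DE genes; must sum to 1.
#' @param enhance_low,enhance_high Bounds of the absolute extra same-direction
#'   treatment effect for enhanced genes.
#' @param tech_rep_sd Per-measurement technical noise SD (log2 units).
#' @param patient_sd SD of the per-gene random patient intercept in the
#'   treatment dataset.
#' @param d0_true,s0_true Prior degrees of freedom and prior variance of the
#'   scaled inverse chi-square gene-variance law.
#' @param baseline_mean,baseline_sd Normal law of gene baseline log2 levels.
#' @param ct_noise_sd Per-reaction Ct measurement noise SD.
#' @param ct_offset Additive constant of the Ct scale (Ct = offset - log2
#'   expression + noise; slope -1, perfect amplification efficiency).
#' @param seed Integer random seed; identical config + seed reproduces every
#'   output bitwise.
#'
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 10000,
                              n_per_group_A = 6,
                              n_per_group_B = 6,
                              n_tech_reps = 3,
                              n_patients_treatment = 10,
                              frac_de = 0.2,
                              effect_low = 0.7,
                              effect_high = 2.0,
                              cross_dataset_rho = 0.676,
                              class_probs = c(rescued = 0.742,
                                              enhanced = 0.106,
                                              independent = 0.152),
                              enhance_low = 0.7,
                              enhance_high = 2.0,
                              tech_rep_sd = 0.18,
                              patient_sd = 0.5,
                              d0_true = 4,
                              s0_true = 0.04,
                              baseline_mean = 7,
                              baseline_sd = 1.5,
                              ct_noise_sd = 0.15,
                              ct_offset = 30,
                              seed = 1L) {
  cfg <- list(
    n_genes = n_genes, n_per_group_A = n_per_group_A,
    n_per_group_B = n_per_group_B, n_tech_reps = n_tech_reps,
    n_patients_treatment = n_patients_treatment, frac_de = frac_de,
    effect_low = effect_low, effect_high = effect_high,
    cross_dataset_rho = cross_dataset_rho, class_probs = class_probs,
    enhance_low = enhance_low, enhance_high = enhance_high,
    tech_rep_sd = tech_rep_sd, patient_sd = patient_sd,
    d0_true = d0_true, s0_true = s0_true,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    ct_noise_sd = ct_noise_sd, ct_offset = ct_offset,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_genes", "n_per_group_A", "n_per_group_B", "n_tech_reps",
              "n_patients_treatment")
  for (nm in counts) {
    v <- cfg[[nm]]
    if (length(v) != 1 || !is.finite(v) || v < 1 || v != round(v)) {
      stop("configuration error: `", nm, "` must be a positive integer")
    }
  }
  if (cfg$frac_de < 0 || cfg$frac_de > 1) {
    stop("configuration error: `frac_de` must lie in [0, 1]")
  }
  if (abs(sum(cfg$class_probs) - 1) > 1e-12 || length(cfg$class_probs) != 3 ||
      any(cfg$class_probs < 0)) {
    stop("configuration error: `class_probs` must be 3 non-negative ",
         "probabilities summing to 1")
  }
  if (cfg$cross_dataset_rho < 0 || cfg$cross_dataset_rho > 1) {
    stop("configuration error: `cross_dataset_rho` must lie in [0, 1]")
  }
  sds <- c("tech_rep_sd", "patient_sd", "baseline_sd", "ct_noise_sd")
  for (nm in sds) {
    if (cfg[[nm]] < 0) stop("configuration error: `", nm, "` must be >= 0")
  }
  for (nm in c("d0_true", "s0_true")) {
    if (cfg[[nm]] <= 0) stop("configuration error: `", nm, "` must be > 0")
  }
  if (cfg$effect_low <= 0 || cfg$effect_high < cfg$effect_low) {
    stop("configuration error: need 0 < effect_low <= effect_high")
  }
  if (cfg$enhance_low <= 0 || cfg$enhance_high < cfg$enhance_low) {
    stop("configuration error: need 0 < enhance_low <= enhance_high")
  }
  invisible(cfg)
}

# deterministic sub-stream seeds so each generator stage is reproducible from
# (config, seed) regardless of call order; kept below 2^31
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 104729 * k) %% (.Machine$integer.max - 1L))
}

gene_ids <- function(n) sprintf("g%05d", seq_len(n))

#' Generate the paired disease-vs-healthy cohort datasets
#'
#' Draws per-gene residual variances from a scaled inverse chi-square law,
#' baselines from a normal law, assigns a disease effect to a fixed fraction
#' of genes (uniform magnitude, random sign) and emits two two-group datasets:
#' dataset A with technical replicates, dataset B without. The dataset-B
#' effect is an attenuated copy of the dataset-A effect plus independent
#' noise, so the cross-dataset effect correlation is tunable via
#' `cross_dataset_rho`. Treatment classes (rescued / enhanced / independent)
#' are pre-assigned here so [generate_treatment_dataset()] and
#' [generate_qpcr_table()] act on the same truth.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `matrix_A`, `matrix_B` (class `expr_matrix`)
#'   and `truth`, a data frame with one row per gene: `gene_id`, `is_de`,
#'   `delta_A`, `delta_B`, `treat_class`, `treat_effect`, `sigma2`.
#' @export
generate_cohort_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 0))
  n <- config$n_genes
  ids <- gene_ids(n)

  sigma2 <- config$s0_true * config$d0_true / stats::rchisq(n, config$d0_true)
  mu <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)

  n_de <- round(config$frac_de * n)
  de_idx <- sort(sample.int(n, n_de))
  is_de <- rep(FALSE, n)
  is_de[de_idx] <- TRUE

  delta_A <- numeric(n)
  delta_A[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
    stats::runif(n_de, config$effect_low, config$effect_high)

  # dataset-B effect: rho-attenuated copy + independent noise with variance
  # (1 - rho^2) * Var(delta) where Var(delta) = E[delta^2] of the signed
  # uniform effect law, so marginal variances match across datasets
  rho <- config$cross_dataset_rho
  var_delta <- (config$effect_low^2 + config$effect_low * config$effect_high +
                  config$effect_high^2) / 3
  delta_B <- numeric(n)
  delta_B[de_idx] <- rho * delta_A[de_idx] +
    stats::rnorm(n_de, 0, sqrt((1 - rho^2) * var_delta))

  treat_class <- rep("none", n)
  treat_effect <- numeric(n)
  if (n_de > 0) {
    cls <- sample(c("rescued", "enhanced", "independent"), n_de,
                  replace = TRUE, prob = config$class_probs)
    treat_class[de_idx] <- cls
    resc <- de_idx[cls == "rescued"]
    enh <- de_idx[cls == "enhanced"]
    treat_effect[resc] <- -delta_A[resc]
    treat_effect[enh] <- sign(delta_A[enh]) *
      stats::runif(length(enh), config$enhance_low, config$enhance_high)
  }

  truth <- data.frame(
    gene_id = ids, is_de = is_de, delta_A = delta_A, delta_B = delta_B,
    treat_class = treat_class, treat_effect = treat_effect, sigma2 = sigma2,
    stringsAsFactors = FALSE
  )

  matrix_A <- simulate_two_group(mu, delta_A, sigma2, config$n_per_group_A,
                                 config$n_tech_reps, config$tech_rep_sd, "A")
  matrix_B <- simulate_two_group(mu, delta_B, sigma2, config$n_per_group_B,
                                 1L, 0, "B")
  list(matrix_A = matrix_A, matrix_B = matrix_B, truth = truth)
}

# one two-group dataset: biological sample value = mu + effect (disease only)
# + N(0, sigma2); each technical replicate re-measures it with
# N(0, tech_rep_sd^2) noise
simulate_two_group <- function(mu, delta, sigma2, n_per_group, n_reps,
                               tech_rep_sd, prefix) {
  n <- length(mu)
  groups <- rep(c("disease", "control"), each = n_per_group)
  pat <- c(sprintf("%s_d%02d", prefix, seq_len(n_per_group)),
           sprintf("%s_c%02d", prefix, seq_len(n_per_group)))
  bio_means <- sapply(seq_along(groups), function(j) {
    eff <- if (groups[j] == "disease") delta else 0
    mu + eff + stats::rnorm(n, 0, sqrt(sigma2))
  })
  cols <- vector("list", length(groups) * n_reps)
  meta <- vector("list", length(cols))
  k <- 0
  for (j in seq_along(groups)) {
    for (r in seq_len(n_reps)) {
      k <- k + 1
      noise <- if (tech_rep_sd > 0) stats::rnorm(n, 0, tech_rep_sd) else 0
      cols[[k]] <- bio_means[, j] + noise
      meta[[k]] <- data.frame(
        sample_id = if (n_reps > 1) sprintf("%s_r%d", pat[j], r) else pat[j],
        patient_id = pat[j], group = groups[j], tech_rep_index = r,
        stringsAsFactors = FALSE
      )
    }
  }
  values <- do.call(cbind, cols)
  rownames(values) <- gene_ids(n)
  samples <- do.call(rbind, meta)
  colnames(values) <- samples$sample_id
  expression_matrix(values, samples)
}

#' Generate the paired TKI-treatment dataset
#'
#' Paired design: each of `n_patients_treatment` disease patients contributes
#' one baseline and one treated sample sharing a per-gene random patient
#' intercept. The treated mean adds the per-gene treatment effect from the
#' truth table (exactly `-delta_A` for rescued genes, zero for independent
#' genes, an extra same-direction shift for enhanced genes); residual noise
#' reuses each gene's `sigma2`.
#'
#' @param truth Truth table from [generate_cohort_pair()] (same config).
#' @param config The same [simulation_config()].
#' @return An `expr_matrix` with `2 * n_patients_treatment` columns and
#'   `group` in `{baseline, treated}`.
#' @export
generate_treatment_dataset <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(truth) != config$n_genes) {
    stop("truth/config mismatch: truth has ", nrow(truth),
         " genes but config$n_genes = ", config$n_genes)
  }
  set.seed(sub_seed(config$seed, 1))
  n <- config$n_genes
  npt <- config$n_patients_treatment
  # baselines are redrawn on the same law: a distinct patient cohort
  mu <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
  sd_g <- sqrt(truth$sigma2)

  cols <- vector("list", 2 * npt)
  meta <- vector("list", 2 * npt)
  k <- 0
  for (p in seq_len(npt)) {
    intercept <- stats::rnorm(n, 0, config$patient_sd)
    base_mean <- mu + truth$delta_A + intercept
    for (cond in c("baseline", "treated")) {
      k <- k + 1
      eff <- if (cond == "treated") truth$treat_effect else 0
      cols[[k]] <- base_mean + eff + stats::rnorm(n, 0, sd_g)
      meta[[k]] <- data.frame(
        sample_id = sprintf("T_p%02d_%s", p, cond),
        patient_id = sprintf("T_p%02d", p), group = cond,
        tech_rep_index = 1L, stringsAsFactors = FALSE
      )
    }
  }
  values <- do.call(cbind, cols)
  rownames(values) <- truth$gene_id
  samples <- do.call(rbind, meta)
  colnames(values) <- samples$sample_id
  expression_matrix(values, samples)
}

#' Generate a qPCR Ct table
#'
#' Emulates a qPCR validation run: Ct is a linear transform of log2 expression
#' with slope -1 (perfect amplification efficiency) plus per-reaction
#' measurement noise. Reference genes carry zero disease and treatment
#' effects. The table contains a cohort contrast (disease vs control) and
#' paired baseline/treated samples per treatment patient, with gene roles
#' labelled.
#'
#' @param truth Truth table from [generate_cohort_pair()].
#' @param config The same [simulation_config()].
#' @param n_ref_genes Number of reference genes (>= 2).
#' @param n_test_genes Number of test genes drawn from the truth table
#'   (ignored when `gene_ids` is given).
#' @param gene_ids Optional explicit test gene ids; default samples
#'   `n_test_genes` genes, preferring DE genes (validation candidates).
#' @return A list of class `ct_table`: `ct` (genes x samples Ct matrix),
#'   `roles` (named `test`/`reference` per gene) and `samples` metadata.
#' @export
generate_qpcr_table <- function(truth, config, n_ref_genes = 4,
                                n_test_genes = 26, gene_ids = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (n_ref_genes < 2) {
    stop("n_ref_genes must be >= 2: the mean of a single reference gene ",
         "is not a robust normaliser")
  }
  set.seed(sub_seed(config$seed, 2))
  if (is.null(gene_ids)) {
    de_pool <- truth$gene_id[truth$is_de]
    pool <- if (length(de_pool) >= n_test_genes) de_pool else truth$gene_id
    gene_ids <- sort(sample(pool, n_test_genes))
  }
  miss <- setdiff(gene_ids, truth$gene_id)
  if (length(miss)) stop("unknown test genes: ", paste(miss, collapse = ", "))
  ti <- match(gene_ids, truth$gene_id)

  ref_ids <- sprintf("REF%d", seq_len(n_ref_genes))
  mu_test <- stats::rnorm(length(ti), config$baseline_mean, config$baseline_sd)
  mu_ref <- stats::rnorm(n_ref_genes, config$baseline_mean, config$baseline_sd)

  npg <- config$n_per_group_A
  npt <- config$n_patients_treatment
  samples <- rbind(
    data.frame(sample_id = sprintf("q_d%02d", seq_len(npg)),
               patient_id = sprintf("q_d%02d", seq_len(npg)),
               group = "disease", tech_rep_index = 1L),
    data.frame(sample_id = sprintf("q_c%02d", seq_len(npg)),
               patient_id = sprintf("q_c%02d", seq_len(npg)),
               group = "control", tech_rep_index = 1L),
    data.frame(sample_id = sprintf("q_p%02d_baseline", seq_len(npt)),
               patient_id = sprintf("q_p%02d", seq_len(npt)),
               group = "baseline", tech_rep_index = 1L),
    data.frame(sample_id = sprintf("q_p%02d_treated", seq_len(npt)),
               patient_id = sprintf("q_p%02d", seq_len(npt)),
               group = "treated", tech_rep_index = 1L)
  )

  # expected log2 expression per gene x sample; reference genes are flat
  expr_for <- function(mu, delta, eff) {
    vapply(seq_len(nrow(samples)), function(j) {
      g <- samples$group[j]
      mu + delta * (g %in% c("disease", "baseline", "treated")) +
        eff * (g == "treated")
    }, numeric(length(mu)))
  }
  x_test <- expr_for(mu_test, truth$delta_A[ti], truth$treat_effect[ti])
  x_ref <- expr_for(mu_ref, rep(0, n_ref_genes), rep(0, n_ref_genes))
  x <- rbind(x_test, x_ref)
  noise <- if (config$ct_noise_sd > 0) {
    matrix(stats::rnorm(length(x), 0, config$ct_noise_sd), nrow(x))
  } else 0
  ct <- config$ct_offset - x + noise
  rownames(ct) <- c(gene_ids, ref_ids)
  colnames(ct) <- samples$sample_id
  roles <- stats::setNames(rep(c("test", "reference"),
                               c(length(gene_ids), n_ref_genes)),
                           rownames(ct))
  structure(list(ct = ct, roles = roles, samples = samples),
            class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf("ct_table: %d test + %d reference genes x %d samples\n",
              sum(x$roles == "test"), sum(x$roles == "reference"),
              ncol(x$ct)))
  invisible(x)
}

#' Write / read a Ct table as TSV
#'
#' Columns: `gene_id`, `role` (`test`/`reference`), then one Ct column per
#' sample; the metadata table has one row per sample.
#'
#' @param tab A `ct_table` from [generate_qpcr_table()].
#' @param ct_path,samples_path Output paths.
#' @export
write_ct_table <- function(tab, ct_path, samples_path) {
  stopifnot(inherits(tab, "ct_table"))
  df <- data.frame(gene_id = rownames(tab$ct), role = unname(tab$roles),
                   tab$ct, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, ct_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(tab$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(ct_path, samples_path))
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(ct_path, samples_path) {
  df <- utils::read.delim(ct_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  ct <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(ct) <- df$gene_id
  structure(list(ct = ct, roles = stats::setNames(df$role, df$gene_id),
                 samples = samples), class = "ct_table")
}
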