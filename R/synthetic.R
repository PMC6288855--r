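#' Specification for a synthetic multi-batch survival cohort
#'
#' Defines the generative model used by [generate_cohort()]: a genes x
#' samples log2 expression matrix with per-batch location/scale artifacts,
#' a subset of genes shifted in late-stage (III/IV) tumors, and a subset of
#' marker genes whose (standardized, batch-free) expression drives overall
#' survival through a proportional-hazards model.
#'
#' @param n_genes,n_samples,n_batches Positive counts. `n_samples` counts
#'   tumor samples; normals are extra (see `n_normal`).
#' @param batch_sizes Integer vector of per-batch tumor sample counts
#'   summing to `n_samples`; default near-equal split.
#' @param batch_shift_sd SD (log2 units) of both the batch-wide location
#'   term and the per-batch per-gene additive offsets.
#' @param batch_scale_sd SD of the log multiplicative per-batch noise scale.
#' @param n_stage_genes,stage_effect Number of genes with a late-stage
#'   log2 shift and the shift size.
#' @param n_marker_genes,marker_beta Number of survival-linked genes and the
#'   log-hazard per SD of expression (scalar recycled or one value per
#'   marker; positive = high expression is hazardous).
#' @param baseline_hazard Baseline event rate (events per month).
#' @param censor_rate Target censoring fraction in `[0, 1]`.
#' @param admin_censor_time Administrative censoring horizon (months).
#' @param frac_late_stage Fraction of tumor samples in stages III/IV.
#' @param n_normal Number of extra normal-tissue samples (no survival).
#' @param tumor_effect Log2 up-shift of marker and stage genes in tumors
#'   relative to normal tissue.
#' @param markers_stage_shifted If `TRUE`, marker genes also receive the
#'   late-stage shift (so they survive a stage-contrast pre-filter); the
#'   overlap is recorded in the ground truth. Default `FALSE` (disjoint sets).
#' @param weibull_shape Shape of the baseline hazard; 1 (default) gives the
#'   exponential model with exact censoring calibration.
#' @param seed Integer seed; identical specs give bit-identical cohorts.
#'
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_genes = 2000, n_samples = 800, n_batches = 7,
                           batch_sizes = NULL, batch_shift_sd = 0.3,
                           batch_scale_sd = 0.1, n_stage_genes = 100,
                           stage_effect = 1.0, n_marker_genes = 20,
                           marker_beta = log(2), baseline_hazard = 0.01,
                           censor_rate = 0.6, admin_censor_time = 120,
                           frac_late_stage = 0.4, n_normal = 0,
                           tumor_effect = 1.0, markers_stage_shifted = FALSE,
                           weibull_shape = 1, seed = 1) {
  n_genes <- check_count(n_genes, "n_genes")
  n_samples <- check_count(n_samples, "n_samples")
  n_batches <- check_count(n_batches, "n_batches")
  if (is.null(batch_sizes)) {
    batch_sizes <- rep(n_samples %/% n_batches, n_batches)
    rem <- n_samples - sum(batch_sizes)
    if (rem > 0) batch_sizes[seq_len(rem)] <- batch_sizes[seq_len(rem)] + 1L
  }
  batch_sizes <- vapply(batch_sizes, check_count, integer(1), name = "batch_sizes")
  if (length(batch_sizes) != n_batches) stop("'batch_sizes' must have n_batches entries")
  if (sum(batch_sizes) != n_samples) stop("'batch_sizes' must sum to n_samples")
  check_nonneg(batch_shift_sd, "batch_shift_sd")
  check_nonneg(batch_scale_sd, "batch_scale_sd")
  n_stage_genes <- check_count(n_stage_genes, "n_stage_genes", min = 0L)
  n_marker_genes <- check_count(n_marker_genes, "n_marker_genes", min = 0L)
  if (n_stage_genes + n_marker_genes > n_genes) {
    stop("'n_marker_genes' + 'n_stage_genes' must not exceed n_genes")
  }
  if (!length(marker_beta) %in% c(1L, max(1L, n_marker_genes))) {
    stop("'marker_beta' must be scalar or one value per marker gene")
  }
  marker_beta <- rep_len(as.numeric(marker_beta), n_marker_genes)
  if (baseline_hazard <= 0) stop("'baseline_hazard' must be positive")
  check_fraction(censor_rate, "censor_rate")
  if (admin_censor_time <= 0) stop("'admin_censor_time' must be positive")
  check_fraction(frac_late_stage, "frac_late_stage")
  n_normal <- check_count(n_normal, "n_normal", min = 0L)
  if (weibull_shape <= 0) stop("'weibull_shape' must be positive")
  spec <- list(n_genes = n_genes, n_samples = n_samples, n_batches = n_batches,
               batch_sizes = batch_sizes, batch_shift_sd = batch_shift_sd,
               batch_scale_sd = batch_scale_sd, n_stage_genes = n_stage_genes,
               stage_effect = as.numeric(stage_effect),
               n_marker_genes = n_marker_genes, marker_beta = marker_beta,
               baseline_hazard = as.numeric(baseline_hazard),
               censor_rate = censor_rate,
               admin_censor_time = as.numeric(admin_censor_time),
               frac_late_stage = frac_late_stage, n_normal = n_normal,
               tumor_effect = as.numeric(tumor_effect),
               markers_stage_shifted = isTRUE(markers_stage_shifted),
               weibull_shape = as.numeric(weibull_shape),
               seed = as.integer(seed))
  class(spec) <- "synthetic_spec"
  spec
}

# Random-censoring rate achieving the target censoring fraction under the
# exponential model with administrative cap A: for subject hazard h and
# censor rate rc, P(censored) = rc/(rc+h)*(1-exp(-(rc+h)A)) + exp(-(rc+h)A).
calibrate_censor_rate <- function(hazards, target, admin_time) {
  p_cens <- function(rc) {
    s <- rc + hazards
    mean(rc / s * (1 - exp(-s * admin_time)) + exp(-s * admin_time))
  }
  if (target <= 0) return(0)
  lo <- 1e-10
  if (p_cens(lo) >= target) return(0)  # administrative censoring alone exceeds target
  hi <- 1
  while (p_cens(hi) < target && hi < 1e6) hi <- hi * 10
  stats::uniroot(function(rc) p_cens(rc) - target, c(lo, hi), tol = 1e-10)$root
}

#' Generate a synthetic cohort with known ground truth
#'
#' Expression model: `x[g,s] = mu_g + stage_shift_g * late_s +
#' tumor_effect_g * tumor_s + loc_b + offset[g,b] + eps`, with
#' `eps ~ N(0, sigma_g * scale_b)`. Survival times are drawn by inverse
#' transform from a proportional-hazards model whose linear predictor is
#' `sum_m beta_m * z[m,s]`, where `z` is the standardized *biological*
#' expression of marker gene `m` (batch artifacts do not enter the hazard).
#' Censoring combines an administrative horizon with a random exponential
#' censoring time calibrated so the total censoring fraction matches
#' `censor_rate` in expectation.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `cohort` (a [cohort()]; normals carry stage
#'   `"normal"` and `NA` survival) and `truth`, a list holding `genes`
#'   (data frame `gene_id`, `role`, `true_beta`, `true_shift`),
#'   `batch_location` (named per-batch location terms), `batch_offsets`
#'   (genes x batches matrix) and `linear_predictor` (per tumor sample).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  ng <- spec$n_genes; ns <- spec$n_samples; nb <- spec$n_batches
  gene_ids <- sprintf("G%05d", seq_len(ng))
  sample_ids <- sprintf("S%05d", seq_len(ns + spec$n_normal))

  idx <- sample.int(ng, spec$n_marker_genes + spec$n_stage_genes)
  marker_idx <- idx[seq_len(spec$n_marker_genes)]
  stage_idx <- idx[spec$n_marker_genes + seq_len(spec$n_stage_genes)]
  stage_shift <- numeric(ng)
  stage_shift[stage_idx] <- spec$stage_effect
  if (spec$markers_stage_shifted) stage_shift[marker_idx] <- spec$stage_effect

  mu <- stats::rnorm(ng, mean = 7, sd = 1)
  sigma <- exp(stats::rnorm(ng, mean = log(0.5), sd = 0.25))
  loc_b <- stats::rnorm(nb, 0, spec$batch_shift_sd)
  offsets <- matrix(stats::rnorm(ng * nb, 0, spec$batch_shift_sd), ng, nb,
                    dimnames = list(gene_ids, paste0("B", seq_len(nb))))
  scale_b <- exp(stats::rnorm(nb, 0, spec$batch_scale_sd))

  batch <- rep(seq_len(nb), times = spec$batch_sizes)
  late <- stats::runif(ns) < spec$frac_late_stage
  stage <- ifelse(late,
                  ifelse(stats::runif(ns) < 0.5, "III", "IV"),
                  ifelse(stats::runif(ns) < 0.5, "I", "II"))

  tumor_up <- numeric(ng)
  tumor_up[c(marker_idx, stage_idx)] <- spec$tumor_effect

  # eps ~ N(0, sigma_g * scale_b): per-gene noise, inflated/deflated per batch
  eps <- matrix(stats::rnorm(ng * ns), ng, ns) * outer(sigma, scale_b[batch])
  # batch-free component: drives the hazard (batch artifacts are technical)
  bio <- mu + outer(stage_shift, as.numeric(late)) + tumor_up + eps
  expr <- bio + offsets[, batch, drop = FALSE] + rep(loc_b[batch], each = ng)

  eta <- rep(0, ns)
  if (spec$n_marker_genes > 0) {
    z <- bio[marker_idx, , drop = FALSE]
    z <- (z - rowMeans(z)) / apply(z, 1L, stats::sd)
    eta <- as.numeric(crossprod(z, spec$marker_beta))
  }
  haz <- spec$baseline_hazard * exp(eta)
  u <- stats::runif(ns)
  t_event <- (-log(u) / haz)^(1 / spec$weibull_shape)
  rc <- calibrate_censor_rate(haz, spec$censor_rate, spec$admin_censor_time)
  t_cens <- if (rc > 0) stats::rexp(ns, rate = rc) else rep(Inf, ns)
  t_cens <- pmin(t_cens, spec$admin_censor_time)
  os_time <- pmin(t_event, t_cens)
  os_event <- as.numeric(t_event <= t_cens)

  pheno <- data.frame(sample_id = sample_ids[seq_len(ns)],
                      batch_id = paste0("B", batch),
                      stage = stage, os_time = os_time, os_event = os_event,
                      stringsAsFactors = FALSE)

  if (spec$n_normal > 0) {
    nn <- spec$n_normal
    nbatch <- sample(seq_len(nb), nn, replace = TRUE)
    neps <- matrix(stats::rnorm(ng * nn), ng, nn) * sigma
    nexpr <- mu + neps + offsets[, nbatch, drop = FALSE] +
      rep(loc_b[nbatch], each = ng)
    expr <- cbind(expr, nexpr)
    pheno <- rbind(pheno, data.frame(
      sample_id = sample_ids[ns + seq_len(nn)],
      batch_id = paste0("B", nbatch), stage = "normal",
      os_time = NA_real_, os_event = NA_real_, stringsAsFactors = FALSE))
  }
  dimnames(expr) <- list(gene_ids, pheno$sample_id)

  role <- rep("null", ng)
  role[stage_idx] <- "stage"
  role[marker_idx] <- if (spec$markers_stage_shifted) "marker_stage" else "marker"
  true_beta <- numeric(ng)
  true_beta[marker_idx] <- spec$marker_beta
  truth_genes <- data.frame(gene_id = gene_ids, role = role,
                            true_beta = true_beta, true_shift = stage_shift,
                            stringsAsFactors = FALSE)
  names(loc_b) <- colnames(offsets)
  list(cohort = cohort(expr, pheno),
       truth = list(genes = truth_genes, batch_location = loc_b,
                    batch_offsets = offsets, linear_predictor = eta,
                    censor_rate_used = rc))
}

#' Write a ground-truth table alongside a simulated cohort
#' @param truth The `truth` element returned by [generate_cohort()].
#' @param path Output TSV path (columns `gene_id`, `role`, `true_beta`,
#'   `true_shift`).
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(truth$genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(truth)
}
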