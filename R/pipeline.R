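#' Pipeline configuration
#'
#' Collects the thresholds and sizes of the full screening pipeline. The
#' defaults are the study settings: batch regression alpha 0.05, stage-DE
#' FDR 0.01, screen adjusted-p cut 3e-4, 100 resampling iterations at 80%
#' with retain threshold 80, top 100 genes into the risk model, 10 CV folds.
#'
#' @param batch_method `"mean_center"`, `"eb"` or `"none"`.
#' @param batch_alpha Batch-factor significance level.
#' @param de_fdr Stage-contrast FDR threshold.
#' @param screen_p_adj_cut Screen adjusted-p threshold.
#' @param resample_frac,resample_iter,retain_min Stability-resampling
#'   settings.
#' @param top_k Genes entering the risk model.
#' @param folds CV folds for lambda and threshold selection.
#' @param seed Master seed; each stage draws from a named substream.
#' @param stability_genes Number of top screened genes carried into the
#'   stability stage (default 200, the top markers of both directions).
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(batch_method = c("mean_center", "eb", "none"),
                            batch_alpha = 0.05, de_fdr = 0.01,
                            screen_p_adj_cut = 3e-4, resample_frac = 0.8,
                            resample_iter = 100, retain_min = 80,
                            top_k = 100, folds = 10, seed = 1,
                            stability_genes = 200) {
  batch_method <- match.arg(batch_method)
  cfg <- list(batch_method = batch_method,
              batch_alpha = check_fraction(batch_alpha, "batch_alpha"),
              de_fdr = check_fraction(de_fdr, "de_fdr"),
              screen_p_adj_cut = check_fraction(screen_p_adj_cut, "screen_p_adj_cut"),
              resample_frac = check_fraction(resample_frac, "resample_frac"),
              resample_iter = check_count(resample_iter, "resample_iter"),
              retain_min = check_count(retain_min, "retain_min", min = 0L),
              top_k = check_count(top_k, "top_k", min = 2L),
              folds = check_count(folds, "folds", min = 2L),
              seed = as.integer(seed),
              stability_genes = check_count(stability_genes, "stability_genes"))
  if (cfg$batch_alpha <= 0 || cfg$batch_alpha >= 1) stop("'batch_alpha' must be in (0, 1)")
  if (cfg$de_fdr <= 0 || cfg$de_fdr >= 1) stop("'de_fdr' must be in (0, 1)")
  if (cfg$screen_p_adj_cut <= 0 || cfg$screen_p_adj_cut >= 1) {
    stop("'screen_p_adj_cut' must be in (0, 1)")
  }
  if (cfg$resample_frac <= 0) stop("'resample_frac' must be in (0, 1]")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a key = value pipeline config file
#'
#' Plain-text format, one `key = value` per line, `#` comments allowed;
#' keys are the arguments of [pipeline_config()].
#'
#' @param path File path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1L]])
  keys <- vapply(kv, `[[`, character(1), 1L)
  vals <- vapply(kv, `[[`, character(1), 2L)
  args <- as.list(vals)
  names(args) <- keys
  known <- names(formals(pipeline_config))
  unknown <- setdiff(keys, known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  num <- suppressWarnings(lapply(args, function(v) {
    x <- as.numeric(v); if (is.na(x)) v else x
  }))
  do.call(pipeline_config, num)
}

#' Run the full screening pipeline
#'
#' Executes the study's stage order on a survival-ready cohort: batch
#' integration, diagnostics, stage-contrast differential expression,
#' optimal-cutpoint screen, stability resampling, marker ranking, and the
#' L1 Cox risk model with cross-validated threshold. All artifacts are
#' returned in memory and, when `out_dir` is given, written as TSVs.
#' Re-running with identical inputs and config is bit-identical.
#'
#' @param c A [cohort()] (normals and samples without survival data are
#'   filtered out at the first stage).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for the stage TSVs.
#' @return List of class `"pipeline_result"` with `manifest`, `cohort`
#'   (corrected), `diagnostics` (regression and mixing reports before and
#'   after correction), `de`, `screen`, `stability`, `ranking`,
#'   `risk_model`, and `config`.
#' @export
run_pipeline <- function(c, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(c, "cohort"), inherits(config, "pipeline_config"))
  seed <- config$seed

  fl <- filter_for_survival(c)
  ch <- fl$cohort
  ss_log("stage integrate: ", ncol(ch$expr), " samples, method ", config$batch_method)
  reg_before <- batch_factor_regression(ch, alpha = config$batch_alpha)
  mix_before <- mixing_diagnostics(ch, seed = substream(seed, "diagnose"))
  ch <- switch(config$batch_method,
               mean_center = mean_center_by_batch(ch),
               eb = eb_location_scale_adjust(ch),
               none = ch)
  reg_after <- batch_factor_regression(ch, alpha = config$batch_alpha)
  mix_after <- mixing_diagnostics(ch, seed = substream(seed, "diagnose"))

  de <- stage_contrast(ch, fdr = config$de_fdr)
  sig <- split_by_direction(de)
  de_genes <- c(sig$up_late, sig$down_late)
  ss_log("stage de: ", length(de_genes), " significant genes at FDR ", config$de_fdr)
  screen_universe <- if (length(de_genes) >= 10L) de_genes else de$gene_id
  if (length(de_genes) < 10L) {
    ss_log("fewer than 10 stage-DE genes; screening all genes instead")
  }

  scr <- screen_genes(ch, screen_universe, p_adj_cut = config$screen_p_adj_cut)
  ss_log("stage screen: ", sum(scr$significant), " significant of ",
         nrow(scr), " screened genes")
  stab_genes <- utils::head(scr$gene_id, config$stability_genes)
  stab <- stability_resample(ch, stab_genes, frac = config$resample_frac,
                             n_iter = config$resample_iter,
                             p_adj_cut = config$screen_p_adj_cut,
                             retain_min = config$retain_min,
                             seed = substream(seed, "stabilize"))
  ranking <- rank_markers(scr, stab)

  risk_genes <- utils::head(ranking$up_poor$gene_id, config$top_k)
  model <- NULL
  if (length(risk_genes) >= 2L) {
    model <- fit_l1_cox(ch, risk_genes, folds = config$folds,
                        seed = substream(seed, "risk"))
    model <- score_and_threshold(model, ch, folds = config$folds,
                                 seed = substream(seed, "threshold"))
    ss_log(sprintf("stage risk: %d high / %d low, log-rank p %.3g",
                   model$n_high, model$n_low, model$separation$logrank_p))
  } else {
    ss_log("stage risk skipped: fewer than 2 ranked up_poor genes")
  }

  res <- structure(list(manifest = fl$manifest, cohort = ch,
                        diagnostics = list(regression_before = reg_before,
                                           regression_after = reg_after,
                                           mixing_before = mix_before,
                                           mixing_after = mix_after),
                        de = de, screen = scr, stability = stab,
                        ranking = ranking, risk_model = model,
                        config = config),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

#' Write pipeline artifacts as TSVs
#' @param res A [run_pipeline()] result.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the result.
#' @export
write_pipeline_result <- function(res, out_dir) {
  stopifnot(inherits(res, "pipeline_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) utils::write.table(d, file.path(out_dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(res$manifest, "manifest.tsv")
  wt(res$diagnostics$regression_before, "batch_regression_before.tsv")
  wt(res$diagnostics$regression_after, "batch_regression_after.tsv")
  mix <- rbind(data.frame(stage = "before",
                          purity = res$diagnostics$mixing_before$clustering_purity,
                          silhouette = res$diagnostics$mixing_before$pca_silhouette),
               data.frame(stage = "after",
                          purity = res$diagnostics$mixing_after$clustering_purity,
                          silhouette = res$diagnostics$mixing_after$pca_silhouette))
  wt(mix, "mixing_report.tsv")
  wt(as.data.frame(res$de), "de_result.tsv")
  wt(as.data.frame(res$screen), "marker_screen.tsv")
  wt(as.data.frame(res$stability), "stability.tsv")
  wt(res$ranking$up_poor, "ranking_up_poor.tsv")
  wt(res$ranking$up_good, "ranking_up_good.tsv")
  if (!is.null(res$risk_model)) {
    write_risk_model(res$risk_model, file.path(out_dir, "risk_model.tsv"))
    wt(export_betas(res$risk_model), "risk_betas.tsv")
    wt(data.frame(sample_id = names(res$risk_model$groups),
                  group = res$risk_model$groups,
                  stringsAsFactors = FALSE), "risk_groups.tsv")
    sep <- res$risk_model$separation
    wt(data.frame(n_high = res$risk_model$n_high, n_low = res$risk_model$n_low,
                  logrank_chi_sq = sep$logrank_chi_sq, logrank_p = sep$logrank_p,
                  hr = sep$hr, hr_lo = sep$hr_ci95[1L, "lo"],
                  hr_hi = sep$hr_ci95[1L, "hi"]), "risk_separation.tsv")
  }
  invisible(res)
}
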