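#' Fit an L1-penalized multivariate Cox risk model
#'
#' Standardizes the selected genes' expression (training mean/SD) and
#' maximizes the L1-penalized Cox partial likelihood over a lambda path,
#' choosing lambda by k-fold cross-validated partial likelihood. The
#' resulting coefficient vector is typically sparse; the risk score of a
#' sample is `sum(beta * standardized expression)`.
#'
#' @param c A [cohort()] with complete survival data.
#' @param genes Gene ids entering the model (at least 2); by convention the
#'   top-ranked genes whose up-regulation marks poor survival.
#' @param lambda_grid Optional decreasing lambda sequence (default: the
#'   automatic path).
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed controlling the fold assignment.
#' @param lambda_fixed Optional: skip cross-validation and fit at this
#'   penalty (0 gives the unpenalized multivariate Cox solution).
#' @return List of class `"risk_model"`: `gene_ids`, `beta` (named, many
#'   exactly 0), `lambda`, `center`, `scale`, `cv_folds`, and placeholders
#'   `threshold`/`separation` filled by [score_and_threshold()].
#' @export
fit_l1_cox <- function(c, genes, lambda_grid = NULL, folds = 10, seed = 1,
                       lambda_fixed = NULL) {
  stopifnot(inherits(c, "cohort"))
  folds <- check_count(folds, "folds", min = 2L)
  if (length(genes) < 2L) stop("at least 2 genes are required for the L1 Cox fit")
  missing <- setdiff(genes, rownames(c$expr))
  if (length(missing)) stop("gene(s) not present: ", paste(utils::head(missing, 5), collapse = ", "))
  ph <- c$pheno
  if (any(is.na(ph$os_time)) || any(is.na(ph$os_event))) {
    stop("cohort has samples without survival data; run filter_for_survival() first")
  }
  X <- t(c$expr[genes, , drop = FALSE])
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  if (any(scl == 0)) stop("degenerate covariate (constant gene): ",
                          genes[which(scl == 0)[1L]])
  Z <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  y <- survival::Surv(ph$os_time, ph$os_event)
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(folds), nrow(Z)))
  if (!is.null(lambda_fixed)) {
    # fit along a short path ending at the requested penalty (glmnet is
    # more stable entering a small lambda via warm starts)
    path <- sort(unique(c(lambda_fixed, lambda_fixed + c(0.5, 0.1, 0.02))),
                 decreasing = TRUE)
    fit <- glmnet::glmnet(Z, y, family = "cox", lambda = path,
                          standardize = FALSE, thresh = 1e-12)
    lam <- lambda_fixed
    beta <- as.numeric(stats::coef(fit, s = lam, exact = FALSE))
  } else {
    cv <- glmnet::cv.glmnet(Z, y, family = "cox", foldid = foldid,
                            lambda = lambda_grid, standardize = FALSE,
                            thresh = 1e-10)
    lam <- cv$lambda.min
    beta <- as.numeric(stats::coef(cv, s = lam))
  }
  if (all(beta == 0)) warning("all coefficients shrunk to zero: empty support")
  structure(list(gene_ids = genes, beta = setNames(beta, genes),
                 lambda = lam, center = setNames(ctr, genes),
                 scale = setNames(scl, genes), cv_folds = folds,
                 threshold = NA_real_, separation = NULL,
                 groups = NULL),
            class = "risk_model")
}

#' Risk scores for a cohort under a fitted model
#'
#' @param model A [fit_l1_cox()] result.
#' @param c A [cohort()] containing the model's genes.
#' @return Named numeric vector of per-sample risk scores.
#' @export
risk_score <- function(model, c) {
  stopifnot(inherits(model, "risk_model"), inherits(c, "cohort"))
  missing <- setdiff(model$gene_ids, rownames(c$expr))
  if (length(missing)) stop("cohort lacks model gene(s): ", paste(utils::head(missing, 5), collapse = ", "))
  Z <- (c$expr[model$gene_ids, , drop = FALSE] - model$center) / model$scale
  setNames(as.numeric(crossprod(Z, model$beta)), colnames(c$expr))
}

#' Cross-validated risk-score threshold and two-group stratification
#'
#' Candidate thresholds are a 41-point grid of training-score percentiles
#' (10% to 90%). For each CV fold and candidate, the held-out samples are
#' split at the candidate and their log-rank chi-square is recorded
#' (candidates leaving an empty group or an event-free group in a fold are
#' skipped for that fold). The threshold maximizing the fold-averaged
#' chi-square wins; the grid is then re-laid between the neighbors of the
#' argmax and the search repeated `refine_rounds` times. The final high/low
#' groups, log-rank separation and Cox hazard ratio are computed on the
#' full cohort.
#'
#' @param model A [fit_l1_cox()] result.
#' @param c The training [cohort()].
#' @param folds CV folds (default 10).
#' @param refine_rounds Refinement passes after the initial grid
#'   (default 1).
#' @param seed Integer seed for the fold assignment.
#' @param grid_points Candidates per pass (default 41).
#' @return The model with `threshold`, `groups` (named character vector
#'   `"high"`/`"low"`), `n_high`, `n_low` and `separation` (list:
#'   `logrank_chi_sq`, `logrank_p`, `hr`, `hr_ci95`) filled in.
#' @export
score_and_threshold <- function(model, c, folds = 10, refine_rounds = 1,
                                seed = 1, grid_points = 41) {
  stopifnot(inherits(model, "risk_model"), inherits(c, "cohort"))
  folds <- check_count(folds, "folds", min = 2L)
  refine_rounds <- check_count(refine_rounds, "refine_rounds", min = 0L)
  grid_points <- check_count(grid_points, "grid_points", min = 3L)
  scores <- risk_score(model, c)
  if (stats::sd(scores) == 0) stop("constant risk score, no threshold")
  ph <- c$pheno
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(folds), length(scores)))

  eval_grid <- function(cand) {
    stat <- matrix(NA_real_, length(cand), folds)
    for (f in seq_len(folds)) {
      ho <- foldid == f
      t_ho <- ph$os_time[ho]; e_ho <- ph$os_event[ho]; s_ho <- scores[ho]
      for (i in seq_along(cand)) {
        hi <- s_ho > cand[i]
        if (!any(hi) || all(hi)) next
        if (sum(e_ho) < 1) next
        lr <- tryCatch(logrank_test(t_ho, e_ho, hi), error = function(e) NULL)
        if (!is.null(lr)) stat[i, f] <- lr$chi_sq
      }
    }
    rowMeans(stat, na.rm = TRUE)
  }

  lo <- stats::quantile(scores, 0.10, names = FALSE)
  hi <- stats::quantile(scores, 0.90, names = FALSE)
  cand <- stats::quantile(scores, seq(0.10, 0.90, length.out = grid_points),
                          names = FALSE)
  for (round in seq_len(refine_rounds + 1L)) {
    val <- eval_grid(cand)
    if (all(!is.finite(val))) stop("no admissible threshold candidate")
    best <- which.max(val)
    thr <- cand[best]
    if (round <= refine_rounds) {
      lo <- cand[max(1L, best - 1L)]
      hi <- cand[min(length(cand), best + 1L)]
      cand <- seq(lo, hi, length.out = grid_points)
    }
  }
  high <- scores > thr
  lr <- logrank_test(ph$os_time, ph$os_event, high)
  grp <- cox_fit(ph$os_time, ph$os_event, as.numeric(high), ties = "efron")
  model$threshold <- thr
  model$groups <- setNames(ifelse(high, "high", "low"), names(scores))
  model$n_high <- sum(high)
  model$n_low <- sum(!high)
  model$separation <- list(logrank_chi_sq = lr$chi_sq, logrank_p = lr$p,
                           hr = grp$hr, hr_ci95 = grp$ci95)
  model
}

#' Export the per-gene coefficients of a risk model
#'
#' @param model A [fit_l1_cox()] result.
#' @return Data frame ordered by |beta| rank (ties broken by gene id):
#'   `gene_id`, `beta`, `abs_rank`, `is_zero`.
#' @export
export_betas <- function(model) {
  stopifnot(inherits(model, "risk_model"))
  d <- data.frame(gene_id = model$gene_ids, beta = as.numeric(model$beta),
                  stringsAsFactors = FALSE)
  d <- d[order(-abs(d$beta), d$gene_id), , drop = FALSE]
  d$abs_rank <- seq_len(nrow(d))
  d$is_zero <- d$beta == 0
  rownames(d) <- NULL
  d
}

#' Serialize / restore a risk model as plain text
#'
#' The model is written as a TSV (columns `gene_id`, `beta`, `mean`, `sd`)
#' preceded by `#`-prefixed header lines carrying `lambda` and `threshold`.
#'
#' @param model A [fit_l1_cox()] result.
#' @param path File path.
#' @return `write_risk_model` the model invisibly; `read_risk_model` the
#'   restored `"risk_model"` object.
#' @export
write_risk_model <- function(model, path) {
  stopifnot(inherits(model, "risk_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# lambda=%.17g", model$lambda), con)
  writeLines(sprintf("# threshold=%.17g", model$threshold), con)
  d <- data.frame(gene_id = model$gene_ids, beta = as.numeric(model$beta),
                  mean = as.numeric(model$center), sd = as.numeric(model$scale))
  utils::write.table(format(d, digits = 17, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(model)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    v <- sub(paste0("^# ", key, "="), "", grep(paste0("^# ", key, "="), hdr, value = TRUE))
    if (length(v)) as.numeric(v) else NA_real_
  }
  d <- utils::read.delim(textConnection(lines[!grepl("^#", lines)]),
                         stringsAsFactors = FALSE)
  structure(list(gene_ids = d$gene_id,
                 beta = setNames(as.numeric(d$beta), d$gene_id),
                 lambda = get("lambda"),
                 center = setNames(as.numeric(d$mean), d$gene_id),
                 scale = setNames(as.numeric(d$sd), d$gene_id),
                 cv_folds = NA_integer_, threshold = get("threshold"),
                 separation = NULL, groups = NULL),
            class = "risk_model")
}
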