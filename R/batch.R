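#' Mean-center expression within each batch
#'
#' For every gene, each batch's values are shifted so the within-batch mean
#' equals the gene's global (pre-correction) mean. A pure location
#' adjustment: values are otherwise unchanged.
#'
#' @param c A [cohort()].
#' @return The corrected cohort.
#' @export
mean_center_by_batch <- function(c) {
  stopifnot(inherits(c, "cohort"))
  batch <- c$pheno$batch_id
  sizes <- table(batch)
  if (any(sizes < 2)) {
    stop("singleton batch cannot be mean-centered: ",
         names(sizes)[which(sizes < 2)[1L]])
  }
  X <- c$expr
  bm <- t(rowsum(t(X), batch) / as.vector(sizes[sort(unique(batch))]))
  # rowsum orders groups by sort(unique); index by name to be safe
  corrected <- X - bm[, batch, drop = FALSE] + rowMeans(X)
  c$expr <- corrected
  c
}

#' Empirical-Bayes location/scale batch adjustment
#'
#' Per-gene per-batch location and scale parameters are estimated on the
#' pooled-standardized data, shrunk toward batch-level priors by parametric
#' empirical Bayes (normal prior for locations, inverse-gamma for scales,
#' moment-matched), and removed. Genes with zero variance within some batch
#' get a location-only adjustment (scale step skipped, logged); an
#' all-constant gene is returned unchanged.
#'
#' @param c A [cohort()].
#' @param shrink If `FALSE` the prior weight is dropped and the adjustment
#'   degenerates to exact per-gene per-batch standardization (rescaled to
#'   the pooled gene moments).
#' @return The corrected cohort.
#' @export
eb_location_scale_adjust <- function(c, shrink = TRUE) {
  stopifnot(inherits(c, "cohort"))
  batch <- factor(c$pheno$batch_id)
  nb <- nlevels(batch)
  if (nb < 2L) return(c)
  sizes <- as.vector(table(batch))
  if (any(sizes < 2)) {
    stop("singleton batch cannot be adjusted: ", levels(batch)[which(sizes < 2)[1L]])
  }
  X <- c$expr
  n <- ncol(X)
  bidx <- as.integer(batch)

  B_hat <- t(rowsum(t(X), bidx) / sizes)          # genes x batches means
  grand <- as.numeric(B_hat %*% (sizes / n))
  resid <- X - B_hat[, bidx, drop = FALSE]
  var_pooled <- rowSums(resid^2) / n
  const_gene <- var_pooled <= 0
  if (any(const_gene)) ss_log(sum(const_gene), " constant gene(s) left unadjusted")

  sd_pooled <- sqrt(pmax(var_pooled, .Machine$double.eps))
  Z <- (X - grand) / sd_pooled

  gamma_hat <- t(rowsum(t(Z), bidx) / sizes)
  delta2_hat <- t(rowsum(t((Z - gamma_hat[, bidx, drop = FALSE])^2), bidx) /
                    (sizes - 1))
  zero_scale <- apply(delta2_hat, 1L, function(v) any(v <= 0))
  if (any(zero_scale & !const_gene)) {
    ss_log(sum(zero_scale & !const_gene),
           " gene(s) with a zero-variance batch: scale adjustment skipped")
  }

  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  if (shrink) {
    for (b in seq_len(nb)) {
      g_hat <- gamma_hat[, b]
      d_hat <- delta2_hat[, b]
      ok <- !zero_scale & !const_gene
      g_bar <- mean(g_hat[ok]); tau2 <- stats::var(g_hat[ok])
      m <- mean(d_hat[ok]); s2 <- stats::var(d_hat[ok])
      a_prior <- (2 * s2 + m^2) / s2
      b_prior <- (m * s2 + m^3) / s2
      nb_s <- sizes[b]
      Zb <- Z[, bidx == b, drop = FALSE]
      g_new <- g_hat; d_new <- d_hat
      for (it in seq_len(100L)) {
        g_old <- g_new; d_old <- d_new
        g_new <- (nb_s * tau2 * g_hat + d_old * g_bar) / (nb_s * tau2 + d_old)
        ss2 <- rowSums((Zb - g_new)^2)
        d_new <- (b_prior + 0.5 * ss2) / (nb_s / 2 + a_prior - 1)
        chg <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                   abs(d_new - d_old) / pmax(abs(d_old), 1e-12))
        if (chg < 1e-4) break
      }
      gamma_star[, b] <- g_new
      delta2_star[, b] <- d_new
    }
  }
  delta2_star[zero_scale | const_gene, ] <- 1  # location-only for degenerate genes
  adj <- (Z - gamma_star[, bidx, drop = FALSE]) /
    sqrt(delta2_star)[, bidx, drop = FALSE] * sd_pooled + grand
  adj[const_gene, ] <- X[const_gene, ]
  dimnames(adj) <- dimnames(X)
  c$expr <- adj
  c
}

#' Batch-factor regression diagnostic
#'
#' Ordinary least squares of the per-sample mean expression (over all
#' genes) on an intercept plus batch dummy variables, the first batch (in
#' order of appearance, or `reference`) folded into the intercept. A factor
#' whose p-value falls below `alpha` is flagged as a remaining batch
#' effect; `alpha_marginal` flags marginally significant factors without
#' affecting decisions.
#'
#' @param c A [cohort()].
#' @param alpha Significance level for the effect flag (default 0.05).
#' @param alpha_marginal Secondary, looser level reported per factor.
#' @param reference Reference batch id (default: first in order of
#'   appearance).
#' @return Data frame of class `"batch_regression"` with one row per
#'   term (intercept first): `factor_id`, `estimate`, `std_error`,
#'   `t_value`, `p_value`, `effect_flag` (`"yes"`/`"no"`; `NA` for the
#'   intercept) and `marginal_flag`. Attributes `reference_batch`, `alpha`.
#' @export
batch_factor_regression <- function(c, alpha = 0.05, alpha_marginal = 0.20,
                                    reference = NULL) {
  stopifnot(inherits(c, "cohort"))
  batch <- c$pheno$batch_id
  lv <- unique(batch)
  if (length(lv) < 2L) stop("at least two batches are required")
  if (is.null(reference)) reference <- lv[1L]
  if (!reference %in% lv) stop("reference batch not present: ", reference)
  f <- factor(batch, levels = c(reference, setdiff(lv, reference)))
  if (any(table(f) == 0)) stop("collinear design: empty batch level")
  y <- colMeans(c$expr)
  fit <- stats::lm(y ~ f)
  sm <- summary(fit)$coefficients
  terms <- c("(Intercept)", levels(f)[-1L])
  out <- data.frame(factor_id = terms,
                    estimate = sm[, 1L], std_error = sm[, 2L],
                    t_value = sm[, 3L], p_value = sm[, 4L],
                    stringsAsFactors = FALSE)
  out$effect_flag <- ifelse(out$p_value < alpha, "yes", "no")
  out$marginal_flag <- ifelse(out$p_value < alpha_marginal, "yes", "no")
  out$effect_flag[1L] <- NA_character_
  out$marginal_flag[1L] <- NA_character_
  rownames(out) <- NULL
  attr(out, "reference_batch") <- reference
  attr(out, "alpha") <- alpha
  attr(out, "alpha_marginal") <- alpha_marginal
  class(out) <- c("batch_regression", "data.frame")
  out
}

#' Batch-mixing diagnostics (clustering purity and PCA silhouette)
#'
#' On a balanced random subsample (`per_batch` samples per batch), computes
#' (i) average-linkage hierarchical clustering of samples under the
#' 1 - Pearson-correlation distance of whole expression profiles, cut at
#' K = number of batches, summarized as *clustering purity* (fraction of
#' samples whose cluster is dominated by their own batch); and (ii) the
#' mean silhouette width of the batch labels on the first two principal
#' components of the gene-centered matrix. Well-mixed batches give low
#' purity and near-zero silhouette.
#'
#' @param c A [cohort()].
#' @param per_batch Samples drawn per batch (default 30; lowered to the
#'   smallest batch size when necessary, with a log line).
#' @param seed Integer seed for the subsample.
#' @return List of class `"mixing_report"` with `clustering_purity`,
#'   `pca_silhouette`, `subsample_size_per_batch` and `n_batches`.
#' @export
mixing_diagnostics <- function(c, per_batch = 30, seed = 1) {
  stopifnot(inherits(c, "cohort"))
  batch <- c$pheno$batch_id
  lv <- unique(batch)
  nb <- length(lv)
  if (nb < 2L) stop("at least two batches are required")
  per_batch <- check_count(per_batch, "per_batch")
  min_size <- min(table(batch))
  if (per_batch > min_size) {
    ss_log("per_batch lowered from ", per_batch, " to smallest batch size ", min_size)
    per_batch <- min_size
  }
  set.seed(seed)
  # draw over id-sorted samples so the report is invariant to column order
  ids <- colnames(c$expr)
  sel <- unlist(lapply(lv, function(b) sample(sort(ids[batch == b]), per_batch)))
  X <- c$expr[, sel, drop = FALSE]
  lab <- factor(batch[match(sel, ids)], levels = lv)

  D <- 1 - stats::cor(X)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  cl <- stats::cutree(hc, k = nb)
  dominant <- vapply(split(as.integer(lab), cl), function(v) {
    as.integer(names(which.max(table(v))))
  }, integer(1))
  purity <- mean(dominant[as.character(cl)] == as.integer(lab))

  Xc <- X - rowMeans(X)
  sv <- svd(t(Xc), nu = 2L, nv = 0L)
  coords <- sv$u[, 1:2, drop = FALSE] * rep(sv$d[1:2], each = nrow(sv$u))
  sil <- cluster::silhouette(as.integer(lab), stats::dist(coords))
  structure(list(clustering_purity = purity,
                 pca_silhouette = mean(sil[, "sil_width"]),
                 subsample_size_per_batch = per_batch, n_batches = nb),
            class = "mixing_report")
}

#' @export
print.mixing_report <- function(x, ...) {
  cat(sprintf("mixing report: purity %.3f, PCA silhouette %.3f (%d/batch, %d batches)\n",
              x$clustering_purity, x$pca_silhouette,
              x$subsample_size_per_batch, x$n_batches))
  invisible(x)
}
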