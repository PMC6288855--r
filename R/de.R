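#' Stage-contrast differential expression (early vs late)
#'
#' Two-group moderated differential expression of late-stage (III/IV)
#' versus early-stage (I/II) tumors. Per-gene linear models are fit and
#' residual variances are shrunk toward a common prior by empirical Bayes
#' (prior df `d0` and prior variance `s0^2` estimated by moment matching on
#' the log sample variances), giving a moderated t with `d0 + d_g` degrees
#' of freedom; p-values are Benjamini-Hochberg adjusted.
#'
#' @param c A [cohort()]; samples with stage `NA` or `"normal"` are ignored.
#' @param fdr Adjusted-p threshold defining the significant set
#'   (default 0.01).
#' @return Data frame of class `"de_result"`, one row per gene: `gene_id`,
#'   `log_fc` (late minus early, log2), `t_moderated`, `p_value`,
#'   `p_adjusted`, `direction` (`"up_late"`/`"down_late"`), `significant`.
#'   Attributes: `d0`, `s0_sq`, `contrast`, `fdr`, `n_early`, `n_late`.
#' @export
stage_contrast <- function(c, fdr = 0.01) {
  stopifnot(inherits(c, "cohort"))
  check_fraction(fdr, "fdr")
  st <- c$pheno$stage
  early <- !is.na(st) & st %in% c("I", "II")
  late <- !is.na(st) & st %in% c("III", "IV")
  if (sum(early) < 2L || sum(late) < 2L) {
    stop("each stage group needs at least 2 samples (early: ",
         sum(early), ", late: ", sum(late), ")")
  }
  keep <- early | late
  X <- c$expr[, keep, drop = FALSE]
  design <- cbind(intercept = 1, late = as.numeric(late[keep]))
  fit <- limma::eBayes(limma::lmFit(X, design))
  out <- data.frame(gene_id = rownames(X),
                    log_fc = fit$coefficients[, "late"],
                    t_moderated = fit$t[, "late"],
                    p_value = fit$p.value[, "late"],
                    stringsAsFactors = FALSE)
  out$p_adjusted <- bh_adjust(out$p_value)
  out$direction <- ifelse(out$log_fc > 0, "up_late", "down_late")
  out$significant <- out$p_adjusted <= fdr
  rownames(out) <- NULL
  attr(out, "d0") <- fit$df.prior
  attr(out, "s0_sq") <- fit$s2.prior
  attr(out, "contrast") <- "late_vs_early"
  attr(out, "fdr") <- fdr
  attr(out, "n_early") <- sum(early)
  attr(out, "n_late") <- sum(late)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Moderated two-group t-statistics with explicit shrinkage weights
#'
#' Reference implementation of the moderated t used for checking limits:
#' with `d0 = 0` it reduces exactly to the ordinary pooled-variance t;
#' as `d0 -> Inf` the statistic uses the prior variance `s0_sq` alone.
#'
#' @param x_early,x_late Numeric matrices (genes x samples per group).
#' @param d0 Prior degrees of freedom (may be `Inf`).
#' @param s0_sq Prior variance.
#' @return Data frame with `log_fc`, `t`, `df`, `p_value`.
#' @export
moderated_t <- function(x_early, x_late, d0, s0_sq) {
  stopifnot(nrow(x_early) == nrow(x_late))
  n1 <- ncol(x_early); n2 <- ncol(x_late)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")
  m1 <- rowMeans(x_early); m2 <- rowMeans(x_late)
  ss <- rowSums((x_early - m1)^2) + rowSums((x_late - m2)^2)
  dg <- n1 + n2 - 2L
  s2 <- ss / dg
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else {
    (d0 * s0_sq + dg * s2) / (d0 + dg)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tt <- (m2 - m1) / se
  df <- if (is.infinite(d0)) Inf else d0 + dg
  data.frame(log_fc = m2 - m1, t = tt, df = df,
             p_value = 2 * stats::pt(-abs(tt), df = df))
}

#' Partition significant genes by direction of change
#'
#' @param de A [stage_contrast()] result.
#' @param annotation Optional data frame with a `gene_id` column (e.g. the
#'   protein-coding genes); when supplied, the lists are restricted to the
#'   annotated genes.
#' @return List with character vectors `up_late` and `down_late`.
#' @export
split_by_direction <- function(de, annotation = NULL) {
  stopifnot(inherits(de, "de_result"))
  sig <- de[de$significant, , drop = FALSE]
  if (!is.null(annotation)) {
    if (!"gene_id" %in% names(annotation)) stop("annotation needs a 'gene_id' column")
    sig <- sig[sig$gene_id %in% annotation$gene_id, , drop = FALSE]
  }
  list(up_late = sig$gene_id[sig$direction == "up_late"],
       down_late = sig$gene_id[sig$direction == "down_late"])
}

#' Repeated tumor-versus-normal expression comparison
#'
#' For each repeat, a random subset of `n_per_group` tumor samples is
#' compared against the `n_per_group` normal-tissue samples, gene by gene:
#' group medians and quartiles plus a Wilcoxon rank-sum p-value. The
#' summary reports, per gene, the fraction of repeats in which the tumor
#' median exceeded the normal median.
#'
#' @param c A [cohort()] containing samples with stage `"normal"`.
#' @param genes Gene ids to compare.
#' @param n_per_group Samples per group (default 25).
#' @param repeats Number of random tumor subsets (default 20).
#' @param seed Integer seed.
#' @return List with `summary` (per gene: `gene_id`, `frac_tumor_higher`,
#'   `median_p`) and `panels` (long data frame, one row per gene and
#'   repeat with medians, quartiles and `p_value`).
#' @export
tumor_vs_normal_panels <- function(c, genes, n_per_group = 25, repeats = 20,
                                   seed = 1) {
  stopifnot(inherits(c, "cohort"))
  n_per_group <- check_count(n_per_group, "n_per_group")
  repeats <- check_count(repeats, "repeats")
  st <- c$pheno$stage
  normal_idx <- which(!is.na(st) & st == "normal")
  tumor_idx <- which(!is.na(st) & st != "normal")
  if (length(normal_idx) < n_per_group) {
    stop(sprintf("too few normal samples: %d available, %d required",
                 length(normal_idx), n_per_group))
  }
  if (length(tumor_idx) < n_per_group) {
    stop(sprintf("too few tumor samples: %d available, %d required",
                 length(tumor_idx), n_per_group))
  }
  genes <- intersect(genes, rownames(c$expr))
  if (!length(genes)) stop("none of the requested genes are present")
  set.seed(seed)
  normal_use <- if (length(normal_idx) > n_per_group) {
    sample(normal_idx, n_per_group)
  } else normal_idx
  rows <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    tum <- sample(tumor_idx, n_per_group)
    Xt <- c$expr[genes, tum, drop = FALSE]
    Xn <- c$expr[genes, normal_use, drop = FALSE]
    qs_t <- t(apply(Xt, 1L, stats::quantile, probs = c(0.25, 0.5, 0.75)))
    qs_n <- t(apply(Xn, 1L, stats::quantile, probs = c(0.25, 0.5, 0.75)))
    pv <- vapply(seq_along(genes), function(i) {
      stats::wilcox.test(Xt[i, ], Xn[i, ], exact = FALSE)$p.value
    }, numeric(1))
    rows[[r]] <- data.frame(gene_id = genes, repeat_id = r,
                            tumor_q1 = qs_t[, 1L], tumor_median = qs_t[, 2L],
                            tumor_q3 = qs_t[, 3L], normal_q1 = qs_n[, 1L],
                            normal_median = qs_n[, 2L], normal_q3 = qs_n[, 3L],
                            p_value = pv, stringsAsFactors = FALSE)
  }
  panels <- do.call(rbind, rows)
  rownames(panels) <- NULL
  agg <- split(panels, panels$gene_id)
  summary <- data.frame(
    gene_id = names(agg),
    frac_tumor_higher = vapply(agg, function(d) {
      mean(d$tumor_median > d$normal_median)
    }, numeric(1)),
    median_p = vapply(agg, function(d) stats::median(d$p_value), numeric(1)),
    stringsAsFactors = FALSE)
  summary <- summary[match(genes, summary$gene_id), , drop = FALSE]
  rownames(summary) <- NULL
  list(summary = summary, panels = panels)
}
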