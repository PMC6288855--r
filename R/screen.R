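## Minimum-p-value cutpoint screening.
##
## For one gene, samples are sorted by expression and every admissible split
## position k (ceil(0.25 n) <= k <= floor(0.75 n), never splitting tied
## values) defines low (<= cut) vs high (> cut) groups. The log-rank
## chi-square for every candidate split is computed in one pass from
## cumulative risk-set / event-count matrices, which reproduces the classic
## hypergeometric-variance log-rank statistic exactly.

# Precompute cohort-level risk-set structures shared by all genes.
logrank_precompute <- function(time, event) {
  dt <- sort(unique(time[event == 1]))
  if (!length(dt)) stop("at least one event is required")
  M_risk <- outer(time, dt, ">=") * 1
  M_event <- outer(time, dt, "==") * event
  n_j <- colSums(M_risk)
  d_j <- colSums(M_event)
  c_j <- ifelse(n_j > 1, d_j * (n_j - d_j) / (n_j - 1), 0)
  list(M_risk = M_risk, M_event = M_event, n_j = n_j, d_j = d_j, c_j = c_j,
       n = length(time))
}

# Log-rank chi-square for all candidate splits of one gene.
# Returns NULL when no admissible split exists (near-constant gene).
cutpoint_scan <- function(pre, x) {
  n <- pre$n
  ord <- order(x)
  xs <- x[ord]
  kmin <- ceiling(0.25 * n)
  kmax <- floor(0.75 * n)
  if (kmin < 1L || kmax >= n || kmin > kmax) return(NULL)
  ks <- kmin:kmax
  ks <- ks[xs[ks] < xs[ks + 1L]]          # ties never split
  if (!length(ks)) return(NULL)

  Rcum <- apply(pre$M_risk[ord, , drop = FALSE], 2L, cumsum)
  ecum <- cumsum(pre$M_event[ord, , drop = FALSE] %*% rep(1, ncol(pre$M_event)))
  w_u <- pre$d_j / pre$n_j
  w_v1 <- pre$c_j / pre$n_j
  w_v2 <- pre$c_j / pre$n_j^2
  U <- as.numeric(Rcum %*% w_u) - ecum     # sum_j (O1j - E1j), high = above split
  V <- as.numeric(Rcum %*% w_v1) - as.numeric((Rcum^2) %*% w_v2)
  U <- U[ks]; V <- V[ks]
  chi <- ifelse(V > 0, U^2 / V, 0)
  p <- ifelse(V > 0, stats::pchisq(chi, df = 1, lower.tail = FALSE), 1)
  list(k = ks, chi_sq = chi, p = p, ord = ord, xs = xs)
}

# Pick the winning split: minimum p, ties broken by the more balanced
# split (smaller |n_low - n_high|), then by the lower k.
select_cut <- function(scan, n) {
  idx <- which(scan$p <= min(scan$p) * (1 + 1e-12))
  if (length(idx) > 1L) {
    bal <- abs(n - 2 * scan$k[idx])
    idx <- idx[bal == min(bal)]
    idx <- idx[which.min(scan$k[idx])]
  }
  idx
}

#' Optimal-cutpoint survival split for one gene
#'
#' Scans every admissible expression threshold between the 25% and 75%
#' quantile positions, computes the two-group log-rank p-value for each,
#' and keeps the split with the minimum p-value. The reported hazard ratio
#' comes from a Cox fit on the high-group indicator, so HR > 1 means high
#' expression is hazardous.
#'
#' @param c A [cohort()] with complete survival data (see
#'   [filter_for_survival()]).
#' @param gene Gene id.
#' @param ties Ties method for the Cox fit (`"efron"` default).
#' @return A one-row data frame (`gene_id`, `cut_value`, `n_low`, `n_high`,
#'   `km_p`, `km_chi_sq`, `hr`, `hr_lo`, `hr_hi`, `direction`), or `NULL`
#'   with attribute-free skip when no admissible split exists (reason
#'   `"no_valid_cut"` is signalled via a `condition` message by the callers).
#' @export
optimal_cutpoint <- function(c, gene, ties = "efron") {
  stopifnot(inherits(c, "cohort"))
  if (!gene %in% rownames(c$expr)) stop("gene not present: ", gene)
  ph <- c$pheno
  if (any(is.na(ph$os_time)) || any(is.na(ph$os_event))) {
    stop("cohort has samples without survival data; run filter_for_survival() first")
  }
  pre <- logrank_precompute(ph$os_time, ph$os_event)
  record_for_gene(pre, c$expr[gene, ], gene, ph$os_time, ph$os_event, ties)
}

record_for_gene <- function(pre, x, gene, time, event, ties = "efron") {
  scan <- cutpoint_scan(pre, x)
  if (is.null(scan)) return(NULL)
  i <- select_cut(scan, pre$n)
  k <- scan$k[i]
  cut_value <- (scan$xs[k] + scan$xs[k + 1L]) / 2
  high <- as.numeric(x > cut_value)
  cf <- cox_quick(time, event, high, ties = ties)
  hr <- exp(cf[["beta"]])
  data.frame(gene_id = gene, cut_value = cut_value,
             n_low = k, n_high = pre$n - k,
             km_p = scan$p[i], km_chi_sq = scan$chi_sq[i],
             hr = hr, hr_lo = exp(cf[["beta"]] - 1.96 * cf[["se"]]),
             hr_hi = exp(cf[["beta"]] + 1.96 * cf[["se"]]),
             direction = if (hr > 1) "up_poor" else "up_good",
             stringsAsFactors = FALSE)
}

#' Screen genes for survival association by optimal cutpoint
#'
#' Runs [optimal_cutpoint()] for every gene, adjusts the minimum log-rank
#' p-values across the screened gene set (Benjamini-Hochberg), and marks as
#' significant the genes with adjusted p below `p_adj_cut` (default 3e-4, a
#' deliberately stringent cut because the per-gene minimum-p scan inflates
#' the raw p-values).
#'
#' @param c A [cohort()] with complete survival data.
#' @param genes Gene ids to screen (default: all genes; typically the
#'   stage-contrast significant set).
#' @param p_adj_cut Adjusted-p significance threshold.
#' @param ties Ties method for the per-gene Cox hazard ratios.
#' @return Data frame of class `"marker_screen"`, one row per screened
#'   gene, ranked by `km_p` ascending: the [optimal_cutpoint()] columns
#'   plus `km_p_adjusted` and `significant`. Genes without an admissible
#'   split are dropped and listed in `attr(, "skipped")` with reason
#'   `"no_valid_cut"`.
#' @export
screen_genes <- function(c, genes = NULL, p_adj_cut = 3e-4, ties = "efron") {
  stopifnot(inherits(c, "cohort"))
  check_fraction(p_adj_cut, "p_adj_cut")
  if (is.null(genes)) genes <- rownames(c$expr)
  if (!length(genes)) stop("empty gene list")
  missing <- setdiff(genes, rownames(c$expr))
  if (length(missing)) stop("gene(s) not present: ", paste(utils::head(missing, 5), collapse = ", "))
  ph <- c$pheno
  if (any(is.na(ph$os_time)) || any(is.na(ph$os_event))) {
    stop("cohort has samples without survival data; run filter_for_survival() first")
  }
  pre <- logrank_precompute(ph$os_time, ph$os_event)
  recs <- vector("list", length(genes))
  skipped <- character(0)
  for (i in seq_along(genes)) {
    r <- record_for_gene(pre, c$expr[genes[i], ], genes[i],
                         ph$os_time, ph$os_event, ties)
    if (is.null(r)) skipped <- c(skipped, genes[i]) else recs[[i]] <- r
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs)) stop("no screenable genes (all skipped)")
  out <- do.call(rbind, recs)
  out$km_p_adjusted <- bh_adjust(out$km_p)
  out$significant <- out$km_p_adjusted < p_adj_cut
  out <- out[order(out$km_p, -abs(log(out$hr))), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) {
    data.frame(gene_id = skipped, reason = "no_valid_cut", stringsAsFactors = FALSE)
  } else NULL
  attr(out, "p_adj_cut") <- p_adj_cut
  attr(out, "n_samples") <- pre$n
  class(out) <- c("marker_screen", "data.frame")
  out
}

#' Resampling stability of the cutpoint screen
#'
#' Repeats the whole screen (cutpoint re-optimization plus within-iteration
#' BH adjustment over the same gene universe) on random subsamples of
#' `floor(frac * n)` subjects drawn without replacement, and counts per
#' gene how many iterations called it significant. A gene is retained when
#' its count exceeds `retain_min`.
#'
#' @param c A [cohort()] with complete survival data.
#' @param genes Gene ids to assess (typically the top screened genes).
#' @param frac Subsample fraction (default 0.8).
#' @param n_iter Number of iterations (default 100).
#' @param p_adj_cut Within-iteration adjusted-p threshold (default 3e-4).
#' @param retain_min Minimum significant-iteration count, exclusive
#'   (default 80, i.e. retained iff count > 80 of 100).
#' @param seed Integer seed; counts are bit-reproducible given the seed.
#' @param ties Ties method for per-iteration hazard ratios.
#' @return Data frame of class `"stability_result"`: `gene_id`,
#'   `n_signif`, `hr_mean` (arithmetic mean of per-iteration HRs over the
#'   iterations where the gene was screenable), `n_screened`, `retained`.
#' @export
stability_resample <- function(c, genes, frac = 0.8, n_iter = 100,
                               p_adj_cut = 3e-4, retain_min = 80, seed = 1,
                               ties = "efron") {
  stopifnot(inherits(c, "cohort"))
  if (frac <= 0 || frac > 1) stop("'frac' must be in (0, 1]")
  n_iter <- check_count(n_iter, "n_iter")
  retain_min <- check_count(retain_min, "retain_min", min = 0L)
  if (!length(genes)) stop("empty gene list")
  ph <- c$pheno
  n <- nrow(ph)
  m <- floor(frac * n)
  if (m < 10) stop("resample too small: floor(frac * n) = ", m)
  X <- c$expr[genes, , drop = FALSE]
  set.seed(seed)
  n_sig <- setNames(integer(length(genes)), genes)
  n_scr <- setNames(integer(length(genes)), genes)
  hr_sum <- setNames(numeric(length(genes)), genes)
  for (it in seq_len(n_iter)) {
    idx <- if (m == n) seq_len(n) else sample.int(n, m)
    time <- ph$os_time[idx]; event <- ph$os_event[idx]
    pre <- logrank_precompute(time, event)
    pv <- rep(NA_real_, length(genes))
    hrs <- rep(NA_real_, length(genes))
    for (g in seq_along(genes)) {
      r <- record_for_gene(pre, X[g, idx], genes[g], time, event, ties)
      if (!is.null(r)) {
        pv[g] <- r$km_p
        hrs[g] <- r$hr
      }
    }
    ok <- !is.na(pv)
    if (!any(ok)) next
    padj <- rep(NA_real_, length(genes))
    padj[ok] <- bh_adjust(pv[ok])
    sig <- !is.na(padj) & padj < p_adj_cut
    n_sig[sig] <- n_sig[sig] + 1L
    n_scr[ok] <- n_scr[ok] + 1L
    hr_sum[ok] <- hr_sum[ok] + hrs[ok]
  }
  out <- data.frame(gene_id = genes, n_signif = as.integer(n_sig),
                    hr_mean = ifelse(n_scr > 0, hr_sum / n_scr, NA_real_),
                    n_screened = as.integer(n_scr),
                    retained = n_sig > retain_min,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_iter") <- n_iter
  attr(out, "frac") <- frac
  attr(out, "retain_min") <- retain_min
  class(out) <- c("stability_result", "data.frame")
  out
}

#' Rank stable survival markers
#'
#' Joins the whole-data screen with the stability counts, keeps only
#' retained genes, and emits one ranked table per direction (up-regulation
#' associated with poor vs good survival), sorted by whole-data log-rank p
#' ascending, ties broken by the larger |log HR|.
#'
#' @param markers A [screen_genes()] result.
#' @param stability A [stability_resample()] result on the same genes.
#' @return List of class `"marker_ranking"` with data frames `up_poor` and
#'   `up_good` (columns: `rank`, `gene_id`, `km_p`, `km_p_adjusted`, `hr`,
#'   `hr_lo`, `hr_hi`, `n_signif`, `hr_mean`, `cut_value`).
#' @export
rank_markers <- function(markers, stability) {
  stopifnot(inherits(markers, "marker_screen"),
            inherits(stability, "stability_result"))
  j <- merge(as.data.frame(markers), as.data.frame(stability), by = "gene_id")
  j <- j[j$retained, , drop = FALSE]
  j <- j[order(j$km_p, -abs(log(j$hr))), , drop = FALSE]
  mk <- function(d) {
    d <- d[, c("gene_id", "km_p", "km_p_adjusted", "hr", "hr_lo", "hr_hi",
               "n_signif", "hr_mean", "cut_value")]
    if (nrow(d)) d <- cbind(rank = seq_len(nrow(d)), d)
    rownames(d) <- NULL
    d
  }
  structure(list(up_poor = mk(j[j$direction == "up_poor", , drop = FALSE]),
                 up_good = mk(j[j$direction == "up_good", , drop = FALSE])),
            class = "marker_ranking")
}

#' Evaluate marker genes on an external cohort
#'
#' Re-runs the optimal-cutpoint analysis per listed gene on an external
#' cohort, and additionally fits a combined multivariate Cox model on the
#' genes' standardized expression, splitting the cohort at the median of
#' the combined linear predictor and reporting its log-rank separation and
#' hazard ratio.
#'
#' @param external A [cohort()] with complete survival data.
#' @param genes Gene ids (genes absent from the external matrix are listed
#'   in `skipped` and the run completes).
#' @param ties Ties method for Cox fits.
#' @return List with `per_gene` (optimal-cutpoint records), `skipped`
#'   (character vector), and `combined` (list: `beta`, `logrank_chi_sq`,
#'   `logrank_p`, `hr`, `hr_ci95`, `n_high`, `n_low`).
#' @export
apply_markers <- function(external, genes, ties = "efron") {
  stopifnot(inherits(external, "cohort"))
  present <- intersect(genes, rownames(external$expr))
  skipped <- setdiff(genes, present)
  if (length(skipped)) ss_log(length(skipped), " gene(s) absent from external cohort")
  if (!length(present)) stop("no listed gene present in the external cohort")
  per_gene <- screen_genes(external, present, ties = ties)
  ph <- external$pheno
  Z <- external$expr[present, , drop = FALSE]
  Z <- (Z - rowMeans(Z)) / apply(Z, 1L, stats::sd)
  combined <- NULL
  if (length(present) >= 1L) {
    fit <- cox_fit(ph$os_time, ph$os_event, t(Z), ties = ties)
    lp <- as.numeric(crossprod(Z, fit$beta))
    high <- lp > stats::median(lp)
    lr <- logrank_test(ph$os_time, ph$os_event, high)
    grp <- cox_fit(ph$os_time, ph$os_event, as.numeric(high), ties = ties)
    combined <- list(beta = setNames(fit$beta, present),
                     logrank_chi_sq = lr$chi_sq, logrank_p = lr$p,
                     hr = grp$hr, hr_ci95 = grp$ci95,
                     n_high = sum(high), n_low = sum(!high))
  }
  list(per_gene = per_gene, skipped = skipped, combined = combined)
}
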