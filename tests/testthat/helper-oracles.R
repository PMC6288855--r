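## Independent brute-force oracles used across the suite. These enumerate
## risk sets directly and never touch the package's computational paths.

options(survscreen.verbose = FALSE)

# Product-limit estimator by direct risk-set enumeration.
oracle_km <- function(time, event) {
  dt <- sort(unique(time[event == 1]))
  surv <- numeric(length(dt))
  s <- 1
  for (j in seq_along(dt)) {
    n_j <- sum(time >= dt[j])
    d_j <- sum(time == dt[j] & event == 1)
    s <- s * (1 - d_j / n_j)
    surv[j] <- s
  }
  data.frame(time = dt, survival = surv)
}

# Two-group log-rank chi-square by direct risk-set enumeration.
oracle_logrank <- function(time, event, group) {
  g <- as.integer(factor(group)) == 1L
  dt <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in dt) {
    at_risk <- time >= t
    n_j <- sum(at_risk)
    n1j <- sum(at_risk & g)
    d_j <- sum(time == t & event == 1)
    d1j <- sum(time == t & event == 1 & g)
    o_minus_e <- o_minus_e + (d1j - d_j * n1j / n_j)
    if (n_j > 1) {
      v <- v + d_j * (n1j / n_j) * (1 - n1j / n_j) * (n_j - d_j) / (n_j - 1)
    }
  }
  chi <- if (v > 0) o_minus_e^2 / v else 0
  list(chi_sq = chi, p = stats::pchisq(chi, 1, lower.tail = FALSE))
}

# Brute-force optimal-cutpoint scan: every admissible split, log-rank p by
# the enumeration oracle, minimum p with the package's stated tie rules.
oracle_cutpoint <- function(time, event, x) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  ks <- ceiling(0.25 * n):floor(0.75 * n)
  ks <- ks[xs[ks] < xs[ks + 1]]
  if (!length(ks)) return(NULL)
  ps <- vapply(ks, function(k) {
    cut <- (xs[k] + xs[k + 1]) / 2
    oracle_logrank(time, event, x > cut)$p
  }, numeric(1))
  idx <- which(ps <= min(ps) * (1 + 1e-12))
  if (length(idx) > 1L) {
    bal <- abs(n - 2 * ks[idx])
    idx <- idx[bal == min(bal)]
    idx <- idx[which.min(ks[idx])]
  }
  list(k = ks[idx], p = ps[idx])
}

# Random survival fixture without tied times.
surv_fixture <- function(n, seed, censor_p = 0.3) {
  set.seed(seed)
  list(time = round(stats::runif(n, 1, 100), 6),
       event = as.numeric(stats::runif(n) > censor_p))
}

# Tiny cohort built directly from matrices (bypasses the generator).
tiny_cohort <- function(expr, batch = NULL, stage = NULL, time = NULL,
                        event = NULL) {
  n <- ncol(expr)
  if (is.null(colnames(expr))) colnames(expr) <- sprintf("s%02d", seq_len(n))
  if (is.null(rownames(expr))) rownames(expr) <- sprintf("g%02d", seq_len(nrow(expr)))
  cohort(expr, data.frame(
    sample_id = colnames(expr),
    batch_id = if (is.null(batch)) rep("B1", n) else batch,
    stage = if (is.null(stage)) rep("II", n) else stage,
    os_time = if (is.null(time)) seq_len(n) else time,
    os_event = if (is.null(event)) rep(1, n) else event,
    stringsAsFactors = FALSE))
}
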