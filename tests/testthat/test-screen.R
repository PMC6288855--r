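test_that("candidate splits respect the quantile band and never split ties", {
  fx <- surv_fixture(8, seed = 80)
  pre <- survscreen:::logrank_precompute(fx$time, fx$event)
  # 8 distinct values: candidates k in {2,...,6}
  scan <- survscreen:::cutpoint_scan(pre, c(1, 2, 3, 4, 5, 6, 7, 8))
  expect_equal(scan$k, 2:6)
  # tie spanning the middle removes those candidates
  scan2 <- survscreen:::cutpoint_scan(pre, c(1, 2, 3, 5, 5, 5, 7, 8))
  expect_equal(scan2$k, c(2, 3, 6))
})

test_that("constant genes are skipped with a reason code", {
  fx <- surv_fixture(20, seed = 81)
  expr <- rbind(gconst = rep(3, 20), gvar = rnorm(20))
  colnames(expr) <- sprintf("s%02d", 1:20)
  ch <- tiny_cohort(expr, time = fx$time, event = fx$event)
  expect_null(optimal_cutpoint(ch, "gconst"))
  scr <- screen_genes(ch)
  expect_identical(attr(scr, "skipped")$gene_id, "gconst")
  expect_identical(attr(scr, "skipped")$reason, "no_valid_cut")
  expect_equal(nrow(scr), 1L)
})

test_that("cutpoint scan agrees with the brute-force oracle", {
  for (s in 1:15) {
    n <- sample(6:12, 1)
    fx <- surv_fixture(n, seed = 1000 + s)
    set.seed(2000 + s)
    x <- if (s %% 3 == 0) sample(rep(1:4, length.out = n)) else rnorm(n)
    pre <- survscreen:::logrank_precompute(fx$time, fx$event)
    scan <- survscreen:::cutpoint_scan(pre, x)
    oc <- oracle_cutpoint(fx$time, fx$event, x)
    if (is.null(oc)) {
      expect_true(is.null(scan) || length(scan$k) == 0)
    } else {
      i <- survscreen:::select_cut(scan, n)
      expect_equal(scan$k[i], oc$k)
      expect_equal(scan$p[i], oc$p, tolerance = 1e-10)
    }
  }
})

test_that("the cutpoint is invariant under strictly monotone transforms", {
  fx <- surv_fixture(40, seed = 83)
  set.seed(84)
  x <- rnorm(40, 7)
  expr <- rbind(graw = x, gexp = exp(x / 2))
  colnames(expr) <- sprintf("s%02d", 1:40)
  ch <- tiny_cohort(expr, time = fx$time, event = fx$event)
  a <- optimal_cutpoint(ch, "graw")
  b <- optimal_cutpoint(ch, "gexp")
  expect_equal(a$km_p, b$km_p, tolerance = 1e-12)
  expect_equal(a$n_low, b$n_low)
  expect_equal(a$hr, b$hr, tolerance = 1e-8)
  # the cut value transforms with the expression scale
  xs <- sort(exp(x / 2))
  expect_equal(b$cut_value, (xs[b$n_low] + xs[b$n_low + 1]) / 2)
})

test_that("screen orders by km_p with the |log HR| tie-break", {
  sp <- synthetic_spec(n_genes = 150, n_samples = 200, n_batches = 2,
                       batch_shift_sd = 0, n_marker_genes = 8, n_stage_genes = 0,
                       marker_beta = log(2.5), seed = 86)
  ch <- filter_for_survival(generate_cohort(sp)$cohort)$cohort
  scr <- screen_genes(ch, p_adj_cut = 0.01)
  expect_true(!is.unsorted(scr$km_p))
  expect_true(all(scr$km_p_adjusted >= scr$km_p - 1e-15))
  expect_identical(scr$direction, ifelse(scr$hr > 1, "up_poor", "up_good"))
  expect_equal(scr$n_low + scr$n_high, rep(200L, nrow(scr)))
  expect_error(screen_genes(ch, genes = character(0)), "empty gene list")
  expect_error(screen_genes(ch, genes = "nope"), "not present")
})

test_that("stability resampling is reproducible and degenerate at frac = 1", {
  sp <- synthetic_spec(n_genes = 60, n_samples = 120, n_batches = 2,
                       batch_shift_sd = 0, n_marker_genes = 4, n_stage_genes = 0,
                       marker_beta = log(3), seed = 88)
  ch <- filter_for_survival(generate_cohort(sp)$cohort)$cohort
  genes <- rownames(ch$expr)[1:30]
  a <- stability_resample(ch, genes, n_iter = 10, retain_min = 8,
                          p_adj_cut = 0.05, seed = 5)
  b <- stability_resample(ch, genes, n_iter = 10, retain_min = 8,
                          p_adj_cut = 0.05, seed = 5)
  expect_identical(a, b)

  deg <- stability_resample(ch, genes, frac = 1.0, n_iter = 7, retain_min = 5,
                            p_adj_cut = 0.05, seed = 6)
  expect_true(all(deg$n_signif %in% c(0L, 7L)))

  expect_error(stability_resample(ch, genes, frac = 0.05, n_iter = 5,
                                  retain_min = 3), "resample too small")
})

test_that("stability counts separate true markers from null genes", {
  cors <- vapply(1:5, function(s) {
    sp <- synthetic_spec(n_genes = 60, n_samples = 150, n_batches = 2,
                         batch_shift_sd = 0, n_marker_genes = 6, n_stage_genes = 0,
                         marker_beta = seq(0.5, 1.5, length.out = 6),
                         censor_rate = 0.3, seed = 3000 + s)
    g <- generate_cohort(sp)
    ch <- filter_for_survival(g$cohort)$cohort
    st <- stability_resample(ch, rownames(ch$expr), n_iter = 10, retain_min = 8,
                             p_adj_cut = 0.05, seed = s)
    j <- merge(st, g$truth$genes, by = "gene_id")
    suppressWarnings(stats::cor(abs(j$true_beta), j$n_signif, method = "spearman"))
  }, numeric(1))
  expect_true(all(cors > 0))
})

test_that("ranking filters to retained genes and separates directions", {
  scr <- structure(data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    cut_value = 1:4, n_low = 5L, n_high = 5L,
    km_p = c(1e-6, 1e-6, 1e-4, 2e-3), km_chi_sq = 20,
    hr = c(2.0, 3.5, 0.4, 2.2), hr_lo = 1, hr_hi = 9,
    direction = c("up_poor", "up_poor", "up_good", "up_poor"),
    km_p_adjusted = c(4e-6, 4e-6, 2e-4, 2e-3), significant = TRUE,
    stringsAsFactors = FALSE), class = c("marker_screen", "data.frame"))
  stab <- structure(data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    n_signif = c(95L, 90L, 85L, 10L), hr_mean = c(2.1, 3.4, 0.45, 2.0),
    n_screened = 100L, retained = c(TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE), class = c("stability_result", "data.frame"))
  rk <- rank_markers(scr, stab)
  # g4 excluded (not retained) despite a fine km_p; directions never mixed
  expect_identical(rk$up_poor$gene_id, c("g2", "g1"))  # tie on km_p -> larger |log hr|
  expect_identical(rk$up_good$gene_id, "g3")
  expect_equal(rk$up_poor$rank, 1:2)
})

test_that("apply_markers reproduces training records and combines genes", {
  sp <- synthetic_spec(n_genes = 80, n_samples = 250, n_batches = 2,
                       batch_shift_sd = 0, n_marker_genes = 5, n_stage_genes = 0,
                       marker_beta = log(2.2), censor_rate = 0.4, seed = 91)
  g <- generate_cohort(sp)
  ch <- filter_for_survival(g$cohort)$cohort
  markers <- g$truth$genes$gene_id[g$truth$genes$true_beta > 0]
  scr <- screen_genes(ch, markers)
  res <- apply_markers(ch, markers)
  expect_equal(res$per_gene$km_p, scr$km_p, tolerance = 1e-12)
  expect_equal(res$per_gene$hr, scr$hr, tolerance = 1e-10)
  expect_length(res$skipped, 0)
  expect_equal(res$combined$n_high + res$combined$n_low, 250)
  # the combined multivariate score separates at least as well as expected
  expect_lt(res$combined$logrank_p, 0.01)
  expect_gt(res$combined$hr, 1)

  # a missing gene lands on the skip list and the run completes
  res2 <- apply_markers(ch, c(markers, "absent_gene"))
  expect_identical(res2$skipped, "absent_gene")
  expect_equal(nrow(res2$per_gene), 5L)
})
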