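test_that("mean-centering maps every batch mean to the gene's global mean", {
  # one gene, batches {5,7} and {9,11}: global mean 8 -> (7,9,7,9)
  expr <- matrix(c(5, 7, 9, 11), 1, 4,
                 dimnames = list("g1", paste0("s", 1:4)))
  ch <- tiny_cohort(expr, batch = rep(c("B1", "B2"), each = 2))
  out <- mean_center_by_batch(ch)
  expect_equal(as.numeric(out$expr), c(7, 9, 7, 9))

  # idempotence
  out2 <- mean_center_by_batch(out)
  expect_equal(out2$expr, out$expr, tolerance = 1e-12)

  # singleton batch errors with the batch name
  ch3 <- tiny_cohort(expr, batch = c("B1", "B1", "B1", "Bsolo"))
  expect_error(mean_center_by_batch(ch3), "Bsolo")
})

test_that("batch regression reports zero coefficients after mean-centering", {
  sp <- synthetic_spec(n_genes = 60, n_samples = 90, n_batches = 3,
                       batch_shift_sd = 0.5, n_marker_genes = 2,
                       n_stage_genes = 5, seed = 14)
  ch <- filter_for_survival(generate_cohort(sp)$cohort)$cohort
  rep_before <- batch_factor_regression(ch)
  expect_true(any(rep_before$effect_flag[-1] == "yes"))
  rep_after <- batch_factor_regression(mean_center_by_batch(ch))
  expect_true(all(abs(rep_after$estimate[-1]) < 1e-10))
  expect_true(all(rep_after$effect_flag[-1] == "no"))
})

test_that("batch regression uses the first batch as reference and flags by alpha", {
  set.seed(40)
  expr <- matrix(rnorm(50 * 60), 50, 60,
                 dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:60)))
  expr[, 31:60] <- expr[, 31:60] + 2  # strong shift on batch Bz
  ch <- tiny_cohort(expr, batch = rep(c("Ba", "Bz"), each = 30))
  r <- batch_factor_regression(ch, alpha = 0.05)
  expect_identical(attr(r, "reference_batch"), "Ba")
  expect_identical(r$factor_id, c("(Intercept)", "Bz"))
  expect_identical(r$effect_flag[2], "yes")
  expect_equal(r$estimate[2], 2, tolerance = 0.3)
  expect_error(batch_factor_regression(tiny_cohort(expr)), "two batches")
})

test_that("two batches from the same distribution are rarely flagged", {
  flags <- vapply(1:50, function(s) {
    set.seed(500 + s)
    expr <- matrix(rnorm(20 * 200, 7), 20, 200,
                   dimnames = list(sprintf("g%02d", 1:20), sprintf("s%03d", 1:200)))
    ch <- tiny_cohort(expr, batch = rep(c("B1", "B2"), each = 100))
    any(batch_factor_regression(ch, alpha = 0.05)$effect_flag[-1] == "yes")
  }, logical(1))
  expect_gte(mean(!flags), 0.9)
})

test_that("EB location/scale adjustment matches the reference ComBat", {
  sp <- synthetic_spec(n_genes = 120, n_samples = 90, n_batches = 3,
                       batch_shift_sd = 0.4, batch_scale_sd = 0.2,
                       n_marker_genes = 2, n_stage_genes = 5, seed = 17)
  ch <- filter_for_survival(generate_cohort(sp)$cohort)$cohort
  mine <- eb_location_scale_adjust(ch)
  ref <- sva::ComBat(dat = ch$expr, batch = factor(ch$pheno$batch_id),
                     par.prior = TRUE, prior.plots = FALSE)
  expect_equal(mine$expr, ref, tolerance = 1e-6)
})

test_that("EB adjustment removes injected location offsets at large n", {
  sp <- synthetic_spec(n_genes = 80, n_samples = 400, n_batches = 2,
                       batch_shift_sd = 0.8, batch_scale_sd = 0,
                       n_marker_genes = 2, n_stage_genes = 0, seed = 19)
  ch <- filter_for_survival(generate_cohort(sp)$cohort)$cohort
  out <- eb_location_scale_adjust(ch)
  batch <- out$pheno$batch_id
  bm <- t(rowsum(t(out$expr), batch) / as.vector(table(batch)))
  gap <- abs(bm[, 1] - bm[, 2])
  # corrected batch means agree; compare against the mean-centering result,
  # exact for pure location effects
  mc <- mean_center_by_batch(ch)
  expect_lt(max(gap), 0.1)
  expect_equal(out$expr, mc$expr, tolerance = 0.1)
})

test_that("EB adjustment degenerates as documented", {
  sp <- synthetic_spec(n_genes = 40, n_samples = 60, n_batches = 2,
                       batch_shift_sd = 0.5, n_marker_genes = 1,
                       n_stage_genes = 2, seed = 23)
  ch <- filter_for_survival(generate_cohort(sp)$cohort)$cohort

  # single batch: identity
  one <- ch
  one$pheno$batch_id <- "B1"
  expect_identical(eb_location_scale_adjust(one)$expr, one$expr)

  # shrinkage off: exact per-gene per-batch standardization on the pooled scale
  out <- eb_location_scale_adjust(ch, shrink = FALSE)
  X <- ch$expr
  batch <- ch$pheno$batch_id
  sizes <- as.vector(table(batch))
  bm <- t(rowsum(t(X), batch) / sizes)
  grand <- as.numeric(bm %*% (sizes / ncol(X)))
  varp <- rowSums((X - bm[, match(batch, sort(unique(batch)))])^2) / ncol(X)
  for (b in unique(batch)) {
    sel <- batch == b
    Z <- (X[, sel] - grand) / sqrt(varp)
    Zs <- (Z - rowMeans(Z)) / apply(Z, 1, sd)
    expect_equal(out$expr[, sel], Zs * sqrt(varp) + grand, tolerance = 1e-10)
  }
})

test_that("mixing diagnostics quantify batch separation and mixing", {
  # perfectly confounded batches (distinct per-gene batch profiles, so
  # within-batch correlation is high and between-batch correlation low)
  set.seed(51)
  prof1 <- rnorm(40, sd = 4); prof2 <- rnorm(40, sd = 4)
  expr <- cbind(prof1 + matrix(rnorm(40 * 12, sd = 0.5), 40, 12),
                prof2 + matrix(rnorm(40 * 12, sd = 0.5), 40, 12))
  dimnames(expr) <- list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:24))
  ch <- tiny_cohort(expr, batch = rep(c("B1", "B2"), each = 12))
  m <- mixing_diagnostics(ch, per_batch = 12, seed = 1)
  expect_equal(m$clustering_purity, 1.0)
  expect_gt(m$pca_silhouette, 0.5)

  # random labels over an i.i.d. matrix -> silhouette near zero
  sils <- vapply(1:20, function(s) {
    set.seed(700 + s)
    e <- matrix(rnorm(30 * 40), 30, 40,
                dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:40)))
    cc <- tiny_cohort(e, batch = sample(rep(c("B1", "B2"), 20)))
    mixing_diagnostics(cc, per_batch = 20, seed = s)$pca_silhouette
  }, numeric(1))
  expect_lt(mean(abs(sils)), 0.05)

  # two identical copies of one batch labeled differently -> purity ~ 0.5
  set.seed(52)
  half <- matrix(rnorm(30 * 15), 30, 15)
  e2 <- cbind(half, half)
  dimnames(e2) <- list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:30))
  cc2 <- tiny_cohort(e2, batch = rep(c("B1", "B2"), each = 15))
  m2 <- mixing_diagnostics(cc2, per_batch = 15, seed = 2)
  expect_lt(abs(m2$clustering_purity - 0.5), 0.25)
})

test_that("diagnostics are invariant to gene and sample order", {
  sp <- synthetic_spec(n_genes = 50, n_samples = 80, n_batches = 2,
                       batch_shift_sd = 0.4, n_marker_genes = 2,
                       n_stage_genes = 4, seed = 29)
  ch <- filter_for_survival(generate_cohort(sp)$cohort)$cohort
  perm <- ch
  set.seed(30)
  perm$expr <- perm$expr[sample(nrow(perm$expr)), sample(ncol(perm$expr))]
  perm$pheno <- perm$pheno[match(colnames(perm$expr), perm$pheno$sample_id), ]
  perm <- cohort(perm$expr, perm$pheno)

  a <- mixing_diagnostics(ch, per_batch = 20, seed = 5)
  b <- mixing_diagnostics(perm, per_batch = 20, seed = 5)
  expect_equal(a$clustering_purity, b$clustering_purity)
  expect_equal(a$pca_silhouette, b$pca_silhouette, tolerance = 1e-8)

  ra <- batch_factor_regression(ch)
  rb <- batch_factor_regression(perm)
  expect_equal(ra$estimate, rb$estimate, tolerance = 1e-10)
})

test_that("EB adjustment reduces the PCA silhouette of shifted cohorts", {
  deltas <- vapply(1:5, function(s) {
    sp <- synthetic_spec(n_genes = 60, n_samples = 90, n_batches = 3,
                         batch_shift_sd = 0.5, n_marker_genes = 2,
                         n_stage_genes = 4, seed = 800 + s)
    ch <- filter_for_survival(generate_cohort(sp)$cohort)$cohort
    before <- mixing_diagnostics(ch, per_batch = 25, seed = s)$pca_silhouette
    after <- mixing_diagnostics(eb_location_scale_adjust(ch),
                                per_batch = 25, seed = s)$pca_silhouette
    before - after
  }, numeric(1))
  expect_true(all(deltas > 0))
})
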