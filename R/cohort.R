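#' Construct an expression + phenotype cohort
#'
#' A cohort couples a log2 expression matrix (genes x samples) with a
#' phenotype table carrying batch, tumor stage, and overall-survival (OS)
#' outcome per sample. It is the object every pipeline stage consumes.
#'
#' @param expr Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). Values are log2 intensities; every
#'   value must be finite.
#' @param pheno Data frame with columns `sample_id`, `batch_id`, `stage`
#'   (one of `"I"`, `"II"`, `"III"`, `"IV"`, `"normal"`, or `NA`), `os_time`
#'   (months, `NA` allowed) and `os_event` (0/1, `NA` allowed). Extra
#'   clinical columns are carried through opaquely. Rows are matched to the
#'   expression columns by `sample_id`; samples present in only one of the
#'   two inputs are dropped with a log line.
#'
#' @return An object of class `"cohort"`: a list with elements `expr`
#'   (matrix) and `pheno` (data frame), columns/rows aligned in the same
#'   sample order.
#' @export
cohort <- function(expr, pheno) {
  if (!is.matrix(expr) || !is.numeric(expr)) stop("'expr' must be a numeric matrix")
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("'expr' must have gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(expr))) stop("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(expr))) stop("duplicate sample ids in expression matrix")
  if (!all(is.finite(expr))) {
    bad <- which(!is.finite(expr), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 rownames(expr)[bad[1L]], colnames(expr)[bad[2L]]))
  }
  req <- c("sample_id", "batch_id", "stage", "os_time", "os_event")
  miss <- setdiff(req, names(pheno))
  if (length(miss)) stop("phenotype table missing column(s): ", paste(miss, collapse = ", "))
  pheno <- as.data.frame(pheno, stringsAsFactors = FALSE)
  pheno$sample_id <- as.character(pheno$sample_id)
  pheno$batch_id <- as.character(pheno$batch_id)
  if (anyDuplicated(pheno$sample_id)) {
    stop("duplicate sample id in phenotype table: ",
         pheno$sample_id[anyDuplicated(pheno$sample_id)])
  }
  pheno$stage <- normalize_stage(pheno$stage)
  pheno$os_time <- as.numeric(pheno$os_time)
  pheno$os_event <- as.numeric(pheno$os_event)
  if (any(pheno$os_time < 0, na.rm = TRUE)) stop("negative os_time")
  bad_ev <- !is.na(pheno$os_event) & !pheno$os_event %in% c(0, 1)
  if (any(bad_ev)) stop("os_event must be 0/1; offending sample: ",
                        pheno$sample_id[which(bad_ev)[1L]])

  common <- intersect(colnames(expr), pheno$sample_id)
  if (!length(common)) stop("no samples shared between expression matrix and phenotype table")
  n_drop <- (ncol(expr) - length(common)) + (nrow(pheno) - length(common))
  if (n_drop > 0) ss_log(n_drop, " sample(s) present in only one input were dropped")
  expr <- expr[, common, drop = FALSE]
  pheno <- pheno[match(common, pheno$sample_id), , drop = FALSE]
  rownames(pheno) <- NULL
  structure(list(expr = expr, pheno = pheno), class = "cohort")
}

normalize_stage <- function(stage) {
  s <- toupper(trimws(as.character(stage)))
  s[s %in% c("", "NA")] <- NA_character_
  s[s == "NORMAL"] <- "normal"
  ok <- is.na(s) | s %in% c("I", "II", "III", "IV", "normal")
  if (!all(ok)) stop("unrecognized stage value(s): ",
                     paste(unique(s[!ok]), collapse = ", "))
  s
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d genes x %d samples, %d batch(es)\n",
              nrow(x$expr), ncol(x$expr), length(unique(x$pheno$batch_id))))
  st <- table(x$pheno$stage, useNA = "ifany")
  cat("stages:", paste(sprintf("%s=%d", names(st), st), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.cohort <- function(x) dim(x$expr)

#' Read a cohort from a TSV pair
#'
#' Expression format: first column `gene_id`, remaining columns one per
#' sample, tab-separated, `.` decimal, literal `NA` not allowed in
#' expression cells. Phenotype format: required columns `sample_id`,
#' `batch_id`, `stage`, `os_time`, `os_event`; literal `NA` for missing.
#'
#' @param expr_path,pheno_path Paths to the two TSV files.
#' @param time_unit `"months"` (default) or `"days"`; day-scale inputs are
#'   converted to months (divide by 30.44) with a log line.
#' @return A [cohort()].
#' @export
read_cohort <- function(expr_path, pheno_path, time_unit = c("months", "days")) {
  time_unit <- match.arg(time_unit)
  etab <- utils::read.delim(expr_path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  if (names(etab)[1L] != "gene_id") stop("malformed expression header: first column must be 'gene_id'")
  gid <- as.character(etab[[1L]])
  vals <- as.matrix(etab[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  if (any(!is.finite(vals))) {
    bad <- which(!is.finite(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric expression cell at row %d (gene '%s'), column '%s'",
                 bad[1L], gid[bad[1L]], colnames(vals)[bad[2L]]))
  }
  rownames(vals) <- gid
  ptab <- utils::read.delim(pheno_path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE,
                            na.strings = "NA")
  if (time_unit == "days") {
    ptab$os_time <- as.numeric(ptab$os_time) / 30.44
    ss_log("os_time converted from days to months (/30.44)")
  }
  cohort(vals, ptab)
}

#' Write a cohort to a TSV pair
#'
#' Inverse of [read_cohort()]; numeric values are written with full
#' precision (up to 15 significant digits) so a read/write cycle
#' round-trips.
#'
#' @param c A [cohort()].
#' @param expr_path,pheno_path Output paths.
#' @return Invisibly, the cohort.
#' @export
write_cohort <- function(c, expr_path, pheno_path) {
  stopifnot(inherits(c, "cohort"))
  df <- data.frame(gene_id = rownames(c$expr),
                   format(c$expr, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(c$pheno, pheno_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(c)
}

#' Restrict a cohort to samples usable for survival analysis
#'
#' Drops samples with missing OS time or event and normal-tissue samples,
#' and returns a per-batch assembly manifest in the style of a cohort
#' bookkeeping table (total / discarded / processed per series).
#'
#' @param c A [cohort()].
#' @return A list with `cohort` (the filtered cohort) and `manifest`
#'   (see [assembly_manifest()]).
#' @export
filter_for_survival <- function(c) {
  stopifnot(inherits(c, "cohort"))
  ph <- c$pheno
  keep <- !is.na(ph$os_time) & !is.na(ph$os_event) &
    (is.na(ph$stage) | ph$stage != "normal")
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) stop("no samples with survival data")
  batches <- unique(ph$batch_id)
  man <- assembly_manifest(
    series_id = batches,
    n_total = as.integer(table(factor(ph$batch_id, levels = batches))),
    n_discarded = as.integer(table(factor(ph$batch_id[!keep], levels = batches)))
  )
  out <- cohort(c$expr[, keep, drop = FALSE], ph[keep, , drop = FALSE])
  ss_log(sum(!keep), " sample(s) discarded (no survival data or normal tissue)")
  list(cohort = out, manifest = man)
}

#' Cohort-assembly manifest
#'
#' Per-series sample accounting: total collected, discarded, and processed
#' (`n_processed = n_total - n_discarded`), with a grand-total row
#' available via [manifest_totals()].
#'
#' @param series_id Character vector of series/batch identifiers.
#' @param n_total,n_discarded Non-negative integer vectors, one per series.
#' @return Data frame of class `"assembly_manifest"` with columns
#'   `series_id`, `n_total`, `n_discarded`, `n_processed`.
#' @export
assembly_manifest <- function(series_id, n_total, n_discarded) {
  stopifnot(length(series_id) == length(n_total),
            length(series_id) == length(n_discarded))
  n_total <- vapply(n_total, check_count, integer(1), name = "n_total", min = 0L)
  n_discarded <- vapply(n_discarded, check_count, integer(1), name = "n_discarded", min = 0L)
  if (any(n_discarded > n_total)) stop("n_discarded exceeds n_total")
  out <- data.frame(series_id = as.character(series_id),
                    n_total = n_total, n_discarded = n_discarded,
                    n_processed = n_total - n_discarded,
                    stringsAsFactors = FALSE)
  class(out) <- c("assembly_manifest", "data.frame")
  out
}

#' Totals row of an assembly manifest
#' @param m An [assembly_manifest()].
#' @return Named numeric vector with `n_total`, `n_discarded`, `n_processed`.
#' @export
manifest_totals <- function(m) {
  stopifnot(inherits(m, "assembly_manifest"))
  c(n_total = sum(m$n_total), n_discarded = sum(m$n_discarded),
    n_processed = sum(m$n_processed))
}

#' Merge cohorts on their common gene set
#'
#' Column-wise concatenation on the intersection of gene ids (sorted);
#' batch ids are preserved per sample. Sample ids must be globally unique.
#'
#' @param cohorts A list of [cohort()] objects.
#' @return A single merged [cohort()].
#' @export
merge_cohorts <- function(cohorts) {
  stopifnot(is.list(cohorts), length(cohorts) >= 1L,
            all(vapply(cohorts, inherits, logical(1), "cohort")))
  if (length(cohorts) == 1L) return(cohorts[[1L]])
  genes <- Reduce(intersect, lapply(cohorts, function(x) rownames(x$expr)))
  if (!length(genes)) stop("empty gene intersection across cohorts")
  genes <- sort(genes)
  ids <- unlist(lapply(cohorts, function(x) colnames(x$expr)))
  if (anyDuplicated(ids)) {
    stop("duplicate sample id across cohorts: ", ids[anyDuplicated(ids)])
  }
  expr <- do.call(cbind, lapply(cohorts, function(x) x$expr[genes, , drop = FALSE]))
  common_cols <- Reduce(intersect, lapply(cohorts, function(x) names(x$pheno)))
  pheno <- do.call(rbind, lapply(cohorts, function(x) x$pheno[, common_cols, drop = FALSE]))
  ss_log("merged ", length(cohorts), " cohorts on ", length(genes), " common genes")
  cohort(expr, pheno)
}
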