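# Residual-confounding audits: per-feature correlations with each confound,
# a multivariate r^2 / adjusted-r^2 check (can the confound be predicted back
# from the residual features?), and the group-difference test that
# establishes a variable as a confound in the first place.

#' Per-feature correlation of residual features with a confound
#'
#' Pearson r of every residual column with the confound, with a two-sided
#' p-value from `t = r sqrt(n-2) / sqrt(1-r^2)` on `n - 2` df. Constant
#' residual columns are reported as `r = 0` with a flag. A Bonferroni-
#' adjusted p column is included alongside the raw p-values; no correction is
#' applied by default.
#'
#' @param residuals numeric `n x p` residual-feature matrix, `n >= 4`.
#' @param confound length-`n` numeric confound vector, non-constant.
#' @return data frame with `feature`, `r`, `p`, `p_bonferroni`,
#'   `constant_feature`.
#' @export
univariate_residual_check <- function(residuals, confound) {
  residuals <- as_matrix_named(residuals, "residuals")
  n <- nrow(residuals)
  if (n < 4) stop2("need n >= 4")
  if (length(confound) != n) stop2("confound length must match rows")
  if (stats::sd(confound) == 0) stop2("confound is constant")
  sds <- apply(residuals, 2, stats::sd)
  const <- sds == 0
  r <- rep(0, ncol(residuals))
  if (any(!const)) {
    r[!const] <- as.numeric(stats::cor(residuals[, !const, drop = FALSE],
                                       confound))
  }
  r_t <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tstat <- r_t * sqrt(n - 2) / sqrt(1 - r_t^2)
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[const] <- 1
  data.frame(feature = colnames(residuals), r = r, p = p,
             p_bonferroni = stats::p.adjust(p, "bonferroni"),
             constant_feature = const, row.names = NULL)
}

#' Multivariate residual-confounding check (r-squared audit)
#'
#' Least-squares fit of the confound on `[1 | residuals]`; `r^2` from the
#' fitted values and `adjusted r^2 = 1 - (1 - r^2)(n - 1)/(n - p - 1)`.
#' After in-sample confound removal `r^2` is 0 by orthogonality and the
#' adjusted value is `1 - (n-1)/(n-p-1)`, i.e. negative for every `p >= 1` —
#' the signature of residual features carrying no confound information.
#' When `p >= n - 1` the fit is minimum-norm (flagged) and when
#' `n - p - 1 <= 0` the adjusted value is undefined (`NA`, flagged): in that
#' regime the formula's denominator is non-positive and the audit is not
#' interpretable.
#'
#' @param residuals numeric `n x p` residual-feature matrix.
#' @param confound length-`n` numeric confound vector, non-constant.
#' @return list: `r_squared`, `adj_r_squared` (NA when undefined), `n`, `p`,
#'   `min_norm` and `adj_undefined` flags.
#' @export
multivariate_residual_check <- function(residuals, confound) {
  residuals <- as_matrix_named(residuals, "residuals")
  n <- nrow(residuals)
  p <- ncol(residuals)
  if (n < 3) stop2("need n >= 3")
  if (length(confound) != n) stop2("confound length must match rows")
  if (stats::sd(confound) == 0) stop2("confound is constant")
  A <- cbind(1, residuals)
  min_norm <- p >= n - 1
  if (min_norm) {
    sv <- svd(A)
    pos <- sv$d > max(sv$d) * 1e-12
    fitted <- sv$u[, pos, drop = FALSE] %*%
      crossprod(sv$u[, pos, drop = FALSE], confound)
  } else {
    fitted <- qr.fitted(qr(A), confound)
  }
  ss_res <- sum((confound - fitted)^2)
  ss_tot <- sum((confound - mean(confound))^2)
  r2 <- 1 - ss_res / ss_tot
  adj_undef <- (n - p - 1) <= 0
  adj <- if (adj_undef) NA_real_ else 1 - (1 - r2) * (n - 1) / (n - p - 1)
  list(r_squared = r2, adj_r_squared = adj, n = n, p = p,
       min_norm = min_norm, adj_undefined = adj_undef)
}

#' Two-sample (Welch) t-test for a group difference
#'
#' The test used to establish a variable as a confound: e.g. a significant
#' sex difference in brain size. Welch's unequal-variance form.
#'
#' @param values numeric vector.
#' @param labels binary 0/1 group labels, at least 2 per group.
#' @return list with `t` (statistic, group 1 minus group 0) and `p`
#'   (two-sided).
#' @export
group_difference_test <- function(values, labels) {
  labels <- check_binary_target(labels)
  if (min(table(labels)) < 2) stop2("need at least 2 samples per group")
  ht <- stats::t.test(values[labels == 1], values[labels == 0])
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Full residual-confounding diagnostics for a residual matrix
#'
#' Runs [univariate_residual_check()] and [multivariate_residual_check()]
#' against every confound column and bundles the results with a context tag.
#'
#' @param residuals numeric `n x p` residual matrix.
#' @param confounds numeric `n x c` confound matrix.
#' @param context tag for reporting: `"train"`, `"validation"` or `"oos"`.
#' @return an object of class `diagnostics_report`: per-confound list of
#'   `univariate` (data frame) and `multivariate` (list), plus `n`, `p`,
#'   `context`.
#' @export
residual_diagnostics <- function(residuals, confounds,
                                 context = c("train", "validation", "oos")) {
  context <- match.arg(context)
  confounds <- as_matrix_named(confounds, "confounds")
  per_conf <- lapply(seq_len(ncol(confounds)), function(k) {
    list(univariate = univariate_residual_check(residuals, confounds[, k]),
         multivariate = multivariate_residual_check(residuals, confounds[, k]))
  })
  names(per_conf) <- colnames(confounds)
  structure(list(confounds = per_conf, n = nrow(residuals),
                 p = ncol(residuals), context = context),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat(sprintf("<diagnostics_report> context = %s, n = %d, p = %d\n",
              x$context, x$n, x$p))
  for (nm in names(x$confounds)) {
    u <- x$confounds[[nm]]$univariate
    m <- x$confounds[[nm]]$multivariate
    cat(sprintf("  %s: max |r| = %.4g, min p = %.3g; r2 = %.4g, adj r2 = %s%s\n",
                nm, max(abs(u$r)), min(u$p), m$r_squared,
                if (is.na(m$adj_r_squared)) "undefined"
                else sprintf("%.4g", m$adj_r_squared),
                if (m$min_norm) " [min-norm fit]" else ""))
  }
  invisible(x)
}

#' Write a diagnostics report as TSV + JSON summary
#'
#' @param report a `diagnostics_report`.
#' @param prefix output path prefix.
#' @return invisibly, the file paths.
#' @export
write_diagnostics_report <- function(report, prefix) {
  tab <- do.call(rbind, lapply(names(report$confounds), function(nm) {
    u <- report$confounds[[nm]]$univariate
    cbind(confound = nm, u)
  }))
  f_tsv <- paste0(prefix, "_univariate.tsv")
  f_json <- paste0(prefix, "_summary.json")
  utils::write.table(tab, f_tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(context = report$context, n = report$n, p = report$p,
         multivariate = lapply(report$confounds, `[[`, "multivariate"),
         max_abs_r = lapply(report$confounds,
                            function(z) max(abs(z$univariate$r)))),
    f_json, auto_unbox = TRUE, digits = NA
  )
  invisible(c(univariate = f_tsv, summary = f_json))
}
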