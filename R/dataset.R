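#' Assemble a dataset of features, confounds and a binary target
#'
#' The basic container moved through every pipeline stage: an `n x p` feature
#' matrix, an aligned `n x c` confound matrix (`c >= 1`, e.g. brain size and
#' age) and a binary target (e.g. sex coded 0/1), with sample ids.
#'
#' @param features numeric `n x p` matrix or data frame of features.
#' @param confounds numeric `n x c` matrix or data frame of confounds.
#' @param target length-`n` binary (0/1) vector.
#' @param ids optional character sample identifiers.
#' @param feature_roles optional character vector of per-feature ground-truth
#'   roles (used by the synthetic generator).
#' @return an object of class `confound_dataset`.
#' @export
#' @examples
#' ds <- confound_dataset(matrix(rnorm(20), 10), matrix(rnorm(10), 10),
#'                        rep(c(0, 1), 5))
#' ds
confound_dataset <- function(features, confounds, target, ids = NULL,
                             feature_roles = NULL) {
  features <- as_matrix_named(features, "features")
  confounds <- as_matrix_named(confounds, "confounds")
  target <- check_binary_target(target)
  n <- nrow(features)
  if (nrow(confounds) != n || length(target) != n) {
    stop2("features, confounds and target must have matching row counts")
  }
  if (ncol(confounds) < 1) stop2("at least one confound is required")
  if (is.null(ids)) ids <- sprintf("sample_%04d", seq_len(n))
  if (!is.null(feature_roles) && length(feature_roles) != ncol(features)) {
    stop2("feature_roles length must equal the number of features")
  }
  structure(
    list(features = features, confounds = confounds, target = target,
         ids = ids, feature_roles = feature_roles),
    class = "confound_dataset"
  )
}

#' @export
print.confound_dataset <- function(x, ...) {
  cat(sprintf(
    "<confound_dataset> %d samples x %d features, %d confound(s); class balance %d/%d\n",
    nrow(x$features), ncol(x$features), ncol(x$confounds),
    sum(x$target == 1), sum(x$target == 0)
  ))
  if (!is.null(x$feature_roles)) {
    cat("  feature roles:", paste(sprintf("%s=%d", names(table(x$feature_roles)),
                                          table(x$feature_roles)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset a dataset by row indices
#'
#' @param dataset a [confound_dataset()].
#' @param idx integer or logical row index.
#' @return a `confound_dataset` restricted to `idx`.
#' @export
dataset_subset <- function(dataset, idx) {
  confound_dataset(
    dataset$features[idx, , drop = FALSE],
    dataset$confounds[idx, , drop = FALSE],
    dataset$target[idx],
    ids = dataset$ids[idx],
    feature_roles = dataset$feature_roles
  )
}

#' Write a dataset to delimited text files plus a JSON sidecar
#'
#' Writes `<prefix>_features.csv`, `<prefix>_pheno.csv` (confounds + target +
#' ids) and `<prefix>_meta.json` (ground-truth feature roles and, for
#' synthetic data, the full generator configuration).
#'
#' @param dataset a [confound_dataset()].
#' @param prefix output path prefix.
#' @param sep field separator: `","` (csv, default) or `"\t"` (tsv).
#' @return invisibly, the three file paths.
#' @export
write_dataset <- function(dataset, prefix, sep = ",") {
  ext <- if (sep == "\t") "tsv" else "csv"
  f_feat <- paste0(prefix, "_features.", ext)
  f_pheno <- paste0(prefix, "_pheno.", ext)
  f_meta <- paste0(prefix, "_meta.json")
  utils::write.table(
    data.frame(id = dataset$ids, dataset$features, check.names = FALSE),
    f_feat, sep = sep, row.names = FALSE, quote = FALSE
  )
  utils::write.table(
    data.frame(id = dataset$ids, dataset$confounds, target = dataset$target,
               check.names = FALSE),
    f_pheno, sep = sep, row.names = FALSE, quote = FALSE
  )
  meta <- list(
    feature_names = colnames(dataset$features),
    confound_names = colnames(dataset$confounds),
    feature_roles = dataset$feature_roles,
    config = attr(dataset, "config")
  )
  jsonlite::write_json(meta, f_meta, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(features = f_feat, pheno = f_pheno, meta = f_meta))
}

#' Read a dataset written by [write_dataset()]
#'
#' @param prefix path prefix used when writing.
#' @param sep field separator used when writing.
#' @return a [confound_dataset()].
#' @export
read_dataset <- function(prefix, sep = ",") {
  ext <- if (sep == "\t") "tsv" else "csv"
  feat <- utils::read.table(paste0(prefix, "_features.", ext), sep = sep,
                            header = TRUE, check.names = FALSE)
  pheno <- utils::read.table(paste0(prefix, "_pheno.", ext), sep = sep,
                             header = TRUE, check.names = FALSE)
  meta_path <- paste0(prefix, "_meta.json")
  roles <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    roles <- meta$feature_roles
  }
  confound_dataset(
    as.matrix(feat[, -1, drop = FALSE]),
    as.matrix(pheno[, setdiff(colnames(pheno), c("id", "target")), drop = FALSE]),
    pheno$target, ids = as.character(feat$id), feature_roles = roles
  )
}

#' Assemble a dataset from user-supplied tables
#'
#' Convenience loader for arbitrary feature/confound tables: reads a feature
#' table and a phenotype table (both with an id column), takes `target_col`
#' from the phenotype table as the binary target and the remaining named
#' columns as confounds.
#'
#' @param features_path delimited file of samples x features, first column id.
#' @param pheno_path delimited file with id, confound columns and the target.
#' @param target_col name of the binary target column in `pheno_path`.
#' @param confound_cols confound column names; default all non-id, non-target.
#' @param sep field separator (`","` or `"\t"`; inferred from extension if NULL).
#' @return a [confound_dataset()].
#' @export
load_dataset <- function(features_path, pheno_path, target_col,
                         confound_cols = NULL, sep = NULL) {
  infer <- function(p) if (grepl("\\.tsv$", p)) "\t" else ","
  feat <- utils::read.table(features_path, sep = sep %||% infer(features_path),
                            header = TRUE, check.names = FALSE)
  pheno <- utils::read.table(pheno_path, sep = sep %||% infer(pheno_path),
                             header = TRUE, check.names = FALSE)
  if (!target_col %in% colnames(pheno)) {
    stop2("target column '", target_col, "' not found")
  }
  id_col <- colnames(pheno)[1]
  m <- match(feat[[1]], pheno[[id_col]])
  if (anyNA(m)) stop2("sample ids do not align between the two tables")
  pheno <- pheno[m, , drop = FALSE]
  confound_cols <- confound_cols %||%
    setdiff(colnames(pheno), c(id_col, target_col))
  confound_dataset(
    as.matrix(feat[, -1, drop = FALSE]),
    as.matrix(pheno[, confound_cols, drop = FALSE]),
    pheno[[target_col]], ids = as.character(feat[[1]])
  )
}
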