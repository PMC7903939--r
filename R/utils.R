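# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop2 <- function(...) stop(..., call. = FALSE)

#' Run code under a seed without disturbing the caller's RNG state
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  code
}

# Deterministic sub-seed derivation, kept below 2^31 (R integers are 32-bit).
derive_seed <- function(seed, ...) {
  v <- c(seed, ...)
  x <- 0
  for (k in v) x <- (x * 69069 + abs(k) + 1) %% 2147483647
  as.integer(x)
}

#' Largest-remainder apportionment of a total into integer counts
#'
#' Splits `total` into integer counts proportional to `fractions`, summing
#' exactly to `total`; ties on the fractional remainder are broken by
#' ascending index so the result is deterministic.
#'
#' @param fractions nonnegative numeric vector summing to 1.
#' @param total positive integer total.
#' @return integer vector of the same length as `fractions`.
#' @keywords internal
#' @noRd
largest_remainder <- function(fractions, total) {
  raw <- fractions * total
  base <- floor(raw)
  short <- total - sum(base)
  if (short > 0) {
    rem <- raw - base
    take <- order(-rem, seq_along(rem))[seq_len(short)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

# Stratified fold assignment: within each class, a seeded permutation is dealt
# round-robin into folds, so folds partition the sample exactly.
stratified_folds <- function(y, n_folds, seed, stratified = TRUE) {
  n <- length(y)
  folds <- integer(n)
  with_seed(seed, {
    if (stratified) {
      # deal each class round-robin, continuing the fold counter across
      # classes so fold sizes stay balanced even when k exceeds class counts
      start <- 0L
      for (cls in unique(y)) {
        idx <- which(y == cls)
        idx <- idx[sample.int(length(idx))]
        folds[idx] <- ((start + seq_along(idx) - 1L) %% n_folds) + 1L
        start <- start + length(idx)
      }
    } else {
      folds[sample.int(n)] <- rep_len(seq_len(n_folds), n)
    }
  })
  folds
}

as_matrix_named <- function(x, what) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  if (!is.numeric(x)) stop2(what, " must be numeric")
  if (anyNA(x)) stop2(what, " contains missing values")
  if (is.null(colnames(x))) {
    colnames(x) <- paste0(sub("s$", "", what), "_", seq_len(ncol(x)))
  }
  x
}

check_binary_target <- function(y) {
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop2("target must be binary 0/1")
  y
}

# md5 of an in-memory object, for provenance stamps in reports.
content_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}
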