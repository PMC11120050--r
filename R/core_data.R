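#' Bundle a data table with its labels and normalization state
#'
#' A `data_bundle` holds one table on the normalized scale: the numeric
#' matrix `X` (samples in rows, features in columns), an optional integer
#' class label vector `y` coded `0..C-1`, the column names, and the
#' per-column `(min, max)` pairs on the raw scale that invert the
#' normalization.
#'
#' @param X numeric matrix, samples x features. Finite entries are expected
#'   to lie in `[0, 1]`; `NaN`/`NA` marks missing cells.
#' @param y optional integer vector of class labels, length `nrow(X)`,
#'   values in `0..C-1`.
#' @param col_names character vector of feature names; defaults to
#'   `colnames(X)` or `V1..Vn`.
#' @param norm optional 2 x n matrix with rows `min` and `max` on the raw
#'   scale, as produced by [minmax_normalize()].
#' @return an object of class `data_bundle`: a list with elements `X`, `y`,
#'   `col_names`, `norm`.
#' @seealso [minmax_normalize()], [generate_fixture()]
#' @export
data_bundle <- function(X, y = NULL, col_names = NULL, norm = NULL) {
  X <- as_num_matrix(X, "X")
  n <- ncol(X)
  if (is.null(col_names)) {
    col_names <- colnames(X)
    if (is.null(col_names)) col_names <- paste0("V", seq_len(n))
  }
  if (length(col_names) != n) stop("col_names must have one entry per column")
  fin <- X[is.finite(X)]
  if (length(fin) && (min(fin) < -1e-9 || max(fin) > 1 + 1e-9)) {
    stop("X must be on the normalized [0, 1] scale; run minmax_normalize() first")
  }
  if (!is.null(y)) {
    y <- as.integer(y)
    if (length(y) != nrow(X)) stop("y must have one label per row of X")
    if (anyNA(y) || any(y < 0)) stop("labels must be non-negative integers 0..C-1")
  }
  if (!is.null(norm)) {
    norm <- as_num_matrix(norm, "norm")
    if (nrow(norm) != 2L || ncol(norm) != n) stop("norm must be a 2 x n matrix")
    if (any(norm[1, ] > norm[2, ])) stop("norm must satisfy min <= max per column")
  }
  colnames(X) <- col_names
  structure(list(X = X, y = y, col_names = col_names, norm = norm),
            class = "data_bundle")
}

#' @export
print.data_bundle <- function(x, ...) {
  C <- n_classes(x)
  cat(sprintf("data_bundle: %d samples x %d features, %s\n",
              nrow(x$X), ncol(x$X),
              if (is.null(x$y)) "unlabelled" else sprintf("%d classes", C)))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", sum(!is.finite(x$X)),
              100 * mean(!is.finite(x$X))))
  invisible(x)
}

n_classes <- function(bundle) {
  if (is.null(bundle$y)) 0L else max(bundle$y) + 1L
}

#' Min-max normalize a raw table column by column
#'
#' Linearly maps each column so its observed minimum becomes 0 and its
#' observed maximum becomes 1, ignoring missing cells, and records the
#' `(min, max)` pair so the map is exactly invertible with
#' [minmax_denormalize()]. A constant column maps to all zeros (its raw
#' value is still recovered on inversion).
#'
#' @param raw numeric matrix; `NaN`/`NA` cells are ignored when computing
#'   the per-column range and stay missing in the output.
#' @return list with `X` (normalized matrix) and `norm` (2 x n matrix with
#'   rows `min` and `max`).
#' @examples
#' minmax_normalize(cbind(a = c(0, 5, 10)))$X
#' @export
minmax_normalize <- function(raw) {
  raw <- as_num_matrix(raw, "raw")
  if (nrow(raw) < 1L) stop("raw must have at least one row")
  n <- ncol(raw)
  nm <- colnames(raw)
  if (is.null(nm)) nm <- paste0("V", seq_len(n))
  lo <- hi <- numeric(n)
  X <- raw
  for (j in seq_len(n)) {
    v <- raw[, j]
    obs <- v[is.finite(v)]
    if (!length(obs)) {
      stop(sprintf("column '%s' is entirely missing; cannot normalize", nm[j]))
    }
    lo[j] <- min(obs)
    hi[j] <- max(obs)
    rng <- hi[j] - lo[j]
    X[, j] <- if (rng > 0) (v - lo[j]) / rng else ifelse(is.finite(v), 0, v)
  }
  norm <- rbind(min = lo, max = hi)
  colnames(norm) <- nm
  list(X = X, norm = norm)
}

#' Invert min-max normalization
#'
#' @param X matrix on the normalized scale.
#' @param norm 2 x n matrix of per-column `(min, max)` from
#'   [minmax_normalize()].
#' @return matrix on the raw scale; missing cells stay missing.
#' @export
minmax_denormalize <- function(X, norm) {
  X <- as_num_matrix(X, "X")
  norm <- as_num_matrix(norm, "norm")
  if (ncol(norm) != ncol(X) || nrow(norm) != 2L) {
    stop("norm must be a 2 x ncol(X) matrix")
  }
  sweep(sweep(X, 2, norm[2, ] - norm[1, ], `*`), 2, norm[1, ], `+`)
}

#' Mask a matrix: keep observed cells, blank missing ones
#'
#' Applies the binary mask `M` (1 = observed, 0 = missing) to `X`,
#' producing the incomplete matrix with `NaN` at masked positions. `NaN`
#' rather than 0 is used so that a masked cell can never be confused with
#' a legitimate zero.
#'
#' @param X numeric matrix.
#' @param M binary mask matrix of the same shape.
#' @return matrix equal to `X` where `M == 1` and `NaN` where `M == 0`.
#' @export
apply_mask <- function(X, M) {
  X <- as_num_matrix(X, "X")
  M <- check_binary_mask(M)
  check_same_shape(X, M, c("X", "M"))
  X[M == 0] <- NaN
  X
}

#' Replace missing cells with clipped Gaussian noise
#'
#' Converts the incomplete matrix into a fully numeric training input by
#' drawing independent zero-mean Gaussian noise (sd `z_sigma`, clipped to
#' `[0, 1]` to stay on the normalized scale) at every missing cell.
#' Observed cells are untouched. Reproducible: the same seed gives the
#' same fill.
#'
#' @param X_tilde matrix with `NaN` at missing cells.
#' @param z_sigma noise standard deviation (>= 0); default 0.01.
#' @param seed integer seed for the draws.
#' @return list of class `noise_fill` with `X_prime` (no missing cells),
#'   `Z` (the noise matrix used, zero at observed cells), `z_sigma`,
#'   `seed`.
#' @export
noise_fill <- function(X_tilde, z_sigma = 0.01, seed = 1L) {
  X_tilde <- as_num_matrix(X_tilde, "X_tilde")
  if (z_sigma < 0) stop("z_sigma must be >= 0")
  miss <- !is.finite(X_tilde)
  Z <- matrix(0, nrow(X_tilde), ncol(X_tilde))
  if (any(miss)) {
    z <- with_seed(seed, stats::rnorm(sum(miss), mean = 0, sd = z_sigma))
    Z[miss] <- clip01(z)
  }
  X_prime <- X_tilde
  X_prime[miss] <- Z[miss]
  structure(list(X_prime = X_prime, Z = Z, z_sigma = z_sigma, seed = seed),
            class = "noise_fill")
}

#' Compose the final imputed matrix
#'
#' Keeps observed values verbatim and substitutes generator (or baseline)
#' outputs only at missing positions:
#' `X_hat = M * X_tilde + (1 - M) * G_out`.
#'
#' @param X_tilde incomplete matrix (`NaN` at missing cells).
#' @param M binary mask, 1 = observed.
#' @param G_out candidate fill matrix, same shape, no missing values.
#' @return the composed matrix.
#' @export
compose_imputed <- function(X_tilde, M, G_out) {
  X_tilde <- as_num_matrix(X_tilde, "X_tilde")
  M <- check_binary_mask(M)
  G_out <- as_num_matrix(G_out, "G_out")
  check_same_shape(X_tilde, M, c("X_tilde", "M"))
  check_same_shape(X_tilde, G_out, c("X_tilde", "G_out"))
  if (any(!is.finite(G_out))) stop("G_out must not contain NaN/Inf")
  out <- G_out
  out[M == 1] <- X_tilde[M == 1]
  out
}

#' Repeated k-fold cross-validation splits
#'
#' Builds `n_repeats` independent k-fold partitions of `1..m` (the default
#' 5 folds give the 4:1 train:test ratio of the experimental protocol).
#' When labels are supplied, folds are stratified so each class's
#' proportions are preserved to within one sample per fold.
#'
#' @param m number of samples.
#' @param k_folds folds per repeat (default 5).
#' @param n_repeats number of repeats (default 10).
#' @param seed integer seed; repeat `r` uses the derived seed `seed + r - 1`.
#' @param y optional label vector for stratification.
#' @return list of length `n_repeats`; each element is a list of `k_folds`
#'   integer vectors of test indices that partition `1..m`.
#' @export
make_splits <- function(m, k_folds = 5L, n_repeats = 10L, seed = 1L, y = NULL) {
  if (m < k_folds) stop(sprintf("m = %d is smaller than k_folds = %d", m, k_folds))
  if (!is.null(y) && length(y) != m) stop("y must have length m")
  lapply(seq_len(n_repeats), function(r) {
    fold_of <- with_seed(seed + r - 1L, {
      f <- integer(m)
      if (is.null(y)) {
        f <- sample(rep_len(seq_len(k_folds), m))
      } else {
        for (cls in unique(y)) {
          idx <- which(y == cls)
          f[sample(idx)] <- rep_len(seq_len(k_folds), length(idx))
        }
      }
      f
    })
    lapply(seq_len(k_folds), function(k) which(fold_of == k))
  })
}

#' Read a table in the package CSV schema
#'
#' Header row carries column names; an empty cell, `NA` or `NaN` marks a
#' missing value. One column may be designated as the class label.
#'
#' @param path CSV file path.
#' @param label_col name of the label column, or `NULL` for unlabelled data.
#' @return list with `X` (numeric matrix on the raw scale, `NaN` for
#'   missing), `y` (integer labels 0..C-1 or `NULL`), `col_names`, and
#'   `label_levels` (original label values, or `NULL`).
#' @export
read_table_csv <- function(path, label_col = NULL) {
  df <- utils::read.csv(path, check.names = FALSE,
                        na.strings = c("", "NA", "NaN", "nan"))
  y <- NULL
  label_levels <- NULL
  if (!is.null(label_col)) {
    if (!label_col %in% names(df)) {
      stop(sprintf("label column '%s' not found", label_col))
    }
    raw_y <- df[[label_col]]
    if (anyNA(raw_y)) stop("label column must not contain missing values")
    label_levels <- sort(unique(raw_y))
    y <- as.integer(match(raw_y, label_levels) - 1L)
    df[[label_col]] <- NULL
  }
  X <- as.matrix(df)
  storage.mode(X) <- "double"
  X[!is.finite(X)] <- NaN
  list(X = X, y = y, col_names = colnames(X), label_levels = label_levels)
}

#' Write a table in the package CSV schema
#'
#' Finite values are written with 12 significant digits (round-trips
#' bit-identically through [read_table_csv()] at that precision); missing
#' cells are written as empty fields.
#'
#' @param X numeric matrix with optional `NaN` missing cells.
#' @param path output CSV path.
#' @param y optional label vector, written as column `label`.
#' @param col_names column names; defaults to `colnames(X)`.
#' @export
write_table_csv <- function(X, path, y = NULL, col_names = colnames(X)) {
  X <- as_num_matrix(X, "X")
  if (is.null(col_names)) col_names <- paste0("V", seq_len(ncol(X)))
  fmt <- function(v) ifelse(is.finite(v), sprintf("%.12g", v), "")
  cells <- apply(X, 2, fmt)
  if (!is.matrix(cells)) cells <- matrix(cells, nrow = nrow(X))
  colnames(cells) <- col_names
  df <- as.data.frame(cells, check.names = FALSE)
  if (!is.null(y)) df$label <- y
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}
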