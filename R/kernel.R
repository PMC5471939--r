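#' Tanimoto similarity between two fingerprint vectors
#'
#' For binary vectors the Tanimoto coefficient is the ratio of the number of
#' shared on-bits to the number of bits on in either vector. For non-negative
#' real vectors (weighted fingerprints) the continuous generalization
#' \deqn{T(a,b) = a\cdot b / (\|a\|^2 + \|b\|^2 - a\cdot b)}
#' is used; it reduces exactly to the binary form on 0/1 input. Two all-zero
#' vectors have, by convention, similarity 0 (with a warning).
#'
#' @param a,b Non-negative numeric vectors of equal length.
#' @param variant `"continuous"` (default) or `"binary"`; the binary variant
#'   additionally requires 0/1 entries.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b, variant = c("continuous", "binary")) {
  variant <- match.arg(variant)
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (any(a < 0) || any(b < 0)) stop("Tanimoto similarity requires non-negative entries")
  if (variant == "binary" && !all(c(a, b) %in% c(0, 1))) {
    stop("binary variant requires 0/1 vectors")
  }
  ab <- sum(a * b)
  den <- sum(a * a) + sum(b * b) - ab
  if (den == 0) {
    warning("both vectors are all-zero; Tanimoto similarity defined as 0")
    return(0)
  }
  ab / den
}

#' Pairwise Tanimoto kernel matrix
#'
#' Assembles the matrix of pairwise Tanimoto similarities, either within one
#' dataset (square, symmetric, unit diagonal for nonzero rows — usable as a
#' precomputed SVM kernel) or between two sets of fingerprints (e.g. test
#' compounds vs. training compounds). Replacing the 881-dimensional feature
#' space by compound-compound similarities reduces the model dimension to the
#' number of compounds.
#'
#' @param X_rows Fingerprint matrix providing the rows of the kernel.
#' @param X_cols Optional second matrix providing the columns; defaults to
#'   `X_rows` (self-kernel).
#' @param variant `"continuous"` or `"binary"` as in [tanimoto()].
#' @return An object of class `kernel_matrix`: list with the similarity
#'   matrix `K`, `row_ids`, `col_ids` and `variant`.
#' @export
kernel_matrix <- function(X_rows, X_cols = NULL, variant = c("continuous", "binary")) {
  variant <- match.arg(variant)
  X_rows <- as.matrix(X_rows)
  square <- is.null(X_cols)
  X_cols <- if (square) X_rows else as.matrix(X_cols)
  if (ncol(X_rows) != ncol(X_cols)) {
    stop("fingerprint bit dimensions differ: ", ncol(X_rows), " vs ", ncol(X_cols))
  }
  if (any(X_rows < 0) || any(X_cols < 0)) stop("Tanimoto similarity requires non-negative entries")
  if (variant == "binary" && (!all(X_rows %in% c(0, 1)) || !all(X_cols %in% c(0, 1)))) {
    stop("binary variant requires 0/1 matrices")
  }
  S <- X_rows %*% t(X_cols)
  nr <- rowSums(X_rows^2)
  nc <- rowSums(X_cols^2)
  den <- outer(nr, nc, `+`) - S
  if (any(nr == 0) || any(nc == 0)) {
    warning("all-zero fingerprint row(s); their Tanimoto similarities are set to 0")
  }
  K <- ifelse(den == 0, 0, S / den)
  structure(list(K = K,
                 row_ids = rownames(X_rows) %||% as.character(seq_len(nrow(X_rows))),
                 col_ids = rownames(X_cols) %||% as.character(seq_len(nrow(X_cols))),
                 variant = variant, square = square),
            class = "kernel_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.kernel_matrix <- function(x, ...) {
  cat("<kernel_matrix> ", nrow(x$K), " x ", ncol(x$K), " (", x$variant, ")\n", sep = "")
  invisible(x)
}

#' Export a kernel matrix as CSV
#'
#' Square CSV with compound IDs as header row and first column, suitable as a
#' precomputed-kernel input file.
#'
#' @param km A `kernel_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_kernel_csv <- function(km, path) {
  stopifnot(inherits(km, "kernel_matrix"))
  df <- data.frame(id = km$row_ids, km$K, check.names = FALSE)
  colnames(df) <- c("id", km$col_ids)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
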