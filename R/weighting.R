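#' Count substructure occurrences per class
#'
#' For each fingerprint bit, counts how many DILI-positive and DILI-negative
#' compounds contain the substructure. Unlabeled compounds are ignored.
#'
#' @param ds A labeled [fp_dataset()] with at least one positive and one
#'   negative compound.
#' @return An object of class `substructure_counts`: a list with integer
#'   vectors `c_SP`, `c_SN` (per-bit presence counts among positives and
#'   negatives) and scalars `N_P`, `N_N` (class sizes).
#' @export
count_substructures <- function(ds) {
  stopifnot(inherits(ds, "fp_dataset"))
  pos <- ds$labels == "positive"
  neg <- ds$labels == "negative"
  if (!any(pos) || !any(neg)) {
    stop("dataset must contain at least one positive and one negative labeled compound")
  }
  structure(list(c_SP = colSums(ds$X[pos, , drop = FALSE]),
                 c_SN = colSums(ds$X[neg, , drop = FALSE]),
                 N_P = sum(pos), N_N = sum(neg)),
            class = "substructure_counts")
}

#' Smoothed Bayesian substructure statistics
#'
#' Turns raw per-bit class counts into the statistics driving feature
#' weighting. The conditional probability that a substructure S is present in
#' a class is Laplace-smoothed with pseudo-count `k` over the
#' `outcome_card` = 2 outcomes (bit present / absent):
#' \deqn{P(S|P) = (c_{SP} + k) / (N_P + k\,|X|)}
#' The posterior that a compound carrying S is DILI-positive follows from
#' Bayes' rule with class priors \eqn{P(P) = N_P/(N_P+N_N)}:
#' \deqn{P(P|S) = P(S|P)P(P) / (P(S|P)P(P) + P(S|N)P(N))}
#' and each bit is scored by its log2 odds ratio
#' \eqn{L = \log_2(P(P|S)/P(N|S))}. A large L marks a substructure enriched in
#' hepatotoxic compounds.
#'
#' @param counts A `substructure_counts` object from [count_substructures()],
#'   or a list with fields `c_SP`, `c_SN`, `N_P`, `N_N`.
#' @param k Laplace pseudo-count (non-negative; default 1, classic add-one
#'   smoothing). With `k = 0` any bit absent from (or fixed in) an entire
#'   class has a degenerate probability and an error is raised.
#' @param outcome_card Cardinality of the smoothed outcome space (2: a bit is
#'   present or absent).
#' @param smooth_priors Smooth the class priors with the same pseudo-count as
#'   well (default `FALSE`: priors are the empirical class frequencies).
#' @return An object of class `substructure_stats` carrying the counts plus
#'   per-bit `p_S_given_P`, `p_S_given_N`, `post_P`, `post_N`, `L`, and the
#'   scalars `prior_P`, `prior_N`, `k`.
#' @export
smoothed_stats <- function(counts, k = 1, outcome_card = 2L, smooth_priors = FALSE) {
  c_SP <- counts$c_SP; c_SN <- counts$c_SN
  N_P <- counts$N_P; N_N <- counts$N_N
  stopifnot(length(c_SP) == length(c_SN), N_P >= 1, N_N >= 1)
  if (any(c_SP < 0) || any(c_SP > N_P) || any(c_SN < 0) || any(c_SN > N_N)) {
    stop("counts must satisfy 0 <= c_SP <= N_P and 0 <= c_SN <= N_N")
  }
  if (k < 0) stop("Laplace pseudo-count k must be non-negative")
  if (k == 0 && (any(c_SP == 0) || any(c_SP == N_P) || any(c_SN == 0) || any(c_SN == N_N))) {
    stop("k = 0 with a bit absent from (or fixed in) an entire class gives a ",
         "degenerate probability; use Laplace smoothing with k > 0")
  }
  p_S_given_P <- (c_SP + k) / (N_P + k * outcome_card)
  p_S_given_N <- (c_SN + k) / (N_N + k * outcome_card)
  if (smooth_priors) {
    prior_P <- (N_P + k) / (N_P + N_N + k * outcome_card)
  } else {
    prior_P <- N_P / (N_P + N_N)
  }
  prior_N <- 1 - prior_P
  num <- p_S_given_P * prior_P
  den <- num + p_S_given_N * prior_N
  post_P <- num / den
  post_N <- 1 - post_P
  structure(list(c_SP = c_SP, c_SN = c_SN, N_P = N_P, N_N = N_N, k = k,
                 outcome_card = outcome_card,
                 p_S_given_P = p_S_given_P, p_S_given_N = p_S_given_N,
                 prior_P = prior_P, prior_N = prior_N,
                 post_P = post_P, post_N = post_N,
                 L = log2(post_P / post_N)),
            class = "substructure_stats")
}

#' @export
print.substructure_stats <- function(x, ...) {
  cat("<substructure_stats> ", length(x$L), " bits; N_P=", x$N_P, " N_N=", x$N_N,
      " k=", x$k, "\n  L range [", round(min(x$L), 3), ", ", round(max(x$L), 3),
      "]\n", sep = "")
  invisible(x)
}

#' Build a multiplicative weight vector from log-odds scores
#'
#' Bits whose log2 odds ratio reaches the selection threshold `theta` receive
#' the weight `n_mult * L` (the thresholded score itself, amplified by the
#' user multiplier); all other bits keep weight 1 so the fingerprint stays
#' binary there. Only positively-associated (high-L) bits are ever weighted:
#' the aim is to emphasise substructures frequent in hepatotoxic compounds.
#' `theta = Inf` is the "no weighting" sentinel and yields an all-ones vector.
#'
#' @param stats A `substructure_stats` object.
#' @param theta Selection threshold on L; must be strictly positive so that
#'   every selected weight `n_mult * L` is positive. Selection uses `L >= theta`
#'   (ties at the threshold are included).
#' @param n_mult Amplification multiplier, positive (default 15).
#' @return An object of class `weight_vector`: list with numeric `w` (one
#'   weight per bit), `selected` (1-based column indices of weighted bits; the
#'   0-based PubChem bit index is `selected - 1`), `theta`, `n_mult`.
#' @export
build_weight_vector <- function(stats, theta, n_mult = 15) {
  stopifnot(inherits(stats, "substructure_stats"))
  if (!is.finite(n_mult) || n_mult <= 0) stop("n_mult must be a positive number")
  if (is.na(theta) || theta <= 0) {
    stop("theta must be > 0 (a non-positive threshold would select bits with ",
         "non-positive weights); use theta = Inf to disable weighting")
  }
  selected <- as.integer(which(stats$L >= theta))
  w <- rep(1, length(stats$L))
  w[selected] <- n_mult * stats$L[selected]
  names(w) <- names(stats$L)
  structure(list(w = w, selected = selected, theta = theta, n_mult = n_mult,
                 k = stats$k, N_P = stats$N_P, N_N = stats$N_N, L = stats$L),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("<weight_vector> ", length(x$w), " bits; theta=", x$theta, ", n_mult=",
      x$n_mult, "; ", length(x$selected), " bits weighted\n", sep = "")
  invisible(x)
}

#' Apply a weight vector to a fingerprint matrix
#'
#' Element-wise product of each fingerprint row with the weight vector:
#' `result[i, j] = X[i, j] * w[j]`. Zero bits stay zero; selected bits carry
#' their amplified log-odds weight instead of 1.
#'
#' @param X Binary fingerprint matrix (compounds x bits).
#' @param w A `weight_vector` or a plain numeric vector of per-bit weights.
#' @return Weighted numeric matrix of the same shape.
#' @export
apply_weights <- function(X, w) {
  wv <- if (inherits(w, "weight_vector")) w$w else as.numeric(w)
  X <- as.matrix(X)
  if (ncol(X) != length(wv)) {
    stop("weight vector length (", length(wv), ") does not match number of ",
         "fingerprint bits (", ncol(X), ")")
  }
  sweep(X, 2L, wv, `*`)
}

#' Export a weight table
#'
#' Writes the per-bit weight table as CSV (`bit_index,L,selected,weight`,
#' 0-based bit indices) plus a JSON sidecar recording `theta`, `n_mult`, `k`
#' and the class counts, so a weighting run can be reproduced and re-parsed.
#'
#' @param wv A `weight_vector`.
#' @param csv_path Output CSV path.
#' @param json_path Output JSON path (default: `csv_path` with `.json`).
#' @return `csv_path`, invisibly.
#' @export
write_weight_table <- function(wv, csv_path, json_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(wv, "weight_vector"))
  df <- data.frame(bit_index = seq_along(wv$w) - 1L,
                   L = wv$L,
                   selected = seq_along(wv$w) %in% wv$selected,
                   weight = wv$w)
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(theta = wv$theta, n_mult = wv$n_mult, k = wv$k,
                            N_P = wv$N_P, N_N = wv$N_N,
                            n_selected = length(wv$selected)),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' Re-read an exported weight table
#'
#' @param csv_path Weight CSV written by [write_weight_table()].
#' @param json_path Matching JSON sidecar.
#' @return A `weight_vector`.
#' @export
read_weight_table <- function(csv_path, json_path = sub("\\.csv$", ".json", csv_path)) {
  df <- utils::read.csv(csv_path)
  meta <- jsonlite::read_json(json_path)
  structure(list(w = df$weight, selected = which(df$selected),
                 theta = meta$theta, n_mult = meta$n_mult, k = meta$k,
                 N_P = meta$N_P, N_N = meta$N_N, L = df$L),
            class = "weight_vector")
}
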