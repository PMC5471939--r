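#' Specification of a synthetic fingerprint study
#'
#' Describes a generative model for labeled binary fingerprint data with a
#' planted discriminative signal: a subset of "causal" bits occurs at a
#' higher Bernoulli rate in DILI-positive than in DILI-negative compounds,
#' while background bits fire at one common rate in both classes and all bits
#' are independent. Defaults mirror the package's standard study conditions:
#' a 180:132 positive:negative imbalance, 881 bits, ten causal bits at rate
#' 0.6 in positives vs 0.1 in negatives, and a background rate of 0.15
#' (a typical set-bit density for PubChem fingerprints of drug-like
#' molecules). Real fingerprints have correlated bits; this generator does
#' not, by design, so analytical expectations stay tractable.
#'
#' @param n_pos,n_neg Class sizes (default 180 and 132).
#' @param n_bits Fingerprint length (default 881).
#' @param causal_bits 0-based indices of the planted bits (default `0:9`).
#' @param p_causal_pos,p_causal_neg Causal-bit rates in positives/negatives
#'   (defaults 0.6 and 0.1).
#' @param p_background Rate of every other bit in both classes (default 0.15).
#' @param seed Integer seed.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_pos = 180L, n_neg = 132L, n_bits = 881L,
                       causal_bits = 0:9, p_causal_pos = 0.6,
                       p_causal_neg = 0.1, p_background = 0.15, seed = 1L) {
  causal_bits <- as.integer(causal_bits)
  stopifnot(n_pos >= 1, n_neg >= 1, n_bits >= 1,
            all(causal_bits >= 0), all(causal_bits < n_bits),
            !anyDuplicated(causal_bits),
            p_causal_pos >= 0, p_causal_pos <= 1,
            p_causal_neg >= 0, p_causal_neg <= 1,
            p_background >= 0, p_background <= 1)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 n_bits = as.integer(n_bits), causal_bits = causal_bits,
                 p_causal_pos = p_causal_pos, p_causal_neg = p_causal_neg,
                 p_background = p_background, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a synthetic labeled fingerprint dataset
#'
#' Draws every bit independently from its class-specific Bernoulli rate as
#' described by the [synth_spec()]. Deterministic given the spec's seed.
#' Compound IDs are `pos_0001...`/`neg_0001...` and each record carries a
#' synthetic structure key (`synthkey_<id>`), so downstream duplicate
#' handling is exercisable without chemistry.
#'
#' @param spec A [synth_spec()].
#' @return A labeled [fp_dataset()] with `n_pos + n_neg` rows (positives
#'   first).
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  n <- spec$n_pos + spec$n_neg
  labels <- rep(c("positive", "negative"), c(spec$n_pos, spec$n_neg))
  rates <- matrix(spec$p_background, n, spec$n_bits)
  causal_cols <- spec$causal_bits + 1L
  rates[labels == "positive", causal_cols] <- spec$p_causal_pos
  rates[labels == "negative", causal_cols] <- spec$p_causal_neg
  X <- matrix(stats::rbinom(n * spec$n_bits, 1L, as.vector(rates)), n, spec$n_bits)
  colnames(X) <- paste0("PubchemFP", seq_len(spec$n_bits) - 1L)
  ids <- c(sprintf("pos_%04d", seq_len(spec$n_pos)),
           sprintf("neg_%04d", seq_len(spec$n_neg)))
  fp_dataset(ids, X, labels, structure_key = paste0("synthkey_", ids))
}

#' Theoretical per-bit log2 odds ratio under a synthetic spec
#'
#' Plugs the population bit rates and class priors into the Bayes
#' posterior-odds formula the weighting stage estimates from data:
#' \deqn{L = \log_2(p_1 \pi_P) - \log_2(p_0 \pi_N)}
#' where \eqn{p_1, p_0} are the bit's rates in positives and negatives and
#' \eqn{\pi_P, \pi_N} the class priors implied by the spec's class sizes.
#' With `k > 0` the rates are first shrunk by finite-sample Laplace smoothing
#' at the spec's class sizes, `(n p + k) / (n + 2k)`, matching what
#' [smoothed_stats()] estimates in expectation; with the default `k = 0` the
#' pure population value is returned. The empirical L converges to this as
#' class sizes grow, which makes the generator a quantitative oracle for the
#' weighting stage.
#'
#' @param spec A [synth_spec()].
#' @param k Laplace pseudo-count applied at the spec's class sizes
#'   (default 0: no smoothing, population value).
#' @return Numeric vector of length `n_bits`.
#' @export
expected_log_odds <- function(spec, k = 0) {
  stopifnot(inherits(spec, "synth_spec"), k >= 0)
  p1 <- rep(spec$p_background, spec$n_bits)
  p0 <- p1
  p1[spec$causal_bits + 1L] <- spec$p_causal_pos
  p0[spec$causal_bits + 1L] <- spec$p_causal_neg
  if (k > 0) {
    p1 <- (spec$n_pos * p1 + k) / (spec$n_pos + 2 * k)
    p0 <- (spec$n_neg * p0 + k) / (spec$n_neg + 2 * k)
  } else if (any(p1 %in% c(0, 1)) || any(p0 %in% c(0, 1))) {
    stop("a degenerate rate (0 or 1) gives an infinite log odds ratio; use k > 0")
  }
  prior_P <- spec$n_pos / (spec$n_pos + spec$n_neg)
  log2(p1 * prior_P) - log2(p0 * (1 - prior_P))
}
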