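#' The favorability transform
#'
#' Converts occurrence probability to environmental favorability,
#'
#' \deqn{F = \frac{P/(1-P)}{n_1/n_0 + P/(1-P)}}
#'
#' which removes the effect of the species' prevalence: `F = 0.5` exactly
#' where the local probability equals the overall prevalence
#' `n1/(n1 + n0)`, regardless of how common the species is.  F is a fuzzy
#' membership degree in \[0, 1\]: the degree to which a cell belongs to the
#' set of favorable cells for the species.
#'
#' Computed in the algebraically equivalent, overflow-safe form
#' `F = P / (P + r (1 - P))` with `r = n1/n0`, so the limits `P = 0` and
#' `P = 1` map to 0 and 1 exactly.
#'
#' @param p occurrence probabilities in \[0, 1\].
#' @param n1,n0 number of presence and absence cells; both must be positive
#'   (with `n0 = 0` the prevalence odds are undefined).
#' @return favorability values, same shape as `p`.
#' @seealso [prob_from_favorability()] for the exact inverse.
#' @export
#' @examples
#' favorability(0.3, n1 = 30, n0 = 70)   # at prevalence: 0.5
#' favorability(0.5, n1 = 20, n0 = 80)   # 0.8
favorability <- function(p, n1, n0) {
  if (length(n1) != 1 || length(n0) != 1 || is.na(n1) || is.na(n0) ||
      n1 <= 0 || n0 <= 0)
    stop("undefined prevalence: n1 and n0 must both be positive")
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]")
  r <- n1 / n0
  p / (p + r * (1 - p))
}

#' Invert the favorability transform
#'
#' @param f favorability values in \[0, 1\].
#' @inheritParams favorability
#' @return the occurrence probabilities that [favorability()] maps to `f`.
#' @export
prob_from_favorability <- function(f, n1, n0) {
  if (length(n1) != 1 || length(n0) != 1 || is.na(n1) || is.na(n0) ||
      n1 <= 0 || n0 <= 0)
    stop("undefined prevalence: n1 and n0 must both be positive")
  if (any(f < 0 | f > 1, na.rm = TRUE))
    stop("favorability must lie in [0, 1]")
  r <- n1 / n0
  r * f / (r * f + (1 - f))
}
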