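# Transfer functions mapping continuous search coordinates to bit
# probabilities, and the stochastic probability-to-bit rule.

#' S-shaped (sigmoid) transfer function
#'
#' Maps a continuous coordinate to the probability of setting the
#' corresponding bit to 1. The sigmoid is strictly increasing with
#' `tf_sigmoid(0) = 0.5`, so positive coordinates favour selecting the
#' feature and negative coordinates favour dropping it. Selecting this
#' transfer function gives the BPO-S variant.
#'
#' @param x Numeric vector of finite coordinates.
#' @return Numeric vector of probabilities in (0, 1).
#' @seealso [tf_vshaped()], [binarize_position()]
#' @examples
#' tf_sigmoid(c(-2, 0, 2))
#' @export
tf_sigmoid <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  1 / (1 + exp(-x))
}

#' V-shaped (|tanh|) transfer function
#'
#' Maps a continuous coordinate to a bit probability through the absolute
#' hyperbolic tangent. The function is even with `tf_vshaped(0) = 0`: only
#' coordinates far from the origin (in either direction) are likely to set
#' their bit, which drives sparser masks than the sigmoid. Selecting this
#' transfer function gives the BPO-V variant.
#'
#' `tanh` itself is negative for negative input and therefore not a
#' probability; the absolute value restores the even, non-negative V shape
#' standard for this transfer-function family.
#'
#' @inheritParams tf_sigmoid
#' @return Numeric vector of probabilities in \[0, 1).
#' @seealso [tf_sigmoid()], [binarize_position()]
#' @examples
#' tf_vshaped(c(-1, 0, 1))
#' @export
tf_vshaped <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  abs(tanh(x))
}

#' Resolve a transfer-function name to its function
#'
#' @param kind `"s"` (sigmoid, BPO-S) or `"v"` (|tanh|, BPO-V).
#' @return The transfer function.
#' @export
transfer_function <- function(kind = c("s", "v")) {
  kind <- match.arg(tolower(kind), c("s", "v"))
  if (kind == "s") tf_sigmoid else tf_vshaped
}

#' Binarize a continuous position into a feature mask
#'
#' Applies the chosen transfer function coordinate-wise to obtain per-bit
#' probabilities, then draws one uniform number per coordinate and sets the
#' bit to 1 when the probability is at least the draw. Consumes the current
#' R random stream, so results are reproducible under `set.seed()`.
#'
#' @param position Numeric vector, the continuous member position.
#' @param kind `"s"` or `"v"`, selecting [tf_sigmoid()] or [tf_vshaped()].
#' @return Integer vector of 0/1 bits, same length as `position`.
#' @examples
#' set.seed(1)
#' binarize_position(c(-3, 0, 3), kind = "s")
#' @export
binarize_position <- function(position, kind = c("s", "v")) {
  tf <- transfer_function(kind)
  p <- tf(position)
  as.integer(p >= stats::runif(length(position)))
}
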