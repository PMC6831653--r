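#' Round half away from zero
#'
#' Base `round()` rounds half to even; biogeographic tables conventionally
#' round half up (44.05 -> 44.1). Used only at report time; all internal
#' arithmetic stays in full precision.
#'
#' @param x numeric vector
#' @param digits integer number of decimal places
#' @return numeric vector rounded half-up
#' @export
#' @examples
#' round_half_up(c(29.45, 6.58, 44.078), 1)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# strict upper triangle of a symmetric matrix, as a vector (column-major)
upper_tri_vec <- function(m) m[upper.tri(m)]

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic, collision-free key for a set of labels
set_key <- function(labels) paste(sort(labels), collapse = "\r")

abort_archipel <- function(msg, class) {
  rlang::abort(msg, class = c(class, "archipel_error"))
}
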