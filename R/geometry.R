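#' Depth scaling factor for a power-law indenter
#'
#' For a rigid axisymmetric indenter whose contact profile follows the
#' power law \eqn{h_c = c a^n}, the total indentation depth \eqn{h} and the
#' contact depth \eqn{h_c} are related by \eqn{h = \kappa h_c} with
#' \deqn{\kappa = \sqrt{\pi}\,\Gamma((n+2)/2)/\Gamma((n+1)/2).}
#' Special cases: \eqn{\kappa = 2} for a paraboloid (\eqn{n = 2}) and
#' \eqn{\kappa = \pi/2} for a cone (\eqn{n = 1}).
#'
#' @param n profile index (> 0); may be a vector.
#' @return numeric vector of \eqn{\kappa} values (all > 1).
#' @export
#' @examples
#' depth_scaling_kappa(2)   # 2, paraboloid
#' depth_scaling_kappa(1)   # pi/2, cone
depth_scaling_kappa <- function(n) {
  if (!is.numeric(n) || any(!is.finite(n)) || any(n <= 0)) {
    stop("profile index `n` must be finite and > 0", call. = FALSE)
  }
  # lgamma keeps this stable for very blunt profiles (large n)
  exp(0.5 * log(pi) + lgamma((n + 2) / 2) - lgamma((n + 1) / 2))
}

#' Profile index from load index
#'
#' The elastic loading curve of a power-law indenter follows
#' \eqn{F = b h^m}; the indenter profile index is \eqn{n = 1/(m - 1)}.
#' \eqn{m = 1.5} (Hertzian loading) gives \eqn{n = 2}, a paraboloid;
#' \eqn{m = 2} gives \eqn{n = 1}, a cone.
#'
#' @param m load index (> 1); may be a vector.
#' @return profile index \eqn{n > 0}.
#' @seealso [load_index_from_profile()] for the inverse.
#' @export
profile_index <- function(m) {
  if (!is.numeric(m) || any(!is.finite(m))) {
    stop("load index `m` must be finite numeric", call. = FALSE)
  }
  if (any(m <= 1)) {
    stop("profile index undefined at/below linear loading (m <= 1)",
         call. = FALSE)
  }
  1 / (m - 1)
}

#' Load index from profile index
#'
#' Inverse of [profile_index()]: \eqn{m = 1 + 1/n}.
#'
#' @param n profile index (> 0).
#' @return load index \eqn{m \in (1, \infty)}.
#' @export
load_index_from_profile <- function(n) {
  if (!is.numeric(n) || any(!is.finite(n)) || any(n <= 0)) {
    stop("profile index `n` must be finite and > 0", call. = FALSE)
  }
  1 + 1 / n
}

#' Convert the profile coefficient c between length conventions
#'
#' The profile coefficient in \eqn{h_c = c a^n} carries units of
#' length\eqn{^{1-n}}, so its numeric value depends on the length unit used
#' for both \eqn{a} and \eqn{h_c}.  Published tip-geometry tables
#' conventionally quote \eqn{c} in \eqn{\mu m^{1-n}}; this package stores
#' SI (metre) values internally.
#'
#' @param c_value coefficient value in the source unit convention.
#' @param n profile index.
#' @param from,to length unit of the source/target convention:
#'   one of `"m"`, `"um"`, `"nm"`.
#' @return coefficient value in the target convention.
#' @export
#' @examples
#' convert_profile_coefficient(1, n = 1, from = "m", to = "um")  # 1: c is
#' # dimensionless for a cone
convert_profile_coefficient <- function(c_value, n, from = "m", to = "um") {
  scale <- c(m = 1, um = 1e-6, nm = 1e-9)
  if (!from %in% names(scale) || !to %in% names(scale)) {
    stop("units must be one of 'm', 'um', 'nm'", call. = FALSE)
  }
  # h_c[to] = c_to a[to]^n ; a[to] = a[from] * s, s = scale[from]/scale[to]
  s <- scale[[from]] / scale[[to]]
  c_value * s^(1 - n)
}
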