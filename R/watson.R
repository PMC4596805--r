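# Bipolar Watson distribution on the unit sphere.
#
# The Watson distribution is the fundamental antipodally symmetric
# distribution for axial data: p(+/-n; mu, kappa) is proportional to
# exp(kappa (mu'n)^2). For kappa > 0 (the bipolar regime, the only one
# supported here) mass concentrates around +/-mu; kappa = 0 is the uniform
# distribution on the sphere. The density here is taken with respect to the
# uniform surface measure, so the normalizer is 4 pi M(1/2, 3/2, kappa) with
# M the confluent hypergeometric (Kummer) function, and it integrates to 1
# over the sphere.

#' Kummer confluent hypergeometric function M(1/2, 3/2, kappa)
#'
#' Normalizing constant of the Watson density, evaluated by direct series
#' summation `sum_k [(1/2)_k / (3/2)_k] kappa^k / k!` to relative tolerance
#' 1e-12. Only the bipolar regime `kappa >= 0` is supported.
#'
#' @param kappa concentration parameter, >= 0.
#' @return value of M(1/2, 3/2, kappa).
#' @export
kummer_m <- function(kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1 || is.na(kappa) || kappa < 0)
    stop("kappa must be a single non-negative number", call. = FALSE)
  term <- 1
  total <- 1
  k <- 0
  repeat {
    # ratio of consecutive terms: (1/2 + k) / (3/2 + k) * kappa / (k + 1)
    term <- term * (0.5 + k) / (1.5 + k) * kappa / (k + 1)
    total <- total + term
    k <- k + 1
    if (term < 1e-12 * total || k > 10000) break
  }
  total
}

#' Watson log-density
#'
#' `log p(n) = kappa (mu'n)^2 - log M(1/2, 3/2, kappa) - log(4 pi)`, with
#' respect to the uniform surface measure on the sphere, so that
#' `exp(log p)` integrates to 1. At `kappa = 0` this is the uniform density
#' `1/(4 pi)`.
#'
#' @param n unit axis (length-3), or an M x 3 matrix of unit axes (rows).
#' @param mu unit mean axis.
#' @param kappa concentration, >= 0.
#' @return log-density value(s).
#' @export
watson_log_density <- function(n, mu, kappa) {
  stopifnot_unit(mu, "mu")
  if (is.null(dim(n))) n <- matrix(n, nrow = 1)
  nrm <- sqrt(rowSums(n * n))
  if (any(abs(nrm - 1) > 1e-6))
    stop("axes n must have unit norm", call. = FALSE)
  d <- as.vector(n %*% mu)
  kappa * d^2 - log(kummer_m(kappa)) - log(4 * pi)
}

#' Sample axes from a bipolar Watson distribution
#'
#' Rejection sampling with a uniform-sphere proposal and envelope
#' `exp(kappa)`: a uniform axis n is accepted with probability
#' `exp(kappa ((mu'n)^2 - 1))`. The expected acceptance rate is
#' `M(1/2, 3/2, kappa) exp(-kappa)` and is reported via `attr(, "acceptance")`.
#' Deterministic for a given seed.
#'
#' @param n number of axes to draw.
#' @param mu unit mean axis.
#' @param kappa concentration, >= 0.
#' @param seed optional integer; when given, `set.seed(seed)` is applied so
#'   the draw is reproducible.
#' @return n x 3 matrix of unit axes, with attribute `"acceptance"` (realized
#'   acceptance rate).
#' @export
sample_watson <- function(n, mu, kappa, seed = NULL) {
  stopifnot(n >= 1)
  stopifnot_unit(mu, "mu")
  if (!is.numeric(kappa) || kappa < 0)
    stop("kappa must be >= 0 (bipolar regime)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(NA_real_, n, 3)
  got <- 0L
  proposed <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 256L)
    z <- stats::runif(m, -1, 1)
    phi <- stats::runif(m, 0, 2 * pi)
    r <- sqrt(pmax(1 - z^2, 0))
    cand <- cbind(r * cos(phi), r * sin(phi), z)
    d2 <- as.vector(cand %*% mu)^2
    acc <- stats::runif(m) < exp(kappa * (d2 - 1))
    proposed <- proposed + m
    take <- which(acc)
    if (length(take)) {
      take <- take[seq_len(min(length(take), n - got))]
      out[(got + 1):(got + length(take)), ] <- cand[take, , drop = FALSE]
      got <- got + length(take)
    }
  }
  attr(out, "acceptance") <- n / proposed
  out
}

#' Maximum-likelihood mean axis of axial data
#'
#' The ML estimate of the Watson mean axis +/-mu is the first eigenvector of
#' the sample scatter matrix of the axes; this delegates to
#' [scatter_summary()], inheriting its deterministic sign and tie rules.
#'
#' @param axes M x 3 matrix of unit axes (rows).
#' @return unit 3-vector.
#' @export
estimate_mean_axis <- function(axes) {
  scatter_summary(axes)$s1
}

#' Angle between two axes
#'
#' Axial angular distance in degrees, ignoring sign: 0 for identical or
#' antipodal axes, at most 90.
#'
#' @param a,b unit 3-vectors.
#' @return angle in degrees in \[0, 90\].
#' @export
axis_angle_deg <- function(a, b) {
  d <- abs(sum(unitize(a) * unitize(b)))
  acos(min(d, 1)) * 180 / pi
}
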