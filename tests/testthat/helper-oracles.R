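# Independent oracles and small fixture builders used across the suite.

# Planar circular arc streamline of given angular range, radius, in xy-plane.
arc_points <- function(theta0, theta1, n, radius = 30) {
  th <- seq(theta0, theta1, length.out = n)
  cbind(radius * cos(th), radius * sin(th), 0)
}

random_unit_axis <- function() {
  z <- stats::runif(1, -1, 1)
  phi <- stats::runif(1, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  c(r * cos(phi), r * sin(phi), z)
}

# Brute-force eigenvalues of a symmetric 3x3 matrix from the explicit
# characteristic polynomial  l^3 - tr l^2 + m l - det = 0, solved with
# polyroot; independent of LAPACK's eigen().
charpoly_eigvals <- function(S) {
  tr <- sum(diag(S))
  m2 <- (S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]) +
    (S[1, 1] * S[3, 3] - S[1, 3] * S[3, 1]) +
    (S[2, 2] * S[3, 3] - S[2, 3] * S[3, 2])
  dt <- det(S)
  r <- polyroot(c(-dt, m2, -tr, 1))
  sort(Re(r), decreasing = TRUE)
}

# Max distance from each row of `pts` to the polyline `poly` (own segment
# distance code, independent of the implementation under test).
max_dist_to_polyline <- function(pts, poly) {
  seg_dist <- function(p, a, b) {
    d <- b - a
    len2 <- sum(d * d)
    if (len2 == 0) return(sqrt(sum((p - a)^2)))
    t <- max(0, min(1, sum((p - a) * d) / len2))
    sqrt(sum((p - (a + t * d))^2))
  }
  worst <- 0
  for (i in seq_len(nrow(pts))) {
    best <- Inf
    for (s in seq_len(nrow(poly) - 1))
      best <- min(best, seg_dist(pts[i, ], poly[s, ], poly[s + 1, ]))
    worst <- max(worst, best)
  }
  worst
}

# Uniform product-grid quadrature nodes and weights on the unit sphere.
sphere_quadrature <- function(n_theta = 200, n_phi = 400) {
  th <- (seq_len(n_theta) - 0.5) * pi / n_theta
  ph <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  g <- expand.grid(th = th, ph = ph)
  list(
    nodes = cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th)),
    weights = sin(g$th) * (pi / n_theta) * (2 * pi / n_phi)
  )
}

# Tiny tractogram of straight 2-point streamlines, one per supplied axis.
axes_as_tractogram <- function(axes) {
  tractogram(lapply(seq_len(nrow(axes)), function(i)
    rbind(c(0, 0, 0), axes[i, ])))
}
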