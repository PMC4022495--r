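# Independent oracles used to cross-check the implementation.

# SASA by latitude-longitude quadrature: a genuine surface integral with
# sin(theta) weights, independent of the equal-area golden-spiral counting.
sasa_quadrature <- function(s, probe = 1.4, radii = swapbp::DEFAULT_RADII,
                            default_radius = 1.70, n_theta = 90,
                            n_phi = 180) {
  a <- s$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  r <- unname(radii[a$elesy])
  r[is.na(r)] <- default_radius
  R <- r + probe
  th <- (seq_len(n_theta) - 0.5) * pi / n_theta
  ph <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  grid <- expand.grid(th = th, ph = ph)
  dirs <- cbind(sin(grid$th) * cos(grid$ph),
                sin(grid$th) * sin(grid$ph),
                cos(grid$th))
  w <- sin(grid$th) * (pi / n_theta) * (2 * pi / n_phi)
  total <- 0
  n <- nrow(xyz)
  for (i in seq_len(n)) {
    P <- sweep(dirs * R[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, nrow(P))
    for (j in seq_len(n)) {
      if (j == i) next
      dd <- (P[, 1] - xyz[j, 1])^2 + (P[, 2] - xyz[j, 2])^2 +
            (P[, 3] - xyz[j, 3])^2
      exposed <- exposed & dd > R[j]^2
    }
    total <- total + sum(w[exposed]) * R[i]^2
  }
  total
}

# closed-form area of two equal intersecting spheres (radius R, centres d
# apart): each sphere loses a cap of height h = R - d/2
two_sphere_area <- function(R, d) 2 * (4 * pi * R^2 - 2 * pi * R * (R - d / 2))
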