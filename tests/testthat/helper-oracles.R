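# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct complex sums, dense enumerations and
# closed forms.

# direct complex vector sum (oracle for vector_sum_index)
oracle_vs <- function(angles_deg, R, order) {
  z <- sum(R * exp(1i * order * angles_deg * pi / 180)) / sum(R)
  list(index = Mod(z), pref = (Arg(z) * 180 / pi / order) %% (360 / order))
}

# Hodges-Ajne statistic by dense rotation-grid enumeration of half-planes
oracle_ha_m <- function(angles_deg, n_grid = 14400) {
  a <- (angles_deg * pi / 180) %% (2 * pi)
  phis <- 2 * pi * (seq_len(n_grid) - 1) / n_grid
  min(vapply(phis, function(phi) sum(((a - phi) %% (2 * pi)) < pi),
             numeric(1)))
}

# exact Hodges-Ajne tail probability, valid for m < n/3 (evaluated
# independently of the package)
oracle_ha_p <- function(n, m) min(1, 2^(1 - n) * (n - 2 * m) * choose(n, m))

# dense arc-length DOI oracle for an ellipse with semi-axes a >= b rotated
# by theta0 (degrees): magnitude-weighted orientation-doubled vector sum
# over arc-length-uniform perimeter points
oracle_ellipse_doi <- function(a, b, theta0_deg, n = 1e5) {
  tt <- 2 * pi * (seq_len(8 * n) - 1) / (8 * n)
  x0 <- a * cos(tt); y0 <- b * sin(tt)
  seg <- sqrt(diff(c(x0, x0[1]))^2 + diff(c(y0, y0[1]))^2)
  cum <- c(0, cumsum(seg))
  s_targets <- (seq_len(n) - 1) / n * cum[length(cum)]
  ix <- findInterval(s_targets, cum, rightmost.closed = TRUE)
  x <- x0[ix]; y <- y0[ix]
  th0 <- theta0_deg * pi / 180
  xr <- x * cos(th0) - y * sin(th0)
  yr <- x * sin(th0) + y * cos(th0)
  r <- sqrt(xr^2 + yr^2)
  phi <- atan2(yr, xr)
  z <- sum(r * exp(2i * phi)) / sum(r)
  list(doi = Mod(z), angle = (Arg(z) * 90 / pi) %% 180)
}

# closed-form inter-spike interval of the LIF under constant current I
# (pA, outward positive), including the refractory tau swap for the first
# d ms after reset
oracle_lif_isi <- function(tau, R_mohm, V_rest, V_th, V_reset,
                           tau_refr, d, I_pA) {
  Vinf <- V_rest - R_mohm * 1e-3 * I_pA
  stopifnot(Vinf > V_th)
  Vd <- Vinf + (V_reset - Vinf) * exp(-d / tau_refr)
  d + tau * log((Vinf - Vd) / (Vinf - V_th))
}

# random star-shaped polygon (simple by construction) for property tests
random_star_polygon <- function(n_vertices = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- 1:3
  a <- runif(3, 0, 0.25); b <- runif(3, 0, 0.25)
  phi <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  r <- 1 + colSums(a * t(outer(phi, k, function(p, k) cos(k * p)))) +
    colSums(b * t(outer(phi, k, function(p, k) sin(k * p))))
  r <- pmax(r, 0.2) * runif(1, 20, 200)
  cbind(r * cos(phi), r * sin(phi))
}

rotate_xy <- function(xy, deg) {
  th <- deg * pi / 180
  cbind(xy[, 1] * cos(th) - xy[, 2] * sin(th),
        xy[, 1] * sin(th) + xy[, 2] * cos(th))
}

default_angles <- seq(0, 330, by = 30)
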