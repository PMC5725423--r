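#' Hodges-Ajne test of circular uniformity
#'
#' Tests whether angles are uniformly distributed on the circle using the
#' Hodges-Ajne statistic m: the minimum number of observations contained in
#' any half-circle. Small m (most points bunched into one half) is evidence
#' against uniformity. For `m < n/3` the exact null probability
#' \deqn{P(M \le m) = 2^{1-n} (n - 2m) \binom{n}{m}}
#' is used; otherwise Ajne's large-sample approximation.
#'
#' Used here for the direction of soma-to-centre-of-mass vectors (ventral
#' clustering in vertical-preferring cells) and for angle-difference
#' distributions.
#'
#' @param angles_deg Angles in degrees (directions, mod 360); n >= 4.
#' @return List with `m` (statistic), `n`, `p_value`, and `method`
#'   (`"exact"` or `"large-sample"`).
#' @examples
#' hodges_ajne_test(rep(10, 10))$p_value # 10 * 2^-9
#' @export
hodges_ajne_test <- function(angles_deg) {
  a <- deg2rad(as.numeric(angles_deg)) %% (2 * pi)
  n <- length(a)
  if (n < 4) stop("Hodges-Ajne test needs at least 4 angles")
  m <- hodges_ajne_m(a)
  if (m < n / 3) {
    p <- min(1, 2^(1 - n) * (n - 2 * m) * choose(n, m))
    method <- "exact"
  } else {
    # Ajne (1968) large-sample approximation
    A <- pi * sqrt(n) / (2 * (n - 2 * m))
    p <- min(1, sqrt(2 * pi) / A * exp(-pi^2 / (8 * A^2)))
    method <- "large-sample"
  }
  list(m = m, n = n, p_value = p, method = method)
}

# minimum count over all half-circles [phi, phi + pi); the piecewise-constant
# count changes only where a point enters or leaves, so evaluating just after
# each data angle and each antipode is exhaustive
hodges_ajne_m <- function(a_rad) {
  eps <- 1e-9
  bounds <- c(a_rad, a_rad + eps, a_rad + pi, a_rad + pi + eps) %% (2 * pi)
  counts <- vapply(bounds, function(phi) {
    sum(((a_rad - phi) %% (2 * pi)) < pi)
  }, numeric(1))
  as.integer(min(counts))
}

#' Hartigan's dip statistic and Monte-Carlo dip test for bimodality
#'
#' `dip_statistic` computes Hartigan's dip of a numeric sample: the smallest
#' sup-norm distance between the empirical distribution function and any
#' unimodal distribution function. It is computed directly from that
#' definition (bisection over the band half-width, with a convex/concave band
#' feasibility check; an atom is permitted at the mode).
#'
#' `dip_test` applies it to preferred orientations: angles are reduced modulo
#' 180 degrees and mapped to `[0, 1)`, and the p-value is obtained by
#' Monte-Carlo simulation against the uniform null with a fixed seed, which is
#' exact up to simulation error at any sample size. A bimodal distribution of
#' preferred orientations (horizontal and vertical clusters) yields a large
#' dip and a small p.
#'
#' @param x Numeric sample (for `dip_statistic`).
#' @param orientations_deg Preferred orientations in degrees (mod 180); n >= 4.
#' @param n_null Number of Monte-Carlo null replicates (default 2000).
#' @param seed Integer seed for the null simulation.
#' @return `dip_statistic`: the dip (scalar). `dip_test`: list with `dip`,
#'   `n`, `p_value`, `n_null`.
#' @examples
#' dip_statistic(c(0, 0, 1, 1)) # 0.25, the maximal two-atom dip
#' @export
dip_statistic <- function(x) {
  x <- sort(as.numeric(x))
  if (anyNA(x)) stop("x must not contain NA")
  dip_stat_cpp(x)
}

#' @rdname dip_statistic
#' @export
dip_test <- function(orientations_deg, n_null = 2000L, seed = 1L) {
  u <- (as.numeric(orientations_deg) %% 180) / 180
  n <- length(u)
  if (n < 4) stop("dip test needs at least 4 orientations")
  d_obs <- dip_statistic(u)
  d_null <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_null), function(i) dip_statistic(stats::runif(n)),
           numeric(1))
  })
  p <- (1 + sum(d_null >= d_obs)) / (n_null + 1)
  list(dip = d_obs, n = n, p_value = p, n_null = as.integer(n_null))
}
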