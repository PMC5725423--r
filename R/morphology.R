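#' Dendritic-field outline container
#'
#' An `arbor_polygon` holds a soma position and a simple closed outline of
#' the dendritic field, resampled to a fixed number of perimeter points at
#' uniform arc length (so every perimeter point carries equal weight in the
#' moment computations). Analyses are planar: the z coordinate of traced
#' arbors is discarded.
#'
#' `arbor_polygon_from_perimeter` builds the container from an ordered
#' closed perimeter; [arbor_polygon()] fits the outline from a raw point
#' cloud first.
#'
#' @param perimeter_xy Two-column matrix of ordered perimeter points
#'   (micrometres); the closing edge is implicit.
#' @param soma_xy Length-2 soma position.
#' @param n Number of uniform-arc-length resampling points (default 1000).
#' @param provenance `"traced"` or `"synthetic"`.
#' @return An object of class `arbor_polygon`.
#' @export
arbor_polygon_from_perimeter <- function(perimeter_xy, soma_xy, n = 1000L,
                                         provenance = c("traced", "synthetic")) {
  provenance <- match.arg(provenance)
  perimeter_xy <- as.matrix(perimeter_xy)
  stopifnot(ncol(perimeter_xy) == 2L, nrow(perimeter_xy) >= 3L,
            length(soma_xy) == 2L)
  structure(
    list(perimeter_um = resample_closed(perimeter_xy, as.integer(n)),
         soma_xy_um = as.numeric(soma_xy), provenance = provenance),
    class = "arbor_polygon"
  )
}

#' @export
print.arbor_polygon <- function(x, ...) {
  cat(sprintf("<arbor_polygon> %d perimeter points (%s), soma (%.1f, %.1f) um\n",
              nrow(x$perimeter_um), x$provenance,
              x$soma_xy_um[1], x$soma_xy_um[2]))
  invisible(x)
}

# resample an ordered closed polygon to n points at uniform arc length
resample_closed <- function(xy, n) {
  closed <- rbind(xy, xy[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(closed)^2))
  if (sum(seg) <= 0) stop("degenerate perimeter: zero total arc length")
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  targets <- (seq_len(n) - 1L) / n * total
  ix <- findInterval(targets, cum, rightmost.closed = TRUE)
  frac <- (targets - cum[ix]) / pmax(seg[ix], .Machine$double.eps)
  closed[ix, , drop = FALSE] +
    (closed[ix + 1L, , drop = FALSE] - closed[ix, , drop = FALSE]) * frac
}

#' Read a neuron reconstruction in SWC format (planar projection)
#'
#' Parses the standard seven-column SWC table (sample, type, x, y, z,
#' radius, parent), projects to the x-y plane, and returns the dendritic
#' point cloud (type-3 nodes) with the soma position (centroid of type-1
#' nodes). Malformed lines and orphan parent references are reported with
#' their line numbers.
#'
#' @param path Path to an SWC file.
#' @return List with `dendrite_xy` (matrix), `soma_xy`, and `nodes` (full
#'   parsed data frame).
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) stop("SWC file has no data lines")
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad))
    stop(sprintf("malformed SWC line %d: expected 7 fields", idx[bad[1]]))
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 7L, byrow = TRUE)
  if (anyNA(m)) {
    bad <- idx[which(rowSums(is.na(m)) > 0)[1]]
    stop(sprintf("malformed SWC line %d: non-numeric field", bad))
  }
  nodes <- data.frame(sample = as.integer(m[, 1]), type = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                      parent = as.integer(m[, 7]))
  orphan <- !(nodes$parent %in% c(-1L, nodes$sample))
  if (any(orphan))
    stop(sprintf("SWC line %d: parent %d does not exist",
                 idx[which(orphan)[1]], nodes$parent[which(orphan)[1]]))
  soma_nodes <- nodes[nodes$type == 1L, , drop = FALSE]
  if (!nrow(soma_nodes)) stop("SWC file has no soma (type 1) node")
  dend <- nodes[nodes$type == 3L, , drop = FALSE]
  if (!nrow(dend)) stop("SWC file has no dendrite (type 3) nodes")
  list(dendrite_xy = cbind(x = dend$x, y = dend$y),
       soma_xy = c(mean(soma_nodes$x), mean(soma_nodes$y)),
       nodes = nodes)
}

#' Write an arbor outline as a 2-D SWC file
#'
#' Node 1 is the soma (type 1, parent -1); the perimeter points follow as a
#' chain of dendrite nodes (type 3). z is written as 0 and radius as 1.
#'
#' @param poly An `arbor_polygon`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_swc <- function(poly, path) {
  stopifnot(inherits(poly, "arbor_polygon"))
  per <- poly$perimeter_um
  n <- nrow(per)
  df <- data.frame(
    sample = seq_len(n + 1L),
    type = c(1L, rep(3L, n)),
    x = c(poly$soma_xy_um[1], per[, 1]),
    y = c(poly$soma_xy_um[2], per[, 2]),
    z = 0, radius = 1,
    parent = c(-1L, 1L, seq_len(n - 1L) + 1L)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# synthetic arbor outline (2-D): soma=1, dendrite=3", con)
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     con, sep = " ", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Fit a dendritic-field outline to a point cloud
#'
#' Fits a simple closed polygon around the dendritic points and resamples
#' its perimeter to `n` points at uniform arc length. The default
#' `convex_hull` outline is appropriate for the mostly convex fields
#' analysed here; `alpha_outline` hugs concavities using a radial angular
#' sweep about the cloud centroid (the farthest point within each angular
#' bin of width `alpha_deg` becomes a vertex).
#'
#' @param points_xy Two-column matrix of dendrite positions (>= 3
#'   non-collinear points).
#' @param soma_xy Length-2 soma position.
#' @param method `"convex_hull"` (default) or `"alpha_outline"`.
#' @param n Perimeter resampling count (default 1000).
#' @param alpha_deg Angular bin width for `alpha_outline` (default 10).
#' @return An `arbor_polygon` with provenance `"traced"`.
#' @export
arbor_polygon <- function(points_xy, soma_xy,
                          method = c("convex_hull", "alpha_outline"),
                          n = 1000L, alpha_deg = 10) {
  method <- match.arg(method)
  points_xy <- as.matrix(points_xy)
  stopifnot(ncol(points_xy) == 2L)
  if (nrow(points_xy) < 3L) stop("need at least 3 points")
  if (qr(sweep(points_xy, 2, colMeans(points_xy)))$rank < 2L)
    stop("points are collinear: no planar field to outline")
  outline <- switch(method,
    convex_hull = points_xy[rev(grDevices::chull(points_xy)), , drop = FALSE],
    alpha_outline = radial_outline(points_xy, alpha_deg))
  arbor_polygon_from_perimeter(outline, soma_xy = soma_xy, n = n,
                               provenance = "traced")
}

radial_outline <- function(points_xy, alpha_deg) {
  ctr <- colMeans(points_xy)
  rel <- sweep(points_xy, 2, ctr)
  ang <- atan2(rel[, 2], rel[, 1]) %% (2 * pi)
  r <- sqrt(rowSums(rel^2))
  bins <- floor(ang / deg2rad(alpha_deg))
  pick <- vapply(split(seq_len(nrow(points_xy)), bins),
                 function(ix) ix[which.max(r[ix])], integer(1))
  ord <- pick[order(ang[pick])]
  if (length(ord) < 3L)
    stop("alpha_outline: too few occupied angular bins; increase alpha_deg")
  points_xy[ord, , drop = FALSE]
}

#' Polygon area, centre of mass, and the soma-to-COM vector
#'
#' Area and centroid by the shoelace first-moment formulas on the resampled
#' outline; the asymmetry vector is reported from the soma to the centre of
#' mass (length in micrometres, angle in the global convention:
#' counter-clockwise degrees, 0 = temporal/horizontal axis, 90 = dorsal, so
#' a ventrally displaced field has angle 270).
#'
#' @param poly An `arbor_polygon`.
#' @return List with `area_um2`, `com_xy_um`, `com_vector_length_um`,
#'   `com_vector_angle_deg`.
#' @export
compute_com <- function(poly) {
  stopifnot(inherits(poly, "arbor_polygon"))
  p <- poly$perimeter_um
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cross <- x * y2 - x2 * y
  A_signed <- sum(cross) / 2
  if (abs(A_signed) < .Machine$double.eps * max(1, sum(p^2)))
    stop("polygon has zero area")
  cx <- sum((x + x2) * cross) / (6 * A_signed)
  cy <- sum((y + y2) * cross) / (6 * A_signed)
  v <- c(cx, cy) - poly$soma_xy_um
  list(area_um2 = abs(A_signed),
       com_xy_um = c(cx, cy),
       com_vector_length_um = sqrt(sum(v^2)),
       com_vector_angle_deg = (rad2deg(atan2(v[2], v[1]))) %% 360)
}

#' Dendritic orientation index (DOI)
#'
#' The orientation-doubled vector sum over centroid-to-perimeter vectors:
#' with r_k the distance from the field centre of mass to perimeter point k
#' and phi_k its angle,
#' \deqn{DOI = |\sum_k r_k e^{2 i \phi_k}| / \sum_k r_k}
#' and the DOI angle is half the complex phase, modulo 180 degrees. A circle
#' gives 0; a degenerate segment gives 1. Perimeter vectors are
#' magnitude-weighted by default (`weighted = FALSE` uses unit vectors; the
#' original analysis does not state which, and the two differ little for
#' realistic fields).
#'
#' @param poly An `arbor_polygon`.
#' @param weighted Weight perimeter vectors by their length (default TRUE).
#' @return List with `doi` in `[0, 1]` and `doi_angle_deg` (mod 180;
#'   `NA` for an exactly isotropic outline).
#' @export
compute_doi <- function(poly, weighted = TRUE) {
  stopifnot(inherits(poly, "arbor_polygon"))
  com <- compute_com(poly)
  rel <- sweep(poly$perimeter_um, 2, com$com_xy_um)
  r <- sqrt(rowSums(rel^2))
  if (max(r) <= 0) stop("degenerate outline: all perimeter points at the centroid")
  phi <- atan2(rel[, 2], rel[, 1])
  wts <- if (weighted) r else rep(1, length(r))
  z <- sum(wts * exp(2i * phi)) / sum(wts)
  doi <- Mod(z)
  ang <- if (doi < .Machine$double.eps * 100) NA_real_ else
    (rad2deg(Arg(z)) / 2) %% 180
  list(doi = doi, doi_angle_deg = ang)
}

#' One-row morphometric summary of an arbor
#'
#' @param poly An `arbor_polygon`.
#' @param cell_id Identifier carried into the row.
#' @return Data frame with columns `cell_id`, `area_um2`, `com_len_um`,
#'   `com_angle_deg`, `doi`, `doi_angle_deg`.
#' @export
morphometrics <- function(poly, cell_id = NA_character_) {
  com <- compute_com(poly)
  doi <- compute_doi(poly)
  data.frame(cell_id = cell_id,
             area_um2 = com$area_um2,
             com_len_um = com$com_vector_length_um,
             com_angle_deg = com$com_vector_angle_deg,
             doi = doi$doi,
             doi_angle_deg = doi$doi_angle_deg)
}
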