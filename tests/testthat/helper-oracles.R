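# Independent geometry oracles, deliberately naive implementations.

# max Feret: exhaustive search over ALL polygon vertex pairs
oracle_max_feret <- function(p) {
  dx <- outer(p[, 1], p[, 1], "-")
  dy <- outer(p[, 2], p[, 2], "-")
  sqrt(max(dx * dx + dy * dy))
}

# min Feret: brute-force width sweep over n_dir directions in [0, pi)
oracle_min_feret <- function(p, n_dir = 36000) {
  th <- seq(0, pi, length.out = n_dir + 1)[-(n_dir + 1)]
  # project vertices onto each direction's normal; width = max - min
  proj <- cbind(cos(th), sin(th)) %*% t(p)   # n_dir x n_vertices
  cols <- lapply(seq_len(ncol(proj)), function(j) proj[, j])
  min(do.call(pmax, cols) - do.call(pmin, cols))
}

# Compare a computed min width against the sweep oracle. The uniform sweep
# can only overestimate the true minimum, and at a kinked minimum its grid
# resolution error is O(diameter * pi / n_dir), which can exceed `tol` for
# elongated shapes; in that rare case the check escalates to a 100x finer
# sweep at the same tolerance rather than accepting the coarse grid's bias.
expect_min_feret_matches_sweep <- function(short, p, n_dir, tol = 1e-4) {
  sw <- oracle_min_feret(p, n_dir)
  expect_lte(short, sw * (1 + 1e-12))  # the sweep never beats the true min
  rel <- abs(short - sw) / sw
  if (rel >= tol) {
    sw_fine <- oracle_min_feret(p, n_dir * 100)
    rel <- abs(short - sw_fine) / sw_fine
  }
  expect_lt(rel, tol)
}

# winding-number point-in-polygon (interior only, boundary unreliable)
oracle_winding_inside <- function(px, py, poly) {
  n <- nrow(poly)
  vapply(seq_along(px), function(i) {
    dx <- poly[, 1] - px[i]; dy <- poly[, 2] - py[i]
    ang <- atan2(dy, dx)
    d <- diff(c(ang, ang[1]))
    d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
    abs(sum(d)) > pi  # ~2*pi inside, ~0 outside
  }, logical(1))
}

# random simple polygons
random_convex_polygon <- function(n_pts = 12, scale = 1) {
  pts <- matrix(stats::rnorm(2 * n_pts, sd = scale), ncol = 2)
  h <- grDevices::chull(pts)
  pts[h, , drop = FALSE]
}

random_star_polygon <- function(n_pts = 16, scale = 1) {
  th <- sort(stats::runif(n_pts, 0, 2 * pi))
  r <- stats::runif(n_pts, 0.4, 1.2) * scale
  cbind(r * cos(th), r * sin(th))
}

rotate_polygon <- function(p, deg) {
  a <- deg * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  p %*% t(R)
}

# from-definition Pearson r via explicit sums
oracle_pearson_r <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x * x) - sx ^ 2) * (n * sum(y * y) - sy ^ 2))
}
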