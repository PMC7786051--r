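# Minimal enclosing circle of a 2-D point set (the "circular reference"
# assigned to each frame of the falling spheroid). Welzl's randomized
# incremental algorithm, run on the convex hull only -- the MEC of a set
# equals the MEC of its hull, and hulls of pixel components are small.

circle_from_2 <- function(p, q) {
  c0 <- (p + q) / 2
  list(center = c0, radius = sqrt(sum((p - c0)^2)))
}

circle_from_3 <- function(a, b, c) {
  # circumcircle; falls back to the widest 2-point circle when collinear
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12) {
    cands <- list(circle_from_2(a, b), circle_from_2(a, c), circle_from_2(b, c))
    return(cands[[which.max(vapply(cands, `[[`, numeric(1), "radius"))]])
  }
  a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
  ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
  uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
  ctr <- c(ux, uy)
  list(center = ctr, radius = sqrt(sum((a - ctr)^2)))
}

in_circle <- function(p, circ, tol = 1e-9) {
  sqrt(sum((p - circ$center)^2)) <= circ$radius * (1 + tol) + tol
}

trivial_circle <- function(R) {
  n <- length(R)
  if (n == 0L) return(list(center = c(0, 0), radius = 0))
  if (n == 1L) return(list(center = R[[1]], radius = 0))
  if (n == 2L) return(circle_from_2(R[[1]], R[[2]]))
  circle_from_3(R[[1]], R[[2]], R[[3]])
}

welzl <- function(P, R) {
  if (length(P) == 0L || length(R) == 3L) return(trivial_circle(R))
  p <- P[[1]]
  circ <- welzl(P[-1L], R)
  if (in_circle(p, circ)) return(circ)
  welzl(P[-1L], c(R, list(p)))
}

#' Minimal enclosing circle of a point set
#'
#' Exact smallest circle containing all points, via Welzl's algorithm on the
#' convex hull. Used as the circular reference fitted to the segmented
#' spheroid silhouette in each frame.
#'
#' @param pts Two-column numeric matrix of point coordinates (x, y order is
#'   immaterial; the result uses the same axes).
#' @return List with `center` (length-2 numeric) and `radius`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 50)
#' min_enclosing_circle(cbind(3 + 2 * cos(th), -1 + 2 * sin(th)))
#' @export
min_enclosing_circle <- function(pts) {
  pts <- as.matrix(pts)
  if (!is.numeric(pts) || ncol(pts) != 2L || nrow(pts) < 1L) {
    stop_invalid("pts must be a numeric matrix with two columns and >= 1 row")
  }
  if (nrow(pts) > 2L) {
    hull <- grDevices::chull(pts[, 1], pts[, 2])
    pts <- pts[hull, , drop = FALSE]
  }
  P <- lapply(seq_len(nrow(pts)), function(i) as.numeric(pts[i, ]))
  if (length(P) > 1L) {
    # deterministic scramble (multiplicative hash) so the expected-linear
    # behaviour of Welzl holds without touching R's RNG state
    n <- length(P)
    P <- P[order((seq_len(n) * 2654435761) %% (n + 1L))]
  }
  welzl(P, list())
}
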