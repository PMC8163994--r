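#' Subdivided icosahedral sphere mesh with quadrature weights
#'
#' Builds a triangulated unit sphere by recursive midpoint subdivision of a
#' regular icosahedron, the standard direction set for segmenting fiber
#' orientation distribution lobes and integrating them numerically. The
#' icosahedron is antipodally symmetric and subdivision preserves that
#' symmetry, so every vertex has an exact antipode in the set — required for
#' merging the two halves of an (even-order, hence symmetric) FOD lobe.
#'
#' Per-vertex solid angles are computed by assigning each spherical triangle's
#' area (l'Huilier's theorem) in equal thirds to its corners; they sum to
#' `4 * pi` exactly up to floating point.
#'
#' @param subdivisions Number of subdivision levels (0 = bare icosahedron,
#'   12 vertices; each level roughly quadruples the count; 3 gives 642,
#'   4 gives 2562).
#' @return Object of class `sphere_mesh`: list with `vertices` (n x 3 unit
#'   rows), `faces` (m x 3 vertex indices), `solid_angles` (length n, sums to
#'   4 pi), `adjacency` (list of integer neighbor vectors), `antipode`
#'   (index of -v for each vertex v), `subdivisions`.
#' @export
sphere_mesh <- function(subdivisions = 3L) {
  stopifnot(subdivisions >= 0)
  p <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  p, 0), c(1,  p, 0), c(-1, -p, 0), c(1, -p, 0),
    c(0, -1,  p), c(0, 1,  p), c(0, -1, -p), c(0, 1, -p),
    c( p, 0, -1), c(p, 0,  1), c(-p, 0, -1), c(-p, 0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdivisions)) {
    edge_key <- new.env(hash = TRUE, parent = emptyenv())
    nv <- nrow(v)
    new_pts <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      idx <- edge_key[[key]]
      if (!is.null(idx)) return(idx)
      m <- v[a, ] + v[b, ]
      m <- m / sqrt(sum(m^2))
      new_pts[[length(new_pts) + 1L]] <<- m
      idx <- nv + length(new_pts)
      edge_key[[key]] <- idx
      idx
    }
    nf <- matrix(0L, 4 * nrow(f), 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf[4 * i - 3, ] <- c(a, ab, ca)
      nf[4 * i - 2, ] <- c(b, bc, ab)
      nf[4 * i - 1, ] <- c(c_, ca, bc)
      nf[4 * i, ]     <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, new_pts))
    f <- nf
  }

  # spherical triangle areas (l'Huilier), split equally among corners
  sa <- numeric(nrow(v))
  for (i in seq_len(nrow(f))) {
    A <- v[f[i, 1], ]; B <- v[f[i, 2], ]; C <- v[f[i, 3], ]
    a <- acos(pmin(1, pmax(-1, sum(B * C))))
    b <- acos(pmin(1, pmax(-1, sum(A * C))))
    c_ <- acos(pmin(1, pmax(-1, sum(A * B))))
    s <- (a + b + c_) / 2
    t <- sqrt(max(0, tan(s / 2) * tan((s - a) / 2) *
                    tan((s - b) / 2) * tan((s - c_) / 2)))
    area <- 4 * atan(t)
    sa[f[i, ]] <- sa[f[i, ]] + area / 3
  }

  adj <- vector("list", nrow(v))
  for (i in seq_len(nrow(f))) {
    tri <- f[i, ]
    adj[[tri[1]]] <- c(adj[[tri[1]]], tri[2], tri[3])
    adj[[tri[2]]] <- c(adj[[tri[2]]], tri[1], tri[3])
    adj[[tri[3]]] <- c(adj[[tri[3]]], tri[1], tri[2])
  }
  adj <- lapply(adj, function(x) sort(unique(x)))

  # exact antipode lookup (subdivision of a symmetric base keeps -v in the set)
  antipode <- integer(nrow(v))
  ord <- seq_len(nrow(v))
  nn <- function(pt) {
    d <- v[, 1] * pt[1] + v[, 2] * pt[2] + v[, 3] * pt[3]
    which.max(d)
  }
  for (i in ord) antipode[i] <- nn(-v[i, ])
  if (any(rowSums((v + v[antipode, , drop = FALSE])^2) > 1e-12))
    stop("internal error: mesh not antipodally symmetric")

  structure(list(vertices = v, faces = f, solid_angles = sa,
                 adjacency = adj, antipode = antipode,
                 subdivisions = as.integer(subdivisions)),
            class = "sphere_mesh")
}

#' @export
print.sphere_mesh <- function(x, ...) {
  cat("sphere_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces),
      "faces,", x$subdivisions, "subdivision level(s)\n")
  invisible(x)
}
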