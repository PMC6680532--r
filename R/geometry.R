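# Small 3D computational-geometry kernel used by the pocket descriptor panel:
# convex hull volume/area (incremental hull), smallest enclosing sphere (Welzl)
# and least-squares rigid superposition (Kabsch).

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Convex hull of a 3D point set
#'
#' Incremental convex hull. Returns the hull volume (cubic units of the input
#' coordinates), surface area, and the facet index matrix. Degenerate inputs
#' (fewer than 4 points, or all points coplanar/collinear) yield `NA` volume
#' and area rather than an error, because a flat pocket still has meaningful
#' composition descriptors.
#'
#' @param pts numeric matrix with 3 columns (x, y, z), one row per point.
#' @return list with `volume`, `area`, `faces` (integer matrix, one facet per
#'   row, counter-clockwise seen from outside) and `degenerate` flag.
#' @export
convex_hull_3d <- function(pts) {
  pts <- as.matrix(pts)
  storage.mode(pts) <- "double"
  stopifnot(ncol(pts) == 3)
  pts <- unique(pts)
  n <- nrow(pts)
  degenerate <- list(volume = NA_real_, area = NA_real_, faces = NULL,
                     degenerate = TRUE)
  if (n < 4) return(degenerate)

  scale <- max(1, max(abs(pts)))
  eps <- 1e-9 * scale

  ## seed tetrahedron: two extreme points, then max-distance point from the
  ## line, then max-distance point from the plane
  i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
  if (sqrt(sum((pts[i1, ] - pts[i2, ])^2)) < eps) {
    i2 <- which.max(rowSums(sweep(pts, 2, pts[i1, ])^2))
  }
  d12 <- pts[i2, ] - pts[i1, ]
  if (sqrt(sum(d12^2)) < eps) return(degenerate)
  rel <- sweep(pts, 2, pts[i1, ])
  cr <- t(apply(rel, 1, function(v) cross3(d12, v)))
  line_d <- sqrt(rowSums(cr^2))
  i3 <- which.max(line_d)
  if (line_d[i3] < eps * sqrt(sum(d12^2))) return(degenerate)
  nrm <- cross3(d12, pts[i3, ] - pts[i1, ])
  plane_d <- abs(rel %*% nrm) / sqrt(sum(nrm^2))
  i4 <- which.max(plane_d)
  if (plane_d[i4] < eps) return(degenerate)

  faces <- rbind(c(i1, i2, i3), c(i1, i3, i4), c(i1, i4, i2), c(i2, i4, i3))
  centroid <- colMeans(pts[c(i1, i2, i3, i4), ])
  orient <- function(f) {
    nn <- cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
    if (sum(nn * (centroid - pts[f[1], ])) > 0) f[c(1, 3, 2)] else f
  }
  faces <- t(apply(faces, 1, orient))

  face_sees <- function(f, p) {
    nn <- cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
    sum(nn * (p - pts[f[1], ])) > eps * sqrt(sum(nn^2))
  }

  for (ip in setdiff(seq_len(n), c(i1, i2, i3, i4))) {
    p <- pts[ip, ]
    vis <- vapply(seq_len(nrow(faces)), function(k) face_sees(faces[k, ], p),
                  logical(1))
    if (!any(vis)) next
    ## horizon: edges of visible faces shared with exactly one visible face
    vis_faces <- faces[vis, , drop = FALSE]
    edges <- do.call(rbind, lapply(seq_len(nrow(vis_faces)), function(k) {
      f <- vis_faces[k, ]
      rbind(f[c(1, 2)], f[c(2, 3)], f[c(3, 1)])
    }))
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    horizon <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    faces <- faces[!vis, , drop = FALSE]
    faces <- rbind(faces,
                   t(apply(horizon, 1, function(e) c(e[1], e[2], ip))))
  }

  vol <- 0; area <- 0
  origin <- colMeans(pts)
  for (k in seq_len(nrow(faces))) {
    a <- pts[faces[k, 1], ] - origin
    b <- pts[faces[k, 2], ] - origin
    cc <- pts[faces[k, 3], ] - origin
    cr <- cross3(b - a, cc - a)
    area <- area + sqrt(sum(cr^2)) / 2
    vol <- vol + abs(sum(a * cross3(b, cc))) / 6
  }
  list(volume = vol, area = area, faces = faces, degenerate = FALSE)
}

## minimal sphere through 1..4 boundary points; returns NULL when undefined
sphere_through <- function(R) {
  m <- length(R)
  if (m == 0) return(list(center = c(0, 0, 0), radius = -1))
  if (m == 1) return(list(center = R[[1]], radius = 0))
  if (m == 2) {
    ctr <- (R[[1]] + R[[2]]) / 2
    return(list(center = ctr, radius = sqrt(sum((R[[1]] - ctr)^2))))
  }
  if (m == 3) {
    a <- R[[1]]; b <- R[[2]]; cc <- R[[3]]
    ab <- b - a; ac <- cc - a
    cr <- cross3(ab, ac)
    den <- 2 * sum(cr^2)
    if (den < 1e-18) return(NULL)
    ctr <- a + (sum(ac^2) * cross3(cr, ab) + sum(ab^2) * cross3(ac, cr)) / den
    return(list(center = ctr, radius = sqrt(sum((a - ctr)^2))))
  }
  a <- R[[1]]
  A <- t(vapply(R[2:4], function(p) 2 * (p - a), numeric(3)))
  rhs <- vapply(R[2:4], function(p) sum(p^2) - sum(a^2), numeric(1))
  ctr <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (is.null(ctr)) return(NULL)
  list(center = as.numeric(ctr), radius = sqrt(sum((a - ctr)^2)))
}

## smallest sphere with all points of R on or inside, boundary a subset of R
sphere_trivial <- function(R) {
  m <- length(R)
  best <- NULL
  for (size in seq_len(m)) {
    combs <- utils::combn(m, size, simplify = FALSE)
    for (idx in combs) {
      s <- sphere_through(R[idx])
      if (is.null(s)) next
      ok <- all(vapply(R, function(p)
        sqrt(sum((p - s$center)^2)) <= s$radius + 1e-7 * (1 + s$radius),
        logical(1)))
      if (ok && (is.null(best) || s$radius < best$radius)) best <- s
    }
    if (!is.null(best)) return(best)
  }
  list(center = c(0, 0, 0), radius = -1)
}

welzl_rec <- function(pts, idx, R) {
  if (length(idx) == 0 || length(R) == 4) return(sphere_trivial(R))
  p <- pts[idx[1], ]
  s <- welzl_rec(pts, idx[-1], R)
  if (s$radius >= 0 &&
      sqrt(sum((p - s$center)^2)) <= s$radius + 1e-7 * (1 + s$radius)) {
    return(s)
  }
  welzl_rec(pts, idx[-1], c(R, list(p)))
}

#' Smallest enclosing sphere of a 3D point set
#'
#' Welzl's algorithm (deterministic insertion order). Used for the pocket
#' convexity index, where the hull volume is related to the volume of the
#' smallest sphere containing the pocket.
#'
#' @param pts numeric matrix with 3 columns.
#' @return list with `center` (length-3) and `radius`.
#' @export
enclosing_sphere <- function(pts) {
  pts <- unique(as.matrix(pts))
  storage.mode(pts) <- "double"
  stopifnot(ncol(pts) == 3, nrow(pts) >= 1)
  welzl_rec(pts, seq_len(nrow(pts)), list())
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation (det = +1) and translation that superpose
#' `moving` onto `fixed` minimizing the RMSD over paired rows.
#'
#' @param moving,fixed numeric matrices of identical dimension (n x 3), rows
#'   paired.
#' @return list with `rotation` (3 x 3), `translation` (length 3) and `rmsd`;
#'   the fitted coordinates are `moving %*% t(rotation) + translation` (row
#'   convention).
#' @export
kabsch <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  stopifnot(ncol(moving) == 3, identical(dim(moving), dim(fixed)))
  if (nrow(moving) < 3) stop("kabsch needs >= 3 paired points")
  cm <- colMeans(moving); cf <- colMeans(fixed)
  X <- sweep(moving, 2, cm); Y <- sweep(fixed, 2, cf)
  dX <- svd(X)$d
  if (dX[1] < 1e-12 || dX[2] < 1e-9 * dX[1]) {
    stop("degenerate (collinear) point set: rotation not determined")
  }
  H <- t(X) %*% Y
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  Rm <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- X %*% t(Rm)
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  list(rotation = Rm, translation = as.numeric(cf - (Rm %*% cm)), rmsd = rmsd)
}

apply_transform <- function(xyz, rotation, translation) {
  sweep(as.matrix(xyz) %*% t(rotation), 2, -translation)
}
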