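#' @title Geometry utilities
#' @description Polyline resampling, rotation-minimizing frames, structured
#'   tube meshes, implicit tube distance fields with marching-tetrahedra
#'   polygonization, and plain-text mesh export (ASCII STL, legacy VTK).
#'   All coordinates are millimetres in a right-handed frame; arclength is
#'   measured from the proximal main-vessel inlet.
#' @name geometry-utils
NULL

## Cumulative arclength of an n x 3 polyline matrix.
cumulative_arclength <- function(pts) {
  if (nrow(pts) < 2L) return(rep(0, nrow(pts)))
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                       pts[-nrow(pts), , drop = FALSE])^2))
  c(0, cumsum(seg))
}

## Linear resampling of a polyline (n x k matrix) at new arclengths.
resample_polyline <- function(pts, s, s_new) {
  apply(pts, 2L, function(col) stats::approx(s, col, xout = s_new,
                                             rule = 2)$y)
}

## Parallel-transport (rotation-minimizing) frames along an n x 3 polyline.
## Returns list(tangent, n1, n2), each n x 3, orthonormal per row.
rm_frames <- function(pts) {
  n <- nrow(pts)
  stopifnot(n >= 2L)
  tan_seg <- pts[-1L, , drop = FALSE] - pts[-n, , drop = FALSE]
  len <- sqrt(rowSums(tan_seg^2))
  ## carry the previous direction across degenerate (duplicate) samples
  for (i in seq_along(len)) {
    if (len[i] < 1e-12) {
      tan_seg[i, ] <- if (i > 1L) tan_seg[i - 1L, ] else c(1, 0, 0)
      len[i] <- 1
    }
  }
  tan_seg <- tan_seg / sqrt(rowSums(tan_seg^2))
  tang <- rbind(tan_seg[1L, ], (tan_seg[-nrow(tan_seg), , drop = FALSE] +
                                tan_seg[-1L, , drop = FALSE]) / 2,
                tan_seg[nrow(tan_seg), ])
  tang <- tang / sqrt(rowSums(tang^2))
  n1 <- matrix(0, n, 3L)
  ## seed normal: any vector not parallel to the first tangent
  seed <- if (abs(tang[1L, 3L]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  v <- seed - sum(seed * tang[1L, ]) * tang[1L, ]
  n1[1L, ] <- v / sqrt(sum(v^2))
  for (i in 2:n) {
    v <- n1[i - 1L, ] - sum(n1[i - 1L, ] * tang[i, ]) * tang[i, ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) v <- n1[i - 1L, ] else v <- v / nv
    n1[i, ] <- v
  }
  n2 <- cbind(tang[, 2L] * n1[, 3L] - tang[, 3L] * n1[, 2L],
              tang[, 3L] * n1[, 1L] - tang[, 1L] * n1[, 3L],
              tang[, 1L] * n1[, 2L] - tang[, 2L] * n1[, 1L])
  list(tangent = tang, n1 = n1, n2 = n2)
}

## Shoelace area of a planar polygon given x, y vertex vectors (open ring).
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

## --- triangle meshes ------------------------------------------------------
## A mesh is list(vertices = n x 3 matrix, triangles = m x 3 integer matrix).

make_mesh <- function(vertices, triangles) {
  structure(list(vertices = vertices,
                 triangles = matrix(as.integer(triangles), ncol = 3L)),
            class = "stent_mesh")
}

#' @export
print.stent_mesh <- function(x, ...) {
  cat("Triangle mesh:", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "triangles\n")
  invisible(x)
}

## Weld vertices closer than tol (default 1e-6 mm) and drop degenerate faces.
weld_mesh <- function(mesh, tol = 1e-6) {
  key <- apply(round(mesh$vertices / tol) * tol, 1L, paste, collapse = ",")
  ids <- match(key, key)
  remap <- match(ids, sort(unique(ids)))
  verts <- mesh$vertices[sort(unique(ids)), , drop = FALSE]
  tris <- matrix(remap[mesh$triangles], ncol = 3L)
  keep <- tris[, 1L] != tris[, 2L] & tris[, 2L] != tris[, 3L] &
    tris[, 1L] != tris[, 3L]
  make_mesh(verts, tris[keep, , drop = FALSE])
}

## Number of boundary edges (edges used by != 2 triangles) after welding.
mesh_boundary_edges <- function(mesh, tol = 1e-6) {
  m <- weld_mesh(mesh, tol)
  e <- rbind(m$triangles[, c(1L, 2L)], m$triangles[, c(2L, 3L)],
             m$triangles[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  cnt <- table(paste(e[, 1L], e[, 2L]))
  sum(cnt != 2L)
}

mesh_is_watertight <- function(mesh, tol = 1e-6) {
  mesh_boundary_edges(mesh, tol) == 0L
}

mesh_area <- function(mesh) {
  v <- mesh$vertices
  t <- mesh$triangles
  a <- v[t[, 2L], , drop = FALSE] - v[t[, 1L], , drop = FALSE]
  b <- v[t[, 3L], , drop = FALSE] - v[t[, 1L], , drop = FALSE]
  cx <- a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L]
  cy <- a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L]
  cz <- a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

## Structured tube mesh through a stack of rings. `rings` is a list of
## n_ang x 3 matrices with corresponding angular samples; ends optionally
## capped with triangle fans (watertight when capped).
tube_mesh <- function(rings, cap = TRUE) {
  stopifnot(length(rings) >= 2L)
  na <- nrow(rings[[1L]])
  verts <- do.call(rbind, rings)
  nf <- length(rings)
  tris <- vector("list", nf - 1L)
  for (i in seq_len(nf - 1L)) {
    base0 <- (i - 1L) * na
    j <- seq_len(na)
    jn <- c(2:na, 1L)
    tris[[i]] <- rbind(cbind(base0 + j, base0 + jn, base0 + na + j),
                       cbind(base0 + jn, base0 + na + jn, base0 + na + j))
  }
  tris <- do.call(rbind, tris)
  if (cap) {
    c1 <- colMeans(rings[[1L]])
    c2 <- colMeans(rings[[nf]])
    verts <- rbind(verts, c1, c2)
    i1 <- nrow(verts) - 1L
    i2 <- nrow(verts)
    j <- seq_len(na); jn <- c(2:na, 1L)
    tris <- rbind(tris,
                  cbind(j, i1, jn),
                  cbind((nf - 1L) * na + j, (nf - 1L) * na + jn, i2))
  }
  make_mesh(verts, tris)
}

## --- implicit tube fields and marching tetrahedra -------------------------

## Signed distance-like field of a finite tube of varying radius around a
## centerline polyline: F(x) = min_seg (distance to segment - radius at foot).
## Negative inside. `pts` is N x 3; `cl` M x 3; `radii` length M.
tube_field <- function(pts, cl, radii) {
  n <- nrow(pts)
  best <- rep(Inf, n)
  for (j in seq_len(nrow(cl) - 1L)) {
    a <- cl[j, ]; b <- cl[j + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 < 1e-18) next
    t <- ((pts[, 1L] - a[1L]) * ab[1L] + (pts[, 2L] - a[2L]) * ab[2L] +
          (pts[, 3L] - a[3L]) * ab[3L]) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- pts[, 1L] - (a[1L] + t * ab[1L])
    dy <- pts[, 2L] - (a[2L] + t * ab[2L])
    dz <- pts[, 3L] - (a[3L] + t * ab[3L])
    d <- sqrt(dx^2 + dy^2 + dz^2) - (radii[j] + t * (radii[j + 1L] - radii[j]))
    best <- pmin(best, d)
  }
  best
}

## Kuhn 6-tetrahedra subdivision of the unit cube (corner offsets 0/1).
## Faces of adjacent cubes are split along the same diagonal, so the
## extracted isosurface is watertight on a closed field.
kuhn_tets <- local({
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  lapply(seq_len(6L), function(k) {
    steps <- diag(3L)[perms[k, ], , drop = FALSE]
    v <- rbind(c(0, 0, 0), steps[1L, ], steps[1L, ] + steps[2L, ], c(1, 1, 1))
    v
  })
})

## Marching tetrahedra over a regular grid. xs/ys/zs are coordinate vectors,
## vals an array dim (nx, ny, nz) of field values (negative inside).
## Returns a welded triangle mesh.
marching_tets <- function(xs, ys, zs, vals) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  vals[vals == 0] <- 1e-12
  ## candidate cubes: any sign difference among the 8 corners
  neg <- vals < 0
  sub <- function(a, i, j, k) a[i, j, k, drop = FALSE]
  i <- seq_len(nx - 1L); j <- seq_len(ny - 1L); k <- seq_len(nz - 1L)
  s <- sub(neg, i, j, k)
  any_neg <- s; all_neg <- s
  for (off in list(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(0, 0, 1),
                   c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))) {
    t <- sub(neg, i + off[1L], j + off[2L], k + off[3L])
    any_neg <- any_neg | t
    all_neg <- all_neg & t
  }
  cand <- which(any_neg & !all_neg, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(make_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)))

  tri_list <- list()
  for (tet in kuhn_tets) {
    ## corner grid indices (n_cand x 3 each) and values for the 4 vertices
    P <- vector("list", 4L); Fv <- vector("list", 4L)
    for (v in 1:4) {
      ii <- cand[, 1L] + tet[v, 1L]
      jj <- cand[, 2L] + tet[v, 2L]
      kk <- cand[, 3L] + tet[v, 3L]
      P[[v]] <- cbind(xs[ii], ys[jj], zs[kk])
      Fv[[v]] <- vals[cbind(ii, jj, kk)]
    }
    Fm <- cbind(Fv[[1L]], Fv[[2L]], Fv[[3L]], Fv[[4L]])
    negm <- Fm < 0
    kneg <- rowSums(negm)

    interp <- function(rows, a, b) {
      t <- Fm[rows, a] / (Fm[rows, a] - Fm[rows, b])
      P[[a]][rows, , drop = FALSE] +
        t * (P[[b]][rows, , drop = FALSE] - P[[a]][rows, , drop = FALSE])
    }
    ## single-vertex cases (1 neg or 3 neg): lone vertex vs other three
    for (lone in 1:4) {
      others <- setdiff(1:4, lone)
      rows <- which((kneg == 1L & negm[, lone]) |
                    (kneg == 3L & !negm[, lone]))
      if (length(rows) == 0L) next
      q1 <- interp(rows, lone, others[1L])
      q2 <- interp(rows, lone, others[2L])
      q3 <- interp(rows, lone, others[3L])
      tri_list[[length(tri_list) + 1L]] <- cbind(q1, q2, q3)
    }
    ## two-two cases: quad split into two triangles
    pairs <- list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
    for (pr in pairs) {
      os <- setdiff(1:4, pr)
      rows <- which(kneg == 2L & negm[, pr[1L]] & negm[, pr[2L]])
      if (length(rows) == 0L) next
      q11 <- interp(rows, pr[1L], os[1L])
      q12 <- interp(rows, pr[1L], os[2L])
      q21 <- interp(rows, pr[2L], os[1L])
      q22 <- interp(rows, pr[2L], os[2L])
      tri_list[[length(tri_list) + 1L]] <- cbind(q11, q12, q22)
      tri_list[[length(tri_list) + 1L]] <- cbind(q11, q22, q21)
    }
  }
  tri <- do.call(rbind, tri_list)
  nt <- nrow(tri)
  verts <- rbind(tri[, 1:3, drop = FALSE], tri[, 4:6, drop = FALSE],
                 tri[, 7:9, drop = FALSE])
  tris <- cbind(seq_len(nt), seq_len(nt) + nt, seq_len(nt) + 2L * nt)
  weld_mesh(make_mesh(verts, tris), tol = 1e-9)
}

## Polygonize an implicit field over a bounding box. field_fn(pts) takes an
## N x 3 matrix and returns N field values. Returns list(mesh, volume_mm3)
## where volume is voxel-counted on the same grid (see methods vignette).
implicit_surface <- function(field_fn, lower, upper, h = 0.4) {
  xs <- seq(lower[1L], upper[1L], by = h)
  ys <- seq(lower[2L], upper[2L], by = h)
  zs <- seq(lower[3L], upper[3L], by = h)
  g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  vals <- array(field_fn(g), dim = c(length(xs), length(ys), length(zs)))
  mesh <- marching_tets(xs, ys, zs, vals)
  list(mesh = mesh, volume_mm3 = sum(vals < 0) * h^3,
       grid = list(xs = xs, ys = ys, zs = zs))
}

## --- plain-text mesh export -----------------------------------------------

#' Write a triangle mesh as ASCII STL
#'
#' @param mesh a mesh produced by the reconstruction or anatomy functions.
#' @param path output file path.
#' @param name solid name embedded in the file.
#' @return `path`, invisibly.
#' @export
write_stl_ascii <- function(mesh, path, name = "stentsim") {
  v <- mesh$vertices; t <- mesh$triangles
  a <- v[t[, 2L], , drop = FALSE] - v[t[, 1L], , drop = FALSE]
  b <- v[t[, 3L], , drop = FALSE] - v[t[, 1L], , drop = FALSE]
  nrm <- cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
               a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
               a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
  nl <- sqrt(rowSums(nrm^2)); nl[nl == 0] <- 1
  nrm <- nrm / nl
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("solid", name), con)
  fmt <- function(m) apply(m, 1L, function(r) paste(format(r, digits = 9),
                                                    collapse = " "))
  lines <- paste0("facet normal ", fmt(nrm), "\n outer loop\n  vertex ",
                  fmt(v[t[, 1L], , drop = FALSE]), "\n  vertex ",
                  fmt(v[t[, 2L], , drop = FALSE]), "\n  vertex ",
                  fmt(v[t[, 3L], , drop = FALSE]), "\n endloop\nendfacet")
  writeLines(lines, con)
  writeLines(paste("endsolid", name), con)
  invisible(path)
}

#' Write polylines as legacy ASCII VTK
#'
#' @param polylines list of n x 3 coordinate matrices.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vtk_polylines <- function(polylines, path) {
  pts <- do.call(rbind, polylines)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "stentsim polylines", "ASCII",
               "DATASET POLYDATA",
               paste("POINTS", nrow(pts), "double")), con)
  writeLines(apply(pts, 1L, function(r) paste(format(r, digits = 9),
                                              collapse = " ")), con)
  sizes <- vapply(polylines, nrow, integer(1L))
  writeLines(paste("LINES", length(polylines), sum(sizes + 1L)), con)
  off <- 0L
  for (i in seq_along(polylines)) {
    writeLines(paste(c(sizes[i], off + seq_len(sizes[i]) - 1L),
                     collapse = " "), con)
    off <- off + sizes[i]
  }
  invisible(path)
}
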