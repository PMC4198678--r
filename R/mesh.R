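#' Triangle mesh
#'
#' Extracted/smoothable surface: vertices in world mm, triangle
#' vertex-index triples (1-based), optional per-vertex anatomic labels and
#' unit vertex normals.
#'
#' @param vertices numeric n x 3 matrix.
#' @param triangles integer m x 3 matrix of 1-based vertex indices.
#' @param vertex_labels optional integer vector of length n.
#' @param vertex_normals optional numeric n x 3 matrix of unit vectors; if
#'   `NULL` they are computed by area-weighted face-normal averaging.
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, triangles, vertex_labels = NULL,
                          vertex_normals = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  triangles <- matrix(as.integer(triangles), ncol = 3)
  n <- nrow(vertices)
  if (nrow(triangles) && (min(triangles) < 1L || max(triangles) > n))
    stop("triangle indices out of range", call. = FALSE)
  if (is.null(vertex_labels)) vertex_labels <- integer(n)
  m <- structure(list(vertices = vertices, triangles = triangles,
                      vertex_labels = as.integer(vertex_labels),
                      vertex_normals = vertex_normals),
                 class = "triangle_mesh")
  if (is.null(vertex_normals)) m$vertex_normals <- vertex_normals_of(m)
  m
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh: %d vertices, %d triangles%s>\n",
              nrow(x$vertices), nrow(x$triangles),
              if (mesh_is_closed(x)) ", closed" else ""))
  invisible(x)
}

empty_mesh <- function() {
  triangle_mesh(matrix(numeric(0), ncol = 3),
                matrix(integer(0), ncol = 3))
}

face_cross <- function(mesh) {
  V <- mesh$vertices; TR <- mesh$triangles
  a <- V[TR[, 1], , drop = FALSE]
  cross3(V[TR[, 2], , drop = FALSE] - a, V[TR[, 3], , drop = FALSE] - a)
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

# area-weighted average of incident face normals, unit length; vertices
# with no incident area get c(0,0,1) so the unit-norm invariant holds
vertex_normals_of <- function(mesh) {
  n <- nrow(mesh$vertices)
  N <- matrix(0, n, 3)
  if (nrow(mesh$triangles)) {
    fc <- face_cross(mesh)   # length = 2 * area, direction = face normal
    for (c in 1:3) {
      acc <- rowsum(fc, mesh$triangles[, c])
      ids <- as.integer(rownames(acc))
      N[ids, ] <- N[ids, ] + acc
    }
  }
  len <- sqrt(rowSums(N^2))
  zero <- len < 1e-300
  if (any(zero)) N[zero, ] <- matrix(c(0, 0, 1), sum(zero), 3, byrow = TRUE)
  len[zero] <- 1
  N / len
}

#' Enclosed volume of a closed mesh (divergence theorem)
#'
#' Sum of signed tetrahedron volumes against the origin; positive when
#' triangle winding gives outward normals.
#'
#' @param mesh a `triangle_mesh`.
#' @return signed volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  if (!nrow(mesh$triangles)) return(0)
  V <- mesh$vertices; TR <- mesh$triangles
  a <- V[TR[, 1], , drop = FALSE]
  b <- V[TR[, 2], , drop = FALSE]
  cc <- V[TR[, 3], , drop = FALSE]
  sum(rowSums(a * cross3(b, cc))) / 6
}

#' Total surface area of a mesh
#' @param mesh a `triangle_mesh`.
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) {
  if (!nrow(mesh$triangles)) return(0)
  sum(sqrt(rowSums(face_cross(mesh)^2))) / 2
}

mesh_edges <- function(mesh) {
  TR <- mesh$triangles
  rbind(TR[, c(1, 2), drop = FALSE], TR[, c(2, 3), drop = FALSE],
        TR[, c(3, 1), drop = FALSE])
}

#' Closedness and Euler characteristic
#'
#' A mesh is closed (watertight and consistently oriented) when every
#' directed edge appears exactly once and every undirected edge exactly
#' twice.  `mesh_euler` returns V - E + F over unique undirected edges
#' (2 for a sphere, 0 for a torus).
#'
#' @param mesh a `triangle_mesh`.
#' @return logical / integer.
#' @export
mesh_is_closed <- function(mesh) {
  if (!nrow(mesh$triangles)) return(FALSE)
  E <- mesh_edges(mesh)
  dkey <- paste(E[, 1], E[, 2])
  if (anyDuplicated(dkey)) return(FALSE)          # orientation consistency
  ukey <- paste(pmin(E[, 1], E[, 2]), pmax(E[, 1], E[, 2]))
  all(table(ukey) == 2L)
}

#' @rdname mesh_is_closed
#' @export
mesh_euler <- function(mesh) {
  E <- mesh_edges(mesh)
  ukey <- unique(paste(pmin(E[, 1], E[, 2]), pmax(E[, 1], E[, 2])))
  used <- sort(unique(as.vector(mesh$triangles)))
  length(used) - length(ukey) + nrow(mesh$triangles)
}

#' Mean dihedral roughness
#'
#' Mean of `|dihedral angle - pi|` over interior edges: 0 for a perfectly
#' flat surface, large for step-like voxellation artifacts.  Used to show
#' that smoothing actually smooths.
#'
#' @param mesh a `triangle_mesh`.
#' @return mean absolute deviation from a flat dihedral, radians.
#' @export
mesh_dihedral_roughness <- function(mesh) {
  TR <- mesh$triangles
  if (!nrow(TR)) return(0)
  fc <- face_cross(mesh)
  fn <- fc / pmax(sqrt(rowSums(fc^2)), 1e-300)
  E <- mesh_edges(mesh)
  face_of <- rep(seq_len(nrow(TR)), 3)
  ukey <- paste(pmin(E[, 1], E[, 2]), pmax(E[, 1], E[, 2]))
  ord <- order(ukey)
  ukey <- ukey[ord]; face_of <- face_of[ord]
  runs <- rle(ukey)$lengths
  idx2 <- cumsum(runs)
  keep <- runs == 2L
  f1 <- face_of[idx2 - 1L][keep]
  f2 <- face_of[idx2][keep]
  cosang <- pmin(1, pmax(-1, rowSums(fn[f1, , drop = FALSE] *
                                     fn[f2, , drop = FALSE])))
  mean(acos(cosang))   # angle between normals = pi - dihedral
}

# canonical sorted triangle set for order-independent comparison: each
# triangle's 9 coordinates with vertex rotation so the lexicographically
# smallest vertex comes first (winding preserved), rows sorted
mesh_triangle_set <- function(mesh) {
  TR <- mesh$triangles
  if (!nrow(TR)) return(matrix(numeric(0), ncol = 9))
  V <- mesh$vertices
  tri9 <- cbind(V[TR[, 1], , drop = FALSE], V[TR[, 2], , drop = FALSE],
                V[TR[, 3], , drop = FALSE])
  rot <- function(t9, k) {
    idx <- c(((0:2 + k) %% 3) + 1)
    t9[, c((idx[1] - 1) * 3 + 1:3, (idx[2] - 1) * 3 + 1:3,
           (idx[3] - 1) * 3 + 1:3), drop = FALSE]
  }
  lexmin <- function(a, b) {   # TRUE where row of a < row of b
    lt <- a[, 1] < b[, 1]
    eq <- a[, 1] == b[, 1]
    for (c in 2:3) {
      lt <- lt | (eq & (a[, c] < b[, c]))
      eq <- eq & (a[, c] == b[, c])
    }
    lt
  }
  best <- tri9
  for (k in 1:2) {
    cand <- rot(tri9, k)
    swap <- lexmin(cand[, 1:3, drop = FALSE], best[, 1:3, drop = FALSE])
    best[swap, ] <- cand[swap, , drop = FALSE]
  }
  best[do.call(order, as.data.frame(best)), , drop = FALSE]
}

#' Compare two meshes as unordered triangle sets
#'
#' @param a,b `triangle_mesh` objects.
#' @param tol coordinate tolerance.
#' @return TRUE when both meshes contain the same triangles (any order,
#'   any vertex indexing) with coordinates within `tol`.
#' @export
mesh_sets_equal <- function(a, b, tol = 1e-12) {
  A <- mesh_triangle_set(a); B <- mesh_triangle_set(b)
  nrow(A) == nrow(B) && (nrow(A) == 0 || max(abs(A - B)) <= tol)
}
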