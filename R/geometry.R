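## Low-level vector geometry shared across modules. All coordinates are in
## Angstrom; all angles returned in degrees unless noted.

`%||%` <- function(a, b) if (is.null(a)) b else a

vec_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vec_norm <- function(a) sqrt(sum(a * a))

unit_vec <- function(a) {
  n <- vec_norm(a)
  if (n < 1e-12) stop("degenerate zero-length vector", call. = FALSE)
  a / n
}

#' Angle at a vertex between two points, degrees
#' @noRd
vertex_angle <- function(p_outer, p_vertex, p_inner) {
  u <- p_outer - p_vertex
  v <- p_inner - p_vertex
  cosang <- sum(u * v) / (vec_norm(u) * vec_norm(v))
  acos(min(1, max(-1, cosang))) * 180 / pi
}

## Pairwise squared distances between row-sets A (m x 3) and B (n x 3),
## minimum-image on an orthorhombic box when `box` (length-3) is given.
pair_dist2 <- function(A, B, box = NULL) {
  A <- matrix(A, ncol = 3)
  B <- matrix(B, ncol = 3)
  d2 <- matrix(0, nrow(A), nrow(B))
  for (k in 1:3) {
    d <- outer(A[, k], B[, k], "-")
    if (!is.null(box) && is.finite(box[k]) && box[k] > 0) {
      d <- d - box[k] * round(d / box[k])
    }
    d2 <- d2 + d * d
  }
  d2
}

min_pair_dist <- function(A, B, box = NULL) sqrt(min(pair_dist2(A, B, box)))

## Proper dihedral for four points, IUPAC sign convention, in (-180, 180].
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vec_cross(b1, b2)
  n2 <- vec_cross(b2, b3)
  m1 <- vec_cross(b2 / vec_norm(b2), n1)
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

## Natural-extension placement: position atom D given A, B, C, the C-D bond
## length, the B-C-D angle (deg) and the A-B-C-D torsion (deg).
nerf_place <- function(a, b, c, bond, angle, torsion) {
  angle <- angle * pi / 180
  torsion <- torsion * pi / 180
  bc <- unit_vec(c - b)
  n <- unit_vec(vec_cross(b - a, bc))
  m <- vec_cross(n, bc)
  d <- c(-bond * cos(angle),
         bond * sin(angle) * cos(torsion),
         bond * sin(angle) * sin(torsion))
  c + d[1] * bc + d[2] * m + d[3] * n
}

## Rotation matrix about a unit axis by theta degrees (Rodrigues).
rotation_matrix <- function(axis, theta_deg) {
  u <- unit_vec(axis)
  th <- theta_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## Least-squares superposition: rotation R and translation such that the
## moving set M (rows = atoms) best fits the reference set Rf.
kabsch_fit <- function(M, Rf) {
  cm <- colMeans(M)
  cr <- colMeans(Rf)
  Mc <- sweep(M, 2, cm)
  Rc <- sweep(Rf, 2, cr)
  H <- crossprod(Mc, Rc)
  sv <- svd(H)
  s <- sign(det(sv$u %*% t(sv$v)))
  if (s == 0) s <- 1
  R <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  sweep(Mc %*% R, 2, cr, "+")
}

## Principal direction of a point cloud (rows = atoms), oriented so that it
## points from the first toward the last row.
principal_axis <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 0, nv = 3)
  if (sv$d[1] < 1e-9) {
    stop("degenerate atom set: no principal direction", call. = FALSE)
  }
  v <- sv$v[, 1]
  span <- X[nrow(X), ] - X[1, ]
  if (sum(v * span) < 0) v <- -v
  v
}
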