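#' Define the three segments of a helix bend measurement
#'
#' The bend is measured at the centroid of a pivot segment (default the TM2
#' hinge region, GIRK1 I167-G169) between vectors to the centroids of one
#' helical turn above (GIRK1 G158-F162) and one below (GIRK1 A174-G178).
#' Centroids use the backbone atoms (N, CA, C, O), unweighted by default.
#'
#' @param chain chain id carrying the helix.
#' @param outer,pivot,inner residue ranges `c(lo, hi)`; defaults are the
#'   GIRK1 TM2 segments.
#' @return A `BendAngleDef`.
#' @export
bend_angle_def <- function(chain, outer = c(158, 162), pivot = c(167, 169),
                           inner = c(174, 178)) {
  segs <- list(outer = outer, pivot = pivot, inner = inner)
  lo <- vapply(segs, min, numeric(1))
  hi <- vapply(segs, max, numeric(1))
  if (!(hi[1] < lo[2] && hi[2] < lo[3])) {
    stop("bend segments must be disjoint and in ascending sequence order",
         call. = FALSE)
  }
  structure(list(chain = chain, outer = outer, pivot = pivot,
                 inner = inner), class = "BendAngleDef")
}

segment_backbone_indices <- function(top, chain, resid_range,
                                     mass_weighted = FALSE) {
  idx <- sel_indices(select_atoms(top, chain = chain,
                                  resid = resid_range[1]:resid_range[2],
                                  scope = "backbone"))
  if (!length(idx)) {
    stop("segment ", chain, ":", resid_range[1], "-", resid_range[2],
         " resolves to no backbone atoms", call. = FALSE)
  }
  idx
}

ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                 P = 30.974, K = 39.098)

segment_centroid <- function(X, idx, elements = NULL) {
  M <- X[idx, , drop = FALSE]
  if (is.null(elements)) return(colMeans(M))
  w <- ATOMIC_MASS[elements]
  w[is.na(w)] <- 12
  colSums(M * w) / sum(w)
}

#' Per-frame helix bend angle
#'
#' The angle at the pivot centroid between vectors to the outer and inner
#' segment centroids, in degrees; 180 is a straight helix, smaller values a
#' sharper kink at the hinge.
#'
#' @param traj a [Trajectory].
#' @param def a [bend_angle_def()]; when `NULL`, the definition attached by
#'   [simulate_bent_helix()] is used if present.
#' @param window an [analysis_window()] or `NULL`.
#' @param mass_weighted use mass-weighted centroids instead of unweighted
#'   backbone-atom centroids.
#' @return A `TimeSeries` in degrees.
#' @export
bend_angle_series <- function(traj, def = NULL, window = NULL,
                              mass_weighted = FALSE) {
  if (is.null(def)) {
    ad <- attr(traj, "bend_def")
    if (is.null(ad)) stop("no bend definition supplied", call. = FALSE)
    def <- bend_angle_def(ad$chain, ad$outer, ad$pivot, ad$inner)
  }
  stopifnot(inherits(def, "BendAngleDef"))
  top <- traj$topology
  io <- segment_backbone_indices(top, def$chain, def$outer)
  ip <- segment_backbone_indices(top, def$chain, def$pivot)
  ii <- segment_backbone_indices(top, def$chain, def$inner)
  elems <- if (mass_weighted) top$atoms$element else NULL
  frames <- window_frames(traj, window)
  vals <- vapply(frames, function(f) {
    X <- frame_coords(traj, f)
    vertex_angle(segment_centroid(X, io, elems[io]),
                 segment_centroid(X, ip, elems[ip]),
                 segment_centroid(X, ii, elems[ii]))
  }, numeric(1))
  new_timeseries(traj$times[frames], vals, units = "deg")
}

#' Per-frame angle between two helix axes
#'
#' Each segment axis is the principal direction of its backbone atoms
#' (largest-variance direction), oriented N-terminus to C-terminus; the
#' returned angle between the oriented axes lies in `[0, 180)`. Defaults
#' mirror the TM1 (GIRK1 W82-I105) versus slide-helix (GIRK1 Y67-V76)
#' comparison. The `"endpoint"` method uses the first-to-last C-alpha
#' vector instead of the principal direction.
#'
#' @param traj a [Trajectory].
#' @param segA,segB segments as `list(chain =, resid = c(lo, hi))`, each
#'   spanning at least 4 residues.
#' @param window an [analysis_window()] or `NULL`.
#' @param method `"principal"` (default) or `"endpoint"`.
#' @return A `TimeSeries` in degrees.
#' @export
axis_angle_series <- function(traj, segA, segB, window = NULL,
                              method = c("principal", "endpoint")) {
  method <- match.arg(method)
  top <- traj$topology
  seg_idx <- function(seg) {
    if (diff(range(seg$resid)) + 1 < 4) {
      stop("axis segments must span at least 4 residues", call. = FALSE)
    }
    segment_backbone_indices(top, seg$chain,
                             c(min(seg$resid), max(seg$resid)))
  }
  ia <- seg_idx(segA)
  ib <- seg_idx(segB)
  seg_axis <- function(X, idx) {
    if (method == "principal") {
      principal_axis(X[idx, , drop = FALSE])
    } else {
      unit_vec(X[idx[length(idx)], ] - X[idx[1], ])
    }
  }
  frames <- window_frames(traj, window)
  vals <- vapply(frames, function(f) {
    X <- frame_coords(traj, f)
    a <- seg_axis(X, ia)
    b <- seg_axis(X, ib)
    ang <- acos(min(1, max(-1, sum(a * b)))) * 180 / pi
    if (ang >= 180) ang <- 0
    ang
  }, numeric(1))
  new_timeseries(traj$times[frames], vals, units = "deg")
}

#' Backbone phi/psi dihedral series for one residue
#'
#' Standard definitions: phi = C(i-1)-N-CA-C, psi = N-CA-C-N(i+1), degrees
#' in (-180, 180]. Terminal residues (missing a neighbor) are rejected.
#'
#' @param traj a [Trajectory].
#' @param chain,resid residue identity.
#' @param window an [analysis_window()] or `NULL`.
#' @return A `DihedralSeries`: list with `chain`, `resid`, `times`, `phi`,
#'   `psi` (degrees).
#' @export
backbone_dihedrals <- function(traj, chain, resid, window = NULL) {
  top <- traj$topology
  one <- function(rs, nm) {
    i <- sel_indices(select_atoms(top, chain = chain, resid = rs, name = nm))
    if (length(i) != 1) {
      stop("residue ", chain, ":", resid, " lacks neighbor atom ", nm,
           " of residue ", rs, " (terminal residue?)", call. = FALSE)
    }
    i
  }
  iCp <- one(resid - 1, "C")
  iN <- one(resid, "N")
  iCA <- one(resid, "CA")
  iC <- one(resid, "C")
  iNn <- one(resid + 1, "N")
  frames <- window_frames(traj, window)
  phi <- numeric(length(frames))
  psi <- numeric(length(frames))
  for (k in seq_along(frames)) {
    X <- frame_coords(traj, frames[k])
    phi[k] <- dihedral_angle(X[iCp, ], X[iN, ], X[iCA, ], X[iC, ])
    psi[k] <- dihedral_angle(X[iN, ], X[iCA, ], X[iC, ], X[iNn, ])
  }
  structure(list(chain = chain, resid = resid, times = traj$times[frames],
                 phi = phi, psi = psi), class = "DihedralSeries")
}

#' Largest circular dihedral shift relative to the first frame
#'
#' Flags residues whose backbone dihedrals move by 20 degrees or more over
#' the trajectory - the magnitude associated with shifting between
#' Ramachandran regions at the hinge.
#'
#' @param series a [backbone_dihedrals()] result.
#' @param threshold flag threshold, degrees.
#' @return list with `max_abs_dphi`, `max_abs_dpsi` and `flagged`.
#' @export
dihedral_shift <- function(series, threshold = 20) {
  stopifnot(inherits(series, "DihedralSeries"))
  circ <- function(x) {
    d <- (x - x[1] + 180) %% 360 - 180
    max(abs(d))
  }
  dphi <- circ(series$phi)
  dpsi <- circ(series$psi)
  list(max_abs_dphi = dphi, max_abs_dpsi = dpsi,
       flagged = max(dphi, dpsi) >= threshold)
}

## Ramachandran rectangles: favored alpha / beta cores, allowed = each core
## dilated by 20 degrees plus the left-handed-helix box, else outlier.
RAMA_BOXES <- list(
  favored = list(alpha = list(phi = c(-100, -30), psi = c(-67, -7)),
                 beta = list(phi = c(-180, -100), psi = c(90, 180))),
  lh_box = list(phi = c(40, 80), psi = c(20, 80)),
  dilation = 20)

in_box_circular <- function(ang, lim) {
  (ang >= lim[1] & ang <= lim[2]) |
    (ang + 360 >= lim[1] & ang + 360 <= lim[2]) |
    (ang - 360 >= lim[1] & ang - 360 <= lim[2])
}

#' Classify a phi/psi pair into Ramachandran regions
#'
#' Fixed rectangular regions: favored alpha (phi in \[-100, -30\], psi in
#' \[-67, -7\]) and beta (phi in \[-180, -100\], psi in \[90, 180\]);
#' allowed is a 20-degree dilation of each favored box plus the left-handed
#' box (phi in \[40, 80\], psi in \[20, 80\]); anything else is an outlier.
#' Vectorized and deterministic.
#'
#' @param phi,psi backbone dihedrals in degrees, (-180, 180].
#' @return Character vector in `{"favored", "allowed", "outlier"}`.
#' @export
ramachandran_region <- function(phi, psi) {
  stopifnot(length(phi) == length(psi),
            all(phi > -180 - 1e-9 & phi <= 180 + 1e-9),
            all(psi > -180 - 1e-9 & psi <= 180 + 1e-9))
  out <- rep("outlier", length(phi))
  dil <- RAMA_BOXES$dilation
  for (box in RAMA_BOXES$favored) {
    wide <- in_box_circular(phi, box$phi + c(-dil, dil)) &
      in_box_circular(psi, box$psi + c(-dil, dil))
    out[wide] <- "allowed"
  }
  lh <- RAMA_BOXES$lh_box
  out[in_box_circular(phi, lh$phi) & in_box_circular(psi, lh$psi)] <-
    "allowed"
  for (box in RAMA_BOXES$favored) {
    core <- in_box_circular(phi, box$phi) & in_box_circular(psi, box$psi)
    out[core] <- "favored"
  }
  out
}
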