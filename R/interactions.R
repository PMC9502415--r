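#' Specify a salt-bridge measurement
#'
#' Basic atoms default to lysine terminal nitrogens (atom name `NZ`);
#' acceptor atoms to the PIP2 phosphate group atoms (`O11`-`O16`, `P2`,
#' `P3`). The cutoff defaults to 4.0 A, the standard heavy-atom salt-bridge
#' criterion.
#'
#' @param basic,acceptor `Selection`s of basic and acceptor atoms
#'   (non-empty).
#' @param cutoff engagement cutoff, A (> 0).
#' @return A `SaltBridgeSpec`.
#' @export
salt_bridge_spec <- function(basic, acceptor, cutoff = 4.0) {
  if (!length(sel_indices(basic)) || !length(sel_indices(acceptor))) {
    stop("basic and acceptor selections must be non-empty", call. = FALSE)
  }
  stopifnot(cutoff > 0)
  structure(list(basic = basic, acceptor = acceptor, cutoff = cutoff),
            class = "SaltBridgeSpec")
}

## PIP2 phosphate atom names (the lipid's phosphate groups).
PIP2_PHOSPHATE_NAMES <- c("O11", "O12", "O13", "O14", "O15", "O16",
                          "P2", "P3")

#' Per-frame count of engaged basic atoms
#'
#' A basic atom is engaged in a frame iff its minimum distance to any
#' acceptor atom is within the cutoff (minimum-image when the trajectory
#' carries a box).
#'
#' @param traj a [Trajectory].
#' @param spec a [salt_bridge_spec()].
#' @param window an [analysis_window()] or `NULL`.
#' @return A `TimeSeries` of engaged-atom counts.
#' @export
salt_bridge_series <- function(traj, spec, window = NULL) {
  stopifnot(inherits(spec, "SaltBridgeSpec"))
  bi <- sel_indices(spec$basic)
  ai <- sel_indices(spec$acceptor)
  frames <- window_frames(traj, window)
  vals <- vapply(frames, function(f) {
    X <- frame_coords(traj, f)
    d2 <- pair_dist2(X[bi, , drop = FALSE], X[ai, , drop = FALSE],
                     frame_box(traj, f))
    sum(apply(d2, 1, min) <= spec$cutoff^2)
  }, numeric(1))
  new_timeseries(traj$times[frames], vals, units = "count")
}

#' Normalized salt-bridge formation and fold change
#'
#' Normalized formation is the mean per-frame engaged count divided by the
#' number of candidate basic atoms, a bounded quantity in `[0, 1]`; the
#' fold change divides it by a reference formation (e.g. the apo
#' condition), so activator-like conditions report 1.1-1.2x increases and
#' inhibitor-like conditions ~0.8x decreases.
#'
#' @param series a [salt_bridge_series()] result.
#' @param n_candidates number of candidate basic atoms (>= 1).
#' @param reference optional reference normalized formation (> 0).
#' @return list with `normalized` (in `[0, 1]`) and `fold_change` (or `NA`
#'   when no reference is supplied).
#' @export
normalized_salt_bridge <- function(series, n_candidates, reference = NULL) {
  stopifnot(inherits(series, "TimeSeries"), n_candidates >= 1)
  normalized <- mean(series$values) / n_candidates
  fold <- NA_real_
  if (!is.null(reference)) {
    if (!(is.numeric(reference) && reference > 0)) {
      stop("reference formation must be positive", call. = FALSE)
    }
    fold <- normalized / reference
  }
  list(normalized = normalized, fold_change = fold)
}

#' Per-frame inter-segment contact totals
#'
#' Counts, per frame, the unordered heavy-atom pairs (one atom from each
#' selection) within the cutoff - the per-atom per-frame contact total used
#' to compare TM1-TM2 packing between conditions.
#'
#' @param traj a [Trajectory].
#' @param selA,selB disjoint `Selection`s (hydrogens are ignored).
#' @param cutoff contact cutoff, A; default 4.0.
#' @param window an [analysis_window()] or `NULL`.
#' @return A `TimeSeries` of contact-pair counts.
#' @export
intersegment_contact_series <- function(traj, selA, selB, cutoff = 4.0,
                                        window = NULL) {
  ia <- sel_indices(selA)
  ib <- sel_indices(selB)
  if (length(intersect(ia, ib))) {
    stop("contact selections must be disjoint", call. = FALSE)
  }
  if (!length(ia) || !length(ib)) {
    stop("contact selections must be non-empty", call. = FALSE)
  }
  at <- traj$topology$atoms
  ia <- ia[!is_hydrogen(at[ia, ])]
  ib <- ib[!is_hydrogen(at[ib, ])]
  frames <- window_frames(traj, window)
  vals <- vapply(frames, function(f) {
    X <- frame_coords(traj, f)
    d2 <- pair_dist2(X[ia, , drop = FALSE], X[ib, , drop = FALSE],
                     frame_box(traj, f))
    sum(d2 <= cutoff^2)
  }, numeric(1))
  new_timeseries(traj$times[frames], vals, units = "pairs")
}

#' Typed interaction classes
#'
#' Distance classes for residue-pair interactions, each with one cutoff and
#' one measurement rule: pi-stacking (4.0 A, ring-centroid to ring-centroid),
#' Van der Waals packing (3.0 A - twice the smallest heavy-atom VdW radius
#' - minimum sidechain heavy-atom distance), charge-dipole hydrogen bonds
#' and charge-charge salt bridges (both 4.0 A, minimum polar sidechain
#' heavy-atom distance).
#'
#' @return data.frame with columns `class`, `cutoff`, `rule`.
#' @export
interaction_classes <- function() {
  data.frame(
    class = c("pi_pi", "vdw", "dipole_hbond", "charge_charge"),
    cutoff = c(4.0, vdw_cutoff_from_radius(), 4.0, 4.0),
    rule = c("ring-centroid", "min-heavy", "min-polar", "min-polar"),
    stringsAsFactors = FALSE)
}

#' Contact cutoff from a Van der Waals radius
#'
#' Center-to-center distances count two radii: doubling the smallest
#' heavy-atom Van der Waals radius (1.5 A for C/N/O) gives the conservative
#' 3.0 A upper cutoff for hydrophobic packing contacts.
#'
#' @param radius smallest Van der Waals radius, A.
#' @return Upper distance cutoff, A.
#' @export
vdw_cutoff_from_radius <- function(radius = 1.5) {
  stopifnot(radius > 0)
  2 * radius
}

## Aromatic ring atom names per residue type: the 6-membered ring for
## Phe/Tyr/Trp, the 5-membered imidazole for His.
RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  HSD = c("CG", "ND1", "CD2", "CE1", "NE2"),
  HSE = c("CG", "ND1", "CD2", "CE1", "NE2"))

residue_atoms <- function(top, res) {
  idx <- sel_indices(select_atoms(top, chain = res$chain, resid = res$resid))
  if (!length(idx)) {
    stop("residue ", res$chain, ":", res$resid, " not found", call. = FALSE)
  }
  idx
}

class_atom_indices <- function(top, res, class) {
  at <- top$atoms
  idx <- residue_atoms(top, res)
  if (class == "pi_pi") {
    resname <- at$resname[idx][1]
    ring <- RING_ATOMS[[resname]]
    if (is.null(ring)) {
      stop("pi_pi measurement requested on non-aromatic residue ",
           res$chain, ":", res$resid, " (", resname, ")", call. = FALSE)
    }
    out <- idx[at$name[idx] %in% ring]
    if (length(out) < length(ring)) {
      stop("residue ", res$chain, ":", res$resid,
           " is missing aromatic ring atoms", call. = FALSE)
    }
    out
  } else if (class %in% c("dipole_hbond", "charge_charge")) {
    out <- idx[!(at$name[idx] %in% BACKBONE_NAMES) &
                 grepl("^[NO]", at$name[idx]) & !is_hydrogen(at[idx, ])]
    if (!length(out)) {
      stop("residue ", res$chain, ":", res$resid,
           " has no polar sidechain heavy atoms for class '", class, "'",
           call. = FALSE)
    }
    out
  } else {
    out <- idx[!(at$name[idx] %in% BACKBONE_NAMES) & !is_hydrogen(at[idx, ])]
    if (!length(out)) {
      stop("residue ", res$chain, ":", res$resid,
           " has no sidechain heavy atoms", call. = FALSE)
    }
    out
  }
}

#' Distance distribution for a typed residue pair
#'
#' Measures, per frame, the class-specific distance between two residues
#' (ring centroid for pi-stacking, minimum relevant heavy-atom distance
#' otherwise), bins it into a histogram and reports the engaged fraction
#' (frames within the class cutoff).
#'
#' @param traj a [Trajectory].
#' @param pair list of two residue identifiers, each
#'   `list(chain = , resid = )`.
#' @param class one of [interaction_classes()]`$class`.
#' @param window an [analysis_window()] or `NULL`.
#' @param edges histogram bin edges; default 0.25 A bins over 0-12 A.
#' @return list with `histogram`, `engaged_fraction`, `series` (the
#'   per-frame distances) and `cutoff`.
#' @export
pair_distance_distribution <- function(traj, pair, class, window = NULL,
                                       edges = seq(0, 12, by = 0.25)) {
  classes <- interaction_classes()
  if (!class %in% classes$class) {
    stop("unknown interaction class '", class, "'", call. = FALSE)
  }
  cutoff <- classes$cutoff[classes$class == class]
  top <- traj$topology
  ia <- class_atom_indices(top, pair[[1]], class)
  ib <- class_atom_indices(top, pair[[2]], class)
  frames <- window_frames(traj, window)
  vals <- vapply(frames, function(f) {
    X <- frame_coords(traj, f)
    box <- frame_box(traj, f)
    if (class == "pi_pi") {
      ca <- colMeans(X[ia, , drop = FALSE])
      cb <- colMeans(X[ib, , drop = FALSE])
      sqrt(pair_dist2(matrix(ca, 1), matrix(cb, 1), box)[1, 1])
    } else {
      min_pair_dist(X[ia, , drop = FALSE], X[ib, , drop = FALSE], box)
    }
  }, numeric(1))
  list(histogram = make_histogram(vals, edges),
       engaged_fraction = mean(vals <= cutoff),
       series = new_timeseries(traj$times[frames], vals, units = "A"),
       cutoff = cutoff)
}
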