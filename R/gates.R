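#' Specify a channel gate
#'
#' A gate is the four-fold pseudo-symmetric constriction formed by one
#' residue per subunit: the helix-bundle-crossing (HBC) phenylalanines
#' (GIRK1 F181 / GIRK2 F192) or the G-loop girdle methionines (GIRK2
#' M313/M319). The gate "distance" is measured between diagonal subunit
#' pairs (first-third and second-fourth chain in pore order), matching the
#' diameter framing of the 5.7 A occlusion threshold.
#'
#' @param name `"HBC"` or `"G-loop"`.
#' @param top a [Topology].
#' @param assignment a [subunit_assignment()] for the four chains.
#' @param roles a `ResidueRoleMap`; the gate residues come from the
#'   `"HBC-gate"` / `"G-loop-gate"` roles.
#' @param occlusion_threshold minimum gate distance (A) that permits
#'   permeation of partially solvated potassium; default 5.7.
#' @param scope atom scope for the distance measurement; default
#'   sidechain-heavy.
#' @return A `GateSpec`: the per-chain gate residue table plus the diagonal
#'   pairing.
#' @export
gate_spec <- function(name = c("HBC", "G-loop"), top, assignment,
                      roles = default_role_map(),
                      occlusion_threshold = 5.7,
                      scope = "sidechain-heavy") {
  name <- match.arg(name)
  stopifnot(inherits(assignment, "SubunitAssignment"),
            occlusion_threshold > 0)
  role_name <- if (name == "HBC") "HBC-gate" else "G-loop-gate"
  chains <- names(assignment)
  residues <- list()
  for (ch in chains) {
    entry <- roles[[role_name]][[assignment[[ch]]]]
    if (!is.null(entry)) {
      residues[[ch]] <- as.integer(entry)
    }
  }
  n_res <- sum(lengths(residues))
  if (n_res != 4) {
    stop("gate '", name, "' must resolve to exactly 4 residues across the ",
         "assigned chains; got ", n_res, call. = FALSE)
  }
  ## diagonal chain pairs in pore order
  diag_pairs <- list(c(chains[1], chains[3]), c(chains[2], chains[4]))
  pairs <- list()
  for (dp in diag_pairs) {
    common <- intersect(residues[[dp[1]]] %||% integer(),
                        residues[[dp[2]]] %||% integer())
    for (r in common) {
      pairs[[length(pairs) + 1]] <- list(chain_a = dp[1], chain_b = dp[2],
                                         resid = r)
    }
  }
  if (!length(pairs)) {
    stop("gate '", name, "' has no diagonal residue pairs under this ",
         "assignment", call. = FALSE)
  }
  structure(list(name = name, residues = residues, pairs = pairs,
                 occlusion_threshold = occlusion_threshold, scope = scope),
            class = "GateSpec")
}

gate_pair_indices <- function(top, gate) {
  lapply(gate$pairs, function(pr) {
    ia <- sel_indices(select_atoms(top, chain = pr$chain_a,
                                   resid = pr$resid, scope = gate$scope))
    ib <- sel_indices(select_atoms(top, chain = pr$chain_b,
                                   resid = pr$resid, scope = gate$scope))
    if (!length(ia) || !length(ib)) {
      stop("gate residue ", pr$resid, " (chains ", pr$chain_a, "/",
           pr$chain_b, ") has no ", gate$scope, " atoms", call. = FALSE)
    }
    list(a = ia, b = ib)
  })
}

#' Per-frame minimum gate distance
#'
#' For each frame, the minimum over the diagonal residue pairs of the
#' minimum heavy-atom center-to-center distance between the paired gate
#' residues (minimum-image when the trajectory carries a box).
#'
#' @param traj a [Trajectory].
#' @param gate a [gate_spec()].
#' @param window an [analysis_window()] or `NULL` for all frames.
#' @return A `TimeSeries` in Angstrom.
#' @export
gate_min_distance <- function(traj, gate, window = NULL) {
  stopifnot(inherits(gate, "GateSpec"))
  idx <- gate_pair_indices(traj$topology, gate)
  frames <- window_frames(traj, window)
  vals <- vapply(frames, function(f) {
    X <- frame_coords(traj, f)
    box <- frame_box(traj, f)
    min(vapply(idx, function(pr) {
      min_pair_dist(X[pr$a, , drop = FALSE], X[pr$b, , drop = FALSE], box)
    }, numeric(1)))
  }, numeric(1))
  new_timeseries(traj$times[frames], vals, units = "A")
}

#' Fraction of frames in which a gate is open
#'
#' A frame counts as open when the gate distance is at least the occlusion
#' threshold (default 5.7 A, the minimal diameter that permits partially
#' solvated potassium).
#'
#' @param series a gate-distance `TimeSeries`.
#' @param threshold occlusion threshold, A.
#' @return Open fraction in `[0, 1]`.
#' @export
classify_occlusion <- function(series, threshold = 5.7) {
  stopifnot(inherits(series, "TimeSeries"))
  if (!length(series$values)) stop("empty time series", call. = FALSE)
  mean(series$values >= threshold)
}

## Unwrap a per-frame z series across periodic images.
unwrap_z <- function(z, box_z = NULL) {
  if (is.null(box_z) || length(z) < 2) return(z)
  dz <- diff(z)
  dz <- dz - box_z * round(dz / box_z)
  c(z[1], z[1] + cumsum(dz))
}

#' Count ion-conduction events
#'
#' An ion conducts when it traverses both gate planes in sequence. Each ion
#' runs a three-state machine: ABOVE (`z > z_HBC + delta`), IN_PORE
#' (between the planes and within `pore_radius` of the pore axis), BELOW
#' (`z < z_Gloop - delta`). Reaching BELOW from IN_PORE after entering from
#' ABOVE emits one inward event; leaving the pore laterally or returning
#' ABOVE resets the machine. The symmetric upward passage is recorded with
#' direction `"outward"`. z coordinates are unwrapped across periodic
#' images before detection.
#'
#' @param traj a [Trajectory].
#' @param ions a `Selection` of ion atoms (non-empty).
#' @param gate_planes `c(z_HBC, z_Gloop)` in A with `z_HBC > z_Gloop`, or
#'   an `n_frames x 2` matrix of per-frame planes.
#' @param window an [analysis_window()] restricting which events are
#'   counted (events are detected over the full trajectory so state is not
#'   truncated); `NULL` counts all.
#' @param hysteresis plane hysteresis delta, A (>= 0); default 2.
#' @param pore_radius lateral pore radius, A; default 10.
#' @param axis pore axis x/y, default `c(0, 0)`.
#' @return list with `count` (inward events in the window) and `events`
#'   (data.frame ion, entry_frame, exit_frame, direction).
#' @export
count_conductions <- function(traj, ions, gate_planes, window = NULL,
                              hysteresis = 2, pore_radius = 10,
                              axis = c(0, 0)) {
  ion_idx <- sel_indices(ions)
  if (!length(ion_idx)) stop("empty ion selection", call. = FALSE)
  stopifnot(hysteresis >= 0, pore_radius > 0)
  nf <- n_frames(traj)
  if (is.null(dim(gate_planes))) {
    stopifnot(length(gate_planes) == 2, gate_planes[1] > gate_planes[2])
    gate_planes <- matrix(rep(as.numeric(gate_planes), each = nf), nf, 2)
  }
  stopifnot(nrow(gate_planes) == nf)
  box_z <- if (is.null(traj$box)) NULL else traj$box[1, 3]
  events <- list()
  for (ii in ion_idx) {
    z <- unwrap_z(traj$coords[, ii, 3], box_z)
    r <- sqrt((traj$coords[, ii, 1] - axis[1])^2 +
              (traj$coords[, ii, 2] - axis[2])^2)
    st <- "NEUTRAL"
    came_from <- NA_character_
    entry <- NA_integer_
    for (f in seq_len(nf)) {
      hi <- gate_planes[f, 1] + hysteresis
      lo <- gate_planes[f, 2] - hysteresis
      in_pore <- z[f] <= gate_planes[f, 1] & z[f] >= gate_planes[f, 2] &
        r[f] <= pore_radius
      if (z[f] > hi) {
        if (st == "IN_PORE" && identical(came_from, "below")) {
          events[[length(events) + 1]] <-
            data.frame(ion = ii, entry_frame = entry, exit_frame = f,
                       direction = "outward")
        }
        st <- "ABOVE"; came_from <- NA; entry <- NA_integer_
      } else if (z[f] < lo) {
        if (st == "IN_PORE" && identical(came_from, "above")) {
          events[[length(events) + 1]] <-
            data.frame(ion = ii, entry_frame = entry, exit_frame = f,
                       direction = "inward")
        }
        st <- "BELOW"; came_from <- NA; entry <- NA_integer_
      } else if (in_pore) {
        if (st == "ABOVE") {
          st <- "IN_PORE"; came_from <- "above"; entry <- f
        } else if (st == "BELOW") {
          st <- "IN_PORE"; came_from <- "below"; entry <- f
        }
        ## st == "IN_PORE": stay; st == "NEUTRAL": unseeded, stay neutral
      } else if (st == "IN_PORE" && r[f] > pore_radius) {
        ## lateral exit from the pore cylinder resets; an ion merely
        ## sitting inside a hysteresis margin keeps its state
        st <- "NEUTRAL"; came_from <- NA; entry <- NA_integer_
      }
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(ion = integer(), entry_frame = integer(),
               exit_frame = integer(), direction = character())
  keep <- rep(TRUE, nrow(ev))
  if (!is.null(window) && nrow(ev)) {
    t_exit <- traj$times[ev$exit_frame]
    keep <- t_exit >= window$start_ns & t_exit < window$end_ns
  }
  list(count = sum(ev$direction[keep] == "inward"), events = ev[keep, ])
}

#' Per-frame gate planes from the z centroid of gate C-alpha atoms
#'
#' Tracks channel drift along the membrane normal; useful when the gate
#' planes cannot be taken as static.
#'
#' @param traj a [Trajectory].
#' @param hbc,gloop [gate_spec()]s for the two gates.
#' @return `n_frames x 2` matrix of plane heights (HBC, G-loop), A.
#' @export
gate_planes_from_spec <- function(traj, hbc, gloop) {
  top <- traj$topology
  plane_z <- function(gate) {
    idx <- integer()
    for (ch in names(gate$residues)) {
      idx <- c(idx, sel_indices(select_atoms(top, chain = ch,
                                             resid = gate$residues[[ch]],
                                             name = "CA")))
    }
    if (!length(idx)) {
      stop("gate '", gate$name, "' has no C-alpha atoms for plane ",
           "derivation", call. = FALSE)
    }
    rowMeans(traj$coords[, idx, 3, drop = FALSE])
  }
  cbind(plane_z(hbc), plane_z(gloop))
}
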