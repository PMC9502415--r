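## Synthetic-trajectory generators with exact ground truth. Every generator
## is a pure function of its spec (seed included); randomness never touches
## the caller's global RNG state.

## Ion drift mobility, Angstrom * nm / (V * ns): frozen so that the
## physiological -0.06 V/nm field gives a 0.15 A/frame drift at dt = 0.1 ns
## and an open 5 A pore conducts at least once per 1000 frames.
DRIFT_MOBILITY <- 25

## Minimum gate radius (A) that lets an ion pass the gate plane.
GATE_PASS_RADIUS <- 2.0

## Ions are driven this far past the lower gate plane before an exit is
## logged, so ground-truth traversals hold for any detector hysteresis
## delta <= 2 A.
EXIT_OVERSHOOT <- 3.2

#' Specification of a synthetic gated-pore trajectory
#'
#' Describes a membrane-normal-aligned pore (z is the membrane normal,
#' extracellular side at +z) with two stacked gate planes, four-fold
#' pseudo-symmetric single-atom gate "residues" at a controllable radius,
#' and potassium ions performing an overdamped biased walk under a constant
#' electric field.
#'
#' @param n_ions number of ions.
#' @param gate_z `c(z_HBC, z_Gloop)` gate plane heights in A,
#'   `z_HBC - z_Gloop >= 5`.
#' @param gate_radius per-gate radius in A: length-2 vector (constant) or
#'   `n_frames x 2` matrix (per-frame schedule), columns HBC then G-loop.
#' @param field membrane-normal electric field in V/nm; negative drives
#'   cations toward -z (inward).
#' @param noise_scale per-step Gaussian displacement sigma, A.
#' @param box orthorhombic box lengths, A.
#' @param n_frames,dt_ns frame count (>= 2) and spacing.
#' @param seed integer RNG seed.
#' @return A validated `SyntheticPoreSpec`.
#' @export
pore_spec <- function(n_ions = 20, gate_z = c(7.5, -7.5),
                      gate_radius = c(5, 5), field = -0.06,
                      noise_scale = 0.5, box = c(40, 40, 70),
                      n_frames = 2000, dt_ns = 0.1, seed = 1) {
  if (gate_z[1] - gate_z[2] < 5) {
    stop("gate planes must be at least 5 A apart", call. = FALSE)
  }
  if (n_frames < 2) stop("n_frames must be >= 2", call. = FALSE)
  if (is.null(dim(gate_radius))) {
    gate_radius <- matrix(rep(as.numeric(gate_radius), each = n_frames),
                          n_frames, 2)
  }
  stopifnot(nrow(gate_radius) == n_frames, ncol(gate_radius) == 2)
  if (any(gate_radius < 0)) stop("gate radii must be >= 0", call. = FALSE)
  stopifnot(n_ions >= 1, noise_scale >= 0, dt_ns > 0, length(box) == 3)
  structure(list(n_ions = as.integer(n_ions), gate_z = as.numeric(gate_z),
                 gate_radius = gate_radius, field = field,
                 noise_scale = noise_scale, box = as.numeric(box),
                 n_frames = as.integer(n_frames), dt_ns = dt_ns,
                 seed = as.integer(seed)),
            class = "SyntheticPoreSpec")
}

pore_topology <- function(spec) {
  rows <- list()
  ser <- 0
  add <- function(name, element, resname, resid, chain) {
    ser <<- ser + 1
    data.frame(serial = ser, name = name, element = element,
               resname = resname, resid = resid, chain = chain,
               stringsAsFactors = FALSE)
  }
  ## HBC gate Phe on all four chains (GIRK1 F181 on A/C, GIRK2 F192 on B/D),
  ## G-loop gate Met M313/M319 on the GIRK2 chains only.
  for (ch in c("A", "B", "C", "D")) {
    hbc_res <- if (ch %in% c("A", "C")) 181L else 192L
    rows <- c(rows, list(add("CA", "C", "PHE", hbc_res, ch),
                         add("CZ", "C", "PHE", hbc_res, ch)))
    if (ch %in% c("B", "D")) {
      for (r in c(313L, 319L)) {
        rows <- c(rows, list(add("CA", "C", "MET", r, ch),
                             add("SD", "S", "MET", r, ch)))
      }
    }
  }
  for (i in seq_len(spec$n_ions)) {
    rows <- c(rows, list(add("K", "K", "POT", i, "I")))
  }
  topology(do.call(rbind, rows))
}

## Gate-atom coordinates for one frame given the two gate radii. Diagonal
## chain pairs (A-C, B-D) sit across the pore axis, so the gate minimum
## distance equals twice the gate radius.
pore_gate_coords <- function(spec, rad) {
  z1 <- spec$gate_z[1]; z2 <- spec$gate_z[2]
  place <- function(ang, r, z) c(r * cos(ang), r * sin(ang), z)
  out <- matrix(0, 0, 3)
  angs <- c(A = 0, B = pi / 2, C = pi, D = 3 * pi / 2)
  for (ch in c("A", "B", "C", "D")) {
    a <- angs[[ch]]
    out <- rbind(out,
                 place(a, rad[1] + 1.5, z1 + 0.5),  # CA (backbone ring)
                 place(a, rad[1], z1))              # CZ (sidechain tip)
    if (ch %in% c("B", "D")) {
      out <- rbind(out,
                   place(a, rad[2] + 1.5, z2 + 0.5), place(a, rad[2], z2),
                   place(a, rad[2] + 1.5, z2 - 0.5),
                   place(a, rad[2], z2 - 1.0))
    }
  }
  out
}

#' Simulate ions drifting through a two-gate pore
#'
#' Ions start above the upper (HBC) gate plane and perform an overdamped
#' Euler walk `dz = mobility * field * dt + noise`, laterally confined near
#' the pore axis. An ion may cross a gate plane only while that gate's
#' radius is at least 2 A; blocked crossings reflect. Once an ion passes
#' below the lower (G-loop) plane it is driven monotonically to a 3.2 A
#' overshoot, the completed inward traversal is logged, and the ion
#' respawns above the upper gate, so the ground truth is unambiguous for
#' any detector hysteresis up to 2 A. Identical seeds give bit-identical
#' output.
#'
#' @param spec a [pore_spec()].
#' @return list with `trajectory` (a [Trajectory]; four gate chains A-D
#'   plus ion chain I), `truth` (a `GroundTruth` with the traversal-event
#'   table), and `assignment` (the matching [subunit_assignment()]).
#' @export
simulate_pore_trajectory <- function(spec) {
  stopifnot(inherits(spec, "SyntheticPoreSpec"))
  top <- pore_topology(spec)
  n_gate_atoms <- top$n_atoms - spec$n_ions
  nf <- spec$n_frames
  z_hbc <- spec$gate_z[1]; z_glp <- spec$gate_z[2]
  z_top <- z_hbc + 18
  drift <- DRIFT_MOBILITY * spec$field * spec$dt_ns
  coords <- array(0, c(nf, top$n_atoms, 3))
  events <- list()

  withr::with_seed(spec$seed, {
    ion_xy <- cbind(stats::runif(spec$n_ions, -2, 2),
                    stats::runif(spec$n_ions, -2, 2))
    ion_z <- stats::runif(spec$n_ions, z_hbc + 4, z_top - 2)
    exiting <- rep(FALSE, spec$n_ions)
    entry <- rep(NA_integer_, spec$n_ions)
    respawn <- rep(FALSE, spec$n_ions)

    for (f in seq_len(nf)) {
      rad <- spec$gate_radius[f, ]
      if (f > 1) {
        for (i in seq_len(spec$n_ions)) {
          if (respawn[i]) {
            ion_z[i] <- stats::runif(1, z_hbc + 4, z_hbc + 7)
            ion_xy[i, ] <- stats::runif(2, -2, 2)
            respawn[i] <- FALSE
            exiting[i] <- FALSE
            entry[i] <- NA_integer_
            next
          }
          if (exiting[i]) {
            ## brisk forced descent so every logged traversal completes
            step <- -0.6 - abs(stats::rnorm(1, 0, spec$noise_scale))
            ion_z[i] <- ion_z[i] + step
            if (ion_z[i] <= z_glp - EXIT_OVERSHOOT) {
              events[[length(events) + 1]] <-
                data.frame(ion = i, entry_frame = entry[i], exit_frame = f,
                           direction = "inward")
              respawn[i] <- TRUE
            }
            next
          }
          z_old <- ion_z[i]
          z_new <- z_old + drift + stats::rnorm(1, 0, spec$noise_scale)
          ## gate blocking: reflect off an occluded gate plane; the lower
          ## gate also reflects near the trajectory end so that every
          ## logged traversal completes its overshoot before the run stops
          for (g in 1:2) {
            gz <- spec$gate_z[g]
            blocked <- rad[g] < GATE_PASS_RADIUS ||
              (g == 2 && nf - f < 12)
            if ((z_old - gz) * (z_new - gz) < 0 && blocked) {
              z_new <- 2 * gz - z_new
            }
          }
          if (z_new > z_top) z_new <- 2 * z_top - z_new
          ## entry bookkeeping at the upper plane
          if (z_old > z_hbc && z_new <= z_hbc) entry[i] <- f
          if (z_new > z_hbc) entry[i] <- NA_integer_
          if (z_new < z_glp) exiting[i] <- TRUE
          ion_z[i] <- z_new
          xy <- ion_xy[i, ] + stats::rnorm(2, 0, spec$noise_scale / 2)
          if (sqrt(sum(xy^2)) > 6) xy <- xy * (6 / sqrt(sum(xy^2)))
          ion_xy[i, ] <- xy
        }
      }
      coords[f, seq_len(n_gate_atoms), ] <- pore_gate_coords(spec, rad)
      ion_rows <- n_gate_atoms + seq_len(spec$n_ions)
      coords[f, ion_rows, 1] <- ion_xy[, 1]
      coords[f, ion_rows, 2] <- ion_xy[, 2]
      coords[f, ion_rows, 3] <- ion_z
    }
  })

  traj <- trajectory(top, coords, times = (seq_len(nf) - 1) * spec$dt_ns,
                     box = spec$box)
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(ion = integer(), entry_frame = integer(),
               exit_frame = integer(), direction = character())
  truth <- structure(list(traversal_events = ev, programmed_bend_deg = NULL,
                          programmed_correlation = NULL,
                          programmed_engagement = NULL, spec = spec),
                     class = "GroundTruth")
  list(trajectory = traj, truth = truth,
       assignment = default_assignment())
}

#' Specification of a synthetic kinked helix
#'
#' An ideal alpha-helix (backbone dihedrals phi = -57, psi = -47 degrees,
#' giving the canonical ~1.5 A rise and ~100 degree twist per residue)
#' whose C-terminal arm is rotated rigidly about the pivot-segment centroid
#' so that the segment-centroid bend angle equals `bend_deg` exactly in the
#' noise-free construction; isotropic Gaussian noise is added per frame.
#'
#' @param n_residues helix length (>= 21 for the default segment layout).
#' @param bend_deg programmed bend angle at the pivot, degrees; 180 =
#'   straight. Must satisfy `0 < bend_deg <= 180`.
#' @param noise_sigma per-coordinate Gaussian noise, A.
#' @param n_frames,dt_ns,seed frames, spacing (ns) and RNG seed.
#' @param pivot pivot residue index; default is residue 11 (mirroring the
#'   ten-residue offset between the TM2 outer turn and the hinge).
#' @param rise,twist nominal helix parameters (A / degrees per residue);
#'   informational - geometry follows from the ideal dihedrals.
#' @return A validated `HelixSpec`.
#' @export
helix_spec <- function(n_residues = 21, bend_deg = 180, noise_sigma = 0,
                       n_frames = 1, dt_ns = 0.1, seed = 1, pivot = NULL,
                       rise = 1.5, twist = 100) {
  if (!(bend_deg > 0 && bend_deg <= 180)) {
    stop("bend_deg must be in (0, 180]", call. = FALSE)
  }
  pivot <- pivot %||% 11L
  if (n_residues < pivot + 10) {
    stop("n_residues too small for the segment layout (need pivot + 10)",
         call. = FALSE)
  }
  stopifnot(noise_sigma >= 0, n_frames >= 1)
  structure(list(n_residues = as.integer(n_residues), bend_deg = bend_deg,
                 noise_sigma = noise_sigma, n_frames = as.integer(n_frames),
                 dt_ns = dt_ns, seed = as.integer(seed),
                 pivot = as.integer(pivot), rise = rise, twist = twist),
            class = "HelixSpec")
}

## Ideal alpha-helix backbone (atoms N, CA, C, O per residue) by
## internal-coordinate chain extension at phi -57 / psi -47 / omega 180.
build_ideal_helix <- function(n_residues, phi = -57, psi = -47) {
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329; b_co <- 1.231
  a_ncac <- 111.2; a_cacn <- 116.2; a_cnca <- 121.7; a_caco <- 120.8
  coords <- matrix(NA_real_, 4 * n_residues, 3)
  idx <- function(res, k) 4 * (res - 1) + k  # k: 1=N 2=CA 3=C 4=O
  coords[idx(1, 1), ] <- c(0, 0, 0)
  coords[idx(1, 2), ] <- c(b_nca, 0, 0)
  ang <- (180 - a_ncac) * pi / 180
  coords[idx(1, 3), ] <- coords[idx(1, 2), ] +
    b_cac * c(cos(ang), sin(ang), 0)
  for (r in seq_len(n_residues)) {
    N <- coords[idx(r, 1), ]; CA <- coords[idx(r, 2), ]
    C <- coords[idx(r, 3), ]
    coords[idx(r, 4), ] <- nerf_place(N, CA, C, b_co, a_caco, psi + 180)
    if (r < n_residues) {
      Nn <- nerf_place(N, CA, C, b_cn, a_cacn, psi)
      CAn <- nerf_place(CA, C, Nn, b_nca, a_cnca, 180)
      Cn <- nerf_place(C, Nn, CAn, b_cac, a_ncac, phi)
      coords[idx(r + 1, 1), ] <- Nn
      coords[idx(r + 1, 2), ] <- CAn
      coords[idx(r + 1, 3), ] <- Cn
    }
  }
  coords
}

helix_topology <- function(n_residues, chain = "A", resid_offset = 0L) {
  names4 <- c("N", "CA", "C", "O")
  elem4 <- c("N", "C", "C", "O")
  data.frame(serial = seq_len(4 * n_residues),
             name = rep(names4, n_residues),
             element = rep(elem4, n_residues),
             resname = "ALA",
             resid = rep(seq_len(n_residues) + resid_offset, each = 4),
             chain = chain, stringsAsFactors = FALSE)
}

#' Simulate a kinked ideal helix
#'
#' @param spec a [helix_spec()].
#' @return A [Trajectory] (chain A, residues 1..n, backbone atoms only)
#'   with attributes `bend_def` (the outer/pivot/inner segment layout used
#'   by the construction) and `programmed_bend` (degrees).
#' @export
simulate_bent_helix <- function(spec) {
  stopifnot(inherits(spec, "HelixSpec"))
  n <- spec$n_residues
  p <- spec$pivot
  raw <- build_ideal_helix(n)
  at <- helix_topology(n)
  seg <- list(outer = (p - 10):(p - 6), pivot = (p - 1):(p + 1),
              inner = (p + 6):(p + 10))
  cen <- function(resids) {
    colMeans(raw[at$resid %in% resids & at$name %in% BACKBONE_NAMES, ,
                 drop = FALSE])
  }
  c_piv <- cen(seg$pivot)
  u <- cen(seg$outer) - c_piv
  w <- cen(seg$inner) - c_piv
  theta0 <- vertex_angle(cen(seg$outer), c_piv, cen(seg$inner))
  axis <- vec_cross(u, w)
  if (vec_norm(axis) < 1e-9) {
    axis <- vec_cross(u, c(1, 0, 0))
    if (vec_norm(axis) < 1e-9) axis <- vec_cross(u, c(0, 1, 0))
  }
  ## rotate the arm C-terminal of the pivot segment in the (u, w) plane so
  ## the centroid bend equals the programmed value exactly
  R <- rotation_matrix(axis, spec$bend_deg - theta0)
  move <- which(at$resid >= p + 2)
  raw[move, ] <- sweep(sweep(raw[move, , drop = FALSE], 2, c_piv) %*% t(R),
                       2, c_piv, "+")
  coords <- array(0, c(spec$n_frames, nrow(raw), 3))
  withr::with_seed(spec$seed, {
    for (f in seq_len(spec$n_frames)) {
      coords[f, , ] <- raw +
        if (spec$noise_sigma > 0)
          matrix(stats::rnorm(length(raw), 0, spec$noise_sigma),
                 nrow(raw), 3) else 0
    }
  })
  traj <- trajectory(topology(at), coords,
                     times = (seq_len(spec$n_frames) - 1) * spec$dt_ns)
  attr(traj, "bend_def") <- list(chain = "A", outer = range(seg$outer),
                                 pivot = range(seg$pivot),
                                 inner = range(seg$inner))
  attr(traj, "programmed_bend") <- spec$bend_deg
  traj
}

#' Simulate two rigid helices at a programmed inter-axis angle
#'
#' Builds one ideal helix and a rigid rotated copy, so the angle between
#' the two principal axes equals `angle_deg` exactly in the noise-free
#' construction. Used to exercise the TM1 / slide-helix axis-angle
#' analysis.
#'
#' @param angle_deg programmed angle between the helix axes, degrees in
#'   `[0, 180)`.
#' @param n_residues residues per helix.
#' @param separation center-to-center offset between the helices, A.
#' @param noise_sigma,n_frames,dt_ns,seed as in [helix_spec()].
#' @return A [Trajectory] with chains A and B (residues 1..n each).
#' @export
simulate_axis_pair <- function(angle_deg, n_residues = 12, separation = 15,
                               noise_sigma = 0, n_frames = 1, dt_ns = 0.1,
                               seed = 1) {
  stopifnot(angle_deg >= 0, angle_deg < 180, n_residues >= 4)
  raw <- build_ideal_helix(n_residues)
  axis <- principal_axis(raw[seq(2, nrow(raw), by = 4), , drop = FALSE])
  perp <- vec_cross(axis, c(1, 0, 0))
  if (vec_norm(perp) < 1e-6) perp <- vec_cross(axis, c(0, 1, 0))
  R <- rotation_matrix(perp, angle_deg)
  ctr <- colMeans(raw)
  second <- sweep(sweep(raw, 2, ctr) %*% t(R), 2,
                  ctr + separation * unit_vec(vec_cross(axis, perp)), "+")
  atoms <- rbind(helix_topology(n_residues, chain = "A"),
                 helix_topology(n_residues, chain = "B"))
  atoms$serial <- seq_len(nrow(atoms))
  base <- rbind(raw, second)
  coords <- array(0, c(n_frames, nrow(base), 3))
  withr::with_seed(seed, {
    for (f in seq_len(n_frames)) {
      coords[f, , ] <- base +
        if (noise_sigma > 0)
          matrix(stats::rnorm(length(base), 0, noise_sigma),
                 nrow(base), 3) else 0
    }
  })
  traj <- trajectory(topology(atoms), coords,
                     times = (seq_len(n_frames) - 1) * dt_ns)
  attr(traj, "programmed_angle") <- angle_deg
  traj
}

#' Specification of a correlated pseudo-C-alpha walk
#'
#' @param n_residues number of residues (one C-alpha each).
#' @param target symmetric positive semi-definite correlation matrix with
#'   unit diagonal (the programmed cross-correlation structure).
#' @param n_frames,dt_ns,seed frames, spacing, RNG seed.
#' @return A validated `CorrelatedWalkSpec`.
#' @export
corr_walk_spec <- function(n_residues, target, n_frames, dt_ns = 0.1,
                           seed = 1) {
  target <- as.matrix(target)
  stopifnot(nrow(target) == n_residues, ncol(target) == n_residues)
  if (max(abs(target - t(target))) > 1e-8) {
    stop("target correlation matrix must be symmetric", call. = FALSE)
  }
  if (max(abs(diag(target) - 1)) > 1e-8) {
    stop("target correlation matrix must have unit diagonal", call. = FALSE)
  }
  ev <- eigen(target, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("target correlation matrix is not positive semi-definite ",
         "(min eigenvalue ", format(min(ev)), ")", call. = FALSE)
  }
  stopifnot(n_frames >= 2)
  structure(list(n_residues = as.integer(n_residues), target = target,
                 n_frames = as.integer(n_frames), dt_ns = dt_ns,
                 seed = as.integer(seed)),
            class = "CorrelatedWalkSpec")
}

#' Simulate residues with a programmed cross-correlation structure
#'
#' Per-frame displacements of each pseudo-C-alpha are zero-mean Gaussian,
#' independent across the x/y/z components, with the across-residue
#' correlation of every component equal to the target matrix - so the
#' dynamic cross-correlation of the emitted coordinates converges to the
#' target at the Monte-Carlo rate.
#'
#' @param spec a [corr_walk_spec()].
#' @return A [Trajectory] (chain A, one CA per residue) with attribute
#'   `programmed_correlation`.
#' @export
simulate_correlated_walk <- function(spec) {
  stopifnot(inherits(spec, "CorrelatedWalkSpec"))
  n <- spec$n_residues
  eg <- eigen(spec$target, symmetric = TRUE)
  L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), n)
  base <- cbind(5 * seq_len(n), 0, 0)
  coords <- array(0, c(spec$n_frames, n, 3))
  withr::with_seed(spec$seed, {
    for (d in 1:3) {
      U <- matrix(stats::rnorm(spec$n_frames * n), spec$n_frames, n) %*%
        t(L)
      coords[, , d] <- sweep(U, 2, base[, d], "+")
    }
  })
  at <- data.frame(serial = seq_len(n), name = "CA", element = "C",
                   resname = "ALA", resid = seq_len(n), chain = "A",
                   stringsAsFactors = FALSE)
  traj <- trajectory(topology(at), coords,
                     times = (seq_len(spec$n_frames) - 1) * spec$dt_ns)
  attr(traj, "programmed_correlation") <- spec$target
  traj
}

#' Convert a constant membrane-normal field to a transmembrane potential
#'
#' `field [V/nm] * thickness [A]` with unit bookkeeping (10 A per nm,
#' 1000 mV per V): a 0.06 V/nm field across a 35 A membrane is 210 mV.
#'
#' @param field electric field, V/nm.
#' @param thickness membrane thickness, A (> 0).
#' @return Transmembrane potential in mV.
#' @export
field_to_voltage <- function(field, thickness) {
  if (!(is.numeric(thickness) && thickness > 0)) {
    stop("membrane thickness must be positive", call. = FALSE)
  }
  field * (thickness / 10) * 1000
}

#' Simulate stochastic lysine-phosphate salt-bridge engagement
#'
#' Each candidate basic/acceptor pair is engaged in each frame by an
#' independent Bernoulli draw: engaged pairs sit at 3.5 A, disengaged pairs
#' at 6.0 A, so the emitted coordinates reproduce the engagement table
#' exactly under the standard 4.0 A salt-bridge cutoff.
#'
#' @param n_frames frames to simulate.
#' @param engagement_prob per-frame engagement probability in `[0, 1]`.
#' @param n_pairs number of candidate lysine/phosphate pairs.
#' @param seed RNG seed.
#' @param dt_ns frame spacing, ns.
#' @return list with `trajectory` (lysine NZ atoms on chain A, PIP2
#'   phosphate P2 atoms on chain L), `engagement` (`n_frames x n_pairs`
#'   logical matrix) and `engagement_prob`.
#' @export
simulate_bridge_engagement <- function(n_frames, engagement_prob,
                                       n_pairs = 3, seed = 1, dt_ns = 0.1) {
  if (!(is.numeric(engagement_prob) && engagement_prob >= 0 &&
        engagement_prob <= 1)) {
    stop("engagement_prob must be a probability in [0, 1]", call. = FALSE)
  }
  stopifnot(n_frames >= 1, n_pairs >= 1)
  eng <- withr::with_seed(seed, {
    matrix(stats::runif(n_frames * n_pairs) < engagement_prob,
           n_frames, n_pairs)
  })
  rows <- list()
  for (i in seq_len(n_pairs)) {
    rows[[2 * i - 1]] <- data.frame(serial = 2 * i - 1, name = "NZ",
                                    element = "N", resname = "LYS",
                                    resid = 180L + i, chain = "A",
                                    stringsAsFactors = FALSE)
    rows[[2 * i]] <- data.frame(serial = 2 * i, name = "P2", element = "P",
                                resname = "PIP", resid = 500L + i,
                                chain = "L", stringsAsFactors = FALSE)
  }
  top <- topology(do.call(rbind, rows))
  coords <- array(0, c(n_frames, 2 * n_pairs, 3))
  for (i in seq_len(n_pairs)) {
    base_x <- 20 * i
    coords[, 2 * i - 1, 1] <- base_x
    coords[, 2 * i, 1] <- base_x + ifelse(eng[, i], 3.5, 6.0)
  }
  traj <- trajectory(top, coords, times = (seq_len(n_frames) - 1) * dt_ns)
  list(trajectory = traj, engagement = eng,
       engagement_prob = engagement_prob)
}
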