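#' Build a channel topology from an atom table
#'
#' A `Topology` is the static atom identity shared by all frames of a
#' trajectory: serial, atom name, element, residue name, canonical residue
#' index (1-based UniProt numbering) and chain id. Coordinates live in the
#' [Trajectory] object, not here.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resid`, `chain`.
#' @return An object of class `Topology`: the validated atom table plus a
#'   per-chain contiguous residue range.
#' @export
topology <- function(atoms) {
  required <- c("serial", "name", "element", "resname", "resid", "chain")
  missing <- setdiff(required, names(atoms))
  if (length(missing)) {
    stop("atom table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  atoms <- as.data.frame(atoms)[required]
  atoms$serial <- as.integer(atoms$serial)
  atoms$resid <- as.integer(atoms$resid)
  for (col in c("name", "element", "resname", "chain")) {
    atoms[[col]] <- as.character(atoms[[col]])
  }
  key <- paste(atoms$chain, atoms$resid, atoms$name)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (chain, resid, name) atom key: ", dup, call. = FALSE)
  }
  chains <- lapply(split(atoms$resid, atoms$chain), range)
  structure(list(atoms = atoms, chains = chains, n_atoms = nrow(atoms)),
            class = "Topology")
}

#' @export
print.Topology <- function(x, ...) {
  cat("Topology:", x$n_atoms, "atoms,", length(x$chains), "chain(s) [",
      paste(names(x$chains), collapse = " "), "]\n")
  invisible(x)
}

n_atoms <- function(top) top$n_atoms

#' Build a trajectory from a topology and a coordinate array
#'
#' @param topology a [Topology].
#' @param coords numeric array `n_frames x n_atoms x 3`, Angstrom.
#' @param times per-frame time in ns, strictly increasing. Default
#'   `0, 1, ...` ns.
#' @param box optional per-frame orthorhombic box lengths: length-3 vector
#'   (constant box) or `n_frames x 3` matrix, Angstrom. `NULL` disables
#'   minimum-image treatment.
#' @return An object of class `Trajectory`.
#' @export
trajectory <- function(topology, coords, times = NULL, box = NULL) {
  stopifnot(inherits(topology, "Topology"))
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    stop("coords must be an n_frames x n_atoms x 3 array", call. = FALSE)
  }
  nf <- dim(coords)[1]
  if (nf < 1) stop("trajectory needs at least one frame", call. = FALSE)
  if (dim(coords)[2] != topology$n_atoms) {
    stop("frame atom count (", dim(coords)[2],
         ") does not match topology (", topology$n_atoms, ")", call. = FALSE)
  }
  if (!all(is.finite(coords))) stop("non-finite coordinates", call. = FALSE)
  if (is.null(times)) times <- as.numeric(seq_len(nf) - 1)
  if (length(times) != nf || any(diff(times) <= 0)) {
    stop("times must be strictly increasing, one per frame", call. = FALSE)
  }
  if (!is.null(box)) {
    if (is.null(dim(box))) box <- matrix(box, nf, 3, byrow = TRUE)
    stopifnot(nrow(box) == nf, ncol(box) == 3)
  }
  structure(list(topology = topology, coords = coords,
                 times = as.numeric(times), box = box),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", dim(x$coords)[1], "frames x", x$topology$n_atoms,
      "atoms,", sprintf("%.4g-%.4g ns", min(x$times), max(x$times)),
      if (is.null(x$box)) "(no box)" else "(orthorhombic box)", "\n")
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]

frame_coords <- function(traj, frame) traj$coords[frame, , , drop = TRUE]

frame_box <- function(traj, frame) {
  if (is.null(traj$box)) NULL else traj$box[frame, ]
}

#' Analysis time windows
#'
#' A half-open `[start_ns, end_ns)` interval selecting trajectory frames by
#' time. `last_window()` builds the presets used throughout the package
#' ("last 150 ns" for conduction counting and correlation analysis,
#' "last 250 ns" for distance histograms, "last 5 ns" for replicate gate
#' statistics), anchored at the final frame of a given trajectory.
#'
#' @param start_ns,end_ns window bounds in ns, `0 <= start < end`.
#' @return An `AnalysisWindow` object.
#' @export
analysis_window <- function(start_ns, end_ns) {
  if (!(start_ns >= 0 && start_ns < end_ns)) {
    stop("window requires 0 <= start_ns < end_ns", call. = FALSE)
  }
  structure(list(start_ns = start_ns, end_ns = end_ns),
            class = "AnalysisWindow")
}

#' @param traj a [Trajectory].
#' @param duration_ns window length counted back from the final frame time.
#' @rdname analysis_window
#' @export
last_window <- function(traj, duration_ns) {
  tmax <- max(traj$times)
  eps <- max(1e-9, 1e-9 * abs(tmax))
  analysis_window(max(0, tmax - duration_ns), tmax + eps)
}

#' Frame indices of a trajectory falling inside a window
#'
#' @inheritParams last_window
#' @param window an [analysis_window()], or `NULL` for all frames.
#' @return Integer frame indices with `start_ns <= t < end_ns`.
#' @export
window_frames <- function(traj, window = NULL) {
  if (is.null(window)) return(seq_len(n_frames(traj)))
  idx <- which(traj$times >= window$start_ns & traj$times < window$end_ns)
  if (!length(idx)) stop("analysis window selects no frames", call. = FALSE)
  idx
}
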