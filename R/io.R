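#' Read a structure file
#'
#' PDB files are parsed with \pkg{bio3d}; the plain-text `fixture-text`
#' structure format is one header line `natoms`, then one line per atom:
#' `serial name element resname resid chain x y z` (whitespace separated,
#' coordinates in Angstrom). Both formats return the topology plus the
#' first-frame coordinates.
#'
#' @param path file to read.
#' @param format `"pdb"` or `"fixture-text"`; default guessed from the file
#'   extension (`.pdb` vs anything else).
#' @return list with elements `topology` ([Topology]) and `coords`
#'   (`n_atoms x 3` matrix, Angstrom).
#' @export
read_structure <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  format <- format %||% if (grepl("\\.pdb$", path, ignore.case = TRUE))
    "pdb" else "fixture-text"
  format <- match.arg(format, c("pdb", "fixture-text"))
  if (format == "pdb") read_structure_pdb(path) else read_structure_text(path)
}

read_structure_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- substr(gsub("[0-9]", "", at$elety), 1, 1)
  }
  top <- topology(data.frame(
    serial = at$eleno, name = at$elety, element = elem,
    resname = at$resid, resid = at$resno,
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    stringsAsFactors = FALSE))
  list(topology = top, coords = cbind(at$x, at$y, at$z))
}

read_structure_text <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty structure file: ", path, call. = FALSE)
  natoms <- suppressWarnings(as.integer(strsplit(trimws(lines[1]),
                                                 "\\s+")[[1]][1]))
  if (is.na(natoms)) {
    stop("format error at line 1 of ", path, ": expected atom count",
         call. = FALSE)
  }
  if (length(lines) < natoms + 1) {
    stop("format error: ", path, " declares ", natoms, " atoms but has ",
         length(lines) - 1, " atom lines", call. = FALSE)
  }
  rows <- vector("list", natoms)
  for (i in seq_len(natoms)) {
    tok <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    if (length(tok) != 9) {
      stop("format error at line ", i + 1, " of ", path,
           ": expected 9 fields, got ", length(tok), call. = FALSE)
    }
    xyz <- suppressWarnings(as.numeric(tok[7:9]))
    if (any(is.na(xyz))) {
      stop("format error at line ", i + 1, " of ", path,
           ": non-numeric coordinates", call. = FALSE)
    }
    rows[[i]] <- data.frame(serial = as.integer(tok[1]), name = tok[2],
                            element = tok[3], resname = tok[4],
                            resid = as.integer(tok[5]), chain = tok[6],
                            x = xyz[1], y = xyz[2], z = xyz[3],
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  list(topology = topology(tab[1:6]),
       coords = as.matrix(tab[c("x", "y", "z")]))
}

#' Write a structure file
#'
#' Inverse of [read_structure()]; PDB output goes through
#' [bio3d::write.pdb()] (3-decimal coordinates), `fixture-text` is written
#' exactly as documented there with full double precision.
#'
#' @param top a [Topology].
#' @param coords `n_atoms x 3` coordinate matrix, Angstrom.
#' @param path output file.
#' @param format `"pdb"` or `"fixture-text"` (default from extension).
#' @export
write_structure <- function(top, coords, path, format = NULL) {
  stopifnot(inherits(top, "Topology"), nrow(coords) == top$n_atoms)
  format <- format %||% if (grepl("\\.pdb$", path, ignore.case = TRUE))
    "pdb" else "fixture-text"
  format <- match.arg(format, c("pdb", "fixture-text"))
  at <- top$atoms
  if (format == "pdb") {
    bio3d::write.pdb(file = path, xyz = as.numeric(t(coords)),
                     resno = at$resid, resid = at$resname,
                     eleno = at$serial, elety = at$name, chain = at$chain,
                     elesy = at$element)
  } else {
    lines <- c(as.character(top$n_atoms),
               sprintf("%d %s %s %s %d %s %.10g %.10g %.10g",
                       at$serial, at$name, at$element, at$resname, at$resid,
                       at$chain, coords[, 1], coords[, 2], coords[, 3]))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a coordinate trajectory
#'
#' DCD files are read with [bio3d::read.dcd()]. The plain-text fixture
#' format is: a header line `natoms nframes [dt_ns [bx by bz]]`, then for
#' each frame one `x y z` line per atom (Angstrom). A header without box
#' lengths yields a box-free trajectory (minimum-image imaging disabled).
#' XTC is not supported (no installed reader); convert to DCD or the text
#' format first.
#'
#' @param path trajectory file.
#' @param top the matching [Topology].
#' @param format `"dcd"` or `"fixture-text"` (default from extension;
#'   `.xtc` raises an unsupported-format error).
#' @param dt_ns frame spacing used when the file itself carries no times.
#' @param box optional box override, as in [trajectory()].
#' @return A [Trajectory].
#' @export
read_trajectory <- function(path, top, format = NULL, dt_ns = 1, box = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd"
    else if (grepl("\\.xtc$", path, ignore.case = TRUE)) "xtc"
    else "fixture-text"
  }
  if (format == "xtc") {
    stop("unsupported trajectory format 'xtc': convert to DCD or the ",
         "plain-text fixture format", call. = FALSE)
  }
  format <- match.arg(format, c("dcd", "fixture-text"))
  if (format == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    nf <- nrow(xyz)
    coords <- array(0, c(nf, top$n_atoms, 3))
    for (f in seq_len(nf)) {
      coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    }
    return(trajectory(top, coords, times = (seq_len(nf) - 1) * dt_ns,
                      box = box))
  }
  read_trajectory_text(path, top, dt_ns = dt_ns, box = box)
}

read_trajectory_text <- function(path, top, dt_ns = 1, box = NULL) {
  lines <- readLines(path)
  head_tok <- suppressWarnings(as.numeric(strsplit(trimws(lines[1]),
                                                   "\\s+")[[1]]))
  if (length(head_tok) < 2 || any(is.na(head_tok[1:2]))) {
    stop("format error at line 1 of ", path,
         ": expected 'natoms nframes [dt_ns [bx by bz]]'", call. = FALSE)
  }
  na <- as.integer(head_tok[1])
  nf <- as.integer(head_tok[2])
  if (na != top$n_atoms) {
    stop("trajectory declares ", na, " atoms; topology has ", top$n_atoms,
         call. = FALSE)
  }
  if (length(head_tok) >= 3) dt_ns <- head_tok[3]
  if (length(head_tok) >= 6 && is.null(box)) box <- head_tok[4:6]
  need <- na * nf
  if (length(lines) < need + 1) {
    stop("format error: ", path, " declares ", nf, " frames x ", na,
         " atoms but has ", length(lines) - 1, " coordinate lines",
         call. = FALSE)
  }
  vals <- suppressWarnings(
    as.numeric(unlist(strsplit(trimws(lines[2:(need + 1)]), "\\s+"))))
  if (length(vals) != 3 * need || any(is.na(vals))) {
    bad <- which(is.na(suppressWarnings(as.numeric(
      unlist(strsplit(trimws(lines[2:(need + 1)]), "\\s+"))))))[1]
    stop("format error in ", path, " near coordinate line ",
         if (is.na(bad)) "?" else ceiling(bad / 3) + 1,
         ": expected 3 numeric fields per line", call. = FALSE)
  }
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  coords <- array(0, c(nf, na, 3))
  for (f in seq_len(nf)) coords[f, , ] <- m[((f - 1) * na + 1):(f * na), ]
  trajectory(top, coords, times = (seq_len(nf) - 1) * dt_ns, box = box)
}

#' Write the plain-text fixture trajectory format
#'
#' @param traj a [Trajectory].
#' @param path output file.
#' @export
write_trajectory_text <- function(traj, path) {
  nf <- n_frames(traj)
  na <- traj$topology$n_atoms
  dt <- if (nf > 1) traj$times[2] - traj$times[1] else 1
  header <- if (is.null(traj$box)) {
    sprintf("%d %d %.10g", na, nf, dt)
  } else {
    sprintf("%d %d %.10g %.10g %.10g %.10g", na, nf, dt,
            traj$box[1, 1], traj$box[1, 2], traj$box[1, 3])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  for (f in seq_len(nf)) {
    m <- traj$coords[f, , , drop = FALSE]
    writeLines(sprintf("%.10g %.10g %.10g", m[1, , 1], m[1, , 2], m[1, , 3]),
               con)
  }
  invisible(path)
}
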