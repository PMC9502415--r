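## Independent brute-force oracles and small fixture builders. Everything
## here is deliberately naive and coded separately from the package
## internals it checks.

## Name-based selection shorthand for tests.
select_atoms_for_test <- function(top, name) {
  resolve_selection(top, expression = paste0("name:", name))
}

## Random topology of n atoms spread over chains/residues/names.
random_topology <- function(n, seed = 1, chains = c("A", "B"),
                            names = c("N", "CA", "C", "O", "CB", "CZ",
                                      "NZ")) {
  combos <- expand.grid(name = names, resid = 1:40, chain = chains,
                        stringsAsFactors = FALSE)
  stopifnot(n <= nrow(combos))
  withr::with_seed(seed, {
    pick <- combos[sample.int(nrow(combos), n), ]
    topology(data.frame(
      serial = seq_len(n), name = pick$name, element = "C",
      resname = "ALA", resid = pick$resid, chain = pick$chain,
      stringsAsFactors = FALSE))
  })
}

random_coords <- function(n_frames, n_atoms, seed = 1, scale = 20) {
  withr::with_seed(seed, {
    array(stats::runif(n_frames * n_atoms * 3, -scale, scale),
          c(n_frames, n_atoms, 3))
  })
}

## One-frame trajectory around an atom table with explicit coordinates.
frame_trajectory <- function(atoms, xyz, box = NULL, n_frames = 1) {
  top <- topology(atoms)
  coords <- array(0, c(n_frames, nrow(xyz), 3))
  for (f in seq_len(n_frames)) coords[f, , ] <- xyz
  trajectory(top, coords, box = box)
}

## A four-chain, single-gate-residue channel frame: one sidechain atom per
## chain at the given positions (rows = chains A..D).
square_gate_trajectory <- function(positions, resname = "PHE",
                                   atom = "CZ") {
  chains <- c("A", "B", "C", "D")
  resid <- c(181L, 192L, 181L, 192L)
  atoms <- data.frame(serial = 1:4, name = atom, element = "C",
                      resname = resname, resid = resid, chain = chains,
                      stringsAsFactors = FALSE)
  frame_trajectory(atoms, positions)
}

## Independent conduction state machine on one ion track.
bf_conduction_count <- function(z, r, z_hi, z_lo, delta, pore_radius) {
  st <- "NEUTRAL"
  count <- 0
  for (f in seq_along(z)) {
    if (z[f] > z_hi + delta) {
      st <- "ABOVE"
    } else if (z[f] < z_lo - delta) {
      if (st == "IN_FROM_ABOVE") count <- count + 1
      st <- "BELOW"
    } else if (z[f] <= z_hi && z[f] >= z_lo && r[f] <= pore_radius) {
      if (st == "ABOVE") st <- "IN_FROM_ABOVE"
      if (st == "BELOW") st <- "IN_FROM_BELOW"
    } else if (st %in% c("IN_FROM_ABOVE", "IN_FROM_BELOW") &&
               r[f] > pore_radius) {
      st <- "NEUTRAL"
    }
  }
  count
}

## Exhaustive simple-path enumeration sorted by (weight, lexicographic
## node sequence); nodes are integer indices into the weight matrix.
bf_all_simple_paths <- function(W, src, dst) {
  paths <- list()
  wts <- numeric()
  rec <- function(path, wt) {
    u <- path[length(path)]
    if (u == dst) {
      paths[[length(paths) + 1]] <<- path
      wts[length(wts) + 1] <<- wt
      return()
    }
    for (v in which(is.finite(W[u, ]))) {
      if (!(v %in% path)) rec(c(path, v), wt + W[u, v])
    }
  }
  rec(src, 0)
  key <- vapply(paths, function(p) paste(sprintf("%04d", p),
                                         collapse = ","), "")
  ord <- order(wts, key)
  list(paths = paths[ord], weights = wts[ord])
}

## Random thresholded correlation network over n nodes (zero-padded node
## names so lexicographic and numeric orders agree).
random_network <- function(n, seed, p_edge = 0.5) {
  withr::with_seed(seed, {
    cm <- diag(n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (stats::runif(1) < p_edge) {
          cm[i, j] <- cm[j, i] <- stats::runif(1, 0.15, 0.99)
        }
      }
    }
    rownames(cm) <- colnames(cm) <- sprintf("%04d", seq_len(n))
    build_residue_network(cm, cutoff = 0.1)
  })
}

## Apply a rigid rotation + translation to every frame of a trajectory.
rigid_transform <- function(traj, axis = c(1, 2, 3), theta = 35,
                            shift = c(5, -3, 8)) {
  R <- poregate:::rotation_matrix(axis, theta)
  out <- traj
  for (f in seq_len(dim(traj$coords)[1])) {
    out$coords[f, , ] <- sweep(traj$coords[f, , ] %*% t(R), 2, shift, "+")
  }
  out
}

## Closed-form one-way ANOVA from sums of squares.
bf_anova_F <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1
  dfw <- length(all_v) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}
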