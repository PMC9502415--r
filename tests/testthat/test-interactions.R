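bridge_fixture <- function(dist_a) {
  atoms <- data.frame(serial = 1:2, name = c("NZ", "P2"),
                      element = c("N", "P"), resname = c("LYS", "PIP"),
                      resid = c(183L, 501L), chain = c("A", "L"),
                      stringsAsFactors = FALSE)
  frame_trajectory(atoms, rbind(c(0, 0, 0), c(dist_a, 0, 0)))
}

test_that("salt-bridge engagement flips exactly at the 4.0 A cutoff", {
  for (case in list(list(d = 3.9, want = 1), list(d = 4.1, want = 0))) {
    traj <- bridge_fixture(case$d)
    spec <- salt_bridge_spec(select_atoms_for_test(traj$topology, "NZ"),
                             select_atoms_for_test(traj$topology, "P2"))
    expect_equal(salt_bridge_series(traj, spec)$values, case$want)
  }
  expect_error(salt_bridge_spec(
    resolve_selection(bridge_fixture(3)$topology, expression = "name:XX"),
    select_atoms_for_test(bridge_fixture(3)$topology, "P2")), "non-empty")
})

test_that("per-frame engaged counts equal the exhaustive pairwise oracle", {
  n_basic <- 12; n_acc <- 32; nf <- 5
  atoms <- rbind(
    data.frame(serial = 1:n_basic, name = "NZ", element = "N",
               resname = "LYS", resid = seq_len(n_basic), chain = "A"),
    data.frame(serial = n_basic + (1:n_acc),
               name = rep(c("O11", "O12", "O13", "O14", "O15", "O16", "P2",
                            "P3"), 4),
               element = "O", resname = "PIP",
               resid = rep(500 + 1:4, each = 8), chain = "L"))
  top <- topology(atoms)
  coords <- random_coords(nf, nrow(atoms), seed = 23, scale = 8)
  traj <- trajectory(top, coords)
  spec <- salt_bridge_spec(
    select_atoms_for_test(top, "NZ"),
    resolve_selection(top, expression = "resname:PIP"))
  got <- salt_bridge_series(traj, spec)$values
  want <- vapply(seq_len(nf), function(f) {
    engaged <- 0
    for (b in 1:n_basic) {
      dmin <- Inf
      for (a in (n_basic + 1):nrow(atoms)) {
        dmin <- min(dmin, sqrt(sum((coords[f, b, ] - coords[f, a, ])^2)))
      }
      if (dmin <= 4.0) engaged <- engaged + 1
    }
    engaged
  }, numeric(1))
  expect_equal(got, want)
})

test_that("normalized formation is bounded and self-fold is exactly 1", {
  sim <- simulate_bridge_engagement(400, 0.55, n_pairs = 3, seed = 12)
  spec <- salt_bridge_spec(
    select_atoms_for_test(sim$trajectory$topology, "NZ"),
    select_atoms_for_test(sim$trajectory$topology, "P2"))
  series <- salt_bridge_series(sim$trajectory, spec)
  nb <- normalized_salt_bridge(series, n_candidates = 3)
  expect_gte(nb$normalized, 0)
  expect_lte(nb$normalized, 1)
  self <- normalized_salt_bridge(series, 3, reference = nb$normalized)
  expect_identical(self$fold_change, 1)
  expect_error(normalized_salt_bridge(series, 3, reference = 0),
               "positive")
})

test_that("programmed engagement shifts reproduce the reported fold changes", {
  ref <- 0.5
  up <- simulate_bridge_engagement(10000, 0.6, n_pairs = 3, seed = 101)
  down <- simulate_bridge_engagement(10000, 0.4, n_pairs = 3, seed = 102)
  fold_of <- function(sim) {
    spec <- salt_bridge_spec(
      select_atoms_for_test(sim$trajectory$topology, "NZ"),
      select_atoms_for_test(sim$trajectory$topology, "P2"))
    normalized_salt_bridge(salt_bridge_series(sim$trajectory, spec), 3,
                           reference = ref)$fold_change
  }
  expect_equal(fold_of(up), 1.2, tolerance = 0.03 / 1.2)
  expect_equal(fold_of(down), 0.8, tolerance = 0.03 / 0.8)
})

test_that("contact totals match an exhaustive double loop and rigid motion", {
  na <- 50; nb <- 60
  atoms <- rbind(
    data.frame(serial = 1:na, name = "CB", element = "C", resname = "ALA",
               resid = 1:na, chain = "A"),
    data.frame(serial = na + (1:nb), name = "CB", element = "C",
               resname = "ALA", resid = 1:nb, chain = "B"))
  top <- topology(atoms)
  coords <- random_coords(3, na + nb, seed = 37, scale = 10)
  traj <- trajectory(top, coords)
  sa <- resolve_selection(top, expression = "chain:A")
  sb <- resolve_selection(top, expression = "chain:B")
  got <- intersegment_contact_series(traj, sa, sb, cutoff = 4.0)$values
  want <- vapply(1:3, function(f) {
    n <- 0
    for (i in 1:na) for (j in (na + 1):(na + nb)) {
      if (sqrt(sum((coords[f, i, ] - coords[f, j, ])^2)) <= 4.0) n <- n + 1
    }
    n
  }, numeric(1))
  expect_equal(got, want)
  rot <- rigid_transform(traj)
  expect_equal(intersegment_contact_series(rot, sa, sb, 4.0)$values, want)
  expect_error(intersegment_contact_series(traj, sa, sa, 4.0), "disjoint")
})

test_that("two atoms at 3.9 vs 4.1 A give one vs zero contacts", {
  traj <- bridge_fixture(3.9)
  sa <- resolve_selection(traj$topology, expression = "chain:A")
  sb <- resolve_selection(traj$topology, expression = "chain:L")
  expect_equal(intersegment_contact_series(traj, sa, sb, 4.0)$values, 1)
  traj2 <- bridge_fixture(4.1)
  expect_equal(intersegment_contact_series(traj2,
    resolve_selection(traj2$topology, expression = "chain:A"),
    resolve_selection(traj2$topology, expression = "chain:L"),
    4.0)$values, 0)
})

test_that("engaged fraction is monotone nondecreasing in the cutoff", {
  sim <- simulate_bridge_engagement(300, 0.5, n_pairs = 4, seed = 3)
  spec_at <- function(cut) salt_bridge_spec(
    select_atoms_for_test(sim$trajectory$topology, "NZ"),
    select_atoms_for_test(sim$trajectory$topology, "P2"), cutoff = cut)
  means <- vapply(c(2, 3.6, 4, 5.9, 6.1), function(cut) {
    mean(salt_bridge_series(sim$trajectory, spec_at(cut))$values)
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("minimum-image distances are correct across the box boundary", {
  traj <- bridge_fixture(38)
  traj$box <- matrix(c(40, 40, 40), 1, 3)
  spec <- salt_bridge_spec(select_atoms_for_test(traj$topology, "NZ"),
                           select_atoms_for_test(traj$topology, "P2"))
  expect_equal(salt_bridge_series(traj, spec)$values, 1)  # image at 2 A
  sa <- resolve_selection(traj$topology, expression = "chain:A")
  sb <- resolve_selection(traj$topology, expression = "chain:L")
  expect_equal(intersegment_contact_series(traj, sa, sb, 3.0)$values, 1)
})

phenyl_ring <- function(center, chain, resid) {
  ## regular hexagon of ring atoms in the xy plane plus CB/CA stubs
  names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  ang <- seq(0, 300, by = 60) * pi / 180
  xyz <- cbind(center[1] + 1.39 * cos(ang), center[2] + 1.39 * sin(ang),
               center[3])
  atoms <- data.frame(serial = 0, name = names, element = "C",
                      resname = "PHE", resid = resid, chain = chain,
                      stringsAsFactors = FALSE)
  list(atoms = atoms, xyz = xyz)
}

test_that("pi-stacking distance is the ring-centroid separation", {
  r1 <- phenyl_ring(c(0, 0, 0), "A", 137L)
  r2 <- phenyl_ring(c(0, 0, 3.5), "A", 87L)
  atoms <- rbind(r1$atoms, r2$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  traj <- frame_trajectory(atoms, rbind(r1$xyz, r2$xyz))
  res <- pair_distance_distribution(
    traj, list(list(chain = "A", resid = 137), list(chain = "A", resid = 87)),
    class = "pi_pi")
  expect_equal(res$series$values, 3.5, tolerance = 1e-9)
  expect_equal(res$engaged_fraction, 1)
  expect_equal(res$cutoff, 4.0)
})

test_that("distant dipole partners are disengaged beyond 4 A", {
  atoms <- data.frame(serial = 1:2, name = c("NE1", "OE1"),
                      element = c("N", "O"), resname = c("TRP", "GLU"),
                      resid = c(95L, 141L), chain = "A",
                      stringsAsFactors = FALSE)
  traj <- frame_trajectory(atoms, rbind(c(0, 0, 0), c(6.5, 0, 0)))
  res <- pair_distance_distribution(
    traj, list(list(chain = "A", resid = 95), list(chain = "A", resid = 141)),
    class = "dipole_hbond")
  expect_equal(res$series$values, 6.5)
  expect_equal(res$engaged_fraction, 0)
})

test_that("pi-stacking on a non-aromatic residue is rejected", {
  atoms <- data.frame(serial = 1:2, name = c("CB", "CB"), element = "C",
                      resname = "ALA", resid = c(1L, 2L), chain = "A",
                      stringsAsFactors = FALSE)
  traj <- frame_trajectory(atoms, rbind(c(0, 0, 0), c(4, 0, 0)))
  expect_error(pair_distance_distribution(
    traj, list(list(chain = "A", resid = 1), list(chain = "A", resid = 2)),
    class = "pi_pi"), "non-aromatic")
})

test_that("distance histograms match a per-frame binning oracle", {
  nf <- 60
  withr::with_seed(71, {
    d <- stats::runif(nf, 2, 9)
  })
  atoms <- data.frame(serial = 1:2, name = c("CB", "CG"), element = "C",
                      resname = c("VAL", "LEU"), resid = c(1L, 2L),
                      chain = "A", stringsAsFactors = FALSE)
  coords <- array(0, c(nf, 2, 3))
  coords[, 2, 1] <- d
  traj <- trajectory(topology(atoms), coords)
  res <- pair_distance_distribution(
    traj, list(list(chain = "A", resid = 1), list(chain = "A", resid = 2)),
    class = "vdw")
  edges <- res$histogram$edges
  want <- integer(length(edges) - 1)
  for (v in d) {
    k <- max(which(edges <= v))
    want[k] <- want[k] + 1
  }
  expect_equal(res$histogram$counts, want)
  expect_equal(sum(res$histogram$counts), res$histogram$n)
  expect_equal(res$engaged_fraction, mean(d <= 3.0))
})

test_that("the VdW cutoff derives from doubling the smallest radius", {
  expect_equal(vdw_cutoff_from_radius(1.5), 3.0)
  classes <- interaction_classes()
  expect_equal(classes$cutoff[classes$class == "vdw"], 3.0)
  expect_equal(classes$cutoff[classes$class == "pi_pi"], 4.0)
  expect_equal(nrow(classes), 4)
  expect_false(anyDuplicated(classes$class) > 0)
})
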