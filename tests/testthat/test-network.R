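test_that("self-correlation is exactly 1 and matrices are well-formed", {
  w <- simulate_correlated_walk(corr_walk_spec(5, diag(5), 200, seed = 3))
  cij <- compute_dccm(w, superpose = FALSE)
  m <- unclass(cij)
  expect_equal(diag(m), setNames(rep(1, 5), rownames(m)))
  expect_lt(max(abs(m - t(m))), 1e-10)
  expect_lte(max(abs(m)), 1 + 1e-10)
})

test_that("identical and mirrored motion force c = +1 and -1", {
  atoms <- data.frame(serial = 1:2, name = "CA", element = "C",
                      resname = "ALA", resid = 1:2, chain = "A",
                      stringsAsFactors = FALSE)
  nf <- 50
  withr::with_seed(8, {
    disp <- matrix(stats::rnorm(nf * 3), nf, 3)
  })
  coords <- array(0, c(nf, 2, 3))
  coords[, 1, ] <- disp
  coords[, 2, ] <- sweep(disp, 2, c(10, 0, 0), "+")
  traj <- trajectory(topology(atoms), coords)
  expect_equal(unclass(compute_dccm(traj, superpose = FALSE))[1, 2], 1)
  coords[, 2, ] <- sweep(-disp, 2, c(10, 0, 0), "+")
  traj2 <- trajectory(topology(atoms), coords)
  expect_equal(unclass(compute_dccm(traj2, superpose = FALSE))[1, 2], -1)
})

test_that("DCCM matches the established reference implementation", {
  w <- simulate_correlated_walk(corr_walk_spec(
    6, {
      m <- diag(6); m[1, 4] <- m[4, 1] <- 0.6; m[2, 3] <- m[3, 2] <- -0.3
      m
    }, 400, seed = 17))
  own <- unclass(compute_dccm(w, superpose = FALSE))
  xyz <- matrix(aperm(w$coords, c(1, 3, 2)), dim(w$coords)[1],
                3 * dim(w$coords)[2])
  ## bio3d expects frames x (x1 y1 z1 x2 ...) layout
  xyz <- do.call(cbind, lapply(seq_len(dim(w$coords)[2]), function(i) {
    w$coords[, i, ]
  }))
  ref <- bio3d::dccm.xyz(xyz)
  expect_equal(own, unclass(ref), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("superposition removes rigid-body motion before correlating", {
  ## internally static pair tumbling rigidly: raw correlation is +1,
  ## superposed correlations collapse (zero internal variance -> error)
  atoms <- data.frame(serial = 1:3, name = "CA", element = "C",
                      resname = "ALA", resid = 1:3, chain = "A",
                      stringsAsFactors = FALSE)
  base <- rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0))
  nf <- 30
  coords <- array(0, c(nf, 3, 3))
  withr::with_seed(9, {
    for (f in 1:nf) {
      R <- poregate:::rotation_matrix(stats::rnorm(3), stats::runif(1, 0, 40))
      coords[f, , ] <- sweep(base %*% t(R), 2, stats::rnorm(3, sd = 2), "+")
    }
  })
  traj <- trajectory(topology(atoms), coords)
  expect_error(compute_dccm(traj, superpose = TRUE), "zero-variance")
  raw <- compute_dccm(traj, superpose = FALSE)
  expect_gt(unclass(raw)[1, 2], 0.2)  # apparent coupling from tumbling
})

test_that("network edges equal a brute-force threshold scan", {
  withr::with_seed(29, {
    n <- 10
    cm <- diag(n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      cm[i, j] <- cm[j, i] <- stats::runif(1, -1, 1)
    }
    rownames(cm) <- colnames(cm) <- paste0("A:", 1:n)
  })
  net <- build_residue_network(cm, cutoff = 0.4)
  want <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (abs(cm[i, j]) >= 0.4) {
      want <- want + 1
      row <- net$edges[net$edges$node_i == paste0("A:", i) &
                         net$edges$node_j == paste0("A:", j), ]
      expect_equal(nrow(row), 1)
      expect_equal(row$weight, -log(abs(cm[i, j])))
    }
  }
  expect_equal(nrow(net$edges), want)
  expect_true(all(net$edges$weight >= 0))
  expect_false(any(net$edges$node_i == net$edges$node_j))
})

test_that("thresholds behave at the boundaries", {
  cm <- diag(2)
  cm[1, 2] <- cm[2, 1] <- 0.39
  rownames(cm) <- colnames(cm) <- c("a", "b")
  expect_equal(nrow(build_residue_network(cm, 0.4)$edges), 0)
  cm[1, 2] <- cm[2, 1] <- 1.0
  net <- build_residue_network(cm, 0.4)
  expect_equal(net$edges$weight, 0)
  expect_error(build_residue_network(cm, 0), "cutoff")
  expect_error(build_residue_network(cm, 1.2), "cutoff")
})

test_that("raising the cutoff never adds edges", {
  m <- diag(8)
  withr::with_seed(5, {
    for (i in 1:7) for (j in (i + 1):8) {
      m[i, j] <- m[j, i] <- stats::runif(1, 0.05, 0.99)
    }
  })
  rownames(m) <- colnames(m) <- sprintf("%04d", 1:8)
  sizes <- vapply(c(0.2, 0.4, 0.6, 0.8), function(cut) {
    nrow(build_residue_network(m, cutoff = cut)$edges)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("a unique path and exhausted cycles are handled", {
  cm <- diag(3)
  cm[1, 2] <- cm[2, 1] <- 0.9
  cm[2, 3] <- cm[3, 2] <- 0.8
  rownames(cm) <- colnames(cm) <- c("A", "B", "C")
  net <- build_residue_network(cm, 0.4)
  ens <- suboptimal_paths(net, "A", "C", k = 10)
  expect_equal(length(ens$paths), 1)
  expect_equal(ens$paths[[1]], c("A", "B", "C"))
  expect_equal(ens$weights, -log(0.9) - log(0.8))

  ## 4-cycle: exactly two simple paths between opposite corners
  cm4 <- diag(4)
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))) {
    cm4[e[1], e[2]] <- cm4[e[2], e[1]] <- 0.7
  }
  rownames(cm4) <- colnames(cm4) <- c("n1", "n2", "n3", "n4")
  net4 <- build_residue_network(cm4, 0.4)
  ens4 <- suboptimal_paths(net4, "n1", "n3", k = 250)
  expect_equal(length(ens4$paths), 2)
  expect_true(all(diff(ens4$weights) >= 0))

  ## disconnected source/sink
  cm0 <- diag(4)
  cm0[1, 2] <- cm0[2, 1] <- 0.9
  cm0[3, 4] <- cm0[4, 3] <- 0.9
  rownames(cm0) <- colnames(cm0) <- c("a", "b", "c", "d")
  expect_error(suboptimal_paths(build_residue_network(cm0, 0.4), "a", "d"),
               "no path")
})

test_that("path ensembles equal exhaustive enumeration on small graphs", {
  for (s in 1:10) {
    net <- random_network(sample(4:8, 1, prob = rep(0.2, 5)), seed = 100 + s)
    W <- poregate:::network_weight_matrix(net)
    n <- length(net$nodes)
    oracle <- bf_all_simple_paths(W, 1, n)
    if (!length(oracle$paths)) {
      expect_error(suboptimal_paths(net, net$nodes[1], net$nodes[n], 10),
                   "no path")
      next
    }
    k <- 15
    ens <- suboptimal_paths(net, net$nodes[1], net$nodes[n], k = k)
    kk <- min(k, length(oracle$paths))
    expect_equal(length(ens$paths), kk)
    expect_equal(ens$weights, oracle$weights[1:kk], tolerance = 1e-9)
    expect_identical(ens$paths,
                     lapply(oracle$paths[1:kk],
                            function(p) net$nodes[p]))
    expect_true(all(diff(ens$weights) >= -1e-12))
  }
})

test_that("the first path weight equals an independent shortest-path oracle", {
  skip_if_not_installed("igraph")
  for (s in 1:5) {
    net <- random_network(7, seed = 200 + s, p_edge = 0.7)
    g <- igraph::graph_from_data_frame(
      net$edges[c("node_i", "node_j")], directed = FALSE,
      vertices = net$nodes)
    d <- igraph::distances(g, v = net$nodes[1], to = net$nodes[7],
                           weights = net$edges$weight)[1, 1]
    if (!is.finite(d)) next
    ens <- suboptimal_paths(net, net$nodes[1], net$nodes[7], k = 1)
    expect_equal(ens$weights[1], d, tolerance = 1e-9)
  }
})

test_that("edge usage counts each edge once per containing path", {
  ens <- structure(list(
    paths = list(c("A", "B", "C"), c("A", "D", "B", "C")),
    weights = c(1, 2), source = "A", sink = "C", k = 2),
    class = "PathEnsemble")
  u <- edge_usage(ens)
  expect_equal(u$count[u$node_i == "B" & u$node_j == "C"], 2)
  expect_equal(u$count[u$node_i == "A" & u$node_j == "B"], 1)
  expect_true(all(u$count <= 2))

  empty <- structure(list(paths = list(), weights = numeric(),
                          source = "A", sink = "B", k = 0),
                     class = "PathEnsemble")
  expect_equal(nrow(edge_usage(empty)), 0)
})

test_that("edge usage matches a per-path counting oracle", {
  net <- random_network(7, seed = 301, p_edge = 0.8)
  ens <- suboptimal_paths(net, net$nodes[1], net$nodes[7], k = 30)
  u <- edge_usage(ens)
  bf <- new.env()
  for (p in ens$paths) {
    for (i in seq_len(length(p) - 1)) {
      key <- paste(sort(c(p[i], p[i + 1])), collapse = "|")
      bf[[key]] <- (if (is.null(bf[[key]])) 0 else bf[[key]]) + 1
    }
  }
  expect_equal(nrow(u), length(ls(bf)))
  for (r in seq_len(nrow(u))) {
    key <- paste(sort(c(u$node_i[r], u$node_j[r])), collapse = "|")
    expect_equal(u$count[r], bf[[key]])
  }
  expect_true(all(u$count <= length(ens$paths)))
})

test_that("degenerate DCCM inputs are rejected with the residue named", {
  atoms <- data.frame(serial = 1:2, name = "CA", element = "C",
                      resname = "ALA", resid = c(7L, 8L), chain = "A",
                      stringsAsFactors = FALSE)
  coords <- array(0, c(20, 2, 3))
  withr::with_seed(2, {
    coords[, 1, ] <- matrix(stats::rnorm(60), 20, 3)
  })
  coords[, 2, 1] <- 5  # atom 2 never moves
  traj <- trajectory(topology(atoms), coords)
  expect_error(compute_dccm(traj, superpose = FALSE), "A:8")
  short <- trajectory(topology(atoms), coords[1:5, , , drop = FALSE])
  expect_error(compute_dccm(short, superpose = FALSE), "10 frames")
})
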