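#' Dynamic cross-correlation matrix of C-alpha motion
#'
#' `cij = <dri . drj> / sqrt(<|dri|^2> <|drj|^2>)` where `dri` is the
#' deviation of residue i's C-alpha from its time-mean position, computed
#' over the window (conventionally the last 150 ns). By default the C-alpha
#' set is first superposed onto its running mean by iterative least-squares
#' fitting, removing rigid-body motion.
#'
#' @param traj a [Trajectory].
#' @param calpha a `Selection` of one atom per residue (>= 2 atoms); when
#'   `NULL`, all atoms named `CA` are used.
#' @param window an [analysis_window()] or `NULL` (>= 10 frames required).
#' @param superpose remove rigid-body motion before correlating (default
#'   TRUE).
#' @param max_iter,tol superposition iteration controls.
#' @return A `CorrelationMatrix`: symmetric matrix with unit diagonal and
#'   `|cij| <= 1`, dimnames `chain:resid`.
#' @export
compute_dccm <- function(traj, calpha = NULL, window = NULL,
                         superpose = TRUE, max_iter = 10, tol = 1e-7) {
  top <- traj$topology
  if (is.null(calpha)) calpha <- select_atoms(top, name = "CA")
  idx <- sel_indices(calpha)
  if (length(idx) < 2) {
    stop("DCCM needs at least 2 residues", call. = FALSE)
  }
  frames <- window_frames(traj, window)
  if (length(frames) < 10) {
    stop("DCCM needs at least 10 frames in the window", call. = FALSE)
  }
  n <- length(idx)
  nf <- length(frames)
  ## coords as a list of nf (n x 3) matrices
  M <- lapply(frames, function(f) {
    matrix(traj$coords[f, idx, ], n, 3)
  })
  if (superpose) {
    ref <- M[[1]]
    for (it in seq_len(max_iter)) {
      M <- lapply(M, kabsch_fit, Rf = ref)
      new_ref <- Reduce(`+`, M) / nf
      delta <- max(abs(new_ref - ref))
      ref <- new_ref
      if (delta < tol) break
    }
  }
  mean_pos <- Reduce(`+`, M) / nf
  dev <- lapply(M, function(X) X - mean_pos)
  cov_ij <- matrix(0, n, n)
  for (f in seq_len(nf)) {
    cov_ij <- cov_ij + tcrossprod(dev[[f]])
  }
  cov_ij <- cov_ij / nf
  v <- diag(cov_ij)
  if (any(v < 1e-12)) {
    at <- top$atoms[idx[which(v < 1e-12)[1]], ]
    stop("zero-variance residue in DCCM: ", at$chain, ":", at$resid,
         call. = FALSE)
  }
  cij <- cov_ij / sqrt(outer(v, v))
  cij <- (cij + t(cij)) / 2
  cij[cij > 1] <- 1
  cij[cij < -1] <- -1
  diag(cij) <- 1
  ids <- paste0(top$atoms$chain[idx], ":", top$atoms$resid[idx])
  dimnames(cij) <- list(ids, ids)
  class(cij) <- c("CorrelationMatrix", "matrix")
  cij
}

#' Threshold a correlation matrix into a residue network
#'
#' Undirected edges connect residue pairs with `|cij| >= cutoff` (default
#' 0.4); edge length is `-log(|cij|)`, so perfectly coupled residues are at
#' zero distance. Anticorrelation counts as coupling by default; set
#' `absolute = FALSE` to keep only positive correlations.
#'
#' @param dccm a [compute_dccm()] result (or any symmetric correlation
#'   matrix with dimnames).
#' @param cutoff threshold in `(0, 1]`.
#' @param absolute use `|cij|` for thresholding and weighting.
#' @return A `ResidueNetwork`: list with `nodes` and an edge table
#'   (`node_i`, `node_j`, `cij`, `weight`).
#' @export
build_residue_network <- function(dccm, cutoff = 0.4, absolute = TRUE) {
  if (!(is.numeric(cutoff) && cutoff > 0 && cutoff <= 1)) {
    stop("cutoff must be in (0, 1]", call. = FALSE)
  }
  m <- unclass(dccm)
  nodes <- rownames(m) %||% as.character(seq_len(nrow(m)))
  strength <- if (absolute) abs(m) else m
  keep <- which(upper.tri(m) & strength >= cutoff, arr.ind = TRUE)
  edges <- data.frame(
    node_i = nodes[keep[, 1]], node_j = nodes[keep[, 2]],
    cij = m[keep], weight = -log(strength[keep]),
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, cutoff = cutoff),
            class = "ResidueNetwork")
}

#' @export
print.ResidueNetwork <- function(x, ...) {
  cat("ResidueNetwork:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges (|cij| >=", x$cutoff, ")\n")
  invisible(x)
}

## Dense adjacency (weight) matrix from a ResidueNetwork; Inf = no edge.
network_weight_matrix <- function(net) {
  n <- length(net$nodes)
  W <- matrix(Inf, n, n, dimnames = list(net$nodes, net$nodes))
  i <- match(net$edges$node_i, net$nodes)
  j <- match(net$edges$node_j, net$nodes)
  W[cbind(i, j)] <- net$edges$weight
  W[cbind(j, i)] <- net$edges$weight
  W
}

## Lexicographic comparison of two integer node sequences; TRUE if a < b.
lex_less <- function(a, b) {
  k <- min(length(a), length(b))
  for (i in seq_len(k)) {
    if (a[i] != b[i]) return(a[i] < b[i])
  }
  length(a) < length(b)
}

## Dijkstra on a dense weight matrix with optional banned nodes/edges.
## banned_edges: 2-column matrix of directed (from, to) pairs.
dijkstra_path <- function(W, src, dst, banned_nodes = integer(),
                          banned_edges = NULL) {
  n <- nrow(W)
  dist <- rep(Inf, n)
  prev <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  done[banned_nodes] <- TRUE
  if (done[src] || done[dst]) return(NULL)
  dist[src] <- 0
  repeat {
    u <- which(!done & is.finite(dist))
    if (!length(u)) break
    u <- u[which.min(dist[u])]
    if (u == dst) break
    done[u] <- TRUE
    for (v in which(is.finite(W[u, ]))) {
      if (done[v]) next
      if (!is.null(banned_edges) &&
          any(banned_edges[, 1] == u & banned_edges[, 2] == v)) next
      alt <- dist[u] + W[u, v]
      if (alt < dist[v] - 1e-15) {
        dist[v] <- alt
        prev[v] <- u
      }
    }
  }
  if (!is.finite(dist[dst])) return(NULL)
  path <- dst
  while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
  if (path[1] != src) return(NULL)
  list(path = path, dist = dist[dst])
}

path_weight <- function(W, path) {
  sum(W[cbind(path[-length(path)], path[-1])])
}

#' k-shortest suboptimal paths through a residue network
#'
#' Yen's algorithm for the k lowest-total-weight distinct simple paths
#' between a source and sink residue, in nondecreasing weight order (ties
#' broken by lexicographic node order, so results are deterministic). The
#' first path is the optimal (shortest) path. Fewer than k paths are
#' returned when the graph has fewer simple paths.
#'
#' @param net a [build_residue_network()] result.
#' @param source,sink node ids (e.g. `"A:97"`); the ligand-site source role
#'   is GIRK1 F97.
#' @param k ensemble size; default 250.
#' @return A `PathEnsemble`: list with `paths` (character node sequences),
#'   `weights`, `source`, `sink`.
#' @export
suboptimal_paths <- function(net, source, sink, k = 250) {
  stopifnot(inherits(net, "ResidueNetwork"), k >= 1)
  W <- network_weight_matrix(net)
  src <- match(source, net$nodes)
  dst <- match(sink, net$nodes)
  if (is.na(src) || is.na(dst)) {
    stop("source or sink not in network: ", source, " / ", sink,
         call. = FALSE)
  }
  first <- dijkstra_path(W, src, dst)
  if (is.null(first)) {
    stop("no path between ", source, " and ", sink,
         " (disconnected components)", call. = FALSE)
  }
  A_paths <- list(first$path)
  A_wts <- first$dist
  B <- list()  # candidates keyed by path string
  repeat {
    if (length(A_paths) >= k) break
    prev_path <- A_paths[[length(A_paths)]]
    for (jj in seq_len(length(prev_path) - 1)) {
      spur <- prev_path[jj]
      root <- prev_path[seq_len(jj)]
      banned_edges <- NULL
      for (p in A_paths) {
        if (length(p) > jj && identical(p[seq_len(jj)], root)) {
          banned_edges <- rbind(banned_edges, c(p[jj], p[jj + 1]))
        }
      }
      banned_nodes <- setdiff(root, spur)
      sp <- dijkstra_path(W, spur, dst, banned_nodes, banned_edges)
      if (is.null(sp)) next
      total <- c(root[-length(root)], sp$path)
      key <- paste(total, collapse = ",")
      if (is.null(B[[key]]) &&
          !any(vapply(A_paths, identical, logical(1), y = total))) {
        B[[key]] <- list(path = total, weight = path_weight(W, total))
      }
    }
    if (!length(B)) break
    wts <- vapply(B, `[[`, numeric(1), "weight")
    best <- which(wts <= min(wts) + 1e-12)
    if (length(best) > 1) {
      cand <- lapply(B[best], `[[`, "path")
      ord <- 1
      for (m in seq_along(cand)[-1]) {
        if (lex_less(cand[[m]], cand[[ord]])) ord <- m
      }
      best <- best[ord]
    }
    A_paths[[length(A_paths) + 1]] <- B[[best]]$path
    A_wts <- c(A_wts, B[[best]]$weight)
    B[[best]] <- NULL
  }
  structure(list(paths = lapply(A_paths, function(p) net$nodes[p]),
                 weights = A_wts, source = source, sink = sink, k = k),
            class = "PathEnsemble")
}

#' @export
print.PathEnsemble <- function(x, ...) {
  cat("PathEnsemble:", length(x$paths), "paths", x$source, "->", x$sink,
      sprintf("(weights %.4g - %.4g)\n", min(x$weights), max(x$weights)))
  invisible(x)
}

#' Per-edge usage counts of a path ensemble
#'
#' Counts how many ensemble paths traverse each undirected edge - the
#' weighting used when drawing the ensemble as splines between residue
#' pairs.
#'
#' @param ensemble a [suboptimal_paths()] result.
#' @return data.frame with `node_i`, `node_j`, `count` (each edge counted
#'   once per path containing it), sorted by decreasing count.
#' @export
edge_usage <- function(ensemble) {
  stopifnot(inherits(ensemble, "PathEnsemble"))
  tab <- new.env(parent = emptyenv())
  for (p in ensemble$paths) {
    if (length(p) < 2) next
    for (s in seq_len(length(p) - 1)) {
      e <- sort(c(p[s], p[s + 1]))
      key <- paste(e, collapse = "|")
      tab[[key]] <- (tab[[key]] %||% 0) + 1
    }
  }
  keys <- ls(tab)
  if (!length(keys)) {
    return(data.frame(node_i = character(), node_j = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(keys, "|", fixed = TRUE)
  out <- data.frame(node_i = vapply(parts, `[`, "", 1),
                    node_j = vapply(parts, `[`, "", 2),
                    count = vapply(keys, function(k) tab[[k]], numeric(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(-out$count, out$node_i, out$node_j), ]
}
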