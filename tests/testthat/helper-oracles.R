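# Independent oracles used by the unit and acceptance tests. Everything
# here is deliberately brute-force and shares no code with the package's
# own algorithms.

IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"),
  `-` = c("A", "C", "G", "T"), `?` = c("A", "C", "G", "T")
)

# Exhaustive minimum-change count for one column on a rooted tree:
# enumerate every base assignment to the internal nodes; a leaf edge costs
# nothing iff the parent's state is a member of the leaf's allowed set.
brute_force_site_steps <- function(phy, col) {
  bases <- c("A", "C", "G", "T")
  nt <- length(phy$tip.label)
  n_int <- phy$Nnode
  leaf_sets <- IUPAC_ORACLE[toupper(col[phy$tip.label])]
  edges <- phy$edge
  best <- Inf
  idx <- rep(1L, n_int)
  repeat {
    assign_int <- bases[idx]
    changes <- 0L
    for (e in seq_len(nrow(edges))) {
      p_state <- assign_int[edges[e, 1] - nt]
      child <- edges[e, 2]
      if (child <= nt) {
        if (!(p_state %in% leaf_sets[[child]])) changes <- changes + 1L
      } else {
        if (p_state != assign_int[child - nt]) changes <- changes + 1L
      }
    }
    best <- min(best, changes)
    # next assignment (base-4 counter)
    j <- 1L
    while (j <= n_int) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= 4L) break
      idx[j] <- 1L
      j <- j + 1L
    }
    if (j > n_int) break
  }
  best
}

# Edge incidence of the path between two tips, found by BFS on the tree's
# edge list treated as an undirected graph.
path_edges <- function(phy, from, to) {
  edges <- phy$edge
  n_nodes <- max(edges)
  adj <- vector("list", n_nodes)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, e))
    adj[[b]] <- rbind(adj[[b]], c(a, e))
  }
  prev_edge <- rep(NA_integer_, n_nodes)
  prev_node <- rep(NA_integer_, n_nodes)
  visited <- rep(FALSE, n_nodes)
  queue <- from; visited[from] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v == to) break
    for (k in seq_len(NROW(adj[[v]]))) {
      w <- adj[[v]][k, 1]
      if (!visited[w]) {
        visited[w] <- TRUE
        prev_edge[w] <- adj[[v]][k, 2]
        prev_node[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  out <- integer(0)
  v <- to
  while (v != from) {
    out <- c(out, prev_edge[v])
    v <- prev_node[v]
  }
  out
}

# Least-squares topology oracle: enumerate every unrooted topology on the
# labels, fit branch lengths by ordinary least squares to the distance
# matrix, and return the topology (with fitted lengths) of the unique
# minimum-RSS fit.
ls_best_topology <- function(D) {
  labs <- rownames(D)
  cands <- phangorn::allTrees(length(labs), rooted = FALSE, tip.label = labs)
  pair_idx <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[upper.tri(D)]
  best <- NULL
  for (ci in seq_along(cands)) {
    tr <- cands[[ci]]  # [[ ]] restores tip labels from the multiPhylo store
    n_edges <- nrow(tr$edge)
    X <- matrix(0, length(d), n_edges)
    for (r in seq_len(nrow(pair_idx))) {
      i <- match(labs[pair_idx[r, 1]], tr$tip.label)
      j <- match(labs[pair_idx[r, 2]], tr$tip.label)
      X[r, path_edges(tr, i, j)] <- 1
    }
    fit <- stats::lm.fit(X, d)
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss) {
      tr$edge.length <- fit$coefficients
      best <- list(tree = tr, rss = rss)
    }
  }
  best
}

# Direct textbook Pearson product-moment formula.
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# Minimal hand-built trace object for testing the downstream analyses in
# isolation from the engine.
fake_trace <- function(hi, maxd = NULL, series = NULL, ci = NULL) {
  n_steps <- length(hi)
  if (is.null(maxd)) maxd <- seq(0.05, by = 0.05, length.out = n_steps)
  if (is.null(series)) series <- paste0("t", seq_len(n_steps + 3))
  if (is.null(ci)) ci <- 1 - hi
  steps <- tibble::tibble(
    step = seq_len(n_steps),
    added_taxon = series[-seq_len(3)],
    n_taxa = seq_len(n_steps) + 3L,
    disCen = maxd,
    MaxD = maxd,
    nj_S = NA_real_, nj_M = NA_real_, nj_G = NA_real_,
    nj_CI = ci, nj_RI = NA_real_, nj_HI = hi, nj_RCI = NA_real_,
    nj_SHI = ifelse(maxd == 0, 0, hi / maxd)
  )
  structure(list(center = series[1], series = series, steps = steps,
                 trees = list(), model = "F84", tree_methods = "nj",
                 distance_matrix = NULL),
            class = "homodist_trace")
}

# Homoplasy-free alignment with an exact, chosen number of derived sites
# per tree edge (deterministic block construction; used to control the
# distance structure of fixtures).
blocks_alignment <- function(phy, sites_per_edge, n_invariant = 20) {
  nt <- length(phy$tip.label)
  phy2 <- stats::reorder(phy, "postorder")
  below <- vector("list", nt + phy2$Nnode)
  for (i in seq_len(nt)) below[[i]] <- i
  for (e in seq_len(nrow(phy2$edge))) {
    below[[phy2$edge[e, 1]]] <- c(below[[phy2$edge[e, 1]]],
                                  below[[phy2$edge[e, 2]]])
  }
  cols <- list()
  for (e in seq_len(nrow(phy2$edge))) {
    k <- sites_per_edge[e]
    if (is.na(k) || k == 0) next
    clade <- below[[phy2$edge[e, 2]]]
    for (s in seq_len(k)) {
      col <- rep("A", nt)
      col[clade] <- "G"
      cols[[length(cols) + 1]] <- col
    }
  }
  # invariant filler alternating C/T so every base occurs alignment-wide
  # (the F84 frequency estimate requires all four)
  for (s in seq_len(n_invariant)) {
    cols[[length(cols) + 1]] <- rep(c("C", "T")[1 + s %% 2], nt)
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- phy2$tip.label
  homodist::alignment(apply(mat, 1, paste, collapse = ""), phy2$tip.label)
}
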