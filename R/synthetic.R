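BASES <- c("A", "C", "G", "T")

#' Random coalescent-style binary tree
#'
#' Uniform random binary coalescent topology with exponential branch
#' lengths (via [ape::rcoal()]), deterministic per seed. Tip labels are
#' `t1 ... tn`.
#'
#' @param n_taxa Number of leaves (>= 3).
#' @param seed Mandatory integer seed.
#' @return A rooted binary `phylo` tree.
#' @export
random_binary_tree <- function(n_taxa, seed) {
  if (n_taxa < 3) stop("need at least 3 taxa", call. = FALSE)
  stopifnot(is.numeric(seed))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ape::rcoal(n_taxa, tip.label = paste0("t", seq_len(n_taxa)))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Leaf sets below each edge of a rooted tree, as index vectors into
# tip.label. Element e corresponds to edge row e.
edge_leaf_sets <- function(phy) {
  nt <- length(phy$tip.label)
  phy <- stats::reorder(phy, "postorder")
  sets <- vector("list", nt + phy$Nnode)
  for (i in seq_len(nt)) sets[[i]] <- i
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]; k <- phy$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[k]])
  }
  list(phy = phy, below = lapply(phy$edge[, 2], function(k) sort(sets[[k]])))
}

#' Simulate a homoplasy-free alignment on a tree
#'
#' Builds an alignment in which every variable site is, by construction,
#' perfectly congruent with the generating topology: each of `n_mutations`
#' randomly chosen sites is assigned exactly one tree edge, and all taxa
#' below that edge receive a derived base different from the site's
#' ancestral base. Every variable column therefore fits the generating
#' tree with exactly one change (CI = 1); remaining sites are invariant.
#' This gives an exact CI = 1 oracle rather than a probabilistic one.
#'
#' @param t A rooted binary `phylo` tree.
#' @param n_sites Alignment length.
#' @param n_mutations Number of variable sites (<= `n_sites`).
#' @param seed Mandatory integer seed.
#' @return A `homodist_alignment` over the tree's tip labels.
#' @export
simulate_homoplasy_free_alignment <- function(t, n_sites, n_mutations, seed) {
  if (n_mutations > n_sites) stop("n_mutations must be <= n_sites", call. = FALSE)
  stopifnot(is.numeric(seed))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  nt <- length(t$tip.label)
  els <- edge_leaf_sets(t)
  n_edges <- length(els$below)
  anc <- sample(BASES, n_sites, replace = TRUE)
  mat <- matrix(rep(anc, each = nt), nrow = nt,
                dimnames = list(t$tip.label, NULL))
  if (n_mutations > 0) {
    var_sites <- sample.int(n_sites, n_mutations)
    edges <- sample.int(n_edges, n_mutations, replace = TRUE)
    for (i in seq_len(n_mutations)) {
      s <- var_sites[i]
      derived <- sample(setdiff(BASES, anc[s]), 1)
      mat[els$below[[edges[i]]], s] <- derived
    }
  }
  structure(mat, class = c("homodist_alignment", class(mat)))
}

# TRUE if the leaf-index set u (or its complement) is a clade/split of the
# unrooted version of phy.
is_tree_split <- function(u, els, nt) {
  all_idx <- seq_len(nt)
  for (below in els$below) {
    if (setequal(below, u) || setequal(below, setdiff(all_idx, u))) {
      return(TRUE)
    }
  }
  FALSE
}

#' Append convergent (homoplasious) sites to an alignment
#'
#' Models convergent evolution: each appended site gives the same derived
#' base to two disjoint clades whose union is not a split of the
#' generating tree. Such a site needs at least two changes on the true
#' topology while its minimum is one, so each injected column contributes
#' exactly one unit of homoplasy (2 actual steps, 1 minimum step) and
#' HI > 0 on the true tree is guaranteed.
#'
#' @param aln A `homodist_alignment` over the tree's tips.
#' @param t The generating `phylo` tree.
#' @param k Number of convergent sites to append (>= 1).
#' @param seed Mandatory integer seed.
#' @param clades Optional list of two character vectors of tip labels to
#'   use as the convergent clades for every site (checked); by default a
#'   random eligible pair is drawn per site.
#' @return A `homodist_alignment` with `k` extra columns. Attribute
#'   `convergent_clades` records the clade pair used per site.
#' @export
inject_convergent_sites <- function(aln, t, k, seed, clades = NULL) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  stopifnot(is.numeric(seed))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  nt <- length(t$tip.label)
  stopifnot(setequal(t$tip.label, taxa_labels(aln)))
  els <- edge_leaf_sets(t)
  below <- els$below
  labs <- els$phy$tip.label
  # candidate clade pairs: disjoint, union a proper subset, union not a split
  pairs <- list()
  if (is.null(clades)) {
    for (i in seq_along(below)) {
      for (j in seq_along(below)) {
        if (j <= i) next
        u <- union(below[[i]], below[[j]])
        if (length(intersect(below[[i]], below[[j]])) > 0) next
        if (length(u) >= nt) next
        if (is_tree_split(u, els, nt)) next
        pairs[[length(pairs) + 1]] <- list(below[[i]], below[[j]])
      }
    }
    if (length(pairs) == 0) {
      stop("tree has no pair of disjoint, non-adjacent clades", call. = FALSE)
    }
  } else {
    c1 <- match(clades[[1]], labs); c2 <- match(clades[[2]], labs)
    u <- union(c1, c2)
    if (anyNA(c(c1, c2)) || length(intersect(c1, c2)) > 0 ||
        length(u) >= nt || is_tree_split(u, els, nt)) {
      stop("supplied clades are not disjoint non-adjacent clades of the tree",
           call. = FALSE)
    }
    pairs <- list(list(c1, c2))
  }
  mat <- unclass(aln)[labs, , drop = FALSE]
  used <- vector("list", k)
  newcols <- matrix("", nt, k, dimnames = list(labs, NULL))
  for (s in seq_len(k)) {
    pr <- pairs[[sample.int(length(pairs), 1)]]
    anc <- sample(BASES, 1)
    derived <- sample(setdiff(BASES, anc), 1)
    col <- rep(anc, nt)
    col[c(pr[[1]], pr[[2]])] <- derived
    newcols[, s] <- col
    used[[s]] <- list(labs[pr[[1]]], labs[pr[[2]]])
  }
  out <- cbind(mat, newcols)
  # keep the original row order of the input alignment
  out <- out[taxa_labels(aln), , drop = FALSE]
  structure(out, class = c("homodist_alignment", class(out)),
            convergent_clades = used)
}

#' Simulate sequences under the F84 substitution process
#'
#' Markov simulation of F84 evolution along a tree: the root state is
#' drawn from the stationary base frequencies and each branch applies the
#' transition-probability matrix `expm(Q * t)` of the F84 rate matrix,
#' normalized to one expected substitution per unit branch length. Used to
#' validate that estimated pairwise F84 distances recover path lengths.
#'
#' @param t A rooted `phylo` tree with branch lengths in expected
#'   substitutions per site.
#' @param freqs Stationary base frequencies `c(A=,C=,G=,T=)`.
#' @param kappa Transition-excess parameter of F84 (>= 0; 0 reduces to the
#'   equal-input F81 process).
#' @param n_sites Number of independent sites.
#' @param seed Mandatory integer seed.
#' @return A `homodist_alignment` over the tree's tips.
#' @export
simulate_f84_sequences <- function(t, freqs = c(A = 0.25, C = 0.25,
                                                G = 0.25, T = 0.25),
                                   kappa = 1, n_sites = 1000, seed = 1) {
  stopifnot(is.numeric(seed))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  Q <- f84_rate_matrix(freqs, kappa)
  nt <- length(t$tip.label)
  n_nodes <- nt + t$Nnode
  phy <- stats::reorder(t, "postorder")
  root <- nt + 1L
  states <- matrix(0L, n_nodes, n_sites)
  states[root, ] <- sample.int(4, n_sites, replace = TRUE, prob = freqs)
  # preorder = reversed postorder edge list
  for (e in rev(seq_len(nrow(phy$edge)))) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    len <- phy$edge.length[e]
    if (len <= 0) {
      states[ch, ] <- states[p, ]
      next
    }
    P <- as.matrix(Matrix::expm(Q * len))
    child <- integer(n_sites)
    for (b in 1:4) {
      idx <- which(states[p, ] == b)
      if (length(idx)) {
        child[idx] <- sample.int(4, length(idx), replace = TRUE, prob = P[b, ])
      }
    }
    states[ch, ] <- child
  }
  mat <- matrix(BASES[states[seq_len(nt), ]], nrow = nt,
                dimnames = list(phy$tip.label, NULL))
  structure(mat, class = c("homodist_alignment", class(mat)))
}

# F84 instantaneous rate matrix, scaled to unit expected substitution rate.
# Transitions (A<->G, C<->T) get the extra within-group term kappa.
f84_rate_matrix <- function(freqs, kappa) {
  freqs <- freqs[BASES]
  stopifnot(abs(sum(freqs) - 1) < 1e-8, all(freqs > 0), kappa >= 0)
  piR <- freqs[["A"]] + freqs[["G"]]
  piY <- freqs[["C"]] + freqs[["T"]]
  group <- c(A = piR, C = piY, G = piR, T = piY)
  Q <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  for (i in BASES) {
    for (j in BASES) {
      if (i == j) next
      rate <- freqs[[j]]
      transition <- (i %in% PURINES) == (j %in% PURINES)
      if (transition) rate <- rate * (1 + kappa / group[[j]])
      Q[i, j] <- rate
    }
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  Q / scale
}
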