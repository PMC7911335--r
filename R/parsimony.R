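# Encode an alignment as the bitmask matrix consumed by the Fitch pass:
# A=1, C=2, G=4, T=8; ambiguity codes are the union of their bases; '-' and
# '?' carry the full set (missing data, never a fifth state).
encode_state_bits <- function(aln) {
  m <- matrix(IUPAC_BITS[unclass(aln)], nrow = nrow(aln),
              dimnames = dimnames(aln))
  storage.mode(m) <- "integer"
  m
}

# Vectorized Fitch pass over all sites at once. Works on the given rooted
# representation; multifurcations are folded child-by-child (exact for
# binary trees and for the basal trifurcation of an unrooted binary tree,
# where folding is identical to rooting along the last child's edge).
fitch_pass <- function(phy, bits) {
  nt <- length(phy$tip.label)
  if (!all(phy$tip.label %in% rownames(bits))) {
    missing <- setdiff(phy$tip.label, rownames(bits))
    stop("no character data for leaf/leaves: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  phy <- stats::reorder(phy, "postorder")
  n_nodes <- nt + phy$Nnode
  n_sites <- ncol(bits)
  state <- matrix(0L, n_nodes, n_sites)
  state[seq_len(nt), ] <- bits[phy$tip.label, , drop = FALSE]
  steps <- integer(n_sites)
  parents <- phy$edge[, 1]
  kids <- phy$edge[, 2]
  for (e in seq_along(parents)) {
    p <- parents[e]
    cur <- state[p, ]
    child <- state[kids[e], ]
    if (all(cur == 0L)) {
      state[p, ] <- child
    } else {
      inter <- bitwAnd(cur, child)
      empty <- inter == 0L
      steps <- steps + empty
      inter[empty] <- bitwOr(cur, child)[empty]
      state[p, ] <- inter
    }
  }
  steps
}

#' Fitch parsimony steps for one site
#'
#' Minimum number of state changes a single alignment column requires on a
#' tree, computed with the Fitch bottom-up pass (set intersection where
#' non-empty, otherwise union plus one step). Taxa with missing data (`-`,
#' `?`) carry the full base set and therefore never force a change. The
#' count is invariant to rooting for unordered characters.
#'
#' @param t A `phylo` tree whose leaves are a subset of the column's taxa.
#' @param col Named character vector: one IUPAC residue per taxon.
#' @return Integer step count.
#' @examples
#' tr <- ape::read.tree(text = "((a,b),(c,d));")
#' fitch_site_steps(tr, c(a = "A", b = "A", c = "C", d = "C"))
#' @export
fitch_site_steps <- function(t, col) {
  col <- toupper(as.character(col)[match(t$tip.label, names(col))])
  names(col) <- t$tip.label
  if (anyNA(col)) {
    stop("no character data for leaf/leaves: ",
         paste(t$tip.label[is.na(col)], collapse = ", "), call. = FALSE)
  }
  bits <- matrix(IUPAC_BITS[col], ncol = 1, dimnames = list(names(col), NULL))
  storage.mode(bits) <- "integer"
  fitch_pass(t, bits)[1]
}

# Per-site counts of each unambiguous base (taxa with gaps or ambiguity
# codes are not scored).
site_base_counts <- function(aln) {
  chars <- unclass(aln)
  counts <- vapply(names(BASE_BITS),
                   function(b) colSums(chars == b),
                   numeric(ncol(aln)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list(NULL, names(counts)))
  counts
}

#' Minimum possible steps for one site
#'
#' The number of distinct unambiguous states minus one: any tree can fit
#' the column with at least that many changes, and a perfectly congruent
#' tree needs no more.
#'
#' @param col Named character vector of IUPAC residues.
#' @return Integer.
#' @export
site_min_steps <- function(col) {
  col <- toupper(as.character(col))
  max(0L, length(unique(col[col %in% names(BASE_BITS)])) - 1L)
}

#' Maximum steps for one site
#'
#' The Fitch length of the column on the worst-case (star) resolution: the
#' number of taxa that cannot match the best central state, minimized over
#' the four bases. For unambiguous data this is the familiar "scored taxa
#' minus the multiplicity of the most frequent state"; taxa with an
#' ambiguity set count as matching whenever the central state lies in their
#' set, and missing data (`-`, `?`) never count. This is the per-site
#' denominator term of the retention index.
#'
#' @param col Named character vector of IUPAC residues.
#' @return Integer.
#' @export
site_max_steps <- function(col) {
  col <- toupper(as.character(col))
  bits <- IUPAC_BITS[col]
  if (anyNA(bits)) stop("invalid residue in column", call. = FALSE)
  min(vapply(BASE_BITS, function(b) sum(bitwAnd(bits, b) == 0L), integer(1)))
}

#' Consistency, retention and homoplasy indices on a tree
#'
#' Scores every alignment column on the tree with the Fitch pass and sums
#' the actual steps `S`, the minimum steps `M` and the maximum (star-tree)
#' steps `G` over all sites (uninformative sites included; they add equally
#' to `M` and `S`). The indices are
#' `CI = M/S` (with `CI = 1` when `S = 0`, i.e. no change required at all),
#' `HI = 1 - CI`, `RI = (G - S)/(G - M)` (reported `NA` when `G = M`, where
#' no character is parsimony-informative and apparent synapomorphy is
#' undefined), and `RCI = CI * RI`.
#'
#' @param t A `phylo` tree whose leaf set equals the alignment's taxa.
#' @param aln A `homodist_alignment`.
#' @return An object of class `parsimony_scores`: list with `S`, `M`, `G`,
#'   `CI`, `RI`, `HI`, `RCI`, `n_taxa`, `n_sites`.
#' @examples
#' aln <- alignment(c("AAC", "AAC", "ACA", "ACA"), c("a", "b", "c", "d"))
#' tr <- ape::read.tree(text = "((a,b),(c,d));")
#' consistency_indices(tr, aln)
#' @export
consistency_indices <- function(t, aln) {
  if (!setequal(t$tip.label, taxa_labels(aln))) {
    stop("tree leaves and alignment labels differ", call. = FALSE)
  }
  bits <- encode_state_bits(aln)
  s_site <- fitch_pass(t, bits)
  counts <- site_base_counts(aln)
  m_site <- pmax(0L, rowSums(counts > 0) - 1L)
  # star-tree maximum, set-aware: taxa whose base set excludes the best
  # central state each force one change
  excludes <- vapply(BASE_BITS, function(b) {
    colSums(matrix(bitwAnd(bits, b) == 0L, nrow = nrow(bits)))
  }, numeric(ncol(bits)))
  if (is.null(dim(excludes))) excludes <- matrix(excludes, nrow = 1)
  g_site <- apply(excludes, 1, min)
  S <- sum(s_site); M <- sum(m_site); G <- sum(g_site)
  CI <- if (S == 0) 1 else M / S
  HI <- 1 - CI
  RI <- if (G == M) NA_real_ else (G - S) / (G - M)
  RCI <- if (is.na(RI)) NA_real_ else CI * RI
  structure(list(S = S, M = M, G = G, CI = CI, RI = RI, HI = HI, RCI = RCI,
                 n_taxa = n_taxa(aln), n_sites = n_sites(aln)),
            class = "parsimony_scores")
}

#' @export
print.parsimony_scores <- function(x, ...) {
  cat("Parsimony scores (", x$n_taxa, " taxa, ", x$n_sites, " sites)\n",
      sep = "")
  cat(sprintf("  steps S = %d, min M = %d, max G = %d\n", x$S, x$M, x$G))
  cat(sprintf("  CI = %.4f  HI = %.4f  RI = %s  RCI = %s\n", x$CI, x$HI,
              ifelse(is.na(x$RI), "NA", sprintf("%.4f", x$RI)),
              ifelse(is.na(x$RCI), "NA", sprintf("%.4f", x$RCI))))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy parsimony scores into a one-row tibble
#'
#' @param x A `parsimony_scores` object.
#' @param ... Unused.
#' @return A one-row tibble with columns `S`, `M`, `G`, `CI`, `RI`, `HI`,
#'   `RCI`, `n_taxa`, `n_sites`.
#' @method tidy parsimony_scores
#' @export
tidy.parsimony_scores <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
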