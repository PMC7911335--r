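check_distance_input <- function(D, min_taxa) {
  if (anyNA(D)) {
    idx <- which(is.na(D), arr.ind = TRUE)[1, ]
    stop("distance matrix has undefined (saturated) cells, e.g. '",
         rownames(D)[idx[1]], "' vs '", colnames(D)[idx[2]], "'",
         call. = FALSE)
  }
  if (nrow(D) < min_taxa) {
    stop("need at least ", min_taxa, " taxa, got ", nrow(D), call. = FALSE)
  }
  invisible(D)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}). The result is unrooted and
#' represented with a basal trifurcation; parsimony scoring is unaffected by
#' this arbitrary rooting. Negative branch lengths, which NJ can produce,
#' are kept in the returned object for diagnostics and clamped to zero only
#' at Newick serialization.
#'
#' @param D Symmetric distance matrix with taxon dimnames; no `NA` cells.
#' @return An \pkg{ape} `phylo` tree.
#' @export
build_nj <- function(D) {
  check_distance_input(D, 3)
  ape::nj(stats::as.dist(D))
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomerative clustering; node heights are half the
#' cluster distance at each merge, so on an ultrametric input the tree
#' reproduces the distances exactly.
#'
#' @inheritParams build_nj
#' @return A rooted ultrametric `phylo` tree.
#' @export
build_upgma <- function(D) {
  check_distance_input(D, 2)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  ape::as.phylo(hc)
}

#' Serialize a tree to canonical Newick
#'
#' Writes Newick with branch lengths, ordering the children of every node
#' by their smallest contained leaf label so the same topology always
#' yields the same string (diffable across runs). Negative branch lengths
#' are clamped to zero. Labels containing Newick-reserved characters are
#' single-quoted.
#'
#' @param t A `phylo` tree.
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string, terminated with `;`.
#' @examples
#' tr <- ape::read.tree(text = "(b:1,(d:1,c:1):1,a:1);")
#' to_newick(tr)
#' @export
to_newick <- function(t, digits = 10) {
  nt <- length(t$tip.label)
  root <- nt + 1L
  children <- split(seq_len(nrow(t$edge)), t$edge[, 1])
  has_len <- !is.null(t$edge.length)
  quote_label <- function(l) {
    if (grepl("[](),:;'\"[ \t]", l)) {
      paste0("'", gsub("'", "''", l, fixed = TRUE), "'")
    } else l
  }
  fmt_len <- function(x) {
    if (!has_len) return("")
    paste0(":", format(max(0, x), digits = digits, scientific = FALSE,
                       trim = TRUE))
  }
  rec <- function(node) {
    if (node <= nt) {
      return(list(str = quote_label(t$tip.label[node]),
                  min_leaf = t$tip.label[node]))
    }
    kids <- lapply(children[[as.character(node)]], function(e) {
      sub <- rec(t$edge[e, 2])
      sub$str <- paste0(sub$str, fmt_len(if (has_len) t$edge.length[e] else NA))
      sub
    })
    ord <- order(vapply(kids, `[[`, character(1), "min_leaf"))
    kids <- kids[ord]
    list(str = paste0("(", paste(vapply(kids, `[[`, character(1), "str"),
                                 collapse = ","), ")"),
         min_leaf = kids[[1]]$min_leaf)
  }
  paste0(rec(root)$str, ";")
}
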