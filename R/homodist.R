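#' Find the central taxon of a distance matrix
#'
#' The center of the distribution is the taxon with the lowest average
#' distance to all other taxa. Ties go to the earliest taxon in input
#' order.
#'
#' @param D Symmetric distance matrix with taxon dimnames; no `NA` cells.
#' @return The central taxon's label.
#' @export
find_center <- function(D) {
  check_distance_input(D, 2)
  means <- rowSums(D) / (nrow(D) - 1)
  rownames(D)[which.min(means)]
}

#' Order taxa by increasing distance from a center
#'
#' Returns the center first, then every other taxon sorted by ascending
#' distance from it. Ties preserve input order (stable sort), so the
#' series is fully deterministic.
#'
#' @inheritParams find_center
#' @param center A taxon label present in `D`.
#' @return Character vector: the ordered taxon series.
#' @export
order_by_center_distance <- function(D, center) {
  labs <- rownames(D)
  if (!center %in% labs) stop("center '", center, "' not in matrix", call. = FALSE)
  d <- D[center, ]
  if (anyNA(d)) {
    stop("undefined distance from center to '",
         labs[which(is.na(d))[1]], "'", call. = FALSE)
  }
  others <- setdiff(labs, center)
  c(center, others[order(d[others])])
}

method_cols <- c("S", "M", "G", "CI", "RI", "HI", "RCI", "SHI")

#' Run the HomoDist trace
#'
#' The core procedure: taxa are ordered by increasing distance from a
#' central taxon, a first tree is built from the center plus its three
#' nearest neighbors, and then taxa are added one at a time in distance
#' order. At every step the distance submatrix of the current taxon set is
#' clustered with neighbor joining and/or UPGMA, the sub-alignment is
#' scored with Fitch parsimony, and the step records `disCen` (distance of
#' the newest taxon from the center), `MaxD` (maximum pairwise distance in
#' the current set), and per tree method the parsimony sums `S`, `M`, `G`
#' and indices `CI`, `RI`, `HI`, `RCI` plus `SHI = HI / MaxD` (0 when
#' `MaxD` is 0). The full distance matrix is computed once and sliced per
#' step; pairwise deletion makes pairwise distances independent of the
#' taxon subset. The whole pipeline is deterministic: no random seed is
#' involved.
#'
#' @param aln A `homodist_alignment` with at least 4 taxa (the first tree
#'   uses 4), or a path to a FASTA alignment.
#' @param auto_center If `TRUE` (default) the center is found with
#'   [find_center()]; otherwise `center` must be given.
#' @param center Taxon label or 1-based input position of the starting
#'   taxon, used when `auto_center = FALSE`.
#' @param model Distance model passed to [distance_matrix()].
#' @param tree_methods Subset of `c("nj", "upgma")`; both by default.
#' @param trim If `TRUE`, gap-containing flanking columns are removed with
#'   [trim_flanking_columns()] before anything else.
#' @return An object of class `homodist_trace` with elements `center`,
#'   `series` (ordered taxon labels), `steps` (a tibble, one row per
#'   addition step with per-method columns prefixed `nj_`/`upgma_`),
#'   `trees` (per-step list of `phylo` objects), `model`, and
#'   `distance_matrix`.
#' @examples
#' tr <- random_binary_tree(6, seed = 1)
#' aln <- simulate_homoplasy_free_alignment(tr, n_sites = 120,
#'                                          n_mutations = 40, seed = 1)
#' trace <- run_homodist(aln)
#' tidy(trace)
#' @export
run_homodist <- function(aln, auto_center = TRUE, center = NULL,
                         model = "F84", tree_methods = c("nj", "upgma"),
                         trim = FALSE) {
  if (is.character(aln) && length(aln) == 1) aln <- read_fasta_alignment(aln)
  tree_methods <- match.arg(tree_methods, c("nj", "upgma"),
                            several.ok = TRUE)
  if (trim) aln <- trim_flanking_columns(aln)
  if (n_taxa(aln) < 4) {
    stop("HomoDist needs at least 4 taxa (first tree is center + 3 nearest)",
         call. = FALSE)
  }
  D <- distance_matrix(aln, model = model)
  if (anyNA(D)) {
    idx <- which(is.na(D), arr.ind = TRUE)[1, ]
    stop("saturated (undefined) distance between '", rownames(D)[idx[1]],
         "' and '", colnames(D)[idx[2]], "'; cannot order taxa",
         call. = FALSE)
  }
  if (auto_center) {
    ctr <- find_center(D)
  } else {
    if (is.null(center)) stop("center must be given when auto_center = FALSE",
                              call. = FALSE)
    ctr <- if (is.numeric(center)) taxa_labels(aln)[as.integer(center)] else center
    if (is.na(ctr) || !ctr %in% taxa_labels(aln)) {
      stop("center '", center, "' not found in alignment", call. = FALSE)
    }
  }
  series <- order_by_center_distance(D, ctr)
  n <- length(series)
  n_steps <- n - 3L
  trees <- vector("list", n_steps)
  rows <- vector("list", n_steps)
  for (k in seq_len(n_steps)) {
    taxa <- series[seq_len(k + 3L)]
    newest <- taxa[length(taxa)]
    sub_d <- D[taxa, taxa]
    sub_aln <- subset_alignment(aln, taxa)
    max_d <- max(sub_d)
    row <- tibble::tibble(
      step = k,
      added_taxon = newest,
      n_taxa = k + 3L,
      disCen = D[ctr, newest],
      MaxD = max_d
    )
    step_trees <- list()
    for (m in tree_methods) {
      tr <- if (m == "nj") build_nj(sub_d) else build_upgma(sub_d)
      step_trees[[m]] <- tr
      sc <- consistency_indices(tr, sub_aln)
      shi <- if (max_d == 0) 0 else sc$HI / max_d
      vals <- c(sc$S, sc$M, sc$G, sc$CI, sc$RI, sc$HI, sc$RCI, shi)
      row[paste0(m, "_", method_cols)] <- as.list(vals)
    }
    trees[[k]] <- step_trees
    rows[[k]] <- row
  }
  structure(list(
    center = ctr,
    series = series,
    steps = dplyr::bind_rows(rows),
    trees = trees,
    model = model,
    tree_methods = tree_methods,
    distance_matrix = D
  ), class = "homodist_trace")
}

#' @export
print.homodist_trace <- function(x, ...) {
  cat("HomoDist trace: ", length(x$series), " taxa, ",
      nrow(x$steps), " steps, model ", x$model, "\n", sep = "")
  cat("center: ", x$center, "\n", sep = "")
  print(x$steps, n = 8)
  invisible(x)
}

#' Tidy a HomoDist trace
#'
#' @param x A `homodist_trace`.
#' @param ... Unused.
#' @return The per-step tibble (`step`, `added_taxon`, `n_taxa`, `disCen`,
#'   `MaxD`, then `S`, `M`, `G`, `CI`, `RI`, `HI`, `RCI`, `SHI` per tree
#'   method, prefixed `nj_` / `upgma_`).
#' @method tidy homodist_trace
#' @export
tidy.homodist_trace <- function(x, ...) x$steps

#' One-row summary of a HomoDist trace
#'
#' @param x A `homodist_trace`.
#' @param ... Unused.
#' @return One-row tibble: center, taxon and step counts, final HI/CI of
#'   the first configured tree method, and the maximum distance spanned.
#' @method glance homodist_trace
#' @export
glance.homodist_trace <- function(x, ...) {
  m <- x$tree_methods[1]
  last <- x$steps[nrow(x$steps), ]
  tibble::tibble(
    center = x$center,
    n_taxa = length(x$series),
    n_steps = nrow(x$steps),
    model = x$model,
    final_CI = last[[paste0(m, "_CI")]],
    final_HI = last[[paste0(m, "_HI")]],
    final_SHI = last[[paste0(m, "_SHI")]],
    max_distance = last$MaxD
  )
}

trace_method_col <- function(trace, method, what) {
  method <- match.arg(method, c("nj", "upgma"))
  col <- paste0(method, "_", what)
  if (!col %in% names(trace$steps)) {
    stop("trace was not run with tree method '", method, "'", call. = FALSE)
  }
  trace$steps[[col]]
}

#' First appearance of homoplasy along the trace
#'
#' Returns the earliest step whose homoplasy index is positive for the
#' chosen tree method, together with both candidate "detection distances":
#' the new taxon's distance from the center (`disCen`) and the maximum
#' pairwise distance of the subset (`MaxD`).
#'
#' @param trace A `homodist_trace`.
#' @param method `"nj"` or `"upgma"`.
#' @return A one-row tibble (`step`, `added_taxon`, `n_taxa`, `disCen`,
#'   `MaxD`, `HI`), or a zero-row tibble when HI is zero throughout.
#' @export
first_homoplasy_step <- function(trace, method = "nj") {
  hi <- trace_method_col(trace, method, "HI")
  out <- dplyr::select(trace$steps, "step", "added_taxon", "n_taxa",
                       "disCen", "MaxD")
  out$HI <- hi
  dplyr::slice_head(dplyr::filter(out, .data$HI > 0), n = 1)
}

#' Pearson correlation between maximum distance and CI
#'
#' Correlates `MaxD` with the consistency index over the trace steps that
#' show some homoplasy (CI < 1). Steps with CI = 1 carry no signal about
#' the homoplasy-distance relationship and are excluded. Returns `NA` when
#' fewer than 3 qualifying steps remain or either variable has zero
#' variance.
#'
#' @inheritParams first_homoplasy_step
#' @return Pearson r, or `NA_real_`.
#' @export
ci_distance_correlation <- function(trace, method = "nj") {
  ci <- trace_method_col(trace, method, "CI")
  keep <- !is.na(ci) & ci < 1
  if (sum(keep) < 3) return(NA_real_)
  x <- trace$steps$MaxD[keep]
  y <- ci[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Partition taxa into groups of constant HI
#'
#' Walks the taxon series in addition order: the center and the three taxa
#' of the first tree share the first step's HI; every later taxon carries
#' the HI of the step at which it entered. A new group opens whenever the
#' HI changes from the previous step (comparison after rounding to
#' `digits` decimals, since CI is a ratio of integer step counts and exact
#' float comparison would split groups on representation noise). These
#' change points typically fall at transitions between species, which is
#' what makes the partition useful as delimitation evidence.
#'
#' @inheritParams first_homoplasy_step
#' @param digits Decimals used when comparing HI values; set `Inf` for
#'   exact comparison.
#' @return An object of class `hi_partition`: tibble with columns `group`,
#'   `taxon`, `HI`, plus attribute `boundaries` (the step indices where HI
#'   changed).
#' @export
delimit_hi_groups <- function(trace, method = "nj", digits = 4) {
  hi_steps <- trace_method_col(trace, method, "HI")
  hi_cmp <- if (is.finite(digits)) round(hi_steps, digits) else hi_steps
  # HI carried by each taxon, in series order
  taxon_hi <- c(rep(hi_steps[1], 4), hi_steps[-1])
  changed <- c(FALSE, diff(hi_cmp) != 0)
  group_of_step <- cumsum(changed) + 1L
  group <- c(rep(1L, 4), group_of_step[-1])
  out <- tibble::tibble(group = group, taxon = trace$series, HI = taxon_hi)
  structure(out,
            class = c("hi_partition", class(out)),
            boundaries = which(changed),
            method = method)
}

#' @export
print.hi_partition <- function(x, ...) {
  cat("HI partition (", attr(x, "method"), " tree): ",
      max(x$group), " group(s)\n", sep = "")
  for (g in unique(x$group)) {
    rows <- x[x$group == g, ]
    cat(sprintf("  group %d (HI = %.4f): %s\n", g, rows$HI[1],
                paste(rows$taxon, collapse = ", ")))
  }
  invisible(x)
}

#' Write a trace to TSV
#'
#' One row per step with the fixed header `step`, `added_taxon`, `n_taxa`,
#' `disCen`, `MaxD`, then `S M G CI RI HI RCI SHI` per tree method
#' (prefixed `nj_`/`upgma_`). Missing values are spelled `NA`.
#'
#' @param trace A `homodist_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_tsv <- function(trace, path) {
  utils::write.table(trace$steps, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a trace TSV back into a tibble
#'
#' @param path Path to a file written by [write_trace_tsv()].
#' @return A tibble with the trace-step columns.
#' @export
read_trace_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' Write per-step Newick trees
#'
#' Writes one canonical Newick file per step and tree method, named
#' `step_<k>_<method>.nwk`.
#'
#' @param trace A `homodist_trace`.
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
write_trace_trees <- function(trace, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (k in seq_along(trace$trees)) {
    for (m in names(trace$trees[[k]])) {
      p <- file.path(dir, sprintf("step_%d_%s.nwk", k, m))
      writeLines(to_newick(trace$trees[[k]][[m]]), p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
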