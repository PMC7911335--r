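PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Count pairwise transition/transversion differences
#'
#' Compares two aligned sequences under pairwise deletion: any site where
#' either sequence carries a gap, `?` or an IUPAC ambiguity code is excluded
#' from the comparison. Transitions are A<->G and C<->T; all other base
#' differences are transversions.
#'
#' @param row_i,row_j Equal-length sequence strings or character vectors of
#'   single residues.
#' @return A list with `n_compared`, `n_transitions`, `n_transversions`, and
#'   the proportions `P` (transitions) and `Q` (transversions).
#' @examples
#' count_pair_differences("ACGT", "ACGA")
#' @export
count_pair_differences <- function(row_i, row_j) {
  x <- to_chars(row_i)
  y <- to_chars(row_j)
  if (length(x) != length(y)) {
    stop("sequences differ in length", call. = FALSE)
  }
  ok <- x %in% names(BASE_BITS) & y %in% names(BASE_BITS)
  n <- sum(ok)
  if (n == 0) stop("no comparable sites (all positions gapped or ambiguous)",
                   call. = FALSE)
  xs <- x[ok]; ys <- y[ok]
  diff <- xs != ys
  ts <- sum(diff & (xs %in% PURINES) == (ys %in% PURINES))
  tv <- sum(diff) - ts
  list(n_compared = n, n_transitions = ts, n_transversions = tv,
       P = ts / n, Q = tv / n)
}

to_chars <- function(s) {
  if (length(s) == 1L && nchar(s) > 1L) {
    strsplit(toupper(s), "", fixed = TRUE)[[1]]
  } else {
    toupper(as.character(s))
  }
}

#' Estimate base frequencies from a whole alignment
#'
#' Counts A, C, G, T over all rows and sites, ignoring gaps and ambiguity
#' codes, and normalizes to sum to one. Frequencies are estimated once from
#' the full alignment (not per pair) so that distances stay consistent
#' across taxon subsets. A frequency of exactly zero is an error because
#' the F84 closed form divides by frequency sums; such compositions need a
#' different model.
#'
#' @param aln A `homodist_alignment`.
#' @return Named numeric vector `c(A=, C=, G=, T=)` summing to 1.
#' @export
estimate_base_frequencies <- function(aln) {
  chars <- unclass(aln)
  counts <- vapply(names(BASE_BITS), function(b) sum(chars == b), numeric(1))
  if (sum(counts) == 0) stop("no unambiguous bases in alignment", call. = FALSE)
  if (any(counts == 0)) {
    stop("base(s) ", paste(names(counts)[counts == 0], collapse = ", "),
         " absent from alignment; F84 frequencies would be degenerate - ",
         "use a different distance model", call. = FALSE)
  }
  counts / sum(counts)
}

#' F84 pairwise distance (closed form)
#'
#' Evolutionary distance under the F84 substitution model (unequal base
#' frequencies, transition/transversion distinction), computed from the
#' observed transition proportion `P`, transversion proportion `Q` and
#' alignment-wide base frequencies. With
#' \deqn{A = \pi_C\pi_T/\pi_Y + \pi_A\pi_G/\pi_R,\quad
#'       B = \pi_C\pi_T + \pi_A\pi_G,\quad C = \pi_R\pi_Y}
#' the distance is
#' \deqn{d = -2A\,\ln\!\big(1 - P/(2A) - (A-B)Q/(2AC)\big)
#'        + 2(A-B-C)\,\ln\!\big(1 - Q/(2C)\big).}
#' When base frequencies are all equal the expression reduces algebraically
#' to the K80 two-parameter distance. If either logarithm's argument is
#' non-positive the sequences are saturated for this model and `NA` is
#' returned with a warning rather than an error, so callers can flag the
#' pair.
#'
#' @param pc Pair counts from [count_pair_differences()], or any list with
#'   elements `P` and `Q`.
#' @param freqs Base frequencies as returned by [estimate_base_frequencies()].
#' @return The distance in expected substitutions per site, or `NA_real_`
#'   (with a warning) when saturated.
#' @export
f84_distance <- function(pc, freqs) {
  P <- pc$P; Q <- pc$Q
  piA <- freqs[["A"]]; piC <- freqs[["C"]]
  piG <- freqs[["G"]]; piT <- freqs[["T"]]
  piR <- piA + piG; piY <- piC + piT
  A <- piC * piT / piY + piA * piG / piR
  B <- piC * piT + piA * piG
  C <- piR * piY
  arg1 <- 1 - P / (2 * A) - (A - B) * Q / (2 * A * C)
  arg2 <- 1 - Q / (2 * C)
  if (arg1 <= 0 || arg2 <= 0) {
    warning("F84 distance undefined (saturated): log argument <= 0",
            call. = FALSE)
    return(NA_real_)
  }
  -2 * A * log(arg1) + 2 * (A - B - C) * log(arg2)
}

k80_distance <- function(P, Q) {
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) {
    warning("K80 distance undefined (saturated)", call. = FALSE)
    return(NA_real_)
  }
  -0.5 * log(a1) - 0.25 * log(a2)
}

jc69_distance <- function(p) {
  a <- 1 - 4 * p / 3
  if (a <= 0) {
    warning("JC69 distance undefined (saturated)", call. = FALSE)
    return(NA_real_)
  }
  -0.75 * log(a)
}

#' Pairwise distance matrix for an alignment
#'
#' Computes all pairwise distances under the chosen substitution model.
#' `F84` (the default) uses base frequencies estimated once from the whole
#' alignment; `K80` and `JC69` are the usual closed forms; `raw` is the
#' observed proportion of differing sites (P + Q). Missing data are handled
#' by pairwise deletion. Saturated pairs become `NA` with a warning.
#'
#' @param aln A `homodist_alignment`.
#' @param model One of `"F84"`, `"K80"`, `"JC69"`, `"raw"`.
#' @return A symmetric numeric matrix (zero diagonal) with taxon labels as
#'   dimnames and attribute `model`. Distances are proportions
#'   (substitutions/site); multiply by 100 for the percentage scale.
#' @examples
#' aln <- alignment(c("ACGTACGT", "ACGTACGA", "ACGAACTA"), c("a", "b", "c"))
#' distance_matrix(aln, model = "raw")
#' @export
distance_matrix <- function(aln, model = c("F84", "K80", "JC69", "raw")) {
  model <- match.arg(model)
  n <- n_taxa(aln)
  if (n < 2) stop("need at least 2 taxa", call. = FALSE)
  labs <- taxa_labels(aln)
  freqs <- if (model == "F84") estimate_base_frequencies(aln) else NULL
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  chars <- unclass(aln)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      pc <- tryCatch(
        count_pair_differences(chars[i, ], chars[j, ]),
        error = function(e) {
          stop("no comparable sites between '", labs[i], "' and '", labs[j],
               "'", call. = FALSE)
        }
      )
      d <- switch(model,
        F84 = f84_distance(pc, freqs),
        K80 = k80_distance(pc$P, pc$Q),
        JC69 = jc69_distance(pc$P + pc$Q),
        raw = pc$P + pc$Q
      )
      D[i, j] <- D[j, i] <- d
    }
  }
  attr(D, "model") <- model
  D
}

#' Tidy a distance matrix into long format
#'
#' @param x A symmetric distance matrix with dimnames.
#' @param ... Unused.
#' @return A tibble with columns `taxon_a`, `taxon_b`, `distance`, one row
#'   per unordered pair.
#' @export
tidy_distances <- function(x, ...) {
  labs <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(
    taxon_a = labs[idx[, 1]],
    taxon_b = labs[idx[, 2]],
    distance = x[idx]
  )
}

#' Export a distance matrix as TSV or PHYLIP square format
#'
#' @param D Distance matrix from [distance_matrix()].
#' @param path Output path.
#' @param format `"tsv"` (header row + row labels) or `"phylip"` (square).
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(D, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  labs <- rownames(D)
  if (format == "tsv") {
    lines <- c(paste(c("taxon", labs), collapse = "\t"),
               vapply(seq_along(labs), function(i) {
                 paste(c(labs[i], format(D[i, ], digits = 10)), collapse = "\t")
               }, character(1)))
  } else {
    lines <- c(as.character(length(labs)),
               vapply(seq_along(labs), function(i) {
                 paste(c(formatC(labs[i], width = -10),
                         format(D[i, ], digits = 10)), collapse = " ")
               }, character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}
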