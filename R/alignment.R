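#' @importFrom rlang .data %||%
#' @importFrom stats cor setNames
#' @importFrom utils head tail
NULL

# IUPAC nucleotide codes as base sets; '-' and '?' are missing data and
# carry the full set, like 'N'.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"),
  `-` = c("A", "C", "G", "T"), `?` = c("A", "C", "G", "T")
)

ALLOWED_CHARS <- names(IUPAC_SETS)

# Bitmask encoding A=1, C=2, G=4, T=8 used by the Fitch pass.
BASE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)
IUPAC_BITS <- vapply(IUPAC_SETS, function(s) sum(BASE_BITS[s]), integer(1))

#' Construct a DNA alignment object
#'
#' An alignment is stored as a character matrix with one row per taxon and
#' one column per site; row names are the (unique, non-empty) taxon labels.
#' Characters are uppercased and `U` is mapped to `T`. Only IUPAC nucleotide
#' codes plus `-` (gap) and `?` (unknown) are accepted; anything else is a
#' hard error so that miscoded data cannot silently distort the homoplasy
#' counts downstream.
#'
#' @param seqs Character vector of equal-length sequence strings.
#' @param labels Character vector of taxon labels, same length as `seqs`.
#' @return An object of class `homodist_alignment`: the character matrix of
#'   single residues with taxa as row names.
#' @examples
#' aln <- alignment(c("ACGT", "ACGA"), c("a", "b"))
#' n_taxa(aln)
#' n_sites(aln)
#' @export
alignment <- function(seqs, labels) {
  if (length(seqs) != length(labels)) {
    stop("`seqs` and `labels` must have the same length", call. = FALSE)
  }
  if (length(seqs) < 2) {
    stop("an alignment needs at least 2 sequences", call. = FALSE)
  }
  labels <- as.character(labels)
  if (anyNA(labels) || any(!nzchar(labels))) {
    stop("taxon labels must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    dup <- unique(labels[duplicated(labels)])
    stop("duplicate taxon labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(seqs))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    ref <- as.integer(names(which.max(table(lens))))
    off <- labels[lens != ref]
    stop("sequences differ in length (expected ", ref, "): ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  if (lens[1] == 0L) stop("alignment has zero columns", call. = FALSE)
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE,
                dimnames = list(labels, NULL))
  bad <- !(mat %in% ALLOWED_CHARS)
  if (any(bad)) {
    chars <- sort(unique(mat[bad]))
    stop("invalid characters in alignment: ",
         paste(chars, collapse = " "),
         " (allowed: IUPAC DNA codes, '-', '?')", call. = FALSE)
  }
  structure(mat, class = c("homodist_alignment", class(mat)))
}

#' @rdname alignment
#' @param x A `homodist_alignment`.
#' @export
n_taxa <- function(x) nrow(x)

#' @rdname alignment
#' @export
n_sites <- function(x) ncol(x)

#' @rdname alignment
#' @export
taxa_labels <- function(x) rownames(x)

#' @export
print.homodist_alignment <- function(x, ...) {
  cat("DNA alignment: ", nrow(x), " taxa x ", ncol(x), " sites\n", sep = "")
  show <- head(rownames(x), 6)
  for (l in show) {
    s <- paste(x[l, seq_len(min(50, ncol(x)))], collapse = "")
    if (ncol(x) > 50) s <- paste0(s, "...")
    cat(format(l, width = min(24, max(nchar(show)))), " ", s, "\n", sep = "")
  }
  if (nrow(x) > 6) cat("... and ", nrow(x) - 6, " more taxa\n", sep = "")
  invisible(x)
}

# Subset rows, keeping the class.
subset_alignment <- function(aln, taxa) {
  m <- unclass(aln)[taxa, , drop = FALSE]
  structure(m, class = c("homodist_alignment", class(m)))
}

as_seq_strings <- function(aln) {
  apply(unclass(aln), 1, paste, collapse = "")
}

#' Read an aligned multi-FASTA file
#'
#' Reads a multi-FASTA file (wrapped or single-line) of equal-length DNA
#' sequences and validates it as a [alignment()]. Record order is preserved:
#' input order is the tie-break reference for the distance ordering
#' downstream. Sequences are uppercased and `U` mapped to `T`.
#'
#' @param path Path to a FASTA file.
#' @return A `homodist_alignment`.
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  if (length(set) < 2) stop("alignment needs at least 2 records: ", path, call. = FALSE)
  labels <- sub("\\s.*$", "", names(set))
  alignment(as.character(set), labels)
}

#' Write an alignment to multi-FASTA
#'
#' Sequences are wrapped at 60 columns. Round-trips exactly through
#' [read_fasta_alignment()].
#'
#' @param aln A `homodist_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  set <- Biostrings::BStringSet(setNames(as_seq_strings(aln), taxa_labels(aln)))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Trim gap-containing flanking columns
#'
#' Removes leading and trailing alignment columns in which any sequence has
#' a gap, the usual cleanup for ragged alignment ends where sequences start
#' and stop at different positions. Interior columns are untouched, so the
#' operation is idempotent.
#'
#' @param aln A `homodist_alignment`.
#' @return A trimmed `homodist_alignment`.
#' @export
trim_flanking_columns <- function(aln) {
  gap_col <- apply(unclass(aln) == "-", 2, any)
  clean <- which(!gap_col)
  if (length(clean) == 0) stop("alignment fully trimmed: every column has a gap",
                               call. = FALSE)
  keep <- seq(min(clean), max(clean))
  m <- unclass(aln)[, keep, drop = FALSE]
  structure(m, class = c("homodist_alignment", class(m)))
}
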