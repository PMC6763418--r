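#' Build the binary intra-group (B.I.G) matrix of an alphabet
#'
#' A 20 x 20 symmetric 0/1 matrix in canonical letter order whose cell
#' `[i, j]` is 1 exactly when letters `i` and `j` share a group in the
#' alphabet. The diagonal is stored as 1 (an amino acid always groups with
#' itself) but carries no information and is excluded from every statistic.
#'
#' @param alphabet A `simplified_alphabet`.
#' @return Integer matrix with class `big_matrix` and attribute `source_id`.
#' @examples
#' b <- build_big(simplified_alphabet("toy", "DG,W,ACEFHIKLMNPQRSTVY"))
#' b["D", "G"]  # 1: D and G are grouped
#' b["D", "W"]  # 0
#' @export
build_big <- function(alphabet) {
  stopifnot(inherits(alphabet, "simplified_alphabet"))
  mem <- alphabet_membership(alphabet)
  cells <- outer(mem, mem, `==`) * 1L
  dimnames(cells) <- list(AMINO_ACIDS, AMINO_ACIDS)
  structure(cells, class = c("big_matrix", class(cells)),
            source_id = alphabet$id)
}

#' Similarity between two alphabets over the informative cells
#'
#' Counts the off-diagonal positions at which the two B.I.G matrices agree
#' and divides by the 380 informative positions, giving a value in
#' `[0, 1]`: 1 for identical partitions, 0 for partitions that agree on no
#' pair relation. Equivalently `1 - hamming/380` on the off-diagonal cells.
#'
#' @param a,b `big_matrix` objects (or `simplified_alphabet`s, which are
#'   converted).
#' @return A single number in `[0, 1]`, always an integer multiple of 1/380.
#' @export
compare_alphabets <- function(a, b) {
  if (inherits(a, "simplified_alphabet")) a <- build_big(a)
  if (inherits(b, "simplified_alphabet")) b <- build_big(b)
  stopifnot(identical(dim(a), c(20L, 20L)), identical(dim(b), c(20L, 20L)))
  mask <- offdiag_mask()
  sum(a[mask] == b[mask]) / N_INFORMATIVE_CELLS
}

#' All-against-all alphabet similarity matrix
#'
#' @param collection An `alphabet_collection` of at least 2 alphabets.
#' @return Symmetric numeric matrix (class `alphabet_similarity`) with unit
#'   diagonal, rows/columns labelled and ordered by alphabet id as in the
#'   collection.
#' @export
build_similarity_matrix <- function(collection) {
  stopifnot(inherits(collection, "alphabet_collection"))
  n <- length(collection)
  if (n < 2L) stop("need at least 2 alphabets", call. = FALSE)
  bigs <- lapply(collection, build_big)
  ids <- names(collection)
  values <- diag(1, n)
  dimnames(values) <- list(ids, ids)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      values[i, j] <- values[j, i] <- compare_alphabets(bigs[[i]], bigs[[j]])
    }
  }
  structure(values, class = c("alphabet_similarity", "matrix", "array"))
}

#' Consensus amino-acid similarity matrix of a collection
#'
#' Sums the B.I.G matrices of all alphabets cellwise and divides by the
#' number of alphabets, so each informative cell is the fraction of input
#' alphabets that group that amino-acid pair. The diagonal is stored as 1
#' and is uninformative.
#'
#' @param collection An `alphabet_collection`.
#' @return Numeric 20 x 20 matrix with class `consensus_similarity` and
#'   attribute `n_sources`.
#' @export
build_consensus <- function(collection) {
  stopifnot(inherits(collection, "alphabet_collection"))
  counts <- Reduce(`+`, lapply(collection, function(a) {
    b <- unclass(build_big(a))
    attr(b, "source_id") <- NULL
    b
  }))
  values <- counts / length(collection)
  diag(values) <- 1
  structure(values, class = c("consensus_similarity", "matrix", "array"),
            n_sources = length(collection))
}

#' Complement a consensus similarity matrix into a distance matrix
#'
#' Maps every informative cell `s` to `1 - s`, so 0 means a pair is grouped
#' together by every input alphabet and 1 means it is never grouped. The
#' diagonal is stored as 0.
#'
#' @param m A `consensus_similarity` (or any 20 x 20 similarity matrix in
#'   `[0, 1]`).
#' @return Numeric 20 x 20 matrix with class `aa_distance`.
#' @export
similarity_to_distance <- function(m) {
  stopifnot(is.matrix(m), all(m >= 0 & m <= 1))
  d <- 1 - unclass(m)
  diag(d) <- 0
  structure(d, class = c("aa_distance", "matrix", "array"),
            n_sources = attr(m, "n_sources"))
}

#' Consensus distance matrices for the two derivation classes
#'
#' Splits a collection into the physico-chemistry alphabets
#' (`category == "chemistry"`) and the within-protein alphabets (all other
#' categories), builds the consensus similarity matrix of each subset and
#' complements both to distances.
#'
#' @param collection An `alphabet_collection` containing at least one
#'   alphabet of each class.
#' @return List with elements `protein` and `chemistry`, each an
#'   `aa_distance` matrix.
#' @export
category_distance_matrices <- function(collection) {
  cats <- collection_categories(collection)
  chem <- collection[cats == "chemistry"]
  prot <- collection[cats != "chemistry"]
  list(protein = similarity_to_distance(build_consensus(prot)),
       chemistry = similarity_to_distance(build_consensus(chem)))
}

#' Write a labelled matrix as TSV
#'
#' First row and first column carry the labels; cells are written with 4
#' decimal places (matching the precision used for all matrix output).
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @param digits Decimal places for cells.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, digits = 4L) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  body <- paste(rownames(m),
                apply(m, 1L, function(r) {
                  paste(formatC(r, format = "f", digits = digits),
                        collapse = "\t")
                }), sep = "\t")
  writeLines(c(paste(c("", colnames(m)), collapse = "\t"), body), path)
  invisible(path)
}

#' Read a labelled matrix from TSV
#'
#' @param path Path to a TSV written by [write_matrix_tsv()].
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  as.matrix(df)
}
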