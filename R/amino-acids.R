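#' The 20 standard amino acids in canonical order
#'
#' One-letter codes of the 20 amino acids of the standard genetic code, in the
#' fixed order `ACDEFGHIKLMNPQRSTVWY`. Every 20 x 20 matrix in the package is
#' indexed row/column `i` by letter `i` of this vector; the order is shared by
#' all modules so that matrices from different operations are cell-comparable.
#'
#' @format Character vector of length 20.
#' @export
AMINO_ACIDS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Number of informative (off-diagonal) cells in a 20 x 20 amino-acid matrix
#'
#' The main diagonal of a co-membership matrix records whether an amino acid
#' groups with itself, which carries no information, so every similarity,
#' distance and comparison statistic in the package runs over the
#' 20 x 20 - 20 = 380 off-diagonal cells only.
#'
#' @export
N_INFORMATIVE_CELLS <- 20L * 20L - 20L

# Valid derivation categories: the five ways the source studies derived their
# alphabets, plus a catch-all. "chemistry" marks studies of isolated
# amino-acid physico-chemistry; everything else is a within-protein view.
ALPHABET_CATEGORIES <- c(
  "chemistry", "sequence_alignment", "structure_alignment",
  "protein_blocks", "contact_potentials", "other"
)

# Logical off-diagonal mask for 20 x 20 matrices, reused throughout.
offdiag_mask <- function(n = 20L) {
  m <- matrix(TRUE, n, n)
  diag(m) <- FALSE
  m
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
# All seeded operations in the package funnel through here so that a single
# user-supplied seed gives reproducible results without clobbering the
# session RNG.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-stage sub-seed from a master seed so pipeline stages can be
# re-run in isolation. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587)
}
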