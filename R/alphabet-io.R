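#' Construct a simplified amino-acid alphabet
#'
#' A simplified (reduced) alphabet is a partition of the 20 standard amino
#' acids into disjoint, jointly exhaustive groups of mutually similar
#' residues. Group sizes and counts are free (1 to 20 groups); letter order
#' within a group does not affect identity.
#'
#' @param id Short unique token identifying the alphabet.
#' @param groups List of character vectors of one-letter codes, or a single
#'   comma-delimited string such as `"GAVLIMC,FWY,ST,DE,NQ,KRH,P"`.
#' @param name Free-text description (typically the source citation).
#' @param category Derivation category; one of `"chemistry"`,
#'   `"sequence_alignment"`, `"structure_alignment"`, `"protein_blocks"`,
#'   `"contact_potentials"`, `"other"`.
#' @return An object of class `simplified_alphabet` with fields `id`, `name`,
#'   `category` and `groups` (a list of sorted character vectors).
#' @examples
#' simplified_alphabet("dayhoff6", "AGPST,C,DENQ,FWY,HKR,ILMV",
#'                     name = "Dayhoff-style 6 groups",
#'                     category = "sequence_alignment")
#' @export
simplified_alphabet <- function(id, groups, name = id, category = "other") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("`id` must be a non-empty string", call. = FALSE)
  }
  if (is.character(groups) && length(groups) == 1L) {
    groups <- strsplit(strsplit(groups, ",", fixed = TRUE)[[1]], "")
  }
  if (!is.list(groups)) groups <- as.list(groups)
  groups <- lapply(groups, function(g) sort(as.character(g)))
  if (!is.character(category) || length(category) != 1L ||
      !category %in% ALPHABET_CATEGORIES) {
    stop(sprintf(
      "unknown category %s; expected one of: %s",
      deparse(category), paste(ALPHABET_CATEGORIES, collapse = ", ")
    ), call. = FALSE)
  }
  check_partition(groups)
  structure(
    list(id = id, name = as.character(name), category = category,
         groups = groups),
    class = "simplified_alphabet"
  )
}

# Validate that `groups` is a partition of the 20-letter set; errors name the
# offending letters.
check_partition <- function(groups) {
  if (length(groups) < 1L || length(groups) > 20L) {
    stop("an alphabet must have between 1 and 20 groups", call. = FALSE)
  }
  if (any(vapply(groups, length, 1L) == 0L)) {
    stop("empty group in alphabet", call. = FALSE)
  }
  letters_all <- unlist(groups, use.names = FALSE)
  unknown <- setdiff(letters_all, AMINO_ACIDS)
  if (length(unknown) > 0L) {
    stop(sprintf("partition violation: unknown letters %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  dup <- unique(letters_all[duplicated(letters_all)])
  if (length(dup) > 0L) {
    stop(sprintf("partition violation: duplicated letters %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  missing <- setdiff(AMINO_ACIDS, letters_all)
  if (length(missing) > 0L) {
    stop(sprintf("partition violation: missing letters %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.simplified_alphabet <- function(x, ...) {
  cat(sprintf("<simplified_alphabet> %s [%s], %d group%s\n  %s\n",
              x$id, x$category, length(x$groups),
              if (length(x$groups) == 1L) "" else "s",
              paste(vapply(x$groups, paste, "", collapse = ""),
                    collapse = ",")))
  invisible(x)
}

#' Membership vector of an alphabet
#'
#' Integer group label for each of the 20 amino acids in canonical order.
#'
#' @param alphabet A `simplified_alphabet`.
#' @return Named integer vector of length 20; values in `1:length(groups)`.
#' @export
alphabet_membership <- function(alphabet) {
  stopifnot(inherits(alphabet, "simplified_alphabet"))
  mem <- integer(20L)
  names(mem) <- AMINO_ACIDS
  for (k in seq_along(alphabet$groups)) {
    mem[alphabet$groups[[k]]] <- k
  }
  mem
}

#' Parse one TSV record into a simplified alphabet
#'
#' The record dialect has four tab-separated fields: `id`, `name`,
#' `category`, `groups`, where `groups` is a comma-delimited list of
#' letter runs, e.g. `"GAVLIMC,FWY,ST,DE,NQ,KRH,P"`.
#'
#' @param record A single text line.
#' @return A `simplified_alphabet`.
#' @export
parse_alphabet <- function(record) {
  stopifnot(is.character(record), length(record) == 1L)
  fields <- strsplit(record, "\t", fixed = TRUE)[[1]]
  if (length(fields) != 4L) {
    stop(sprintf("expected 4 tab-separated fields, got %d", length(fields)),
         call. = FALSE)
  }
  simplified_alphabet(id = fields[[1]], name = fields[[2]],
                      category = fields[[3]], groups = fields[[4]])
}

#' Serialize a simplified alphabet to its TSV record
#'
#' Inverse of [parse_alphabet()] up to letter order within groups.
#'
#' @param alphabet A `simplified_alphabet`.
#' @return A single text line (no trailing newline).
#' @export
format_alphabet <- function(alphabet) {
  stopifnot(inherits(alphabet, "simplified_alphabet"))
  paste(alphabet$id, alphabet$name, alphabet$category,
        paste(vapply(alphabet$groups, paste, "", collapse = ""),
              collapse = ","),
        sep = "\t")
}

#' Load a collection of simplified alphabets
#'
#' Reads one alphabet record per line; lines starting with `#` and blank
#' lines are skipped. File order is preserved.
#'
#' @param source Path to a TSV file, or a character vector of lines.
#' @return An object of class `alphabet_collection`: a named list of
#'   `simplified_alphabet` objects.
#' @export
load_collection <- function(source) {
  lines <- if (length(source) == 1L && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    as.character(source)
  }
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) {
    stop("collection is empty", call. = FALSE)
  }
  alphabets <- lapply(lines, parse_alphabet)
  as_alphabet_collection(alphabets)
}

#' Assemble an alphabet collection from a list of alphabets
#'
#' @param alphabets List of `simplified_alphabet` objects with unique ids.
#' @return An `alphabet_collection`.
#' @export
as_alphabet_collection <- function(alphabets) {
  if (length(alphabets) == 0L) stop("collection is empty", call. = FALSE)
  stopifnot(all(vapply(alphabets, inherits, TRUE, "simplified_alphabet")))
  ids <- vapply(alphabets, `[[`, "", "id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop(sprintf("duplicate alphabet ids: %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  names(alphabets) <- ids
  structure(alphabets, class = "alphabet_collection")
}

#' @export
print.alphabet_collection <- function(x, ...) {
  cat(sprintf("<alphabet_collection> %d alphabets (%s)\n", length(x),
              paste(sprintf("%s: %d",
                            names(table(collection_categories(x))),
                            as.integer(table(collection_categories(x)))),
                    collapse = ", ")))
  invisible(x)
}

#' @export
`[.alphabet_collection` <- function(x, i) {
  as_alphabet_collection(unclass(x)[i])
}

#' Derivation category of each alphabet in a collection
#' @param collection An `alphabet_collection`.
#' @return Named character vector of categories.
#' @export
collection_categories <- function(collection) {
  stopifnot(inherits(collection, "alphabet_collection"))
  vapply(collection, `[[`, "", "category")
}

#' Write a collection to a TSV file
#'
#' @param collection An `alphabet_collection`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_collection <- function(collection, path) {
  stopifnot(inherits(collection, "alphabet_collection"))
  writeLines(c("# id\tname\tcategory\tgroups",
               vapply(collection, format_alphabet, "")), path)
  invisible(path)
}

#' The bundled 34-alphabet fixture
#'
#' Loads the packaged collection of 34 reduced alphabets reconstructed from
#' the peer-reviewed literature (29 derived from amino-acid residues within
#' protein sequences/structures, 5 from the physico-chemistry of isolated
#' amino acids). The groupings are a synthetic best-effort reconstruction of
#' the cited studies -- see the file header of
#' `inst/extdata/alphabets_synthetic34.tsv` -- suitable for exercising the
#' full analysis end-to-end.
#'
#' @return An `alphabet_collection` of 34 alphabets.
#' @export
bundled_collection <- function() {
  load_collection(system.file("extdata", "alphabets_synthetic34.tsv",
                              package = "redalph", mustWork = TRUE))
}

#' Generate a random simplified alphabet
#'
#' Draws a random surjective assignment of the 20 letters onto exactly
#' `n_groups` non-empty groups: a random subset of `n_groups` letters seeds
#' one group each (guaranteeing no group is empty), and every remaining
#' letter is assigned a group label uniformly in `1:n_groups`. Deterministic
#' for a fixed seed; `n_groups = 20` forces the all-singleton partition and
#' `n_groups = 1` the single-group partition.
#'
#' @param seed Integer seed.
#' @param n_groups Number of groups, between 1 and 20.
#' @param id Id for the generated alphabet.
#' @return A `simplified_alphabet`.
#' @export
generate_random_alphabet <- function(seed, n_groups,
                                     id = sprintf("rand_s%d_k%d", seed,
                                                  n_groups)) {
  if (!is.numeric(n_groups) || n_groups < 1L || n_groups > 20L) {
    stop("`n_groups` must be between 1 and 20", call. = FALSE)
  }
  n_groups <- as.integer(n_groups)
  with_seed(seed, {
    labels <- integer(20L)
    anchors <- sample.int(20L, n_groups)
    labels[anchors] <- seq_len(n_groups)
    rest <- labels == 0L
    labels[rest] <- sample.int(n_groups, sum(rest), replace = TRUE)
    groups <- split(AMINO_ACIDS, labels)
    simplified_alphabet(id, unname(groups), name = "random partition",
                        category = "other")
  })
}

#' Generate a planted-partition collection
#'
#' Produces `n` noisy copies of a base alphabet: each letter of each copy is,
#' independently with probability `noise`, reassigned to a uniformly chosen
#' existing group of the base (possibly its own). Copies whose perturbation
#' empties a group keep the surviving groups only. Used as ground truth for
#' consensus-recovery experiments.
#'
#' @param base A `simplified_alphabet` to perturb.
#' @param n Number of alphabets to generate.
#' @param noise Per-letter reassignment probability in `[0, 1]`.
#' @param seed Integer seed; the whole collection is deterministic given it.
#' @return An `alphabet_collection` of `n` alphabets with ids
#'   `<base id>_rep<i>`.
#' @export
generate_planted_collection <- function(base, n, noise, seed) {
  stopifnot(inherits(base, "simplified_alphabet"))
  if (!is.numeric(noise) || noise < 0 || noise > 1) {
    stop("`noise` must be a probability in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(n) || n < 1L) stop("`n` must be >= 1", call. = FALSE)
  k <- length(base$groups)
  base_mem <- alphabet_membership(base)
  with_seed(seed, {
    reps <- lapply(seq_len(as.integer(n)), function(i) {
      mem <- base_mem
      flip <- stats::runif(20L) < noise
      mem[flip] <- sample.int(k, sum(flip), replace = TRUE)
      groups <- split(AMINO_ACIDS, mem)
      simplified_alphabet(sprintf("%s_rep%d", base$id, i), unname(groups),
                          name = sprintf("planted copy of %s", base$id),
                          category = base$category)
    })
    as_alphabet_collection(reps)
  })
}

# Set-of-sets equality of two alphabets (ignores ids, group order, letter
# order).
same_partition <- function(a, b) {
  key <- function(x) {
    sort(vapply(x$groups, paste, "", collapse = ""))
  }
  identical(key(a), key(b))
}
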