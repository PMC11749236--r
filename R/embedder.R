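#' Embedding backends
#'
#' A backend maps one amino-acid sequence to a fixed-width numeric vector,
#' deterministically. Two constructors are provided:
#'
#' * [hashed_backend()] — an offline stand-in: a k-mer-seeded pseudo-random
#'   projection to a unit vector. Same sequence, same vector; no model
#'   download, no network. Its vectors carry no biology beyond sequence
#'   identity, which is exactly what deterministic pipeline tests need.
#' * [custom_backend()] — wraps any user-supplied embedding function, e.g. a
#'   pretrained protein language model (the production choice is a 1280-wide
#'   transformer representation, mean-pooled over residues) driven through
#'   reticulate or an external process. The heavy model itself is an
#'   external dependency and is not bundled.
#'
#' @param dim output width (default 1280, the conventional language-model
#'   embedding width).
#' @param seed integer; varies the projection family.
#' @return an `embedder_backend` object with fields `name`, `dim`, `embed`.
#' @examples
#' b <- hashed_backend(dim = 16)
#' v <- b$embed("ACDE")
#' sqrt(sum(v^2))  # 1
#' @export
hashed_backend <- function(dim = 1280L, seed = 0L) {
  assert_scalar_number(dim, "dim", lo = 1)
  new_backend(name = sprintf("hashed-%d-%d", dim, seed), dim = as.integer(dim),
              embed = function(sequence) hashed_embedding(sequence, dim, seed))
}

#' @rdname hashed_backend
#' @param name backend label recorded in outputs.
#' @param embed function(sequence) returning a numeric vector of length `dim`.
#' @export
custom_backend <- function(name, dim, embed) {
  stopifnot(is.function(embed))
  new_backend(name = name, dim = as.integer(dim), embed = embed)
}

new_backend <- function(name, dim, embed) {
  structure(list(name = name, dim = dim, embed = embed),
            class = "embedder_backend")
}

#' Deterministic hashed sequence embedding
#'
#' Hashes the sequence's residue 3-mers with a polynomial rolling hash,
#' seeds a pseudo-random generator with `(hash, seed)`, draws `dim` normal
#' deviates, and scales the result to unit Euclidean norm. Distinct
#' sequences give near-orthogonal vectors in high dimension; identical
#' sequences give identical vectors. The caller's RNG state is untouched.
#'
#' @param sequence nonempty amino-acid string.
#' @param dim output width (>= 1).
#' @param seed integer.
#' @return numeric vector of length `dim` with unit L2 norm.
#' @export
hashed_embedding <- function(sequence, dim = 1280L, seed = 0L) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop_hiersys("hashed_embedding requires a single nonempty sequence")
  }
  assert_scalar_number(dim, "dim", lo = 1)
  codes <- utf8ToInt(toupper(sequence))
  h <- 7
  m <- 2147483647  # 2^31 - 1
  n <- length(codes)
  for (i in seq_len(max(1L, n - 2L))) {
    kmer <- sum(codes[i:min(i + 2L, n)] * c(1, 131, 17161)[seq_len(min(3L, n - i + 1L))])
    h <- (h * 131 + kmer) %% m
  }
  key <- (h + as.numeric(seed) * 7919) %% m
  v <- with_seed(as.integer(key), rnorm(dim))
  v / sqrt(sum(v^2))
}

#' Embed a collection of protein records
#'
#' @param records a `protein_records` data frame (see [read_fasta()]), or
#'   any data frame with `id` and `sequence` columns.
#' @param backend an `embedder_backend`.
#' @return numeric matrix, one row per record in input order, `backend$dim`
#'   columns, record ids as row names.
#' @export
embed_sequences <- function(records, backend) {
  stopifnot(inherits(backend, "embedder_backend"))
  n <- nrow(records)
  out <- matrix(0, nrow = n, ncol = backend$dim,
                dimnames = list(records$id, NULL))
  for (i in seq_len(n)) {
    v <- tryCatch(backend$embed(records$sequence[i]), error = function(e) {
      stop_hiersys("backend '", backend$name, "' failed on record '",
                   records$id[i], "': ", conditionMessage(e))
    })
    if (length(v) != backend$dim || any(!is.finite(v))) {
      stop_hiersys("backend '", backend$name, "' returned an invalid vector ",
                   "for record '", records$id[i], "'")
    }
    out[i, ] <- v
  }
  out
}
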