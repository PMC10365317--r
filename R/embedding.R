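# Fixed-length protein vectorization: per-residue embedders, mean pooling
# and non-overlapping chunking for length-limited embedders.
#
# An embedder is a list with fields `name`, `dim`, `max_len` (NULL when the
# embedder accepts arbitrary lengths) and `embed`, a function mapping an
# amino-acid string of r residues to an r x dim numeric matrix. Real
# language-model encoders plug in behind this contract; the package ships a
# deterministic fixture embedder for testing and simulation.

#' Create an embedder object
#'
#' @param name Embedder name (used in caches and manifests).
#' @param dim Embedding length s (columns of the per-residue matrix).
#' @param embed Function `(sequence) -> r x dim matrix`.
#' @param max_len Optional maximum residues per call; longer sequences are
#'   chunked by [embed_protein()].
#'
#' @return An object of class `embedder`.
#' @export
embedder <- function(name, dim, embed, max_len = NULL) {
  stopifnot_scalar_count(dim, "dim")
  if (!is.null(max_len)) stopifnot_scalar_count(max_len, "max_len")
  stopifnot(is.function(embed))
  structure(list(name = name, dim = as.integer(dim), embed = embed,
                 max_len = if (is.null(max_len)) NULL else as.integer(max_len)),
            class = "embedder")
}

#' Mean-pool a per-residue embedding matrix
#'
#' Averages the r x s per-residue matrix M over residues to a length-s
#' protein vector: `v_j = (1/r) * sum_i M[i, j]`.
#'
#' @param M Numeric matrix with one row per residue; all entries finite.
#' @return Numeric vector of length `ncol(M)`.
#' @export
#' @examples
#' mean_pool(rbind(c(1, 2), c(3, 4)))  # c(2, 3)
mean_pool <- function(M) {
  if (!is.matrix(M) || nrow(M) < 1L) {
    stop("mean_pool needs a matrix with at least one residue row", call. = FALSE)
  }
  if (!all(is.finite(M))) {
    stop("per-residue embedding matrix contains non-finite entries", call. = FALSE)
  }
  colMeans(M)
}

#' Embed a protein sequence as a fixed-length vector
#'
#' Runs the embedder and mean-pools the per-residue matrix. When the
#' sequence exceeds the embedder's `max_len`, it is split into
#' non-overlapping chunks of `max_len` residues plus a final remainder
#' chunk, each chunk is embedded separately, the matrices are stacked
#' row-wise, and pooling is applied to the stacked matrix -- so the result
#' for a position-independent embedder is identical to embedding in one
#' call.
#'
#' @param sequence Non-empty amino-acid string.
#' @param emb An [embedder()] object.
#' @return Numeric vector of length `emb$dim`.
#' @export
embed_protein <- function(sequence, emb) {
  stopifnot(inherits(emb, "embedder"))
  sequence <- toupper(sequence)
  r <- nchar(sequence)
  if (r < 1L) {
    stop("cannot embed an empty sequence", call. = FALSE)
  }
  if (is.null(emb$max_len) || r <= emb$max_len) {
    M <- emb$embed(sequence)
  } else {
    starts <- seq.int(1L, r, by = emb$max_len)
    chunks <- substring(sequence, starts, pmin(starts + emb$max_len - 1L, r))
    M <- do.call(rbind, lapply(chunks, emb$embed))
  }
  if (nrow(M) != r || ncol(M) != emb$dim) {
    stop(sprintf("embedder '%s' returned a %d x %d matrix for %d residues (dim %d)",
                 emb$name, nrow(M), ncol(M), r, emb$dim), call. = FALSE)
  }
  mean_pool(M)
}

#' Deterministic fixture embedder
#'
#' A position-independent stand-in for pretrained protein language models:
#' each of the 20 standard amino acids is mapped to a fixed pseudo-random
#' standard-normal vector drawn once from the seed, and a sequence embeds as
#' the matrix of its residues' vectors. The same seed always produces the
#' same embedding table, and pooled vectors are invariant to chunking and to
#' residue order.
#'
#' @param seed Integer seed for the residue-vector table.
#' @param dim Embedding length.
#' @param max_len Optional maximum residues per call, to exercise chunking.
#'
#' @return An [embedder()] object.
#' @export
#' @examples
#' emb <- fixture_embedder(seed = 1, dim = 4)
#' embed_protein("MKV", emb)
fixture_embedder <- function(seed, dim, max_len = NULL) {
  stopifnot_scalar_count(dim, "dim")
  tab <- with_seed(seed, matrix(stats::rnorm(20L * dim), nrow = 20L,
                                dimnames = list(AA_ALPHABET20, NULL)))
  embed <- function(sequence) {
    res <- strsplit(sequence, "")[[1L]]
    bad <- which(!(res %in% AA_ALPHABET20))
    if (length(bad)) {
      stop(sprintf("residue '%s' at position %d is outside the embedder alphabet",
                   res[bad[1L]], bad[1L]), call. = FALSE)
    }
    tab[res, , drop = FALSE]
  }
  embedder(name = sprintf("fixture-s%d-d%d", as.integer(seed), dim),
           dim = dim, embed = embed, max_len = max_len)
}

#' Embed a set of protein records
#'
#' @param records Protein-record `data.frame` (or a named character vector of
#'   sequences).
#' @param emb An [embedder()] object.
#' @return A `data.frame` with `protein_id` followed by `emb$dim` numeric
#'   columns `e1 ... es`.
#' @export
embed_proteins <- function(records, emb) {
  if (is.character(records)) {
    ids <- names(records)
    seqs <- unname(records)
  } else {
    ids <- records$protein_id
    seqs <- records$sequence
  }
  V <- do.call(rbind, lapply(seqs, embed_protein, emb = emb))
  colnames(V) <- paste0("e", seq_len(emb$dim))
  cbind(data.frame(protein_id = ids, stringsAsFactors = FALSE),
        as.data.frame(V))
}
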