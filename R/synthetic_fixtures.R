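# Synthetic fixtures: annotated toy corpora with planted RBPs, and
# class-separable Gaussian feature clouds. Sequences are uniform over the
# 20-letter alphabet -- mining and pooling are content-agnostic, so no
# biological realism is claimed.

RBP_PRODUCTS <- c("tail fiber protein", "tail spike protein",
                  "tailspike protein", "receptor binding protein",
                  "putative tail fibre protein", "host specificity protein J")
DECOY_PRODUCTS <- c("portal protein", "hypothetical protein",
                    "tail fiber assembly protein", "terminase large subunit",
                    "major capsid protein", "tail sheath protein")

#' Specification of a synthetic corpus
#'
#' @param n_classes Number of host genera (>= 1).
#' @param phages_per_class Phages per genus (>= 1).
#' @param rbps_per_phage Planted RBP proteins per phage (>= 1).
#' @param decoys_per_phage Non-RBP proteins per phage (>= 1).
#' @param length_range Length-two integer vector, residues per protein.
#' @param separation Distance between class centers in embedding space, in
#'   units of the noise standard deviation (>= 0).
#' @param skew Geometric decay ratio in (0, 1\] applied to per-class sizes
#'   (1 = balanced); class `c` gets `ceiling(size * skew^(c-1))` phages,
#'   exercising minority-class weighting.
#' @param seed Integer seed; all outputs are deterministic given the spec.
#'
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_classes = 3L, phages_per_class = 4L,
                        rbps_per_phage = 2L, decoys_per_phage = 1L,
                        length_range = c(200L, 600L), separation = 4,
                        skew = 1, seed = 1L) {
  for (nm in c("n_classes", "phages_per_class", "rbps_per_phage",
               "decoys_per_phage")) {
    stopifnot_scalar_count(get(nm), nm)
  }
  stopifnot(length(length_range) == 2L, length_range[1L] >= 1L,
            length_range[2L] >= length_range[1L],
            separation >= 0, skew > 0, skew <= 1)
  structure(list(n_classes = as.integer(n_classes),
                 phages_per_class = as.integer(phages_per_class),
                 rbps_per_phage = as.integer(rbps_per_phage),
                 decoys_per_phage = as.integer(decoys_per_phage),
                 length_range = as.integer(length_range),
                 separation = separation, skew = skew,
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

spec_class_sizes <- function(spec, per_class) {
  as.integer(ceiling(per_class * spec$skew^(seq_len(spec$n_classes) - 1L)))
}

synthetic_genus_names <- function(n) {
  sprintf("Genus%s", vapply(seq_len(n), function(i) {
    s <- ""
    i <- i - 1L
    repeat {
      s <- paste0(LETTERS[i %% 26L + 1L], s)
      i <- i %/% 26L - 1L
      if (i < 0L) break
    }
    s
  }, character(1)))
}

random_protein <- function(len) {
  paste(sample(AA_ALPHABET20, len, replace = TRUE), collapse = "")
}

#' Generate an annotated synthetic corpus
#'
#' Per phage, plants `rbps_per_phage` proteins with RBP-matching product
#' annotations and `decoys_per_phage` proteins with excluded or neutral
#' products; sequences are random within `length_range`; each class of
#' phages is assigned one synthetic host genus. Byte-identical output for
#' the same spec.
#'
#' @param spec A [corpus_spec()].
#' @param dir Optional directory; when given, `proteins.faa` and
#'   `hosts.tsv` are written there.
#' @return A list with `records` (protein records plus a logical
#'   `planted_rbp` column), `hosts` (`phage_id`, `host_raw`) and, when `dir`
#'   is given, `paths`.
#' @export
generate_corpus <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "corpus_spec"))
  genera <- synthetic_genus_names(spec$n_classes)
  sizes <- spec_class_sizes(spec, spec$phages_per_class)
  rows <- with_seed(spec$seed, {
    out <- list()
    for (ci in seq_len(spec$n_classes)) {
      for (pi in seq_len(sizes[ci])) {
        phage <- sprintf("phage_%s_%02d", genera[ci], pi)
        n_prot <- spec$rbps_per_phage + spec$decoys_per_phage
        for (k in seq_len(n_prot)) {
          is_rbp <- k <= spec$rbps_per_phage
          prod_pool <- if (is_rbp) RBP_PRODUCTS else DECOY_PRODUCTS
          len <- sample(spec$length_range[1L]:spec$length_range[2L], 1L)
          out[[length(out) + 1L]] <- data.frame(
            protein_id = sprintf("%s_p%02d", phage, k),
            phage_id = phage,
            product = sample(prod_pool, 1L),
            sequence = random_protein(len),
            genus = genera[ci],
            planted_rbp = is_rbp,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    do.call(rbind, out)
  })
  records <- protein_records(rows$protein_id, rows$phage_id, rows$product,
                             rows$sequence)
  records$planted_rbp <- rows$planted_rbp
  hosts <- unique(data.frame(phage_id = rows$phage_id, host_raw = rows$genus,
                             stringsAsFactors = FALSE))
  res <- list(records = records, hosts = hosts)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fasta <- file.path(dir, "proteins.faa")
    tsv <- file.path(dir, "hosts.tsv")
    write_protein_fasta(records, fasta)
    utils::write.table(hosts, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    res$paths <- c(fasta = fasta, hosts = tsv)
  }
  res
}

#' Generate class-separable labeled feature examples
#'
#' Draws, for every class, an isotropic unit-variance Gaussian cloud around
#' a class center; centers sit at the vertices of a regular simplex with
#' pairwise distance `separation` (in noise-standard-deviation units), so
#' `separation = 0` collapses all classes onto one distribution and large
#' values make them linearly separable. Class sizes follow the spec's skew.
#'
#' @param spec A [corpus_spec()]; examples per class =
#'   `phages_per_class * rbps_per_phage`, decayed by `skew`.
#' @param dim Feature dimension (>= `n_classes` so the simplex embeds).
#' @return A labeled example `data.frame` (see [labeled_examples()]).
#' @export
generate_separable_examples <- function(spec, dim) {
  stopifnot(inherits(spec, "corpus_spec"))
  stopifnot_scalar_count(dim, "dim")
  if (dim < spec$n_classes) {
    stop("dim must be at least n_classes to place the class simplex",
         call. = FALSE)
  }
  genera <- synthetic_genus_names(spec$n_classes)
  sizes <- spec_class_sizes(spec, spec$phages_per_class * spec$rbps_per_phage)
  # simplex on scaled unit vectors: |a e_i - a e_j| = a sqrt(2) = separation
  a <- spec$separation / sqrt(2)
  centers <- diag(dim)[seq_len(spec$n_classes), , drop = FALSE] * a
  X <- with_seed(derive_seed(spec$seed, 7L), {
    do.call(rbind, lapply(seq_len(spec$n_classes), function(ci) {
      n <- sizes[ci]
      matrix(stats::rnorm(n * dim), nrow = n) +
        matrix(centers[ci, ], nrow = n, ncol = dim, byrow = TRUE)
    }))
  })
  colnames(X) <- paste0("e", seq_len(dim))
  labels <- rep(genera, sizes)
  labeled_examples(
    protein_id = sprintf("ex_%05d", seq_len(nrow(X))),
    label = labels, features = X
  )
}
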