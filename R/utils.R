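# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Amino-acid alphabet used throughout (20 standard residues).
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Reserved rejection label. Genus names are capitalized Latin binomial stems,
# so the lowercase token cannot collide with a standardized genus.
OTHERS_LABEL <- "others"

#' Reserved "others" class label
#'
#' Returns the reserved label used for test examples whose host genus lies
#' outside the trained class set, and for predictions rejected by the
#' confidence threshold. Treated as a first-class label during evaluation.
#'
#' @return A length-one character string.
#' @export
#' @examples
#' others_label()
others_label <- function() OTHERS_LABEL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls stay side-effect free.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a child seed from a master seed, kept within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% .Machine$integer.max)
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    stop(sprintf("`%s` must be a single positive integer", name), call. = FALSE)
  }
}

# Collapse internal whitespace and trim, for annotation matching.
squish <- function(x) {
  gsub("^\\s+|\\s+$", "", gsub("\\s+", " ", x))
}
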