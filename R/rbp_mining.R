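# Mining receptor-binding proteins (RBPs) from annotated phage proteomes.
#
# RBPs -- tail fibers, tailspikes and related adsorption proteins -- are
# selected from free-text product annotations by inclusion/exclusion regular
# expressions, then filtered for undetermined residues and outlying lengths.

#' Construct a protein-record table
#'
#' The common currency of the mining module: one row per phage protein with
#' its identifier, parent phage, free-text product annotation and amino-acid
#' sequence.
#'
#' @param protein_id Character vector of unique protein identifiers.
#' @param phage_id Character vector of parent phage identifiers.
#' @param product Character vector of free-text product annotations.
#' @param sequence Character vector of amino-acid sequences (uppercase
#'   one-letter code); must be non-empty.
#'
#' @return A `data.frame` with columns `protein_id`, `phage_id`, `product`,
#'   `sequence` and `length`.
#' @export
protein_records <- function(protein_id, phage_id, product, sequence) {
  protein_id <- as.character(protein_id)
  sequence <- toupper(as.character(sequence))
  if (any(!nzchar(sequence))) {
    stop("every protein sequence must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(protein_id)) {
    stop("protein_id values must be unique within a corpus", call. = FALSE)
  }
  data.frame(
    protein_id = protein_id,
    phage_id = as.character(phage_id),
    product = as.character(product),
    sequence = sequence,
    length = nchar(sequence),
    stringsAsFactors = FALSE
  )
}

#' Read phage protein records from GenBank or annotated FASTA
#'
#' GenBank flat files yield one record per CDS feature carrying a
#' `/translation` qualifier; the product is taken from the `/product`
#' qualifier and the phage identifier from the parent record's accession.
#' FASTA description lines are parsed for `phage=` and `product=` key--value
#' pairs (the product runs to the end of the line); the first header token is
#' the protein identifier.
#'
#' @param source Path to a `.gb`/`.gbk`/`.gbff` GenBank flat file or a
#'   FASTA file.
#' @param format `"auto"` (by file extension), `"genbank"` or `"fasta"`.
#'
#' @return A protein-record `data.frame` (see [protein_records()]); zero rows
#'   for an empty file.
#' @export
read_protein_records <- function(source, format = c("auto", "genbank", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(source)) {
    stop(sprintf("cannot read '%s': no such file", source), call. = FALSE)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(source))
    format <- if (ext %in% c("gb", "gbk", "gbff", "genbank")) "genbank" else "fasta"
  }
  if (format == "genbank") {
    read_genbank_proteins(source)
  } else {
    read_fasta_proteins(source)
  }
}

# Minimal GenBank flat-file parser: extracts accession and, per CDS feature,
# the /product, /protein_id and /translation qualifiers. Feature keys start
# at column 6; qualifier and continuation lines are indented to column 22.
read_genbank_proteins <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    return(empty_protein_records())
  }
  rec_breaks <- grep("^//", lines)
  rec_starts <- grep("^LOCUS", lines)
  if (length(rec_starts) == 0L) {
    stop(sprintf("'%s' does not look like a GenBank flat file (no LOCUS line)", path),
         call. = FALSE)
  }
  rec_ends <- vapply(rec_starts, function(s) {
    nxt <- rec_breaks[rec_breaks > s]
    if (length(nxt)) nxt[1L] else length(lines)
  }, integer(1))

  out <- vector("list", length(rec_starts))
  for (r in seq_along(rec_starts)) {
    block <- lines[rec_starts[r]:rec_ends[r]]
    acc_line <- grep("^ACCESSION", block, value = TRUE)
    phage_id <- if (length(acc_line)) {
      strsplit(squish(sub("^ACCESSION", "", acc_line[1L])), " ")[[1L]][1L]
    } else {
      strsplit(squish(sub("^LOCUS", "", block[1L])), " ")[[1L]][1L]
    }
    out[[r]] <- parse_genbank_cds(block, phage_id)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) empty_protein_records() else res
}

parse_genbank_cds <- function(block, phage_id) {
  feat_start <- grep("^FEATURES", block)
  if (!length(feat_start)) {
    return(NULL)
  }
  feat_end <- grep("^ORIGIN", block)
  feat_end <- if (length(feat_end)) feat_end[1L] - 1L else length(block)
  feats <- block[(feat_start[1L] + 1L):feat_end]
  # Feature key lines have a non-space at column 6 and spaces before it.
  is_key <- grepl("^ {5}\\S", feats)
  key_idx <- which(is_key)
  keys <- sub("^ {5}(\\S+).*", "\\1", feats[key_idx])
  cds_pos <- key_idx[keys == "CDS"]
  if (!length(cds_pos)) {
    return(NULL)
  }
  records <- list()
  for (i in cds_pos) {
    nxt <- key_idx[key_idx > i]
    stop_at <- if (length(nxt)) nxt[1L] - 1L else length(feats)
    quals <- parse_genbank_qualifiers(feats[(i + 1L):min(stop_at, length(feats))])
    if (is.null(quals[["translation"]]) || !nzchar(quals[["translation"]])) {
      warning(sprintf("CDS without /translation in record '%s' skipped", phage_id),
              call. = FALSE)
      next
    }
    pid <- quals[["protein_id"]]
    if (is.null(pid)) pid <- sprintf("%s_cds%d", phage_id, i)
    prod <- quals[["product"]]
    if (is.null(prod)) prod <- ""
    records[[length(records) + 1L]] <- data.frame(
      protein_id = pid, phage_id = phage_id, product = prod,
      sequence = gsub("\\s", "", quals[["translation"]]),
      stringsAsFactors = FALSE
    )
  }
  if (!length(records)) {
    return(NULL)
  }
  res <- do.call(rbind, records)
  res$length <- nchar(res$sequence)
  res
}

# Qualifier lines within one feature; values may span continuation lines.
parse_genbank_qualifiers <- function(lines) {
  lines <- lines[!grepl("^ {5}\\S", lines)]
  txt <- squish(paste(lines, collapse = " "))
  pieces <- strsplit(paste0(" ", txt), " /")[[1L]][-1L]
  quals <- list()
  for (p in pieces) {
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq == -1L) {
      quals[[p]] <- TRUE
    } else {
      key <- substr(p, 1L, eq - 1L)
      val <- substr(p, eq + 1L, nchar(p))
      val <- gsub("^\"|\"$", "", val)
      if (key == "translation") val <- gsub(" ", "", val)
      quals[[key]] <- val
    }
  }
  quals
}

read_fasta_proteins <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) {
    return(empty_protein_records())
  }
  headers <- names(seqs)
  protein_id <- vapply(strsplit(headers, "\\s+"), `[[`, character(1), 1L)
  phage_id <- ifelse(grepl("phage=(\\S+)", headers),
                     sub(".*phage=(\\S+).*", "\\1", headers), protein_id)
  product <- ifelse(grepl("product=", headers),
                    sub(".*product=", "", headers), "")
  protein_records(protein_id, phage_id, squish(product), as.character(seqs))
}

empty_protein_records <- function() {
  data.frame(protein_id = character(), phage_id = character(),
             product = character(), sequence = character(),
             length = integer(), stringsAsFactors = FALSE)
}

#' Annotation rule set for RBP selection
#'
#' A record is selected iff its product matches at least one inclusion
#' pattern and no exclusion pattern; matching is case-insensitive on
#' whitespace-normalized product text. The defaults cover the usual RBP
#' annotations (tail fiber/fibre, tail spike, receptor binding, host
#' specificity, distal tail) and exclude RBP-adjacent structural proteins
#' (assembly, portal, chaperone, sheath, tape measure, terminase); both
#' lists are fully overridable.
#'
#' @param inclusion Character vector of regular-expression patterns.
#' @param exclusion Character vector of regular-expression patterns.
#'
#' @return An object of class `rbp_rules`.
#' @export
#' @examples
#' rules <- rbp_rules()
#' rules$inclusion
rbp_rules <- function(inclusion = default_inclusion_patterns(),
                      exclusion = default_exclusion_patterns()) {
  inclusion <- as.character(inclusion)
  exclusion <- as.character(exclusion)
  if (!length(inclusion) || !length(exclusion)) {
    stop("inclusion and exclusion pattern lists must both be non-empty",
         call. = FALSE)
  }
  for (p in c(inclusion, exclusion)) {
    ok <- tryCatch({ suppressWarnings(grepl(p, "x", perl = TRUE)); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop(sprintf("pattern does not compile: '%s'", p), call. = FALSE)
  }
  structure(list(inclusion = inclusion, exclusion = exclusion),
            class = "rbp_rules")
}

#' @rdname rbp_rules
#' @export
default_inclusion_patterns <- function() {
  c("tail ?fib(er|re)", "tail ?spike", "receptor(-| )binding", "\\bRBP\\b",
    "host specificity", "distal tail")
}

#' @rdname rbp_rules
#' @export
default_exclusion_patterns <- function() {
  c("assembly", "portal", "chaperone", "sheath", "tape measure", "terminase")
}

#' Select receptor-binding proteins by annotation
#'
#' @param records Protein-record `data.frame`.
#' @param rules An [rbp_rules()] object.
#'
#' @return The subset of `records` (order preserved) whose product matches at
#'   least one inclusion pattern and no exclusion pattern.
#' @export
select_rbps <- function(records, rules = rbp_rules()) {
  stopifnot(inherits(rules, "rbp_rules"))
  if (nrow(records) == 0L) {
    return(records)
  }
  prod <- squish(records$product)
  inc <- Reduce(`|`, lapply(rules$inclusion, function(p) {
    grepl(p, prod, ignore.case = TRUE, perl = TRUE)
  }))
  exc <- Reduce(`|`, lapply(rules$exclusion, function(p) {
    grepl(p, prod, ignore.case = TRUE, perl = TRUE)
  }))
  records[inc & !exc, , drop = FALSE]
}

#' Drop sequences with undetermined residues
#'
#' Removes records whose sequence contains the undetermined amino-acid
#' character `X`.
#'
#' @param records Protein-record `data.frame`.
#' @return The subset without any `X` in the sequence.
#' @export
drop_undetermined <- function(records) {
  records[!grepl("X", records$sequence, fixed = TRUE), , drop = FALSE]
}

#' Interquartile-range length bounds
#'
#' Computes the first and third quartiles (linear interpolation between order
#' statistics, the type-7 convention) of a set of sequence lengths and the
#' outlier fence `[Q1 - 1.5*IQR, Q3 + 1.5*IQR]`.
#'
#' @param lengths Numeric vector of residue counts (at least two).
#' @return An object of class `length_bounds` with fields `q1`, `q3`, `iqr`,
#'   `lower` and `upper`.
#' @export
#' @examples
#' compute_length_bounds(c(100, 200, 300, 400, 500))
compute_length_bounds <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (length(lengths) < 2L || anyNA(lengths)) {
    stop("need at least two non-missing lengths to compute quartile bounds",
         call. = FALSE)
  }
  q <- stats::quantile(lengths, probs = c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2L] - q[1L]
  structure(
    list(q1 = q[1L], q3 = q[2L], iqr = iqr,
         lower = q[1L] - 1.5 * iqr, upper = q[2L] + 1.5 * iqr),
    class = "length_bounds"
  )
}

#' @export
print.length_bounds <- function(x, ...) {
  cat(sprintf("Length bounds: Q1=%.6g Q3=%.6g IQR=%.6g -> [%.6g, %.6g]\n",
              x$q1, x$q3, x$iqr, x$lower, x$upper))
  invisible(x)
}

#' Filter records by length bounds
#'
#' Retains records whose length lies in the closed interval
#' `[lower, upper]` of `bounds`.
#'
#' @param records Protein-record `data.frame`.
#' @param bounds A [compute_length_bounds()] result.
#' @return The retained subset.
#' @export
filter_by_length <- function(records, bounds) {
  stopifnot(inherits(bounds, "length_bounds"))
  records[records$length >= bounds$lower & records$length <= bounds$upper, ,
          drop = FALSE]
}

#' Full RBP mining pipeline
#'
#' Annotation selection, undetermined-residue filter and IQR length filter in
#' the standard order. The length fence is computed on the annotated pool
#' after the X filter.
#'
#' @param records Protein-record `data.frame`.
#' @param rules An [rbp_rules()] object.
#' @param length_filter Apply the IQR length fence (needs at least two
#'   surviving records; skipped with a warning otherwise).
#'
#' @return A list with `rbps` (the retained records), `bounds` (the length
#'   fence or `NULL`) and `catalog` (a per-input-record `data.frame` with a
#'   `kept`/`dropped` status and reason).
#' @export
mine_rbps <- function(records, rules = rbp_rules(), length_filter = TRUE) {
  status <- rep("dropped:annotation", nrow(records))
  sel <- select_rbps(records, rules)
  status[records$protein_id %in% sel$protein_id] <- "kept"
  nox <- drop_undetermined(sel)
  status[records$protein_id %in% setdiff(sel$protein_id, nox$protein_id)] <-
    "dropped:undetermined"
  bounds <- NULL
  kept <- nox
  if (length_filter) {
    if (nrow(nox) >= 2L) {
      bounds <- compute_length_bounds(nox$length)
      kept <- filter_by_length(nox, bounds)
      status[records$protein_id %in% setdiff(nox$protein_id, kept$protein_id)] <-
        "dropped:length"
    } else {
      warning("fewer than two candidate RBPs; length filter skipped",
              call. = FALSE)
    }
  }
  catalog <- data.frame(
    protein_id = records$protein_id, phage_id = records$phage_id,
    product = records$product, length = records$length,
    status = status, stringsAsFactors = FALSE
  )
  list(rbps = kept, bounds = bounds, catalog = catalog)
}

#' Write protein records as FASTA
#'
#' Headers carry `phage=` and `product=` key--value pairs so the file round
#' trips through [read_protein_records()].
#'
#' @param records Protein-record `data.frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(records, path) {
  seqs <- Biostrings::AAStringSet(records$sequence)
  names(seqs) <- sprintf("%s phage=%s product=%s",
                         records$protein_id, records$phage_id, records$product)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
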