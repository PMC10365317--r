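# Handcrafted genomic and protein sequence properties used in the
# embedding-integration experiments: nucleotide and codon composition of the
# RBP coding sequence, and amino-acid composition, isoelectric point,
# fourth Z-scale mean and molecular weight of the protein.
#
# The pKa, Z-scale and residue-mass tables are shipped as TSV data files so
# tests and implementation read one source.

feature_table_env <- new.env(parent = emptyenv())

read_shipped_table <- function(file) {
  cached <- feature_table_env[[file]]
  if (!is.null(cached)) {
    return(cached)
  }
  path <- system.file("extdata", file, package = "rbphost", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  feature_table_env[[file]] <- tab
  tab
}

#' Shipped physicochemical tables
#'
#' Accessors for the data files behind the protein sequence properties:
#' average residue masses, a Bjellqvist-style pKa set for ionizable groups,
#' and the Sandberg five-component Z-scales.
#'
#' @return A `data.frame` (see the corresponding TSV under `extdata`).
#' @export
aa_mass_table <- function() read_shipped_table("aa_average_mass.tsv")

#' @rdname aa_mass_table
#' @export
pka_table <- function() read_shipped_table("pka_bjellqvist.tsv")

#' @rdname aa_mass_table
#' @export
zscale_table <- function() read_shipped_table("zscales_sandberg.tsv")

check_nucleotide <- function(gene) {
  gene <- toupper(gene)
  if (!nzchar(gene)) stop("gene sequence must be non-empty", call. = FALSE)
  if (grepl("[^ACGT]", gene)) {
    stop("gene sequence contains characters outside A/C/G/T", call. = FALSE)
  }
  gene
}

check_protein <- function(sequence) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("protein sequence must be non-empty", call. = FALSE)
  res <- strsplit(sequence, "")[[1L]]
  bad <- setdiff(unique(res), AA_ALPHABET20)
  if (length(bad)) {
    stop(sprintf("invalid residue(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  res
}

#' Nucleotide frequency
#'
#' Fraction of positions in a gene equal to the given base.
#'
#' @param gene Nucleotide string over A/C/G/T.
#' @param base One of `"A"`, `"C"`, `"G"`, `"T"`.
#' @return A fraction in \[0, 1\].
#' @export
nucleotide_frequency <- function(gene, base) {
  gene <- check_nucleotide(gene)
  base <- match.arg(toupper(base), c("A", "C", "G", "T"))
  lengths(regmatches(gene, gregexpr(base, gene, fixed = TRUE))) / nchar(gene)
}

#' GC content
#'
#' @param gene Nucleotide string over A/C/G/T.
#' @return Fraction of G or C positions.
#' @export
gc_content <- function(gene) {
  gene <- check_nucleotide(gene)
  lengths(regmatches(gene, gregexpr("[GC]", gene))) / nchar(gene)
}

split_codons <- function(gene) {
  gene <- check_nucleotide(gene)
  if (nchar(gene) %% 3L != 0L) {
    stop("gene length must be divisible by 3 for codon features", call. = FALSE)
  }
  starts <- seq.int(1L, nchar(gene), by = 3L)
  substring(gene, starts, starts + 2L)
}

#' Codon frequency
#'
#' Fraction of in-frame codons equal to the given codon.
#'
#' @param gene Nucleotide string over A/C/G/T with length divisible by 3.
#' @param codon A 3-mer, e.g. `"TTA"`.
#' @return A fraction in \[0, 1\].
#' @export
codon_frequency <- function(gene, codon = "TTA") {
  codons <- split_codons(gene)
  codon <- toupper(codon)
  stopifnot(nchar(codon) == 3L)
  sum(codons == codon) / length(codons)
}

#' Codon usage bias
#'
#' Relative synonymous usage: occurrences of the codon divided by
#' occurrences of all codons encoding the same amino acid (standard genetic
#' code). Returns 0 when the amino acid does not occur in the gene.
#'
#' @inheritParams codon_frequency
#' @return A fraction in \[0, 1\].
#' @export
codon_usage_bias <- function(gene, codon = "TTA") {
  codons <- split_codons(gene)
  codon <- toupper(codon)
  code <- Biostrings::GENETIC_CODE
  if (is.na(code[codon])) {
    stop(sprintf("'%s' is not a codon of the standard genetic code", codon),
         call. = FALSE)
  }
  aa <- code[[codon]]
  if (aa == "*") {
    stop("codon usage bias is undefined for stop codons", call. = FALSE)
  }
  synonyms <- names(code)[code == aa]
  fam <- sum(codons %in% synonyms)
  if (fam == 0L) {
    return(0)
  }
  sum(codons == codon) / fam
}

#' Amino-acid frequency
#'
#' @param sequence Protein string over the 20-letter alphabet.
#' @param residue Single residue letter, e.g. `"K"` for lysine.
#' @return A fraction in \[0, 1\].
#' @export
aa_frequency <- function(sequence, residue = "K") {
  res <- check_protein(sequence)
  residue <- toupper(residue)
  if (!(residue %in% AA_ALPHABET20)) {
    stop(sprintf("invalid residue '%s'", residue), call. = FALSE)
  }
  sum(res == residue) / length(res)
}

# Net charge of a peptide at a given pH under Henderson-Hasselbalch, using
# the shipped pKa table (termini plus ionizable side chains).
peptide_net_charge <- function(residues, pH) {
  pka <- pka_table()
  counts <- c(Nterm = 1, Cterm = 1, table(residues)[pka$group[-(1:2)]])
  counts[is.na(counts)] <- 0
  names(counts) <- pka$group
  pos <- pka$charge == "positive"
  charge_pos <- sum(counts[pos] / (1 + 10^(pH - pka$pka[pos])))
  charge_neg <- sum(counts[!pos] / (1 + 10^(pka$pka[!pos] - pH)))
  charge_pos - charge_neg
}

#' Isoelectric point
#'
#' pH at which the peptide's Henderson--Hasselbalch net charge (termini plus
#' ionizable side chains, shipped pKa table) is zero, found by bisection on
#' \[0, 14\] to a tolerance of 1e-4 pH units.
#'
#' @param sequence Protein string over the 20-letter alphabet.
#' @return pI in pH units.
#' @export
#' @examples
#' isoelectric_point("ACDEFGHIK")
isoelectric_point <- function(sequence) {
  res <- check_protein(sequence)
  lo <- 0
  hi <- 14
  # net charge is strictly decreasing in pH, so bisection converges
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (peptide_net_charge(res, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Mean fourth Z-scale
#'
#' Arithmetic mean over residues of the fourth Sandberg Z-scale component
#' (related to heat of formation, hardness, electronegativity and
#' electrophilicity).
#'
#' @param sequence Protein string over the 20-letter alphabet.
#' @return Dimensionless Z-scale units.
#' @export
z4_mean <- function(sequence) {
  res <- check_protein(sequence)
  z <- zscale_table()
  mean(z$z4[match(res, z$residue)])
}

#' Molecular weight
#'
#' Sum of average residue masses (shipped table) plus one water (18.02 Da).
#'
#' @param sequence Protein string over the 20-letter alphabet.
#' @return Mass in daltons.
#' @export
#' @examples
#' molecular_weight("G")  # 75.07
molecular_weight <- function(sequence) {
  res <- check_protein(sequence)
  m <- aa_mass_table()
  sum(m$avg_mass[match(res, m$residue)]) + 18.02
}

#' Concatenate handcrafted features to an embedding
#'
#' @param embedding Numeric protein-embedding vector.
#' @param extras Named or unnamed numeric vector of additional feature
#'   values, appended after the embedding in the given order.
#' @return Numeric vector of length `length(embedding) + length(extras)`.
#' @export
concat_features <- function(embedding, extras = numeric(0)) {
  extras <- unlist(extras, use.names = TRUE)
  if (length(extras) && !all(is.finite(extras))) {
    stop("all extra feature values must be finite", call. = FALSE)
  }
  if (!all(is.finite(embedding))) {
    stop("embedding contains non-finite values", call. = FALSE)
  }
  c(embedding, extras)
}

#' Compute the named handcrafted feature panel for one RBP
#'
#' The genomic panel (A frequency, GC content, C frequency, TTA codon
#' frequency, TTA codon usage bias) requires the protein's in-frame coding
#' sequence; the protein panel (lysine frequency, isoelectric point, mean
#' fourth Z-scale, molecular weight) needs only the amino-acid sequence.
#'
#' @param sequence Protein string.
#' @param gene Optional in-frame coding nucleotide sequence for the same
#'   protein.
#' @return Named numeric vector; genomic entries are `NA` when `gene` is
#'   missing.
#' @export
handcrafted_panel <- function(sequence, gene = NULL) {
  prot <- c(
    freq_K = aa_frequency(sequence, "K"),
    isoelectric_point = isoelectric_point(sequence),
    z4_mean = z4_mean(sequence),
    molecular_weight = molecular_weight(sequence)
  )
  genomic <- if (is.null(gene)) {
    c(freq_A = NA_real_, gc_content = NA_real_, freq_C = NA_real_,
      codon_freq_TTA = NA_real_, codon_usage_bias_TTA = NA_real_)
  } else {
    c(freq_A = nucleotide_frequency(gene, "A"),
      gc_content = gc_content(gene),
      freq_C = nucleotide_frequency(gene, "C"),
      codon_freq_TTA = codon_frequency(gene, "TTA"),
      codon_usage_bias_TTA = codon_usage_bias(gene, "TTA"))
  }
  c(genomic, prot)
}
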