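# Shared fixtures built in code at test time.

# A two-CDS GenBank record (plus one CDS without a translation) written to a
# temporary flat file.
write_test_genbank <- function(path, accession = "TEST0001",
                               with_untranslated = FALSE) {
  cds <- function(pid, product, seq) {
    c("     CDS             1..100",
      sprintf("                     /product=\"%s\"", product),
      sprintf("                     /protein_id=\"%s\"", pid),
      "                     /translation=\"",
      # split translation across continuation lines like real records
      paste0("                     ", substr(seq, 1, 30)),
      paste0("                     ", substr(seq, 31, nchar(seq)), "\""))
  }
  lines <- c(
    sprintf("LOCUS       %s              1000 bp    DNA     linear PHG", accession),
    "DEFINITION  synthetic test phage.",
    sprintf("ACCESSION   %s", accession),
    "FEATURES             Location/Qualifiers",
    "     source          1..1000",
    "                     /organism=\"synthetic phage\"",
    cds(paste0(accession, "_1"), "tail fiber protein",
        paste(rep("MKVLTAGHIE", 5), collapse = "")),
    cds(paste0(accession, "_2"), "portal protein",
        paste(rep("MASTGHKLIE", 5), collapse = "")),
    cds(paste0(accession, "_3"), "hypothetical protein",
        paste(rep("MHEILKAGTV", 5), collapse = ""))
  )
  if (with_untranslated) {
    lines <- c(lines,
               "     CDS             200..300",
               "                     /product=\"tRNA-like protein\"")
  }
  lines <- c(lines, "ORIGIN", "//")
  writeLines(lines, path)
  path
}

# Independent type-7 quartile: linear interpolation between order statistics,
# written out from the definition rather than calling quantile().
type7_quartile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
}

# Independent support-weighted one-vs-rest metrics from raw labels, used as
# the oracle for the weighted-metric implementation.
oracle_weighted_metrics <- function(truths, predictions, classes) {
  N <- length(truths)
  acc <- c(precision = 0, recall = 0, specificity = 0, f1 = 0)
  for (cl in classes) {
    tp <- sum(truths == cl & predictions == cl)
    fp <- sum(truths != cl & predictions == cl)
    fn <- sum(truths == cl & predictions != cl)
    tn <- N - tp - fp - fn
    n_c <- tp + fn
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (n_c > 0) tp / n_c else 0
    spec <- if (tn + fp > 0) tn / (tn + fp) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    acc <- acc + n_c * c(prec, rec, spec, f1)
  }
  acc / N
}
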