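# Host-label preprocessing: genus standardization and polyvalent resolution.

#' Standardize a raw host name to genus
#'
#' Looks the raw name up in a synonym map first; otherwise takes the first
#' whitespace-delimited token with initial capitalization (the genus under
#' binomial nomenclature).
#'
#' @param raw_name Character vector of raw host names (non-empty strings).
#' @param synonym_map Optional named character vector mapping raw names to
#'   canonical genus names.
#'
#' @return Character vector of genus names.
#' @export
#' @examples
#' standardize_genus("Escherichia coli K-12")
#' standardize_genus("salmonella enterica")
#' standardize_genus("E. coli", c("E. coli" = "Escherichia"))
standardize_genus <- function(raw_name, synonym_map = NULL) {
  raw_name <- as.character(raw_name)
  if (any(is.na(raw_name) | !nzchar(trimws(raw_name)))) {
    stop("host names must be non-empty", call. = FALSE)
  }
  out <- character(length(raw_name))
  mapped <- if (!is.null(synonym_map)) raw_name %in% names(synonym_map) else
    rep(FALSE, length(raw_name))
  out[mapped] <- unname(synonym_map[raw_name[mapped]])
  if (any(!mapped)) {
    tok <- vapply(strsplit(trimws(raw_name[!mapped]), "\\s+"), `[[`,
                  character(1), 1L)
    out[!mapped] <- paste0(toupper(substr(tok, 1L, 1L)),
                           tolower(substr(tok, 2L, nchar(tok))))
  }
  out
}

#' Read a phage--host table
#'
#' Expects a TSV with columns `phage_id` and `host_raw` (one row per
#' phage--host pair; polyvalent phages appear on several rows). An optional
#' `host_genus` column overrides standardization for that row, which is how
#' isolation-host fallbacks or non-bacterial exclusions are supplied.
#'
#' @param path TSV path.
#' @param synonym_map Optional named character vector passed to
#'   [standardize_genus()].
#'
#' @return A `data.frame` with columns `phage_id` and `genus`, one row per
#'   distinct phage--genus pair.
#' @export
read_host_table <- function(path, synonym_map = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("phage_id", "host_raw") %in% names(tab))) {
    stop("host table needs columns 'phage_id' and 'host_raw'", call. = FALSE)
  }
  genus <- if ("host_genus" %in% names(tab)) {
    ifelse(!is.na(tab$host_genus) & nzchar(tab$host_genus),
           tab$host_genus, standardize_genus(tab$host_raw, synonym_map))
  } else {
    standardize_genus(tab$host_raw, synonym_map)
  }
  unique(data.frame(phage_id = as.character(tab$phage_id), genus = genus,
                    stringsAsFactors = FALSE))
}

#' Resolve polyvalent phages to a single host genus
#'
#' A phage listed with several host genera is assigned the member genus that
#' interacts with the largest number of phages in the whole table; ties are
#' broken lexicographically. Counts are global: each phage contributes once
#' to every genus it lists, before any resolution.
#'
#' @param host_table `data.frame` with columns `phage_id` and `genus` (one
#'   row per pair), e.g. from [read_host_table()].
#'
#' @return A `data.frame` with columns `phage_id` and `genus`, one row per
#'   phage.
#' @export
#' @examples
#' tab <- data.frame(
#'   phage_id = c("p1", "p2", "p3", "p3"),
#'   genus = c("Escherichia", "Escherichia", "Escherichia", "Bacillus")
#' )
#' resolve_polyvalent(tab)  # p3 -> Escherichia (2 phages vs 1)
resolve_polyvalent <- function(host_table) {
  stopifnot(all(c("phage_id", "genus") %in% names(host_table)))
  if (any(is.na(host_table$genus) | !nzchar(host_table$genus))) {
    stop("every phage must have at least one non-empty genus", call. = FALSE)
  }
  pairs <- unique(host_table[, c("phage_id", "genus")])
  counts <- table(pairs$genus)
  resolved <- vapply(split(pairs$genus, pairs$phage_id), function(gs) {
    if (length(gs) == 1L) {
      return(gs)
    }
    n <- counts[gs]
    cand <- gs[n == max(n)]
    sort(cand)[1L]
  }, character(1))
  data.frame(phage_id = names(resolved), genus = unname(resolved),
             stringsAsFactors = FALSE)
}
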