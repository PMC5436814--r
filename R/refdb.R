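#' Load a curated reference amplicon database
#'
#' Reads reference sequences from FASTA (header word = accession, remainder
#' an optional description) and joins them to a delimited taxonomy table by
#' accession. Sequences are normalised to uppercase; the IUPAC alphabet is
#' enforced.
#'
#' @param fasta_path path to a FASTA file of reference sequences.
#' @param taxonomy_path path to a tab-delimited taxonomy table with columns
#'   `accession`, `species`, and optionally `higher_taxon`.
#' @return a `reference_db`: a data frame with columns `accession`,
#'   `species`, `higher_taxon`, `sequence`, `source`.
#' @export
load_reference_db <- function(fasta_path, taxonomy_path) {
  seqs <- tryCatch(Biostrings::readDNAStringSet(fasta_path),
                   error = function(e) {
                     stop(sprintf("malformed FASTA '%s': %s", fasta_path,
                                  conditionMessage(e)), call. = FALSE)
                   })
  accession <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(accession)) {
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(accession[duplicated(accession)]), collapse = ", "),
         call. = FALSE)
  }
  tax <- read.table(taxonomy_path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, quote = "")
  if (!all(c("accession", "species") %in% names(tax))) {
    stop("taxonomy table must have columns 'accession' and 'species'",
         call. = FALSE)
  }
  if (anyDuplicated(tax$accession)) {
    stop("duplicate accession(s) in taxonomy table: ",
         paste(unique(tax$accession[duplicated(tax$accession)]),
               collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(accession, tax$accession)
  if (length(missing)) {
    stop("no taxonomy row for accession(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  idx <- match(accession, tax$accession)
  sequence <- toupper(as.character(seqs))
  assert_iupac(sequence, "reference sequence")
  db <- data.frame(
    accession = accession,
    species = tax$species[idx],
    higher_taxon = if ("higher_taxon" %in% names(tax))
      tax$higher_taxon[idx] else NA_character_,
    sequence = unname(sequence),
    source = if ("source" %in% names(tax)) tax$source[idx] else "fixture",
    stringsAsFactors = FALSE)
  class(db) <- c("reference_db", "data.frame")
  db
}

#' Write a reference database back to FASTA + taxonomy
#'
#' Round-trips with [load_reference_db()]: accession, order and (normalised
#' uppercase) sequence are preserved byte for byte.
#'
#' @param db a `reference_db`.
#' @param fasta_path,taxonomy_path output paths.
#' @return invisibly, the two paths.
#' @export
write_reference_db <- function(db, fasta_path, taxonomy_path) {
  stopifnot(inherits(db, "reference_db"))
  seqs <- Biostrings::DNAStringSet(db$sequence)
  names(seqs) <- db$accession
  Biostrings::writeXStringSet(seqs, fasta_path, width = 70L)
  write_tsv_report(
    data.frame(accession = db$accession, species = db$species,
               higher_taxon = db$higher_taxon, source = db$source,
               stringsAsFactors = FALSE),
    taxonomy_path)
  invisible(c(fasta_path, taxonomy_path))
}

#' Collapse reference records into amplicon-level OTUs
#'
#' Extracts each record's in-silico amplicon for an assay and partitions the
#' amplifiable records by exact amplicon identity: records sharing an
#' identical amplicon string form one amplicon-level OTU (the grouping
#' convention used when several reference accessions are indistinguishable
#' over the marker). Records yielding no amplicon are reported separately,
#' never silently dropped.
#'
#' @param db a `reference_db`.
#' @param assay an [assay_definition()].
#' @param max_mismatch maximum primer mismatches for in-silico PCR
#'   (default 0: reference predictions are exact-site based).
#' @return a list with `otus` (data frame: `otu_id`, `amplicon_sequence`,
#'   `insert_sequence`, `n_members`, `member_accessions`, `species_set`,
#'   `contains_n`) and `non_amplifiable` (character vector of accessions).
#' @export
collapse_amplicon_otus <- function(db, assay, max_mismatch = 0) {
  stopifnot(inherits(db, "reference_db"), inherits(assay, "assay_definition"))
  amp <- character(nrow(db)); ins <- character(nrow(db))
  has <- logical(nrow(db))
  for (i in seq_len(nrow(db))) {
    hits <- find_amplicons(assay, db$sequence[i], max_mismatch = max_mismatch)
    if (nrow(hits) >= 1) {
      has[i] <- TRUE
      amp[i] <- hits$amplicon[1]
      ins[i] <- hits$insert[1]
    }
  }
  if (!any(has)) {
    return(list(otus = data.frame(otu_id = character(0),
                                  amplicon_sequence = character(0),
                                  insert_sequence = character(0),
                                  n_members = integer(0),
                                  member_accessions = character(0),
                                  species_set = character(0),
                                  contains_n = logical(0),
                                  stringsAsFactors = FALSE),
                non_amplifiable = db$accession))
  }
  keys <- amp[has]
  groups <- split(which(has), factor(keys, levels = unique(keys)))
  otus <- data.frame(
    otu_id = sprintf("AOTU_%03d", seq_along(groups)),
    amplicon_sequence = names(groups),
    insert_sequence = vapply(groups, function(ix) ins[ix[1]], character(1)),
    n_members = vapply(groups, length, integer(1)),
    member_accessions = vapply(groups, function(ix)
      paste(db$accession[ix], collapse = ","), character(1)),
    species_set = vapply(groups, function(ix)
      paste(sort(unique(db$species[ix])), collapse = ","), character(1)),
    contains_n = grepl("N", names(groups), fixed = TRUE),
    stringsAsFactors = FALSE, row.names = NULL)
  list(otus = otus, non_amplifiable = db$accession[!has])
}
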