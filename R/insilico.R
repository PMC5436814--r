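#' In-silico PCR: locate amplicons of an assay on a template
#'
#' Scans both strands of a template for the degenerate forward primer and,
#' downstream of it, the reverse complement of the reverse primer. Candidate
#' amplicons outside the assay's length window are discarded. Amplicon
#' length is primer-inclusive (forward primer start to reverse primer end);
#' the primer-free insert is returned alongside.
#'
#' @param assay an [assay_definition()].
#' @param record a template: either a nucleotide string or anything with a
#'   `$sequence` field (e.g. one row of a `reference_db`).
#' @param max_mismatch maximum mismatches tolerated per primer site.
#' @param length_range optional override of the assay's amplicon length
#'   window, `c(min, max)` in bp.
#' @return data frame with columns `start`, `end` (0-based half-open on the
#'   input's plus strand), `length`, `n_mismatch_fwd`, `n_mismatch_rev`,
#'   `orientation` (`"plus"`/`"minus"`), `amplicon` (5' to 3' of the
#'   amplified strand) and `insert`; sorted by `start`. Zero rows when no
#'   site is found.
#' @export
find_amplicons <- function(assay, record, max_mismatch = 0,
                           length_range = NULL) {
  stopifnot(inherits(assay, "assay_definition"), max_mismatch >= 0)
  seq <- if (is.character(record)) record else record$sequence
  stopifnot(is.character(seq), length(seq) == 1, nzchar(seq))
  seq <- toupper(seq)
  if (is.null(length_range)) length_range <- assay$length_range
  fwd <- assay$forward_primer
  rev_rc <- revcomp(assay$reverse_primer)
  nf <- nchar(fwd); nr <- nchar(rev_rc); L <- nchar(seq)

  scan_strand <- function(s, orientation) {
    fh <- cpp_primer_scan(s, fwd, max_mismatch)
    rh <- cpp_primer_scan(s, rev_rc, max_mismatch)
    if (nrow(fh) == 0 || nrow(rh) == 0) return(NULL)
    out <- NULL
    for (i in seq_len(nrow(fh))) {
      fs <- fh$start[i]
      for (j in seq_len(nrow(rh))) {
        rs <- rh$start[j]
        if (rs < fs + nf) next  # reverse site must lie downstream
        len <- rs + nr - fs
        if (len < length_range[1] || len > length_range[2]) next
        amp <- substr(s, fs + 1, fs + len)
        ins <- substr(s, fs + nf + 1, rs)
        # map to plus-strand coordinates of the input
        if (orientation == "plus") {
          st <- fs; en <- fs + len
        } else {
          st <- L - (fs + len); en <- L - fs
        }
        out <- rbind(out, data.frame(
          start = st, end = en, length = len,
          n_mismatch_fwd = fh$mismatches[i], n_mismatch_rev = rh$mismatches[j],
          orientation = orientation, amplicon = amp, insert = ins,
          stringsAsFactors = FALSE))
      }
    }
    out
  }

  res <- rbind(scan_strand(seq, "plus"), scan_strand(revcomp(seq), "minus"))
  if (is.null(res)) {
    res <- data.frame(start = integer(0), end = integer(0), length = integer(0),
                      n_mismatch_fwd = integer(0), n_mismatch_rev = integer(0),
                      orientation = character(0), amplicon = character(0),
                      insert = character(0), stringsAsFactors = FALSE)
  }
  res[order(res$start), , drop = FALSE]
}

#' Assay specificity across a reference database
#'
#' Runs in-silico PCR for every record and summarises amplifiability per
#' species, the standard screen for assessing whether a primer set is
#' group-specific (e.g. a sphaeriid-only assay leaving dreissenids
#' unamplified).
#'
#' @param assay an [assay_definition()].
#' @param db a `reference_db`.
#' @param max_mismatch maximum mismatches per primer site.
#' @return a list with `records` (one row per record: `accession`,
#'   `species`, `amplifies`, `length`, `mismatches`) and `species` (one row
#'   per species: `species`, `amplifies` = any record amplifies).
#' @export
specificity_matrix <- function(assay, db, max_mismatch = 0) {
  stopifnot(inherits(db, "reference_db"))
  if (nrow(db) == 0) {
    return(list(records = data.frame(accession = character(0),
                                     species = character(0),
                                     amplifies = logical(0),
                                     length = integer(0),
                                     mismatches = integer(0),
                                     stringsAsFactors = FALSE),
                species = data.frame(species = character(0),
                                     amplifies = logical(0),
                                     stringsAsFactors = FALSE)))
  }
  rows <- lapply(seq_len(nrow(db)), function(i) {
    hits <- find_amplicons(assay, db$sequence[i], max_mismatch = max_mismatch)
    if (nrow(hits)) {
      data.frame(accession = db$accession[i], species = db$species[i],
                 amplifies = TRUE, length = hits$length[1],
                 mismatches = hits$n_mismatch_fwd[1] + hits$n_mismatch_rev[1],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(accession = db$accession[i], species = db$species[i],
                 amplifies = FALSE, length = NA_integer_,
                 mismatches = NA_integer_, stringsAsFactors = FALSE)
    }
  })
  records <- do.call(rbind, rows)
  agg <- aggregate(amplifies ~ species, data = records, FUN = any)
  list(records = records,
       species = agg[order(agg$species), , drop = FALSE])
}
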