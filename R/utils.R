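# Internal sequence helpers. All coordinates are 0-based half-open
# internally; anything user-facing in reports is 1-based.

IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of IUPAC nucleotide strings
#'
#' Thin vectorised wrapper over [Biostrings::reverseComplement()]; handles
#' degenerate codes.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @noRd
reverse_string <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' @noRd
assert_iupac <- function(x, what = "sequence") {
  bad <- grepl(sprintf("[^%s]", paste(IUPAC_CODES, collapse = "")), x)
  if (any(bad)) {
    stop(sprintf("%s contains non-IUPAC characters: %s", what,
                 paste(utils::head(x[bad], 3), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' @noRd
phred_to_char <- function(q) {
  q <- pmin(pmax(as.integer(round(q)), 2L), 41L)
  vapply(q, function(v) rawToChar(as.raw(v + 33L)), character(1))
}

#' @noRd
char_to_phred <- function(s) {
  lapply(s, function(x) as.integer(charToRaw(x)) - 33L)
}

# Write a small TSV report in a fixed, diff-friendly form.
#' @noRd
write_tsv_report <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
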