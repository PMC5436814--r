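#' Define a metabarcoding assay
#'
#' An assay bundles the degenerate forward/reverse amplification primers, an
#' optional 3'-blocked blocking primer, the spacer + sequencing-primer
#' constructs used in two-step library preparation, and the admissible
#' amplicon length window.
#'
#' @param name assay name.
#' @param forward_primer,reverse_primer IUPAC primer strings, 5' to 3'.
#' @param blocking_primer optional IUPAC string of a blocking
#'   oligonucleotide, or `NULL`.
#' @param blocking_3p_blocked logical; `TRUE` when the blocking primer
#'   carries a 3' C3 spacer preventing extension.
#' @param spacers data frame with columns `set`, `direction` (`"F"`/`"R"`),
#'   `spacer`, `seq_primer` describing the library constructs, or `NULL`.
#' @param length_range numeric length-2 vector, min/max amplicon length in
#'   bp (primer-inclusive) accepted by in-silico PCR.
#' @return an object of class `assay_definition`.
#' @seealso [mol16s_assay()], [sph16s_assay()], [find_amplicons()]
#' @export
assay_definition <- function(name, forward_primer, reverse_primer,
                             blocking_primer = NULL,
                             blocking_3p_blocked = FALSE,
                             spacers = NULL,
                             length_range = c(100, 500)) {
  stopifnot(is.character(name), length(name) == 1,
            nzchar(forward_primer), nzchar(reverse_primer),
            length(length_range) == 2, length_range[1] <= length_range[2])
  forward_primer <- toupper(forward_primer)
  reverse_primer <- toupper(reverse_primer)
  assert_iupac(forward_primer, "forward_primer")
  assert_iupac(reverse_primer, "reverse_primer")
  if (!is.null(blocking_primer)) {
    blocking_primer <- toupper(blocking_primer)
    assert_iupac(blocking_primer, "blocking_primer")
  }
  if (!is.null(spacers)) {
    stopifnot(all(c("set", "direction", "spacer", "seq_primer") %in%
                    names(spacers)))
  }
  structure(list(name = name,
                 forward_primer = forward_primer,
                 reverse_primer = reverse_primer,
                 blocking_primer = blocking_primer,
                 blocking_3p_blocked = isTRUE(blocking_3p_blocked),
                 spacers = spacers,
                 length_range = as.numeric(length_range)),
            class = "assay_definition")
}

#' @export
print.assay_definition <- function(x, ...) {
  cat(sprintf("<assay_definition> %s\n", x$name))
  cat(sprintf("  forward : 5'-%s-3'\n", x$forward_primer))
  cat(sprintf("  reverse : 5'-%s-3'\n", x$reverse_primer))
  if (!is.null(x$blocking_primer)) {
    cat(sprintf("  blocking: 5'-%s-3'%s\n", x$blocking_primer,
                if (x$blocking_3p_blocked) " [3' extension-blocked]" else ""))
  }
  cat(sprintf("  length window: %d-%d bp; %d spacer construct(s)\n",
              x$length_range[1], x$length_range[2],
              if (is.null(x$spacers)) 0L else nrow(x$spacers)))
  invisible(x)
}

# Illumina sequencing-primer regions of the two-step library construct.
SEQ_PRIMER_F <- "TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG"
SEQ_PRIMER_R <- "GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG"

#' @noRd
builtin_spacers <- function() {
  data.frame(
    set = rep(c("E", "F", "G", "H"), 2),
    direction = rep(c("F", "R"), each = 4),
    spacer = c("TCCTATG", "ATGCTACAGT", "CGAGGCTACAACTC", "GATACGATCTCGCACTC",
               "CGTACTAGATGTACGA", "TCACTAGCTGACGC", "GAGTAGCTGA", "ATCGGCT"),
    seq_primer = rep(c(SEQ_PRIMER_F, SEQ_PRIMER_R), each = 4),
    stringsAsFactors = FALSE)
}

#' Built-in MOL16S mollusc assay
#'
#' Degenerate 16S mini-barcode assay targeting invasive bivalves and snails,
#' with a 3'-blocked fish blocking primer overlapping the reverse primer
#' site. Amplicon lengths vary by species over roughly 183-310 bp.
#'
#' @return an [assay_definition()].
#' @export
mol16s_assay <- function() {
  assay_definition(
    name = "MOL16S",
    forward_primer = "RRWRGACRAGAAGACCCT",
    reverse_primer = "ARTCCAACATCGAGGT",
    blocking_primer = "AGGTCGTAACCCCCTRG",
    blocking_3p_blocked = TRUE,
    spacers = builtin_spacers(),
    length_range = c(100, 500))
}

#' Built-in SPH16S sphaeriid-specific assay
#'
#' Non-degenerate 16S assay specific to fingernail/pea clams (family
#' Sphaeriidae); targeted amplicon length 299 bp.
#'
#' @return an [assay_definition()].
#' @export
sph16s_assay <- function() {
  assay_definition(
    name = "SPH16S",
    forward_primer = "TAGGGGAAGGTATGAATGGTTTG",
    reverse_primer = "ACATCGAGGTCGCAACC",
    blocking_primer = NULL,
    spacers = builtin_spacers(),
    length_range = c(100, 500))
}

#' Degenerate base matching
#'
#' Tests whether concrete target bases fall inside the expansion of IUPAC
#' primer codes. An `N` in the target matches nothing (conservative reading
#' used throughout exact-match assignment).
#'
#' @param primer_base character vector of single IUPAC codes.
#' @param target_base character vector of single target bases
#'   (`A`/`C`/`G`/`T`/`N`); recycled against `primer_base`.
#' @return logical vector.
#' @examples
#' iupac_match("R", "A")  # TRUE:  R = A/G
#' iupac_match("W", "C")  # FALSE: W = A/T
#' @export
iupac_match <- function(primer_base, target_base) {
  n <- max(length(primer_base), length(target_base))
  primer_base <- toupper(rep_len(primer_base, n))
  target_base <- toupper(rep_len(target_base, n))
  if (!all(primer_base %in% IUPAC_CODES)) {
    stop("invalid IUPAC code in primer_base: ",
         paste(setdiff(primer_base, IUPAC_CODES), collapse = ", "),
         call. = FALSE)
  }
  cpp_iupac_match(primer_base, target_base)
}

# Degenerate-aware: two IUPAC codes are compatible when expansions intersect.
#' @noRd
iupac_compatible <- function(a, b) {
  mapply(function(x, y) {
    length(intersect(IUPAC_EXPANSION[[x]], IUPAC_EXPANSION[[y]])) > 0
  }, strsplit(a, "")[[1]], strsplit(b, "")[[1]], USE.NAMES = FALSE)
}

#' Overlap between a blocking primer and the reverse amplification primer
#'
#' Reports the maximal degenerate-aware overlap between the 3' end of the
#' assay's reverse primer and the 5' end of its blocking primer, scanning
#' both the direct orientation (both oligos annealing to the same strand)
#' and the reverse-complement relationship, along with the 3'
#' extension-blocked (C3 spacer) flag.
#'
#' @param assay an [assay_definition()].
#' @return a list with `applicable`, `overlap_length`, `orientation`
#'   (`"direct"` or `"revcomp"`) and `extension_blocked`; when the assay has
#'   no blocking primer, `applicable = FALSE` and the remaining fields are
#'   `NA`.
#' @export
blocking_overlap_report <- function(assay) {
  stopifnot(inherits(assay, "assay_definition"))
  if (is.null(assay$blocking_primer)) {
    return(list(applicable = FALSE, overlap_length = NA_integer_,
                orientation = NA_character_, extension_blocked = NA))
  }
  rev_p <- assay$reverse_primer
  block <- assay$blocking_primer
  best <- function(a, b) {
    # maximal k with suffix(a, k) compatible with prefix(b, k)
    kmax <- 0L
    for (k in seq_len(min(nchar(a), nchar(b)))) {
      sa <- substr(a, nchar(a) - k + 1, nchar(a))
      pb <- substr(b, 1, k)
      if (all(iupac_compatible(sa, pb))) kmax <- k
    }
    kmax
  }
  direct <- best(rev_p, block)
  via_rc <- best(rev_p, revcomp(block))
  if (direct >= via_rc) {
    list(applicable = TRUE, overlap_length = direct, orientation = "direct",
         extension_blocked = assay$blocking_3p_blocked)
  } else {
    list(applicable = TRUE, overlap_length = via_rc, orientation = "revcomp",
         extension_blocked = assay$blocking_3p_blocked)
  }
}
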