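#' Construct a mock community
#'
#' A mock community is a set of per-species target-amplicon copy numbers
#' mixed into one extraction, used to test whether sequencing read
#' abundances recover known input abundances.
#'
#' @param community_id identifier string.
#' @param copies named numeric vector, species -> target amplicon copies
#'   (non-negative; at least one positive).
#' @return an object of class `mock_community`.
#' @export
mock_community <- function(community_id, copies) {
  stopifnot(is.character(community_id), length(community_id) == 1,
            is.numeric(copies), !is.null(names(copies)),
            all(copies >= 0), any(copies > 0))
  structure(list(community_id = community_id, copies = copies),
            class = "mock_community")
}

#' @export
print.mock_community <- function(x, ...) {
  cat(sprintf("<mock_community> %s: %d species, %s total copies\n",
              x$community_id, length(x$copies),
              format(sum(x$copies), big.mark = ",")))
  invisible(x)
}

# Copy-number recipes of the five validation communities: eleven species
# (eight molluscs across a 14-9090 copy gradient rotated between
# communities, two extra bivalve/gastropod series, walleye as the fish
# blocking-primer target, and a constant 18-copy trace species).
MOCK_SPECIES <- c("Sphaerium similie", "Dreissena rostriformis",
                  "Sander vitreus", "Sphaerium corneum",
                  "Pisidium compressum", "Mytilopsis leucophaeata",
                  "Dreissena polymorpha", "Potamopyrgus antipodarum",
                  "Gillia altilis", "Cipangopaludina chinensis",
                  "Melanoides tuberculata")

MOCK_COPIES <- matrix(c(
  9090, 1818,  363,   72,   14,
  1818,  363,   72,   14, 9090,
   363,   72,   14, 9090, 1818,
    72,   14, 9090, 1818,  363,
    14, 9090, 1818,  363,   72,
  2272, 1136,  568,  284,  142,
  1136,  568,  284,  142, 2272,
   568,  284,  142, 2272, 1136,
   284,  142, 2272, 1136,  568,
   142, 2272, 1136,  568,  284,
    18,   18,   18,   18,   18), nrow = 11, byrow = TRUE,
  dimnames = list(MOCK_SPECIES, paste0("MC", 1:5)))

#' The five packaged mock-community recipes
#'
#' @return a named list of five [mock_community()] objects (`MC1`..`MC5`),
#'   each giving target amplicon copies per extraction for the eleven
#'   species of the validation design.
#' @export
builtin_communities <- function() {
  out <- lapply(colnames(MOCK_COPIES), function(cc) {
    mock_community(cc, setNames(MOCK_COPIES[, cc], rownames(MOCK_COPIES)))
  })
  names(out) <- colnames(MOCK_COPIES)
  out
}

#' Assay-conditional expected read fractions of a mock community
#'
#' The expected percentage of reads for species `s` is its copy number over
#' the summed copies of all species the assay amplifies; species outside
#' the amplifiable set expect 0. Conditioning on the amplifiable set is what
#' makes the same community yield different expectations under a broad
#' mollusc assay (all species count) versus a family-specific one (only the
#' sphaeriids count).
#'
#' @param community a [mock_community()].
#' @param amplifiable either a character vector of amplifiable species, a
#'   predicate function over species names, or `NULL` (all species).
#' @return named numeric vector of percentages (one per community species);
#'   amplifiable entries sum to 100.
#' @export
expected_fractions <- function(community, amplifiable = NULL) {
  stopifnot(inherits(community, "mock_community"))
  sp <- names(community$copies)
  amp <- if (is.null(amplifiable)) rep(TRUE, length(sp))
         else if (is.function(amplifiable)) vapply(sp, amplifiable, logical(1))
         else sp %in% amplifiable
  denom <- sum(community$copies[amp])
  if (denom <= 0) {
    stop("no amplifiable species with positive copy number", call. = FALSE)
  }
  out <- setNames(numeric(length(sp)), sp)
  out[amp] <- 100 * community$copies[amp] / denom
  out
}

#' Amplifiable species of an assay, derived from the reference database
#'
#' Convenience wrapper around [specificity_matrix()]: the species whose
#' reference records yield an in-silico amplicon. A manual override can add
#' or remove species, e.g. a taxon amplifiable by the primers but
#' suppressed downstream by a blocking primer (suppression affects observed
#' reads, not the expected denominator).
#'
#' @param assay an [assay_definition()].
#' @param db a `reference_db`.
#' @param max_mismatch primer mismatch tolerance.
#' @param include,exclude character vectors of species forced in or out.
#' @return character vector of amplifiable species.
#' @export
amplifiable_species <- function(assay, db, max_mismatch = 0,
                                include = NULL, exclude = NULL) {
  sm <- specificity_matrix(assay, db, max_mismatch = max_mismatch)
  sp <- sm$species$species[sm$species$amplifies]
  setdiff(union(sp, include), exclude)
}
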