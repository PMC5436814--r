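#' Exhaustive exact-match assignment against reference amplicon OTUs
#'
#' A read is assigned if and only if its full string equals a reference
#' OTU's amplicon (by default the primer-free insert, matching reads that
#' have been construct-trimmed). Exactness makes the assignment immune to
#' chimeras and sequencing errors, which simply fall into the unassigned
#' pool. Reads matching an amplicon shared by several species are counted
#' as ambiguous rather than split.
#'
#' @param reads character vector of read sequences, or a data frame with a
#'   `sequence` column.
#' @param otus the `otus` data frame of [collapse_amplicon_otus()].
#' @param region match against the `"insert"` (primer-free, default) or the
#'   full `"amplicon"` sequence.
#' @return a list of class `assignment_result`: `species_counts` (named),
#'   `ambiguous` (named by comma-separated species set), `n_unassigned`,
#'   `n_reads`.
#' @export
assign_exact <- function(reads, otus, region = c("insert", "amplicon")) {
  region <- match.arg(region)
  if (is.data.frame(reads)) reads <- reads$sequence
  key <- if (region == "insert") otus$insert_sequence else otus$amplicon_sequence
  # several OTUs may share an insert (primer-site bases differ); pool their
  # species sets per distinct key
  sets <- lapply(split(otus$species_set, key), function(s) {
    sort(unique(unlist(strsplit(s, ",", fixed = TRUE))))
  })
  keys <- names(sets)
  hit <- match(reads, keys)
  n_unassigned <- sum(is.na(hit))
  species_counts <- numeric(0); ambiguous <- numeric(0)
  if (any(!is.na(hit))) {
    tab <- table(hit)
    for (k in names(tab)) {
      sp <- sets[[as.integer(k)]]
      cnt <- as.integer(tab[[k]])
      if (length(sp) == 1) {
        species_counts[sp] <- (if (sp %in% names(species_counts))
          species_counts[[sp]] else 0) + cnt
      } else {
        lab <- paste(sp, collapse = ",")
        ambiguous[lab] <- (if (lab %in% names(ambiguous))
          ambiguous[[lab]] else 0) + cnt
      }
    }
  }
  structure(list(species_counts = species_counts, ambiguous = ambiguous,
                 n_unassigned = n_unassigned, n_reads = length(reads)),
            class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat(sprintf("<assignment_result> %d reads: %d assigned to %d species, %d ambiguous, %d unassigned\n",
              x$n_reads, sum(x$species_counts), length(x$species_counts),
              sum(x$ambiguous), x$n_unassigned))
  invisible(x)
}

# Megablast-like pairwise alignment scoring used for clustering identity
# and local identification.
#' @noRd
alignment_scoring <- function() {
  list(mat = Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                      baseOnly = TRUE),
       gap_opening = 5, gap_extension = 2)
}

#' Greedy de-novo OTU clustering at a similarity threshold
#'
#' UCLUST-style greedy centroid clustering: unique sequences are ordered by
#' abundance (descending), then length (descending), then lexicographically;
#' each sequence joins the first existing centroid whose identity reaches
#' the threshold, otherwise it founds a new centroid. Identity is computed
#' on a global alignment with free terminal gaps, as matching columns over
#' the shorter sequence's length — normalising by the shorter sequence
#' (rather than by aligned columns alone) prevents a short, perfectly
#' matching end-overlap between unrelated sequences from counting as 100%
#' identity.
#'
#' @param reads character vector of sequences, or a data frame with a
#'   `sequence` column.
#' @param threshold identity threshold as a fraction (default 0.97). At 1.0
#'   clustering reduces to exact-string deduplication.
#' @return data frame with `otu_id`, `representative` (centroid sequence)
#'   and `read_count`; the `members` attribute maps each input read index
#'   to its OTU.
#' @export
cluster_otus <- function(reads, threshold = 0.97) {
  if (is.data.frame(reads)) reads <- reads$sequence
  if (length(reads) == 0) stop("no reads to cluster", call. = FALSE)
  tab <- table(reads)
  uniq <- names(tab)
  ab <- as.integer(tab)
  ord <- order(-ab, -nchar(uniq), uniq)
  uniq <- uniq[ord]; ab <- ab[ord]
  sc <- alignment_scoring()
  centroids <- character(0)
  counts <- integer(0)
  member_of <- integer(length(uniq))
  for (i in seq_along(uniq)) {
    assigned <- 0L
    if (length(centroids)) {
      if (threshold >= 1) {
        hit <- match(uniq[i], centroids)
        if (!is.na(hit)) assigned <- hit
      } else {
        aln <- Biostrings::pairwiseAlignment(
          pattern = Biostrings::DNAStringSet(centroids),
          subject = uniq[i], type = "overlap",
          substitutionMatrix = sc$mat,
          gapOpening = sc$gap_opening, gapExtension = sc$gap_extension)
        ident <- 100 * Biostrings::nmatch(aln) /
          pmin(nchar(centroids), nchar(uniq[i]))
        hit <- which(ident >= 100 * threshold)
        if (length(hit)) assigned <- hit[1]
      }
    }
    if (assigned == 0L) {
      centroids <- c(centroids, uniq[i])
      counts <- c(counts, ab[i])
      member_of[i] <- length(centroids)
    } else {
      counts[assigned] <- counts[assigned] + ab[i]
      member_of[i] <- assigned
    }
  }
  out <- data.frame(otu_id = sprintf("OTU_%04d", seq_along(centroids)),
                    representative = centroids, read_count = counts,
                    stringsAsFactors = FALSE)
  attr(out, "members") <- member_of[match(reads, uniq)]
  out
}

#' Identify OTUs against a local reference collection
#'
#' Deterministic stand-in for a remote BLAST identification: the best local
#' alignment (megablast-like scoring: match +2, mismatch -3, gap open -5,
#' gap extend -2) of each OTU representative against every reference is
#' computed; the best hit is chosen by score, ties broken by identity, then
#' coverage, then the lexicographically smallest accession. Identity is
#' matching columns over alignment columns; coverage is the aligned query
#' span over the query length. OTUs failing the coverage or read-count
#' retention rules are dropped (and counted); retained OTUs sharing a best-
#' hit accession are grouped into one record with summed read counts.
#'
#' @param otus data frame from [cluster_otus()].
#' @param reference_db a `reference_db` to search against.
#' @param min_coverage minimum query coverage percent (default 80).
#' @param min_reads minimum reads per OTU (default 2: singleton OTUs drop).
#' @param species_identity identity percent at or above which a hit counts
#'   as a species-level identification (default 97).
#' @return data frame of OTU records: `otu_id`, `representative`,
#'   `read_count`, `best_hit_accession`, `best_hit_species`, `identity_pct`,
#'   `identity_min`, `identity_max`, `coverage_pct`, `species_level`,
#'   `n_merged`; a `dropped` attribute records discarded OTUs with reasons.
#' @export
identify_otus <- function(otus, reference_db, min_coverage = 80,
                          min_reads = 2, species_identity = 97) {
  stopifnot(inherits(reference_db, "reference_db"), nrow(reference_db) > 0)
  sc <- alignment_scoring()
  refs <- Biostrings::DNAStringSet(reference_db$sequence)
  hits <- lapply(seq_len(nrow(otus)), function(i) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = refs, subject = otus$representative[i], type = "local",
      substitutionMatrix = sc$mat,
      gapOpening = sc$gap_opening, gapExtension = sc$gap_extension)
    ident <- Biostrings::pid(aln, type = "PID1")
    qspan <- Biostrings::width(Biostrings::subject(aln))
    cov <- 100 * qspan / nchar(otus$representative[i])
    score <- Biostrings::score(aln)
    ord <- order(-score, -ident, -cov, reference_db$accession)
    b <- ord[1]
    data.frame(otu_id = otus$otu_id[i],
               representative = otus$representative[i],
               read_count = otus$read_count[i],
               best_hit_accession = reference_db$accession[b],
               best_hit_species = reference_db$species[b],
               identity_pct = ident[b], coverage_pct = cov[b],
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, hits)
  drop_cov <- rec$coverage_pct < min_coverage
  drop_single <- !drop_cov & rec$read_count < min_reads
  dropped <- rec[drop_cov | drop_single, , drop = FALSE]
  if (nrow(dropped)) {
    dropped$reason <- ifelse(drop_cov[drop_cov | drop_single],
                             "low_coverage", "singleton_otu")
  } else {
    dropped$reason <- character(0)
  }
  rec <- rec[!(drop_cov | drop_single), , drop = FALSE]
  if (nrow(rec)) {
    groups <- split(seq_len(nrow(rec)), rec$best_hit_accession)
    rec <- do.call(rbind, lapply(groups, function(ix) {
      ix <- ix[order(-rec$read_count[ix])]
      top <- ix[1]
      data.frame(otu_id = rec$otu_id[top],
                 representative = rec$representative[top],
                 read_count = sum(rec$read_count[ix]),
                 best_hit_accession = rec$best_hit_accession[top],
                 best_hit_species = rec$best_hit_species[top],
                 identity_pct = rec$identity_pct[top],
                 identity_min = min(rec$identity_pct[ix]),
                 identity_max = max(rec$identity_pct[ix]),
                 coverage_pct = rec$coverage_pct[top],
                 n_merged = length(ix),
                 stringsAsFactors = FALSE)
    }))
    rec <- rec[order(-rec$read_count), , drop = FALSE]
    rownames(rec) <- NULL
    rec$species_level <- rec$identity_pct >= species_identity
  } else {
    rec <- data.frame(otu_id = character(0), representative = character(0),
                      read_count = integer(0),
                      best_hit_accession = character(0),
                      best_hit_species = character(0),
                      identity_pct = numeric(0), identity_min = numeric(0),
                      identity_max = numeric(0), coverage_pct = numeric(0),
                      n_merged = integer(0), species_level = logical(0),
                      stringsAsFactors = FALSE)
  }
  attr(rec, "dropped") <- dropped
  rec
}

#' Composition report over identified OTU records
#'
#' Mirrors the per-sample OTU reporting convention: each record's reads as
#' a percentage of the sample total and as a percentage of just the
#' species-level (identity at or above the threshold) reads.
#'
#' @param otu_records data frame with at least `best_hit_accession`,
#'   `best_hit_species`, `read_count`, `identity_pct`, `coverage_pct`,
#'   `species_level` — or any data frame with `read_count` and
#'   `species_level` (remaining columns are carried through when present).
#' @param total_reads denominator for the percentage of total reads;
#'   defaults to the sum of `read_count` (pass the sample's full read count
#'   to reproduce sample-level totals).
#' @return data frame with the input columns plus `pct_total_reads` and
#'   `pct_species_level_reads` (NA for records below the species threshold).
#' @export
report_composition <- function(otu_records, total_reads = NULL) {
  stopifnot(all(c("read_count", "species_level") %in% names(otu_records)))
  if (is.null(total_reads)) total_reads <- sum(otu_records$read_count)
  out <- otu_records
  out$pct_total_reads <- 100 * out$read_count / total_reads
  denom <- sum(out$read_count[out$species_level])
  out$pct_species_level_reads <- ifelse(
    out$species_level & denom > 0, 100 * out$read_count / denom, NA_real_)
  out
}
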