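#' @noRd
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Replace degenerate codes by a random concrete base from their expansion.
#' @noRd
expand_primer <- function(primer) {
  ch <- strsplit(primer, "")[[1]]
  paste(vapply(ch, function(c) {
    exp <- IUPAC_EXPANSION[[c]]
    if (length(exp) == 1) exp else sample(exp, 1)
  }, character(1)), collapse = "")
}

#' Synthetic reference database for the validation design
#'
#' Builds labelled 16S-like reference templates for the eleven
#' mock-community species. Every template carries a concrete expansion of
#' the mollusc-assay primer sites around a species-specific insert (amplicon
#' lengths spread over the assay's 183-310 bp range); the three sphaeriid
#' species additionally carry the sphaeriid-assay sites spanning a 299 bp
#' amplicon, so a family-specific assay amplifies only them. One species
#' (S. corneum) has two accessions sharing an identical amplicon to exercise
#' amplicon-level OTU collapsing. Synthetic stand-ins for GenBank
#' references; accessions are prefixed `SYN`.
#'
#' @param seed integer seed; the same seed reproduces the same database.
#' @return a `reference_db` data frame.
#' @export
simulate_reference_db <- function(seed = 20170518) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed %% .Machine$integer.max)

  mol <- mol16s_assay(); sph <- sph16s_assay()
  sphaeriids <- c("Sphaerium similie", "Sphaerium corneum", "Pisidium compressum")
  higher <- c("Sphaeriidae", "Dreissenidae", "Percidae", "Sphaeriidae",
              "Sphaeriidae", "Dreissenidae", "Dreissenidae", "Tateidae",
              "Hydrobiidae", "Viviparidae", "Thiaridae")
  # primer-inclusive mollusc-amplicon length per species (183-310 bp range;
  # sphaeriids kept short enough to nest inside their 299 bp family amplicon)
  mol_len <- c(240, 260, 310, 230, 250, 270, 183, 200, 290, 220, 205)
  names(mol_len) <- MOCK_SPECIES
  names(higher) <- MOCK_SPECIES

  nf <- nchar(mol$forward_primer); nr <- nchar(mol$reverse_primer)
  sph_f <- sph$forward_primer; sph_r_rc <- revcomp(sph$reverse_primer)

  recs <- lapply(MOCK_SPECIES, function(sp) {
    fwd_site <- expand_primer(mol$forward_primer)
    rev_site_rc <- revcomp(expand_primer(mol$reverse_primer))
    insert <- random_dna(mol_len[[sp]] - nf - nr)
    mol_amp <- paste0(fwd_site, insert, rev_site_rc)
    if (sp %in% sphaeriids) {
      gap_total <- 299 - nchar(sph_f) - nchar(sph_r_rc) - mol_len[[sp]]
      ga <- floor(gap_total / 2); gb <- gap_total - ga
      core <- paste0(sph_f, random_dna(ga), mol_amp, random_dna(gb), sph_r_rc)
    } else {
      core <- mol_amp
    }
    paste0(random_dna(25), core, random_dna(25))
  })

  accession <- sprintf("SYN%03d", seq_along(MOCK_SPECIES))
  db <- data.frame(accession = accession, species = MOCK_SPECIES,
                   higher_taxon = unname(higher[MOCK_SPECIES]),
                   sequence = unlist(recs), source = "generated",
                   stringsAsFactors = FALSE)
  # second S. corneum accession: identical amplicons, different flanks
  i <- which(db$species == "Sphaerium corneum")
  core <- substr(db$sequence[i], 26, nchar(db$sequence[i]) - 25)
  db <- rbind(db, data.frame(accession = "SYN012",
                             species = "Sphaerium corneum",
                             higher_taxon = "Sphaeriidae",
                             sequence = paste0(random_dna(25), core, random_dna(25)),
                             source = "generated", stringsAsFactors = FALSE))
  class(db) <- c("reference_db", "data.frame")
  db
}

#' Configure a read simulation
#'
#' Collects the parameters of the paired-end amplicon simulator. The
#' defaults emulate the validation sequencing conditions: 2 x 300 bp
#' chemistry, a 40-50% PhiX spike-in (0.45), per-base substitution error
#' typical of the platform, and the two-step library construct
#' (spacer + assay primer + insert read from both ends).
#'
#' @param assay an [assay_definition()].
#' @param community a [mock_community()].
#' @param refdb a `reference_db` resolving community species to templates.
#' @param n_read_pairs number of read pairs to emit.
#' @param read_length read length in bp (default 300).
#' @param error_rate per-base substitution probability (default 0.003).
#' @param q_start,q_decay,q_jitter quality model: mean Phred at cycle 1,
#'   linear decay per cycle, Gaussian jitter SD.
#' @param chimera_rate probability that a template-derived pair is a
#'   two-parent chimera spliced at a uniform interior breakpoint.
#' @param efficiency_bias optional named multiplicative per-species
#'   amplification factors (default all 1).
#' @param blocking_efficiency fraction of blocked-taxon templates suppressed,
#'   in `[0, 1]`.
#' @param blocked_species species subject to the blocking primer.
#' @param phix_fraction fraction of pairs emitted as random-sequence decoys
#'   (unindexed/control reads).
#' @param spacer_set which spacer construct (`"E"`, `"F"`, `"G"`, `"H"`).
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(assay, community, refdb, n_read_pairs,
                              read_length = 300, error_rate = 0.003,
                              q_start = 38, q_decay = 0.02, q_jitter = 2,
                              chimera_rate = 0.01, efficiency_bias = NULL,
                              blocking_efficiency = 0,
                              blocked_species = character(0),
                              phix_fraction = 0.45, spacer_set = "E",
                              seed = 1) {
  stopifnot(inherits(assay, "assay_definition"),
            inherits(community, "mock_community"),
            inherits(refdb, "reference_db"),
            n_read_pairs > 0, read_length > 0,
            error_rate >= 0, error_rate <= 1,
            chimera_rate >= 0, chimera_rate <= 1,
            blocking_efficiency >= 0, blocking_efficiency <= 1,
            phix_fraction >= 0, phix_fraction <= 1,
            spacer_set %in% c("E", "F", "G", "H"))
  structure(list(assay = assay, community = community, refdb = refdb,
                 n_read_pairs = as.integer(n_read_pairs),
                 read_length = as.integer(read_length),
                 error_rate = error_rate, q_start = q_start,
                 q_decay = q_decay, q_jitter = q_jitter,
                 chimera_rate = chimera_rate,
                 efficiency_bias = efficiency_bias,
                 blocking_efficiency = blocking_efficiency,
                 blocked_species = blocked_species,
                 phix_fraction = phix_fraction, spacer_set = spacer_set,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate paired-end amplicon reads with ground truth
#'
#' Draws templates per pair proportionally to community copy number times
#' amplification bias (blocked taxa down-weighted by the blocking
#' efficiency), assembles the library construct
#' `spacer + amplicon + revcomp(spacer)`, reads it from both ends at the
#' configured read length (reads are truncated at the fragment end,
#' emulating read-through of short fragments), injects substitution errors
#' and cycle-decaying qualities, splices chimeras at uniform interior
#' breakpoints, and emits a fraction of random-sequence decoy pairs standing
#' in for PhiX/unindexed clusters. Every pair's provenance is recorded in a
#' truth table.
#'
#' @param config a [simulation_config()].
#' @return a list of class `read_simulation` with `reads` (data frame:
#'   `read_id`, `r1_seq`, `r1_qual`, `r2_seq`, `r2_qual`), `truth` (data
#'   frame: `read_id`, `class` in template/chimera/decoy, `species`,
#'   `accession`), `non_amplifiable` (community species with copies > 0 but
#'   no in-silico amplicon) and the `config`.
#' @export
simulate_reads <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  comm <- config$community
  sp_all <- names(comm$copies)[comm$copies > 0]
  amp_by_sp <- list(); acc_by_sp <- list()
  for (sp in sp_all) {
    recs <- which(config$refdb$species == sp)
    amp <- NULL; acc <- NULL
    for (i in recs) {
      hits <- find_amplicons(config$assay, config$refdb$sequence[i])
      if (nrow(hits)) { amp <- hits$amplicon[1]; acc <- config$refdb$accession[i]; break }
    }
    if (!is.null(amp)) { amp_by_sp[[sp]] <- amp; acc_by_sp[[sp]] <- acc }
  }
  non_amp <- setdiff(sp_all, names(amp_by_sp))
  species <- names(amp_by_sp)
  if (length(species) == 0) {
    stop("no amplifiable species in community '", comm$community_id,
         "'; non-amplifiable: ", paste(non_amp, collapse = ", "),
         call. = FALSE)
  }

  bias <- rep(1, length(species))
  if (!is.null(config$efficiency_bias)) {
    hit <- species %in% names(config$efficiency_bias)
    bias[hit] <- config$efficiency_bias[species[hit]]
  }
  w <- comm$copies[species] * bias
  blocked <- species %in% config$blocked_species
  w[blocked] <- w[blocked] * (1 - config$blocking_efficiency)
  if (sum(w) <= 0) {
    stop("all template weights are zero after blocking/bias", call. = FALSE)
  }

  n <- config$n_read_pairs
  rl <- config$read_length
  spc <- config$assay$spacers
  sp_f <- spc$spacer[spc$set == config$spacer_set & spc$direction == "F"]
  sp_r <- spc$spacer[spc$set == config$spacer_set & spc$direction == "R"]
  if (length(sp_f) != 1 || length(sp_r) != 1) {
    stop("assay lacks spacer constructs for set ", config$spacer_set, call. = FALSE)
  }

  n_decoy <- rbinom(1, n, config$phix_fraction)
  n_tmpl <- n - n_decoy
  draw <- sample(seq_along(species), n_tmpl, replace = TRUE, prob = w)
  is_chim <- runif(n_tmpl) < config$chimera_rate

  amp_vec <- unlist(amp_by_sp)[species]
  frag_by_sp <- paste0(sp_f, amp_vec, revcomp(sp_r))
  frags <- frag_by_sp[draw]

  if (any(is_chim)) {
    idx <- which(is_chim)
    p2 <- sample(seq_along(species), length(idx), replace = TRUE, prob = w)
    for (k in seq_along(idx)) {
      a1 <- amp_vec[draw[idx[k]]]; a2 <- amp_vec[p2[k]]
      b <- sample(seq_len(nchar(a1) - 1), 1)
      chim <- paste0(substr(a1, 1, b),
                     if (b + 1 <= nchar(a2)) substr(a2, b + 1, nchar(a2)) else "")
      frags[idx[k]] <- paste0(sp_f, chim, revcomp(sp_r))
    }
  }

  r1 <- substr(frags, 1, pmin(rl, nchar(frags)))
  fr_rc <- revcomp(frags)
  r2 <- substr(fr_rc, 1, pmin(rl, nchar(fr_rc)))
  r1 <- cpp_add_errors(r1, config$error_rate)
  r2 <- cpp_add_errors(r2, config$error_rate)

  if (n_decoy > 0) {
    decoy1 <- vapply(seq_len(n_decoy), function(i) random_dna(rl), character(1))
    decoy2 <- vapply(seq_len(n_decoy), function(i) random_dna(rl), character(1))
    r1 <- c(r1, decoy1); r2 <- c(r2, decoy2)
  }
  q1 <- cpp_sim_quality(nchar(r1), config$q_start, config$q_decay, config$q_jitter)
  q2 <- cpp_sim_quality(nchar(r2), config$q_start, config$q_decay, config$q_jitter)

  cls <- c(ifelse(is_chim, "chimera", "template"), rep("decoy", n_decoy))
  truth_sp <- c(ifelse(is_chim, NA_character_, species[draw]),
                rep(NA_character_, n_decoy))
  truth_acc <- c(ifelse(is_chim, NA_character_,
                        unlist(acc_by_sp)[species][draw]),
                 rep(NA_character_, n_decoy))
  ord <- sample(length(r1))
  read_id <- sprintf("rp%07d", seq_along(ord))
  reads <- data.frame(read_id = read_id,
                      r1_seq = r1[ord], r1_qual = q1[ord],
                      r2_seq = r2[ord], r2_qual = q2[ord],
                      stringsAsFactors = FALSE)
  truth <- data.frame(read_id = read_id, class = cls[ord],
                      species = truth_sp[ord], accession = truth_acc[ord],
                      stringsAsFactors = FALSE)
  structure(list(reads = reads, truth = truth, non_amplifiable = non_amp,
                 config = config),
            class = "read_simulation")
}

#' Species fractions of the simulation ground truth
#'
#' Percentage of template-derived (non-decoy, non-chimeric) read pairs per
#' species; sums to 100.
#'
#' @param truth the `truth` table of a [simulate_reads()] result (or the
#'   result itself).
#' @return named numeric vector of percentages.
#' @export
truth_fractions <- function(truth) {
  if (inherits(truth, "read_simulation")) truth <- truth$truth
  t <- truth[truth$class == "template", , drop = FALSE]
  if (nrow(t) == 0) stop("no template-derived pairs in truth table", call. = FALSE)
  100 * table(t$species) / nrow(t) -> tab
  setNames(as.numeric(tab), names(tab))
}

#' Write simulated read pairs as FASTQ (+ truth TSV)
#'
#' @param sim a `read_simulation`.
#' @param prefix output path prefix; writes `<prefix>_R1.fastq.gz`,
#'   `<prefix>_R2.fastq.gz` and `<prefix>_truth.tsv`.
#' @return invisibly, the three paths.
#' @export
write_read_pairs <- function(sim, prefix) {
  stopifnot(inherits(sim, "read_simulation"))
  p1 <- paste0(prefix, "_R1.fastq.gz"); p2 <- paste0(prefix, "_R2.fastq.gz")
  pt <- paste0(prefix, "_truth.tsv")
  write_fastq(sim$reads$read_id, sim$reads$r1_seq, sim$reads$r1_qual, p1)
  write_fastq(sim$reads$read_id, sim$reads$r2_seq, sim$reads$r2_qual, p2)
  write_tsv_report(sim$truth, pt)
  invisible(c(p1, p2, pt))
}

#' Write sequences with qualities to FASTQ
#'
#' @param ids,seqs,quals equal-length character vectors.
#' @param path output path; gzip-compressed when it ends in `.gz`.
#' @return invisibly, `path`.
#' @export
write_fastq <- function(ids, seqs, quals, path) {
  stopifnot(length(ids) == length(seqs), length(seqs) == length(quals))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ path (gzip-aware).
#' @return data frame with `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(read_id = vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1),
             sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}
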