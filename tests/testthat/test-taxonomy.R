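toy_otus <- function() {
  set.seed(61)
  assay <- assay_definition("toy", "ACGTACGTAC", "TTGGCCAATT",
                            length_range = c(50, 400))
  t1 <- make_template(assay, insert_len = 120)
  t2 <- make_template(assay, insert_len = 140)
  shared <- make_template(assay, insert_len = 110)
  shared2_seq <- paste0(rand_dna(15), assay$forward_primer, shared$insert,
                        revcomp(assay$reverse_primer), rand_dna(15))
  db <- make_refdb(c("A1", "A2", "A3", "A4"),
                   c("Sp one", "Sp two", "Sp three", "Sp four"),
                   c(t1$sequence, t2$sequence, shared$sequence, shared2_seq))
  list(assay = assay, db = db, t1 = t1, t2 = t2, shared = shared,
       otus = collapse_amplicon_otus(db, assay)$otus)
}

test_that("exact-match assignment is exact, ambiguity-aware and conserves reads", {
  fx <- toy_otus()
  reads <- c(fx$t1$insert,                         # Sp one
             fx$t1$insert,
             fx$t2$insert,                         # Sp two
             mutate_seq(fx$t1$insert, 1),          # 1 substitution: unassigned
             fx$shared$insert,                     # shared by Sp three/four
             rand_dna(120))                        # garbage: unassigned
  res <- assign_exact(reads, fx$otus)
  expect_equal(unname(res$species_counts["Sp one"]), 2)
  expect_equal(unname(res$species_counts["Sp two"]), 1)
  expect_equal(unname(res$ambiguous[["Sp four,Sp three"]]), 1)
  expect_equal(res$n_unassigned, 2)
  expect_equal(sum(res$species_counts) + sum(res$ambiguous) + res$n_unassigned,
               length(reads))
})

test_that("assignment on simulated error reads matches the truth-table oracle", {
  db <- simulate_reference_db()
  mol <- mol16s_assay()
  cm1 <- builtin_communities()$MC1
  cfg <- simulation_config(mol, cm1, db, n_read_pairs = 20000,
                           error_rate = 0.003, chimera_rate = 0,
                           phix_fraction = 0, q_jitter = 0, seed = 62)
  sim <- simulate_reads(cfg)
  m <- merge_pairs(sim$reads)
  tr <- trim_construct(m$reads, mol, max_primer_mismatch = 1)
  otus <- collapse_amplicon_otus(db, mol)$otus
  res <- assign_exact(tr$reads, otus)
  # oracle: a trimmed read is assignable iff its string equals its source
  # species' true insert (errors anywhere in the insert spoil exactness)
  true_insert <- vapply(unique(sim$truth$species), function(sp) {
    find_amplicons(mol, db$sequence[db$species == sp][1])$insert[1]
  }, character(1))
  src <- sim$truth$species[match(tr$reads$read_id, sim$truth$read_id)]
  errorfree <- tr$reads$sequence == true_insert[src]
  oracle_counts <- table(src[errorfree])
  for (sp in names(oracle_counts)) {
    expect_equal(unname(res$species_counts[sp]),
                 as.numeric(oracle_counts[sp]))
  }
  expect_equal(res$n_unassigned, sum(!errorfree))
  expect_gt(res$n_unassigned, 0)
})

test_that("an abundant sequence absorbs its 1-substitution satellite at 97%", {
  set.seed(63)
  centre <- rand_dna(300)
  variant <- mutate_seq(centre, 1)       # 99.7% identity
  reads <- c(rep(centre, 100), rep(variant, 5))
  otus <- cluster_otus(reads, threshold = 0.97)
  expect_equal(nrow(otus), 1)
  expect_equal(otus$representative, centre)
  expect_equal(otus$read_count, 105)
})

test_that("sequences at ~90% identity split into separate OTUs", {
  set.seed(64)
  a <- rand_dna(300)
  b <- mutate_seq(a, 30)                 # ~90% identity
  otus <- cluster_otus(c(rep(a, 10), rep(b, 8)), threshold = 0.97)
  expect_equal(nrow(otus), 2)
  # verify the constructed divergence with the alignment oracle
  o <- ungapped_local_oracle(b, a)
  expect_lt(o$identity, 97)
  # clustering partitions the input
  expect_equal(sum(otus$read_count), 18)
})

test_that("clustering at threshold 1.0 equals exact deduplication", {
  set.seed(65)
  pool <- replicate(6, rand_dna(80))
  reads <- sample(pool, 40, replace = TRUE)
  otus <- cluster_otus(reads, threshold = 1.0)
  expect_equal(nrow(otus), length(unique(reads)))
  expect_equal(sort(otus$representative), sort(unique(reads)))
  tab <- table(reads)
  expect_equal(otus$read_count,
               as.integer(tab[otus$representative]))
})

test_that("well-separated references give exactly k OTUs on error-free reads", {
  db <- simulate_reference_db()
  mol <- mol16s_assay()
  cm1 <- builtin_communities()$MC1
  # restrict to 4 abundant species; synthetic inserts are random, hence far
  # below 90% pairwise identity
  comm <- mock_community("k4", cm1$copies[c("Sphaerium similie",
                                            "Dreissena rostriformis",
                                            "Mytilopsis leucophaeata",
                                            "Dreissena polymorpha")])
  cfg <- simulation_config(mol, comm, db, n_read_pairs = 400, error_rate = 0,
                           chimera_rate = 0, phix_fraction = 0, q_jitter = 0,
                           seed = 66)
  sim <- simulate_reads(cfg)
  m <- merge_pairs(sim$reads)
  tr <- trim_construct(m$reads, mol)
  otus <- cluster_otus(tr$reads, threshold = 0.97)
  expect_equal(nrow(otus), 4)
})

test_that("identification reports identity/coverage and applies retention rules", {
  set.seed(67)
  db <- simulate_reference_db()
  mol <- mol16s_assay()
  ins <- find_amplicons(mol, db$sequence[1])$insert[1]
  # ~95% divergent copy of a *different* reference, so the two OTUs keep
  # distinct best-hit accessions and are not grouped
  ins2 <- find_amplicons(mol, db$sequence[2])$insert[1]
  near95 <- mutate_seq(ins2, round(nchar(ins2) * 0.05),
                       positions = round(seq(10, nchar(ins2) - 10,
                                             length.out = round(nchar(ins2) * 0.05))))
  # a third reference backs the singleton OTU
  ins3 <- find_amplicons(mol, db$sequence[3])$insert[1]
  otus <- data.frame(
    otu_id = c("OTU_0001", "OTU_0002", "OTU_0003"),
    representative = c(ins,                      # exact hit
                       near95,                   # ~95% identity, interior
                       ins3),                    # exact but singleton
    read_count = c(50, 10, 1), stringsAsFactors = FALSE)
  rec <- identify_otus(otus, db, min_coverage = 80, min_reads = 2,
                       species_identity = 97)
  exact <- rec[rec$otu_id == "OTU_0001", ]
  expect_equal(exact$identity_pct, 100)
  expect_equal(exact$coverage_pct, 100)
  expect_true(exact$species_level)
  expect_equal(exact$best_hit_accession, db$accession[1])
  near <- rec[rec$otu_id == "OTU_0002", ]
  expect_false(near$species_level)
  expect_lt(near$identity_pct, 97)
  expect_gte(near$coverage_pct, 80)
  dropped <- attr(rec, "dropped")
  expect_equal(dropped$otu_id, "OTU_0003")
  expect_equal(dropped$reason, "singleton_otu")
})

test_that("identity and coverage agree with the quadratic-time oracle", {
  set.seed(68)
  db <- simulate_reference_db()
  mol <- mol16s_assay()
  for (i in c(1, 4, 7)) {
    ins <- find_amplicons(mol, db$sequence[i])$insert[1]
    # spread isolated substitutions through the interior (never at the ends)
    k <- sample(2:8, 1)
    pos <- sort(sample(seq(10, nchar(ins) - 10, by = 4), k))
    q <- mutate_seq(ins, k, positions = pos)
    rec <- identify_otus(data.frame(otu_id = "q", representative = q,
                                    read_count = 5, stringsAsFactors = FALSE),
                         db, min_reads = 1)
    o <- ungapped_local_oracle(q, db$sequence[i])
    expect_equal(rec$identity_pct, o$identity, tolerance = 1e-9)
    expect_equal(rec$coverage_pct, o$coverage, tolerance = 1e-9)
  }
})

test_that("OTUs sharing a best-hit accession merge with summed read counts", {
  set.seed(69)
  db <- simulate_reference_db()
  mol <- mol16s_assay()
  ins <- find_amplicons(mol, db$sequence[2])$insert[1]
  otus <- data.frame(otu_id = c("OTU_0001", "OTU_0002"),
                     representative = c(ins, mutate_seq(ins, 2,
                                                        positions = c(50, 100))),
                     read_count = c(30, 4), stringsAsFactors = FALSE)
  rec <- identify_otus(otus, db, min_reads = 2)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$read_count, 34)
  expect_equal(rec$n_merged, 2)
  expect_equal(rec$identity_pct, 100)      # top member's identity
  expect_lt(rec$identity_min, 100)
})

test_that("composition percentages mirror the published reporting math", {
  # per-OTU read counts of the densest published aquarium sample, all at
  # species level
  reads <- c(25707, 3037, 235, 218, 132, 117, 74, 56, 52, 10)
  rec <- data.frame(best_hit_accession = sprintf("ACC%02d", seq_along(reads)),
                    best_hit_species = sprintf("Species %02d", seq_along(reads)),
                    read_count = reads, identity_pct = 98,
                    coverage_pct = 100, species_level = TRUE,
                    stringsAsFactors = FALSE)
  comp <- report_composition(rec, total_reads = 285980)
  expect_equal(round(comp$pct_species_level_reads[1], 3), 86.737)
  expect_equal(sum(comp$pct_species_level_reads), 100, tolerance = 0.01)
  # single record: 100% of species-level reads
  one <- report_composition(rec[1, ])
  expect_equal(one$pct_species_level_reads, 100)
})
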