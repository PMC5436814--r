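q40 <- function(n) strrep(rawToChar(as.raw(40 + 33)), n)

pair_from_template <- function(template, read_len = 300, q1 = NULL, q2 = NULL) {
  r1 <- substr(template, 1, min(read_len, nchar(template)))
  rc <- revcomp(template)
  r2 <- substr(rc, 1, min(read_len, nchar(rc)))
  data.frame(read_id = "p1", r1_seq = r1,
             r1_qual = if (is.null(q1)) q40(nchar(r1)) else q1,
             r2_seq = r2,
             r2_qual = if (is.null(q2)) q40(nchar(r2)) else q2,
             stringsAsFactors = FALSE)
}

test_that("error-free 2x300 reads of a 400 bp template merge back to the template", {
  set.seed(31)
  tmpl <- rand_dna(400)
  m <- merge_pairs(pair_from_template(tmpl))
  expect_equal(m$accounting$n_out, 1)
  expect_equal(m$reads$sequence, tmpl)
  expect_equal(nchar(m$reads$quality), 400)
})

test_that("overlap disagreements resolve to the higher-quality base with the lower quality", {
  set.seed(32)
  tmpl <- rand_dna(400)
  pr <- pair_from_template(tmpl)
  # disagreement at template position 250 (inside the 200..400 overlap):
  # flip the base in R2 only; R1 keeps Q40, give R2 Q10 everywhere
  pos_r2 <- 400 - 250 + 1   # position in R2 (reverse-complemented read)
  r2 <- strsplit(pr$r2_seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  orig <- substr(tmpl, 250, 250)
  r2[pos_r2] <- comp[[sample(setdiff(c("A","C","G","T"), orig), 1)]]
  pr$r2_seq <- paste(r2, collapse = "")
  pr$r2_qual <- strrep(rawToChar(as.raw(10 + 33)), 300)
  m <- merge_pairs(pr)
  expect_equal(m$accounting$n_out, 1)
  # R1's base wins; the merged base at 250 is the template base
  expect_equal(substr(m$reads$sequence, 250, 250), orig)
  # and it carries the loser's quality (Q10)
  expect_equal(substr(m$reads$quality, 250, 250), rawToChar(as.raw(10 + 33)))
  # agreements carry max quality capped at Q41
  expect_equal(substr(m$reads$quality, 251, 251), rawToChar(as.raw(40 + 33)))
})

test_that("pairs without a plausible overlap are rejected with a reason", {
  set.seed(33)
  pr <- data.frame(read_id = "x", r1_seq = rand_dna(200),
                   r1_qual = q40(200), r2_seq = rand_dna(200),
                   r2_qual = q40(200), stringsAsFactors = FALSE)
  m <- merge_pairs(pr)
  expect_equal(m$accounting$n_out, 0)
  expect_equal(unname(m$accounting$rejected["no_overlap"]), 1L)
  expect_equal(m$accounting$n_in,
               m$accounting$n_out + sum(m$accounting$rejected))
})

test_that("construct trimming recovers the exact insert from simulated reads", {
  db <- simulate_reference_db()
  mol <- mol16s_assay()
  comm <- mock_community("one", c(`Dreissena polymorpha` = 100))
  cfg <- simulation_config(mol, comm, db, n_read_pairs = 50, error_rate = 0,
                           chimera_rate = 0, phix_fraction = 0, q_jitter = 0,
                           spacer_set = "E", seed = 34)
  sim <- simulate_reads(cfg)
  m <- merge_pairs(sim$reads)
  tr <- trim_construct(m$reads, mol)
  expect_equal(tr$accounting$n_out, 50)
  truth_insert <- find_amplicons(
    mol, db$sequence[db$species == "Dreissena polymorpha"])$insert
  expect_true(all(tr$reads$sequence == truth_insert))
})

test_that("reads missing a primer are rejected; mismatch tolerance is honoured", {
  set.seed(35)
  mol <- mol16s_assay()
  fwd <- concrete_site(mol$forward_primer)
  rev_rc <- revcomp(concrete_site(mol$reverse_primer))
  insert <- rand_dna(180)
  good <- paste0("TCCTATG", fwd, insert, rev_rc)
  no_rev <- paste0("TCCTATG", fwd, insert, rand_dna(16))
  reads <- data.frame(read_id = c("a", "b"), sequence = c(good, no_rev),
                      stringsAsFactors = FALSE)
  tr <- trim_construct(reads, mol, max_primer_mismatch = 0)
  expect_equal(tr$reads$read_id, "a")
  expect_equal(tr$reads$sequence, insert)
  expect_equal(unname(tr$accounting$rejected["no_reverse_primer"]), 1L)

  # single substitution in the forward site: rejected at 0, trimmed at 1
  fwd_mut <- mutate_seq(fwd, 1, positions = 10)
  mut <- data.frame(read_id = "c",
                    sequence = paste0("TCCTATG", fwd_mut, insert, rev_rc),
                    stringsAsFactors = FALSE)
  expect_equal(trim_construct(mut, mol, max_primer_mismatch = 0)$accounting$n_out, 0)
  tr1 <- trim_construct(mut, mol, max_primer_mismatch = 1)
  expect_equal(tr1$reads$sequence, insert)
})

test_that("trimming is anchored: interior primer matches do not trigger", {
  set.seed(36)
  mol <- mol16s_assay()
  fwd <- concrete_site(mol$forward_primer)
  rev_rc <- revcomp(concrete_site(mol$reverse_primer))
  # forward site buried 60 nt into the read, beyond the 25 nt window
  buried <- paste0(rand_dna(60), fwd, rand_dna(150), rev_rc)
  tr <- trim_construct(data.frame(read_id = "d", sequence = buried,
                                  stringsAsFactors = FALSE), mol)
  expect_equal(tr$accounting$n_out, 0)
  expect_equal(unname(tr$accounting$rejected["no_forward_primer"]), 1L)
})

test_that("length filter boundary is inclusive at 100 bp", {
  set.seed(37)
  reads <- data.frame(read_id = c("a", "b"),
                      sequence = c(rand_dna(99), rand_dna(100)),
                      stringsAsFactors = FALSE)
  fl <- retention_filters(reads, min_length = 100, drop_singletons = FALSE)
  expect_equal(fl$reads$read_id, "b")
  expect_equal(unname(fl$accounting$rejected["short"]), 1L)
})

test_that("singleton removal uses exact-sequence multiplicity within the sample", {
  set.seed(38)
  a <- rand_dna(150); b <- rand_dna(150); c <- rand_dna(150)
  reads <- data.frame(read_id = sprintf("r%d", 1:6),
                      sequence = c(a, a, a, b, c, c),
                      stringsAsFactors = FALSE)
  fl <- retention_filters(reads, drop_singletons = TRUE)
  expect_equal(fl$accounting$n_out, 5)
  expect_equal(unname(fl$accounting$rejected["singleton"]), 1L)
  expect_false(b %in% fl$reads$sequence)
})

test_that("read accounting is conserved across every stage of random inputs", {
  db <- simulate_reference_db()
  mol <- mol16s_assay()
  cm <- builtin_communities()
  for (seed in c(51, 52)) {
    cfg <- simulation_config(mol, cm$MC3, db, n_read_pairs = 800,
                             error_rate = 0.01, chimera_rate = 0.05,
                             phix_fraction = 0.4, seed = seed)
    sim <- simulate_reads(cfg)
    m <- merge_pairs(sim$reads)
    expect_equal(m$accounting$n_in,
                 m$accounting$n_out + sum(m$accounting$rejected))
    tr <- trim_construct(m$reads, mol)
    expect_equal(tr$accounting$n_in, m$accounting$n_out)
    expect_equal(tr$accounting$n_in,
                 tr$accounting$n_out + sum(tr$accounting$rejected))
    fl <- retention_filters(tr$reads)
    expect_equal(fl$accounting$n_in,
                 fl$accounting$n_out + sum(fl$accounting$rejected))
  }
})
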