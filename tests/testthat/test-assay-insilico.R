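test_that("degenerate base matching equals the brute-force expansion table", {
  expansions <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  grid <- expand.grid(code = names(expansions), base = c("A", "C", "G", "T"),
                      stringsAsFactors = FALSE)
  want <- mapply(function(cd, b) b %in% expansions[[cd]], grid$code, grid$base)
  expect_equal(iupac_match(grid$code, grid$base), unname(want))
  # N in the target never matches, whatever the primer code
  expect_false(any(iupac_match(names(expansions), rep("N", 15))))
  expect_error(iupac_match("Z", "A"), "IUPAC")
})

test_that("in-silico PCR finds a constructed amplicon at exact coordinates", {
  set.seed(21)
  mol <- mol16s_assay()
  t <- make_template(mol, insert_len = 250)
  hits <- find_amplicons(mol, t$sequence)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, t$start)
  expect_equal(hits$end, t$end)
  expect_equal(hits$length, t$length)
  expect_equal(hits$end - hits$start, hits$length)
  expect_equal(hits$n_mismatch_fwd, 0)
  expect_equal(hits$orientation, "plus")
  expect_equal(hits$insert, t$insert)
  # primer-inclusive amplicon string check
  expect_equal(hits$amplicon, paste0(t$fwd_site, t$insert, revcomp(t$rev_site)))
})

test_that("missing reverse site yields no amplicon; mismatch tolerance is respected", {
  set.seed(22)
  mol <- mol16s_assay()
  t <- make_template(mol, insert_len = 200)
  no_rev <- paste0(rand_dna(20), t$fwd_site, t$insert, rand_dna(40))
  expect_equal(nrow(find_amplicons(mol, no_rev)), 0)

  # one substitution inside the forward site at a non-degenerate position
  fwd_chars <- strsplit(t$fwd_site, "")[[1]]
  pos <- 10  # RRWRGACRAGAAGACCCT: position 10 is a fixed 'G' in the primer
  fwd_mut <- fwd_chars; fwd_mut[pos] <- setdiff(c("A","C","G","T"), fwd_chars[pos])[1]
  seq_mut <- sub(t$fwd_site, paste(fwd_mut, collapse = ""), t$sequence, fixed = TRUE)
  expect_equal(nrow(find_amplicons(mol, seq_mut, max_mismatch = 0)), 0)
  h1 <- find_amplicons(mol, seq_mut, max_mismatch = 1)
  expect_equal(nrow(h1), 1)
  expect_equal(h1$n_mismatch_fwd, 1)
  expect_equal(h1$n_mismatch_rev, 0)
})

test_that("amplicon discovery is strand-symmetric with flipped orientation", {
  set.seed(23)
  mol <- mol16s_assay()
  for (i in 1:5) {
    t <- make_template(mol, insert_len = 150 + 20 * i)
    plus <- find_amplicons(mol, t$sequence)
    minus <- find_amplicons(mol, revcomp(t$sequence))
    expect_equal(nrow(minus), nrow(plus))
    expect_equal(minus$orientation, rep("minus", nrow(minus)))
    expect_equal(minus$amplicon, plus$amplicon)
    # coordinates map back through the reverse complement
    L <- nchar(t$sequence)
    expect_equal(minus$start, L - plus$end)
    expect_equal(minus$end, L - plus$start)
  }
})

test_that("specificity matrix separates target and non-target templates", {
  set.seed(24)
  sph <- sph16s_assay(); mol <- mol16s_assay()
  # two sphaeriid-like templates carry both assays' sites, two carry MOL only
  make_both <- function() {
    inner <- make_template(mol, insert_len = 150, pad5 = 0, pad3 = 0)
    paste0(rand_dna(15), concrete_site(sph$forward_primer), rand_dna(10),
           inner$sequence, rand_dna(10),
           revcomp(concrete_site(sph$reverse_primer)), rand_dna(15))
  }
  seqs <- c(make_both(), make_both(),
            make_template(mol, insert_len = 220)$sequence,
            make_template(mol, insert_len = 240)$sequence)
  db <- make_refdb(paste0("S", 1:4),
                   c("Clam A", "Clam B", "Mussel C", "Mussel D"), seqs)
  got_sph <- specificity_matrix(sph, db)
  expect_equal(got_sph$records$amplifies, c(TRUE, TRUE, FALSE, FALSE))
  got_mol <- specificity_matrix(mol, db)
  expect_true(all(got_mol$records$amplifies))
  # empty database: empty tables
  empty <- specificity_matrix(sph, make_refdb(character(0), character(0),
                                              character(0)))
  expect_equal(nrow(empty$records), 0)
  expect_equal(nrow(empty$species), 0)
})

test_that("blocking-primer overlap matches a brute-force scan", {
  mol <- mol16s_assay()
  rpt <- blocking_overlap_report(mol)
  expect_true(rpt$applicable)
  expect_true(rpt$extension_blocked)
  # independent brute-force suffix/prefix oracle over both orientations
  compat <- function(a, b) {
    ex <- list(A="A",C="C",G="G",T="T",R=c("A","G"),Y=c("C","T"),S=c("C","G"),
               W=c("A","T"),K=c("G","T"),M=c("A","C"),B=c("C","G","T"),
               D=c("A","G","T"),H=c("A","C","T"),V=c("A","C","G"),
               N=c("A","C","G","T"))
    all(mapply(function(x, y) length(intersect(ex[[x]], ex[[y]])) > 0,
               strsplit(a, "")[[1]], strsplit(b, "")[[1]]))
  }
  brute <- function(a, b) {
    best <- 0
    for (k in seq_len(min(nchar(a), nchar(b)))) {
      if (compat(substr(a, nchar(a) - k + 1, nchar(a)), substr(b, 1, k)))
        best <- k
    }
    best
  }
  want <- max(brute(mol$reverse_primer, mol$blocking_primer),
              brute(mol$reverse_primer, revcomp(mol$blocking_primer)))
  expect_equal(rpt$overlap_length, want)

  # no blocking primer: explicit not-applicable result
  na_rep <- blocking_overlap_report(sph16s_assay())
  expect_false(na_rep$applicable)
  expect_true(is.na(na_rep$overlap_length))

  # blocking primer identical to the reverse primer overlaps fully
  ident <- assay_definition("x", "ACGTACGTAC", "TTGGCCAATT",
                            blocking_primer = "TTGGCCAATT")
  expect_equal(blocking_overlap_report(ident)$overlap_length, 10)
})
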