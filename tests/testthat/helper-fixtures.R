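# Fixture builders and independent oracles shared across the test files.
# Everything is generated in code; no binary fixtures.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Replace degenerate positions by the first base of their expansion:
# deterministic concrete primer site.
concrete_site <- function(primer) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "A", Y = "C", S = "C",
           W = "A", K = "G", M = "A", B = "C", D = "A", H = "A", V = "A",
           N = "A")
  paste(map[strsplit(primer, "")[[1]]], collapse = "")
}

# Template with one exact amplicon at known coordinates:
# pad5 + fwd site + insert + revcomp(rev site) + pad3.
make_template <- function(assay, insert_len = 250, pad5 = 20, pad3 = 20,
                          fwd_site = concrete_site(assay$forward_primer),
                          rev_site = concrete_site(assay$reverse_primer)) {
  insert <- rand_dna(insert_len)
  seq <- paste0(rand_dna(pad5), fwd_site, insert,
                molbarval::revcomp(rev_site), rand_dna(pad3))
  list(sequence = seq, insert = insert, fwd_site = fwd_site,
       rev_site = rev_site,
       start = pad5,                                    # 0-based
       end = pad5 + nchar(fwd_site) + insert_len + nchar(rev_site),
       length = nchar(fwd_site) + insert_len + nchar(rev_site))
}

# Small reference_db from explicit sequences.
make_refdb <- function(accessions, species, sequences,
                       higher = rep(NA_character_, length(accessions))) {
  db <- data.frame(accession = accessions, species = species,
                   higher_taxon = higher, sequence = toupper(sequences),
                   source = rep("fixture", length(accessions)),
                   stringsAsFactors = FALSE)
  class(db) <- c("reference_db", "data.frame")
  db
}

write_fixture_fasta <- function(accessions, sequences, path) {
  writeLines(as.vector(rbind(paste0(">", accessions), sequences)), path)
  path
}

write_fixture_taxonomy <- function(accessions, species, path) {
  writeLines(c("accession\tspecies",
               paste(accessions, species, sep = "\t")), path)
  path
}

# Substitute k bases of a sequence at given (or random) positions.
mutate_seq <- function(seq, k, positions = NULL) {
  ch <- strsplit(seq, "")[[1]]
  if (is.null(positions)) positions <- sample(seq_along(ch), k)
  for (p in positions) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

# Brute-force OLS oracle (closed form), independent of stats::lm.
ols_oracle <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  intercept <- my - slope * mx
  yhat <- intercept + slope * x
  ss_res <- sum((y - yhat)^2); ss_tot <- sum((y - my)^2)
  se <- sqrt(ss_res / (n - 2) / sum((x - mx)^2))
  tval <- slope / se
  list(slope = slope, intercept = intercept,
       r_squared = 1 - ss_res / ss_tot,
       p_value = 2 * pt(-abs(tval), df = n - 2))
}

# Quadratic-time local-alignment oracle: exhaustive ungapped segment search
# over all diagonals (Kadane per diagonal) under the package's match +2 /
# mismatch -3 scoring. On substitution-only instances with isolated
# mismatches this equals the affine-gap optimum: under gap open -5 /
# extend -2, bridging even one mismatch with a gap pair costs at least 14
# against a 5-point gain, so gaps never pay. Returns score, identity %
# (matches over alignment columns) and query coverage % of the optimum.
ungapped_local_oracle <- function(query, ref, match = 2, mismatch = -3) {
  q <- strsplit(query, "")[[1]]; r <- strsplit(ref, "")[[1]]
  n <- length(q); m <- length(r)
  best <- list(score = 0, identity = NA_real_, coverage = 0)
  for (d in (-(n - 1)):(m - 1)) {       # diagonal: j = i + d
    i0 <- max(1, 1 - d); i1 <- min(n, m - d)
    if (i0 > i1) next
    run_score <- 0; run_start <- i0; run_match <- 0
    for (i in i0:i1) {
      s <- if (q[i] == r[i + d]) match else mismatch
      if (run_score <= 0) { run_score <- 0; run_start <- i; run_match <- 0 }
      run_score <- run_score + s
      if (s > 0) run_match <- run_match + 1 else run_match <- run_match
      if (run_score > best$score) {
        cols <- i - run_start + 1
        # recount matches within [run_start, i] (run_match tracks adds but
        # resets only at run starts, so it is exact for the current run)
        nm <- sum(q[run_start:i] == r[(run_start:i) + d])
        best <- list(score = run_score, identity = 100 * nm / cols,
                     coverage = 100 * cols / n)
      }
    }
  }
  best
}
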