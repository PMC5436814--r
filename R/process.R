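#' Per-stage read accounting
#'
#' Every processing stage returns, alongside its reads, an accounting record
#' obeying the conservation law `n_in = n_out + sum(rejections)`.
#'
#' @param stage stage name.
#' @param n_in,n_out read counts entering and leaving the stage.
#' @param rejected named integer vector of rejection counts by reason.
#' @return a `stage_accounting` list.
#' @export
stage_accounting <- function(stage, n_in, n_out, rejected = integer(0)) {
  n_in <- as.integer(n_in); n_out <- as.integer(n_out)
  rejected <- setNames(as.integer(rejected), names(rejected))
  if (n_in != n_out + sum(rejected)) {
    stop(sprintf("accounting violation at stage '%s': %d in != %d out + %d rejected",
                 stage, n_in, n_out, sum(rejected)), call. = FALSE)
  }
  structure(list(stage = stage, n_in = n_in, n_out = n_out,
                 rejected = rejected),
            class = "stage_accounting")
}

#' @export
print.stage_accounting <- function(x, ...) {
  cat(sprintf("<stage_accounting> %s: %d in, %d out", x$stage, x$n_in, x$n_out))
  if (length(x$rejected)) {
    cat(" (", paste(sprintf("%s=%d", names(x$rejected), x$rejected),
                    collapse = ", "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @noRd
accounting_df <- function(acc) {
  do.call(rbind, lapply(acc, function(a) {
    data.frame(stage = a$stage, n_in = a$n_in, n_out = a$n_out,
               n_rejected = sum(a$rejected),
               reasons = paste(sprintf("%s=%d", names(a$rejected), a$rejected),
                               collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}

#' Merge paired-end reads by overlap
#'
#' For each pair, R2 is reverse-complemented and slid over R1; the overlap
#' with the smallest mismatch rate (ties to the longer overlap) wins,
#' provided it spans at least `min_overlap` bases at no more than
#' `max_mismatch_rate` mismatches. Disagreeing positions take the
#' higher-quality base and carry the lower of the two qualities; agreements
#' take the max quality capped at Q41. Unmergeable pairs are rejected and
#' counted, never dropped silently.
#'
#' @param pairs data frame with `read_id`, `r1_seq`, `r1_qual`, `r2_seq`,
#'   `r2_qual` (e.g. the `reads` of [simulate_reads()]).
#' @param min_overlap minimum overlap in bp (default 16).
#' @param max_mismatch_rate maximum fraction of mismatching positions in
#'   the overlap (default 0.1).
#' @return list with `reads` (data frame `read_id`, `sequence`, `quality`)
#'   and `accounting` (a [stage_accounting()]).
#' @export
merge_pairs <- function(pairs, min_overlap = 16, max_mismatch_rate = 0.1) {
  stopifnot(all(c("read_id", "r1_seq", "r1_qual", "r2_seq", "r2_qual") %in%
                  names(pairs)))
  n <- nrow(pairs)
  if (n == 0) {
    return(list(reads = data.frame(read_id = character(0),
                                   sequence = character(0),
                                   quality = character(0),
                                   stringsAsFactors = FALSE),
                accounting = stage_accounting("merge", 0L, 0L)))
  }
  r2rc <- revcomp(pairs$r2_seq)
  q2rev <- reverse_string(pairs$r2_qual)
  res <- cpp_merge_pairs(pairs$r1_seq, r2rc, pairs$r1_qual, q2rev,
                         as.integer(min_overlap), max_mismatch_rate)
  ok <- res$ok
  reads <- data.frame(read_id = pairs$read_id[ok],
                      sequence = res$merged[ok],
                      quality = res$quality[ok],
                      stringsAsFactors = FALSE, row.names = NULL)
  acc <- stage_accounting("merge", n, sum(ok),
                          c(no_overlap = sum(!ok)))
  list(reads = reads, accounting = acc)
}

#' Trim the library construct down to the biological insert
#'
#' Locates the degenerate forward primer near the 5' end (its start must
#' fall within `fwd_window` bases — spacers are at most 17 nt, so a matched
#' primer further into the read is treated as a false interior hit) and the
#' reverse complement of the reverse primer near the 3' end, then removes
#' everything outside the insert: spacers, sequencing-primer tails and the
#' primers themselves. Reads lacking either primer are rejected with a
#' reason.
#'
#' @param reads data frame with `read_id`, `sequence` and optionally
#'   `quality` (merged reads).
#' @param assay an [assay_definition()].
#' @param max_primer_mismatch mismatches tolerated per primer (default 1).
#' @param fwd_window,rev_window anchoring windows: the forward primer must
#'   start within `fwd_window` bases of the 5' end, the reverse primer must
#'   end within `rev_window` bases of the 3' end (defaults 25).
#' @return list with `reads` (insert sequences, with qualities when given)
#'   and `accounting`.
#' @export
trim_construct <- function(reads, assay, max_primer_mismatch = 1,
                           fwd_window = 25, rev_window = 25) {
  stopifnot(inherits(assay, "assay_definition"),
            all(c("read_id", "sequence") %in% names(reads)))
  n <- nrow(reads)
  if (n == 0) {
    return(list(reads = reads,
                accounting = stage_accounting("trim", 0L, 0L)))
  }
  fwd <- assay$forward_primer
  rev_rc <- revcomp(assay$reverse_primer)
  fs <- cpp_locate_primer_5p(reads$sequence, fwd,
                             as.integer(max_primer_mismatch),
                             as.integer(fwd_window))
  rs <- cpp_locate_primer_3p(reads$sequence, rev_rc,
                             as.integer(max_primer_mismatch),
                             as.integer(rev_window))
  ins_start <- fs + nchar(fwd)        # 0-based
  ok <- fs >= 0 & rs >= 0 & rs >= ins_start
  reason <- ifelse(fs < 0, "no_forward_primer",
                   ifelse(rs < 0, "no_reverse_primer", "empty_insert"))
  out <- reads[ok, , drop = FALSE]
  out$sequence <- substr(out$sequence, ins_start[ok] + 1, rs[ok])
  if ("quality" %in% names(out)) {
    out$quality <- substr(out$quality, ins_start[ok] + 1, rs[ok])
  }
  rej <- table(factor(reason[!ok],
                      levels = c("no_forward_primer", "no_reverse_primer",
                                 "empty_insert")))
  acc <- stage_accounting("trim", n, sum(ok),
                          setNames(as.integer(rej), names(rej)))
  list(reads = out, accounting = acc)
}

#' Length and singleton retention filters
#'
#' Removes inserts shorter than `min_length` (default 100 bp, boundary
#' inclusive: a 100 bp read is retained) and, when `drop_singletons`,
#' sequences whose exact string occurs only once in the sample —
#' the standard guard against stray error reads and trace contamination.
#'
#' @param reads data frame with `read_id`, `sequence` (and optionally
#'   `quality`).
#' @param min_length minimum insert length in bp.
#' @param drop_singletons remove exact-sequence singletons?
#' @return list with `reads` and `accounting`.
#' @export
retention_filters <- function(reads, min_length = 100, drop_singletons = TRUE) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  n <- nrow(reads)
  if (n == 0) {
    return(list(reads = reads,
                accounting = stage_accounting("filter", 0L, 0L)))
  }
  short <- nchar(reads$sequence) < min_length
  keep <- !short
  singleton <- rep(FALSE, n)
  if (drop_singletons) {
    counts <- table(reads$sequence[keep])
    singleton <- keep & reads$sequence %in% names(counts)[counts == 1]
    keep <- keep & !singleton
  }
  acc <- stage_accounting("filter", n, sum(keep),
                          c(short = sum(short), singleton = sum(singleton)))
  list(reads = reads[keep, , drop = FALSE], accounting = acc)
}
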