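#' Observed read percentages from per-species counts
#'
#' @param counts named numeric vector, species -> read count; at least one
#'   positive.
#' @return data frame with `species`, `read_count`, `pct_observed`
#'   (percentages sum to 100). Rounding is left to the presentation layer.
#' @export
observed_percentages <- function(counts) {
  stopifnot(is.numeric(counts), !is.null(names(counts)))
  total <- sum(counts)
  if (total <= 0) stop("all read counts are zero", call. = FALSE)
  data.frame(species = names(counts),
             read_count = as.numeric(counts),
             pct_observed = 100 * as.numeric(counts) / total,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Observed-versus-expected abundance table for one sample
#'
#' @param counts named numeric vector of per-species read counts.
#' @param community a [mock_community()].
#' @param amplifiable passed to [expected_fractions()].
#' @return data frame with `species`, `read_count`, `pct_observed`,
#'   `pct_expected`.
#' @export
abundance_table <- function(counts, community, amplifiable = NULL) {
  exp <- expected_fractions(community, amplifiable)
  sp <- names(exp)
  cnt <- setNames(numeric(length(sp)), sp)
  cnt[names(counts)[names(counts) %in% sp]] <-
    counts[names(counts) %in% sp]
  obs <- observed_percentages(cnt)
  obs$pct_expected <- as.numeric(exp[obs$species])
  obs
}

#' Log-log regression of observed on expected read percentages
#'
#' Ordinary least squares of `log10(observed)` on `log10(expected)`. A
#' slope of 1 with intercept 0 means read abundances recover input
#' abundances exactly; the slope's two-sided t-test p-value quantifies
#' whether the relationship is significant. Zero observed percentages have
#' no logarithm; the default policy excludes them (and counts the
#' exclusions), the alternative floors them at a pseudo-percentage.
#'
#' @param expected,observed numeric percentage vectors of equal length
#'   (expected must be positive for included points).
#' @param zero_policy `"exclude"` (default) or `"floor"`.
#' @param floor_value pseudo-percentage used under `zero_policy = "floor"`.
#' @return a list of class `loglog_regression`: `slope`, `intercept`,
#'   `r_squared`, `p_value` (two-sided t-test on the slope), `n_points`,
#'   `excluded_zero_count`.
#' @export
loglog_regression <- function(expected, observed,
                              zero_policy = c("exclude", "floor"),
                              floor_value = 1e-3) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(length(expected) == length(observed))
  keep <- expected > 0
  zero_obs <- keep & observed <= 0
  if (zero_policy == "exclude") {
    use <- keep & observed > 0
    excluded <- sum(zero_obs)
  } else {
    observed[zero_obs] <- floor_value
    use <- keep
    excluded <- 0L
  }
  if (sum(use) < 3) {
    stop(sprintf("need >= 3 usable points, have %d", sum(use)), call. = FALSE)
  }
  x <- log10(expected[use]); y <- log10(observed[use])
  fit <- lm(y ~ x)
  s <- suppressWarnings(summary(fit))
  p <- if (df.residual(fit) >= 1) s$coefficients[2, 4] else NA_real_
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = s$r.squared, p_value = p,
                 n_points = sum(use),
                 excluded_zero_count = as.integer(excluded),
                 zero_policy = zero_policy),
            class = "loglog_regression")
}

#' @export
print.loglog_regression <- function(x, ...) {
  cat(sprintf("<loglog_regression> slope %.3f  intercept %.3f  R^2 %.3f  p %.3g  n %d (%d zero-observed excluded)\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n_points,
              x$excluded_zero_count))
  invisible(x)
}

#' Observed-vs-expected regressions across a set of samples
#'
#' Runs [loglog_regression()] within each community (across species) and
#' within each species (across communities), the two standard views of a
#' mock-community validation: per-community fits ask whether rank abundance
#' is preserved inside one sample, per-species fits whether a taxon's
#' recovery scales with its input across samples.
#'
#' @param tbl data frame with columns `community_id`, `species`,
#'   `pct_expected`, `pct_observed`.
#' @param zero_policy passed to [loglog_regression()].
#' @return data frame with `unit_type` (`community`/`species`), `unit`,
#'   `slope`, `intercept`, `r_squared`, `p_value`, `n_points`,
#'   `excluded_zero_count`. Units with fewer than 3 usable points are
#'   skipped.
#' @export
regress_observed_expected <- function(tbl, zero_policy = "exclude") {
  stopifnot(all(c("community_id", "species", "pct_expected", "pct_observed")
                %in% names(tbl)))
  run <- function(unit_type, unit, d) {
    r <- tryCatch(loglog_regression(d$pct_expected, d$pct_observed,
                                    zero_policy = zero_policy),
                  error = function(e) NULL)
    if (is.null(r)) return(NULL)
    data.frame(unit_type = unit_type, unit = unit, slope = r$slope,
               intercept = r$intercept, r_squared = r$r_squared,
               p_value = r$p_value, n_points = r$n_points,
               excluded_zero_count = r$excluded_zero_count,
               stringsAsFactors = FALSE)
  }
  res <- list()
  for (cc in unique(tbl$community_id)) {
    res[[length(res) + 1]] <- run("community", cc,
                                  tbl[tbl$community_id == cc, ])
  }
  for (sp in unique(tbl$species)) {
    res[[length(res) + 1]] <- run("species", sp, tbl[tbl$species == sp, ])
  }
  do.call(rbind, res)
}

#' Blocking-primer reduction of a taxon's amplification
#'
#' Percentage reduction in a taxon's observed read share attributable to
#' the blocking primer: `100 * (1 - with/without)`. Negative values mean
#' the share rose. With observed share 0 with the blocker and positive
#' without, the reduction is complete (100); when the share without the
#' blocker is 0 the ratio is undefined and `NA` is returned.
#'
#' @param pct_with_block,pct_without_block observed percentages with and
#'   without the blocking primer (vectorised).
#' @return numeric vector of percent reductions (`NA` where undefined).
#' @export
blocking_reduction <- function(pct_with_block, pct_without_block) {
  stopifnot(length(pct_with_block) == length(pct_without_block))
  out <- 100 * (1 - pct_with_block / pct_without_block)
  out[pct_without_block == 0] <- NA_real_
  out
}
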