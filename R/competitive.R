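#' Estimate native-template copy number from a competitive-PCR series
#'
#' In competitive PCR a fixed amount of native template (NT) is co-amplified
#' with a serially diluted internal standard (IS) sharing the same primer
#' sites. The log10 ratio of NT to IS product molarity is regressed on the
#' log10 IS input copy number; because NT and IS compete equally, the ideal
#' slope is -1 and the x at which the ratio is 1:1 — read off as
#' 10^intercept — is the NT copy number per reaction.
#'
#' @param series data frame with columns `is_copies` (> 0, copies/reaction),
#'   `nt_molarity` (>= 0) and `is_molarity` (> 0). Points with
#'   `nt_molarity == 0` (NT out-competed) are excluded from the fit and
#'   counted.
#' @param slope_tolerance warn when the fitted slope deviates from -1 by
#'   more than this (default 0.15).
#' @return a list of class `copy_number_estimate`: `nt_copies`
#'   (`10^intercept`), `nt_copies_root` (the diagnostic root-solving
#'   alternative `10^(-intercept/slope)`), `slope`, `intercept`,
#'   `r_squared`, `n_points`, `n_excluded_zero`, `slope_warning`.
#' @export
estimate_copy_number <- function(series, slope_tolerance = 0.15) {
  req <- c("is_copies", "nt_molarity", "is_molarity")
  stopifnot(all(req %in% names(series)))
  if (any(series$is_molarity <= 0)) {
    stop("is_molarity must be strictly positive", call. = FALSE)
  }
  if (any(series$is_copies <= 0)) {
    stop("is_copies must be strictly positive", call. = FALSE)
  }
  usable <- series$nt_molarity > 0
  n_excluded <- sum(!usable)
  s <- series[usable, , drop = FALSE]
  if (nrow(s) < 3) {
    stop(sprintf("need >= 3 usable points, have %d (%d excluded for zero NT molarity)",
                 nrow(s), n_excluded), call. = FALSE)
  }
  x <- log10(s$is_copies)
  y <- log10(s$nt_molarity / s$is_molarity)
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  r2 <- suppressWarnings(summary(fit))$r.squared
  warn <- !is.finite(slope) || abs(slope + 1) > slope_tolerance
  if (warn) {
    warning(sprintf("competitive-PCR slope %.3f deviates from the ideal -1 by more than %.2f; copy-number estimate may be unreliable",
                    slope, slope_tolerance), call. = FALSE)
  }
  structure(list(nt_copies = 10^intercept,
                 nt_copies_root = if (is.finite(slope) && slope != 0)
                   10^(-intercept / slope) else NA_real_,
                 slope = slope, intercept = intercept, r_squared = r2,
                 n_points = nrow(s), n_excluded_zero = n_excluded,
                 slope_warning = warn),
            class = "copy_number_estimate")
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat(sprintf("<copy_number_estimate> NT = %.4g copies/reaction (10^intercept)\n",
              x$nt_copies))
  cat(sprintf("  slope %.3f  intercept %.3f  R^2 %.4f  n %d (%d zero-NT excluded)%s\n",
              x$slope, x$intercept, x$r_squared, x$n_points, x$n_excluded_zero,
              if (x$slope_warning) "  [slope warning]" else ""))
  invisible(x)
}

#' Convert copy-number targets into extraction volumes
#'
#' Mock-community recipes are built by pipetting, per species, the volume of
#' DNA extraction that delivers the desired target-amplicon copy number:
#' `volume = copies / concentration`.
#'
#' @param targets named numeric vector, species -> desired copies.
#' @param extraction_concentrations named numeric vector, species ->
#'   copies/µl (all > 0); must cover every target species.
#' @return data frame with `species`, `copies`, `concentration`,
#'   `volume_ul`, plus a `total_volume_ul` attribute.
#' @export
recipe_volumes <- function(targets, extraction_concentrations) {
  stopifnot(!is.null(names(targets)), !is.null(names(extraction_concentrations)))
  missing <- setdiff(names(targets), names(extraction_concentrations))
  if (length(missing)) {
    stop("no extraction concentration for species: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  conc <- extraction_concentrations[names(targets)]
  zero <- names(conc)[conc <= 0]
  if (length(zero)) {
    stop("non-positive extraction concentration for species: ",
         paste(zero, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(species = names(targets),
                    copies = as.numeric(targets),
                    concentration = as.numeric(conc),
                    volume_ul = as.numeric(targets) / as.numeric(conc),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "total_volume_ul") <- sum(out$volume_ul)
  out
}

#' Design a size-shifted internal standard from a target amplicon
#'
#' Produces the synthetic competitor for competitive PCR: the target
#' amplicon with a centred interior deletion (default 10% of the amplicon
#' length, carved from the insert) so
#' IS and NT products separate by size on an electropherogram while sharing
#' both primer sites.
#'
#' @param amplicon nucleotide string of the full target amplicon
#'   (primer-inclusive).
#' @param deletion_fraction fraction of the insert to delete, in (0, 0.5).
#' @param primer_length length of each terminal primer site, left intact.
#' @return the internal-standard sequence (deterministic).
#' @export
design_internal_standard <- function(amplicon, deletion_fraction = 0.10,
                                     primer_length = 20) {
  stopifnot(is.character(amplicon), length(amplicon) == 1)
  if (!(deletion_fraction > 0 && deletion_fraction < 0.5)) {
    stop("deletion_fraction must lie strictly between 0 and 0.5", call. = FALSE)
  }
  L <- nchar(amplicon)
  insert_len <- L - 2 * primer_length
  if (insert_len <= 0) stop("amplicon shorter than its two primer sites", call. = FALSE)
  # the IS is deletion_fraction shorter than the whole amplicon, with the
  # deletion carved from the insert so both primer sites stay intact
  del <- round(deletion_fraction * L)
  if (del >= insert_len) {
    stop("deletion would reach a primer site", call. = FALSE)
  }
  if (del == 0) return(amplicon)
  # centre the deletion within the insert
  keep_left <- primer_length + floor((insert_len - del) / 2)
  paste0(substr(amplicon, 1, keep_left),
         substr(amplicon, keep_left + del + 1, L))
}
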