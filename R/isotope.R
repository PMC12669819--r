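#' 13C/12C ratio of the VPDB reference standard
#'
#' The Vienna Pee Dee Belemnite (VPDB) carbon isotope ratio used as the
#' reference point of the delta-13C scale. Community values differ in the
#' fifth decimal; every conversion in this package accepts an explicit
#' \code{r_vpdb} so the choice is visible rather than hidden. Downstream
#' ratio-of-fraction quantities (assimilation rates, turnover times) are
#' nearly invariant to it.
#'
#' @return The default 13C/12C ratio, 0.011180.
#' @export
vpdb_ratio <- function() 0.011180

#' Convert delta-13C to 13C atom fraction
#'
#' Converts a delta-13C value (per mil vs VPDB) to the 13C atom fraction
#' F13C = R/(1+R), where R = (delta/1000 + 1) * r_vpdb is the sample
#' 13C/12C ratio. The atom fraction is the mass-balance-linear isotope
#' variable used by all rate estimators.
#'
#' @param delta Numeric vector of delta-13C values in per mil vs VPDB.
#'   Must be greater than -1000 (a delta of -1000 or below implies a
#'   non-positive isotope ratio).
#' @param r_vpdb 13C/12C ratio of the reference standard.
#' @return Numeric vector of 13C atom fractions in (0, 1).
#' @examples
#' delta_to_fraction(0)       # ~0.011056, the VPDB atom fraction
#' delta_to_fraction(4829)    # ~0.0612, a 10%-labelled DIC pool
#' @seealso [fraction_to_delta()] for the inverse.
#' @export
delta_to_fraction <- function(delta, r_vpdb = vpdb_ratio()) {
  stopifnot(is.numeric(delta), is.numeric(r_vpdb), r_vpdb > 0)
  bad <- !is.na(delta) & delta <= -1000
  if (any(bad)) {
    stop("delta-13C must exceed -1000 per mil (got ",
         paste(format(delta[bad]), collapse = ", "),
         "): the implied 13C/12C ratio is not positive")
  }
  r <- (delta / 1000 + 1) * r_vpdb
  r / (1 + r)
}

#' Convert 13C atom fraction to delta-13C
#'
#' Exact inverse of [delta_to_fraction()]:
#' delta = 1000 * (R/r_vpdb - 1) with R = f/(1-f).
#'
#' @param f Numeric vector of atom fractions, each strictly in (0, 1).
#' @param r_vpdb 13C/12C ratio of the reference standard.
#' @return Numeric vector of delta-13C values in per mil vs VPDB.
#' @export
fraction_to_delta <- function(f, r_vpdb = vpdb_ratio()) {
  stopifnot(is.numeric(f), is.numeric(r_vpdb), r_vpdb > 0)
  bad <- !is.na(f) & (f <= 0 | f >= 1)
  if (any(bad)) {
    stop("atom fraction must lie strictly in (0, 1); got ",
         paste(format(f[bad]), collapse = ", "))
  }
  r <- f / (1 - f)
  1000 * (r / r_vpdb - 1)
}

#' Label-induced shift in delta-13C
#'
#' The delta-delta-13C of a labelling experiment: the labelled sample's
#' delta-13C minus its unlabelled baseline (the time-matched non-labelled
#' parallel treatment when available, else the day-0 value).
#'
#' @param labelled,baseline delta-13C values in per mil.
#' @return labelled - baseline, in per mil.
#' @export
label_shift <- function(labelled, baseline) {
  stopifnot(is.numeric(labelled), is.numeric(baseline))
  labelled - baseline
}

#' Excess atom fraction of a labelled source pool
#'
#' The atom-fraction contrast between a 13C-labelled source pool and the
#' unlabelled background it feeds, F(source) - F(background). This is the
#' denominator of the label-transfer methane-oxidation estimator: it is the
#' fraction of source-derived carbon that is detectable as excess 13C.
#'
#' @param source delta-13C (per mil) of the labelled source pool.
#' @param background delta-13C (per mil) of the unlabelled background pool.
#' @param r_vpdb 13C/12C ratio of the reference standard.
#' @return Atom-fraction difference (dimensionless). A warning is issued
#'   when the contrast is not positive (no usable label).
#' @export
excess_fraction <- function(source, background, r_vpdb = vpdb_ratio()) {
  ex <- delta_to_fraction(source, r_vpdb) - delta_to_fraction(background, r_vpdb)
  if (any(!is.na(ex) & ex <= 0)) {
    warning("excess atom fraction is not positive: no usable label contrast ",
            "between source and background")
  }
  ex
}
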