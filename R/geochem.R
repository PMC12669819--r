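#' Incubation bottle metadata
#'
#' @param v_medium_L Liquid medium volume in litres.
#' @param dry_mass_g Sediment dry mass in grams (g_dw), the normalisation
#'   basis of all rates.
#' @param headspace_L Gas headspace volume in litres (informational; the
#'   estimators never use it).
#' @return Object of class \code{sip_bottle}.
#' @export
sip_bottle <- function(v_medium_L = 0.1, dry_mass_g = 3.4, headspace_L = 0.1) {
  stopifnot(is.numeric(v_medium_L), v_medium_L > 0,
            is.numeric(dry_mass_g), dry_mass_g > 0,
            is.numeric(headspace_L), headspace_L >= 0)
  structure(list(v_medium_L = v_medium_L, dry_mass_g = dry_mass_g,
                 headspace_L = headspace_L),
            class = "sip_bottle")
}

#' @export
print.sip_bottle <- function(x, ...) {
  cat(sprintf("Incubation bottle: %.3g L medium, %.3g g dry sediment, %.3g L headspace\n",
              x$v_medium_L, x$dry_mass_g, x$headspace_L))
  invisible(x)
}

#' Per-treatment incubation geochemistry series
#'
#' Bundles the measured geochemical time series of one incubation treatment
#' (delta-13C of CH4 and DIC; concentrations of DIC, sulphate, sulphide in
#' mM) with its bottle metadata. Days must be strictly increasing and
#' include day 0; concentrations must be non-negative.
#'
#' @param data A data.frame with columns \code{day}, and any of
#'   \code{d13c_ch4}, \code{d13c_dic} (per mil), \code{dic_mM},
#'   \code{so4_mM}, \code{h2s_mM}. NA marks not-analysed entries.
#' @param bottle A [sip_bottle()].
#' @param treatment Treatment label.
#' @return Object of class \code{incubation_series} (a data.frame with
#'   \code{bottle} and \code{treatment} attributes).
#' @export
incubation_series <- function(data, bottle = sip_bottle(),
                              treatment = "unnamed") {
  stopifnot(is.data.frame(data), "day" %in% names(data),
            inherits(bottle, "sip_bottle"))
  data <- as.data.frame(data)
  if (anyNA(data$day)) stop("day column must not contain NA")
  if (is.unsorted(data$day, strictly = TRUE)) {
    stop("days must be strictly increasing")
  }
  if (!0 %in% data$day) stop("the series must contain a day-0 record")
  conc_cols <- intersect(c("dic_mM", "so4_mM", "h2s_mM"), names(data))
  for (cc in conc_cols) {
    neg <- !is.na(data[[cc]]) & data[[cc]] < 0
    if (any(neg)) {
      stop("negative concentration in column '", cc, "' at day ",
           paste(data$day[neg], collapse = ", "))
    }
  }
  structure(data, bottle = bottle, treatment = treatment,
            class = c("incubation_series", "data.frame"))
}

series_row <- function(series, day) {
  i <- match(day, series$day)
  if (is.na(i)) {
    stop("no record at day ", day, " in treatment '",
         attr(series, "treatment"), "' (available days: ",
         paste(series$day, collapse = ", "), ")")
  }
  series[i, , drop = FALSE]
}

new_rate_estimate <- function(value, units, analyte, window, provenance) {
  structure(list(value = value, units = units, analyte = analyte,
                 window = window, provenance = provenance),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("%s: %s %s  (window day %g-%g)\n",
              x$analyte, format(x$value, digits = digits), x$units,
              x$window[1], x$window[2]))
  invisible(x)
}

#' Bulk production or consumption rate from a concentration change
#'
#' Converts the measured change in concentration of an analyte (mM) over an
#' incubation window into a rate per gram sediment dry weight:
#' \deqn{rate = \Delta conc \times V_{medium} \times 1000 / (m_{dw} \times \Delta t)}
#' in umol g_dw^-1 d^-1. Negative values signal net consumption (e.g.
#' sulphate drawdown).
#'
#' @param series An [incubation_series()].
#' @param analyte One of \code{"dic"}, \code{"so4"}, \code{"h2s"}.
#' @param window Length-2 numeric: start and end day; both must be sampled.
#'   Defaults to day 0 through the last sampled day.
#' @return A \code{rate_estimate} in umol g_dw^-1 d^-1.
#' @export
production_rate <- function(series, analyte = c("dic", "so4", "h2s"),
                            window = NULL) {
  stopifnot(inherits(series, "incubation_series"))
  analyte <- match.arg(analyte)
  col <- paste0(analyte, "_mM")
  if (!col %in% names(series)) {
    stop("series has no column '", col, "' for analyte '", analyte, "'")
  }
  if (is.null(window)) window <- c(0, max(series$day))
  stopifnot(length(window) == 2L)
  if (window[2] <= window[1]) stop("window must satisfy day_end > day_start")
  c0 <- series_row(series, window[1])[[col]]
  c1 <- series_row(series, window[2])[[col]]
  if (is.na(c0) || is.na(c1)) {
    stop("analyte '", analyte, "' not analysed at one of the window days")
  }
  bottle <- attr(series, "bottle")
  dt <- window[2] - window[1]
  rate <- (c1 - c0) * bottle$v_medium_L * 1000 / (bottle$dry_mass_g * dt)
  new_rate_estimate(rate, "umol g_dw^-1 d^-1", analyte, window,
                    list(conc_start_mM = c0, conc_end_mM = c1,
                         v_medium_L = bottle$v_medium_L,
                         dry_mass_g = bottle$dry_mass_g))
}

#' Methane oxidation rate from 13C label transfer into DIC
#'
#' In incubations with 13C-labelled methane, anaerobic methane oxidation
#' transfers 13C into the DIC pool. The oxidation rate is recovered from the
#' rise of the DIC atom fraction:
#' \deqn{rate = \Delta F^{13}C_{DIC} \times conc_{DIC} /
#'       (excess\,F^{13}C_{CH4} \times \Delta t)}
#' with conc_DIC expressed per gram dry weight. With the default excess mode
#' (labelled-CH4 atom fraction minus the day-0 DIC background) and the
#' window-end DIC concentration, the estimator is exact for a closed DIC
#' pool whose only input is CH4-derived carbon at constant atom fraction.
#'
#' @param series An [incubation_series()] of a 13CH4-labelled treatment with
#'   \code{d13c_dic}, \code{dic_mM} and a day-0 \code{d13c_ch4} record.
#' @param window Length-2 numeric day window (default day 0 to last day).
#' @param excess_mode \code{"background"} (default): excess = F(CH4 initial)
#'   - F(DIC at day 0), the mass-balance-exact contrast; \code{"absolute"}:
#'   the literal initial F(CH4).
#' @param conc_mode DIC concentration entering the estimator:
#'   \code{"end"} (window end, default, exact in the closed-system case) or
#'   \code{"mean"} (mean of window start and end).
#' @param d13c_ch4_initial Optional override of the initial labelled-CH4
#'   delta-13C (per mil); defaults to the series' day-0 \code{d13c_ch4}.
#' @param r_vpdb Reference 13C/12C ratio.
#' @return A \code{rate_estimate} in umol g_dw^-1 d^-1.
#' @export
methane_oxidation_rate <- function(series, window = NULL,
                                   excess_mode = c("background", "absolute"),
                                   conc_mode = c("end", "mean"),
                                   d13c_ch4_initial = NULL,
                                   r_vpdb = vpdb_ratio()) {
  stopifnot(inherits(series, "incubation_series"))
  excess_mode <- match.arg(excess_mode)
  conc_mode <- match.arg(conc_mode)
  if (is.null(window)) window <- c(0, max(series$day))
  if (window[2] <= window[1]) stop("window must satisfy day_end > day_start")
  row0 <- series_row(series, 0)
  rowa <- series_row(series, window[1])
  rowb <- series_row(series, window[2])
  if (is.null(d13c_ch4_initial)) d13c_ch4_initial <- row0$d13c_ch4
  if (is.null(d13c_ch4_initial) || is.na(d13c_ch4_initial)) {
    stop("initial delta-13C of CH4 is unknown: no day-0 d13c_ch4 record ",
         "and no d13c_ch4_initial supplied")
  }
  if (is.na(rowa$d13c_dic) || is.na(rowb$d13c_dic)) {
    stop("d13c_dic missing at a window day")
  }
  f_dic0 <- delta_to_fraction(row0$d13c_dic, r_vpdb)
  df_dic <- delta_to_fraction(rowb$d13c_dic, r_vpdb) -
    delta_to_fraction(rowa$d13c_dic, r_vpdb)
  excess <- switch(excess_mode,
                   background = delta_to_fraction(d13c_ch4_initial, r_vpdb) - f_dic0,
                   absolute   = delta_to_fraction(d13c_ch4_initial, r_vpdb))
  if (excess <= 0) {
    stop("excess F13C of CH4 is not positive: methane appears unlabelled")
  }
  bottle <- attr(series, "bottle")
  conc_mM <- switch(conc_mode,
                    end  = rowb$dic_mM,
                    mean = mean(c(rowa$dic_mM, rowb$dic_mM)))
  if (is.na(conc_mM)) stop("dic_mM missing at a window day")
  conc_umol_gdw <- conc_mM * bottle$v_medium_L * 1000 / bottle$dry_mass_g
  dt <- window[2] - window[1]
  rate <- df_dic * conc_umol_gdw / (excess * dt)
  new_rate_estimate(rate, "umol g_dw^-1 d^-1", "ch4_oxidation", window,
                    list(d13c_ch4_initial = d13c_ch4_initial,
                         d13c_dic = c(rowa$d13c_dic, rowb$d13c_dic),
                         conc_dic_mM = conc_mM, excess_mode = excess_mode,
                         conc_mode = conc_mode, excess_f13c = excess))
}
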