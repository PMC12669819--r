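#' Read and validate a measurement table
#'
#' Reads one of the package's CSV schemas and validates it:
#' \describe{
#'   \item{geochem}{columns \code{treatment, day, d13c_ch4, d13c_dic,
#'     dic_mM, so4_mM, h2s_mM}; long format, one sampling per row.}
#'   \item{lipids}{columns \code{treatment, day, species,
#'     conc_ug_per_gdw, d13c_permil} (optionally \code{compound_class,
#'     formula, group}).}
#'   \item{registry}{columns \code{species, compound_class, formula, group}
#'     (optionally \code{n_oh_groups}), mapping lipid names to identity.}
#' }
#' Unknown columns are preserved but flagged with a message; negative
#' concentrations and malformed values raise errors naming the offending
#' row and column.
#'
#' @param path Path to a CSV file.
#' @param schema One of \code{"geochem"}, \code{"lipids"}, \code{"registry"}.
#' @return A validated data.frame.
#' @export
read_measurements <- function(path, schema = c("geochem", "lipids", "registry")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  required <- switch(schema,
    geochem  = c("treatment", "day", "d13c_ch4", "d13c_dic",
                 "dic_mM", "so4_mM", "h2s_mM"),
    lipids   = c("treatment", "day", "species", "conc_ug_per_gdw",
                 "d13c_permil"),
    registry = c("species", "compound_class", "formula", "group"))
  optional <- switch(schema,
    geochem  = "sample_type",
    lipids   = c("compound_class", "formula", "group"),
    registry = "n_oh_groups")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("file '", path, "' lacks required ", schema, " column(s): ",
         paste(miss, collapse = ", "),
         " (is the delimiter a comma and the header present?)")
  }
  extra <- setdiff(names(df), c(required, optional))
  if (length(extra)) {
    message("note: '", basename(path), "' carries unrecognised column(s) ",
            paste(extra, collapse = ", "), "; they are preserved untouched")
  }
  num_cols <- switch(schema,
    geochem  = c("day", "d13c_ch4", "d13c_dic", "dic_mM", "so4_mM", "h2s_mM"),
    lipids   = c("day", "conc_ug_per_gdw", "d13c_permil"),
    registry = character(0))
  for (cc in num_cols) {
    if (!is.numeric(df[[cc]])) {
      suppressWarnings(v <- as.numeric(df[[cc]]))
      bad <- which(!is.na(df[[cc]]) & df[[cc]] != "" &
                     df[[cc]] != "NA" & is.na(v))
      if (length(bad)) {
        stop("file '", path, "', column '", cc, "', row ", bad[1],
             ": value '", df[[cc]][bad[1]], "' is not numeric")
      }
      df[[cc]] <- v
    }
  }
  conc_cols <- intersect(c("dic_mM", "so4_mM", "h2s_mM", "conc_ug_per_gdw"),
                         names(df))
  for (cc in conc_cols) {
    neg <- which(!is.na(df[[cc]]) & df[[cc]] < 0)
    if (length(neg)) {
      stop("file '", path, "', column '", cc, "', row ", neg[1],
           ": negative concentration (", df[[cc]][neg[1]], ")")
    }
  }
  df
}

#' Infer which pool carries the 13C label from a treatment name
#'
#' Convention: names containing \code{"DI13C"} are DIC-labelled, names
#' containing \code{"13CH4"} are methane-labelled, anything else is
#' unlabelled. Override by passing an explicit treatment table to
#' [lipid_sip()].
#'
#' @param treatment Character vector of treatment labels.
#' @return Character vector: \code{"dic"}, \code{"ch4"} or \code{"none"}.
#' @export
infer_labelled_pool <- function(treatment) {
  ifelse(grepl("DI13C", treatment, fixed = TRUE), "dic",
         ifelse(grepl("13CH4", treatment, fixed = TRUE), "ch4", "none"))
}

#' Estimator settings for a SIP pipeline run
#'
#' @param excess_mode Excess-F13C convention of
#'   [methane_oxidation_rate()]: \code{"background"} or \code{"absolute"}.
#' @param conc_mode DIC-concentration convention of
#'   [methane_oxidation_rate()]: \code{"end"} or \code{"mean"}.
#' @param averaging Medium-averaging rule of [medium_fraction()] for
#'   13CH4-labelled treatments: \code{"all"} or \code{"endpoints"}.
#' @param conc_basis \code{"carbon"}: convert lipid mass to carbon mass via
#'   the underivatized formula (default); \code{"lipid"}: report per ug
#'   lipid.
#' @param r_vpdb Reference 13C/12C ratio.
#' @return A list of validated settings.
#' @export
sip_options <- function(excess_mode = c("background", "absolute"),
                        conc_mode = c("end", "mean"),
                        averaging = c("all", "endpoints"),
                        conc_basis = c("carbon", "lipid"),
                        r_vpdb = vpdb_ratio()) {
  list(excess_mode = match.arg(excess_mode),
       conc_mode = match.arg(conc_mode),
       averaging = match.arg(averaging),
       conc_basis = match.arg(conc_basis),
       r_vpdb = r_vpdb)
}

#' Fit the lipid-SIP estimators to an incubation data set
#'
#' The orchestration entry point: takes the geochemical time series and the
#' compound-specific lipid measurements of a multi-treatment SIP incubation
#' and computes, per treatment and sampling day, (i) bulk production and
#' consumption rates of DIC, sulphate and sulphide, (ii) label-transfer
#' methane-oxidation rates in 13CH4 treatments, (iii) lipid delta-13C
#' shifts relative to the non-labelled parallel, (iv) inorganic-carbon
#' assimilation rates and (hypothetical) methane-carbon assimilation rates,
#' and (v) lipid turnover times.
#'
#' @param geochem Data frame in the geochem schema of
#'   [read_measurements()] (treatments in long format).
#' @param lipids Optional data frame in the lipids schema. If it lacks a
#'   \code{formula} column, \code{registry} must map each species to one.
#' @param registry Optional registry data frame (species, compound_class,
#'   formula, group).
#' @param bottle A [sip_bottle()].
#' @param treatments Optional data frame \code{(treatment, labelled_pool)}
#'   overriding [infer_labelled_pool()].
#' @param baseline_treatment Label of the non-labelled parallel treatment
#'   providing time-matched lipid baselines; species absent there fall back
#'   to their day-0 value within the labelled treatment (with a warning).
#' @param options A [sip_options()] list.
#' @return An object of class \code{sip_fit} with components \code{rates},
#'   \code{delta_shifts}, \code{assim_ic}, \code{assim_ch4} (flagged
#'   hypothetical), \code{turnover}, plus the inputs and settings used.
#' @seealso [simulate_incubation()] to generate synthetic inputs;
#'   [summary.sip_fit()].
#' @export
lipid_sip <- function(geochem, lipids = NULL, registry = NULL,
                      bottle = sip_bottle(), treatments = NULL,
                      baseline_treatment = "DIC w/ CH4",
                      options = sip_options()) {
  stopifnot(is.data.frame(geochem))
  need <- c("treatment", "day", "d13c_dic", "dic_mM")
  miss <- setdiff(need, names(geochem))
  if (length(miss)) stop("geochem table lacks column(s): ",
                         paste(miss, collapse = ", "))
  trt_names <- unique(geochem$treatment)
  if (is.null(treatments)) {
    treatments <- data.frame(treatment = trt_names,
                             labelled_pool = infer_labelled_pool(trt_names),
                             stringsAsFactors = FALSE)
  }
  pool_of <- stats::setNames(treatments$labelled_pool, treatments$treatment)

  if (!is.null(lipids)) {
    if (!"formula" %in% names(lipids)) {
      if (is.null(registry)) {
        stop("lipid table has no 'formula' column and no registry was given")
      }
      i <- match(lipids$species, registry$species)
      if (anyNA(i)) {
        stop("species missing from the registry: ",
             paste(unique(lipids$species[is.na(i)]), collapse = ", "))
      }
      lipids$formula <- registry$formula[i]
      if (!"group" %in% names(lipids)) lipids$group <- registry$group[i]
      if (!"compound_class" %in% names(lipids)) {
        lipids$compound_class <- registry$compound_class[i]
      }
    }
    if (!"group" %in% names(lipids)) lipids$group <- NA_character_
  }

  series_of <- function(trt) {
    sub <- geochem[geochem$treatment == trt, , drop = FALSE]
    sub <- sub[order(sub$day), , drop = FALSE]
    tryCatch(
      incubation_series(sub[, setdiff(names(sub), "treatment"), drop = FALSE],
                        bottle = bottle, treatment = trt),
      error = function(e) {
        message("bulk rates skipped for treatment '", trt, "': ",
                conditionMessage(e))
        NULL
      })
  }

  ## ---- bulk rates, windows anchored at day 0 -------------------------------
  rates <- list()
  for (trt in trt_names) {
    ser <- series_of(trt)
    if (is.null(ser)) next
    for (d in setdiff(ser$day, 0)) {
      for (an in c("so4", "h2s", "dic")) {
        if (!paste0(an, "_mM") %in% names(ser)) next
        r <- tryCatch(production_rate(ser, an, c(0, d)), error = function(e) NULL)
        if (!is.null(r)) {
          rates[[length(rates) + 1L]] <- data.frame(
            treatment = trt, day = d, analyte = an, rate = r$value,
            units = r$units, stringsAsFactors = FALSE)
        }
      }
      if (identical(unname(pool_of[trt]), "ch4")) {
        r <- tryCatch(
          methane_oxidation_rate(ser, c(0, d),
                                 excess_mode = options$excess_mode,
                                 conc_mode = options$conc_mode,
                                 r_vpdb = options$r_vpdb),
          error = function(e) NULL)
        if (!is.null(r)) {
          rates[[length(rates) + 1L]] <- data.frame(
            treatment = trt, day = d, analyte = "ch4_oxidation",
            rate = r$value, units = r$units, stringsAsFactors = FALSE)
        }
      }
    }
  }
  rates <- if (length(rates)) do.call(rbind, rates) else NULL

  ## ---- lipid-level estimates ----------------------------------------------
  dd <- assim_ic <- assim_ch4 <- turn <- list()
  if (!is.null(lipids)) {
    labelled_trts <- treatments$treatment[treatments$labelled_pool != "none"]
    labelled_trts <- intersect(labelled_trts, unique(lipids$treatment))
    for (trt in labelled_trts) {
      pool <- unname(pool_of[trt])
      geo <- geochem[geochem$treatment == trt, , drop = FALSE]
      sub <- lipids[lipids$treatment == trt, , drop = FALSE]
      base <- lipids[lipids$treatment == baseline_treatment, , drop = FALSE]
      for (d in sort(setdiff(unique(sub$day), 0))) {
        fmed <- tryCatch(
          medium_fraction(geo$d13c_dic, geo$day, d, labelled_pool = pool,
                          averaging = options$averaging,
                          r_vpdb = options$r_vpdb),
          error = function(e) NULL)
        fmed_ch4 <- if (pool == "ch4") {
          ok <- !is.na(geo$d13c_ch4) & geo$day <= d
          if (any(ok)) delta_to_fraction(mean(geo$d13c_ch4[ok]),
                                         options$r_vpdb) else NULL
        } else NULL
        for (sp in unique(sub$species[sub$day == d])) {
          row_l <- sub[sub$day == d & sub$species == sp, , drop = FALSE][1, ]
          row_b <- base[base$day == d & base$species == sp, , drop = FALSE]
          if (nrow(row_b) >= 1L && !is.na(row_b$d13c_permil[1])) {
            delta_base <- row_b$d13c_permil[1]
            base_src <- "parallel"
          } else {
            row_b0 <- sub[sub$day == 0 & sub$species == sp, , drop = FALSE]
            if (nrow(row_b0) < 1L || is.na(row_b0$d13c_permil[1])) {
              warning("no baseline for species '", sp, "' day ", d,
                      " in treatment '", trt, "'; estimate skipped")
              next
            }
            delta_base <- row_b0$d13c_permil[1]
            base_src <- "day0"
          }
          shift <- label_shift(row_l$d13c_permil, delta_base)
          dd[[length(dd) + 1L]] <- data.frame(
            treatment = trt, day = d, species = sp, group = row_l$group,
            d13c_labelled = row_l$d13c_permil, d13c_baseline = delta_base,
            baseline_source = base_src, delta_delta = shift,
            stringsAsFactors = FALSE)
          conc_mean <- mean(sub$conc_ug_per_gdw[sub$species == sp],
                            na.rm = TRUE)
          frm <- if (options$conc_basis == "carbon") row_l$formula else NULL
          if (!is.null(fmed)) {
            a <- tryCatch(suppressWarnings(
              assimilation_rate(conc_mean, frm, row_l$d13c_permil, delta_base,
                                fmed, d, r_vpdb = options$r_vpdb)),
              error = function(e) NULL)
            if (!is.null(a)) {
              assim_ic[[length(assim_ic) + 1L]] <- data.frame(
                treatment = trt, day = d, species = sp, group = row_l$group,
                assim_ugC_gdw_yr = a$value, f_medium = fmed,
                stringsAsFactors = FALSE)
            }
            tt <- tryCatch(
              turnover_time(row_l$d13c_permil, delta_base, fmed, d,
                            r_vpdb = options$r_vpdb),
              error = function(e) NULL)
            if (!is.null(tt)) {
              turn[[length(turn) + 1L]] <- data.frame(
                treatment = trt, day = d, species = sp, group = row_l$group,
                turnover_yr = tt$value, f_medium = fmed,
                stringsAsFactors = FALSE)
            }
          }
          if (!is.null(fmed_ch4)) {
            a4 <- tryCatch(suppressWarnings(
              assimilation_rate(conc_mean, frm, row_l$d13c_permil, delta_base,
                                fmed_ch4, d, r_vpdb = options$r_vpdb)),
              error = function(e) NULL)
            if (!is.null(a4)) {
              assim_ch4[[length(assim_ch4) + 1L]] <- data.frame(
                treatment = trt, day = d, species = sp, group = row_l$group,
                assim_ugC_gdw_yr = a4$value, f_medium = fmed_ch4,
                hypothetical = TRUE, stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
  }
  bindrows <- function(x) if (length(x)) do.call(rbind, x) else NULL

  structure(list(rates = rates,
                 delta_shifts = bindrows(dd),
                 assim_ic = bindrows(assim_ic),
                 assim_ch4 = bindrows(assim_ch4),
                 turnover = bindrows(turn),
                 treatments = treatments,
                 baseline_treatment = baseline_treatment,
                 bottle = bottle, options = options),
            class = "sip_fit")
}

#' @export
print.sip_fit <- function(x, ...) {
  n_trt <- nrow(x$treatments)
  cat("Lipid-SIP incubation fit\n")
  cat(sprintf("  %d treatment(s); baseline: '%s'\n", n_trt,
              x$baseline_treatment))
  cat(sprintf("  bulk rate estimates: %d; lipid shift records: %d\n",
              if (is.null(x$rates)) 0L else nrow(x$rates),
              if (is.null(x$delta_shifts)) 0L else nrow(x$delta_shifts)))
  cat(sprintf("  assim_IC: %d; assim_CH4 (hypothetical): %d; turnover: %d\n",
              if (is.null(x$assim_ic)) 0L else nrow(x$assim_ic),
              if (is.null(x$assim_ch4)) 0L else nrow(x$assim_ch4),
              if (is.null(x$turnover)) 0L else nrow(x$turnover)))
  cat(sprintf("  settings: excess=%s, conc=%s, averaging=%s, basis=%s, r_vpdb=%g\n",
              x$options$excess_mode, x$options$conc_mode,
              x$options$averaging, x$options$conc_basis, x$options$r_vpdb))
  invisible(x)
}

#' Summarise a lipid-SIP fit
#'
#' @param object A \code{sip_fit}.
#' @param ... Unused.
#' @return The fit, invisibly; prints the report tables (bulk rates in umol
#'   g_dw^-1 d^-1, delta-13C shifts, assimilation in ug C g_dw^-1 yr^-1
#'   and turnover times in years).
#' @export
summary.sip_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$rates)) {
    cat("\nBulk production/consumption and methane-oxidation rates:\n")
    print(object$rates, row.names = FALSE, digits = 3)
  }
  if (!is.null(object$delta_shifts)) {
    cat("\nLipid delta-13C shifts vs non-labelled baseline (per mil):\n")
    print(object$delta_shifts, row.names = FALSE, digits = 4)
  }
  if (!is.null(object$assim_ic)) {
    cat("\nInorganic-carbon assimilation (ug C g_dw^-1 yr^-1):\n")
    print(object$assim_ic, row.names = FALSE, digits = 3)
  }
  if (!is.null(object$assim_ch4)) {
    cat("\nMethane-carbon assimilation (hypothetical; ug C g_dw^-1 yr^-1):\n")
    print(object$assim_ch4, row.names = FALSE, digits = 3)
  }
  if (!is.null(object$turnover)) {
    cat("\nLipid turnover times (years):\n")
    print(object$turnover, row.names = FALSE, digits = 3)
  }
  invisible(object)
}

#' Extract assimilation estimates from a fit
#'
#' @param object A \code{sip_fit}.
#' @param which \code{"assim_ic"} (default), \code{"assim_ch4"} or
#'   \code{"turnover"}.
#' @param ... Unused.
#' @return Named numeric vector (names \code{treatment/day/species}).
#' @export
coef.sip_fit <- function(object, which = c("assim_ic", "assim_ch4", "turnover"),
                         ...) {
  which <- match.arg(which)
  tab <- object[[which]]
  if (is.null(tab)) return(numeric(0))
  val <- if (which == "turnover") tab$turnover_yr else tab$assim_ugC_gdw_yr
  stats::setNames(val, paste(tab$treatment, tab$day, tab$species, sep = "/"))
}

#' Plot assimilation estimates of a fit
#'
#' Simple diagnostic barplot of inorganic-carbon assimilation per species,
#' one panel group per treatment, at the latest sampled day.
#'
#' @param x A \code{sip_fit}.
#' @param ... Passed to [graphics::barplot()].
#' @return The fit, invisibly.
#' @export
plot.sip_fit <- function(x, ...) {
  if (is.null(x$assim_ic)) {
    warning("no assimilation estimates to plot")
    return(invisible(x))
  }
  tab <- x$assim_ic[x$assim_ic$day == max(x$assim_ic$day), , drop = FALSE]
  m <- tapply(tab$assim_ugC_gdw_yr, list(tab$treatment, tab$species), mean)
  graphics::barplot(m, beside = TRUE, las = 2,
                    ylab = "assim_IC (ug C / g_dw / yr)",
                    legend.text = rownames(m), ...)
  invisible(x)
}
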