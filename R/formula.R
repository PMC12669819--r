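# Element masses (IUPAC standard atomic weights, conventional values).
.atomic_mass <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007,
                  P = 30.974, S = 32.06)

#' Parse a molecular formula into element counts
#'
#' @param formula A single molecular formula string such as "C16H30O2".
#'   Elements C, H, O, N, P, S are supported; an omitted count means 1.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  f <- gsub("\\s", "", formula)
  if (!nzchar(f)) stop("empty molecular formula")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
  toks <- regmatches(f, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(f)) {
    stop("cannot parse molecular formula: '", formula, "'")
  }
  elems <- sub("[0-9]*$", "", toks)
  counts <- as.integer(ifelse(grepl("[0-9]+$", toks),
                              sub("^[A-Za-z]+", "", toks), "1"))
  unknown <- setdiff(elems, names(.atomic_mass))
  if (length(unknown)) {
    stop("unsupported element(s) in '", formula, "': ",
         paste(unknown, collapse = ", "),
         " (supported: ", paste(names(.atomic_mass), collapse = ", "), ")")
  }
  out <- tapply(counts, factor(elems, levels = names(.atomic_mass)), sum)
  out <- out[!is.na(out)]
  storage.mode(out) <- "integer"
  out
}

#' Molar mass of a molecular formula
#'
#' @inheritParams parse_formula
#' @return Molar mass in g/mol.
#' @export
formula_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(counts * .atomic_mass[names(counts)])
}

#' Mass fraction of carbon in a molecule
#'
#' @inheritParams parse_formula
#' @return Dimensionless carbon mass fraction in (0, 1].
#' @export
carbon_mass_fraction <- function(formula) {
  counts <- parse_formula(formula)
  n_c <- if ("C" %in% names(counts)) counts[["C"]] else 0L
  if (n_c < 1L) stop("formula '", formula, "' contains no carbon")
  n_c * .atomic_mass[["C"]] / sum(counts * .atomic_mass[names(counts)])
}

#' Number of carbon atoms in a molecular formula
#'
#' @inheritParams parse_formula
#' @return Integer carbon count.
#' @export
carbon_count <- function(formula) {
  counts <- parse_formula(formula)
  if (!"C" %in% names(counts)) 0L else counts[["C"]]
}
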