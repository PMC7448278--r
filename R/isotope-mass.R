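.MONO_MASS <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069,
  P = 30.97376151,
  "13C" = 13.0033548,
  "2H"  = 2.0141017781,
  "15N" = 15.0001088984,
  "18O" = 17.9991604)

.H_ATOM_MASS <- 1.0078250319
.PROTON_MASS <- 1.0072764666

#' Parse a molecular formula
#'
#' Hill-notation-style formula strings, e.g. \code{"C17H15N3O3"}.  Heavy
#' isotopes may be given in brackets with a count, e.g. \code{"[13C6]"}
#' for six carbon-13 atoms; bracketed isotope counts are additional to any
#' plain-element counts.
#'
#' @param text formula string.
#' @return Named integer vector of element (and heavy-isotope) counts.
#' @examples
#' parseFormula("C17H15N3O3")
#' parseFormula("[13C6]C1H7NO2")
#' @export
parseFormula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  counts <- integer(0)
  add <- function(sym, n) {
    counts[sym] <<- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  s <- text
  pos <- 1L
  while (pos <= nchar(s)) {
    rest <- substr(s, pos, nchar(s))
    m <- regmatches(rest, regexec("^\\[(\\d+)([A-Z][a-z]?)(\\d*)\\]", rest))[[1]]
    if (length(m)) {
      iso <- paste0(m[2], m[3])
      n <- if (nzchar(m[4])) as.integer(m[4]) else 1L
      if (!iso %in% names(.MONO_MASS))
        stop(sprintf("parseFormula: unknown isotope '%s' at offset %d",
                     iso, pos))
      add(iso, n)
      pos <- pos + nchar(m[1])
      next
    }
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)(\\d*)", rest))[[1]]
    if (length(m) && nzchar(m[2])) {
      el <- m[2]
      if (!el %in% names(.MONO_MASS))
        stop(sprintf("parseFormula: unknown element '%s' at offset %d",
                     el, pos))
      n <- if (nzchar(m[3])) as.integer(m[3]) else 1L
      add(el, n)
      pos <- pos + nchar(m[1])
      next
    }
    stop(sprintf("parseFormula: malformed formula at offset %d ('%s')",
                 pos, substr(s, pos, pos)))
  }
  counts
}

#' Monoisotopic mass of a composition
#'
#' Sum of count times monoisotopic atomic mass over all elements and
#' heavy isotopes of the composition (C = 12 exactly, H = 1.0078250319,
#' N = 14.0030740052, O = 15.9949146221; 13C = 13.0033548,
#' 2H = 2.0141017781).
#'
#' @param comp named integer vector from \code{\link{parseFormula}}, or a
#'   formula string.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopicMass("C17H15N3O3")  # 309.1113
#' @export
monoisotopicMass <- function(comp) {
  if (is.character(comp)) comp <- parseFormula(comp)
  if (!length(comp)) return(0)
  if (any(comp < 0)) stop("monoisotopicMass: negative counts")
  unknown <- setdiff(names(comp), names(.MONO_MASS))
  if (length(unknown))
    stop("monoisotopicMass: no mass for: ", paste(unknown, collapse = ", "))
  sum(comp * .MONO_MASS[names(comp)])
}

#' Adduct m/z from a neutral mass
#'
#' For the protonated molecular ion \code{[M+H]+}.  The default "Hatom"
#' convention adds the mass of a hydrogen atom (1.0078250319 Da); the
#' electron-corrected "proton" convention adds 1.0072764666 Da.
#'
#' @param neutralMass neutral monoisotopic mass in Da (> 0).
#' @param adduct adduct name; only \code{"[M+H]+"} is supported.
#' @param convention \code{"Hatom"} (default) or \code{"proton"}.
#' @return Adduct m/z in Da.
#' @examples
#' adductMz(monoisotopicMass("C17H15N3O3"))  # 310.1192
#' @export
adductMz <- function(neutralMass, adduct = "[M+H]+",
                     convention = c("Hatom", "proton")) {
  convention <- match.arg(convention)
  if (!is.numeric(neutralMass) || neutralMass <= 0)
    stop("adductMz: neutral mass must be > 0")
  if (!identical(adduct, "[M+H]+"))
    stop("adductMz: unsupported adduct: ", adduct)
  neutralMass + if (convention == "Hatom") .H_ATOM_MASS else .PROTON_MASS
}

#' Mass accuracy in parts per million
#'
#' \code{(observed - calculated) / calculated * 1e6}.
#'
#' @param observed observed m/z in Da.
#' @param calculated calculated m/z in Da (> 0).
#' @return Signed ppm error.
#' @export
ppmError <- function(observed, calculated) {
  if (!is.numeric(calculated) || any(calculated <= 0))
    stop("ppmError: calculated mass must be > 0")
  (observed - calculated) / calculated * 1e6
}

#' Read a labelled-precursor scenario from JSON
#'
#' Scenario files record a labelled precursor and its atom-retention
#' bookkeeping: for each label, the element, heavy isotope, number of
#' labelled atoms in the precursor and number retained in the product.
#' Two scenarios ship with the package (see
#' \code{system.file("extdata", package = "gcfkit")}): ring-carbon
#' \code{[13C6]}anthranilate (all six carbons retained in the
#' anthraniloyl unit) and ring-pentadeuterated L-tryptophan (indole ring
#' cleavage by IDO makes ring C2 the N-formyl carbon of
#' N-formyl-kynurenine, which is lost with its deuterium on deformylation
#' to kynurenine, so four of five deuteria are retained).
#'
#' @param path path to a scenario JSON file.
#' @return A \linkS4class{LabelScenario}.
#' @export
readLabelScenario <- function(path) {
  if (!file.exists(path)) stop("readLabelScenario: file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  labels <- as.data.frame(doc$labels, stringsAsFactors = FALSE)
  LabelScenario(precursorName = doc$precursor_name, labels = labels,
                note = if (is.null(doc$note)) "" else doc$note)
}

#' Nominal and exact mass shift of a labelling scenario
#'
#' The nominal shift is the count of heavy atoms retained in the product;
#' the exact shift is the sum over labels of retained count times the
#' heavy-minus-light isotope mass difference (1.0033548 Da per 13C,
#' 1.0062767462 Da per 2H).
#'
#' @param scenario a \linkS4class{LabelScenario}.
#' @return list(nominal = integer Da, exact = Da).
#' @examples
#' sc <- LabelScenario("[13C6]anthranilate",
#'   data.frame(element = "C", isotope = "13C",
#'              n_labeled = 6L, n_retained = 6L))
#' labelShift(sc)  # nominal +6
#' @export
labelShift <- function(scenario) {
  stopifnot(is(scenario, "LabelScenario"))
  validObject(scenario)
  l <- scenario@labels
  if (nrow(l) == 0L) return(list(nominal = 0L, exact = 0))
  for (i in seq_len(nrow(l))) {
    if (!l$isotope[i] %in% names(.MONO_MASS))
      stop("labelShift: unknown isotope: ", l$isotope[i])
    if (!l$element[i] %in% names(.MONO_MASS))
      stop("labelShift: unknown element: ", l$element[i])
  }
  diffs <- .MONO_MASS[l$isotope] - .MONO_MASS[l$element]
  list(nominal = as.integer(sum(l$n_retained)),
       exact = sum(l$n_retained * diffs))
}

#' Exact-mass report for a formula and observed m/z
#'
#' Convenience wrapper producing neutral mass, adduct m/z and (optionally)
#' the ppm error against an observed value.
#'
#' @param formula molecular formula string.
#' @param observed optional observed m/z.
#' @param adduct adduct name (see \code{\link{adductMz}}).
#' @param convention adduct mass convention.
#' @return list(formula, neutral_mass, adduct, adduct_mz, ppm_vs_observed).
#' @export
massReport <- function(formula, observed = NULL, adduct = "[M+H]+",
                       convention = "Hatom") {
  neutral <- monoisotopicMass(formula)
  mz <- adductMz(neutral, adduct, convention)
  list(formula = formula,
       neutral_mass = neutral,
       adduct = adduct,
       adduct_mz = mz,
       ppm_vs_observed = if (is.null(observed)) NULL else
         ppmError(observed, mz))
}
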