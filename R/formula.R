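#' Parse an elemental formula string
#'
#' Parses a Hill-style molecular formula (e.g. \code{"C27H23BrN2O5S"}) into a
#' named count vector. Element symbols must belong to the package's periodic
#' subset (see \code{\link{monoisotopic_mass}}); repeated symbols are summed.
#'
#' @param text A single formula string. Digits following a symbol multiply it;
#'   a missing multiplier means 1.
#' @return An object of class \code{elemental_formula}: a named integer vector
#'   of per-element counts.
#' @examples
#' parse_formula("C27H23BrN2O5S")
#' parse_formula("H2O")
#' @seealso [render_formula()], [monoisotopic_mass()]
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string")
  if (grepl("[^A-Za-z0-9]", text))
    stop("formula contains characters outside [A-Za-z0-9]: ", text)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text))
    stop("could not tokenize formula: ", text)
  syms <- sub("[0-9]*$", "", tokens)
  mult <- sub("^[A-Z][a-z]?", "", tokens)
  n <- ifelse(nzchar(mult), suppressWarnings(as.integer(mult)), 1L)
  bad <- setdiff(syms, .known_elements())
  if (length(bad))
    stop("unknown element symbol(s): ", paste(unique(bad), collapse = ", "))
  if (any(is.na(n)) || any(n == 0L))
    stop("zero or invalid multiplier in formula: ", text)
  counts <- tapply(n, factor(syms, levels = unique(syms)), sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  as_formula(out)
}

as_formula <- function(counts) {
  counts <- counts[counts > 0]
  structure(hill_order(counts), class = "elemental_formula")
}

# Hill order: C first, then H, then remaining symbols alphabetically;
# no carbon -> all symbols alphabetical.
hill_order <- function(counts) {
  syms <- names(counts)
  if ("C" %in% syms) {
    rest <- sort(setdiff(syms, c("C", "H")))
    ord <- c("C", intersect("H", syms), rest)
  } else {
    ord <- sort(syms)
  }
  counts[ord]
}

#' Render a formula in canonical Hill order
#'
#' @param formula A named count vector or \code{elemental_formula}.
#' @return A single string, e.g. \code{"C27H23BrN2O5S"}; the empty formula
#'   renders as \code{""}.
#' @export
render_formula <- function(formula) {
  counts <- hill_order(formula[formula > 0])
  if (!length(counts)) return("")
  paste0(names(counts), ifelse(counts > 1, counts, ""), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula> ", render_formula(x), "\n", sep = "")
  invisible(x)
}

#' Combine two elemental formulas
#'
#' @param a,b Formulas (named count vectors).
#' @param op \code{"+"} to add counts, \code{"-"} to subtract (\code{b} from
#'   \code{a}; negative results are an error).
#' @return An \code{elemental_formula}.
#' @export
formula_arith <- function(a, b, op = c("+", "-")) {
  op <- match.arg(op)
  syms <- union(names(a), names(b))
  av <- ifelse(syms %in% names(a), as.integer(a[syms]), 0L)
  bv <- ifelse(syms %in% names(b), as.integer(b[syms]), 0L)
  out <- if (op == "+") av + bv else av - bv
  if (any(out < 0))
    stop("formula subtraction went negative for: ",
         paste(syms[out < 0], collapse = ", "))
  names(out) <- syms
  as_formula(out[out > 0])
}

#' Monoisotopic (exact) mass of a formula
#'
#' Sums the masses of the most abundant stable isotope of each element
#' (AME2020/IUPAC values, tabulated to 9 decimals). Masses refer to the
#' neutral species; ESI adduct arithmetic is opt-in via \code{adduct}.
#'
#' @param formula An \code{elemental_formula}, named count vector, or formula
#'   string (parsed with [parse_formula()]).
#' @param adduct One of \code{"none"} (neutral, default), \code{"M+H"} or
#'   \code{"M-H"} (proton mass added/removed).
#' @return Mass in Da (0 for an empty formula).
#' @examples
#' monoisotopic_mass("H2O")              # 18.0106
#' monoisotopic_mass("C27H23BrN2O5S")    # 566.0511
#' @export
monoisotopic_mass <- function(formula, adduct = c("none", "M+H", "M-H")) {
  adduct <- match.arg(adduct)
  if (is.character(formula)) formula <- parse_formula(formula)
  if (!length(formula)) {
    m <- 0
  } else {
    bad <- setdiff(names(formula), names(.mono_mass))
    if (length(bad))
      stop("no isotope mass tabulated for: ", paste(bad, collapse = ", "))
    m <- sum(.mono_mass[names(formula)] * as.numeric(formula))
  }
  m + switch(adduct, none = 0, `M+H` = .proton_mass, `M-H` = -.proton_mass)
}

#' Average molecular weight of a formula
#'
#' @inheritParams monoisotopic_mass
#' @return Weight in g/mol using IUPAC 2021 standard atomic weights.
#' @export
average_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (!length(formula)) return(0)
  bad <- setdiff(names(formula), names(.avg_weight))
  if (length(bad))
    stop("no atomic weight tabulated for: ", paste(bad, collapse = ", "))
  sum(.avg_weight[names(formula)] * as.numeric(formula))
}
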