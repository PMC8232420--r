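#' Elemental composition
#'
#' A composition is a named integer vector of element counts (hydrogen
#' counted explicitly) plus a net formal charge. It is the basis of the
#' constitutional descriptors: molecular weight, AMW and H%.
#'
#' @param counts named numeric vector, element symbol -> non-negative count.
#' @param charge integer net formal charge.
#' @return object of class `composition`.
#' @examples
#' composition(c(C = 8, H = 9, N = 1, O = 2))
#' @export
composition <- function(counts, charge = 0L) {
  if (length(counts) == 0L)
    stop("composition requires at least one element")
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be named by element symbol")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("element counts must be non-negative integers")
  counts <- counts[counts > 0]
  if (length(counts) == 0L || sum(counts) <= 0)
    stop("composition must contain at least one atom")
  bad <- setdiff(names(counts), names(.default_masses))
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  # merge duplicate symbols, order C, H, then alphabetical (Hill)
  counts <- tapply(as.numeric(counts), names(counts), sum)
  counts <- counts[.hill_order(names(counts))]
  structure(list(counts = counts, charge = as.integer(charge)),
            class = "composition")
}

.hill_order <- function(els) {
  if (!("C" %in% els)) return(sort(els))
  rest <- sort(setdiff(els, c("C", "H")))
  intersect(c("C", "H", rest), els)
}

#' @export
print.composition <- function(x, ...) {
  cat("<composition> ", hill_formula(x), "\n", sep = "")
  invisible(x)
}

#' @export
`==.composition` <- function(e1, e2) {
  identical(names(e1$counts), names(e2$counts)) &&
    all(e1$counts == e2$counts) && e1$charge == e2$charge
}

#' Hill-notation formula of a composition
#'
#' Carbon first, hydrogen second, remaining elements alphabetically; a
#' trailing charge is appended as e.g. `"+"` or `"2-"` when nonzero.
#'
#' @param x a `composition`.
#' @return character scalar.
#' @export
hill_formula <- function(x) {
  stopifnot(inherits(x, "composition"))
  n <- x$counts
  body <- paste0(names(n), ifelse(n > 1, as.character(n), ""), collapse = "")
  ch <- x$charge
  if (ch != 0) {
    sgn <- if (ch > 0) "+" else "-"
    body <- paste0(body, if (abs(ch) > 1) abs(ch) else "", sgn)
  }
  body
}

#' Total atom count of a composition
#' @param x a `composition`.
#' @return integer, strictly positive.
#' @export
n_atoms <- function(x) {
  stopifnot(inherits(x, "composition"))
  as.integer(sum(x$counts))
}

#' Parse a molecular formula
#'
#' Parses Hill-notation molecular formulas with optional parenthesized
#' groups carrying integer multipliers and an optional trailing charge
#' (`"+"`, `"-"`, `"+2"`, `"--"`). Middle-dot separated hydrate parts are not
#' supported; parse components separately instead.
#'
#' @param formula character scalar, e.g. `"C8H9NO2"` or `"Ca(OH)2"`.
#' @return a [composition()].
#' @examples
#' parse_formula("C8H9NO2")
#' parse_formula("Ca(OH)2")
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L)
    stop("formula must be a single character string")
  s <- gsub("[[:space:]]", "", formula)
  if (!nzchar(s)) stop("empty formula")

  # trailing charge: sign then optional magnitude ("+", "-2", "++").
  # (Magnitude-before-sign notation like "SO42-" is ambiguous with element
  # counts in plain text and is not supported.)
  charge <- 0L
  chm <- regmatches(s, regexpr("([+-][0-9]*|\\++|-+)$", s))
  if (length(chm) == 1L && nzchar(chm)) {
    if (grepl("^[+-][0-9]+$", chm)) {
      charge <- as.integer(chm)
    } else {
      charge <- nchar(chm) * (if (startsWith(chm, "+")) 1L else -1L)
    }
    s <- substr(s, 1L, nchar(s) - nchar(chm))
    if (!nzchar(s)) stop("formula has a charge but no atoms")
  }

  chars <- strsplit(s, "")[[1]]
  pos <- 1L
  n <- length(chars)

  read_int <- function() {
    start <- pos
    while (pos <= n && grepl("[0-9]", chars[pos])) pos <<- pos + 1L
    if (pos == start) 1L else as.integer(paste(chars[start:(pos - 1L)], collapse = ""))
  }

  parse_group <- function() {
    acc <- numeric(0)
    add <- function(sym, k) {
      acc[sym] <<- (if (sym %in% names(acc)) acc[[sym]] else 0) + k
    }
    while (pos <= n) {
      ch <- chars[pos]
      if (ch == "(") {
        pos <<- pos + 1L
        inner <- parse_group()
        if (pos > n || chars[pos] != ")")
          stop("unbalanced parenthesis in formula: ", formula)
        pos <<- pos + 1L
        mult <- read_int()
        for (sym in names(inner)) add(sym, inner[[sym]] * mult)
      } else if (ch == ")") {
        break
      } else if (grepl("[A-Z]", ch)) {
        sym <- ch
        pos <<- pos + 1L
        if (pos <= n && grepl("[a-z]", chars[pos])) {
          sym <- paste0(sym, chars[pos])
          pos <<- pos + 1L
        }
        if (!(sym %in% names(.default_masses)))
          stop("unknown element symbol '", sym, "' in formula: ", formula)
        add(sym, read_int())
      } else {
        stop("unexpected character '", ch, "' in formula: ", formula)
      }
    }
    acc
  }

  counts <- parse_group()
  if (pos <= n) stop("unbalanced parenthesis in formula: ", formula)
  if (length(counts) == 0L) stop("formula contains no atoms: ", formula)
  composition(counts, charge)
}

#' Molecular weight of a composition
#'
#' @param x a [composition()].
#' @param masses mass table from [atomic_masses()].
#' @return molecular weight in u, strictly positive.
#' @export
molecular_weight <- function(x, masses = atomic_masses()) {
  stopifnot(inherits(x, "composition"))
  missing <- setdiff(names(x$counts), names(masses))
  if (length(missing))
    stop("no atomic mass for element(s): ", paste(missing, collapse = ", "))
  sum(x$counts * masses[names(x$counts)])
}

#' Average molecular weight (AMW)
#'
#' Molecular weight divided by the total number of atoms, hydrogens counted
#' in both numerator and denominator. A dimensionless per-atom mass: large
#' for halogen-rich molecules, small for hydrogen-saturated ones. The
#' screening rule flags AMW >= 7.4 as DILI-positive.
#'
#' @inheritParams molecular_weight
#' @return average mass per atom.
#' @examples
#' amw(parse_formula("CH4"))        # 3.209
#' amw(parse_formula("C8H9NO2"))    # acetaminophen, 7.56
#' @export
amw <- function(x, masses = atomic_masses()) {
  molecular_weight(x, masses) / n_atoms(x)
}

#' Percentage of hydrogen atoms
#'
#' @param x a [composition()].
#' @return percentage in [0, 100].
#' @export
h_percent <- function(x) {
  stopifnot(inherits(x, "composition"))
  h <- if ("H" %in% names(x$counts)) x$counts[["H"]] else 0
  100 * h / sum(x$counts)
}
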