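# Organic-subset SMILES parser.
#
# Supported: organic-subset atoms (B C N O P S F Cl Br I and aromatic
# b c n o p s), bracket atoms with isotope, symbol, chirality (ignored),
# explicit H count and charge; bonds - = # :, directional bonds / \ read as
# single; branches, ring closures (incl. %nn) and dot-separated components.
# Implicit hydrogens follow the standard default-valence rule for
# non-bracket atoms (lowest normal valence >= bond-order sum, aromatic
# atoms spend one valence on the ring pi system); bracket atoms carry only
# the hydrogen count written in the bracket. Anything else fails loudly:
# a wrong composition must never be produced silently.

.default_valences <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)
.organic_subset_symbols <- c("Cl", "Br", "B", "C", "N", "O", "P", "S",
                             "F", "I")
.aromatic_symbols <- c("b", "c", "n", "o", "p", "s")

#' Parse a SMILES string into a molecular graph
#'
#' Builds an explicit molecular graph (atoms, bonds, formal charges,
#' implicit hydrogen counts) from an organic-subset SMILES string. The
#' result may contain several connected components (dot-separated parts,
#' e.g. salt forms); see [split_components()]. Aromaticity is taken from
#' lowercase input symbols; no perception or kekulization is attempted.
#' Stereo markers are accepted and ignored (composition-level descriptors
#' do not depend on them); genuinely unsupported constructs raise an error
#' rather than returning a wrong atom count.
#'
#' @param smiles character scalar.
#' @return object of class `molgraph`: list with `atoms` (data.frame:
#'   element, aromatic, charge, hcount, component) and `bonds` (data.frame:
#'   from, to, order, aromatic).
#' @examples
#' g <- parse_smiles("CC(=O)Nc1ccc(O)cc1")   # acetaminophen
#' graph_composition(g)
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    stop("smiles must be a non-empty character string")
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  pos <- 1L

  atoms <- list()           # per-atom: element, aromatic, charge, hcount (NA = implicit), component
  bonds <- list()           # from, to, sym ("" = default)
  prev <- NA_integer_       # index of previous atom in chain
  stack <- integer(0)       # branch stack
  pending <- ""             # pending bond symbol
  rings <- list()           # open ring closures: id -> list(atom, sym)
  comp <- 1L

  err <- function(...) stop("SMILES parse error in '", smiles, "': ", ...)

  add_atom <- function(element, aromatic, charge = 0L, hcount = NA_integer_) {
    atoms[[length(atoms) + 1L]] <<- list(element = element, aromatic = aromatic,
                                         charge = charge, hcount = hcount,
                                         component = comp)
    idx <- length(atoms)
    if (!is.na(prev)) {
      bonds[[length(bonds) + 1L]] <<- list(from = prev, to = idx, sym = pending)
    }
    pending <<- ""
    prev <<- idx
    idx
  }

  read_bracket <- function() {
    # pos is at '['; scan to matching ']'
    close <- pos
    while (close <= n && chars[close] != "]") close <- close + 1L
    if (close > n) err("unterminated bracket atom")
    body <- paste(chars[(pos + 1L):(close - 1L)], collapse = "")
    pos <<- close + 1L
    m <- regmatches(body, regexec(
      "^([0-9]*)([A-Z][a-z]?|[bcnops])(@{0,2})(H([0-9]*))?([+-][0-9+-]*)?(:[0-9]+)?$",
      body))[[1]]
    if (length(m) == 0L) err("unsupported bracket atom [", body, "]")
    sym <- m[3]
    aromatic <- sym %in% .aromatic_symbols
    element <- if (aromatic) toupper(sym) else sym
    if (!(element %in% names(.default_masses)))
      err("unknown element '", element, "'")
    h <- if (nzchar(m[5])) {
      if (nzchar(m[6])) as.integer(m[6]) else 1L
    } else 0L
    chg <- 0L
    if (nzchar(m[7])) {
      cs <- m[7]
      if (grepl("^\\+[0-9]+$", cs)) chg <- as.integer(sub("\\+", "", cs))
      else if (grepl("^-[0-9]+$", cs)) chg <- -as.integer(sub("-", "", cs))
      else if (grepl("^\\++$", cs)) chg <- nchar(cs)
      else if (grepl("^-+$", cs)) chg <- -nchar(cs)
      else err("unsupported charge token '", cs, "'")
    }
    add_atom(element, aromatic, chg, h)
  }

  while (pos <= n) {
    ch <- chars[pos]
    if (ch == "[") {
      read_bracket()
    } else if (grepl("[A-Z]", ch)) {
      sym <- ch
      if (pos < n && paste0(ch, chars[pos + 1L]) %in% c("Cl", "Br")) {
        sym <- paste0(ch, chars[pos + 1L])
        pos <- pos + 1L
      }
      if (!(sym %in% .organic_subset_symbols))
        err("atom '", sym, "' must be written as a bracket atom")
      pos <- pos + 1L
      add_atom(sym, FALSE)
    } else if (ch %in% .aromatic_symbols) {
      pos <- pos + 1L
      add_atom(toupper(ch), TRUE)
    } else if (ch %in% c("-", "=", "#", ":")) {
      if (nzchar(pending)) err("two consecutive bond symbols")
      pending <- ch
      pos <- pos + 1L
    } else if (ch %in% c("/", "\\")) {
      pending <- "-"   # stereo direction ignored; plain single bond
      pos <- pos + 1L
    } else if (ch == "(") {
      if (is.na(prev)) err("branch with no preceding atom")
      stack <- c(stack, prev)
      pos <- pos + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) err("unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pos <- pos + 1L
    } else if (ch == ".") {
      prev <- NA_integer_
      comp <- comp + 1L
      pending <- ""
      pos <- pos + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (is.na(prev)) err("ring closure with no preceding atom")
      if (ch == "%") {
        if (pos + 2L > n || !grepl("[0-9]", chars[pos + 1L]) ||
            !grepl("[0-9]", chars[pos + 2L]))
          err("'%' ring closure needs two digits")
        id <- paste0(chars[pos + 1L], chars[pos + 2L])
        pos <- pos + 3L
      } else {
        id <- ch
        pos <- pos + 1L
      }
      if (!is.null(rings[[id]])) {
        op <- rings[[id]]
        if (op$atom == prev) err("ring bond ", id, " closes on its own atom")
        sym <- if (nzchar(pending)) pending else op$sym
        if (nzchar(op$sym) && nzchar(pending) && op$sym != pending)
          err("conflicting bond orders for ring closure ", id)
        bonds[[length(bonds) + 1L]] <- list(from = op$atom, to = prev, sym = sym)
        rings[[id]] <- NULL
        pending <- ""
      } else {
        rings[[id]] <- list(atom = prev, sym = pending)
        pending <- ""
      }
    } else {
      err("unsupported token '", ch, "'")
    }
  }
  if (length(rings)) err("unmatched ring closure(s): ",
                         paste(names(rings), collapse = ", "))
  if (length(stack)) err("unmatched '('")
  if (length(atoms) == 0L) err("no atoms")

  at <- data.frame(
    element = vapply(atoms, `[[`, "", "element"),
    aromatic = vapply(atoms, `[[`, NA, "aromatic"),
    charge = vapply(atoms, `[[`, 0L, "charge"),
    hcount = vapply(atoms, `[[`, NA_integer_, "hcount"),
    component = vapply(atoms, `[[`, 0L, "component"),
    stringsAsFactors = FALSE
  )
  if (length(bonds)) {
    bd <- data.frame(
      from = vapply(bonds, `[[`, 0L, "from"),
      to = vapply(bonds, `[[`, 0L, "to"),
      sym = vapply(bonds, `[[`, "", "sym"),
      stringsAsFactors = FALSE
    )
    both_arom <- at$aromatic[bd$from] & at$aromatic[bd$to]
    bd$aromatic <- bd$sym == ":" | (bd$sym == "" & both_arom)
    bd$order <- ifelse(bd$sym == "=", 2, ifelse(bd$sym == "#", 3, 1))
    bd$sym <- NULL
  } else {
    bd <- data.frame(from = integer(0), to = integer(0),
                     aromatic = logical(0), order = numeric(0))
  }

  g <- structure(list(atoms = at, bonds = bd), class = "molgraph")
  .resolve_implicit_h(g)
}

# Fill hcount for non-bracket atoms from default valences.
.resolve_implicit_h <- function(g) {
  at <- g$atoms
  bsum <- numeric(nrow(at))
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      o <- g$bonds$order[k]
      bsum[g$bonds$from[k]] <- bsum[g$bonds$from[k]] + o
      bsum[g$bonds$to[k]] <- bsum[g$bonds$to[k]] + o
    }
  }
  for (i in seq_len(nrow(at))) {
    if (!is.na(at$hcount[i])) next   # bracket atom: explicit H only
    v <- .default_valences[[at$element[i]]]
    if (is.null(v))
      stop("no default valence for element ", at$element[i])
    used <- bsum[i] + if (at$aromatic[i]) 1 else 0
    if (at$aromatic[i]) {
      # aromatic atoms never promote to a higher valence state: the ring
      # pi system takes one valence, the rest is sigma bonds
      at$hcount[i] <- max(0L, as.integer(min(v) - used))
    } else {
      fit <- v[v >= used]
      at$hcount[i] <- if (length(fit)) as.integer(fit[1] - used) else 0L
    }
  }
  g$atoms <- at
  g
}

#' @export
print.molgraph <- function(x, ...) {
  cat("<molgraph> ", nrow(x$atoms), " heavy atoms, ",
      nrow(x$bonds), " bonds, ", max(x$atoms$component), " component(s): ",
      hill_formula(graph_composition(x)), "\n", sep = "")
  invisible(x)
}

#' Split a molecular graph into connected components
#'
#' Components are the dot-separated parts of the SMILES input merged with
#' graph connectivity (a part that is itself disconnected is split too).
#'
#' @param g a `molgraph`.
#' @return list of `molgraph` objects, each with a single component.
#' @export
split_components <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  na <- nrow(g$atoms)
  parent <- seq_len(na)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(g$bonds)) for (k in seq_len(nrow(g$bonds))) {
    a <- find(g$bonds$from[k]); b <- find(g$bonds$to[k])
    if (a != b) parent[a] <- b
  }
  # also merge atoms sharing a dot-component label (defensive; dots split)
  roots <- vapply(seq_len(na), find, 0L)
  ids <- match(roots, unique(roots))
  lapply(seq_len(max(ids)), function(ci) {
    keep <- which(ids == ci)
    remap <- match(seq_len(na), keep)
    at <- g$atoms[keep, , drop = FALSE]
    at$component <- 1L
    rownames(at) <- NULL
    bd <- g$bonds[g$bonds$from %in% keep & g$bonds$to %in% keep, , drop = FALSE]
    bd$from <- remap[bd$from]; bd$to <- remap[bd$to]
    rownames(bd) <- NULL
    structure(list(atoms = at, bonds = bd), class = "molgraph")
  })
}

#' Elemental composition of a molecular graph
#'
#' Heavy atoms plus all implicit/explicit hydrogens; net charge is the sum
#' of formal charges.
#'
#' @param g a `molgraph`.
#' @return a [composition()].
#' @export
graph_composition <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  tab <- table(g$atoms$element)
  counts <- as.numeric(tab)
  names(counts) <- names(tab)
  counts["H"] <- (if ("H" %in% names(counts)) counts[["H"]] else 0) +
    sum(g$atoms$hcount)
  counts <- counts[counts > 0]
  composition(counts, sum(g$atoms$charge))
}

#' Number of heavy (non-hydrogen) atoms in a graph
#' @param g a `molgraph`.
#' @return integer count.
#' @export
heavy_atoms <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  sum(g$atoms$element != "H")
}
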