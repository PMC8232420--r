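#' Default pharmaceutical counterion (salt) list
#'
#' Components of a multi-component structure whose composition matches an
#' entry here are stripped during standardization. Matching is by Hill
#' formula including net charge, so e.g. maleate and fumarate (same
#' composition) are both treated as counterions. The list is configuration,
#' not chemistry: it is explicit, user-replaceable, and every removal is
#' written to the audit log.
#'
#' @return character vector of Hill-formula keys (charge suffix included).
#' @export
default_salt_list <- function() {
  c(
    # halide anions and hydrohalic acids
    "F-", "Cl-", "Br-", "I-", "FH", "ClH", "BrH", "HI",
    # alkali / alkaline-earth cations
    "Li+", "Na+", "K+", "Rb+", "Cs+", "Mg2+", "Ca2+", "Sr2+", "Ba2+", "Zn2+",
    # ammonium
    "H4N+", "H3N",
    # water of crystallization
    "H2O",
    # sulfate / nitrate / phosphate and parent acids
    "O4S2-", "HO4S-", "H2O4S", "NO3-", "HNO3",
    "O4P3-", "HO4P2-", "H2O4P-", "H3O4P",
    # sulfonates: mesylate, tosylate, besylate (+ parent acids)
    "CH3O3S-", "CH4O3S", "C7H7O3S-", "C7H8O3S", "C6H5O3S-", "C6H6O3S",
    # carboxylate counterions common in salt forms (maleate/fumarate,
    # tartrate, citrate, succinate, oxalate) and their acids
    "C4H3O4-", "C4H2O42-", "C4H4O4",
    "C4H5O6-", "C4H4O62-", "C4H6O6",
    "C6H7O7-", "C6H6O72-", "C6H5O73-", "C6H8O7",
    "C4H5O4-", "C4H6O4", "C2HO4-", "C2O42-", "C2H2O4"
  )
}

#' Standardize a multi-component structure
#'
#' Reproduces the dataset-preparation step of the screening workflow:
#' counterion components on the salt list are removed (desalting, e.g. the
#' hydrochloride of a hydrochloride salt), remaining charged sites are
#' neutralized where chemically consistent (anionic O/N/S protonated,
#' e.g. a sodium carboxylate becomes the carboxylic acid; protonated
#' amines deprotonated), and if several non-salt components remain the one
#' with the most heavy atoms is kept. Every action is recorded in an audit
#' log. Idempotent: standardizing an already standardized structure is a
#' no-op.
#'
#' @param x a `molgraph` (possibly multi-component), a list of `molgraph`
#'   components, or a SMILES string.
#' @param salt_list character vector of Hill-formula keys, see
#'   [default_salt_list()].
#' @return list with elements `graph` (the standardized single-component
#'   `molgraph`) and `log` (character vector of audit lines).
#' @examples
#' standardize_structure("CC(=O)[O-].[Na+]")$graph   # acetic acid
#' @export
standardize_structure <- function(x, salt_list = default_salt_list()) {
  comps <- if (is.character(x)) split_components(parse_smiles(x))
           else if (inherits(x, "molgraph")) split_components(x)
           else if (is.list(x) && all(vapply(x, inherits, NA, "molgraph"))) x
           else stop("x must be a molgraph, list of molgraphs, or SMILES string")
  if (length(comps) == 0L) stop("standardize: no components")

  keys <- vapply(comps, function(g) hill_formula(graph_composition(g)), "")
  is_salt <- keys %in% salt_list
  log <- character(0)
  if (any(is_salt))
    log <- c(log, paste0("removed counterion component: ",
                         keys[is_salt]))
  parents <- comps[!is_salt]
  if (length(parents) == 0L)
    stop("no parent structure: all components are on the salt list (",
         paste(keys, collapse = ", "), ")")
  if (length(parents) > 1L) {
    hv <- vapply(parents, heavy_atoms, 0L)
    pick <- which.max(hv)
    log <- c(log, paste0("multiple non-salt components; kept largest (",
                         keys[!is_salt][pick], ", ", hv[pick],
                         " heavy atoms) of ",
                         paste(keys[!is_salt], collapse = " / ")))
    parents <- parents[pick]
  }
  g <- parents[[1]]

  # neutralization
  at <- g$atoms
  for (i in seq_len(nrow(at))) {
    ch <- at$charge[i]
    if (ch < 0 && at$element[i] %in% c("O", "N", "S")) {
      at$hcount[i] <- at$hcount[i] - ch        # protonate
      at$charge[i] <- 0L
      log <- c(log, paste0("protonated anionic ", at$element[i],
                           " (atom ", i, ", charge ", ch, ")"))
    } else if (ch > 0 && at$element[i] == "N" && at$hcount[i] >= ch) {
      at$hcount[i] <- at$hcount[i] - ch        # deprotonate
      at$charge[i] <- 0L
      log <- c(log, paste0("deprotonated cationic N (atom ", i,
                           ", charge +", ch, ")"))
    }
  }
  g$atoms <- at
  net <- sum(at$charge)
  if (net != 0L)
    log <- c(log, paste0("residual net charge ", net,
                         " could not be neutralized consistently"))
  list(graph = g, log = log)
}

#' Exclusion check for a standardized drug structure
#'
#' The screening dataset excludes peptides, nucleic acids and
#' metal-containing drugs. Metal content is structural: any atom outside
#' the organic element set H, B, C, N, O, F, Si, P, S, Cl, Br, I remaining
#' after standardization triggers exclusion. Peptide/nucleic-acid status is
#' annotation-driven (input flags), since no structural criterion is
#' defined.
#'
#' @param graph standardized `molgraph`, or `NULL` if only flags are known.
#' @param peptide logical annotation flag.
#' @param nucleic_acid logical annotation flag.
#' @return list with `excluded` (logical) and `reason` (character, `NA` if
#'   not excluded).
#' @export
exclusion_check <- function(graph = NULL, peptide = FALSE,
                            nucleic_acid = FALSE) {
  if (isTRUE(peptide))
    return(list(excluded = TRUE, reason = "peptide annotation"))
  if (isTRUE(nucleic_acid))
    return(list(excluded = TRUE, reason = "nucleic-acid annotation"))
  if (!is.null(graph)) {
    stopifnot(inherits(graph, "molgraph"))
    bad <- setdiff(unique(graph$atoms$element), .organic_elements)
    if (length(bad))
      return(list(excluded = TRUE,
                  reason = paste0("metal-containing (",
                                  paste(bad, collapse = ", "), ")")))
  }
  list(excluded = FALSE, reason = NA_character_)
}
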