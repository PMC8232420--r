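# Moriguchi logP (MLOGP): a 13-parameter regression on topological counts.
# The pipeline treats MLOGP as an opaque numeric feature and accepts it as
# a precomputed column; this calculator is the optional from-structure
# path. Structural parameters are derived from the 2D graph with the
# documented rules below; pattern definitions that the original regression
# leaves to chemical judgement (HB, POL, AMP) use explicit conservative
# heuristics, stated in the methods vignette.

.mlogp_coef <- c(
  intercept = -1.014,
  CX = 1.244, NO = -1.017, PRX = 0.406, UB = -0.145, HB = 0.511,
  POL = 0.268, AMP = -2.215, ALK = 0.912, RNG = -0.392, QN = -3.684,
  NO2 = 0.474, NCS = 1.582, BLM = 0.773
)
.mlogp_exp <- c(CX = 0.6, NO = 0.9, UB = 0.8)   # others enter linearly

.adjacency <- function(g) {
  na <- nrow(g$atoms)
  adj <- vector("list", na)
  if (nrow(g$bonds)) for (k in seq_len(nrow(g$bonds))) {
    a <- g$bonds$from[k]; b <- g$bonds$to[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# logical vector: is bond k part of a cycle (endpoints stay connected
# without it)? Molecules are small; O(E^2) is fine.
.ring_bonds <- function(g, adj = .adjacency(g)) {
  nb <- nrow(g$bonds)
  if (nb == 0L) return(logical(0))
  res <- logical(nb)
  for (k in seq_len(nb)) {
    a <- g$bonds$from[k]; b <- g$bonds$to[k]
    seen <- logical(nrow(g$atoms))
    queue <- a; seen[a] <- TRUE
    while (length(queue) && !seen[b]) {
      cur <- queue[1]; queue <- queue[-1]
      for (nbv in adj[[cur]]) {
        skip <- (cur == a && nbv == b) || (cur == b && nbv == a)
        if (!skip && !seen[nbv]) { seen[nbv] <- TRUE; queue <- c(queue, nbv) }
      }
    }
    res[k] <- seen[b]
  }
  res
}

.mlogp_params <- function(g) {
  at <- g$atoms
  bd <- g$bonds
  adj <- .adjacency(g)
  el <- at$element
  nat <- nrow(at)
  ringb <- .ring_bonds(g, adj)
  in_ring <- rep(FALSE, nat)
  if (any(ringb)) in_ring[unique(c(bd$from[ringb], bd$to[ringb]))] <- TRUE

  deg <- lengths(adj)
  is_no <- el %in% c("N", "O")

  # nitro groups: N with exactly two O neighbours that are terminal
  nitro_n <- logical(nat); nitro_o <- logical(nat)
  for (i in which(el == "N")) {
    os <- adj[[i]][el[adj[[i]]] == "O"]
    os <- os[deg[os] == 1L]
    if (length(os) == 2L) {
      ords <- vapply(os, function(o) {
        sel <- (bd$from == i & bd$to == o) | (bd$from == o & bd$to == i)
        max(bd$order[sel])
      }, 0)
      if (any(ords == 2) || at$charge[i] > 0) {
        nitro_n[i] <- TRUE; nitro_o[os] <- TRUE
      }
    }
  }

  hal_w <- c(F = 0.5, Cl = 1.0, Br = 1.5, I = 2.0)
  CX <- sum(el == "C") + sum(hal_w[el[el %in% names(hal_w)]])
  NO <- sum(is_no)

  # PRX: N/O-N/O adjacency = 2 each; N/O pairs geminal on C/S/P = 1 each
  PRX <- 0
  if (nrow(bd)) for (k in seq_len(nrow(bd))) {
    if (is_no[bd$from[k]] && is_no[bd$to[k]]) PRX <- PRX + 2
  }
  for (i in which(el %in% c("C", "S", "P"))) {
    kno <- sum(is_no[adj[[i]]])
    if (kno >= 2) PRX <- PRX + choose(kno, 2)
  }

  # UB: non-aromatic multiple bonds excluding nitro N=O; aromatic systems
  # contribute one double bond per two aromatic bonds (kekule count)
  UB <- 0
  if (nrow(bd)) {
    plain <- !bd$aromatic & bd$order >= 2
    for (k in which(plain)) {
      if (nitro_n[bd$from[k]] || nitro_n[bd$to[k]]) next
      UB <- UB + 1
    }
    UB <- UB + floor(sum(bd$aromatic) / 2)
  }

  donor <- is_no & at$hcount >= 1
  # substituents attached to aromatic atoms
  arom <- at$aromatic
  subst_of <- function(i) adj[[i]][!arom[adj[[i]]]]

  # HB: donor and acceptor substituents on adjacent aromatic atoms
  HB <- 0
  if (nrow(bd)) for (k in which(bd$aromatic)) {
    a <- bd$from[k]; b <- bd$to[k]
    sa <- subst_of(a); sb <- subst_of(b)
    don_a <- any(donor[sa]); acc_a <- any(is_no[sa])
    don_b <- any(donor[sb]); acc_b <- any(is_no[sb])
    if ((don_a && acc_b) || (don_b && acc_a)) { HB <- 1; break }
  }

  # POL: polar substituents on aromatic atoms: first atom is a heteroatom
  # or halogen, or a carbon multiply bonded to N/O (carbonyl, nitrile)
  POL <- 0
  for (i in which(arom)) {
    for (s in subst_of(i)) {
      if (el[s] %in% c("N", "O", "S", "P", "F", "Cl", "Br", "I")) {
        POL <- POL + 1
      } else if (el[s] == "C") {
        mult_het <- any(vapply(seq_len(nrow(bd)), function(k) {
          tchs <- c(bd$from[k], bd$to[k])
          s %in% tchs && bd$order[k] >= 2 &&
            el[setdiff(tchs, s)[1]] %in% c("N", "O")
        }, NA))
        if (isTRUE(mult_het)) POL <- POL + 1
      }
    }
  }

  # carboxyl carbons: C with =O and -OH
  carboxyl <- logical(nat)
  for (i in which(el == "C")) {
    os <- adj[[i]][el[adj[[i]]] == "O" & deg[adj[[i]]] == 1L]
    if (length(os) >= 2) {
      ords <- vapply(os, function(o) {
        sel <- (bd$from == i & bd$to == o) | (bd$from == o & bd$to == i)
        max(bd$order[sel])
      }, 0)
      if (any(ords == 2) && any(ords == 1 & at$hcount[os] >= 1))
        carboxyl[i] <- TRUE
    }
  }
  # amine N: has H, not adjacent to carbonyl carbon (amide excluded)
  carbonyl_c <- logical(nat)
  if (nrow(bd)) for (k in which(!bd$aromatic & bd$order == 2)) {
    a <- bd$from[k]; b <- bd$to[k]
    if (el[a] == "C" && el[b] == "O") carbonyl_c[a] <- TRUE
    if (el[b] == "C" && el[a] == "O") carbonyl_c[b] <- TRUE
  }
  amine <- el == "N" & at$hcount >= 1 & !arom &
    !vapply(seq_len(nat), function(i) any(carbonyl_c[adj[[i]]]), NA)

  AMP <- 0
  for (i in which(amine)) {        # alpha-amino acid: N-C-C(=O)OH
    for (c1 in adj[[i]][el[adj[[i]]] == "C"]) {
      if (any(carboxyl[adj[[c1]]])) { AMP <- 1; break }
    }
    if (AMP == 1) break
  }
  if (AMP == 0) {                  # aminobenzoic / pyridinecarboxylic: 0.5
    ar_cooh <- any(vapply(which(arom), function(i) any(carboxyl[subst_of(i)]), NA))
    ar_amine <- any(vapply(which(arom), function(i) any(amine[subst_of(i)]), NA)) ||
      any(el == "N" & arom)
    if (ar_cooh && ar_amine) AMP <- 0.5
  }

  hydrocarbon <- all(el %in% c("C", "H"))
  ALK <- as.numeric(hydrocarbon && !any(arom) && UB <= 1 &&
                      !any(bd$order == 3))
  # RNG: rings other than benzenoid (all-carbon aromatic) systems
  RNG <- as.numeric(any(in_ring & !(arom & el == "C")) ||
                      (any(ringb) && any(!bd$aromatic[ringb])))

  QN <- 0
  for (i in which(el == "N")) {
    if (nitro_n[i]) next   # nitro has its own correction term
    bo <- 0
    if (nrow(bd)) bo <- sum(bd$order[(bd$from == i | bd$to == i)])
    if (bo + at$hcount[i] >= 4 && at$charge[i] > 0) { QN <- 1; break }
    ox <- adj[[i]][el[adj[[i]]] == "O" & deg[adj[[i]]] == 1L]
    if (at$charge[i] > 0 && length(ox) == 1L && !nitro_n[i]) QN <- max(QN, 0.5)
  }

  NO2 <- sum(nitro_n)

  NCS <- 0
  for (i in which(el == "C")) {
    nn <- adj[[i]]
    has_n <- any(el[nn] == "N"); has_s <- any(el[nn] == "S")
    if (has_n && has_s && nrow(bd)) {
      ords <- bd$order[bd$from == i | bd$to == i]
      if (sum(ords >= 2) >= 2) NCS <- NCS + 1             # N=C=S
      else if (any(ords == 3)) NCS <- NCS + 0.5           # S-C#N
    }
  }

  # beta-lactam: 4-membered ring with N and a ring C bearing exocyclic =O
  BLM <- 0
  if (any(ringb)) {
    for (i in seq_len(nat)) {
      for (j in adj[[i]]) for (k in setdiff(adj[[j]], i))
        for (l in setdiff(adj[[k]], c(i, j))) {
          if (i %in% adj[[l]]) {
            ring <- c(i, j, k, l)
            if (any(el[ring] == "N") && any(carbonyl_c[ring] & el[ring] == "C"))
              BLM <- 1
          }
        }
      if (BLM == 1) break
    }
  }

  c(CX = CX, NO = NO, PRX = PRX, UB = UB, HB = HB, POL = POL, AMP = AMP,
    ALK = ALK, RNG = RNG, QN = QN, NO2 = NO2, NCS = NCS, BLM = BLM)
}

#' Moriguchi logP from a molecular graph
#'
#' Computes the Moriguchi octanol/water partition coefficient estimate, a
#' regression on thirteen topological parameters (weighted carbon/halogen
#' count, N/O count, N/O proximity, unsaturation, and dummy variables for
#' intramolecular hydrogen bonding, aromatic polar substituents,
#' amphotericity, hydrocarbon character, rings, quaternary nitrogen, nitro,
#' iso/thiocyanate and beta-lactam). The screening pipeline only ever uses
#' MLOGP as an opaque numeric feature; prefer a precomputed column when one
#' is available.
#'
#' @param graph a standardized single-component `molgraph`, or SMILES
#'   string.
#' @param detail if `TRUE`, return the parameter vector as attribute
#'   `"params"`.
#' @return numeric MLOGP estimate.
#' @examples
#' moriguchi_logp("c1ccccc1")   # benzene
#' @export
moriguchi_logp <- function(graph, detail = FALSE) {
  if (is.character(graph)) graph <- parse_smiles(graph)
  stopifnot(inherits(graph, "molgraph"))
  if (length(split_components(graph)) != 1L)
    stop("moriguchi_logp requires a single-component (standardized) structure")
  bad <- setdiff(unique(graph$atoms$element), .organic_elements)
  if (length(bad))
    stop("unsupported element(s) for MLOGP: ", paste(bad, collapse = ", "))
  p <- .mlogp_params(graph)
  terms <- p
  for (nm in names(.mlogp_exp)) terms[nm] <- p[nm]^.mlogp_exp[nm]
  val <- .mlogp_coef[["intercept"]] +
    sum(.mlogp_coef[names(terms)] * terms)
  if (detail) attr(val, "params") <- p
  val
}
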