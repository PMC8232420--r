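#' Read a drug table
#'
#' Reads the standard input table: CSV or TSV (by extension, or `sep`),
#' UTF-8, with header columns `id,name,smiles,formula,dili_class,
#' atc_codes,year,peptide_flag,nucleic_acid_flag`. Only `id` and
#' `dili_class` are mandatory; `atc_codes` is semicolon-separated
#' first-level letters. The binary DILI label is derived deterministically:
#' Most/Less concern are DILI-positive, No concern is negative.
#'
#' @param path file path.
#' @param sep field separator; default inferred from extension
#'   (`.tsv`/`.tab` = tab, otherwise comma).
#' @return data.frame with normalized columns plus `dili_label`
#'   (integer 0/1) and `atc_list` (list of character vectors).
#' @export
read_drug_table <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, comment.char = "",
                          fileEncoding = "UTF-8")
  if (!all(c("id", "dili_class") %in% names(df)))
    stop("drug table must have at least columns 'id' and 'dili_class'")
  for (col in c("name", "smiles", "formula", "atc_codes"))
    if (!col %in% names(df)) df[[col]] <- NA_character_
  for (col in c("year"))
    if (!col %in% names(df)) df[[col]] <- NA_integer_
  for (col in c("peptide_flag", "nucleic_acid_flag"))
    if (!col %in% names(df)) df[[col]] <- FALSE
  df$peptide_flag <- as.logical(df$peptide_flag) %in% TRUE
  df$nucleic_acid_flag <- as.logical(df$nucleic_acid_flag) %in% TRUE
  normalize_drug_table(df)
}

#' Normalize an in-memory drug table
#'
#' Validates `dili_class`, attaches `dili_label` (Most/Less -> 1, No -> 0)
#' and parses `atc_codes` into `atc_list`.
#'
#' @param df data.frame with at least `id` and `dili_class`.
#' @return normalized data.frame.
#' @export
normalize_drug_table <- function(df) {
  ok <- df$dili_class %in% c("Most", "Less", "No")
  if (any(!ok))
    stop("invalid dili_class value(s): ",
         paste(unique(df$dili_class[!ok]), collapse = ", "),
         " (expected Most/Less/No)")
  df$dili_label <- as.integer(df$dili_class %in% c("Most", "Less"))
  atc <- df$atc_codes
  if (is.null(atc)) atc <- rep(NA_character_, nrow(df))
  df$atc_list <- lapply(atc, function(s) {
    if (is.na(s) || !nzchar(s)) character(0)
    else toupper(trimws(strsplit(s, ";", fixed = TRUE)[[1]]))
  })
  df
}

#' Compute constitutional descriptors for a drug table
#'
#' End-to-end chemistry stage: for each record, parse the structure
#' (SMILES preferred, formula fallback), desalt/neutralize SMILES
#' structures, apply the exclusion rules, and compute the constitutional
#' descriptors AMW, H%, molecular weight and atom count. MLOGP is taken
#' from a precomputed input column when present (`mlogp = "column"`), or
#' computed with the built-in Moriguchi calculator from SMILES
#' (`mlogp = "moriguchi"`), or omitted.
#'
#' @param df drug table from [read_drug_table()] / [normalize_drug_table()].
#' @param masses mass table, see [atomic_masses()].
#' @param mlogp one of `"column"`, `"moriguchi"`, `"none"`.
#' @param salt_list see [default_salt_list()].
#' @return data.frame `id, AMW, H_PERCENT, MW, N_ATOMS, MLOGP, excluded,
#'   exclusion_reason`; excluded records carry `NA` descriptors. The
#'   standardization audit log (one entry per drug) is attached as
#'   attribute `"audit"`.
#' @export
compute_descriptors <- function(df, masses = atomic_masses(),
                                mlogp = c("column", "moriguchi", "none"),
                                salt_list = default_salt_list()) {
  mlogp <- match.arg(mlogp)
  n <- nrow(df)
  out <- data.frame(id = df$id, AMW = NA_real_, H_PERCENT = NA_real_,
                    MW = NA_real_, N_ATOMS = NA_integer_, MLOGP = NA_real_,
                    excluded = FALSE, exclusion_reason = NA_character_,
                    stringsAsFactors = FALSE)
  audit <- character(n)
  for (i in seq_len(n)) {
    lines <- character(0)
    graph <- NULL
    comp <- NULL
    if (!is.na(df$smiles[i]) && nzchar(df$smiles[i])) {
      std <- standardize_structure(df$smiles[i], salt_list = salt_list)
      graph <- std$graph
      lines <- std$log
      comp <- graph_composition(graph)
    } else if (!is.na(df$formula[i]) && nzchar(df$formula[i])) {
      comp <- parse_formula(df$formula[i])
      lines <- "descriptors from formula (no structure-level standardization)"
    } else {
      out$excluded[i] <- TRUE
      out$exclusion_reason[i] <- "no structure (neither smiles nor formula)"
      audit[i] <- paste0(df$id[i], ": excluded: ", out$exclusion_reason[i])
      next
    }
    excl <- exclusion_check(graph, peptide = df$peptide_flag[i],
                            nucleic_acid = df$nucleic_acid_flag[i])
    if (!excl$excluded && is.null(graph)) {
      bad <- setdiff(names(comp$counts), .organic_elements)
      if (length(bad))
        excl <- list(excluded = TRUE,
                     reason = paste0("metal-containing (",
                                     paste(bad, collapse = ", "), ")"))
    }
    if (excl$excluded) {
      out$excluded[i] <- TRUE
      out$exclusion_reason[i] <- excl$reason
      lines <- c(lines, paste0("excluded: ", excl$reason))
    } else {
      out$AMW[i] <- amw(comp, masses)
      out$H_PERCENT[i] <- h_percent(comp)
      out$MW[i] <- molecular_weight(comp, masses)
      out$N_ATOMS[i] <- n_atoms(comp)
      if (mlogp == "column" && "mlogp" %in% tolower(names(df))) {
        col <- names(df)[tolower(names(df)) == "mlogp"][1]
        out$MLOGP[i] <- as.numeric(df[[col]][i])
      } else if (mlogp == "moriguchi" && !is.null(graph)) {
        out$MLOGP[i] <- moriguchi_logp(graph)
      }
    }
    audit[i] <- paste0(df$id[i], ": ",
                       if (length(lines)) paste(lines, collapse = "; ")
                       else "no changes")
  }
  attr(out, "audit") <- audit
  out
}

#' Write a descriptor table to CSV at full precision
#' @param desc descriptor data.frame from [compute_descriptors()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(desc, path) {
  utils::write.csv(format(desc, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
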