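# Ligand validity and drug-likeness filtering.

#' Default exclusion list for non-valid ligands
#'
#' Het-code-style identifiers for crystallographic additives, buffer
#' components, salts, metal ions and solvents that never count as valid
#' ligands. Shipped as an editable CSV (`extdata/ligand_exclusions.csv`);
#' curation rules differ between databases, so the list is data, not code.
#'
#' @param path optional path to a CSV with columns `ligand_id` and
#'   `category`; defaults to the shipped list.
#' @return tibble with `ligand_id` and `category`.
#' @export
default_exclusions <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ligand_exclusions.csv",
                        package = "promisite")
  }
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Flag valid ligands
#'
#' A ligand is valid when it is a biologically relevant small molecule, a
#' peptide of fewer than 11 amino acids, or an oligonucleotide of fewer than
#' four nucleotides. Covalently bound molecules and anything on the
#' exclusion list (additives, salts, metals, solvents) are invalid. Ligands
#' whose composition cannot be resolved are flagged invalid with reason
#' `"unresolvable"` rather than dropped.
#'
#' @param ligands data frame with `ligand_id`; optional columns
#'   `n_peptide_residues`, `n_nucleotides` (NA when not applicable),
#'   `covalent` (logical) and `smiles`.
#' @param exclusions exclusion table as from [default_exclusions()].
#' @return input with `valid` (logical) and `invalid_reason` columns added.
#' @export
validity_filter <- function(ligands, exclusions = default_exclusions()) {
  stopifnot("ligand_id" %in% names(ligands))
  lig <- tibble::as_tibble(ligands)
  n <- nrow(lig)
  pep <- if ("n_peptide_residues" %in% names(lig)) lig$n_peptide_residues else rep(NA_integer_, n)
  nuc <- if ("n_nucleotides" %in% names(lig)) lig$n_nucleotides else rep(NA_integer_, n)
  cov <- if ("covalent" %in% names(lig)) lig$covalent else rep(FALSE, n)
  cov[is.na(cov)] <- FALSE
  smi <- if ("smiles" %in% names(lig)) lig$smiles else rep(NA_character_, n)

  reason <- rep(NA_character_, n)
  reason[toupper(lig$ligand_id) %in% toupper(exclusions$ligand_id)] <- "excluded"
  reason[is.na(reason) & cov] <- "covalent"
  reason[is.na(reason) & !is.na(pep) & pep >= 11] <- "peptide"
  reason[is.na(reason) & !is.na(nuc) & nuc >= 4] <- "oligonucleotide"
  unresolved <- is.na(reason) & is.na(smi) & is.na(pep) & is.na(nuc)
  reason[unresolved] <- "unresolvable"

  lig$valid <- is.na(reason)
  lig$invalid_reason <- reason
  lig
}

#' Default drug-likeness rule set
#'
#' Three soft drug-likeness rules are always on: at most 6 rings, at most 11
#' rotatable bonds, and an H/C ratio between 0.1 and 1.11 (all boundaries
#' inclusive). The Lipinski bounds (MW <= 500, logP <= 5, HBD <= 5,
#' HBA <= 10) are available but off by default.
#'
#' @param lipinski also apply the four Lipinski bounds.
#' @return tibble with `descriptor`, `min`, `max`.
#' @export
druglike_rules <- function(lipinski = FALSE) {
  rules <- tibble::tribble(
    ~descriptor,       ~min,  ~max,
    "rings",           -Inf,  6,
    "rotatable_bonds", -Inf,  11,
    "ratio_hc",        0.1,   1.11
  )
  if (lipinski) {
    rules <- dplyr::bind_rows(rules, tibble::tribble(
      ~descriptor, ~min, ~max,
      "mw",        -Inf, 500,
      "logp",      -Inf, 5,
      "hbd",       -Inf, 5,
      "hba",       -Inf, 10
    ))
  }
  rules
}

#' Flag drug-like ligands
#'
#' @param descriptors descriptor table as from [ligand_descriptors()] (must
#'   contain `ligand_id` and every descriptor named in `rules`).
#' @param rules rule table as from [druglike_rules()].
#' @return input with `drug_like` (logical; NA when a required descriptor is
#'   missing) and `druglike_reason` columns added.
#' @export
druglike_filter <- function(descriptors, rules = druglike_rules()) {
  stopifnot("ligand_id" %in% names(descriptors))
  missing_cols <- setdiff(rules$descriptor, names(descriptors))
  if (length(missing_cols) > 0) {
    stop("descriptor table lacks rule column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  d <- tibble::as_tibble(descriptors)
  n <- nrow(d)
  pass <- matrix(NA, nrow = n, ncol = nrow(rules),
                 dimnames = list(NULL, rules$descriptor))
  for (j in seq_len(nrow(rules))) {
    x <- d[[rules$descriptor[j]]]
    pass[, j] <- x >= rules$min[j] & x <= rules$max[j]
  }
  any_na <- apply(pass, 1, anyNA)
  all_ok <- apply(pass, 1, function(r) all(r %in% TRUE))
  d$drug_like <- ifelse(any_na, NA, all_ok)
  d$druglike_reason <- vapply(seq_len(n), function(i) {
    if (any_na[i]) return("incomputable")
    fails <- colnames(pass)[!pass[i, ]]
    if (length(fails) == 0) "" else paste(fails, collapse = ";")
  }, character(1))
  d
}
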