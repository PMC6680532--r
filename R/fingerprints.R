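# Fingerprinting and Tanimoto similarity. The default backend is OpenBabel's
# MACCS key set (via ChemmineOB); fingerprints travel as a plain logical
# matrix (one row per ligand) so an alternative key set can be swapped in
# without touching the clustering code.

#' Parse SMILES into an SDF set
#'
#' Thin wrapper around the OpenBabel conversion; invalid SMILES raise an
#' error naming the offending ligand.
#'
#' @param ligands data frame with columns `ligand_id` and `smiles`.
#' @return a `ChemmineR::SDFset` with compound ids set to `ligand_id`.
#' @export
parse_smiles <- function(ligands) {
  stopifnot(is.data.frame(ligands),
            all(c("ligand_id", "smiles") %in% names(ligands)))
  if (anyDuplicated(ligands$ligand_id)) stop("duplicated ligand_id")
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(ligands$smiles))
  if (length(sdf) != nrow(ligands)) {
    ## OpenBabel silently drops unparseable molecules; identify them
    ok <- vapply(ligands$smiles, function(s) {
      length(suppressWarnings(ChemmineR::smiles2sdf(s))) == 1
    }, logical(1))
    stop("unparseable SMILES for ligand(s): ",
         paste(ligands$ligand_id[!ok], collapse = ", "))
  }
  suppressWarnings(ChemmineR::cid(sdf) <- ligands$ligand_id)
  sdf
}

#' MACCS-type fingerprints for a set of ligands
#'
#' @param ligands data frame with `ligand_id` and `smiles`, or an `SDFset`.
#' @param backend fingerprint backend; currently `"maccs"` (OpenBabel MACCS
#'   keys, stored in a fixed 256-bit container).
#' @return logical matrix, one row per ligand (rownames = ligand ids), one
#'   column per key.
#' @export
fingerprint_ligands <- function(ligands, backend = "maccs") {
  backend <- match.arg(backend)
  sdf <- if (methods::is(ligands, "SDFset")) ligands else parse_smiles(ligands)
  fp <- suppressWarnings(ChemmineR::fingerprintOB(sdf, "MACCS"))
  m <- as.matrix(fp) == 1
  rownames(m) <- ChemmineR::cid(sdf)
  m
}

#' Tanimoto similarity between two fingerprints
#'
#' `|a AND b| / |a OR b|`. Symmetric, in \[0, 1\]; equal to 1 for identical
#' non-empty fingerprints and 0 for disjoint ones. Undefined (error) when
#' both fingerprints are all-zero.
#'
#' @param fp_a,fp_b logical vectors of equal length.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(fp_a, fp_b) {
  fp_a <- as.logical(fp_a); fp_b <- as.logical(fp_b)
  if (length(fp_a) != length(fp_b)) stop("fingerprint lengths differ")
  u <- sum(fp_a | fp_b)
  if (u == 0) stop("tanimoto undefined: both fingerprints are empty")
  sum(fp_a & fp_b) / u
}

#' Pairwise Tanimoto similarity matrix
#'
#' @param fps logical matrix of fingerprints (rows = ligands).
#' @return symmetric numeric matrix with unit diagonal.
#' @export
tanimoto_matrix <- function(fps) {
  fps <- as.matrix(fps) * 1
  n <- rowSums(fps)
  if (any(n == 0)) {
    stop("tanimoto undefined: empty fingerprint for ",
         paste(rownames(fps)[n == 0], collapse = ", "))
  }
  inter <- fps %*% t(fps)
  sim <- inter / (outer(n, n, "+") - inter)
  dimnames(sim) <- list(rownames(fps), rownames(fps))
  sim
}
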