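# Protein chain handling: PDB import into a tidy atom table, sequence
# identity, two-step greedy homology clustering (CD-HIT style) and rigid
# superposition of cluster members onto a common reference frame.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Read protein-ligand complexes into a tidy atom table
#'
#' Each PDB file is one complex; ATOM records give the protein chains and
#' HETATM records the bound ligands (waters are skipped). Only the first
#' model of multi-model files is used. Hydrogens are dropped: all downstream
#' geometry operates on heavy atoms.
#'
#' @param paths character vector of PDB files, or a single directory (all
#'   `*.pdb` files in it).
#' @return tibble with one row per heavy atom: `complex_id`, `record`
#'   (`ATOM`/`HETATM`), `chain_id`, `chain_uid`, `residue_number`,
#'   `residue_name`, `atom_name`, `element`, `x`, `y`, `z`, `side_chain`,
#'   and for ligand atoms `ligand_id` (het code) and `ligand_instance`.
#' @export
read_complexes <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- sort(list.files(paths, pattern = "\\.pdb$", full.names = TRUE))
  }
  if (length(paths) == 0) stop("no PDB files found")
  purrr::map_dfr(paths, function(p) {
    pdb <- bio3d::read.pdb(p, multi = FALSE, verbose = FALSE)
    at <- tibble::as_tibble(pdb$atom)
    cid <- sub("\\.pdb$", "", basename(p))
    at <- dplyr::filter(at, .data$resid != "HOH",
                        is.na(.data$elesy) | .data$elesy != "H")
    tibble::tibble(
      complex_id = cid,
      record = at$type,
      chain_id = at$chain,
      chain_uid = paste0(cid, "_", at$chain),
      residue_number = at$resno,
      residue_name = at$resid,
      atom_name = at$elety,
      element = ifelse(is.na(at$elesy) | at$elesy == "",
                       substr(gsub("[0-9']", "", at$elety), 1, 1), at$elesy),
      x = at$x, y = at$y, z = at$z,
      side_chain = at$type == "ATOM" & !(at$elety %in% BACKBONE_ATOMS),
      ligand_id = ifelse(at$type == "HETATM", at$resid, NA_character_),
      ligand_instance = ifelse(at$type == "HETATM",
                               paste0(cid, "_", at$chain, "_", at$resid, "_",
                                      at$resno),
                               NA_character_)
    )
  })
}

#' Extract one-letter sequences of the protein chains
#'
#' @param atoms atom table as from [read_complexes()].
#' @return tibble with `chain_uid`, `complex_id`, `chain_id`, `sequence`,
#'   `n_residues`. Non-standard residues are written as `X`.
#' @export
chain_sequences <- function(atoms) {
  ca <- dplyr::filter(atoms, .data$record == "ATOM", .data$atom_name == "CA")
  ca <- dplyr::arrange(ca, .data$chain_uid, .data$residue_number)
  dplyr::summarise(
    dplyr::group_by(ca, .data$chain_uid, .data$complex_id, .data$chain_id),
    sequence = paste(aa_three_to_one(.data$residue_name), collapse = ""),
    n_residues = dplyr::n(), .groups = "drop")
}

aa_three_to_one <- function(resid) {
  out <- suppressWarnings(bio3d::aa321(resid))
  out[is.na(out) | !out %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]] <- "X"
  out
}

unit_substitution_matrix <- function() {
  alpha <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
  m <- matrix(0, length(alpha), length(alpha), dimnames = list(alpha, alpha))
  diag(m) <- 1
  m["X", "X"] <- 0  # unknown residues never count as matches
  m
}

align_global <- function(seq_a, seq_b) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = unit_substitution_matrix(),
    gapOpening = 10, gapExtension = 0.5)
}

#' Pairwise sequence identity
#'
#' Global alignment with unit scoring (match +1, mismatch 0, affine gaps
#' open 10 / extend 0.5). The identity denominator follows the CD-HIT
#' convention by default (length of the shorter sequence); `"alignment"`
#' divides by the full alignment length including gap columns.
#'
#' @param seq_a,seq_b non-empty amino-acid strings.
#' @param denominator `"shorter"` (default) or `"alignment"`.
#' @return identity fraction in \[0, 1\]; symmetric.
#' @export
sequence_identity <- function(seq_a, seq_b,
                              denominator = c("shorter", "alignment")) {
  denominator <- match.arg(denominator)
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) stop("empty sequence")
  aln <- align_global(seq_a, seq_b)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  matches <- sum(pat == sub & pat != "-" & pat != "X")
  den <- switch(denominator,
                shorter = min(nchar(seq_a), nchar(seq_b)),
                alignment = length(pat))
  matches / den
}

## pattern residue index -> subject residue index over aligned columns
alignment_map <- function(seq_member, seq_ref) {
  aln <- align_global(seq_member, seq_ref)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ip <- cumsum(pat != "-")
  is <- cumsum(sub != "-")
  keep <- pat != "-" & sub != "-"
  tibble::tibble(member_pos = ip[keep], ref_pos = is[keep])
}

#' Two-step greedy clustering of homologous chains
#'
#' Pass 1 (families): chains sorted by decreasing length (ties by uid) are
#' swept greedily; a chain joins the first family whose representative
#' shares identity above `t1`, otherwise it founds a new family. Pass 2
#' merges families whose representatives share identity above `t2`
#' (single-linkage over representatives). The representative of a cluster is
#' its longest chain (ties by uid). Greedy clustering is not transitive in
#' general; on well-separated inputs it recovers the true families.
#'
#' @param chains tibble as from [chain_sequences()].
#' @param t1 family identity threshold (default 0.90, strict `>`).
#' @param t2 merge threshold on family representatives (default 0.80).
#' @param denominator passed to [sequence_identity()].
#' @return tibble `chain_uid`, `family`, `cluster_id`, `reference` (logical:
#'   cluster representative).
#' @export
cluster_chains <- function(chains, t1 = 0.90, t2 = 0.80,
                           denominator = "shorter") {
  stopifnot(t2 <= t1, nrow(chains) >= 1)
  ord <- order(-chains$n_residues, chains$chain_uid)
  chains <- chains[ord, ]
  fam_rep <- integer(0)           # row index of each family representative
  fam_of <- integer(nrow(chains))
  for (i in seq_len(nrow(chains))) {
    assigned <- FALSE
    for (f in seq_along(fam_rep)) {
      idy <- sequence_identity(chains$sequence[i],
                               chains$sequence[fam_rep[f]],
                               denominator = denominator)
      if (idy > t1) { fam_of[i] <- f; assigned <- TRUE; break }
    }
    if (!assigned) { fam_rep <- c(fam_rep, i); fam_of[i] <- length(fam_rep) }
  }
  ## pass 2: single-linkage merge of family representatives above t2
  nf <- length(fam_rep)
  parent <- seq_len(nf)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (nf > 1) {
    for (a in seq_len(nf - 1)) for (b in seq(a + 1, nf)) {
      idy <- sequence_identity(chains$sequence[fam_rep[a]],
                               chains$sequence[fam_rep[b]],
                               denominator = denominator)
      if (idy > t2) parent[find(b)] <- find(a)
    }
  }
  root <- vapply(seq_len(nf), find, integer(1))
  cluster_of_family <- match(root, unique(root))

  out <- tibble::tibble(
    chain_uid = chains$chain_uid,
    family = fam_of,
    cluster = cluster_of_family[fam_of],
    n_residues = chains$n_residues
  )
  ## stable cluster ids ordered by representative (longest member, tie uid)
  reps <- dplyr::slice(dplyr::group_by(out, .data$cluster),
                       order(-.data$n_residues, .data$chain_uid)[1])
  reps <- dplyr::arrange(dplyr::ungroup(reps), .data$chain_uid)
  relabel <- stats::setNames(seq_len(nrow(reps)), reps$cluster)
  out$cluster_id <- sprintf("CC%03d", relabel[as.character(out$cluster)])
  out$reference <- out$chain_uid %in% reps$chain_uid
  dplyr::select(dplyr::arrange(out, .data$cluster_id, .data$chain_uid),
                "chain_uid", "family", "cluster_id", "reference")
}

#' Superpose cluster members onto their reference chains
#'
#' For every chain cluster, members are globally aligned to the reference
#' sequence and superposed by least-squares (Kabsch) over the aligned CA
#' atoms. The reference transform is the identity.
#'
#' @param atoms atom table as from [read_complexes()].
#' @param clusters membership as from [cluster_chains()].
#' @return object of class `promisite_superposition`: list with `members`
#'   (tibble `chain_uid`, `cluster_id`, `reference`, `rmsd`, `n_aligned`),
#'   `transforms` (named list of `rotation`/`translation`), `residue_maps`
#'   (named list of tibbles `residue_number`, `ref_pos`).
#' @export
superpose_chains <- function(atoms, clusters) {
  seqs <- chain_sequences(atoms)
  seqs <- dplyr::left_join(seqs, clusters, by = "chain_uid")
  ca <- dplyr::filter(atoms, .data$record == "ATOM", .data$atom_name == "CA")
  ca <- dplyr::arrange(ca, .data$chain_uid, .data$residue_number)
  ca_by_chain <- split(ca, ca$chain_uid)

  transforms <- list()
  residue_maps <- list()
  rows <- list()
  for (cl in unique(seqs$cluster_id)) {
    mem <- seqs[seqs$cluster_id == cl, ]
    ref_uid <- mem$chain_uid[mem$reference][1]
    ref_seq <- mem$sequence[mem$chain_uid == ref_uid]
    ref_ca <- ca_by_chain[[ref_uid]]
    for (j in seq_len(nrow(mem))) {
      uid <- mem$chain_uid[j]
      map <- alignment_map(mem$sequence[j], ref_seq)
      mem_ca <- ca_by_chain[[uid]]
      residue_maps[[uid]] <- tibble::tibble(
        residue_number = mem_ca$residue_number[map$member_pos],
        ref_pos = map$ref_pos)
      if (uid == ref_uid) {
        transforms[[uid]] <- list(rotation = diag(3),
                                  translation = c(0, 0, 0))
        rows[[uid]] <- tibble::tibble(chain_uid = uid, cluster_id = cl,
                                      reference = TRUE, rmsd = 0,
                                      n_aligned = nrow(map))
        next
      }
      if (nrow(map) < 3) {
        stop("cannot superpose ", uid, ": fewer than 3 aligned residues")
      }
      fit <- kabsch(
        as.matrix(mem_ca[map$member_pos, c("x", "y", "z")]),
        as.matrix(ref_ca[map$ref_pos, c("x", "y", "z")]))
      transforms[[uid]] <- fit[c("rotation", "translation")]
      rows[[uid]] <- tibble::tibble(chain_uid = uid, cluster_id = cl,
                                    reference = FALSE, rmsd = fit$rmsd,
                                    n_aligned = nrow(map))
    }
  }
  structure(list(members = dplyr::bind_rows(rows),
                 transforms = transforms,
                 residue_maps = residue_maps),
            class = "promisite_superposition")
}

#' @export
print.promisite_superposition <- function(x, ...) {
  cat("<promisite_superposition> ", nrow(x$members), " chains in ",
      length(unique(x$members$cluster_id)), " cluster(s); mean RMSD ",
      sprintf("%.3f", mean(x$members$rmsd[!x$members$reference])), " A\n",
      sep = "")
  invisible(x)
}
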