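# Ligand-proximity pocket extraction and the 72-slot pocket descriptor panel.

#' Kyte-Doolittle hydropathy scale
#' @return named numeric vector over the 20 standard residues (3-letter).
#' @keywords internal
kyte_doolittle <- function() {
  c(ILE = 4.5, VAL = 4.2, LEU = 3.8, PHE = 2.8, CYS = 2.5, MET = 1.9,
    ALA = 1.8, GLY = -0.4, THR = -0.7, SER = -0.8, TRP = -0.9, TYR = -1.3,
    PRO = -1.6, HIS = -3.2, GLU = -3.5, GLN = -3.5, ASP = -3.5, ASN = -3.5,
    LYS = -3.9, ARG = -4.5)
}

RESIDUE_CLASSES <- list(
  aliphatic = c("ALA", "VAL", "LEU", "ILE"),
  aromatic = c("PHE", "TRP", "TYR", "HIS"),
  charged = c("ASP", "GLU", "LYS", "ARG", "HIS"),
  positive = c("LYS", "ARG", "HIS"),
  negative = c("ASP", "GLU"),
  polar = c("SER", "THR", "ASN", "GLN", "CYS", "TYR"),
  tiny = c("ALA", "GLY", "SER", "CYS"),
  small = c("ALA", "CYS", "ASP", "GLY", "ASN", "PRO", "SER", "THR", "VAL"),
  hydrophobic = c("ALA", "CYS", "PHE", "ILE", "LEU", "MET", "VAL")
)

STANDARD_AA3 <- names(kyte_doolittle())

#' Extract ligand-proximity pockets from an atom table
#'
#' A pocket is the set of protein heavy atoms of one chain lying within
#' `threshold` (Euclidean, boundary inclusive) of any heavy atom of one
#' bound ligand. Ligands contacting more than one chain (interface ligands)
#' are omitted, and ligands contacting no chain are rejected; both are
#' logged in the `rejected` table rather than silently dropped.
#'
#' When a superposition is supplied, pocket coordinates and barycenters are
#' expressed in the chain-cluster reference frame (required for clustering
#' pockets across homologous chains), each pocket is annotated with its
#' chain's `cluster_id`, and pocket atoms receive correspondence keys
#' (aligned reference position + atom name) used by [score_of_overlap()].
#'
#' @param atoms atom table as from [read_complexes()].
#' @param threshold contact distance in Angstrom (default 5.5).
#' @param superposition optional result of [superpose_chains()].
#' @return list with `pockets` (tibble: `pocket_id`, `complex_id`,
#'   `chain_uid`, `cluster_id`, `ligand_id`, `ligand_instance`, `n_atoms`,
#'   `n_residues`, `bx`, `by`, `bz`, `dmax`, list-columns `atoms` and
#'   `atom_keys`) and `rejected` (tibble: `ligand_instance`, `reason`,
#'   `chains`).
#' @export
extract_pockets <- function(atoms, threshold = 5.5, superposition = NULL) {
  stopifnot(threshold > 0)
  prot <- dplyr::filter(atoms, .data$record == "ATOM")
  lig <- dplyr::filter(atoms, .data$record == "HETATM")
  cluster_of <- NULL
  if (!is.null(superposition)) {
    cluster_of <- stats::setNames(superposition$members$cluster_id,
                                  superposition$members$chain_uid)
  }

  pockets <- list(); rejected <- list()
  for (cid in unique(atoms$complex_id)) {
    pc <- prot[prot$complex_id == cid, ]
    lc <- lig[lig$complex_id == cid, ]
    if (nrow(lc) == 0) next
    pxyz <- as.matrix(pc[, c("x", "y", "z")])
    for (inst in unique(lc$ligand_instance)) {
      la <- lc[lc$ligand_instance == inst, ]
      lxyz <- as.matrix(la[, c("x", "y", "z")])
      ## min distance of each protein atom to any ligand atom
      d2 <- matrix(rowSums(pxyz^2), nrow(pxyz), nrow(lxyz)) +
        matrix(rowSums(lxyz^2), nrow(pxyz), nrow(lxyz), byrow = TRUE) -
        2 * pxyz %*% t(lxyz)
      near <- sqrt(pmax(apply(d2, 1, min), 0)) <= threshold
      chains_hit <- sort(unique(pc$chain_uid[near]))
      if (length(chains_hit) == 0) {
        rejected[[length(rejected) + 1]] <- tibble::tibble(
          ligand_instance = inst, reason = "empty", chains = "")
        next
      }
      if (length(chains_hit) > 1) {
        rejected[[length(rejected) + 1]] <- tibble::tibble(
          ligand_instance = inst, reason = "interface",
          chains = paste(chains_hit, collapse = ";"))
        next
      }
      uid <- chains_hit
      pa <- pc[near & pc$chain_uid == uid, ]
      keys <- paste0(pa$residue_number, "|", pa$atom_name)
      if (!is.null(superposition)) {
        tr <- superposition$transforms[[uid]]
        if (!is.null(tr)) {
          xyz <- apply_transform(as.matrix(pa[, c("x", "y", "z")]),
                                 tr$rotation, tr$translation)
          pa$x <- xyz[, 1]; pa$y <- xyz[, 2]; pa$z <- xyz[, 3]
        }
        map <- superposition$residue_maps[[uid]]
        if (!is.null(map)) {
          ref <- map$ref_pos[match(pa$residue_number, map$residue_number)]
          keys <- ifelse(is.na(ref), NA_character_,
                         paste0(ref, "|", pa$atom_name))
        }
      }
      ctr <- colMeans(pa[, c("x", "y", "z")])
      dists <- sqrt(rowSums(sweep(as.matrix(pa[, c("x", "y", "z")]), 2,
                                  ctr)^2))
      pockets[[length(pockets) + 1]] <- tibble::tibble(
        pocket_id = paste0(inst, "__", sub("^.*_", "", uid)),
        complex_id = cid,
        chain_uid = uid,
        cluster_id = if (is.null(cluster_of)) NA_character_ else
          unname(cluster_of[uid]),
        ligand_id = la$ligand_id[1],
        ligand_instance = inst,
        n_atoms = nrow(pa),
        n_residues = length(unique(pa$residue_number)),
        bx = ctr[1], by = ctr[2], bz = ctr[3],
        dmax = max(dists),
        atoms = list(pa),
        atom_keys = list(keys)
      )
    }
  }
  list(
    pockets = if (length(pockets)) dplyr::bind_rows(pockets) else
      tibble::tibble(),
    rejected = if (length(rejected)) dplyr::bind_rows(rejected) else
      tibble::tibble(ligand_instance = character(), reason = character(),
                     chains = character())
  )
}

#' Names of the 72 pocket descriptor slots
#'
#' The named core (counts, hull volume, convexity index, hydrophobicity,
#' side-chain proportion, elemental and residue-class frequencies, the 20
#' per-residue frequencies) is fixed; the remaining slots are a documented
#' reconstruction (shape moments, composition counts, density measures).
#'
#' @return tibble with `descriptor` and `reconstructed`.
#' @export
pocket_descriptor_slots <- function() {
  core <- c("n_atoms", "n_residues", "volume_hull", "pci",
            "hydrophobicity_kd", "side_chain_prop",
            "freq_c", "freq_n", "freq_o", "freq_s", "freq_otyr", "freq_ntrp",
            "freq_aliphatic", "freq_aromatic", "freq_charged", "freq_polar",
            "freq_tiny",
            paste0("freq_res_", STANDARD_AA3))
  recon <- c("area_hull", "enclosing_radius", "radius_max", "diameter",
             "radius_gyration", "asphericity", "sphericity", "atom_density",
             "backbone_prop", "hydrophobicity_kd_min", "hydrophobicity_kd_max",
             "freq_positive", "freq_negative", "freq_small",
             "freq_hydrophobic_res", "n_c", "n_n", "n_o", "n_s",
             "n_side_chain", "n_backbone", "n_hetero_atoms", "freq_hetero",
             "mean_dist_barycenter", "sd_dist_barycenter",
             "volume_per_residue", "atoms_per_residue", "freq_nonstandard_res",
             "n_aromatic_res", "n_aliphatic_res", "n_charged_res",
             "n_polar_res", "n_tiny_res", "elongation", "flatness")
  tibble::tibble(descriptor = c(core, recon),
                 reconstructed = rep(c(FALSE, TRUE),
                                     c(length(core), length(recon))))
}

## descriptor vector for one pocket atom table
pocket_descriptor_row <- function(pa) {
  xyz <- as.matrix(pa[, c("x", "y", "z")])
  n <- nrow(pa)
  ctr <- colMeans(xyz)
  dists <- sqrt(rowSums(sweep(xyz, 2, ctr)^2))

  hull <- convex_hull_3d(xyz)
  vol <- hull$volume; area <- hull$area
  pci <- NA_real_; enc_r <- NA_real_
  if (!hull$degenerate) {
    enc <- enclosing_sphere(xyz)
    enc_r <- enc$radius
    pci <- vol / (4 / 3 * pi * enc_r^3)
  }

  res <- dplyr::distinct(pa, .data$residue_number, .data$residue_name)
  res_std <- res$residue_name[res$residue_name %in% STANDARD_AA3]
  n_res <- nrow(res)
  n_std <- length(res_std)
  kd <- kyte_doolittle()[res_std]

  res_freq <- function(cls) {
    if (n_std == 0) return(NA_real_)
    sum(res_std %in% RESIDUE_CLASSES[[cls]]) / n_std
  }
  res_count <- function(cls) sum(res_std %in% RESIDUE_CLASSES[[cls]])
  per_res <- vapply(STANDARD_AA3, function(a) {
    if (n_std == 0) NA_real_ else sum(res_std == a) / n_std
  }, numeric(1))

  el <- pa$element
  n_c <- sum(el == "C"); n_n <- sum(el == "N")
  n_o <- sum(el == "O"); n_s <- sum(el == "S")
  otyr <- sum(el == "O" & pa$residue_name == "TYR" & pa$side_chain)
  ntrp <- sum(el == "N" & pa$residue_name == "TRP" & pa$side_chain)

  cov <- stats::cov(xyz)
  ev <- sort(pmax(eigen(cov, symmetric = TRUE)$values, 0), decreasing = TRUE)
  rg <- sqrt(sum(ev))
  asph <- if (rg > 0) (ev[1] - (ev[2] + ev[3]) / 2) / sum(ev) else NA_real_

  d2 <- as.matrix(stats::dist(xyz))
  diam <- max(d2)

  out <- c(
    n_atoms = n, n_residues = n_res, volume_hull = vol, pci = pci,
    hydrophobicity_kd = if (n_std > 0) mean(kd) else NA_real_,
    side_chain_prop = mean(pa$side_chain),
    freq_c = n_c / n, freq_n = n_n / n, freq_o = n_o / n, freq_s = n_s / n,
    freq_otyr = otyr / n, freq_ntrp = ntrp / n,
    freq_aliphatic = res_freq("aliphatic"), freq_aromatic = res_freq("aromatic"),
    freq_charged = res_freq("charged"), freq_polar = res_freq("polar"),
    freq_tiny = res_freq("tiny"),
    stats::setNames(per_res, paste0("freq_res_", STANDARD_AA3)),
    area_hull = area, enclosing_radius = enc_r, radius_max = max(dists),
    diameter = diam, radius_gyration = rg, asphericity = asph,
    sphericity = if (!is.na(vol) && !is.na(area) && area > 0)
      pi^(1 / 3) * (6 * vol)^(2 / 3) / area else NA_real_,
    atom_density = if (!is.na(vol) && vol > 0) n / vol else NA_real_,
    backbone_prop = mean(!pa$side_chain),
    hydrophobicity_kd_min = if (n_std > 0) min(kd) else NA_real_,
    hydrophobicity_kd_max = if (n_std > 0) max(kd) else NA_real_,
    freq_positive = res_freq("positive"), freq_negative = res_freq("negative"),
    freq_small = res_freq("small"),
    freq_hydrophobic_res = res_freq("hydrophobic"),
    n_c = n_c, n_n = n_n, n_o = n_o, n_s = n_s,
    n_side_chain = sum(pa$side_chain), n_backbone = sum(!pa$side_chain),
    n_hetero_atoms = n_n + n_o + n_s, freq_hetero = (n_n + n_o + n_s) / n,
    mean_dist_barycenter = mean(dists),
    sd_dist_barycenter = if (n > 1) stats::sd(dists) else 0,
    volume_per_residue = if (!is.na(vol) && n_res > 0) vol / n_res else
      NA_real_,
    atoms_per_residue = n / n_res,
    freq_nonstandard_res = (n_res - n_std) / n_res,
    n_aromatic_res = res_count("aromatic"),
    n_aliphatic_res = res_count("aliphatic"),
    n_charged_res = res_count("charged"), n_polar_res = res_count("polar"),
    n_tiny_res = res_count("tiny"),
    elongation = if (ev[3] > 0) sqrt(ev[1] / ev[3]) else NA_real_,
    flatness = if (ev[3] > 0) sqrt(ev[2] / ev[3]) else NA_real_
  )
  out
}

#' Compute the 72-slot pocket descriptor panel
#'
#' Volume is the convex hull volume of the pocket atoms; the pocket
#' convexity index (PCI) is reconstructed as hull volume over the volume of
#' the smallest enclosing sphere, so values near 1 indicate globular
#' (convex) pockets. Hydrophobicity is the mean Kyte-Doolittle hydropathy
#' over pocket residues; a residue is in the pocket iff at least one of its
#' atoms is. Per-residue frequencies are computed over standard residues
#' only (non-standard residues are counted separately in
#' `freq_nonstandard_res`). Pockets with fewer than 4 non-coplanar atoms get
#' `NA` volume, area and PCI; composition slots are still computed.
#'
#' @param pockets result of [extract_pockets()] or its `pockets` tibble.
#' @return tibble with `pocket_id` and the 72 descriptor columns.
#' @export
pocket_descriptors <- function(pockets) {
  tbl <- if (is.data.frame(pockets)) pockets else pockets$pockets
  if (nrow(tbl) == 0) return(tibble::tibble())
  rows <- lapply(seq_len(nrow(tbl)), function(i) {
    v <- pocket_descriptor_row(tbl$atoms[[i]])
    tibble::as_tibble(as.list(v))
  })
  dplyr::bind_cols(tibble::tibble(pocket_id = tbl$pocket_id),
                   dplyr::bind_rows(rows))
}
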