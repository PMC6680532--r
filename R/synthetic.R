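# Synthetic protein-ligand complex generator with planted ground truth.
#
# Chains are poly-residue backbones laid on an alpha-helical curve (rise
# 1.5 A/residue, radius 2.3 A, 100 degrees/turn) with 0-5 side-chain
# pseudo-atoms per residue placed radially outward; this gives pocket
# extraction realistic atom/residue identities and geometry without
# pretending to be a folded protein. Binding sites are planted on the helix
# axis at controlled separations; drug-like ligands are generated from
# scaffold families with substituent mutation under acceptance-rejection
# against a target within-family Tanimoto band. Hydrogens are never
# generated (all downstream geometry is heavy-atom only).

HELIX_RISE <- 1.5
HELIX_RADIUS <- 2.3
HELIX_TURN <- 100 * pi / 180

SIDE_CHAIN_TEMPLATES <- list(
  ALA = list(c("CB", "C")),
  GLY = list(),
  VAL = list(c("CB", "C"), c("CG1", "C"), c("CG2", "C")),
  LEU = list(c("CB", "C"), c("CG", "C"), c("CD1", "C"), c("CD2", "C")),
  ILE = list(c("CB", "C"), c("CG1", "C"), c("CG2", "C"), c("CD1", "C")),
  MET = list(c("CB", "C"), c("CG", "C"), c("SD", "S"), c("CE", "C")),
  PHE = list(c("CB", "C"), c("CG", "C"), c("CD1", "C"), c("CD2", "C"),
             c("CZ", "C")),
  TRP = list(c("CB", "C"), c("CG", "C"), c("CD1", "C"), c("NE1", "N"),
             c("CE2", "C")),
  TYR = list(c("CB", "C"), c("CG", "C"), c("CZ", "C"), c("OH", "O")),
  SER = list(c("CB", "C"), c("OG", "O")),
  THR = list(c("CB", "C"), c("OG1", "O"), c("CG2", "C")),
  CYS = list(c("CB", "C"), c("SG", "S")),
  ASN = list(c("CB", "C"), c("CG", "C"), c("OD1", "O"), c("ND2", "N")),
  GLN = list(c("CB", "C"), c("CG", "C"), c("CD", "C"), c("OE1", "O"),
             c("NE2", "N")),
  ASP = list(c("CB", "C"), c("CG", "C"), c("OD1", "O"), c("OD2", "O")),
  GLU = list(c("CB", "C"), c("CG", "C"), c("CD", "C"), c("OE1", "O"),
             c("OE2", "O")),
  LYS = list(c("CB", "C"), c("CG", "C"), c("CD", "C"), c("CE", "C"),
             c("NZ", "N")),
  ARG = list(c("CB", "C"), c("CG", "C"), c("CD", "C"), c("NE", "N"),
             c("NH1", "N")),
  HIS = list(c("CB", "C"), c("CG", "C"), c("ND1", "N"), c("CD2", "C"),
             c("NE2", "N")),
  PRO = list(c("CB", "C"), c("CG", "C"), c("CD", "C"))
)

## aromatic cores: conjugated substituent growth keeps the H/C ratio near 1
## so generated ligands pass the soft drug-likeness rules
LIGAND_CORES <- c(
  "c1ccc(cc1)", "c1ccc2cc(ccc2c1)", "c1ccnc(c1)", "c1cc(oc1)",
  "c1ccc(cc1)S(=O)(=O)N", "c1ccc(cc1)C(=O)N", "c1ccc(cc1)c1ccc(cc1)",
  "c1cc(sc1)")

#' Describe a synthetic study scenario
#'
#' A scenario fixes the statistical structure of a synthetic complex set:
#' how many homologous chain families exist and at what within-family
#' sequence identity, how many spatially distinct binding sites each family
#' carries and how far apart, how many ligand chemotype families exist and
#' how self-similar they are, and the promiscuity planted at every site
#' (how many distinct ligand families bind it). The same seed and scenario
#' always regenerate byte-identical files.
#'
#' @param seed integer master seed.
#' @param n_chain_families number of unrelated chain families.
#' @param chains_per_family distinct sequences per family.
#' @param within_family_identity target pairwise identity in \[0.8, 1\].
#' @param sites_per_family planted binding sites per family.
#' @param pockets_per_site complexes observing each site (= pockets per
#'   site after extraction).
#' @param site_separation minimum anchor-to-anchor distance (Angstrom).
#' @param ligand_families number of ligand scaffold families (max 8).
#' @param ligands_per_family members per ligand family.
#' @param within_family_tanimoto minimum pairwise Tanimoto within a ligand
#'   family, in \[0.8, 1\].
#' @param planted_promiscuity integer vector, one entry per site in family
#'   order (recycled): number of distinct ligand families bound at that
#'   site. Default `c(1, 2, 4)` recycled, covering S, MP and HP.
#' @param coordinate_noise_sd isotropic Gaussian coordinate noise (Angstrom).
#' @param chain_length residues per chain; `NULL` = smallest length that
#'   fits the sites (plus margins).
#' @param max_residues hard upper bound on chain length; scenarios whose
#'   sites do not fit fail fast rather than generate partial output.
#' @return validated object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 1,
                               n_chain_families = 5,
                               chains_per_family = 4,
                               within_family_identity = 0.92,
                               sites_per_family = 2,
                               pockets_per_site = 4,
                               site_separation = 25,
                               ligand_families = 6,
                               ligands_per_family = 4,
                               within_family_tanimoto = 0.80,
                               planted_promiscuity = c(1, 2, 4),
                               coordinate_noise_sd = 0.2,
                               chain_length = NULL,
                               max_residues = 400) {
  counts <- c(n_chain_families = n_chain_families,
              chains_per_family = chains_per_family,
              sites_per_family = sites_per_family,
              pockets_per_site = pockets_per_site,
              ligand_families = ligand_families,
              ligands_per_family = ligands_per_family)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (within_family_identity < 0.8 || within_family_identity > 1) {
    stop("within_family_identity must be in [0.8, 1]")
  }
  if (within_family_tanimoto < 0.8 || within_family_tanimoto > 1) {
    stop("within_family_tanimoto must be in [0.8, 1]")
  }
  if (site_separation <= 0) stop("site_separation must be > 0")
  if (coordinate_noise_sd < 0) stop("coordinate_noise_sd must be >= 0")
  if (ligand_families > length(LIGAND_CORES)) {
    stop("at most ", length(LIGAND_CORES), " ligand families supported")
  }
  n_sites <- n_chain_families * sites_per_family
  prom <- rep_len(as.integer(planted_promiscuity), n_sites)
  if (any(prom < 1)) stop("planted promiscuity counts must be >= 1")
  if (max(prom) > ligand_families) {
    stop("planted promiscuity exceeds the number of ligand families")
  }
  if (max(prom) > pockets_per_site) {
    stop("planted promiscuity exceeds pockets_per_site: a site cannot bind ",
         "more families than it has pockets")
  }
  spacing_res <- ceiling(site_separation / HELIX_RISE)
  margin <- 12L
  need <- 2L * margin + (sites_per_family - 1L) * spacing_res + 1L
  if (is.null(chain_length)) chain_length <- max(need, 60L)
  if (chain_length < need) {
    stop("chain_length ", chain_length, " cannot hold ", sites_per_family,
         " sites at ", site_separation, " A separation (needs >= ", need, ")")
  }
  if (chain_length > max_residues) {
    stop("unsatisfiable scenario: required chain length ", chain_length,
         " exceeds max_residues (", max_residues, ")")
  }
  structure(list(
    seed = as.integer(seed), n_chain_families = n_chain_families,
    chains_per_family = chains_per_family,
    within_family_identity = within_family_identity,
    sites_per_family = sites_per_family, pockets_per_site = pockets_per_site,
    site_separation = site_separation, ligand_families = ligand_families,
    ligands_per_family = ligands_per_family,
    within_family_tanimoto = within_family_tanimoto,
    planted_promiscuity = prom, coordinate_noise_sd = coordinate_noise_sd,
    chain_length = as.integer(chain_length), spacing_res = spacing_res,
    margin = margin), class = "synthetic_scenario")
}

## ---- ligand family construction -------------------------------------------

## Build ligand families against the Tanimoto band. Each family mutates one
## scaffold core by varying the alkyl substituent length under a terminal
## group; candidate series are accepted only when every within-family pair
## reaches the band and no cross-family pair exceeds `cross_max` (so the
## planted families are recoverable at the 0.8 clustering threshold).
## Terminal-group order is drawn from the caller's seeded RNG context.
build_ligand_families <- function(scn, cross_max = 0.6) {
  terminals <- c("Cl", "N", "O", "")
  lens <- 1:6
  n <- scn$ligands_per_family
  if (n > length(lens)) {
    stop("at most ", length(lens), " ligands per family supported")
  }
  fams <- list()
  for (f in seq_len(scn$ligand_families)) {
    core <- LIGAND_CORES[f]
    other_fp <- do.call(rbind, lapply(fams, function(x) x$fp))
    chosen <- NULL
    for (term in sample(terminals)) {
      smis <- paste0(core,
                     vapply(lens, function(k) strrep("C=C", k), ""), term)
      tbl <- tibble::tibble(ligand_id = paste0("x", seq_along(smis)),
                            smiles = smis)
      fp <- tryCatch(fingerprint_ligands(tbl), error = function(e) NULL)
      if (is.null(fp) || any(rowSums(fp) == 0)) next
      dl <- tryCatch(druglike_filter(ligand_descriptors(tbl))$drug_like,
                     error = function(e) rep(FALSE, length(smis)))
      keep <- which(dl %in% TRUE)
      if (length(keep) < n) next
      smis <- smis[keep]; fp <- fp[keep, , drop = FALSE]
      sim <- tanimoto_matrix(fp)
      for (start in seq_len(nrow(fp) - n + 1)) {
        idx <- start:(start + n - 1)
        if (min(sim[idx, idx]) < scn$within_family_tanimoto) next
        if (!is.null(other_fp)) {
          cross <- tcrossprod(fp[idx, , drop = FALSE] * 1, other_fp * 1)
          uni <- outer(rowSums(fp[idx, , drop = FALSE]),
                       rowSums(other_fp), "+") - cross
          if (max(cross / uni) > cross_max) next
        }
        chosen <- list(smiles = smis[idx], fp = fp[idx, , drop = FALSE])
        break
      }
      if (!is.null(chosen)) break
    }
    if (is.null(chosen)) {
      stop("could not satisfy the Tanimoto band for ligand family ", f)
    }
    ids <- sprintf("%s%02d", LETTERS[f], seq_len(n))
    rownames(chosen$fp) <- ids
    fams[[f]] <- list(family = f, ligand_id = ids, smiles = chosen$smiles,
                      fp = chosen$fp)
  }
  fams
}

## ---- chain construction ----------------------------------------------------

## family reference sequence plus per-chain variants with disjoint
## substitution blocks sized to hit the pairwise identity target
build_family_sequences <- function(scn) {
  L <- scn$chain_length
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  k <- floor((1 - scn$within_family_identity) / 2 * L)
  ref <- sample(aa, L, replace = TRUE)
  pos_pool <- sample(seq_len(L))
  if (scn$chains_per_family * k > L) {
    stop("identity target infeasible for ", scn$chains_per_family, " chains")
  }
  lapply(seq_len(scn$chains_per_family), function(ci) {
    s <- ref
    if (k > 0 && ci > 1) {    # chain 1 is the unmutated reference
      posns <- pos_pool[((ci - 1) * k - k + 1):((ci - 1) * k)]
      for (p in posns) s[p] <- sample(setdiff(aa, s[p]), 1)
    }
    paste(s, collapse = "")
  })
}

aa_one_to_three <- function(a) {
  map <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
           H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
           P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
           W = "TRP", Y = "TYR")
  unname(map[a])
}

## heavy-atom tibble for one chain laid on the helix (no noise)
build_chain_atoms <- function(sequence, complex_id, chain_id = "A") {
  res1 <- strsplit(sequence, "")[[1]]
  res3 <- aa_one_to_three(res1)
  L <- length(res1)
  rows <- vector("list", L)
  for (i in seq_len(L)) {
    th <- i * HELIX_TURN
    z <- i * HELIX_RISE
    u <- c(cos(th), sin(th), 0)              # radial unit vector
    ca <- c(HELIX_RADIUS * u[1:2], z)
    tang <- c(-sin(th), cos(th), 0)
    backbone <- rbind(
      N = ca - 0.8 * tang + c(0, 0, -0.6),
      CA = ca,
      C = ca + 0.8 * tang + c(0, 0, 0.6),
      O = ca + 0.9 * tang + 1.2 * u + c(0, 0, 0.8))
    sc <- SIDE_CHAIN_TEMPLATES[[res3[i]]]
    sc_xyz <- NULL
    if (length(sc) > 0) {
      sc_xyz <- t(vapply(seq_along(sc), function(j) {
        ## radially outward ladder with a small deterministic twist
        tw <- 0.35 * j * c(-sin(th + j), cos(th + j), 0)
        ca + (1.2 + 1.1 * j) * u + tw + c(0, 0, 0.3 * ((j %% 2) * 2 - 1))
      }, numeric(3)))
    }
    names_all <- c(rownames(backbone),
                   vapply(sc, `[`, character(1), 1))
    elem_all <- c("N", "C", "C", "O", vapply(sc, `[`, character(1), 2))
    xyz <- rbind(backbone, sc_xyz)
    rows[[i]] <- tibble::tibble(
      complex_id = complex_id, record = "ATOM", chain_id = chain_id,
      chain_uid = paste0(complex_id, "_", chain_id),
      residue_number = i, residue_name = res3[i], atom_name = names_all,
      element = elem_all, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      side_chain = !(names_all %in% BACKBONE_ATOMS),
      ligand_id = NA_character_, ligand_instance = NA_character_)
  }
  dplyr::bind_rows(rows)
}

## deterministic near-spherical cloud for ligand heavy atoms (Fibonacci
## spiral), centred on the site anchor
ligand_atom_cloud <- function(n, center, radius = 1.3) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(center[1] + radius * sin(phi) * cos(theta),
        center[2] + radius * sin(phi) * sin(theta),
        center[3] + radius * cos(phi))
}

## HETATM tibble for one ligand instance placed at a site anchor
build_ligand_atoms <- function(smiles, ligand_id, complex_id, chain_id,
                               resno, anchor) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  ab <- ChemmineR::atomblock(sdf[[1]])
  elements <- gsub("_.*$", "", rownames(ab))
  n <- length(elements)
  xyz <- ligand_atom_cloud(n, anchor)
  inst <- paste0(complex_id, "_", chain_id, "_", ligand_id, "_", resno)
  tibble::tibble(
    complex_id = complex_id, record = "HETATM", chain_id = chain_id,
    chain_uid = paste0(complex_id, "_", chain_id),
    residue_number = resno, residue_name = ligand_id,
    atom_name = paste0(elements, seq_len(n)), element = elements,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], side_chain = FALSE,
    ligand_id = ligand_id, ligand_instance = inst)
}

#' Add isotropic Gaussian noise to atom coordinates
#'
#' @param atoms atom table (needs `x`, `y`, `z`).
#' @param sd noise standard deviation per axis (Angstrom); `sd = 0` returns
#'   the input unchanged.
#' @param seed integer seed (reproducible displacement field).
#' @return the atom table with perturbed coordinates.
#' @export
perturb_coordinates <- function(atoms, sd, seed = 1) {
  if (sd < 0) stop("sd must be >= 0")
  if (sd == 0) return(atoms)
  n <- nrow(atoms)
  noise <- with_seed(seed, matrix(stats::rnorm(3 * n, 0, sd), ncol = 3))
  atoms$x <- atoms$x + noise[, 1]
  atoms$y <- atoms$y + noise[, 2]
  atoms$z <- atoms$z + noise[, 3]
  atoms
}

## write one complex as PDB via bio3d
write_complex_pdb <- function(atoms, path) {
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
    type = atoms$record,
    resno = atoms$residue_number,
    resid = atoms$residue_name,
    eleno = seq_len(nrow(atoms)),
    elety = atoms$atom_name,
    chain = atoms$chain_id,
    elesy = atoms$element)
}

#' Generate a synthetic complex set with ground truth
#'
#' Writes one PDB file per complex (protein ATOM records plus ligand HETATM
#' records), a ligand table (`ligands.csv`: id, SMILES) and four
#' ground-truth CSVs (chain-to-family, ligand-to-family, pocket-to-site,
#' site-to-promiscuity). Unsatisfiable scenarios fail before any file is
#' written. Deterministic: identical scenario and seed give byte-identical
#' files.
#'
#' @param scenario a [synthetic_scenario()].
#' @param out_dir output directory (created; complexes under
#'   `complexes/`).
#' @return invisibly, the ground truth: list of tibbles `chains`,
#'   `ligands`, `pockets`, `sites`, plus `ligand_table` and `paths`.
#' @export
generate_scenario <- function(scenario, out_dir) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  scn <- scenario
  gt <- with_seed(scn$seed, {
    fams_lig <- build_ligand_families(scn)
    lig_table <- dplyr::bind_rows(lapply(fams_lig, function(x) {
      tibble::tibble(ligand_id = x$ligand_id, smiles = x$smiles,
                     family = x$family)
    }))

    sites <- list(); pockets <- list(); chains <- list()
    complexes <- list()
    site_idx <- 0
    fam_offset <- 0
    for (fam in seq_len(scn$n_chain_families)) {
      seqs <- build_family_sequences(scn)
      fam_id <- sprintf("F%02d", fam)
      ## per-site planted promiscuity and bound families
      site_ids <- sprintf("%s_S%d", fam_id, seq_len(scn$sites_per_family))
      site_rows <- list()
      site_fams <- list()
      for (s in seq_len(scn$sites_per_family)) {
        site_idx <- site_idx + 1
        m <- scn$planted_promiscuity[site_idx]
        bound <- ((fam_offset + seq_len(m) - 1) %% scn$ligand_families) + 1
        fam_offset <- fam_offset + m
        site_fams[[s]] <- bound
        site_rows[[s]] <- tibble::tibble(
          site_id = site_ids[s], family = fam_id,
          n_ligand_families = m,
          label = if (m == 1) "S" else if (m <= 3) "MP" else "HP")
      }
      sites[[fam]] <- dplyr::bind_rows(site_rows)

      anchors <- lapply(seq_len(scn$sites_per_family), function(s) {
        c(0, 0, (scn$margin + (s - 1) * scn$spacing_res) * HELIX_RISE)
      })

      for (j in seq_len(scn$pockets_per_site)) {
        ci <- ((j - 1) %% scn$chains_per_family) + 1
        complex_id <- sprintf("%sC%02d", fam_id, j)
        at <- build_chain_atoms(seqs[[ci]], complex_id)
        chains[[paste0(complex_id, "_A")]] <- tibble::tibble(
          chain_uid = paste0(complex_id, "_A"), family = fam_id,
          sequence_variant = ci)
        for (s in seq_len(scn$sites_per_family)) {
          bound <- site_fams[[s]]
          lf <- bound[((j - 1) %% length(bound)) + 1]
          mem <- ((j - 1) %% scn$ligands_per_family) + 1
          lid <- fams_lig[[lf]]$ligand_id[mem]
          smi <- fams_lig[[lf]]$smiles[mem]
          resno <- 1000 + s
          la <- build_ligand_atoms(smi, lid, complex_id, "A", resno,
                                   anchors[[s]])
          at <- dplyr::bind_rows(at, la)
          pockets[[paste0(complex_id, "_", s)]] <- tibble::tibble(
            ligand_instance = la$ligand_instance[1],
            complex_id = complex_id, chain_uid = paste0(complex_id, "_A"),
            ligand_id = lid, site_id = site_ids[s])
        }
        at <- perturb_coordinates(at, scn$coordinate_noise_sd,
                                  seed = scn$seed * 10000 + fam * 100 + j)
        complexes[[complex_id]] <- at
      }
    }
    list(chains = dplyr::bind_rows(chains),
         ligands = lig_table[, c("ligand_id", "family")],
         pockets = dplyr::bind_rows(pockets),
         sites = dplyr::bind_rows(sites),
         ligand_table = lig_table[, c("ligand_id", "smiles")],
         complexes = complexes)
  })

  dir.create(file.path(out_dir, "complexes"), recursive = TRUE,
             showWarnings = FALSE)
  for (cid in names(gt$complexes)) {
    write_complex_pdb(gt$complexes[[cid]],
                      file.path(out_dir, "complexes", paste0(cid, ".pdb")))
  }
  utils::write.csv(gt$ligand_table, file.path(out_dir, "ligands.csv"),
                   row.names = FALSE)
  for (nm in c("chains", "ligands", "pockets", "sites")) {
    utils::write.csv(gt[[nm]],
                     file.path(out_dir, paste0("ground_truth_", nm, ".csv")),
                     row.names = FALSE)
  }
  gt$paths <- list(
    complexes = file.path(out_dir, "complexes"),
    ligand_table = file.path(out_dir, "ligands.csv"))
  invisible(gt)
}
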