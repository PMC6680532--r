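# The 21-slot ligand descriptor panel. Twelve slots follow the standard
# drug-likeness vocabulary (ring count, rigid/rotatable bonds, MW, logP,
# logD, H/C ratio, HBD, HBA, tPSA, carbon frequency, heavy-atom count); the
# remaining nine are a documented reconstruction of a FAF-Drugs-style panel
# (composition counts, ring systems, stereocentres, largest-fragment MW) and
# are flagged as such in `ligand_descriptor_slots()`.

#' Names of the 21 ligand descriptor slots
#'
#' @return tibble with `descriptor` and `reconstructed` (TRUE for the nine
#'   slots not fixed by the standard panel).
#' @export
ligand_descriptor_slots <- function() {
  tibble::tibble(
    descriptor = c("rings", "rigid_bonds", "rotatable_bonds", "mw", "logp",
                   "logd", "ratio_hc", "hbd", "hba", "tpsa", "carbon_freq",
                   "heavy_atoms",
                   "formal_charge", "halogen_count", "oxygen_count",
                   "nitrogen_count", "sulfur_count", "ring_systems",
                   "max_ring_size", "stereocenters", "mw_largest_fragment"),
    reconstructed = rep(c(FALSE, TRUE), c(12L, 9L))
  )
}

## heavy-atom bond graph of one molecule; returns igraph with bond order attr
mol_graph <- function(sdf) {
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ChemmineR::atomblock(sdf))
  if (is.null(bb) || nrow(bb) == 0) {
    return(igraph::make_empty_graph(n, directed = FALSE))
  }
  g <- igraph::graph_from_edgelist(cbind(bb[, 1], bb[, 2]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::E(g)$order <- bb[, 3]
  g
}

## formal charge parsed from a (canonical) SMILES string
smiles_formal_charge <- function(smi) {
  brackets <- regmatches(smi, gregexpr("\\[[^][]*\\]", smi))[[1]]
  if (length(brackets) == 0) return(0L)
  chg <- vapply(brackets, function(b) {
    m <- regmatches(b, regexec("([+-])([0-9]*)\\]$", b))[[1]]
    if (length(m) == 0) return(0L)
    mult <- if (m[3] == "") 1L else as.integer(m[3])
    if (m[2] == "+") mult else -mult
  }, integer(1))
  sum(chg)
}

## number of stereocentres marked in a SMILES string (@ / @@ once each)
smiles_stereocenters <- function(smi) {
  length(regmatches(smi, gregexpr("@+", smi))[[1]])
}

#' Compute the 21-slot ligand descriptor panel
#'
#' Graph-derived slots (rings, rotatable/rigid bonds, ring systems, maximum
#' ring size) are computed on the heavy-atom bond graph: `rings` is the
#' cyclomatic number (equals the SSSR count), a rotatable bond is a non-ring
#' single bond between two non-terminal heavy atoms, and `rigid_bonds` is the
#' complement. Physicochemical slots (MW, logP, tPSA, HBD, HBA) come from
#' OpenBabel; `logd` is approximated by logP (no pKa model) and is therefore
#' labelled approximate. `ratio_hc` counts implicit plus explicit hydrogens
#' over carbons and is `NA` (flagged, never a silent zero) for carbon-free
#' molecules.
#'
#' @param ligands data frame with `ligand_id` and `smiles`, or an `SDFset`.
#' @return tibble with `ligand_id`, the 21 descriptor columns, and
#'   `descriptor_missing` listing any incomputable slots.
#' @export
ligand_descriptors <- function(ligands) {
  sdf <- if (methods::is(ligands, "SDFset")) ligands else parse_smiles(ligands)
  ids <- ChemmineR::cid(sdf)
  props <- suppressWarnings(ChemmineR::propOB(sdf))
  counts <- suppressWarnings(ChemmineR::atomcountMA(sdf, addH = TRUE))
  counts <- as.matrix(counts)
  elem_count <- function(el) {
    if (el %in% colnames(counts)) counts[, el] else rep(0, length(ids))
  }

  rows <- lapply(seq_along(ids), function(i) {
    mol <- sdf[[i]]
    g <- mol_graph(mol)
    n_heavy <- igraph::vcount(g)
    n_bonds <- igraph::ecount(g)
    n_comp <- igraph::components(g)$no
    rings <- n_bonds - n_heavy + n_comp

    bridges <- igraph::bridges(g)
    ring_edge <- setdiff(seq_len(n_bonds), as.integer(bridges))
    deg <- igraph::degree(g)
    rot <- 0L
    if (n_bonds > 0) {
      ends <- igraph::ends(g, igraph::E(g))
      single <- igraph::E(g)$order == 1
      nonring <- seq_len(n_bonds) %in% as.integer(bridges)
      nonterminal <- deg[ends[, 1]] >= 2 & deg[ends[, 2]] >= 2
      rot <- sum(single & nonring & nonterminal)
    }

    ring_systems <- 0L
    max_ring <- NA_real_
    if (length(ring_edge) > 0) {
      gr <- igraph::subgraph_from_edges(g, ring_edge, delete.vertices = TRUE)
      ring_systems <- igraph::components(gr)$no
      ## size of the largest smallest-ring: for each ring edge, the shortest
      ## cycle through it is 1 + shortest path between its ends without it
      cyc <- vapply(ring_edge, function(e) {
        ends_e <- igraph::ends(g, e)
        g2 <- igraph::delete_edges(g, e)
        d <- igraph::distances(g2, v = ends_e[1], to = ends_e[2])[1, 1]
        d + 1
      }, numeric(1))
      max_ring <- max(cyc[is.finite(cyc)])
    }

    n_c <- unname(elem_count("C")[i])
    n_h <- unname(elem_count("H")[i])
    smi <- props$cansmiNS[i]
    frags <- strsplit(props$cansmi[i], ".", fixed = TRUE)[[1]]
    mw_frag <- props$MW[i]
    if (length(frags) > 1) {
      fsdf <- suppressWarnings(ChemmineR::smiles2sdf(frags))
      mw_frag <- max(suppressWarnings(ChemmineR::propOB(fsdf))$MW)
    }

    tibble::tibble(
      ligand_id = ids[i],
      rings = rings,
      rigid_bonds = n_bonds - rot,
      rotatable_bonds = rot,
      mw = props$MW[i],
      logp = props$logP[i],
      logd = props$logP[i],
      ratio_hc = if (n_c > 0) n_h / n_c else NA_real_,
      hbd = props$HBD[i],
      hba = props$HBA1[i],
      tpsa = props$TPSA[i],
      carbon_freq = if (n_heavy > 0) n_c / n_heavy else NA_real_,
      heavy_atoms = n_heavy,
      formal_charge = smiles_formal_charge(smi),
      halogen_count = sum(vapply(c("F", "Cl", "Br", "I"),
                                 function(el) elem_count(el)[i], numeric(1))),
      oxygen_count = unname(elem_count("O")[i]),
      nitrogen_count = unname(elem_count("N")[i]),
      sulfur_count = unname(elem_count("S")[i]),
      ring_systems = ring_systems,
      max_ring_size = max_ring,
      stereocenters = smiles_stereocenters(smi),
      mw_largest_fragment = mw_frag
    )
  })
  out <- dplyr::bind_rows(rows)
  ## max_ring_size is structurally 0-like for acyclic molecules: report 0
  out$max_ring_size[is.na(out$max_ring_size) & out$rings == 0] <- 0
  slot_names <- ligand_descriptor_slots()$descriptor
  out$descriptor_missing <- vapply(seq_len(nrow(out)), function(i) {
    miss <- slot_names[vapply(slot_names, function(s) is.na(out[[s]][i]),
                              logical(1))]
    paste(miss, collapse = ";")
  }, character(1))
  out
}
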