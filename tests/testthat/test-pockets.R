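# Pocket extraction against the brute-force scan, interface filtering,
# descriptor panel.

## minimal atom-table builder for hand-placed geometries
make_atoms <- function(prot_xyz, lig_xyz, chain_ids = NULL,
                       complex_id = "CPX", residue_name = "ALA",
                       elements = NULL) {
  np <- nrow(prot_xyz)
  if (is.null(chain_ids)) chain_ids <- rep("A", np)
  if (is.null(elements)) elements <- rep("C", np)
  prot <- tibble::tibble(
    complex_id = complex_id, record = "ATOM", chain_id = chain_ids,
    chain_uid = paste0(complex_id, "_", chain_ids),
    residue_number = seq_len(np), residue_name = residue_name,
    atom_name = "CA", element = elements,
    x = prot_xyz[, 1], y = prot_xyz[, 2], z = prot_xyz[, 3],
    side_chain = FALSE, ligand_id = NA_character_,
    ligand_instance = NA_character_)
  nl <- nrow(lig_xyz)
  lig <- tibble::tibble(
    complex_id = complex_id, record = "HETATM", chain_id = "A",
    chain_uid = paste0(complex_id, "_A"),
    residue_number = 999L, residue_name = "LIG", atom_name = "C1",
    element = "C", x = lig_xyz[, 1], y = lig_xyz[, 2], z = lig_xyz[, 3],
    side_chain = FALSE, ligand_id = "LIG",
    ligand_instance = paste0(complex_id, "_A_LIG_999"))
  dplyr::bind_rows(prot, lig)
}

test_that("the 5.5 A boundary is inclusive", {
  prot <- rbind(c(5.4, 0, 0), c(5.5, 0, 0), c(5.6, 0, 0))
  atoms <- make_atoms(prot, rbind(c(0, 0, 0)))
  pk <- extract_pockets(atoms, threshold = 5.5)
  expect_equal(nrow(pk$pockets), 1)
  got <- pk$pockets$atoms[[1]]
  expect_equal(got$x, c(5.4, 5.5))   # 5.6 excluded, 5.5 included
})

test_that("far ligands are rejected-empty, not dropped silently", {
  atoms <- make_atoms(rbind(c(0, 0, 0), c(1, 0, 0)), rbind(c(30, 0, 0)))
  pk <- extract_pockets(atoms)
  expect_equal(nrow(pk$pockets), 0)
  expect_equal(pk$rejected$reason, "empty")
})

test_that("interface ligands are omitted with the chains logged", {
  ## ligand equidistant between chains A and B, both within 5.5
  prot <- rbind(c(-3, 0, 0), c(3, 0, 0))
  atoms <- make_atoms(prot, rbind(c(0, 0, 0)), chain_ids = c("A", "B"))
  pk <- extract_pockets(atoms)
  expect_equal(nrow(pk$pockets), 0)
  expect_equal(pk$rejected$reason, "interface")
  expect_match(pk$rejected$chains, "CPX_A")
  expect_match(pk$rejected$chains, "CPX_B")

  ## chain B out of range: pocket kept on chain A only
  prot2 <- rbind(c(-3, 0, 0), c(20, 0, 0))
  pk2 <- extract_pockets(make_atoms(prot2, rbind(c(0, 0, 0)),
                                    chain_ids = c("A", "B")))
  expect_equal(nrow(pk2$pockets), 1)
  expect_equal(pk2$pockets$chain_uid, "CPX_A")
})

test_that("extraction equals the brute-force all-pairs scan", {
  set.seed(33)
  for (rep in 1:25) {
    np <- sample(40:120, 1); nl <- sample(5:20, 1)
    prot <- matrix(rnorm(3 * np, sd = 7), ncol = 3)
    lig <- matrix(rnorm(3 * nl, sd = 2), ncol = 3)
    t <- runif(1, 3, 8)
    want <- oracle_pocket_scan(prot, lig, t)
    pk <- extract_pockets(make_atoms(prot, lig), threshold = t)
    if (length(want) == 0) {
      expect_equal(nrow(pk$pockets), 0)
    } else {
      got <- pk$pockets$atoms[[1]]$residue_number
      expect_equal(sort(got), sort(want))
    }
  }
})

test_that("pocket atom sets are monotone in the threshold", {
  set.seed(8)
  prot <- matrix(rnorm(300, sd = 6), ncol = 3)
  lig <- matrix(rnorm(15, sd = 1), ncol = 3)
  prev <- integer(0)
  for (t in c(3, 4.5, 5.5, 7)) {
    pk <- extract_pockets(make_atoms(prot, lig), threshold = t)
    cur <- if (nrow(pk$pockets)) pk$pockets$atoms[[1]]$residue_number
      else integer(0)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("barycenter and dmax are recomputable from the pocket atoms", {
  set.seed(5)
  prot <- matrix(rnorm(150, sd = 3), ncol = 3)
  lig <- matrix(rnorm(9, sd = 1), ncol = 3)
  pk <- extract_pockets(make_atoms(prot, lig))$pockets
  a <- pk$atoms[[1]]
  ctr <- colMeans(as.matrix(a[, c("x", "y", "z")]))
  expect_equal(unname(c(pk$bx, pk$by, pk$bz)), unname(ctr))
  d <- sqrt(rowSums(sweep(as.matrix(a[, c("x", "y", "z")]), 2, ctr)^2))
  expect_equal(pk$dmax, max(d))
  expect_equal(pk$n_atoms, nrow(a))
})

test_that("descriptor panel has 72 slots with exact composition values", {
  slots <- pocket_descriptor_slots()
  expect_equal(nrow(slots), 72)

  ## 10 atoms, 2 sulfur, all-Ala residues, cube geometry
  xyz <- rbind(as.matrix(expand.grid(0:1, 0:1, 0:1)),
               c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.4))
  pa <- tibble::tibble(
    complex_id = "c", record = "ATOM", chain_id = "A", chain_uid = "c_A",
    residue_number = rep(1:5, each = 2), residue_name = "ALA",
    atom_name = rep(c("CA", "CB"), 5), element = rep(c("C", "S"), c(8, 2)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    side_chain = rep(c(FALSE, TRUE), 5),
    ligand_id = NA_character_, ligand_instance = NA_character_)
  d <- pocket_descriptors(tibble::tibble(pocket_id = "p1", atoms = list(pa)))
  expect_equal(d$freq_s, 0.2)
  expect_equal(d$freq_aliphatic, 1.0)        # ALA is aliphatic
  expect_equal(d$freq_res_ALA, 1.0)
  expect_equal(d$volume_hull, 1.0)           # unit cube
  expect_equal(d$n_atoms, 10)
  expect_equal(d$n_residues, 5)
  expect_true(all(slots$descriptor %in% names(d)))

  ## per-residue frequencies sum to one over standard residues
  res_cols <- grep("^freq_res_", names(d), value = TRUE)
  expect_equal(sum(unlist(d[, res_cols])), 1)
  freq_cols <- grep("^freq_", names(d), value = TRUE)
  expect_true(all(unlist(d[, freq_cols]) >= 0 & unlist(d[, freq_cols]) <= 1))
})

test_that("flat pockets get NA volume but full composition", {
  pa <- tibble::tibble(
    complex_id = "c", record = "ATOM", chain_id = "A", chain_uid = "c_A",
    residue_number = 1:4, residue_name = c("TYR", "TRP", "GLY", "SER"),
    atom_name = c("OH", "NE1", "CA", "CA"),
    element = c("O", "N", "C", "C"),
    x = c(0, 1, 2, 3), y = c(0, 1, 0, 1), z = 0,
    side_chain = c(TRUE, TRUE, FALSE, FALSE),
    ligand_id = NA_character_, ligand_instance = NA_character_)
  d <- pocket_descriptors(tibble::tibble(pocket_id = "p", atoms = list(pa)))
  expect_true(is.na(d$volume_hull))
  expect_true(is.na(d$pci))
  expect_equal(d$freq_otyr, 0.25)
  expect_equal(d$freq_ntrp, 0.25)
  expect_equal(d$side_chain_prop, 0.5)
})
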