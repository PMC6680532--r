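---
title: "Quantifying binding-site promiscuity from protein-ligand complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying binding-site promiscuity from protein-ligand complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promisite)
```

## The question and the model

A druggable binding site (DBS) is promiscuous when it binds chemically
distinct ligand types, and selective when every ligand it has ever been
observed with belongs to one chemotype. promisite quantifies this from a
collection of protein-ligand complex structures by exploiting redundancy:
the same site, crystallized many times on homologous chains with different
ligands, leaves a cluster of overlapping ligand-proximity pockets. The
pipeline is:

1. **Ligand space.** Ligands are filtered for validity (no salts, metals,
   solvents, crystallographic additives; peptides only below 11 residues,
   oligonucleotides below 4) and for soft drug-likeness (ring count at most
   6, rotatable bonds at most 11, H/C ratio within 0.1-1.11, boundaries
   inclusive; Lipinski bounds available but off by default). Drug-like
   ligands are fingerprinted with MACCS keys (OpenBabel backend) and
   clustered by Butina leader clustering at Tanimoto 0.8 into
   *Ligand-Clusters* — each cluster is one ligand "type". The member closest
   to the cluster mean under an inverse-variance-weighted Euclidean distance
   over the 21-slot descriptor panel serves as its representative.
2. **Chain space.** Protein mono-chains are clustered by sequence identity
   in two greedy passes (families above 90%, merged above 80% on family
   representatives — the CD-HIT convention, identity over the shorter
   sequence), then each cluster is superposed onto its longest member by
   least-squares (Kabsch) over sequence-aligned CA atoms.
3. **Pockets.** A pocket is every chain heavy atom within 5.5 Å of any heavy
   atom of one bound ligand (boundary inclusive). Ligands touching more than
   one chain are interface ligands and are omitted; ligands touching none
   are rejected. Each pocket carries its barycenter $g(i)$ (unweighted mean
   of its atom coordinates, expressed in the chain-cluster reference frame)
   and radius $d_{max}(i)$, the largest barycenter-to-atom distance.
4. **DBS identification.** Within one chain cluster with $p$ pockets the
   clustering cutoff is
   $$C = D - k\sigma,$$
   where $D$ and $\sigma$ are the mean and standard deviation of the $p$
   observed $d_{max}$ values and $k = 2$ by default. Two pockets join the
   same Pocket-Cluster when their barycenter distance is strictly below
   $C$; the clusters are the connected components of that graph, so
   transitivity holds by construction for any $k$, and pairs joined only
   through intermediates are counted and reported. One Pocket-Cluster is
   one DBS. The *score of overlap* between two pockets,
   $$SO = \frac{n_{common}}{n_1 + n_2 - n_{common}},$$
   validates each cluster (within-cluster SO must be positive; a pocket
   against itself scores exactly 1). Across homologous chains two atoms are
   "common" when they share the aligned reference residue position and the
   atom name.
5. **Promiscuity.** The label of a DBS is the number $L$ of distinct
   Ligand-Clusters bound by its pockets: selective (S, $L = 1$), moderately
   promiscuous (MP, $L \in \{2,3\}$), highly promiscuous (HP, $L \ge 4$).
   A DBS observed through a single pocket cannot be characterized and is
   reported as UNDETERMINED, separately from S. Promiscuity statistics are
   computed on DBS observed at least `min_pockets = 4` times (the "DBS4"
   convention), so a "selective" call is not an artefact of sparse
   observation.
6. **Statistics.** Descriptor panels (72 slots per pocket, 21 per ligand)
   are compared across S/MP/HP with one-way ANOVA and pairwise t-tests
   under a Bonferroni correction whose denominator is the number of
   descriptors in the family; categorical descriptors use a chi-squared
   test. S-vs-HP discrimination uses a CART (rpart, Gini, cost-complexity
   pruning at the minimum internal CV error) trained on class-balanced data
   (group-level undersampling) and evaluated by five-fold cross-validation
   in which all pockets of one DBS stay on one side of the train/test
   split — pockets of one site resemble each other, and row-level splits
   would leak that similarity. Sensitivity and specificity are
   TP/(TP+FN) and TN/(TN+FP); we report standard accuracy (TP+TN)/total
   and, alongside it, `precision_eq5` = TP/(TP+FP), because published
   "accuracy" figures in this protocol family sometimes use the latter
   form. Both are always labelled.
7. **Network.** DBS and Ligand-Clusters form a bipartite graph with an
   (unweighted) edge wherever at least one pocket-ligand contact exists. A
   ligand node of degree 1 is selective, of degree at least 2 promiscuous.
   Summary tables give the class distribution of DBS and pockets, the
   dedication of Ligand-Clusters to one promiscuity level versus mixed, and
   per-level ligand promiscuity, where the "All DBS" row deliberately uses
   distinct counts rather than the column sum (a cluster can touch several
   levels). Two-step ego expansion (seed DBS, their ligands, all DBS of
   those ligands) extracts protein-class-centred subnetworks.

## Worked example on synthetic data

```{r example, eval = FALSE}
scn <- synthetic_scenario(seed = 1, n_chain_families = 5,
                          sites_per_family = 2,
                          planted_promiscuity = c(1, 2, 4))
dir <- tempfile()
gt <- generate_scenario(scn, dir)
run <- run_pipeline(file.path(dir, "complexes"),
                    file.path(dir, "ligands.csv"),
                    pipeline_config())
run
glance(run)
tabulate_network(run$network)
autoplot(run$network)
```

## What the synthetic generator emulates — and what it does not

The generator plants the *statistical* structure the pipeline consumes,
not physically realistic proteins:

- **Chains** are poly-residue backbones on an α-helical curve (rise 1.5
  Å/residue, radius 2.3 Å, 100°/turn) with one N/CA/C/O backbone set and
  0-5 side-chain pseudo-atoms per residue, placed radially outward with
  residue-appropriate atom names and elements (Tyr carries its OH oxygen,
  Trp its NE1 nitrogen, Cys/Met their sulfurs), so every pocket descriptor
  has the inputs it needs. Within-family sequence identity is tuned by
  substituting disjoint position blocks of size
  $\lfloor (1-t)/2 \cdot L \rfloor$ per chain, which provably bounds every
  pairwise identity at or above the target $t$; between-family
  sequences are independent draws (identity far below any threshold).
- **Sites** are anchors on the helix axis spaced to at least the requested
  separation (default 25 Å); each complex carries one ligand per site, and
  `pockets_per_site` complexes per family observe every site.
- **Ligands** are families built from one aromatic scaffold core each,
  mutated in the substituent under acceptance-rejection against the
  within-family Tanimoto band and a cross-family ceiling of 0.6, and
  additionally required to pass the drug-likeness rules. Substituents grow
  as conjugated chains because the soft drug-likeness band on the H/C ratio
  (0.1-1.11) excludes saturated alkyl growth — a real constraint of the
  filter, not a quirk of the generator. The default band is 0.80, matching
  the clustering threshold semantics: MACCS keys on small scaffolds react
  strongly to heteroatom changes, and 0.80 is the level at which a family
  is still guaranteed to form one Butina cluster. Some accepted series are
  indistinguishable under MACCS (pairwise Tanimoto 1); that mirrors real
  key-set saturation on close homologues.
- **Noise** is isotropic Gaussian on every atom coordinate (default
  sd = 0.2 Å, the order of coordinate uncertainty in good crystal
  structures).
- **Promiscuity** is planted per site as the number of distinct ligand
  families bound (default pattern 1, 2, 4 recycled — one site per label
  class S/MP/HP).

Passing the end-to-end tests on these fixtures shows the machinery is
correct and deterministic; it does not show robustness to conformational
change, gapped alignments with large insertions, alternate locations,
partial occupancy, or cryptic sites — real-data phenomena the generator
deliberately does not model.

## Numerical choices and degenerate inputs

- $\sigma$ in the cutoff uses the population divisor $p$ (configurable to
  $p-1$); with one pocket $\sigma = 0$ and $C = d_{max}$. When the radii
  are so dispersed that $C \le 0$, every pocket becomes a singleton
  cluster, with a warning.
- The barycenter-distance condition is strict (`< C`), and the 5.5 Å
  contact threshold is inclusive (`<= 5.5`), matching the printed
  inequality and the printed contact convention respectively.
- Pocket volume is the convex hull volume of the pocket atoms (incremental
  hull, verified against closed forms); the pocket convexity index is
  reconstructed as hull volume over the volume of the smallest enclosing
  sphere (Welzl's algorithm), so PCI near 1 means globular. The original
  index is defined in software we do not reimplement; our reconstruction
  is monotone in compactness but its published orientation ("smaller =
  more convex") is not asserted in tests. Pockets with fewer than four
  non-coplanar atoms get `NA` volume/PCI; composition descriptors are
  still computed.
- Sequence identity uses unit match scoring with affine gaps (open 10,
  extend 0.5); the denominator defaults to the shorter sequence (the
  convention of the greedy clustering tools this step emulates) and can be
  switched to full alignment length.
- Ties break deterministically everywhere: by id in Butina density
  ranking, representative selection and cluster ordinals; by length then
  id for chain-cluster references.
- The druggability score of a pocket is out of scope: the published model
  belongs to an external server; the descriptor panel reserves no fake
  value for it.
- Bonferroni denominators are the descriptor-family sizes (72 pockets, 21
  ligands), not the number of pairwise comparisons; the family-wise error
  of that convention is verified by null simulation in the test suite for
  the two-class family.

## Problem sizes in the shipped tests

The test suite and acceptance checks run the full pipeline on scenarios of
5 chain families × 2 sites × 4 pockets (40 pockets, 20 complexes), the
oracle-equivalence suites on 100 random instances per operation, the
Bonferroni null on 500 replicates of a 72-descriptor two-class family, and
the CART calibration on 100 balance/split repeats. These sizes give stable
pass/fail behaviour at interactive runtimes; all of them scale up linearly
through the same functions.

## Known limitations

- Pocket extraction is ligand-conditioned; ligand-free (cavity-search)
  detection is a non-goal.
- Chains spanning several models (NMR ensembles) use the first model only.
- Greedy identity clustering is order-dependent and not transitive in
  pathological identity ranges; planted-family recovery is exact only for
  well-separated families, which is the regime the protocol assumes.
- `logd` is approximated by `logP` (no pKa model) and flagged as such.
- Superposition is sequence-guided rigid-body fitting; structure-alignment
  scoring (TM-score-style) import hooks are limited to accepting
  precomputed cluster/transform tables.
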