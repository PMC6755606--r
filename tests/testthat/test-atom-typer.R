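test_that("polar neighbor counting follows the S/O/N/P definition", {
  acetone <- perceive("CC(C)=O")
  carbonyl <- which(acetone$atoms$element == "C" & acetone$atoms$nheavy == 3L)
  expect_equal(polar_neighbor_count(acetone, carbonyl), 1L)

  cf4 <- perceive("FC(F)(F)F")
  cc <- which(cf4$atoms$element == "C")
  expect_equal(polar_neighbor_count(cf4, cc), 0L)  # F is not polar here

  phos <- perceive("O=P(O)(O)O")
  p <- which(phos$atoms$element == "P")
  expect_equal(polar_neighbor_count(phos, p), 4L)
})

test_that("carbon classes split by bond-order group and polar attachment", {
  # methane: sp3, no polar
  methane <- perceive("C")
  cl <- classify_carbon(methane, which(methane$atoms$element == "C"))
  expect_equal(cl$dd, 1L)

  # sp3 next to polar
  ethanol <- perceive("CCO")
  c_on_o <- which(ethanol$atoms$element == "C" &
                    vapply(seq_len(nrow(ethanol$atoms)), function(i)
                      polar_neighbor_count(ethanol, i) > 0, logical(1)))[1]
  expect_equal(classify_carbon(ethanol, c_on_o)$dd, 2L)

  # pyridine alpha carbon vs aniline C1: polar through the aromatic bond
  # vs through a single bond must be different classes
  pyr <- perceive("c1ccncc1")
  n_idx <- which(pyr$atoms$element == "N")
  alpha <- pyr$nbrs[[n_idx]]$idx[pyr$atoms$element[pyr$nbrs[[n_idx]]$idx] == "C"][1]
  ani <- perceive("Nc1ccccc1")
  nh2 <- which(ani$atoms$element == "N")
  c1 <- ani$nbrs[[nh2]]$idx[ani$atoms$element[ani$nbrs[[nh2]]$idx] == "C"][1]
  expect_false(classify_carbon(pyr, alpha)$dd == classify_carbon(ani, c1)$dd)

  # acetone carbonyl carbon: double-bond group, one multiply-bound polar
  acetone <- perceive("CC(C)=O")
  carbonyl <- which(acetone$atoms$element == "C" & acetone$atoms$nheavy == 3L)
  cls <- classify_carbon(acetone, carbonyl)
  expect_equal(cls$dd, 23L)
  expect_match(cls$label, "double")

  expect_error(classify_carbon(acetone, which(acetone$atoms$element == "O")),
               "not carbon")
})

test_that("nitrogen classes: delocalized lone pairs, polar-bound, hybridization", {
  ani_dd <- dd_of("Nc1ccccc1", "N")
  amide_dd <- dd_of("CC(N)=O", "N")
  expect_equal(ani_dd, amide_dd)  # same delocalized family

  expect_equal(dd_of("CCN(CC)CC", "N"), 20L)  # plain sp3
  expect_equal(dd_of("NN", "N"), 1L)          # N-N polar-bound
  expect_false(dd_of("c1ccncc1", "N") == ani_dd)  # ring N is its own class

  mol <- perceive("CCO")
  expect_error(classify_nitrogen(mol, 1L), "not nitrogen")
})

test_that("oxygen classes separate N/S-bound, amide, acid, ester, hydroxyl", {
  nitro <- perceive("O=[N+]([O-])c1ccccc1")
  for (o in which(nitro$atoms$element == "O"))
    expect_equal(classify_oxygen(nitro, o)$dd, 1L)

  ester <- perceive("COC(C)=O")
  o_idx <- which(ester$atoms$element == "O")
  sp2 <- o_idx[vapply(o_idx, function(i) max(ester$nbrs[[i]]$order) == 2, logical(1))]
  amide <- perceive("CC(N)=O")
  ao <- which(amide$atoms$element == "O")
  expect_false(classify_oxygen(ester, sp2)$dd == classify_oxygen(amide, ao)$dd)

  phenol <- perceive("Oc1ccccc1")
  expect_equal(classify_oxygen(phenol, which(phenol$atoms$element == "O"))$dd, 11L)

  acid <- perceive("CC(=O)O")
  oo <- which(acid$atoms$element == "O")
  dds <- vapply(oo, function(i) classify_oxygen(acid, i)$dd, integer(1))
  expect_setequal(dds, c(4L, 8L))  # sp2 acid O + acid hydroxyl O

  expect_error(classify_oxygen(phenol, 2L), "not oxygen")
})

test_that("fluorine classes depend on carrier hybridization and withdrawing substituents", {
  f_ar <- dd_of("Fc1ccccc1", "F")
  f_sp3 <- dd_of("CCF", "F")
  expect_false(f_ar == f_sp3)

  # the three F of a CF3 group: one class, count 3 in the hologram
  h <- type_smiles("FC(F)(F)c1ccccc1")
  fcodes <- grep("^109", names(h), value = TRUE)
  expect_length(fcodes, 1)
  expect_equal(unname(h[fcodes]), 3L)

  expect_false(dd_of("FC(F)(F)F", "F") == dd_of("CF", "F"))

  mol <- perceive("CCO")
  expect_error(classify_fluorine(mol, 1L), "not fluorine")
})

test_that("hydrogen classes depend only on the attached heavy atom", {
  h_ar <- dd_of("c1ccccc1", "H")
  h_sp3 <- dd_of("C", "H")
  expect_false(h_ar == h_sp3)

  phenol <- perceive("Oc1ccccc1")
  hs <- which(phenol$atoms$element == "H")
  dds <- vapply(hs, function(i) classify_hydrogen(phenol, i)$dd, integer(1))
  expect_setequal(dds, c(2L, 10L))  # aromatic-C carriers and the hydroxyl H

  # all six benzene hydrogens collapse to one code with count 6
  hb <- type_smiles("c1ccccc1")
  hcode <- grep("^101", names(hb), value = TRUE)
  expect_length(hcode, 1)
  expect_equal(unname(hb[hcode]), 6L)

  mol <- perceive("CC")
  expect_error(classify_hydrogen(mol, 1L), "not hydrogen")
})

test_that("default family: aromatic flag vs polar-neighbor count", {
  clphenol <- perceive("Oc1ccc(Cl)cc1")
  cl <- which(clphenol$atoms$element == "Cl")
  expect_equal(classify_default(clphenol, cl)$dd, 10L)  # 0 polar, not aromatic

  thio <- perceive("c1ccsc1")
  s <- which(thio$atoms$element == "S")
  expect_equal(classify_default(thio, s)$dd, 1L)  # aromatic class

  sulfa <- perceive("CS(N)(=O)=O")
  s2 <- which(sulfa$atoms$element == "S")
  expect_equal(classify_default(sulfa, s2)$dd, 13L)  # 3 polar neighbors
})

test_that("six-digit code assembly: charge, element, degree, class", {
  methane <- perceive("C")
  c_idx <- which(methane$atoms$element == "C")
  expect_equal(type_atom(methane, c_idx), 106001L)  # A=1 BB=06 C=0 DD=01

  # phenolate O(-): leading charge digit A = 0
  pho <- perceive("[O-]c1ccccc1")
  o <- which(pho$atoms$element == "O")
  code <- type_atom(pho, o)
  expect_lt(code, 100000L)
  expect_equal(code %/% 100000L, 0L)
})

test_that("hologram counts are conserved and symmetric atoms share codes", {
  for (smi in c("C", "c1ccccc1", "CC(C)=O", "Oc1ccc(Cl)cc1", "CC(=O)O")) {
    mol <- perceive(smi)
    h <- type_molecule(mol)
    expect_equal(sum(h), nrow(mol$atoms), label = smi)
  }
  expect_length(type_smiles("c1ccccc1"), 2)   # benzene: aromatic C + aromatic H
  expect_length(type_smiles("C"), 2)          # methane: sp3 C + its H
})

test_that("chloro/bromophenol holograms agree except for the halogen code", {
  hcl <- type_smiles("Oc1ccc(Cl)cc1")
  hbr <- type_smiles("Oc1ccc(Br)cc1")
  d <- hologram_difference(hbr, hcl)
  expect_length(d, 2)
  expect_equal(d[["117110"]], -1L)  # chlorine leaves
  expect_equal(d[["135110"]], 1L)   # bromine arrives
})
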