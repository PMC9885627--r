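test_that("PDB round-trip preserves coordinates and cleans the record set", {
  f <- tempfile(fileext = ".pdb")
  toy <- generateToyStructure(20, "ideal_helix", seed = 1, file = f)
  s <- readStructure(f)
  expect_identical(nrow(s$residues), 20L)
  got <- as.matrix(s$atoms[s$atoms$elety == "CA", c("x", "y", "z")])
  expect_equal(unname(got), unname(toy$coords), tolerance = 1e-3)  # 3-dp PDB
  # waters and heteroatoms are dropped
  lines <- readLines(f)
  extra <- c("HETATM  900  O   HOH A 501      10.000  10.000  10.000  1.00  0.00           O",
             "HETATM  901 FE   HEM A 502      12.000  12.000  12.000  1.00  0.00          FE")
  f2 <- tempfile(fileext = ".pdb")
  writeLines(append(lines, extra, after = length(lines) - 1), f2)
  s2 <- readStructure(f2)
  expect_identical(nrow(s2$residues), 20L)
  expect_false(any(s2$atoms$resid %in% c("HOH", "HEM")))
})

test_that("multi-model files are read as their first model", {
  f <- tempfile(fileext = ".pdb")
  generateToyStructure(5, "straight_chain", spacing = 4, file = f)
  body <- grep("^ATOM", readLines(f), value = TRUE)
  shifted <- gsub("0.000", "9.000", body, fixed = TRUE)
  f2 <- tempfile(fileext = ".pdb")
  writeLines(c("MODEL     1", body, "ENDMDL",
               "MODEL     2", shifted, "ENDMDL", "END"), f2)
  s <- readStructure(f2)
  expect_identical(nrow(s$atoms), 5L)
  expect_equal(s$atoms$y[1], 0)
})

test_that("contact networks match brute-force distance thresholding", {
  # forced tiny case: collinear residues at 0/5/10 A, cutoff 7
  s3 <- generateToyStructure(3, "straight_chain", spacing = 5)
  net3 <- buildAANetwork(s3, "ca_distance", 7)
  expect_identical(contactEdges(net3)[order(contactEdges(net3)[, 1]), ],
                   matrix(c(1L, 2L, 2L, 3L), 2, 2,
                          dimnames = list(NULL, c("res_i", "res_j"))))
  # noisy helix against an O(n^2) oracle
  toy <- generateToyStructure(60, "ideal_helix", noiseSd = 0.2, seed = 41)
  net <- buildAANetwork(toy, "ca_distance", 7)
  dm <- as.matrix(dist(toy$coords))
  oracle <- which(dm <= 7 & upper.tri(dm), arr.ind = TRUE)
  got <- contactEdges(net)
  expect_identical(nrow(got), nrow(oracle))
  expect_setequal(paste(pmin(got[, 1], got[, 2]), pmax(got[, 1], got[, 2])),
                  paste(oracle[, 1], oracle[, 2]))
  # cutoff below the minimum pairwise distance leaves no edges
  expect_identical(nrow(contactEdges(buildAANetwork(toy, "ca_distance", 1))), 0L)
  # monotone in the cutoff
  eSmall <- contactEdges(buildAANetwork(toy, "ca_distance", 5))
  eBig <- contactEdges(buildAANetwork(toy, "ca_distance", 8))
  expect_true(all(paste(eSmall[, 1], eSmall[, 2]) %in%
                    paste(eBig[, 1], eBig[, 2])))
  expect_error(buildAANetwork(toy, "ca_distance", -1), "positive")
})

test_that("heavy-atom contacts use the minimum interatomic distance", {
  # residue 1 has a side-chain atom reaching toward residue 3
  at <- data.frame(
    resno = c(1, 1, 2, 3),
    resid = "ALA", elety = c("CA", "CB", "CA", "CA"), chain = "A",
    x = c(0, 6, 5, 10), y = 0, z = 0)
  s <- structure(list(atoms = at,
                      residues = data.frame(resno = 1:3, resid = "ALA",
                                            chain = "A")),
                 class = "aa_structure")
  net <- buildAANetwork(s, "heavy_atom_contact", 4.5)
  e <- contactEdges(net)
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_setequal(key, c("1 2", "1 3"))  # CB bridges 1-3 (4 A); CA-CA is 10 A
  # hydrogens are ignored
  at2 <- rbind(at, data.frame(resno = 2, resid = "ALA", elety = "H",
                              chain = "A", x = 8.5, y = 0, z = 0))
  s2 <- structure(list(atoms = at2, residues = s$residues),
                  class = "aa_structure")
  e2 <- contactEdges(buildAANetwork(s2, "heavy_atom_contact", 4.5))
  expect_setequal(paste(pmin(e2[, 1], e2[, 2]), pmax(e2[, 1], e2[, 2])),
                  c("1 2", "1 3"))
})

test_that("network construction is invariant to residue input order", {
  toy <- generateToyStructure(25, "ideal_helix", noiseSd = 0.1, seed = 42)
  at <- data.frame(resno = toy$resno, resid = toy$resNames, elety = "CA",
                   chain = "A", x = toy$coords[, 1], y = toy$coords[, 2],
                   z = toy$coords[, 3])
  mk <- function(a) structure(list(atoms = a,
                                   residues = unique(a[, c("resno", "resid", "chain")])),
                              class = "aa_structure")
  set.seed(43)
  shuffled <- at[sample(nrow(at)), ]
  e1 <- contactEdges(buildAANetwork(mk(at), "ca_distance", 7))
  e2 <- contactEdges(buildAANetwork(mk(shuffled), "ca_distance", 7))
  expect_setequal(paste(pmin(e1[, 1], e1[, 2]), pmax(e1[, 1], e1[, 2])),
                  paste(pmin(e2[, 1], e2[, 2]), pmax(e2[, 1], e2[, 2])))
})

test_that("shortest-path hop counts match a Floyd-Warshall oracle", {
  net <- pathNet(9)
  expect_equal(unname(shortestPathLengths(net, 1)), 0:8)
  expect_error(shortestPathLengths(net, 99), "not in network")
  set.seed(44)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    adj <- matrix(runif(n * n) < 0.12, n, n)
    adj <- adj | t(adj); diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    igraph::V(g)$name <- as.character(seq_len(n))
    net <- new("AANetwork", graph = g, mode = "ca_distance", cutoff = 7,
               positions = seq_len(n), residueNames = rep("ALA", n))
    src <- sample(n, 1)
    expect_equal(unname(shortestPathLengths(net, src)),
                 fwDistances(adj)[src, ])
  }
  # disconnected components are infinitely far
  twoComp <- netFromEdges(4, rbind(c(1, 2), c(3, 4)))
  d <- shortestPathLengths(twoComp, 1)
  expect_identical(unname(is.infinite(d)), c(FALSE, FALSE, TRUE, TRUE))
})

test_that("array filtering keeps exactly the covered catalog entries", {
  cat3 <- data.frame(wt_aa = c("L", "P", "G"), position = c(68, 51, 244),
                     mut_aa = c("P", "S", "R"),
                     mutation = c("L68P", "P51S", "G244R"))
  expect_identical(
    suppressMessages(filterCatalogByArray(cat3, c(68, 51)))$mutation,
    c("L68P", "P51S"))
  expect_identical(nrow(suppressMessages(filterCatalogByArray(cat3, integer(0)))), 0L)
  # 56-entry synthetic catalog, 9 array-covered positions
  set.seed(45)
  real <- dhcr7MutationCatalog()
  synth <- data.frame(wt_aa = sample(names(gwasnet:::.AA1TO3), 47, TRUE),
                      position = sample(setdiff(1:475, real$position), 47),
                      mut_aa = sample(names(gwasnet:::.AA1TO3), 47, TRUE),
                      source = "synthetic", on_array = FALSE,
                      mutation = NA)
  synth$mutation <- paste0(synth$wt_aa, synth$position, synth$mut_aa)
  cat56 <- rbind(real, synth)
  kept <- suppressMessages(filterCatalogByArray(cat56, real$position))
  expect_identical(nrow(kept), 9L)
  expect_setequal(kept$mutation, real$mutation)
  expect_identical(attr(kept, "n_dropped"), 47L)
})

test_that("co-mutation selection applies the strict mean-distance rule", {
  # star hub: every distance 1 equals the mean, strict rule selects none
  hub <- selectComutationCandidates(
    starNet(8), 1, data.frame(position = 2:8))
  expect_identical(nrow(candidateSites(hub)), 0L)
  expect_equal(meanPathLength(hub), 1)
  # path 1..9 from residue 1: mean 4.5; catalog {2,3,8} at 1,2,7 hops
  sel <- selectComutationCandidates(
    pathNet(9), 1, data.frame(position = c(2, 3, 8)))
  expect_equal(meanPathLength(sel), 4.5)
  expect_setequal(candidateSites(sel)$position, c(2, 3))
  # catalog in a disconnected component: unreachable, never selected
  twoComp <- netFromEdges(6, rbind(c(1, 2), c(2, 3), c(4, 5), c(5, 6)))
  sel2 <- selectComutationCandidates(twoComp, 1,
                                     data.frame(position = c(4, 5, 6)))
  expect_identical(nrow(candidateSites(sel2)), 0L)
  expect_true(all(!sel2@sites$reachable))
  expect_error(selectComutationCandidates(
    netFromEdges(3, rbind(c(2, 3))), 1, data.frame(position = 2:3)),
    "isolated")
})

test_that("selection on a cycle equals direct ring-distance enumeration", {
  n <- 11
  net <- cycleNet(n)
  sel <- selectComutationCandidates(net, 1, data.frame(position = 2:n))
  ringDist <- pmin(1:(n - 1), n - (1:(n - 1)))
  dbar <- mean(ringDist)
  expect_equal(meanPathLength(sel), dbar)
  expect_setequal(candidateSites(sel)$position,
                  (2:n)[ringDist < dbar])
})

test_that("wild-type cross-checks guard against numbering offsets", {
  net <- netFromEdges(5, cbind(1:4, 2:5),
                      resNames = c("LEU", "PRO", "GLY", "ALA", "TRP"))
  cat <- data.frame(wt_aa = c("L", "G"), position = c(1, 3),
                    mut_aa = c("P", "R"), mutation = c("L1P", "G3R"))
  sel <- selectComutationCandidates(net, 1, cat)
  expect_identical(candidateSites(sel)$mutation, "G3R")
  catBad <- transform(cat, wt_aa = c("K", "G"))
  expect_error(selectComutationCandidates(net, 1, catBad),
               "wild-type mismatch")
})

test_that("stability ranking orders pairs and counts the destabilizers", {
  ddg <- dhcr7StabilityTable()
  rk <- rankDDGTable(ddg, reference = attr(ddg, "reference"))
  expect_identical(rk$best$pair, "L68P + P51S")
  expect_equal(rk$best$multi_ddg, -2.9)
  expect_identical(rk$ranked$pair[1], "L68P + P51S")
  expect_true(!is.unsorted(rk$ranked$multi_ddg))
  expect_identical(rk$n_below_reference, 7L)
  one <- rankDDGTable(data.frame(pair = "A + B", multi_ddg = 0.2,
                                 single_ddg = 0.1))
  expect_identical(one$best$pair, "A + B")
  tied <- rankDDGTable(data.frame(pair = c("A + B", "A + C", "A + D"),
                                  multi_ddg = c(-1, -1, 0),
                                  single_ddg = 0))
  expect_setequal(tied$best$pair, c("A + B", "A + C"))
})

test_that("the lookup scorer answers only what its table predicts", {
  scorer <- ddgLookupScorer(dhcr7StabilityTable())
  expect_equal(scorer("L68P + W248C"), -1.91)
  expect_equal(scorer("L68P+W248C"), -1.91)  # whitespace-insensitive
  expect_error(scorer("L68P + Q999X"), "no prediction")
  flat <- ddgLookupScorer(data.frame(pair = c("a", "b"), multi_ddg = c(1, 1),
                                     single_ddg = 0))
  rk <- rankDDGTable(data.frame(pair = c("a", "b"),
                                multi_ddg = flat(c("a", "b")),
                                single_ddg = 0))
  expect_identical(nrow(rk$best), 2L)  # constant scorer degenerates to ties
})

test_that("ddG and catalog files round-trip through their readers", {
  dir <- tempfile(); dir.create(dir)
  ddgFile <- file.path(dir, "ddg.csv")
  write.csv(dhcr7StabilityTable(), ddgFile, row.names = FALSE, quote = FALSE)
  dd <- readDDGTable(ddgFile)
  expect_equal(dd$multi_ddg, dhcr7StabilityTable()$multi_ddg)
  catFile <- file.path(dir, "catalog.tsv")
  write.table(dhcr7MutationCatalog()[, 1:5], catFile, sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat <- readVariantCatalog(catFile)
  expect_identical(cat$mutation, dhcr7MutationCatalog()$mutation)
})
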