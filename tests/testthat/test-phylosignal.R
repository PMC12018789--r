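# Newick utilities, VCV, Blomberg's K and its randomization test.

test_that("Newick parsing, round trip and pruning preserve distances", {
  tr <- read_newick("(A:1,B:1):0;")
  expect_equal(length(tr$tip.label), 2)
  expect_equal(max(ape::node.depth.edgelength(tr)), 1)

  set.seed(5); big <- ape::rcoal(12)
  txt <- ape::write.tree(big)
  back <- read_newick(txt)
  expect_equal(ape::dist.nodes(back)[1:12, 1:12],
               ape::dist.nodes(big)[1:12, 1:12], tolerance = 1e-8)

  keep <- big$tip.label[c(1, 4, 7, 10)]
  pr <- prune_tree(big, keep)
  d_full <- ape::cophenetic.phylo(big)[keep, keep]
  expect_equal(ape::cophenetic.phylo(pr)[keep, keep], d_full)
  expect_error(prune_tree(big, "nope"), "not in tree")
  expect_error(read_newick("(A:1,A:1);"), "duplicate")
})

test_that("VCV matches the hand example, ape, and is PSD", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  V <- phylo_vcv(tr)
  expect_equal(V["A", "B"], 1)
  expect_equal(V["A", "C"], 0)
  expect_equal(unname(diag(V)), c(2, 2, 2))

  set.seed(9); rt <- ape::rcoal(15)
  V2 <- phylo_vcv(rt)
  ref <- ape::vcv(rt)
  expect_equal(V2[rownames(ref), colnames(ref)], ref, tolerance = 1e-10)
  expect_true(all(eigen(V2, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-10))
  # star tree: V = t * I
  star <- read_newick("(A:3,B:3,C:3,D:3);")
  expect_equal(unname(phylo_vcv(star)), diag(3, 4))
})

test_that("pruning commutes with VCV row/column deletion", {
  set.seed(11); tr <- ape::rcoal(10)
  keep <- tr$tip.label[c(2, 3, 5, 8, 9)]
  V_then <- phylo_vcv(tr)[keep, keep]
  then_V <- phylo_vcv(prune_tree(tr, keep))[keep, keep]
  expect_equal(then_V, V_then, tolerance = 1e-10)
})

test_that("K is exactly 1 on star phylogenies and matches picante", {
  star <- read_newick("(A:1,B:1,C:1,D:1,E:1,F:1);")
  set.seed(2)
  for (i in 1:5) {
    x <- setNames(rnorm(6), star$tip.label)
    expect_lt(abs(blombergs_k(star, x) - 1), 1e-10)
  }
  set.seed(13); tr <- ape::rcoal(25)
  y <- simulate_bm_trait(tr, 1.5, seed = 14)
  expect_equal(blombergs_k(tr, y),
               as.numeric(picante::Kcalc(y[tr$tip.label], tr)),
               tolerance = 1e-8)
})

test_that("K matches a brute-force dense-algebra evaluation on 4 tips", {
  tr <- read_newick("((A:1,B:1):0.5,(C:0.7,D:0.7):0.8);")
  x <- setNames(c(2.1, 1.7, -0.4, 0.2), c("A", "B", "C", "D"))
  V <- ape::vcv(tr)[names(x), names(x)]
  Vi <- qr.solve(V)
  one <- rep(1, 4)
  a <- drop((t(one) %*% Vi %*% x) / (t(one) %*% Vi %*% one))
  mse0 <- sum((x - a)^2) / 3
  mse <- drop(t(x - a) %*% Vi %*% (x - a)) / 3
  expected <- (sum(diag(V)) - 4 / sum(Vi)) / 3
  expect_equal(blombergs_k(tr, x), (mse0 / mse) / expected, tolerance = 1e-10)
})

test_that("K is invariant to affine transformation of the trait", {
  set.seed(21); tr <- ape::rcoal(18)
  x <- simulate_bm_trait(tr, 0.5, seed = 22)
  k <- blombergs_k(tr, x)
  expect_equal(blombergs_k(tr, 3.2 * x - 40), k, tolerance = 1e-10)
  expect_error(blombergs_k(tr, setNames(rep(1, 18), tr$tip.label)),
               "constant")
})

test_that("BM traits recover K near 1; shuffling destroys the signal", {
  set.seed(33); tr <- ape::rcoal(30)
  ks <- vapply(1:120, function(i) blombergs_k(tr, simulate_bm_trait(tr, 1)), 0)
  ci <- mean(ks) + c(-2, 2) * sd(ks) / sqrt(length(ks))
  expect_gt(1, ci[1]); expect_lt(1, ci[2])
  # destroying signal by shuffling an increasing fraction of tips
  x <- simulate_bm_trait(tr, 1, seed = 34)
  set.seed(35)
  kfrac <- vapply(c(0, 0.5, 1), function(fr) {
    mean(vapply(1:40, function(i) {
      y <- x
      idx <- sample(length(y), round(fr * length(y)))
      y[idx] <- sample(y[idx])
      blombergs_k(tr, y)
    }, 0))
  }, 0)
  expect_true(all(diff(kfrac) < 0))
})

test_that("randomization test is deterministic and detects BM signal", {
  set.seed(41); tr <- ape::rcoal(40)
  x <- simulate_bm_trait(tr, 1, seed = 42)
  r1 <- k_randomization_test(tr, x, n_perm = 199, seed = 7)
  r2 <- k_randomization_test(tr, x, n_perm = 199, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  expect_lte(r1$p_value, 0.05)
  expect_gt(r1$p_value, 0)
  expect_equal(r1$n_permutations, 199)
})

test_that("genus-level tip addition preserves ultrametricity and depths", {
  tr <- read_newick(paste0("(((Pinus_sylvestris:10,Pinus_nigra:10):5,",
                           "Picea_abies:15):10,Quercus_robur:25);"))
  t2 <- add_tip_to_genus(tr, "Pinus_bungeana")
  expect_true("Pinus_bungeana" %in% t2$tip.label)
  expect_true(ape::is.ultrametric(t2, tol = 1e-8))
  d <- ape::node.depth.edgelength(t2)
  expect_equal(max(d), 25)
  # attached at the genus MRCA: patristic distance to both congeners is 20
  coph <- ape::cophenetic.phylo(t2)
  expect_equal(coph["Pinus_bungeana", "Pinus_sylvestris"], 20)
  expect_equal(coph["Pinus_bungeana", "Pinus_nigra"], 20)

  t3 <- add_tip_to_genus(tr, "Picea_omorika")   # single congener: midpoint
  expect_true(ape::is.ultrametric(t3, tol = 1e-8))
  expect_equal(ape::cophenetic.phylo(t3)["Picea_omorika", "Picea_abies"], 15)

  expect_identical(add_tip_to_genus(tr, "Quercus_robur"), tr)
  expect_error(add_tip_to_genus(tr, "Betula_pendula"), "no congeneric")
})

test_that("tip renaming follows the explicit map and rejects collisions", {
  tr <- read_newick("((Elytrigia_repens:1,Carex_ovalis:1):1,Poa_annua:2);")
  t2 <- rename_tips(tr, c(Elytrigia_repens = "Elymus_repens",
                          Carex_ovalis = "Carex_leporina"))
  expect_setequal(t2$tip.label,
                  c("Elymus_repens", "Carex_leporina", "Poa_annua"))
  expect_error(rename_tips(tr, c(Elytrigia_repens = "Poa_annua")),
               "duplicate")
})
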