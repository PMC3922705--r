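test_that("nj_tree solves the 3-taxon case in closed form", {
  D <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  # three-point formulas: la = (dAB + dAC - dBC)/2 etc.
  lens <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(lens["A"]), 0.1)
  expect_equal(unname(lens["B"]), 0.2)
  expect_equal(unname(lens["C"]), 0.4)
})

test_that("nj_tree recovers the generating topology from additive matrices", {
  set.seed(77)
  ok <- 0L
  for (i in 1:100) {
    n <- sample(5:8, 1)
    tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    D <- ape::cophenetic.phylo(tr)
    est <- nj_tree(D[tr$tip.label, tr$tip.label])
    if (rf_distance(est, tr)$rf == 0L) ok <- ok + 1L
    # recovered branch lengths of an additive matrix are exact
    expect_equal(sort(ape::cophenetic.phylo(est)[tr$tip.label, tr$tip.label]),
                 sort(D), tolerance = 1e-6)
  }
  expect_equal(ok, 100L)
})

test_that("nj_tree matches ape's neighbor joining topology", {
  set.seed(31)
  for (i in 1:10) {
    base <- random_seq(300)
    seqs <- setNames(vapply(c(5, 12, 20, 30, 45), function(k)
      mutate_sites(base, k), character(1)), paste0("t", 1:5))
    dm <- pairwise_matrix(seqs)
    expect_equal(rf_distance(nj_tree(dm), ape::nj(dm$d))$rf, 0L)
  }
})

test_that("identical taxa form a zero-length cherry", {
  # additive matrix from ((a:0, b:0):0.05, c:0.3, d:0.4)
  labs <- c("a", "b", "c", "d")
  D <- matrix(c(0, 0, 0.35, 0.45,
                0, 0, 0.35, 0.45,
                0.35, 0.35, 0, 0.7,
                0.45, 0.45, 0.7, 0), 4, 4, dimnames = list(labs, labs))
  tr <- nj_tree(D)
  coph <- ape::cophenetic.phylo(tr)
  expect_equal(coph["a", "b"], 0)
  expect_equal(coph["c", "d"], 0.7, tolerance = 1e-9)
  expect_error(nj_tree(matrix(0, 2, 2)), "at least 3")
})

test_that("nj_tree rejects undefined entries, naming the pairs", {
  D <- matrix(c(0, NA, 1, NA, 0, 1, 1, 1, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_error(nj_tree(D), "A:B")
})

test_that("dollo_min_losses counts hand-checkable patterns", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  all_present <- setNames(rep(TRUE, 4), c("A", "B", "C", "D"))
  expect_equal(dollo_min_losses(tr, all_present)$losses, 0L)

  patchy <- setNames(c(TRUE, FALSE, TRUE, FALSE), c("A", "B", "C", "D"))
  res <- dollo_min_losses(tr, patchy)
  expect_equal(res$gains, 1L)
  expect_equal(res$losses, 2L)

  single <- setNames(c(TRUE, FALSE, FALSE, FALSE), c("A", "B", "C", "D"))
  expect_equal(dollo_min_losses(tr, single)$losses, 0L)

  none <- setNames(rep(FALSE, 4), c("A", "B", "C", "D"))
  expect_error(dollo_min_losses(tr, none), "no present leaf")
})

test_that("dollo_min_losses equals exhaustive search on random trees", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    pres <- setNames(runif(n) < 0.5, tr$tip.label)
    if (!any(pres)) pres[sample(n, 1)] <- TRUE
    expect_equal(dollo_min_losses(tr, pres)$losses, dollo_oracle(tr, pres))
  }
})

test_that("copy_monophyly detects species clades in the copy tree", {
  mono <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  sp <- setNames(c("a", "a", "b", "b"), c("a1", "a2", "b1", "b2"))
  res <- copy_monophyly(mono, sp)
  expect_equal(res$n_monophyletic, 2L)
  expect_equal(res$n_species_with_multiple_copies, 2L)

  mixed <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  res2 <- copy_monophyly(mixed, sp)
  expect_equal(res2$n_monophyletic, 0L)

  # singleton species are flagged, not counted among multi-copy species
  tr3 <- ape::read.tree(text = "((a1:1,a2:1):1,c1:2);")
  sp3 <- setNames(c("a", "a", "c"), c("a1", "a2", "c1"))
  res3 <- copy_monophyly(tr3, sp3)
  expect_true(res3$per_species$singleton[res3$per_species$species == "c"])
  expect_equal(res3$n_species_with_multiple_copies, 1L)

  expect_error(copy_monophyly(mono, sp[-1]), "a1")
})

test_that("copy_monophyly is invariant to rerooting", {
  set.seed(53)
  tr <- ape::rtree(8)
  sp <- setNames(sample(c("x", "y", "z"), 8, replace = TRUE), tr$tip.label)
  base <- copy_monophyly(ape::unroot(tr), sp)
  for (tip in tr$tip.label[1:4]) {
    rerooted <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
    res <- copy_monophyly(rerooted, sp)
    expect_equal(res$per_species$monophyletic, base$per_species$monophyletic)
  }
})

test_that("rf_distance counts bipartition differences", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(rf_distance(t1, t1), list(rf = 0L, max_rf = 2L))

  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(rf_distance(t1, t2)$rf, 2L)

  cat6 <- ape::read.tree(text = "(A,(B,(C,(D,(E,F)))));")
  bal6 <- ape::read.tree(text = "((A,(B,C)),(D,(E,F)));")
  res <- rf_distance(cat6, bal6)
  expect_equal(res$max_rf, 6L)

  t3 <- ape::read.tree(text = "((A,B),(C,E));")
  expect_error(rf_distance(t1, t3), "D.*E|E.*D")
})

test_that("rf_distance equals brute-force split comparison and RF.dist", {
  set.seed(19)
  for (i in 1:15) {
    n <- sample(5:8, 1)
    t1 <- ape::rtree(n)
    t2 <- ape::rtree(n)
    t2$tip.label <- sample(t1$tip.label)
    got <- rf_distance(t1, t2)$rf
    expect_equal(got, as.integer(phangorn::RF.dist(t1, t2)))
    # brute force: count splits of each tree absent from the other by
    # deleting edges and collecting components
    splits_of <- function(tr) {
      tru <- ape::unroot(tr)
      leaves <- sort(tru$tip.label)
      out <- list()
      for (sz in 2:(n - 2)) {
        subs <- combn(leaves, sz, simplify = FALSE)
        for (s in subs) if (is_split_bruteforce(tru, s)) {
          side <- if (leaves[1] %in% s) setdiff(leaves, s) else s
          out[[paste(side, collapse = "|")]] <- TRUE
        }
      }
      names(out)
    }
    if (n <= 6) {  # subset enumeration is exponential; keep it small
      s1 <- splits_of(t1); s2 <- splits_of(t2)
      brute <- length(setdiff(s1, s2)) + length(setdiff(s2, s1))
      expect_equal(got, as.integer(brute))
    }
  }
})

test_that("rf_distance behaves as a metric on random triples", {
  set.seed(23)
  for (i in 1:10) {
    trees <- lapply(1:3, function(k) {
      tr <- ape::rtree(7)
      tr$tip.label <- paste0("t", 1:7)
      tr
    })
    ab <- rf_distance(trees[[1]], trees[[2]])$rf
    bc <- rf_distance(trees[[2]], trees[[3]])$rf
    ac <- rf_distance(trees[[1]], trees[[3]])$rf
    expect_equal(ab, rf_distance(trees[[2]], trees[[1]])$rf)  # symmetry
    expect_lte(ac, ab + bc)                                    # triangle
    expect_equal(rf_distance(trees[[1]], trees[[1]])$rf, 0L)  # identity
  }
})
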