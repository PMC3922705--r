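test_that("simulate_species_tree yields seeded ultrametric trees at depth", {
  tr2 <- simulate_species_tree(2, 400)
  depths <- ape::node.depth.edgelength(tr2)
  expect_equal(unname(depths[1:2]), c(400, 400))

  tr <- simulate_species_tree(7, 10, seed = 5)
  d <- ape::node.depth.edgelength(tr)
  expect_equal(unname(d[1:7]), rep(10, 7), tolerance = 1e-9)
  tr_again <- simulate_species_tree(7, 10, seed = 5)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr_again))
  expect_error(simulate_species_tree(1, 10), "at least 2")
})

test_that("evolve_sequence is deterministic and inert at rate 0", {
  tr <- simulate_species_tree(4, 10, seed = 2)
  root <- random_root_seq(150, seed = 3)
  frozen <- evolve_sequence(tr, root, rate = 0, seed = 1)
  expect_true(all(frozen == root))

  a <- evolve_sequence(tr, root, rate = 0.02, seed = 9)
  b <- evolve_sequence(tr, root, rate = 0.02, seed = 9)
  expect_identical(a, b)
  expect_false(all(a == root))
})

test_that("simulated pairwise distances are unbiased for 2 * rate * t", {
  # analytic expectation under JC: two leaves separated by 2 t myr at a
  # given rate have expected corrected distance 2 * rate * t; checked at
  # t = 1, 10, 100 myr with rates keeping distances below saturation
  set.seed(71)
  cases <- list(c(t = 1, rate = 0.0346), c(t = 10, rate = 0.0346),
                c(t = 100, rate = 0.003))
  for (cs in cases) {
    tr <- ape::read.tree(text = sprintf("(a:%g,b:%g);", cs["t"], cs["t"]))
    ests <- replicate(300, {
      aln <- evolve_sequence(tr, random_root_seq(3000), rate = cs["rate"])
      jc69_distance(p_distance(aln[["a"]], aln[["b"]])$p)
    })
    expected <- 2 * cs[["rate"]] * cs[["t"]]
    se <- sd(ests) / sqrt(length(ests))
    expect_lt(abs(mean(ests) - expected), 2 * se + 1e-4)
  }
})

test_that("inject_te_history realizes vertical and horizontal histories", {
  tree <- simulate_species_tree(2, 10, seed = 13)
  vert <- transfer_scenario(
    species_tree = tree,
    insertions = list(list(species = "sp1", time_myr = 10)),
    copies_per_species = 2, copy_age_myr = 0, seed = 13)
  h <- inject_te_history(vert)
  expect_setequal(h$carriers, c("sp1", "sp2"))
  expect_equal(length(h$copies), 4L)
  # expected cross-species copy distance: 2 * rate * 10 myr
  expect_equal(unname(h$truth$expected_copy_dist["sp1_copy1", "sp2_copy1"]),
               2 * 0.0346 * 10)
  h2 <- inject_te_history(vert)
  expect_identical(h$copies, h2$copies)  # seeded determinism
})

test_that("an HT event grafts the element across the host split", {
  tree <- simulate_species_tree(2, 200, seed = 17)
  sc <- transfer_scenario(
    species_tree = tree,
    insertions = list(list(species = "sp1", time_myr = 150)),
    ht_events = list(list(donor = "sp1", recipient = "sp2", time_myr = 3)),
    copies_per_species = 1, copy_age_myr = 0,
    te_length = 10000, seed = 17)
  h <- inject_te_history(sc)
  expect_setequal(h$carriers, c("sp1", "sp2"))
  # element MRCA of the two species is the transfer at 3 myr, not the
  # 200-myr host split: expected distance 2 * 0.0346 * 3
  expect_equal(unname(h$truth$expected_copy_dist["sp1_copy1", "sp2_copy1"]),
               2 * 0.0346 * 3, tolerance = 1e-9)
  # observed divergence agrees within 2 SE over replicate seeds
  obs <- vapply(1:30, function(s) {
    sc_s <- transfer_scenario(
      species_tree = tree,
      insertions = list(list(species = "sp1", time_myr = 150)),
      ht_events = list(list(donor = "sp1", recipient = "sp2", time_myr = 3)),
      copies_per_species = 1, copy_age_myr = 0, te_length = 10000, seed = s)
    hs <- inject_te_history(sc_s)
    jc69_distance(p_distance(hs$copies[["sp1_copy1"]],
                             hs$copies[["sp2_copy1"]])$p)
  }, numeric(1))
  se <- sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - 2 * 0.0346 * 3), 2 * se + 1e-3)
})

test_that("inject_te_history rejects impossible event histories", {
  tree <- simulate_species_tree(2, 10, seed = 3)
  too_old <- transfer_scenario(
    species_tree = tree,
    insertions = list(list(species = "sp1", time_myr = 5)),
    ht_events = list(list(donor = "sp1", recipient = "sp2", time_myr = 7)),
    seed = 1)
  expect_error(inject_te_history(too_old), "predates the element insertion")

  not_carrier <- transfer_scenario(
    species_tree = tree,
    insertions = list(list(species = "sp1", time_myr = 5)),
    ht_events = list(list(donor = "sp2", recipient = "sp1", time_myr = 2)),
    seed = 1)
  expect_error(inject_te_history(not_carrier), "does not carry")

  before_root <- transfer_scenario(
    species_tree = tree,
    insertions = list(list(species = "sp1", time_myr = 10)),
    ht_events = list(list(donor = "sp1", recipient = "sp2", time_myr = 20)),
    seed = 1)
  expect_error(inject_te_history(before_root), "predates")
})

test_that("gene panels evolve below the neutral rate", {
  tree <- simulate_species_tree(2, 10, seed = 23)
  sc <- transfer_scenario(species_tree = tree, n_genes = 30,
                          gene_length = 2000, seed = 23)
  set.seed(23)
  genes <- simulate_gene_panel(sc, tree)
  expect_length(genes$alignments, 30L)
  expect_true(all(genes$scalings > 0 & genes$scalings < 1))
  dists <- vapply(genes$alignments, function(a) {
    jc69_distance(p_distance(a[["sp1"]], a[["sp2"]])$p)
  }, numeric(1))
  # mean over genes close to 2 * rate * depth * mean scaling = 0.346
  expect_lt(abs(mean(dists) - 0.346), 0.05)
  expect_lt(max(dists), 2 * 0.0346 * 10)  # all below the neutral expectation
})

test_that("generate_dataset writes a complete, reproducible dataset", {
  sc <- default_scenario(seed = 101, type = "ht")
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  generate_dataset(sc, d1)
  generate_dataset(sc, d2)
  expect_true(file.exists(file.path(d1, "species_tree.nwk")))
  expect_true(file.exists(file.path(d1, "presence.tsv")))
  expect_true(file.exists(file.path(d1, "truth.json")))
  expect_gt(length(list.files(file.path(d1, "genes"))), 0L)
  expect_gt(length(list.files(file.path(d1, "te"))), 0L)
  # identical scenario => byte-identical outputs
  for (f in c("species_tree.nwk", "presence.tsv", "truth.json",
              "te/fam1.fasta", "genes/gene_001.fasta")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("truth-scored verdicts separate HT from vertical scenarios", {
  ht <- evaluate_scenario(default_scenario(seed = 7, type = "ht"),
                          pairs = "planted")
  expect_identical(unname(ht$verdicts[1]), "HT")
  vert <- evaluate_scenario(default_scenario(seed = 7, type = "vertical"),
                            pairs = "all")
  expect_false(any(vert$verdicts == "HT"))
  expect_error(evaluate_scenario(default_scenario(seed = 7, type = "vertical"),
                                 pairs = "planted"), "no HT event")
})
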