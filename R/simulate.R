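#' Simulate an ultrametric host species tree
#'
#' Pure-birth tree with `n_species` tips, rescaled so every root-to-tip
#' path equals `depth_myr` (branch lengths in myr).
#'
#' @param n_species Number of species (>= 2).
#' @param depth_myr Root depth in myr.
#' @param seed Optional integer seed.
#' @return An ultrametric `phylo` tree with tips `sp1..spN`.
#' @export
simulate_species_tree <- function(n_species, depth_myr, seed = NULL) {
  if (n_species < 2L) stop("need at least 2 species")
  if (!is.null(seed)) set.seed(seed)
  if (n_species == 2L) {
    tr <- ape::read.tree(text = sprintf("(sp1:%g,sp2:%g);", depth_myr, depth_myr))
    return(tr)
  }
  tr <- ape::rphylo(n_species, birth = 1, death = 0)
  depths <- ape::node.depth.edgelength(tr)
  tr$edge.length <- tr$edge.length * depth_myr / max(depths[seq_len(n_species)])
  tr$tip.label <- paste0("sp", seq_len(n_species))
  tr
}

#' Generate a random root nucleotide sequence
#'
#' @param length Sequence length in bp.
#' @param seed Optional integer seed.
#' @return A single nucleotide string with equal base frequencies.
#' @export
random_root_seq <- function(length, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

# One JC69 step: evolve a character vector of bases for d expected
# substitutions/site. P(change) = 3/4 * (1 - exp(-4d/3)), uniform over the
# three alternative bases conditional on change.
jc_evolve_branch <- function(chars, d) {
  if (d <= 0) return(chars)
  p_change <- 0.75 * (1 - exp(-4 * d / 3))
  hit <- runif(length(chars)) < p_change
  n_hit <- sum(hit)
  if (n_hit > 0L) {
    bases <- c("A", "C", "G", "T")
    cur <- match(chars[hit], bases)
    shift <- sample.int(3L, n_hit, replace = TRUE)
    chars[hit] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  }
  chars
}

#' Evolve a sequence along a tree under Jukes-Cantor
#'
#' Simulates substitutions along every branch with expected
#' `rate * branch_length` substitutions/site (equal exchange rates and base
#' frequencies; no indels, so the leaf sequences are trivially aligned).
#' A `root.edge`, if present on the tree, is evolved before the first split.
#'
#' @param tree `phylo` tree with branch lengths in myr.
#' @param root_seq Root nucleotide string.
#' @param rate Substitution rate in substitutions/site/myr.
#' @param seed Optional integer seed.
#' @return Named character vector of leaf sequences (an ungapped alignment).
#' @export
evolve_sequence <- function(tree, root_seq, rate, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  chars0 <- strsplit(toupper(root_seq), "", fixed = TRUE)[[1L]]
  if (!all(chars0 %in% c("A", "C", "G", "T"))) {
    stop("root sequence must be over A/C/G/T")
  }
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  if (!is.null(tree$root.edge) && tree$root.edge > 0) {
    chars0 <- jc_evolve_branch(chars0, rate * tree$root.edge)
  }
  states <- vector("list", n_tip + tree$Nnode)
  states[[root]] <- chars0
  tr <- ape::reorder.phylo(tree, "cladewise")
  edge <- tr$edge
  lens <- tr$edge.length
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]
    ch <- edge[e, 2L]
    states[[ch]] <- jc_evolve_branch(states[[p]], rate * lens[e])
  }
  out <- vapply(seq_len(n_tip), function(i) paste(states[[i]], collapse = ""),
                character(1))
  names(out) <- tree$tip.label
  out
}

#' Describe a transposon transfer scenario
#'
#' Collects the full generative model for one TE family on a host tree:
#' genes evolving under purifying selection (neutral rate scaled by a
#' per-gene factor < 1), element copies evolving neutrally after insertion,
#' explicit horizontal transfer events, and a star-like terminal burst of
#' copies per carrier species. Defaults emulate the distance structure of
#' a deep arthropod-style host split scaled to avoid Jukes-Cantor
#' saturation: at the default neutral rate (0.0346 substitutions/site/myr)
#' and 10-myr depth, ortholog distances for the deepest species pair span
#' roughly 0.21-0.49 substitutions/site (mean 0.35) while vertical TE
#' distances reach about 0.69.
#'
#' @param species_tree Optional ultrametric `phylo` in myr; simulated from
#'   `n_species`/`depth_myr` when NULL.
#' @param n_species,depth_myr Host tree shape when simulated.
#' @param te_rate Neutral element rate, substitutions/site/myr.
#' @param gene_rate Neutral gene-region rate (defaults to `te_rate`).
#' @param gene_scaling Mean purifying-selection multiplier in (0, 1].
#' @param gene_scaling_spread Per-gene scalings are drawn uniformly from
#'   `gene_scaling * (1 +/- spread)`.
#' @param n_genes,gene_length Ortholog panel size and length (bp).
#' @param te_length Element length (bp).
#' @param insertions List of `list(species=, time_myr=)`: the element
#'   enters the lineage ancestral to `species` at `time_myr` before present
#'   and is inherited by all its descendants.
#' @param ht_events List of `list(donor=, recipient=, time_myr=)`: the
#'   recipient lineage at `time_myr` acquires the donor lineage's element
#'   state and evolves it onward independently.
#' @param copies_per_species Copies sampled per carrier species.
#' @param copy_age_myr Age of the terminal star burst: each copy diverged
#'   from its species' element lineage this many myr ago.
#' @param seed Integer seed; all randomness flows from it.
#' @return An object of class `transfer_scenario`.
#' @export
transfer_scenario <- function(species_tree = NULL,
                              n_species = 6L,
                              depth_myr = 10,
                              te_rate = 0.0346,
                              gene_rate = te_rate,
                              gene_scaling = 0.5,
                              gene_scaling_spread = 0.4,
                              n_genes = 46L,
                              gene_length = 600L,
                              te_length = 1000L,
                              insertions = list(list(species = "sp1",
                                                     time_myr = depth_myr)),
                              ht_events = list(),
                              copies_per_species = 5L,
                              copy_age_myr = 0.5,
                              seed = 1L) {
  stopifnot(te_rate > 0, gene_rate > 0,
            gene_scaling > 0, gene_scaling <= 1,
            gene_scaling_spread >= 0, gene_scaling_spread < 1,
            n_genes >= 1, gene_length >= 1, te_length >= 1,
            copies_per_species >= 1, copy_age_myr >= 0,
            length(insertions) >= 1)
  structure(list(
    species_tree = species_tree, n_species = as.integer(n_species),
    depth_myr = depth_myr, te_rate = te_rate, gene_rate = gene_rate,
    gene_scaling = gene_scaling, gene_scaling_spread = gene_scaling_spread,
    n_genes = as.integer(n_genes), gene_length = as.integer(gene_length),
    te_length = as.integer(te_length), insertions = insertions,
    ht_events = ht_events, copies_per_species = as.integer(copies_per_species),
    copy_age_myr = copy_age_myr, seed = as.integer(seed)
  ), class = "transfer_scenario")
}

# Node ages (myr before present) of an ultrametric phylo.
node_ages <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  max(depths[seq_along(tree$tip.label)]) - depths
}

# The node whose ancestral lineage contains the given leaf's history at
# `age`: the child node of the edge spanning that age on the root->leaf path.
lineage_node_at <- function(tree, leaf, age, ages) {
  root <- length(tree$tip.label) + 1L
  if (age > ages[root] + 1e-9) {
    stop("event at ", age, " myr predates the root (", ages[root], " myr)")
  }
  node <- which(tree$tip.label == leaf)
  if (length(node) != 1L) stop("unknown species: ", leaf)
  parent <- integer(length(ages))
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  # climb until the parent is strictly older than the event; a time equal to
  # a node's age places the event on that node itself (its ancestral lineage)
  while (node != root && ages[parent[node]] < age + 1e-9) {
    node <- parent[node]
  }
  node
}

# Build the element genealogy (branch lengths in myr) as a newick string,
# descending the species tree from the insertion point and grafting
# horizontal-transfer recipients onto the donor lineage at the event time.
build_element_genealogy <- function(tree, insertion, ht_events,
                                    copies_per_species, copy_age_myr) {
  ages <- node_ages(tree)
  sets <- node_leafsets(tree)
  children_of <- function(node) tree$edge[tree$edge[, 1L] == node, 2L]
  n_tip <- length(tree$tip.label)
  fmt <- function(x) sprintf("%.12g", x)

  # validate the event history: donors must carry the element when they give
  # it, recipients must not already carry it
  carrier_set <- sets[[lineage_node_at(tree, insertion$species,
                                       insertion$time_myr, ages)]]
  evs_desc <- ht_events
  if (length(evs_desc) > 1L) {
    evs_desc <- evs_desc[order(-vapply(evs_desc, `[[`, numeric(1), "time_myr"))]
  }
  for (ev in evs_desc) {
    if (ev$time_myr > insertion$time_myr) {
      stop("HT event at ", ev$time_myr, " myr predates the element insertion (",
           insertion$time_myr, " myr)")
    }
    if (!(ev$donor %in% carrier_set)) {
      stop("HT donor ", ev$donor, " does not carry the element at ",
           ev$time_myr, " myr")
    }
    if (ev$recipient %in% carrier_set) {
      stop("HT recipient ", ev$recipient, " already carries the element at ",
           ev$time_myr, " myr")
    }
    carrier_set <- union(carrier_set,
                         sets[[lineage_node_at(tree, ev$recipient,
                                               ev$time_myr, ages)]])
  }

  copy_star <- function(leaf_name) {
    k <- copies_per_species
    labs <- paste0(leaf_name, "_copy", seq_len(k))
    if (k == 1L) {
      list(str = labs, top = 0)
    } else {
      list(str = paste0("(", paste0(labs, ":", fmt(copy_age_myr),
                                    collapse = ","), ")"),
           top = copy_age_myr)
    }
  }

  # subtree from `node` downwards, returning string + the age it represents
  inner <- function(node) {
    if (node <= n_tip) return(copy_star(tree$tip.label[node]))
    ch <- children_of(node)
    parts <- vapply(ch, function(c) seg(c, ages[node]), character(1))
    list(str = paste0("(", paste(parts, collapse = ","), ")"),
         top = ages[node])
  }

  # lineage segment ending at `node`, starting at `top_age`; HT events whose
  # donor lineage passes through this segment split it and graft recipients
  seg <- function(node, top_age) {
    seg_leaves <- sets[[node]]
    evs <- Filter(function(ev) {
      ev$donor %in% seg_leaves &&
        ev$time_myr >= ages[node] - 1e-12 && ev$time_myr < top_age - 1e-12
    }, ht_events)
    if (length(evs) > 1L) {
      evs <- evs[order(vapply(evs, `[[`, numeric(1), "time_myr"))]
    }
    base <- inner(node)
    s <- base$str
    cur_top <- base$top
    for (ev in evs) {
      t <- ev$time_myr
      if (t <= cur_top + 1e-12) {
        stop("HT event at ", t, " myr conflicts with copy burst age on the ",
             "donor terminal branch")
      }
      r_node <- lineage_node_at(tree, ev$recipient, t, ages)
      rec <- seg(r_node, t)
      s <- paste0("(", s, ":", fmt(t - cur_top), ",", rec, ")")
      cur_top <- t
    }
    paste0(s, ":", fmt(top_age - cur_top))
  }

  ins_node <- lineage_node_at(tree, insertion$species, insertion$time_myr, ages)
  top <- seg(ins_node, insertion$time_myr)
  # `top` is "subtree:root_edge"; keep the root edge so evolution from the
  # insertion-time element state is applied before the first split
  nwk <- paste0(top, ";")
  g <- ape::read.tree(text = nwk)
  if (is.null(g)) stop("internal error: could not parse element genealogy")
  carriers <- unique(sub("_copy[0-9]+$", "", g$tip.label))
  list(genealogy = g, carriers = carriers)
}

#' Simulate a TE family's history on a host tree
#'
#' Realizes a [transfer_scenario()]: builds the element genealogy implied
#' by the insertion and horizontal-transfer events (branch lengths in myr),
#' evolves the ancestral element along it at the neutral element rate, and
#' returns the copy alignment together with the ground truth (genealogy,
#' ancestral sequence, analytic expected distances `rate * path_length`).
#'
#' @param scenario A `transfer_scenario`.
#' @param species_tree Host tree override (a `phylo` in myr); defaults to
#'   the scenario's tree, simulated if absent.
#' @return An object of class `te_history`: list with `copies` (named
#'   character vector, ungapped alignment), `species_of_copy`, `carriers`,
#'   `genealogy`, `ancestral_seq`, and `truth` (expected pairwise copy
#'   distances in substitutions/site, scenario echo).
#' @export
inject_te_history <- function(scenario, species_tree = NULL) {
  stopifnot(inherits(scenario, "transfer_scenario"))
  set.seed(scenario$seed)
  tree <- species_tree
  if (is.null(tree)) tree <- scenario$species_tree
  if (is.null(tree)) {
    tree <- simulate_species_tree(scenario$n_species, scenario$depth_myr)
  }
  if (length(scenario$insertions) != 1L) {
    stop("exactly one insertion per family is supported; use one scenario per family")
  }
  ages <- node_ages(tree)
  # validate HT events: recipient must not already carry the element
  gen <- build_element_genealogy(tree, scenario$insertions[[1L]],
                                 scenario$ht_events,
                                 scenario$copies_per_species,
                                 scenario$copy_age_myr)
  anc <- random_root_seq(scenario$te_length)
  copies <- evolve_sequence(gen$genealogy, anc, scenario$te_rate)
  species_of_copy <- sub("_copy[0-9]+$", "", names(copies))
  names(species_of_copy) <- names(copies)
  expected <- scenario$te_rate * ape::cophenetic.phylo(gen$genealogy)
  structure(list(
    copies = copies,
    species_of_copy = species_of_copy,
    carriers = gen$carriers,
    genealogy = gen$genealogy,
    ancestral_seq = anc,
    truth = list(expected_copy_dist = expected,
                 scenario = unclass(scenario)[setdiff(names(scenario),
                                                      "species_tree")])
  ), class = "te_history")
}

#' Simulate an orthologous gene panel under purifying selection
#'
#' Each gene evolves along the host tree at `gene_rate * s_g`, where the
#' per-gene scaling `s_g` is drawn uniformly from
#' `gene_scaling * (1 - spread, 1 + spread)` — a deterministic-rate proxy
#' for gene-specific functional constraint.
#'
#' @param scenario A `transfer_scenario`.
#' @param species_tree Host tree (`phylo`, myr).
#' @return A list with `alignments` (one named character vector per gene),
#'   `scalings` (per-gene multipliers) and `expected_pair_dist` (matrix of
#'   analytic expected mean distances, `gene_rate * gene_scaling *
#'   path_length`).
#' @export
simulate_gene_panel <- function(scenario, species_tree) {
  stopifnot(inherits(scenario, "transfer_scenario"))
  lo <- scenario$gene_scaling * (1 - scenario$gene_scaling_spread)
  hi <- scenario$gene_scaling * (1 + scenario$gene_scaling_spread)
  scalings <- runif(scenario$n_genes, lo, hi)
  alignments <- lapply(seq_len(scenario$n_genes), function(g) {
    root <- random_root_seq(scenario$gene_length)
    evolve_sequence(species_tree, root, scenario$gene_rate * scalings[g])
  })
  names(alignments) <- sprintf("gene_%03d", seq_len(scenario$n_genes))
  list(alignments = alignments,
       scalings = scalings,
       expected_pair_dist = scenario$gene_rate * scenario$gene_scaling *
         ape::cophenetic.phylo(species_tree))
}

#' Generate a complete synthetic dataset on disk
#'
#' Writes everything the pipeline consumes: the host species tree (newick),
#' one aligned FASTA per orthologous gene, one copy-alignment FASTA per TE
#' family, a species-by-family presence table, and a `truth.json` recording
#' the scenario, seeds and analytic expectations.
#'
#' @param scenarios A `transfer_scenario` or named list of them (one per TE
#'   family); all families share the first scenario's host tree and gene
#'   panel.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of written paths plus the in-memory objects.
#' @export
generate_dataset <- function(scenarios, out_dir) {
  if (inherits(scenarios, "transfer_scenario")) {
    scenarios <- list(fam1 = scenarios)
  }
  if (is.null(names(scenarios)) || any(!nzchar(names(scenarios)))) {
    names(scenarios) <- paste0("fam", seq_along(scenarios))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2L) != 0L) stop("output directory not writable: ", out_dir)
  sc1 <- scenarios[[1L]]
  set.seed(sc1$seed)
  tree <- sc1$species_tree
  if (is.null(tree)) tree <- simulate_species_tree(sc1$n_species, sc1$depth_myr)
  write_newick(tree, file.path(out_dir, "species_tree.nwk"))

  genes <- simulate_gene_panel(sc1, tree)
  gene_dir <- file.path(out_dir, "genes")
  dir.create(gene_dir, showWarnings = FALSE)
  for (g in names(genes$alignments)) {
    write_fasta(genes$alignments[[g]], file.path(gene_dir, paste0(g, ".fasta")))
  }

  te_dir <- file.path(out_dir, "te")
  dir.create(te_dir, showWarnings = FALSE)
  histories <- list()
  presence <- matrix(FALSE, nrow = length(tree$tip.label),
                     ncol = length(scenarios),
                     dimnames = list(tree$tip.label, names(scenarios)))
  for (f in names(scenarios)) {
    hist <- inject_te_history(scenarios[[f]], species_tree = tree)
    names(hist$copies) <- paste0(f, "_", names(hist$copies))
    write_fasta(hist$copies, file.path(te_dir, paste0(f, ".fasta")))
    presence[hist$carriers, f] <- TRUE
    histories[[f]] <- hist
  }
  pres_df <- data.frame(species = rownames(presence), presence,
                        check.names = FALSE)
  write.table(pres_df, file.path(out_dir, "presence.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  truth <- list(
    families = lapply(histories, function(h) {
      list(carriers = h$carriers,
           ancestral_seq = h$ancestral_seq,
           expected_copy_dist = h$truth$expected_copy_dist,
           scenario = h$truth$scenario)
    }),
    gene_scalings = genes$scalings,
    expected_gene_pair_dist = genes$expected_pair_dist
  )
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dir = out_dir, tree = tree, genes = genes,
                 histories = histories, presence = presence))
}

#' Simulate one scenario replicate and score the vertical-inheritance test
#'
#' Realizes the scenario in memory (element history, then the orthologous
#' gene panel from the same seeded stream) and runs [vertical_null_test()]
#' for carrier species pairs, without touching disk. Used for truth-scored
#' power and false-positive-rate estimation over many replicate seeds.
#'
#' @param scenario A `transfer_scenario`.
#' @param pairs `"all"` carrier pairs, or `"planted"` for only the
#'   donor-recipient pair of the first HT event.
#' @return A list with `verdicts` (named character vector, one per scored
#'   species pair), `margins`, and `planted_pair` (or `NULL` for vertical
#'   scenarios).
#' @export
evaluate_scenario <- function(scenario, pairs = c("all", "planted")) {
  pairs <- match.arg(pairs)
  stopifnot(inherits(scenario, "transfer_scenario"))
  tree <- scenario$species_tree
  if (is.null(tree)) tree <- simulate_species_tree(scenario$n_species,
                                                   scenario$depth_myr,
                                                   seed = scenario$seed)
  hist <- inject_te_history(scenario, species_tree = tree)  # seeds the stream
  genes <- simulate_gene_panel(scenario, tree)              # continues it
  gene_mats <- lapply(genes$alignments, as_alignment_matrix)
  copy_mat <- as_alignment_matrix(hist$copies)
  sp_of <- hist$species_of_copy
  planted <- if (length(scenario$ht_events) > 0L) {
    c(scenario$ht_events[[1L]]$donor, scenario$ht_events[[1L]]$recipient)
  } else NULL
  pair_mat <- if (pairs == "planted") {
    if (is.null(planted)) stop("no HT event planted; nothing to score")
    matrix(planted, nrow = 2L)
  } else {
    if (length(hist$carriers) < 2L) stop("fewer than 2 carrier species")
    utils::combn(sort(hist$carriers), 2L)
  }
  jc_pair <- function(a_chars, b_chars) {
    pd <- p_distance(a_chars, b_chars)
    if (pd$p >= 0.75) NA_real_ else jc69_distance(pd$p)
  }
  verdicts <- character(ncol(pair_mat))
  margins <- numeric(ncol(pair_mat))
  names(verdicts) <- names(margins) <- paste(pair_mat[1L, ], pair_mat[2L, ],
                                             sep = ":")
  for (k in seq_len(ncol(pair_mat))) {
    a <- pair_mat[1L, k]; b <- pair_mat[2L, k]
    ia <- which(sp_of == a); ib <- which(sp_of == b)
    te_d <- as.vector(outer(ia, ib, Vectorize(function(i, j)
      jc_pair(copy_mat[i, ], copy_mat[j, ]))))
    gene_d <- vapply(gene_mats, function(m) jc_pair(m[a, ], m[b, ]), numeric(1))
    gene_d <- gene_d[!is.na(gene_d)]
    te_d <- te_d[!is.na(te_d)]
    if (length(te_d) == 0L || length(gene_d) == 0L) {
      verdicts[k] <- "indeterminate"
      margins[k] <- NA_real_
      next
    }
    call <- vertical_null_test(te_d, gene_d, taxon_pair = c(a, b))
    verdicts[k] <- call$verdict
    margins[k] <- call$margin
  }
  list(verdicts = verdicts, margins = margins, planted_pair = planted)
}

#' Default horizontal-transfer and vertical scenarios
#'
#' The default HT scenario inserts the element at the root of a 6-species,
#' 10-myr host tree and transfers it 1 myr ago between the two most
#' distantly related species; the vertical scenario has the root insertion
#' only. All other parameters are the [transfer_scenario()] defaults.
#'
#' @param seed Integer seed.
#' @param type `"ht"` or `"vertical"`.
#' @return A `transfer_scenario`.
#' @export
default_scenario <- function(seed = 1L, type = c("ht", "vertical")) {
  type <- match.arg(type)
  set.seed(seed)
  tree <- simulate_species_tree(6L, 10)
  if (type == "ht") {
    # element ancestral to one side of the root only (patchy distribution),
    # then transferred 1 myr ago across the deepest host split
    root_children <- tree$edge[tree$edge[, 1L] == length(tree$tip.label) + 1L, 2L]
    sets <- node_leafsets(tree)
    ages <- node_ages(tree)
    donor <- sets[[root_children[1L]]][1L]
    recipient <- sets[[root_children[2L]]][1L]
    transfer_scenario(species_tree = tree,
                      insertions = list(list(species = donor,
                                             time_myr = 0.99 * max(ages))),
                      ht_events = list(list(donor = donor,
                                            recipient = recipient,
                                            time_myr = 1)),
                      seed = seed)
  } else {
    transfer_scenario(species_tree = tree,
                      insertions = list(list(species = tree$tip.label[1L],
                                             time_myr = 10)),
                      seed = seed)
  }
}
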