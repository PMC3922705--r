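#' Run the full HTT inference pipeline on a dataset directory
#'
#' Consumes a directory in the layout written by [generate_dataset()]
#' (`species_tree.nwk`, `genes/*.fasta` aligned ortholog panels,
#' `te/<family>.fasta` copy alignments, optional `presence.tsv`) and runs
#' every stage: consensus reconstruction and anatomy annotation per family,
#' Jukes-Cantor distance matrices, the vertical-inheritance test per family
#' and species pair, burst-age dating per carrier species, and the tree
#' concordance battery (NJ copy tree, per-species copy monophyly, Dollo
#' loss count, Robinson-Foulds host/TE incongruence). Writes `report.json`
#' (machine-readable, full precision) and `report.tsv` (one row per HTT
#' call) into `out_dir`.
#'
#' Copy sequence names must follow `<family>_<species>_copy<i>`.
#'
#' @param dataset_dir Input directory.
#' @param config An [htt_config()].
#' @param out_dir Output directory for the reports (default `dataset_dir`).
#' @return Invisibly, the report list.
#' @export
run_pipeline <- function(dataset_dir, config = htt_config(),
                         out_dir = dataset_dir) {
  stopifnot(inherits(config, "htt_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  message("run_pipeline: min_identity=", config$min_identity,
          " min_hit_length=", config$min_hit_length,
          " min_consensus_depth=", config$min_consensus_depth,
          " max_missing_fraction=", config$max_missing_fraction,
          " neutral_rate=", config$neutral_rate,
          " min_margin=", config$min_margin,
          " gap_deletion=", config$gap_deletion,
          " rng_seed=", config$rng_seed)
  set.seed(config$rng_seed)

  species_tree <- stage("read_species_tree",
                        read_newick(file.path(dataset_dir, "species_tree.nwk")))
  gene_files <- sort(list.files(file.path(dataset_dir, "genes"),
                                pattern = "\\.fa(sta)?$", full.names = TRUE))
  if (length(gene_files) == 0L) stop("pipeline stage 'read_genes' failed: no gene alignments found")
  genes <- stage("read_genes", lapply(gene_files, read_fasta))
  names(genes) <- sub("\\.fa(sta)?$", "", basename(gene_files))

  te_files <- sort(list.files(file.path(dataset_dir, "te"),
                              pattern = "\\.fa(sta)?$", full.names = TRUE))
  if (length(te_files) == 0L) stop("pipeline stage 'read_te' failed: no TE copy alignments found")
  families <- sub("\\.fa(sta)?$", "", basename(te_files))
  te_copies <- stage("read_te", lapply(te_files, read_fasta))
  names(te_copies) <- families

  # per-gene distance matrices (trimmed under the configured missingness rule)
  gene_dms <- stage("gene_distances", lapply(genes, function(a) {
    pairwise_matrix(trim_columns(a, config$max_missing_fraction),
                    deletion = config$gap_deletion)
  }))
  gene_pair_dist <- function(sp_a, sp_b) {
    vapply(gene_dms, function(dm) {
      if (!(sp_a %in% dm$labels) || !(sp_b %in% dm$labels)) return(NA_real_)
      dm$d[sp_a, sp_b]
    }, numeric(1))
  }

  report_families <- list()
  htt_rows <- list()
  for (f in families) {
    copies <- te_copies[[f]]
    sp_of <- sub("_copy[0-9]+$", "", sub(paste0("^", f, "_"), "", names(copies)))
    names(sp_of) <- names(copies)
    unknown <- setdiff(unique(sp_of), species_tree$tip.label)
    if (length(unknown) > 0L) {
      stop("pipeline stage 'map_copies' failed: copy species not in tree: ",
           paste(unknown, collapse = ", "))
    }
    carriers <- sort(unique(sp_of))

    cons <- stage("consensus", annotate_element(
      build_consensus(copies, min_depth = config$min_consensus_depth, name = f)))

    te_aln <- stage("te_trim", trim_columns(copies, config$max_missing_fraction))
    te_dm <- stage("te_distances",
                   pairwise_matrix(te_aln, deletion = config$gap_deletion))

    # vertical-inheritance test per carrier species pair
    calls <- list()
    if (length(carriers) >= 2L) {
      pairs <- utils::combn(carriers, 2L)
      for (k in seq_len(ncol(pairs))) {
        a <- pairs[1L, k]; b <- pairs[2L, k]
        te_d <- as.vector(te_dm$d[names(sp_of)[sp_of == a],
                                  names(sp_of)[sp_of == b]])
        g_d <- gene_pair_dist(a, b)
        g_d <- g_d[!is.na(g_d)]
        if (length(g_d) == 0L || anyNA(te_d)) next
        call <- stage("vertical_null_test",
                      vertical_null_test(te_d, g_d, te_family = f,
                                         taxon_pair = c(a, b),
                                         min_margin = config$min_margin))
        calls[[paste(a, b, sep = ":")]] <- call
        htt_rows[[length(htt_rows) + 1L]] <- data.frame(
          te_family = f, taxon_a = a, taxon_b = b, verdict = call$verdict,
          margin = call$margin,
          te_mean = call$te_dist_summary$mean, te_min = call$te_dist_summary$min,
          te_max = call$te_dist_summary$max,
          gene_mean = call$gene_dist_summary$mean,
          gene_min = call$gene_dist_summary$min,
          gene_max = call$gene_dist_summary$max,
          n_genes = call$n_genes, mw_p = call$mw_p,
          stringsAsFactors = FALSE)
      }
    }

    # burst dating per carrier species with enough copies for a consensus
    bursts <- list()
    for (s in carriers) {
      s_copies <- copies[sp_of == s]
      if (length(s_copies) < config$min_consensus_depth) next
      s_cons <- stage("species_consensus",
                      build_consensus(s_copies,
                                      min_depth = config$min_consensus_depth,
                                      name = paste(f, s, sep = "_")))
      aligned <- substr_columns(s_copies, s_cons$kept_columns)
      div <- stage("copy_divergence",
                   copy_consensus_divergence(aligned, s_cons$seq))
      bursts[[s]] <- burst_age(div$mean_dist, config$neutral_rate,
                               te_family = f, species = s)
    }

    # tree concordance
    presence <- setNames(species_tree$tip.label %in% carriers,
                         species_tree$tip.label)
    dollo <- if (ape::is.rooted(species_tree)) {
      stage("dollo", dollo_min_losses(species_tree, presence))
    } else {
      list(gains = NA_integer_, losses = NA_integer_)
    }
    copy_tree <- if (length(copies) >= 3L) stage("nj_copy_tree", nj_tree(te_dm)) else NULL
    mono <- if (!is.null(copy_tree)) {
      stage("copy_monophyly", copy_monophyly(copy_tree, sp_of))
    } else NULL
    rf <- NULL
    if (length(carriers) >= 4L) {
      mean_d <- matrix(0, length(carriers), length(carriers),
                       dimnames = list(carriers, carriers))
      for (i in seq_along(carriers)) for (j in seq_along(carriers)) {
        if (i < j) {
          v <- mean(te_dm$d[names(sp_of)[sp_of == carriers[i]],
                            names(sp_of)[sp_of == carriers[j]]])
          mean_d[i, j] <- mean_d[j, i] <- v
        }
      }
      if (!anyNA(mean_d)) {
        sp_nj <- stage("species_nj", nj_tree(mean_d))
        pruned <- ape::keep.tip(species_tree, carriers)
        rf <- stage("rf", rf_distance(sp_nj, pruned))
      }
    }

    report_families[[f]] <- list(
      consensus = list(
        length_bp = nchar(cons$seq),
        n_copies = cons$n_copies,
        min_depth = min(cons$depth_profile),
        tir_length = if (is.null(cons$tir)) NA_integer_ else unname(cons$tir["length"]),
        tir_mismatches = if (is.null(cons$tir)) NA_integer_ else unname(cons$tir["mismatches"]),
        longest_orf_aa = cons$longest_orf$aa_length
      ),
      carriers = carriers,
      htt_calls = lapply(calls, function(cl) {
        list(taxon_pair = cl$taxon_pair, verdict = cl$verdict,
             margin = cl$margin, te = cl$te_dist_summary[c("mean", "min", "max")],
             genes = cl$gene_dist_summary[c("mean", "min", "max")],
             n_genes = cl$n_genes, mw_p = cl$mw_p)
      }),
      burst_ages = lapply(bursts, function(b) {
        list(species = b$species, mean_copy_consensus_dist = b$mean_copy_consensus_dist,
             neutral_rate = b$neutral_rate, age_myr = b$age,
             age_myr_2sf = signif(b$age, 2))
      }),
      concordance = list(
        dollo_gains = dollo$gains, dollo_losses = dollo$losses,
        n_monophyletic_species = if (is.null(mono)) NA_integer_ else mono$n_monophyletic,
        n_species_with_multiple_copies = if (is.null(mono)) NA_integer_ else mono$n_species_with_multiple_copies,
        rf_distance = if (is.null(rf)) NA_integer_ else rf$rf,
        max_rf = if (is.null(rf)) NA_integer_ else rf$max_rf
      )
    )
  }

  report <- list(
    config = unclass(config),
    coordinate_convention = "1-based inclusive in hit tables; minus-strand hits stored in element orientation",
    n_genes = length(genes),
    species = species_tree$tip.label,
    families = report_families
  )
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tsv <- if (length(htt_rows) > 0L) do.call(rbind, htt_rows) else
    data.frame(te_family = character(), taxon_a = character(),
               taxon_b = character(), verdict = character())
  write.table(tsv, file.path(out_dir, "report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(report)
}

# Subset aligned sequences to the given columns (used to place copies in
# consensus coordinates after low-depth columns are dropped).
substr_columns <- function(seqs, columns) {
  m <- as_alignment_matrix(seqs)
  alignment_to_seqs(m[, columns, drop = FALSE])
}
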