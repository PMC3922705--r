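#' Test transposon distances against the vertical-inheritance null
#'
#' Under vertical transmission, transposable elements evolve neutrally after
#' insertion and so accumulate divergence at least as fast as host genes
#' under purifying selection: between two taxa, TE distances should be at
#' least as large as orthologous gene distances. The verdict is `HT` when
#' the TE distance range falls strictly below the gene range
#' (`max(te) < min(genes)`, optionally by at least `min_margin`),
#' `vertical-compatible` when `min(te) >= min(genes)`, and `indeterminate`
#' when the ranges overlap. A Mann-Whitney U p-value between the two lists
#' is reported as supporting evidence only; gene distances are not
#' exchangeable samples, so it never decides the verdict.
#'
#' @param te_dists Pairwise TE distances between the two taxa,
#'   substitutions/site.
#' @param gene_dists Orthologous gene distances between the two taxa,
#'   substitutions/site.
#' @param te_family Family name recorded on the call.
#' @param taxon_pair Length-2 character vector of taxon names.
#' @param min_margin Minimum `min(genes) - max(te)` separation required for
#'   an HT verdict, substitutions/site.
#' @return An object of class `htt_call` with the verdict, the margin
#'   `min(genes) - max(te)`, both distance summaries, `n_genes`, and `mw_p`.
#' @export
vertical_null_test <- function(te_dists, gene_dists, te_family = NA_character_,
                               taxon_pair = c(NA_character_, NA_character_),
                               min_margin = 0) {
  if (length(te_dists) == 0L || length(gene_dists) == 0L) {
    stop("both distance lists must be nonempty")
  }
  if (anyNA(te_dists) || anyNA(gene_dists)) stop("undefined distance in input")
  if (any(te_dists < 0) || any(gene_dists < 0)) stop("negative distance in input")
  te_s <- summarize_distances(te_dists)
  gene_s <- summarize_distances(gene_dists)
  margin <- gene_s$min - te_s$max
  verdict <- if (margin > min_margin) {
    "HT"
  } else if (te_s$min >= gene_s$min) {
    "vertical-compatible"
  } else {
    "indeterminate"
  }
  mw_p <- if (length(te_dists) > 0L && length(gene_dists) > 0L) {
    suppressWarnings(wilcox.test(te_dists, gene_dists)$p.value)
  } else NA_real_
  structure(list(
    te_family = te_family,
    taxon_pair = taxon_pair,
    verdict = verdict,
    margin = margin,
    te_dist_summary = te_s,
    gene_dist_summary = gene_s,
    n_genes = length(gene_dists),
    mw_p = mw_p
  ), class = "htt_call")
}

#' @export
print.htt_call <- function(x, ...) {
  cat(sprintf("<htt_call %s %s-%s: %s (margin %.4f subst/site)>\n",
              x$te_family, x$taxon_pair[1L], x$taxon_pair[2L],
              x$verdict, x$margin))
  cat(sprintf("  TE    mean/min/max: %.4f / %.4f / %.4f (n pairs = %d)\n",
              x$te_dist_summary$mean, x$te_dist_summary$min,
              x$te_dist_summary$max, x$te_dist_summary$n))
  cat(sprintf("  genes mean/min/max: %.4f / %.4f / %.4f (n genes = %d)\n",
              x$gene_dist_summary$mean, x$gene_dist_summary$min,
              x$gene_dist_summary$max, x$n_genes))
  invisible(x)
}

#' Mean Jukes-Cantor divergence of copies from their consensus
#'
#' Each copy's corrected distance to the family consensus is computed in
#' consensus coordinates; saturated copies (p >= 0.75) are excluded with a
#' warning. The mean divergence is the numerator of burst-age dating.
#'
#' @param copies Aligned copies in consensus coordinates (named character
#'   vector or matrix).
#' @param consensus A `consensus_element` or a plain consensus string of the
#'   same length as the copies.
#' @return A list with `mean_dist` (substitutions/site), `per_copy`
#'   distances, and `n_excluded` saturated copies.
#' @export
copy_consensus_divergence <- function(copies, consensus) {
  cons_seq <- if (inherits(consensus, "consensus_element")) consensus$seq else consensus
  m <- as_alignment_matrix(copies)
  if (nchar(cons_seq) != ncol(m)) {
    stop("copies are not in consensus coordinates (length mismatch)")
  }
  per <- setNames(numeric(nrow(m)), rownames(m))
  for (i in seq_len(nrow(m))) {
    pd <- p_distance(m[i, ], cons_seq)
    per[i] <- if (pd$p >= 0.75) NA_real_ else jc69_distance(pd$p)
  }
  n_excluded <- sum(is.na(per))
  if (n_excluded > 0L) {
    warning(n_excluded, " saturated copy(ies) excluded from mean divergence")
  }
  kept <- per[!is.na(per)]
  if (length(kept) == 0L) stop("all copies saturated; mean divergence undefined")
  list(mean_dist = mean(kept), per_copy = per, n_excluded = n_excluded)
}

#' Date a transposition burst from copy divergence
#'
#' Copies created during an amplification burst evolve neutrally and
#' independently afterwards, so the mean copy-to-consensus divergence
#' divided by the host's neutral substitution rate estimates the time since
#' the burst: `age = mean_dist / neutral_rate`.
#'
#' @param mean_dist Mean copy-to-consensus distance, substitutions/site.
#' @param neutral_rate Neutral substitution rate, substitutions/site/myr.
#'   No default: dating is refused unless a rate is supplied explicitly,
#'   because neutral rates are lineage-specific (none exists for isopods,
#'   for example).
#' @param te_family,species Optional labels recorded on the estimate.
#' @return An object of class `burst_age_estimate` with `age` in myr.
#' @export
burst_age <- function(mean_dist, neutral_rate, te_family = NA_character_,
                      species = NA_character_) {
  if (missing(neutral_rate) || is.null(neutral_rate) || is.na(neutral_rate)) {
    stop("no neutral substitution rate supplied; burst dating refused")
  }
  if (neutral_rate <= 0) stop("neutral_rate must be > 0")
  if (is.na(mean_dist) || mean_dist < 0) stop("mean_dist must be >= 0")
  structure(list(
    te_family = te_family,
    species = species,
    mean_copy_consensus_dist = mean_dist,
    neutral_rate = neutral_rate,
    age = mean_dist / neutral_rate
  ), class = "burst_age_estimate")
}

#' @export
print.burst_age_estimate <- function(x, ...) {
  cat(sprintf("<burst_age %s/%s: %s myr (mean dist %.4g / rate %.4g)>\n",
              x$te_family, x$species, signif(x$age, 2),
              x$mean_copy_consensus_dist, x$neutral_rate))
  invisible(x)
}
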