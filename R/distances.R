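#' Observed proportion of differing sites between two aligned sequences
#'
#' Columns where either sequence carries a gap or N are excluded
#' (pairwise deletion); `p` is the mismatch count over the remaining sites.
#'
#' @param a,b Aligned sequences (equal-length character strings).
#' @return A list with `p` (mismatch proportion) and `n_sites` (compared
#'   columns).
#' @export
p_distance <- function(a, b) {
  ca <- if (length(a) > 1L) a else strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- if (length(b) > 1L) b else strsplit(b, "", fixed = TRUE)[[1L]]
  if (length(ca) != length(cb)) stop("sequences are not aligned (unequal length)")
  ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  n <- sum(ok)
  if (n == 0L) stop("no comparable sites")
  list(p = sum(ca[ok] != cb[ok]) / n, n_sites = n)
}

#' Jukes-Cantor corrected distance
#'
#' `d = -(3/4) * log(1 - (4/3) * p)` substitutions/site. Undefined at and
#' beyond the JC69 saturation point p = 0.75.
#'
#' @param p Observed mismatch proportion(s) in `[0, 0.75)`.
#' @return Corrected distance(s), substitutions/site.
#' @export
jc69_distance <- function(p) {
  if (any(p < 0)) stop("negative mismatch proportion")
  if (any(p >= 0.75)) stop("saturated distance: p >= 0.75 is undefined under JC69")
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise Jukes-Cantor distance matrix
#'
#' Applies [p_distance()] then [jc69_distance()] to every pair. Saturated
#' pairs (p >= 0.75) are flagged `NA` rather than dropped, with a warning.
#'
#' @param aln Named character vector of aligned sequences, or a character
#'   matrix (rows = sequences).
#' @param deletion `"pairwise"` (default) excludes gap/N columns per pair;
#'   `"complete"` excludes any column with a gap or N in any sequence before
#'   comparison.
#' @return An object of class `distance_matrix`: list with `labels`,
#'   `d` (symmetric matrix, substitutions/site, `NA` where saturated or no
#'   comparable sites) and `n_sites` (per-pair compared columns).
#' @export
pairwise_matrix <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  m <- as_alignment_matrix(aln)
  if (nrow(m) < 2L) stop("need at least 2 sequences")
  if (deletion == "complete") {
    informative <- colSums(!(m == "A" | m == "C" | m == "G" | m == "T")) == 0L
    if (!any(informative)) stop("no comparable sites under complete deletion")
    m <- m[, informative, drop = FALSE]
  }
  n <- nrow(m)
  labels <- rownames(m)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  ns <- matrix(0L, n, n, dimnames = list(labels, labels))
  diag(ns) <- ncol(m)
  n_saturated <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      pd <- tryCatch(p_distance(m[i, ], m[j, ]), error = function(e) NULL)
      if (is.null(pd)) {
        d[i, j] <- d[j, i] <- NA_real_
        next
      }
      ns[i, j] <- ns[j, i] <- pd$n_sites
      if (pd$p >= 0.75) {
        d[i, j] <- d[j, i] <- NA_real_
        n_saturated <- n_saturated + 1L
      } else {
        d[i, j] <- d[j, i] <- jc69_distance(pd$p)
      }
    }
  }
  if (n_saturated > 0L) {
    warning(n_saturated, " saturated pair(s) flagged NA (p >= 0.75)")
  }
  structure(list(labels = labels, d = d, n_sites = ns), class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix: %d taxa, JC69 substitutions/site>\n",
              length(x$labels)))
  print(round(x$d, 4))
  invisible(x)
}

#' Trim poorly covered alignment columns
#'
#' Removes columns whose fraction of gaps plus N exceeds
#' `max_missing_fraction` (strict `>`: a column missing in exactly that
#' fraction of sequences is kept). Row order is preserved.
#'
#' @param aln Named character vector of aligned sequences or character matrix.
#' @param max_missing_fraction Proportion in `[0, 1)`.
#' @return Trimmed alignment in the same representation as the input.
#' @export
trim_columns <- function(aln, max_missing_fraction = 0.25) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction < 1)
  m <- as_alignment_matrix(aln)
  missing_frac <- colSums(m == "-" | m == "N") / nrow(m)
  keep <- missing_frac <= max_missing_fraction
  if (!any(keep)) stop("all columns removed by trimming")
  out <- m[, keep, drop = FALSE]
  if (is.matrix(aln)) out else alignment_to_seqs(out)
}

#' Summarize a set of pairwise distances
#'
#' @param dm A `distance_matrix`, or a numeric vector of distances.
#' @param pairs For a `distance_matrix`: a 2-column matrix (or list of
#'   length-2 vectors) of label pairs to summarize; default all pairs.
#' @return A list with `mean`, `min`, `max` (substitutions/site), their
#'   percent forms (`mean_pct`, ...), and `n` pairs.
#' @export
summarize_distances <- function(dm, pairs = NULL) {
  if (is.numeric(dm)) {
    vals <- dm
  } else {
    stopifnot(inherits(dm, "distance_matrix"))
    if (is.null(pairs)) {
      vals <- dm$d[upper.tri(dm$d)]
      pair_names <- NULL
    } else {
      if (is.list(pairs)) pairs <- do.call(rbind, pairs)
      missing_lab <- setdiff(unique(as.vector(pairs)), dm$labels)
      if (length(missing_lab) > 0L) {
        stop("label(s) not in distance matrix: ", paste(missing_lab, collapse = ", "))
      }
      vals <- dm$d[cbind(pairs[, 1L], pairs[, 2L])]
      pair_names <- paste(pairs[, 1L], pairs[, 2L], sep = ":")
    }
    if (anyNA(vals)) {
      bad <- if (is.null(pair_names)) "some pairs" else
        paste(pair_names[is.na(vals)], collapse = ", ")
      stop("undefined (saturated) distance for: ", bad)
    }
  }
  if (length(vals) == 0L) stop("no distances selected")
  if (anyNA(vals)) stop("undefined distance in input")
  list(mean = mean(vals), min = min(vals), max = max(vals),
       mean_pct = 100 * mean(vals), min_pct = 100 * min(vals),
       max_pct = 100 * max(vals), n = length(vals))
}
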