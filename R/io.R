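# Allowed residue alphabet after normalization. IUPAC ambiguity codes other
# than N carry no information under Jukes-Cantor and are mapped to N on read.
.DNA_ALPHABET <- c("A", "C", "G", "T", "N", "-")
.IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Read nucleotide sequences from a FASTA file
#'
#' Sequences are uppercased, `U` is mapped to `T` and IUPAC ambiguity codes
#' other than `N` are mapped to `N` (they carry no information under the
#' Jukes-Cantor model used downstream).
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences; names are the FASTA ids
#'   (first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1L)
  if (any(!nzchar(ids))) stop("empty sequence id in ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate sequence id(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  seqs <- chartr(paste(.IUPAC_AMBIG, collapse = ""),
                 strrep("N", length(.IUPAC_AMBIG)), seqs)
  if (any(!nzchar(seqs))) {
    stop("empty sequence(s) in ", path, ": ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  bad <- grepl(paste0("[^", paste(.DNA_ALPHABET, collapse = ""), "]"), seqs)
  if (any(bad)) {
    stop("non-nucleotide characters in sequence(s): ",
         paste(ids[bad], collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a single tree from a newick file
#'
#' @param path Path to a newick file containing one tree.
#' @return An [ape::read.tree] `phylo` object with unique leaf labels.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("newick file not found: ", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("newick parse error in ", path, ": ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("newick parse error in ", path)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single tree in ", path,
                               ", found ", length(tr))
    tr <- tr[[1L]]
  }
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup) > 0L) {
    stop("duplicate leaf label(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  tr
}

#' Write a tree to a newick file
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a 12-column tabular similarity-search hit file
#'
#' Consumes the standard tab-separated output of BLAST-like tools
#' (query id, subject id, percent identity, alignment length, mismatches,
#' gap opens, query start/end, subject start/end, e-value, bit score).
#' Subject coordinates are normalized so that start <= end, with the
#' original orientation recorded in a `strand` column.
#'
#' @param path Path to the tab-separated hit table.
#' @return A data.frame with columns `query_id`, `subject_id`,
#'   `pct_identity`, `aln_length`, `subject_start`, `subject_end`, `strand`.
#' @export
read_hits_table <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("hit table is empty: ", path)
    return(data.frame(query_id = character(), subject_id = character(),
                      pct_identity = numeric(), aln_length = integer(),
                      subject_start = integer(), subject_end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1L]
    stop("expected 12 tab-separated columns, found ", nf[bad],
         " at line ", bad, " of ", path)
  }
  m <- do.call(rbind, fields)
  sstart <- as.integer(m[, 9L])
  send <- as.integer(m[, 10L])
  strand <- ifelse(sstart <= send, "+", "-")
  hits <- data.frame(
    query_id = m[, 1L],
    subject_id = m[, 2L],
    pct_identity = as.numeric(m[, 3L]),
    aln_length = as.integer(m[, 4L]),
    subject_start = pmin(sstart, send),
    subject_end = pmax(sstart, send),
    strand = strand,
    stringsAsFactors = FALSE
  )
  if (any(is.na(hits$pct_identity)) || any(is.na(hits$aln_length))) {
    stop("non-numeric identity or length field in ", path)
  }
  if (any(hits$pct_identity < 0 | hits$pct_identity > 100)) {
    stop("percent identity outside [0, 100] in ", path)
  }
  if (any(hits$aln_length < 1L)) stop("alignment length < 1 in ", path)
  hits
}

#' Pipeline configuration
#'
#' Holds the thresholds applied across the pipeline. Defaults are the
#' values used throughout the package's reference analysis: hits are kept
#' above 90% identity over more than 500 bp, consensus columns require five
#' covering copies, alignment columns missing in more than 25% of sequences
#' are trimmed, and burst ages use the Drosophila melanogaster neutral rate
#' of 0.0346 substitutions/site/myr.
#'
#' @param min_identity Minimum percent identity for similarity hits (strict).
#' @param min_hit_length Minimum hit alignment length in bp (strict).
#' @param min_consensus_depth Minimum copy coverage per consensus column.
#' @param max_missing_fraction Column-trim threshold (gaps+N fraction, strict).
#' @param neutral_rate Neutral substitution rate in substitutions/site/myr.
#' @param min_margin Minimum gene_min - te_max separation demanded for an
#'   HT verdict (substitutions/site).
#' @param gap_deletion `"pairwise"` or `"complete"` deletion of gap/N sites
#'   in distance computation.
#' @param rng_seed Integer seed controlling all randomness.
#' @return An object of class `htt_config`.
#' @export
htt_config <- function(min_identity = 90,
                       min_hit_length = 500,
                       min_consensus_depth = 5L,
                       max_missing_fraction = 0.25,
                       neutral_rate = 0.0346,
                       min_margin = 0,
                       gap_deletion = c("pairwise", "complete"),
                       rng_seed = 1L) {
  gap_deletion <- match.arg(gap_deletion)
  stopifnot(min_identity > 0, min_hit_length > 0, min_consensus_depth > 0,
            max_missing_fraction >= 0, max_missing_fraction < 1,
            neutral_rate > 0, min_margin >= 0)
  structure(list(
    min_identity = min_identity,
    min_hit_length = min_hit_length,
    min_consensus_depth = as.integer(min_consensus_depth),
    max_missing_fraction = max_missing_fraction,
    neutral_rate = neutral_rate,
    min_margin = min_margin,
    gap_deletion = gap_deletion,
    rng_seed = as.integer(rng_seed)
  ), class = "htt_config")
}

#' @export
print.htt_config <- function(x, ...) {
  cat("httdetect pipeline configuration:\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}

# Convert a set of equal-length sequences into a character matrix
# (rows = sequences, columns = alignment sites).
as_alignment_matrix <- function(seqs) {
  if (is.matrix(seqs)) return(seqs)
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("sequences are not aligned: lengths ", paste(unique(lens), collapse = ", "))
  }
  if (lens[1L] < 1L) stop("alignment has zero columns")
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

alignment_to_seqs <- function(m) {
  stopifnot(is.matrix(m))
  out <- apply(m, 1L, paste, collapse = "")
  names(out) <- rownames(m)
  out
}
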