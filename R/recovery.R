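#' Filter similarity hits by identity and length
#'
#' Keeps hits with strictly more than `min_identity` percent identity over
#' strictly more than `min_hit_length` aligned bp — the screen used to call
#' a sequence a candidate copy of a transferred element family.
#'
#' @param hits Data.frame from [read_hits_table()].
#' @param min_identity Percent identity threshold (strict `>`).
#' @param min_hit_length Alignment length threshold in bp (strict `>`).
#' @return The subset of `hits` passing both thresholds, order preserved.
#' @export
filter_hits <- function(hits, min_identity = 90, min_hit_length = 500) {
  stopifnot(min_identity > 0, min_hit_length > 0)
  keep <- hits$pct_identity > min_identity & hits$aln_length > min_hit_length
  hits[keep, , drop = FALSE]
}

#' Extract copy sequences for filtered hits
#'
#' Pulls the subject interval of each hit out of the subject sequences
#' (1-based inclusive coordinates); minus-strand hits are
#' reverse-complemented so every copy is returned in element orientation.
#'
#' @param hits Data.frame from [read_hits_table()] / [filter_hits()].
#' @param subjects Named character vector of subject sequences.
#' @return Named character vector of copy sequences
#'   (`<subject>:<start>-<end>(<strand>)`).
#' @export
extract_hit_sequences <- function(hits, subjects) {
  missing_subj <- setdiff(unique(hits$subject_id), names(subjects))
  if (length(missing_subj) > 0L) {
    stop("subject sequence(s) not provided: ", paste(missing_subj, collapse = ", "))
  }
  out <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    s <- substr(subjects[[hits$subject_id[i]]],
                hits$subject_start[i], hits$subject_end[i])
    if (nchar(s) < hits$subject_end[i] - hits$subject_start[i] + 1L) {
      stop("hit ", i, " extends past the end of subject ", hits$subject_id[i])
    }
    out[i] <- if (hits$strand[i] == "-") revcomp(s) else s
  }
  names(out) <- sprintf("%s:%d-%d(%s)", hits$subject_id, hits$subject_start,
                        hits$subject_end, hits$strand)
  out
}

#' Build a consensus element from aligned copies
#'
#' Per alignment column, coverage depth is the number of informative
#' residues (A/C/G/T; gaps and N are non-informative). Columns with depth
#' below `min_depth` are excluded; each retained column takes the plurality
#' residue, with ties broken in fixed order A < C < G < T for determinism.
#' The consensus is reported gap-free.
#'
#' @param copies Aligned copies: a named character vector of equal-length
#'   sequences or a character matrix (rows = copies).
#' @param min_depth Minimum number of copies covering a retained column.
#' @param name Family name recorded on the consensus.
#' @return An object of class `consensus_element` with fields `name`, `seq`,
#'   `depth_profile` (per retained column), and annotation slots (`tir`,
#'   `tsd_is_TA`, `longest_orf`) filled by [annotate_element()].
#' @export
build_consensus <- function(copies, min_depth = 5L, name = "consensus") {
  m <- as_alignment_matrix(copies)
  if (nrow(m) < min_depth) {
    stop("insufficient coverage: ", nrow(m), " copies < min_depth ", min_depth)
  }
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(b) colSums(m == b), numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L, dimnames = list(NULL, bases))
  depth <- rowSums(counts)
  keep <- depth >= min_depth
  if (!any(keep)) stop("insufficient coverage: no column reaches depth ", min_depth)
  # plurality; max.col(ties.method = "first") realizes the A<C<G<T tie-break
  winner <- bases[max.col(counts[keep, , drop = FALSE], ties.method = "first")]
  structure(list(
    name = name,
    seq = paste(winner, collapse = ""),
    depth_profile = as.integer(depth[keep]),
    kept_columns = which(keep),
    n_copies = nrow(m),
    tir = NULL,
    tsd_is_TA = NA,
    longest_orf = NULL
  ), class = "consensus_element")
}

#' @export
print.consensus_element <- function(x, ...) {
  cat(sprintf("<consensus_element %s: %d bp from %d copies, min depth %d>\n",
              x$name, nchar(x$seq), x$n_copies, min(x$depth_profile)))
  if (!is.null(x$tir)) {
    cat(sprintf("  TIR: %d bp (%d mismatches)\n", x$tir["length"], x$tir["mismatches"]))
  }
  if (!is.null(x$longest_orf)) {
    cat(sprintf("  longest ORF: %d aa (frame %d, strand %s)\n",
                x$longest_orf$aa_length, x$longest_orf$frame, x$longest_orf$strand))
  }
  if (!is.na(x$tsd_is_TA)) cat("  TA target-site duplication:", x$tsd_is_TA, "\n")
  invisible(x)
}

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "", fixed = TRUE)[[1L]]),
                                 collapse = ""))
}

#' Detect terminal inverted repeats
#'
#' Finds the longest prefix whose reverse complement matches the sequence's
#' suffix with at most `max_mismatch` mismatches (ungapped, end-anchored —
#' appropriate for the short terminal TIRs of Tc1/Mariner elements).
#'
#' @param seq Nucleotide string.
#' @param min_len Minimum TIR length to report, bp.
#' @param max_mismatch Maximum mismatches tolerated between prefix and
#'   reverse-complemented suffix.
#' @return A named integer vector `c(length=, mismatches=)`, or `NULL` when
#'   no terminal repeat of at least `min_len` bp is found.
#' @export
detect_tirs <- function(seq, min_len = 10L, max_mismatch = 2L) {
  n <- nchar(seq)
  if (n < 2L * min_len) stop("sequence shorter than twice min_len")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  comp <- chartr("ACGTN", "TGCAN", chars)
  max_l <- n %/% 2L
  for (l in seq(max_l, min_len)) {
    prefix <- chars[seq_len(l)]
    # reverse complement of the l-bp suffix, aligned against the prefix
    suffix_rc <- rev(comp[seq(n - l + 1L, n)])
    mm <- sum(prefix != suffix_rc)
    if (mm <= max_mismatch) {
      return(c(length = l, mismatches = as.integer(mm)))
    }
  }
  NULL
}

#' Check for a TA target-site duplication
#'
#' Tc1/Mariner elements duplicate a TA dinucleotide on insertion; both
#' flanks of a genuine copy therefore read TA.
#'
#' @param left_flank,right_flank The 2-nt host flanks of a copy.
#' @return `TRUE` iff both flanks equal "TA".
#' @export
check_tsd <- function(left_flank, right_flank) {
  identical(toupper(left_flank), "TA") && identical(toupper(right_flank), "TA")
}

translate_codons <- function(codons) {
  # standard genetic code; codons containing N or gaps translate to X
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  aa
}

frame_codons <- function(chars, offset) {
  n <- length(chars)
  ncod <- (n - offset) %/% 3L
  if (ncod < 1L) return(character(0))
  idx <- offset + seq_len(ncod * 3L)
  m <- matrix(chars[idx], nrow = 3L)
  paste0(m[1L, ], m[2L, ], m[3L, ])
}

#' Find the longest open reading frame across all six frames
#'
#' An ORF runs from an ATG to the next in-frame stop codon; its length in
#' amino acids excludes the stop. Codons containing N translate to X, never
#' to a stop. Used to check whether an element consensus encodes an intact
#' transposase.
#'
#' @param seq Nucleotide string (N allowed).
#' @return A list with `aa_length` (0 when no ATG..stop ORF exists),
#'   `frame` (1-3), `strand` ("+"/"-"), `nt_start`/`nt_end` (1-based on the
#'   reported strand), and `is_intact` (no internal stop; true by
#'   construction for the reported ORF).
#' @export
find_longest_orf <- function(seq) {
  best <- list(aa_length = 0L, frame = NA_integer_, strand = NA_character_,
               nt_start = NA_integer_, nt_end = NA_integer_, is_intact = NA)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") toupper(seq) else revcomp(toupper(seq))
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    for (offset in 0:2) {
      codons <- frame_codons(chars, offset)
      if (length(codons) == 0L) next
      aa <- translate_codons(codons)
      starts <- which(codons == "ATG")
      stops <- which(aa == "*")
      for (st in starts) {
        stop_after <- stops[stops > st]
        if (length(stop_after) == 0L) break  # later ATGs have no stop either
        sp <- stop_after[1L]
        len <- sp - st  # aa count from ATG to codon before the stop
        if (len > best$aa_length) {
          best <- list(aa_length = as.integer(len),
                       frame = offset + 1L,
                       strand = strand,
                       nt_start = offset + (st - 1L) * 3L + 1L,
                       nt_end = offset + sp * 3L,
                       is_intact = TRUE)
        }
      }
    }
  }
  best
}

#' Assess whether a copy's transposase ORF is intact
#'
#' A copy is intact when, read in the frame and span of the consensus ORF,
#' it contains no premature stop codon — the copy-level analogue of a
#' transposase "devoid of non-sense mutations". Gapped or N-containing
#' codons translate to X and are not counted as stops.
#'
#' @param copy_seq Copy sequence in consensus coordinates (same length).
#' @param consensus_orf The `longest_orf` entry of the family consensus.
#' @return `TRUE` iff no stop codon occurs before the ORF's final codon.
#' @export
copy_orf_intact <- function(copy_seq, consensus_orf) {
  if (is.null(consensus_orf) || consensus_orf$aa_length == 0L) {
    stop("consensus has no ORF to assess against")
  }
  s <- toupper(copy_seq)
  if (consensus_orf$strand == "-") s <- revcomp(s)
  span <- substr(s, consensus_orf$nt_start, consensus_orf$nt_end)
  span <- gsub("-", "N", span, fixed = TRUE)
  chars <- strsplit(span, "", fixed = TRUE)[[1L]]
  codons <- frame_codons(chars, 0L)
  aa <- translate_codons(codons)
  internal <- aa[seq_len(length(aa) - 1L)]  # last codon is the consensus stop
  !any(internal == "*")
}

#' Annotate a consensus element's anatomy
#'
#' Fills the TIR, target-site-duplication and longest-ORF slots of a
#' [build_consensus()] result.
#'
#' @param elem A `consensus_element`.
#' @param min_tir_len,max_tir_mismatch Passed to [detect_tirs()].
#' @param left_flank,right_flank Optional 2-nt host flanks for the TSD check.
#' @return The annotated `consensus_element`.
#' @export
annotate_element <- function(elem, min_tir_len = 10L, max_tir_mismatch = 2L,
                             left_flank = NULL, right_flank = NULL) {
  stopifnot(inherits(elem, "consensus_element"))
  elem$tir <- detect_tirs(elem$seq, min_len = min_tir_len,
                          max_mismatch = max_tir_mismatch)
  elem$longest_orf <- find_longest_orf(elem$seq)
  if (!is.null(left_flank) && !is.null(right_flank)) {
    elem$tsd_is_TA <- check_tsd(left_flank, right_flank)
  }
  elem
}
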