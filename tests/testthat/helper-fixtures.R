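# Shared fixture builders for the suite. Everything is generated in code;
# no binary or downloaded data.

write_temp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

# Mutate exactly `k` distinct sites of a sequence to a different base.
mutate_sites <- function(seq, k) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  idx <- sample(seq_along(chars), k)
  bases <- c("A", "C", "G", "T")
  for (i in idx) chars[i] <- sample(setdiff(bases, chars[i]), 1L)
  paste(chars, collapse = "")
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A synthetic Tc1/Mariner-style element: TIR + filler + ORF + filler +
# reverse-complemented TIR, with exact total length and ORF size. Stands in
# for real deposited consensuses, which are not bundled with the package.
synthetic_mariner_element <- function(total_bp, tir_bp, orf_aa, seed) {
  set.seed(seed)
  revcomp_str <- function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
  }
  tir <- random_seq(tir_bp)
  # ORF: ATG + (orf_aa - 1) non-stop, non-ATG-irrelevant codons + stop
  codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                              c("A","C","G","T")), 1L, paste, collapse = "")
  stops <- c("TAA", "TAG", "TGA")
  safe <- setdiff(codons, c(stops, "ATG"))
  orf <- paste0("ATG", paste(sample(safe, orf_aa - 1L, replace = TRUE),
                             collapse = ""), "TAA")
  orf_nt <- nchar(orf)
  filler_total <- total_bp - 2L * tir_bp - orf_nt
  stopifnot(filler_total >= 2L)
  left <- filler_total %/% 2L
  right <- filler_total - left
  # fillers free of ATG (so no longer ORF can start) and breaking any frame:
  # use C/T-only filler, which can contain neither ATG nor any stop codon
  filler <- function(n) paste(sample(c("C", "T"), n, replace = TRUE),
                              collapse = "")
  f1 <- filler(left); f2 <- filler(right)
  # pin the bases flanking the TIRs so the inverted repeat cannot extend by
  # chance past its designed length (C vs complement(C)=G never matches)
  substr(f1, 1L, 1L) <- "C"
  substr(f2, right, right) <- "C"
  seq <- paste0(tir, f1, orf, f2, revcomp_str(tir))
  stopifnot(nchar(seq) == total_bp)
  seq
}

# Brute-force TIR oracle: longest end-anchored prefix/suffix inverted
# repeat, checked by direct substring comparison on the reverse complement.
tir_oracle <- function(seq, min_len, max_mismatch) {
  n <- nchar(seq)
  rc <- chartr("ACGTN", "TGCAN",
               paste(rev(strsplit(seq, "", fixed = TRUE)[[1L]]), collapse = ""))
  for (l in seq(n %/% 2L, min_len)) {
    a <- strsplit(substr(seq, 1L, l), "")[[1L]]
    b <- strsplit(substr(rc, 1L, l), "")[[1L]]  # revcomp of the l-bp suffix
    mm <- sum(a != b)
    if (mm <= max_mismatch) return(c(length = l, mismatches = mm))
  }
  NULL
}

# Brute-force split oracle: is `s` (a sorted character vector of leaves)
# one side of an edge-split of the tree? Checked by deleting each edge and
# collecting the leaf component by BFS over the remaining edges.
is_split_bruteforce <- function(tree, s) {
  edges <- tree$edge
  n_tip <- length(tree$tip.label)
  for (e in seq_len(nrow(edges))) {
    rest <- edges[-e, , drop = FALSE]
    adj <- rbind(rest, rest[, 2:1, drop = FALSE])
    comp <- edges[e, 2L]
    frontier <- comp
    while (length(frontier) > 0L) {
      nb <- adj[adj[, 1L] %in% frontier, 2L]
      nb <- setdiff(nb, comp)
      comp <- c(comp, nb)
      frontier <- nb
    }
    leaves <- sort(tree$tip.label[comp[comp <= n_tip]])
    if (identical(leaves, s)) return(TRUE)
  }
  FALSE
}

# Exhaustive Dollo oracle: minimum number of loss edges (within the clade
# of the single gain at the MRCA of present leaves) reproducing a
# presence pattern. Enumerates all subsets of candidate edges.
dollo_oracle <- function(tree, presence) {
  pres <- presence[tree$tip.label]
  present_leaves <- tree$tip.label[pres]
  if (length(present_leaves) == 1L) return(0L)
  mrca <- ape::getMRCA(tree, present_leaves)
  n_tip <- length(tree$tip.label)
  parent <- integer(n_tip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  # leaves below mrca and the edge path from mrca to each
  below <- function(node) {
    if (node <= n_tip) return(node)
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    unlist(lapply(kids, below))
  }
  clade_leaves <- below(mrca)
  path_edges <- lapply(clade_leaves, function(l) {
    p <- integer(0)
    v <- l
    while (v != mrca) {
      p <- c(p, v)  # identify each edge by its child node
      v <- parent[v]
    }
    p
  })
  # candidate loss edges: all edges within the clade
  cand <- unique(unlist(path_edges))
  target <- pres[tree$tip.label[clade_leaves]]
  best <- Inf
  for (mask in 0:(2^length(cand) - 1L)) {
    S <- cand[bitwAnd(bitwShiftL(1L, seq_along(cand) - 1L), mask) != 0L]
    if (length(S) >= best) next
    got <- vapply(path_edges, function(p) !any(p %in% S), logical(1))
    if (all(got == target)) best <- length(S)
  }
  as.integer(best)
}
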