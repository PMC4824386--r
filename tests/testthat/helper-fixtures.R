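# construct a read pair by hand (bypassing the simulator)
make_pair <- function(seq1, seq2, qual1, qual2, offset1 = 0L, offset2 = 0L,
                      id = "p1", amplicon = "amplicon") {
  structure(list(id = id, amplicon = amplicon,
                 seq1 = seq1, qual1 = as.integer(qual1), offset1 = offset1,
                 seq2 = seq2, qual2 = as.integer(qual2), offset2 = offset2),
            class = "read_pair")
}

# a fully accepted single-read "consensus" (no error suppression), used to
# contrast raw first-read error rates with merged-read error rates
raw_read_as_consensus <- function(pair, which = 1L) {
  seqc <- strsplit(pair[[paste0("seq", which)]], "")[[1]]
  structure(list(id = pair$id, amplicon = pair$amplicon,
                 offset = pair[[paste0("offset", which)]],
                 bases = seqc, accepted = rep(TRUE, length(seqc)),
                 status = "merged"),
            class = "consensus_read")
}

# presence/absence matrix of tree mutations across a set of sampled leaves
leaf_presence <- function(tree, leaves) {
  tv <- truth_variants(tree)
  m <- vapply(leaves, function(leaf) {
    anc <- if (nchar(leaf) > 0) substring(leaf, 1, seq_len(nchar(leaf)))
           else character(0)
    tv$id %in% c(tree$founder_mutations,
                 unlist(tree$branch_mutations[anc]))
  }, logical(nrow(tv)))
  rownames(m) <- tv$id
  colnames(m) <- leaves
  m[rowSums(m) > 0, , drop = FALSE]
}

# true clades (as sets of sampled leaves) implied by a division tree,
# restricted to the sampled leaves; excludes the root set and singletons
true_clades <- function(tree, leaves) {
  anc <- unique(unlist(lapply(leaves, function(leaf)
    substring(leaf, 1, seq_len(nchar(leaf))))))
  cl <- lapply(anc, function(a) sort(leaves[startsWith(leaves, a)]))
  cl <- unique(cl[lengths(cl) > 1 & lengths(cl) < length(leaves)])
  cl
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# canonical representation of a clade set for topology comparison
clade_keys <- function(clades) {
  sort(vapply(clades, function(x) paste(sort(x), collapse = "|"), ""))
}
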