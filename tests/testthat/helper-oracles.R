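# Independent, brute-force oracles used against the package implementation.
# These deliberately avoid the package's internal code paths.

# p-distance by explicit character loop (pairwise deletion, plain bases only)
oracle_pdist <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  stopifnot(length(ca) == length(cb))
  bases <- c("A", "C", "G", "T")
  comparable <- 0L; mismatch <- 0L
  for (i in seq_along(ca)) {
    if (ca[i] %in% bases && cb[i] %in% bases) {
      comparable <- comparable + 1L
      if (ca[i] != cb[i]) mismatch <- mismatch + 1L
    }
  }
  if (comparable == 0L) return(NA_real_)
  mismatch / comparable
}

# minimum single-column parsimony cost by enumerating every internal-node
# state assignment (leaves constrained to their allowed state sets)
oracle_fitch_column <- function(tree, leaf_states) {
  tree <- ape::unroot(tree)
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  edges <- tree$edge
  grids <- c(leaf_states[tree$tip.label], rep(list(1:4), m))
  sizes <- vapply(grids, length, 1L)
  idx <- rep(1L, n + m)
  best <- Inf
  repeat {
    assign <- vapply(seq_len(n + m), function(k) grids[[k]][idx[k]], 1L)
    cost <- sum(assign[edges[, 1]] != assign[edges[, 2]])
    if (cost < best) best <- cost
    k <- 1L
    while (k <= n + m) {
      idx[k] <- idx[k] + 1L
      if (idx[k] <= sizes[k]) break
      idx[k] <- 1L; k <- k + 1L
    }
    if (k > n + m) break
  }
  best
}

# bipartitions of a tree by adjacency-list BFS over each internal edge
# (independent of ape::prop.part and of barcodeval::tree_splits)
oracle_splits <- function(tree) {
  tree <- ape::unroot(tree)
  n <- ape::Ntip(tree)
  edges <- tree$edge
  adj <- list()
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[as.character(a)]] <- c(adj[[as.character(a)]], b)
    adj[[as.character(b)]] <- c(adj[[as.character(b)]], a)
  }
  ref <- min(tree$tip.label)
  out <- character()
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    if (b <= n) next  # trivial split
    # tips on b's side when edge (a,b) is cut
    side_nodes <- reach_cut(adj, a, b)
    side <- tree$tip.label[side_nodes[side_nodes <= n]]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) < 2 || length(side) > n - 2) next
    out <- c(out, paste(sort(side), collapse = ","))
  }
  sort(unique(out))
}

# nodes reachable from `start` without crossing the (cut_from, start) edge
reach_cut <- function(adj, cut_from, start) {
  seen <- c(start)
  queue <- start
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[as.character(v)]]) {
      if (v == start && w == cut_from) next
      if (!(w %in% seen)) { seen <- c(seen, w); queue <- c(queue, w) }
    }
  }
  seen
}

# monophyly by rooting at an outside tip and comparing MRCA descendants
oracle_monophyletic <- function(tree, members) {
  n <- ape::Ntip(tree)
  if (length(members) <= 1L || length(members) >= n - 1L) return(TRUE)
  out_tip <- setdiff(tree$tip.label, members)[1L]
  rt <- ape::root(tree, outgroup = out_tip, resolve.root = TRUE)
  mrca <- ape::getMRCA(rt, members)
  desc <- ape::extract.clade(rt, mrca)$tip.label
  setequal(desc, members)
}

# a small random alignment as a named character vector
random_seqs <- function(n_taxa, n_cols, seed) {
  set.seed(seed)
  stats::setNames(
    vapply(seq_len(n_taxa), function(i)
      paste(sample(c("A", "C", "G", "T"), n_cols, replace = TRUE),
            collapse = ""), character(1)),
    paste0("t", seq_len(n_taxa)))
}

# minimal three-marker library fixture built in code
tiny_library <- function() {
  meta <- data.frame(
    specimen_id = c("s1", "s2", "s3", "s4", "s5", "s6"),
    species = c("A x", "A x", "A y", "A y", "B z", "B z"),
    genus = c("A", "A", "A", "A", "B", "B"),
    family = c("F1", "F1", "F1", "F1", "F1", "F1"),
    order = "O1",
    source = c("fresh", "fresh", "fresh", "herbarium", "herbarium", "fresh"),
    collection_year = c(2009L, 2009L, 2009L, 1999L, 1989L, 2009L),
    stringsAsFactors = FALSE)
  aln1 <- marker_alignment("rbcL", c(
    s1 = "ACGTACGT", s2 = "ACGTACGT", s3 = "ACGTACGA", s4 = "ACGTACGA",
    s5 = "TCGTACGA", s6 = "TCGTACGA"))
  aln2 <- marker_alignment("ITS2", c(
    s1 = "GGGCCC", s2 = "GGGCCC", s3 = "GGACCC", s4 = "GGACCC",
    s5 = "GGGCCA", s6 = "GGGCCA"))
  link_dataset(list(aln1, aln2), meta)
}
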