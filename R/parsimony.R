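# Maximum parsimony: Fitch length, stepwise-addition starts, SPR hill
# climbing (phangorn engine), the parsimony ratchet, strict consensus and
# Newick I/O.  Trees are ape "phylo" objects, treated as unrooted and
# compared by their bipartition (split) sets.

# ---- sequence containers -> phangorn phyDat ---------------------------------

#' @noRd
sm_seqs <- function(x) {
  if (inherits(x, "supermatrix")) x$seqs
  else if (inherits(x, "marker_alignment")) x$seqs
  else if (is.character(x) && !is.null(names(x))) x
  else stop("expected a supermatrix, marker_alignment or named sequence vector")
}

#' @noRd
as_phydat <- function(x) {
  seqs <- sm_seqs(x)
  m <- do.call(rbind, strsplit(tolower(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  phangorn::phyDat(m, type = "DNA")
}

# phyDat with pattern weights implied by per-column weights.
#' @noRd
weighted_phydat <- function(data, col_weights) {
  idx <- attr(data, "index")
  w <- as.vector(tapply(col_weights, idx, sum))
  w[is.na(w)] <- 0
  attr(data, "weight") <- w
  data
}

# ---- bipartitions -----------------------------------------------------------

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge splits the leaf set in two; the split is canonicalised
#' as the sorted side that does not contain the lexicographically smallest
#' leaf label, serialised as a comma-joined string.
#'
#' @param tree A \code{phylo} tree.
#' @return Character vector of canonical split strings (possibly empty for a
#'   star tree).
#' @export
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  n <- ape::Ntip(tree)
  if (n < 4L) return(character())
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  ref <- min(labs)
  out <- character()
  for (clade in pp) {
    side <- labs[clade]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) < 2L || length(side) > n - 2L) next
    out <- c(out, paste(sort(side), collapse = ","))
  }
  sort(unique(out))
}

#' Canonical topology key of an unrooted tree
#'
#' Two trees over the same leaves get the same key exactly when they share
#' the same bipartition set.
#' @param tree A \code{phylo} tree.
#' @return Character scalar.
#' @export
topology_key <- function(tree) {
  paste(c(paste(sort(tree$tip.label), collapse = ","), tree_splits(tree)),
        collapse = ";")
}

#' @noRd
dedupe_trees <- function(trees) {
  keys <- vapply(trees, topology_key, character(1))
  trees[!duplicated(keys)]
}

# ---- Fitch length -----------------------------------------------------------

#' Fitch parsimony length of a tree
#'
#' Sum over columns of weight times the minimum number of state changes
#' under the Fitch set rule.  A base maps to its singleton set, an IUPAC
#' ambiguity code to its base set, and \code{'-'}/\code{'?'} to the full set
#' \{A,C,G,T\} (missing).  Polytomies are scored by merging children
#' sequentially, which is exact for binary trees (including the basal
#' trifurcation of unrooted binary trees).
#'
#' @param tree A \code{phylo} tree whose tips are matrix rows.
#' @param x A \code{supermatrix}, \code{marker_alignment} or named sequence
#'   vector.
#' @param weights Optional positive per-column weights (default all 1).
#' @return The weighted parsimony length (numeric scalar).
#' @export
fitch_length <- function(tree, x, weights = NULL) {
  seqs <- sm_seqs(x)
  missing_tips <- setdiff(tree$tip.label, names(seqs))
  if (length(missing_tips))
    stop("tree leaf absent from matrix: ",
         paste(missing_tips, collapse = ", "))
  bits <- encode_states(seqs[tree$tip.label])
  L <- ncol(bits)
  if (is.null(weights)) weights <- rep(1, L)
  stopifnot(length(weights) == L, all(weights > 0))
  tr <- stats::reorder(tree, "postorder")
  n_node <- max(tr$edge)
  S <- matrix(0L, n_node, L)
  S[seq_len(ape::Ntip(tr)), ] <- bits
  changes <- numeric(L)
  parents <- tr$edge[, 1L]
  children <- tr$edge[, 2L]
  for (e in seq_along(parents)) {
    p <- parents[e]; ch <- children[e]
    if (all(S[p, ] == 0L)) {
      S[p, ] <- S[ch, ]
    } else {
      inter <- bitwAnd(S[p, ], S[ch, ])
      empty <- inter == 0L
      changes[empty] <- changes[empty] + 1
      S[p, ] <- ifelse(empty, bitwOr(S[p, ], S[ch, ]), inter)
    }
  }
  sum(weights * changes)
}

# ---- tree surgery -----------------------------------------------------------

# Graft tip `label` onto edge row `e` of `tree` (edge lengths not preserved).
#' @noRd
insert_tip <- function(tree, label, e) {
  tree$edge.length <- rep(1, nrow(tree$edge))
  y <- structure(list(edge = matrix(c(2L, 1L), 1L, 2L), tip.label = label,
                      Nnode = 1L, edge.length = 0.5, root.edge = 0.5),
                 class = "phylo")
  out <- ape::bind.tree(tree, y, where = tree$edge[e, 2L], position = 0.5)
  out <- ape::collapse.singles(out)
  out$edge.length <- NULL
  out
}

# All topologies obtained by pruning one leaf and regrafting it on another
# edge (the leaf-SPR neighbourhood), used to collect equally parsimonious
# ties around an optimum.
#' @noRd
leaf_spr_neighbours <- function(tree) {
  tree <- ape::unroot(tree)
  out <- list()
  if (ape::Ntip(tree) < 5L) return(out)
  for (t in tree$tip.label) {
    backbone <- ape::unroot(ape::drop.tip(tree, t))
    for (e in seq_len(nrow(backbone$edge)))
      out[[length(out) + 1L]] <- insert_tip(backbone, t, e)
  }
  out
}

#' All unrooted topologies over a leaf set
#'
#' Recursive edge-insertion enumeration; (2n-5)!! trees, so capped at 9
#' leaves.
#'
#' @param labels Character vector of at least 3 leaf labels.
#' @return List of \code{phylo} trees.
#' @export
all_topologies <- function(labels) {
  n <- length(labels)
  if (n < 3L) stop("need at least 3 labels")
  if (n > 9L) stop("refusing to enumerate more than 9 leaves")
  trees <- list(ape::read.tree(text = paste0("(", labels[1L], ",", labels[2L],
                                             ",", labels[3L], ");")))
  for (i in seq_len(n - 3L) + 3L) {
    nxt <- list()
    for (tr in trees)
      for (e in seq_len(nrow(tr$edge)))
        nxt[[length(nxt) + 1L]] <- insert_tip(tr, labels[i], e)
    trees <- nxt
  }
  trees
}

#' Exhaustive maximum-parsimony search
#'
#' Scores every unrooted topology with \code{\link{fitch_length}}; intended
#' as a small-problem reference, capped at 9 leaves.
#'
#' @inheritParams fitch_length
#' @return List with \code{length} (the global minimum) and \code{trees}
#'   (all optima, as a list of \code{phylo}).
#' @export
exhaustive_search <- function(x, weights = NULL) {
  seqs <- sm_seqs(x)
  trees <- all_topologies(sort(names(seqs)))
  lens <- vapply(trees, fitch_length, numeric(1), x = x, weights = weights)
  best <- min(lens)
  list(length = best, trees = trees[lens == best])
}

# ---- search -----------------------------------------------------------------

#' Search parameters for the parsimony ratchet
#'
#' Defaults follow the original ratchet recipe: 50 iterations, 25\% of
#' characters upweighted by a factor of 2.
#'
#' @param ratchet_iterations Number of ratchet iterations.
#' @param reweight_fraction Fraction of columns perturbed per iteration,
#'   in (0, 1).
#' @param weight_multiplier Integer weight multiplier (>= 2).
#' @param n_start_trees Number of random-addition start trees.
#' @param spr_max_rounds Unused placeholder (the SPR engine always runs to a
#'   local optimum); kept for forward compatibility.
#' @param collect_ties \code{"auto"} (sweep for equally parsimonious
#'   neighbours when the matrix has at most \code{tie_limit} rows),
#'   \code{TRUE} or \code{FALSE}.
#' @param tie_limit Row limit for the automatic tie sweep.
#' @param seed Integer seed; all search randomness flows from it.
#' @return List of class \code{search_params}.
#' @export
search_params <- function(ratchet_iterations = 50L, reweight_fraction = 0.25,
                          weight_multiplier = 2L, n_start_trees = 5L,
                          spr_max_rounds = NULL, collect_ties = "auto",
                          tie_limit = 12L, seed = 1L) {
  stopifnot(reweight_fraction > 0, reweight_fraction < 1,
            weight_multiplier >= 2, ratchet_iterations >= 0,
            n_start_trees >= 1)
  structure(list(ratchet_iterations = as.integer(ratchet_iterations),
                 reweight_fraction = reweight_fraction,
                 weight_multiplier = as.integer(weight_multiplier),
                 n_start_trees = as.integer(n_start_trees),
                 spr_max_rounds = spr_max_rounds,
                 collect_ties = collect_ties, tie_limit = as.integer(tie_limit),
                 seed = as.integer(seed)),
            class = "search_params")
}

#' Random-addition (stepwise) start tree
#'
#' Seeded random taxon-addition order; each taxon joins on the edge
#' minimising the Fitch length.
#'
#' @inheritParams fitch_length
#' @param seed Integer seed.
#' @return An unrooted \code{phylo} tree.
#' @export
stepwise_addition <- function(x, seed = 1L) {
  seqs <- sm_seqs(x)
  if (length(seqs) < 3L) stop("need at least 3 rows for a start tree")
  data <- as_phydat(x)
  with_seed(seed, ape::unroot(phangorn::random.addition(data,
                                                        method = "fitch")))
}

#' SPR hill climbing from a start tree
#'
#' Subtree-prune-regraft rearrangements until no improvement (phangorn's
#' Fitch SPR engine).  When tie collection is on, the leaf-SPR neighbourhood
#' of the optimum is swept and all distinct equally parsimonious topologies
#' are returned.
#'
#' @param start Start tree (\code{phylo}).
#' @inheritParams fitch_length
#' @param collect_ties \code{TRUE}, \code{FALSE} or \code{"auto"} (on for
#'   matrices with at most \code{tie_limit} rows).
#' @param tie_limit Row limit for \code{"auto"}.
#' @return List with \code{trees} (distinct optima, list of \code{phylo})
#'   and \code{length}.
#' @export
spr_search <- function(start, x, weights = NULL, collect_ties = "auto",
                       tie_limit = 12L) {
  seqs <- sm_seqs(x)
  data <- as_phydat(x)
  if (!is.null(weights)) data <- weighted_phydat(data, weights)
  best <- suppressMessages(
    phangorn::optim.parsimony(start, data, method = "fitch",
                              rearrangements = "SPR", trace = 0))
  best <- ape::unroot(best)
  best$edge.length <- NULL
  len <- fitch_length(best, x, weights)
  trees <- list(best)
  do_ties <- isTRUE(collect_ties) ||
    (identical(collect_ties, "auto") && length(seqs) <= tie_limit)
  if (do_ties) {
    for (cand in leaf_spr_neighbours(best))
      if (fitch_length(cand, x, weights) == len)
        trees[[length(trees) + 1L]] <- cand
    trees <- dedupe_trees(trees)
  }
  list(trees = trees, length = len)
}

#' Parsimony ratchet search
#'
#' Iterated search alternating character-reweighted and original-weight SPR
#' optimisation.  Each iteration upweights a random fraction of columns,
#' hill-climbs, restores unit weights and hill-climbs again; all distinct
#' topologies attaining the global best length are pooled.  Fully
#' reproducible given \code{params$seed}.
#'
#' @inheritParams fitch_length
#' @param params A \code{\link{search_params}} object.
#' @return List of class \code{ratchet_result}: \code{trees} (pooled optima),
#'   \code{length}, \code{log} (per-iteration best length), \code{seed}.
#' @export
parsimony_ratchet <- function(x, params = search_params()) {
  seqs <- sm_seqs(x)
  if (length(seqs) < 4L) stop("need at least 4 rows for a ratchet search")
  data <- as_phydat(x)
  L <- sum(attr(data, "weight"))
  do_ties <- isTRUE(params$collect_ties) ||
    (identical(params$collect_ties, "auto") &&
       length(seqs) <= params$tie_limit)
  with_seed(params$seed, {
    pool <- list()
    best_len <- Inf
    absorb <- function(res) {
      if (res$length < best_len) {
        best_len <<- res$length
        pool <<- res$trees
      } else if (res$length == best_len) {
        pool <<- dedupe_trees(c(pool, res$trees))
      }
    }
    cur <- NULL
    for (s in seq_len(params$n_start_trees)) {
      st <- ape::unroot(phangorn::random.addition(data, method = "fitch"))
      res <- spr_search(st, x, collect_ties = do_ties,
                        tie_limit = params$tie_limit)
      absorb(res)
      if (res$length == best_len) cur <- res$trees[[1L]]
    }
    log <- data.frame(iteration = 0L, length = best_len)
    n_col <- as.integer(L)
    for (it in seq_len(params$ratchet_iterations)) {
      k <- max(1L, round(params$reweight_fraction * n_col))
      up <- sample.int(n_col, k)
      w <- rep(1, n_col)
      w[up] <- params$weight_multiplier
      r1 <- spr_search(cur, x, weights = w, collect_ties = FALSE)
      r2 <- spr_search(r1$trees[[1L]], x, collect_ties = do_ties,
                       tie_limit = params$tie_limit)
      absorb(r2)
      cur <- r2$trees[[1L]]
      log <- rbind(log, data.frame(iteration = it, length = best_len))
    }
    structure(list(trees = pool, length = best_len, log = log,
                   seed = params$seed),
              class = "ratchet_result")
  })
}

#' @export
print.ratchet_result <- function(x, ...) {
  cat(sprintf(
    "<ratchet_result> best length %s; %d distinct optimal topolog%s; seed %d\n",
    format(x$length), length(x$trees),
    if (length(x$trees) == 1L) "y" else "ies", x$seed))
  invisible(x)
}

# ---- consensus and Newick ---------------------------------------------------

#' Strict consensus of a set of trees
#'
#' The output contains exactly the bipartitions present in every input tree,
#' with polytomies where the trees disagree.
#'
#' @param trees A list of \code{phylo} trees (or a \code{multiPhylo}) over
#'   identical leaf sets.
#' @return A \code{phylo} tree, possibly multifurcating.
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 0L) stop("empty tree set")
  leaf_sets <- lapply(trees, function(t) sort(t$tip.label))
  if (length(unique(vapply(leaf_sets, paste, "", collapse = "\r"))) > 1L)
    stop("trees have differing leaf sets")
  if (length(trees) == 1L) return(ape::unroot(trees[[1L]]))
  class(trees) <- "multiPhylo"
  cons <- ape::consensus(trees, p = 1, rooted = FALSE)
  cons$node.label <- NULL
  ape::unroot(cons)
}

#' Write a tree as Newick text
#' @param tree A \code{phylo} tree.
#' @param path Optional file path; when \code{NULL} the Newick string is
#'   returned.
#' @return The Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, path = NULL) {
  needs_quote <- grepl("[ ,():;]", tree$tip.label) &
    !grepl("^'.*'$", tree$tip.label)
  tree$tip.label[needs_quote] <- paste0("'", tree$tip.label[needs_quote], "'")
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(txt, con, sep = "\n")
  invisible(txt)
}

#' Read a tree from Newick text
#' @param text Newick string (used when \code{path} is \code{NULL}).
#' @param path Optional file path to read instead.
#' @return A \code{phylo} tree.
#' @export
read_newick <- function(text = NULL, path = NULL) {
  if (is.null(text) && is.null(path)) stop("supply 'text' or 'path'")
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE),
                                   collapse = "")
  depth <- cumsum(vapply(chars_of(text),
                         function(ch) (ch == "(") - (ch == ")"), 0))
  if (length(depth) && any(depth < 0))
    stop("Newick parse error: unbalanced ')' at offset ",
         which(depth < 0)[1L])
  if (length(depth) && utils::tail(depth, 1L) != 0)
    stop("Newick parse error: ", utils::tail(depth, 1L),
         " unclosed '(' at end of input")
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("Newick parse error in: ",
         substr(text, 1L, 60L))
  tr$tip.label <- sub("^'(.*)'$", "\\1", tr$tip.label)
  tr
}
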