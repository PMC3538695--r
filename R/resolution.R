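# The species-resolution criterion: a species is resolved when its specimens
# form a monophyletic clade in the MP tree AND share at least one consistent
# diagnostic character against every other specimen in the matrix.

#' Is a leaf subset monophyletic on an unrooted tree?
#'
#' True when the subset is a single leaf, the complement of a single leaf,
#' or matches one side of some internal-edge bipartition.  Works on
#' multifurcating (consensus) trees.
#'
#' @param tree A \code{phylo} tree.
#' @param members Character vector of leaf labels.
#' @return Logical scalar.
#' @export
bipartition_monophyly <- function(tree, members) {
  members <- unique(members)
  bad <- setdiff(members, tree$tip.label)
  if (length(bad))
    stop("not a leaf of the tree: ", paste(bad, collapse = ", "))
  n <- ape::Ntip(tree)
  k <- length(members)
  if (k == 0L) stop("empty member set")
  if (k == 1L || k >= n - 1L) return(TRUE)
  key <- paste(sort(members), collapse = ",")
  comp <- paste(sort(setdiff(tree$tip.label, members)), collapse = ",")
  splits <- tree_splits(tree)
  key %in% splits || comp %in% splits
}

#' Diagnostic columns for a specimen subset
#'
#' A column is diagnostic for \code{members} against \code{others} when
#' every member carries the same single unambiguous base there and no
#' specimen in \code{others} carries that base.  Missing or ambiguous cells
#' in \code{others} do not block a column; a missing or ambiguous cell in
#' any member does.
#'
#' @param sm A \code{supermatrix} (or \code{marker_alignment} / named
#'   sequence vector).
#' @param members,others Disjoint, non-empty character vectors of row IDs.
#' @return Integer vector of 1-based diagnostic column indices.
#' @export
diagnostic_sites <- function(sm, members, others) {
  seqs <- sm_seqs(sm)
  if (length(members) == 0L) stop("empty member set")
  if (length(others) == 0L) stop("empty other set")
  if (length(intersect(members, others)))
    stop("members and others must be disjoint")
  missing_ids <- setdiff(c(members, others), names(seqs))
  if (length(missing_ids))
    stop("IDs absent from matrix: ", paste(missing_ids, collapse = ", "))
  m <- encode_resolved(seqs[c(members, others)])
  diagnostic_sites_enc(m, members, others)
}

# Core of diagnostic_sites on a pre-encoded resolved-state matrix.
#' @noRd
diagnostic_sites_enc <- function(m, members, others) {
  mm <- m[members, , drop = FALSE]
  mo <- m[others, , drop = FALSE]
  member_base <- mm[1L, ]
  same <- sweep(mm, 2L, member_base, `==`)
  consistent <- !is.na(member_base) & colSums(is.na(mm)) == 0L &
    colSums(!same, na.rm = TRUE) == 0L
  hit <- sweep(mo, 2L, member_base, `==`)
  blocked <- colSums(hit, na.rm = TRUE) > 0L
  which(consistent & !blocked)
}

#' Score species resolution on a tree and matrix
#'
#' For every species with at least one specimen in the matrix, checks
#' monophyly on \code{tree} and counts diagnostic columns against all other
#' specimens in the matrix (or only congeneric specimens with
#' \code{congener_only = TRUE}).  A species is resolved when it is
#' monophyletic and has at least one diagnostic column; singleton species
#' are trivially monophyletic but still need a diagnostic column.
#'
#' Genus class (\code{monotypic} versus \code{polytypic}) is taken from the
#' full metadata, not just the species present in the matrix.
#'
#' @param tree A \code{phylo} tree whose leaves are the matrix rows.
#' @param sm The \code{supermatrix} the tree was inferred from.
#' @param dataset The \code{barcode_library} supplying taxonomy.
#' @param congener_only Restrict the diagnostic comparison to congeners.
#' @return List of class \code{resolution_report}: \code{species} (data
#'   frame: species, genus, family, genus_class, n_specimens, monophyletic,
#'   n_diagnostic_sites, resolved) and \code{summary} (n_species_evaluated,
#'   n_species_missing, overall_percent, polytypic_percent,
#'   monotypic_percent, n_polytypic, n_monotypic).
#' @export
species_resolution <- function(tree, sm, dataset, congener_only = FALSE) {
  stopifnot(inherits(dataset, "barcode_library"))
  seqs <- sm_seqs(sm)
  rows <- names(seqs)
  if (!setequal(tree$tip.label, rows))
    stop("tree leaves and matrix rows differ")
  meta <- dataset$specimens
  sp_of <- stats::setNames(meta$species, meta$specimen_id)
  gen_of_sp <- stats::setNames(meta$genus, meta$species)
  fam_of_sp <- stats::setNames(meta$family, meta$species)
  genus_n_species <- tapply(meta$species, meta$genus,
                            function(s) length(unique(s)))
  eval_species <- sort(unique(sp_of[rows]))
  enc <- encode_resolved(seqs)
  splits <- tree_splits(tree)
  n_rows <- length(rows)
  mono_fast <- function(members) {
    k <- length(members)
    if (k == 1L || k >= n_rows - 1L) return(TRUE)
    paste(sort(members), collapse = ",") %in% splits ||
      paste(sort(setdiff(rows, members)), collapse = ",") %in% splits
  }
  recs <- lapply(eval_species, function(sp) {
    members <- rows[sp_of[rows] == sp]
    if (congener_only) {
      gen <- gen_of_sp[[sp]]
      others <- rows[sp_of[rows] != sp & gen_of_sp[sp_of[rows]] == gen]
    } else {
      others <- setdiff(rows, members)
    }
    mono <- mono_fast(members)
    n_diag <- if (length(others))
      length(diagnostic_sites_enc(enc, members, others)) else 0L
    gclass <- if (genus_n_species[[gen_of_sp[[sp]]]] == 1L) "monotypic"
              else "polytypic"
    data.frame(species = sp, genus = gen_of_sp[[sp]],
               family = fam_of_sp[[sp]], genus_class = gclass,
               n_specimens = length(members), monophyletic = mono,
               n_diagnostic_sites = n_diag,
               resolved = mono && n_diag >= 1L, stringsAsFactors = FALSE)
  })
  per_species <- do.call(rbind, recs)
  rownames(per_species) <- NULL
  pct <- function(x) if (length(x)) 100 * mean(x) else NA_real_
  poly <- per_species$genus_class == "polytypic"
  summary <- list(
    n_species_evaluated = nrow(per_species),
    n_species_missing = length(setdiff(unique(meta$species),
                                       per_species$species)),
    overall_percent = pct(per_species$resolved),
    polytypic_percent = pct(per_species$resolved[poly]),
    monotypic_percent = pct(per_species$resolved[!poly]),
    n_polytypic = sum(poly),
    n_monotypic = sum(!poly))
  structure(list(species = per_species, summary = summary),
            class = "resolution_report")
}

#' @export
print.resolution_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<resolution_report> %d species evaluated (%d absent from matrix)\n",
           "  overall resolved: %.1f%%  congeners (polytypic genera, n=%d): %.1f%%",
           "  monotypic genera (n=%d): %.1f%%\n"),
    s$n_species_evaluated, s$n_species_missing, s$overall_percent,
    s$n_polytypic, s$polytypic_percent, s$n_monotypic, s$monotypic_percent))
  invisible(x)
}

#' Compare species resolution across marker combinations
#'
#' For each marker combination: build the supermatrix (inclusion rule
#' adapted to the combination), run the parsimony ratchet, take the strict
#' consensus of the pooled optima, and score species resolution.
#'
#' @param dataset A \code{barcode_library}.
#' @param combos List of character vectors of marker names.
#' @param params \code{\link{search_params}} for the ratchet (per-combination
#'   seeds are derived from \code{params$seed}).
#' @param rule Inclusion rule name or predicate (default the three-gene
#'   "nuclear plus at least one chloroplast" rule, which degrades to
#'   any-marker for combinations lacking one side).
#' @param congener_only Passed to \code{\link{species_resolution}}.
#' @return List of class \code{combo_comparison}: \code{table} (one row per
#'   combination with the summary percentages), \code{resolved_by} (logical
#'   species x combination matrix), \code{reports}, \code{trees} (strict
#'   consensus per combination).
#' @export
marker_combination_compare <- function(dataset, combos,
                                       params = search_params(),
                                       rule = "paper",
                                       congener_only = FALSE) {
  combo_names <- vapply(combos, paste, "", collapse = "+")
  reports <- list(); trees <- list()
  rows <- list()
  for (i in seq_along(combos)) {
    cmb <- combos[[i]]
    sm <- concatenate(dataset, cmb, rule = rule)
    p <- params
    p$seed <- substream(params$seed, combo_names[i])
    rr <- parsimony_ratchet(sm, p)
    cons <- strict_consensus(rr$trees)
    rep <- species_resolution(cons, sm, dataset,
                              congener_only = congener_only)
    reports[[combo_names[i]]] <- rep
    trees[[combo_names[i]]] <- cons
    s <- rep$summary
    rows[[i]] <- data.frame(
      combo = combo_names[i], n_specimens = length(sm$seqs),
      n_species = s$n_species_evaluated, tree_length = rr$length,
      n_optimal_trees = length(rr$trees),
      overall_percent = s$overall_percent,
      polytypic_percent = s$polytypic_percent,
      monotypic_percent = s$monotypic_percent, stringsAsFactors = FALSE)
  }
  all_species <- sort(unique(unlist(lapply(reports,
                                           function(r) r$species$species))))
  resolved_by <- sapply(reports, function(r) {
    v <- stats::setNames(rep(NA, length(all_species)), all_species)
    v[r$species$species] <- r$species$resolved
    v
  })
  resolved_by <- matrix(resolved_by, nrow = length(all_species),
                        dimnames = list(all_species, combo_names))
  structure(list(table = do.call(rbind, rows), resolved_by = resolved_by,
                 reports = reports, trees = trees),
            class = "combo_comparison")
}

#' @export
print.combo_comparison <- function(x, ...) {
  cat("<combo_comparison>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
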