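# Pairwise distances (p, K2P), within-family MPD tables, cross-marker
# correlations, recovery tabulations and intraspecific-variation calls.
#
# Comparison convention: a column contributes to a pair only when BOTH
# sequences carry a single unambiguous base there (pairwise deletion;
# ambiguity codes are excluded entirely, with no partial-match credit).

.is_transition <- function(a, b) {
  # bitmasks: A=1 G=4 (purines), C=2 T=8 (pyrimidines)
  (a + b) %in% c(5L, 10L)
}

#' Pairwise distance between two aligned sequences
#'
#' @param a,b Equal-length aligned sequences (character scalars).
#' @param model \code{"p"} (proportion of differing sites) or \code{"k2p"}
#'   (Kimura two-parameter).
#' @return Distance in \code{[0, 1]} for \code{"p"} (K2P may exceed 1), or
#'   \code{NA} when no column is comparable or the K2P logarithms are
#'   undefined (saturation).
#' @export
pairwise_distance <- function(a, b, model = c("p", "k2p")) {
  model <- match.arg(model)
  if (nchar(a) != nchar(b))
    stop("sequences have different lengths (", nchar(a), " vs ", nchar(b), ")")
  m <- encode_resolved(c(x = a, y = b))
  ok <- !is.na(m[1L, ]) & !is.na(m[2L, ])
  n <- sum(ok)
  if (n == 0L) return(NA_real_)
  av <- m[1L, ok]; bv <- m[2L, ok]
  diff <- av != bv
  if (model == "p") return(sum(diff) / n)
  P <- sum(diff & .is_transition(av, bv)) / n
  Q <- sum(diff & !.is_transition(av, bv)) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1) - 0.25 * log(w2)
}

# All-pairs distance matrix over a named sequence vector, via indicator
# cross-products (BLAS).  Returns a symmetric matrix with NA where a pair has
# no comparable column (diagonal 0).
#' @noRd
distance_matrix <- function(seqs, model = c("p", "k2p")) {
  model <- match.arg(model)
  m <- encode_resolved(seqs)
  ind <- lapply(.single_bits, function(b) {
    x <- (m == b); x[is.na(x)] <- FALSE; storage.mode(x) <- "double"; x
  })
  B <- !is.na(m); storage.mode(B) <- "double"
  comparable <- tcrossprod(B)
  matches <- Reduce(`+`, lapply(ind, tcrossprod))
  if (model == "p") {
    d <- (comparable - matches) / comparable
  } else {
    transitions <- tcrossprod(ind[[1L]], ind[[3L]]) +
      tcrossprod(ind[[3L]], ind[[1L]]) +
      tcrossprod(ind[[2L]], ind[[4L]]) + tcrossprod(ind[[4L]], ind[[2L]])
    P <- transitions / comparable
    Q <- (comparable - matches - transitions) / comparable
    w1 <- 1 - 2 * P - Q
    w2 <- 1 - 2 * Q
    # saturation (non-positive log arguments) is an undefined distance, NA
    d <- suppressWarnings(-0.5 * log(w1) - 0.25 * log(w2))
    d[!is.finite(d)] <- NA_real_
  }
  d[comparable == 0] <- NA_real_
  diag(d) <- ifelse(diag(comparable) > 0, 0, NA_real_)
  dimnames(d) <- list(names(seqs), names(seqs))
  d
}

#' Within-family mean pairwise distance (MPD) table
#'
#' For each family with at least two specimens carrying the marker, averages
#' the distances over all within-family specimen pairs (inter- and
#' intra-specific alike).  Pairs with no comparable column are dropped from
#' both the mean and the dispersion.
#'
#' @param dataset A \code{barcode_library}.
#' @param marker Marker name.
#' @param model Distance model, \code{"p"} or \code{"k2p"}.
#' @return Data frame of class \code{mpd_table} with columns \code{family},
#'   \code{n_species}, \code{n_specimens}, \code{n_pairs},
#'   \code{mpd_percent}, \code{sigma_percent}; attribute \code{marker}.
#'   \code{sigma_percent} is the sample (n-1) standard deviation of the pair
#'   distances, 0 when only one pair exists.
#' @export
mpd_by_family <- function(dataset, marker, model = c("p", "k2p")) {
  model <- match.arg(model)
  stopifnot(inherits(dataset, "barcode_library"))
  aln <- dataset$alignments[[marker]]
  if (is.null(aln)) stop("marker '", marker, "' not in dataset")
  meta <- dataset$specimens
  ids <- intersect(meta$specimen_id, names(aln$seqs))
  fam_of <- stats::setNames(meta$family, meta$specimen_id)
  sp_of <- stats::setNames(meta$species, meta$specimen_id)
  rows <- list()
  for (fam in sort(unique(fam_of[ids]))) {
    fid <- ids[fam_of[ids] == fam]
    if (length(fid) < 2L) next
    dm <- distance_matrix(aln$seqs[fid], model)
    dvec <- dm[upper.tri(dm)]
    dvec <- dvec[!is.na(dvec)]
    if (length(dvec) == 0L) next
    rows[[fam]] <- data.frame(
      family = fam,
      n_species = length(unique(sp_of[fid])),
      n_specimens = length(fid),
      n_pairs = length(dvec),
      mpd_percent = mean(dvec) * 100,
      sigma_percent = if (length(dvec) > 1L) stats::sd(dvec) * 100 else 0,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    warning("no family has two or more specimens with '", marker,
            "' data; MPD table is empty", call. = FALSE)
    out <- data.frame(family = character(), n_species = integer(),
                      n_specimens = integer(), n_pairs = integer(),
                      mpd_percent = numeric(), sigma_percent = numeric())
  } else out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "marker") <- marker
  attr(out, "model") <- model
  class(out) <- c("mpd_table", "data.frame")
  out
}

#' Correlation between two markers' family MPD profiles
#'
#' Pearson correlation over families shared by the two MPD tables, with a
#' two-sided p-value from the Fisher z-transform normal test
#' (\eqn{z = \mathrm{atanh}(r)\sqrt{n-3}}).
#'
#' @param t1,t2 \code{mpd_table} objects for two markers.
#' @return List of class \code{mpd_correlation}: \code{marker_a},
#'   \code{marker_b}, \code{r}, \code{n_families}, \code{p_value}.
#' @export
mpd_correlation <- function(t1, t2) {
  shared <- intersect(t1$family, t2$family)
  if (length(shared) < 3L)
    stop("insufficient data: need at least 3 shared families, have ",
         length(shared))
  x <- t1$mpd_percent[match(shared, t1$family)]
  y <- t2$mpd_percent[match(shared, t2$family)]
  r <- stats::cor(x, y)
  n <- length(shared)
  z <- atanh(min(max(r, -1), 1)) * sqrt(n - 3)
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(marker_a = attr(t1, "marker"), marker_b = attr(t2, "marker"),
                 r = r, n_families = n, p_value = p),
            class = "mpd_correlation")
}

#' @export
print.mpd_correlation <- function(x, ...) {
  cat(sprintf("%s / %s: r = %.3f (n = %d families, p = %.3g)\n",
              x$marker_a, x$marker_b, x$r, x$n_families, x$p_value))
  invisible(x)
}

#' Sequencing-success tabulations
#'
#' Success percentages (succeeded / attempted) per marker stratified by
#' tissue source and by herbarium-age bin.  Strata with zero attempts are
#' absent, not reported as 0.
#'
#' @param dataset A \code{barcode_library} with a recovery table.
#' @param age_bin_years Width of the age bins (default 5).
#' @param reference_year Year ages are measured from (default: the maximum
#'   collection year in the metadata).
#' @return List with data frames \code{by_source} (marker, source,
#'   n_attempted, n_succeeded, success_percent) and \code{by_age} (marker,
#'   age_bin, ...), the latter restricted to specimens with a collection
#'   year.
#' @export
recovery_stats <- function(dataset, age_bin_years = 5, reference_year = NULL) {
  stopifnot(inherits(dataset, "barcode_library"))
  rec <- dataset$recovery
  if (is.null(rec) || nrow(rec) == 0L)
    stop("dataset has no recovery table; skip the recovery report")
  meta <- dataset$specimens
  rec <- rec[rec$status %in% c("succeeded", "attempted_failed"), , drop = FALSE]
  rec$source <- meta$source[match(rec$specimen_id, meta$specimen_id)]
  rec$year <- meta$collection_year[match(rec$specimen_id, meta$specimen_id)]
  tab <- function(df, strat) {
    df <- df[!is.na(df[[strat]]), , drop = FALSE]
    if (nrow(df) == 0L)
      return(data.frame(marker = character(), stratum = character(),
                        n_attempted = integer(), n_succeeded = integer(),
                        success_percent = numeric()))
    agg <- stats::aggregate(list(n_attempted = df$status),
                            by = list(marker = df$marker, stratum = df[[strat]]),
                            FUN = length)
    succ <- stats::aggregate(list(n_succeeded = df$status == "succeeded"),
                             by = list(marker = df$marker, stratum = df[[strat]]),
                             FUN = sum)
    agg$n_succeeded <- succ$n_succeeded
    agg$success_percent <- 100 * agg$n_succeeded / agg$n_attempted
    agg[order(agg$marker, agg$stratum), ]
  }
  by_source <- tab(rec, "source")
  names(by_source)[names(by_source) == "stratum"] <- "source"
  ref <- reference_year %||% suppressWarnings(max(meta$collection_year,
                                                  na.rm = TRUE))
  rec$age <- ref - rec$year
  rec$age_bin <- ifelse(is.na(rec$age), NA_character_,
    sprintf("%d-%d", (rec$age %/% age_bin_years) * age_bin_years,
            (rec$age %/% age_bin_years) * age_bin_years + age_bin_years - 1L))
  by_age <- tab(rec, "age_bin")
  names(by_age)[names(by_age) == "stratum"] <- "age_bin"
  list(by_source = by_source, by_age = by_age)
}

#' Intraspecific variation calls per species
#'
#' A species is \code{variable} for a marker when at least two conspecific
#' sequences differ at one or more mutually resolved columns;
#' \code{invariant} when multiple records exist but never conflict; and
#' \code{single_record} otherwise.
#'
#' @param dataset A \code{barcode_library}.
#' @param marker Marker name.
#' @return Data frame \code{species}, \code{n_records}, \code{status}.
#' @export
intraspecific_variation <- function(dataset, marker) {
  aln <- dataset$alignments[[marker]]
  if (is.null(aln)) stop("marker '", marker, "' not in dataset")
  meta <- dataset$specimens
  ids <- intersect(meta$specimen_id, names(aln$seqs))
  sp_of <- stats::setNames(meta$species, meta$specimen_id)
  res <- lapply(sort(unique(sp_of[ids])), function(sp) {
    sid <- ids[sp_of[ids] == sp]
    status <- if (length(sid) < 2L) "single_record" else {
      dm <- distance_matrix(aln$seqs[sid], "p")
      dv <- dm[upper.tri(dm)]
      if (any(dv > 0, na.rm = TRUE)) "variable" else "invariant"
    }
    data.frame(species = sp, n_records = length(sid), status = status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res) %||%
    data.frame(species = character(), n_records = integer(),
               status = character())
  rownames(out) <- NULL
  out
}
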