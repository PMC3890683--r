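# Kimura 2-parameter pairwise distances and dataset-level distance summaries.
#
# Conventions, applied throughout:
#  * pairwise deletion: an alignment column enters a pair's comparison only
#    when BOTH sequences carry an unambiguous A/C/G/T there; partial-ambiguity
#    matches (e.g. R vs A) are never credited;
#  * distances are stored as proportions; percent appears only in reporting;
#  * saturated pairs (outside the K2P domain) and empty comparisons are
#    recorded as undefined (NA) and excluded from pools with a warning, the
#    run continues.

#' Count compared sites, transitions and transversions for one pair
#'
#' @param a,b aligned sequences of equal length (character strings).
#' @return a list of class \code{site_pair_counts}: \code{n_compared},
#'   \code{n_transitions}, \code{n_transversions}, and the proportions
#'   \code{P} (transitions) and \code{Q} (transversions). \code{P} and
#'   \code{Q} are \code{NaN} when no site is comparable.
#' @export
count_site_pairs <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("sequences differ in length (", nchar(a), " vs ", nchar(b), ")")
  va <- strsplit(toupper(a), "")[[1L]]
  vb <- strsplit(toupper(b), "")[[1L]]
  acgt <- c("A", "C", "G", "T")
  ok <- va %in% acgt & vb %in% acgt
  va <- va[ok]; vb <- vb[ok]
  n <- length(va)
  diff <- va != vb
  # transitions: purine<->purine (A,G) or pyrimidine<->pyrimidine (C,T)
  purine <- c("A", "G")
  ts <- diff & ((va %in% purine) == (vb %in% purine))
  n_ts <- sum(ts)
  n_tv <- sum(diff) - n_ts
  structure(list(n_compared = n, n_transitions = n_ts, n_transversions = n_tv,
                 P = n_ts / n, Q = n_tv / n),
            class = "site_pair_counts")
}

#' Kimura 2-parameter distance from site-pair counts
#'
#' Evaluates \eqn{d = -\frac{1}{2}\ln\{(1-2P-Q)\sqrt{1-2Q}\}} where P and Q
#' are the observed proportions of transitional and transversional
#' differences. Outside the formula's domain (saturation) the distance is
#' undefined and \code{NA} is returned rather than an error, so that a full
#' matrix computation can record the pair and continue.
#'
#' @param counts a \code{site_pair_counts} object, or any list with elements
#'   \code{P} and \code{Q}.
#' @return the distance (substitutions per site), or \code{NA} if undefined.
#' @export
k2p_distance <- function(counts) {
  P <- counts$P; Q <- counts$Q
  if (is.null(P) || is.null(Q)) stop("counts must carry P and Q")
  if (!is.finite(P) || !is.finite(Q)) return(NA_real_)
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) return(NA_real_)
  -0.5 * log(a1 * sqrt(a2))
}

#' Construct a pairwise K2P distance-matrix object
#'
#' Container used by every downstream analysis; also the way to supply a
#' hand-built toy matrix. Validates symmetry, a zero diagonal and
#' non-negativity of defined entries; \code{NA} entries are recorded as
#' undefined pairs.
#'
#' @param d square numeric matrix with dimnames giving specimen ids.
#' @param ids specimen ids; defaults to \code{rownames(d)}.
#' @return an object of class \code{k2p_distmat}: list with \code{ids},
#'   \code{d} and \code{undefined_pairs} (two-column data.frame).
#' @export
k2p_distmat <- function(d, ids = rownames(d)) {
  d <- as.matrix(d)
  if (is.null(ids)) stop("distance matrix needs specimen ids (rownames)")
  stopifnot(nrow(d) == ncol(d), length(ids) == nrow(d))
  dimnames(d) <- list(ids, ids)
  if (any(abs(diag(d)) > 1e-12, na.rm = TRUE)) stop("diagonal must be zero")
  diag(d) <- 0
  if (any(abs(d - t(d)) > 1e-12, na.rm = TRUE)) stop("matrix must be symmetric")
  if (any(d < 0, na.rm = TRUE)) stop("defined distances must be >= 0")
  undef <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
  undefined_pairs <- data.frame(id1 = ids[undef[, 1L]], id2 = ids[undef[, 2L]],
                                stringsAsFactors = FALSE)
  structure(list(ids = ids, d = d, undefined_pairs = undefined_pairs),
            class = "k2p_distmat")
}

#' @export
print.k2p_distmat <- function(x, ...) {
  cat(sprintf("k2p_distmat: %d specimens, %d undefined pair(s)\n",
              length(x$ids), nrow(x$undefined_pairs)))
  invisible(x)
}

# dataset sequences as an n x L character matrix
.seq_matrix <- function(dataset) {
  r <- dataset$records
  m <- matrix(unlist(strsplit(r$sequence, ""), use.names = FALSE),
              nrow = nrow(r), byrow = TRUE)
  rownames(m) <- r$specimen_id
  m
}

# K2P distances from a character matrix, via base-indicator cross-products:
# one pass of dense matrix algebra instead of an O(n^2) pair loop.
.k2p_from_matrix <- function(m) {
  n <- nrow(m)
  XA <- (m == "A") * 1; XC <- (m == "C") * 1
  XG <- (m == "G") * 1; XT <- (m == "T") * 1
  valid <- XA + XC + XG + XT
  ncomp <- tcrossprod(valid)
  ts <- tcrossprod(XA, XG) + tcrossprod(XG, XA) +
        tcrossprod(XC, XT) + tcrossprod(XT, XC)
  same <- tcrossprod(XA) + tcrossprod(XC) + tcrossprod(XG) + tcrossprod(XT)
  tv <- ncomp - same - ts
  P <- ts / ncomp
  Q <- tv / ncomp
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  d <- suppressWarnings(-0.5 * log(a1 * sqrt(a2)))
  d[!is.finite(d)] <- NA_real_
  d[ncomp == 0] <- NA_real_
  d[a1 <= 0 | a2 <= 0] <- NA_real_
  d[!is.na(d) & d == 0] <- 0   # normalise -0 from log(1)
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Pairwise K2P distance matrix for a dataset
#'
#' Computes every pairwise distance once under pairwise deletion. Undefined
#' pairs (no comparable sites, or K2P saturation) are recorded in
#' \code{undefined_pairs} with a warning; the computation never aborts on
#' them.
#'
#' @param dataset a \code{barcode_dataset}.
#' @return a \code{\link{k2p_distmat}}.
#' @export
distance_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "barcode_dataset"))
  d <- .k2p_from_matrix(.seq_matrix(dataset))
  out <- k2p_distmat(d)
  if (nrow(out$undefined_pairs))
    warning(nrow(out$undefined_pairs),
            " pair(s) have undefined K2P distances; they are excluded from pools")
  out
}

# classify each upper-triangle pair of the matrix; returns a data.frame with
# indices, distance and pool membership flags
.pair_table <- function(dm, dataset) {
  r <- dataset$records
  idx <- match(dm$ids, r$specimen_id)
  if (anyNA(idx)) stop("distance matrix ids do not match the dataset")
  sp <- r$species[idx]; ge <- r$genus[idx]
  ing <- !dm$ids %in% dataset$outgroup_ids
  ut <- which(upper.tri(dm$d), arr.ind = TRUE)
  i <- ut[, 1L]; j <- ut[, 2L]
  data.frame(i = i, j = j, d = dm$d[ut],
             both_ingroup = ing[i] & ing[j],
             outgroup_pair = xor(ing[i], ing[j]),
             same_species = sp[i] == sp[j],
             same_genus = ge[i] == ge[j],
             stringsAsFactors = FALSE)
}

.pool_stats <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(c(mean = NA_real_, min = NA_real_, max = NA_real_, n = 0))
  c(mean = mean(x), min = min(x), max = max(x), n = length(x))
}

#' Summarise a distance matrix into taxonomic pools
#'
#' Pools over all ingroup pairwise comparisons: intraspecific (same species),
#' interspecific (different species), intrageneric (different species, same
#' genus) and intergeneric (different genera); outgroup--ingroup pairs are
#' reported separately. Means are simple averages over all pairwise
#' comparisons in a pool; empty pools are reported as absent (\code{NA}),
#' never as zero. Undefined distances are excluded.
#'
#' @param dm a \code{k2p_distmat}.
#' @param dataset the matching \code{barcode_dataset}.
#' @return an object of class \code{distance_summary}: a list of
#'   \code{c(mean, min, max, n)} vectors per pool (proportions), plus
#'   \code{barcode_gap_overlap_fraction} (NA when either bounding pool is
#'   empty).
#' @export
summarize_distances <- function(dm, dataset) {
  stopifnot(inherits(dm, "k2p_distmat"))
  pt <- .pair_table(dm, dataset)
  ing <- pt[pt$both_ingroup, ]
  out <- list(
    intraspecific = .pool_stats(ing$d[ing$same_species]),
    interspecific = .pool_stats(ing$d[!ing$same_species]),
    intrageneric  = .pool_stats(ing$d[!ing$same_species & ing$same_genus]),
    intergeneric  = .pool_stats(ing$d[!ing$same_genus]),
    outgroup      = .pool_stats(pt$d[pt$outgroup_pair])
  )
  gap <- NA_real_
  if (out$intraspecific[["n"]] > 0 && out$interspecific[["n"]] > 0) {
    lo <- out$interspecific[["min"]]; hi <- out$intraspecific[["max"]]
    dd <- ing$d[!is.na(ing$d)]
    gap <- if (lo > hi) 0 else mean(dd >= lo & dd <= hi)
  }
  out$barcode_gap_overlap_fraction <- gap
  structure(out, class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  fmt <- function(s, label) {
    if (s[["n"]] == 0) return(sprintf("  %-14s absent (empty pool)\n", label))
    sprintf("  %-14s %5.2f%% (%.2f-%.2f%%), %d pairs\n", label,
            100 * s[["mean"]], 100 * s[["min"]], 100 * s[["max"]], s[["n"]])
  }
  cat("K2P distance summary (percent):\n")
  cat(fmt(x$intraspecific, "intraspecific"))
  cat(fmt(x$interspecific, "interspecific"))
  cat(fmt(x$intrageneric, "intrageneric"))
  cat(fmt(x$intergeneric, "intergeneric"))
  cat(fmt(x$outgroup, "vs outgroup"))
  if (!is.na(x$barcode_gap_overlap_fraction))
    cat(sprintf("  barcode-gap overlap: %.2f%% of all ingroup comparisons\n",
                100 * x$barcode_gap_overlap_fraction))
  invisible(x)
}

#' Barcode-gap overlap
#'
#' Fraction of all ingroup pairwise comparisons falling between the minimum
#' interspecific and the maximum intraspecific distance. A value of zero
#' means a clean barcode gap; large values undermine threshold-based
#' identification.
#'
#' @param dm a \code{k2p_distmat}.
#' @param dataset the matching \code{barcode_dataset}.
#' @return list with \code{min_interspecific}, \code{max_intraspecific} and
#'   \code{overlap_fraction}.
#' @export
barcode_gap_overlap <- function(dm, dataset) {
  pt <- .pair_table(dm, dataset)
  ing <- pt[pt$both_ingroup & !is.na(pt$d), ]
  intra <- ing$d[ing$same_species]
  inter <- ing$d[!ing$same_species]
  if (!length(intra) || !length(inter))
    stop("barcode-gap overlap is undefined: intraspecific and interspecific ",
         "pools must both be non-empty")
  lo <- min(inter); hi <- max(intra)
  frac <- if (lo > hi) 0 else mean(ing$d >= lo & ing$d <= hi)
  list(min_interspecific = lo, max_intraspecific = hi, overlap_fraction = frac)
}

#' Mean distances between species (or custom groups)
#'
#' Entry (s, t) is the mean of all cross-pair distances between members of
#' s and t, in percent. Groups default to species but can be redefined, e.g.
#' to split a species into host races or merge species into complexes.
#'
#' @param dm a \code{k2p_distmat}.
#' @param dataset the matching \code{barcode_dataset}.
#' @param groups either \code{NULL} (group = species), a named character
#'   vector mapping species names to group labels (species absent from the
#'   map keep their own name; unknown species names are an error), or an
#'   unnamed per-record character vector of length \code{nrow(records)}.
#' @return symmetric numeric matrix of mean K2P distances in percent;
#'   diagonal entries hold within-group means (NA for single-member groups).
#'   Outgroup records are excluded.
#' @export
species_pair_mean_distances <- function(dm, dataset, groups = NULL) {
  stopifnot(inherits(dm, "k2p_distmat"))
  r <- dataset$records
  idx <- match(dm$ids, r$specimen_id)
  sp <- r$species[idx]
  if (is.null(groups)) {
    grp <- sp
  } else if (!is.null(names(groups))) {
    unknown <- setdiff(names(groups), r$species)
    if (length(unknown))
      stop("groups map references unknown species: ",
           paste(unknown, collapse = ", "))
    grp <- ifelse(sp %in% names(groups), unname(groups[sp]), sp)
  } else {
    if (length(groups) != length(dm$ids))
      stop("per-record groups must have length ", length(dm$ids))
    grp <- as.character(groups)[idx]  # groups aligned to dataset record order
  }
  ing <- !dm$ids %in% dataset$outgroup_ids
  grp[!ing] <- NA
  levs <- sort(unique(grp[!is.na(grp)]))
  if (length(levs) < 2L) stop("need at least two groups")
  out <- matrix(NA_real_, length(levs), length(levs), dimnames = list(levs, levs))
  for (a in seq_along(levs)) for (b in seq_len(a)) {
    ia <- which(grp == levs[a]); ib <- which(grp == levs[b])
    if (a == b) {
      if (length(ia) < 2L) next
      vals <- dm$d[ia, ia][upper.tri(matrix(0, length(ia), length(ia)))]
    } else {
      vals <- as.vector(dm$d[ia, ib, drop = FALSE])
    }
    out[a, b] <- out[b, a] <- mean(vals, na.rm = TRUE) * 100
  }
  out
}

#' Export a distance matrix
#'
#' @param dm a \code{k2p_distmat}.
#' @param path output file.
#' @param format \code{"tsv"} (square, with a leading id column) or
#'   \code{"phylip"} (square PHYLIP matrix).
#' @param digits decimal places.
#' @return \code{path}, invisibly.
#' @export
write_distance_matrix <- function(dm, path, format = c("tsv", "phylip"),
                                  digits = 6) {
  stopifnot(inherits(dm, "k2p_distmat"))
  format <- match.arg(format)
  vals <- formatC(dm$d, digits = digits, format = "f")
  vals[is.na(dm$d)] <- "NA"
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (format == "tsv") {
    writeLines(paste(c("specimen_id", dm$ids), collapse = "\t"), con, sep = "\n")
    for (i in seq_along(dm$ids))
      writeLines(paste(c(dm$ids[i], vals[i, ]), collapse = "\t"), con, sep = "\n")
  } else {
    writeLines(sprintf("%5d", length(dm$ids)), con, sep = "\n")
    nm <- formatC(substr(dm$ids, 1L, 10L), width = -10L)
    for (i in seq_along(dm$ids))
      writeLines(paste0(nm[i], "  ", paste(vals[i, ], collapse = "  ")),
                 con, sep = "\n")
  }
  invisible(path)
}
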