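# Threshold derivation, true/false positive-negative accounting, threshold
# sweeps, the ad hoc threshold regression, dataset stripping and
# problem-taxon flagging.

#' Percentile threshold of the intraspecific distance distribution
#'
#' The distance below which the given percentage of all pooled ingroup
#' intraspecific pairwise distances fall; with the default 95 this is the
#' conventional threshold for Best Close Match and All Species Barcodes.
#' Percentile computed by linear interpolation between order statistics
#' (h = (n-1)p + 1, \code{stats::quantile} type 7).
#'
#' @param dm a \code{k2p_distmat}.
#' @param dataset the matching \code{barcode_dataset}.
#' @param percentile percentile in (0, 100]; default 95.
#' @return the threshold, as a proportion.
#' @export
intraspecific_percentile_threshold <- function(dm, dataset, percentile = 95) {
  if (percentile <= 0 || percentile > 100) stop("percentile must be in (0, 100]")
  pt <- .pair_table(dm, dataset)
  x <- pt$d[pt$both_ingroup & pt$same_species & !is.na(pt$d)]
  if (!length(x))
    stop("no intraspecific pairs (all species are singletons); ",
         "the percentile threshold is undefined")
  unname(stats::quantile(x, probs = percentile / 100, type = 7, names = FALSE))
}

#' Classify leave-one-out verdicts into TP/FP/FN/TN at a threshold
#'
#' Takes threshold-free Best-Match-style verdicts (each carrying an
#' \code{outcome} and a \code{best_distance}) and applies the threshold:
#' a query at or below the threshold is a true positive when correctly
#' identified, otherwise a false positive (ambiguous counts as false,
#' matching how these rates are tabulated); a query above the threshold is a
#' false negative when its best match is conspecific (it would have been
#' correct) and a true negative otherwise (correctly rejected).
#'
#' @param verdicts a verdict data.frame from
#'   \code{evaluate_dataset(..., criterion = "BM")}, or any data.frame with
#'   \code{outcome} and \code{best_distance} columns (no missing
#'   best_distance allowed).
#' @param threshold distance threshold (>= 0).
#' @return a \code{confusion_summary}: proportions \code{TP}, \code{FP},
#'   \code{FN}, \code{TN} over all queries, the corresponding counts, the
#'   threshold and \code{n_queries}. TP+FP+FN+TN = 1 exactly in counts.
#' @export
classify_confusion <- function(verdicts, threshold) {
  stopifnot(is.data.frame(verdicts),
            all(c("outcome", "best_distance") %in% names(verdicts)))
  if (threshold < 0) stop("threshold must be >= 0")
  if (anyNA(verdicts$best_distance))
    stop("verdict(s) without best_distance: confusion classes undefined")
  n <- nrow(verdicts)
  below <- verdicts$best_distance <= threshold
  correct <- verdicts$outcome == "correct"
  counts <- c(TP = sum(below & correct), FP = sum(below & !correct),
              FN = sum(!below & correct), TN = sum(!below & !correct))
  structure(list(TP = counts[["TP"]] / n, FP = counts[["FP"]] / n,
                 FN = counts[["FN"]] / n, TN = counts[["TN"]] / n,
                 counts = counts, threshold = threshold, n_queries = n),
            class = "confusion_summary")
}

#' Performance metrics from a confusion summary
#'
#' accuracy = TP + TN; precision = TP / (TP + FP); overall identification
#' error = FP + FN; relative identification error = FP / (TP + FP)
#' = 1 - precision. Precision and relative error are reported as absent
#' (NA) when nothing falls below the threshold; absence is a value, not an
#' error.
#'
#' @param confusion a \code{confusion_summary}.
#' @return list with \code{accuracy}, \code{precision},
#'   \code{overall_id_error}, \code{relative_id_error}.
#' @export
performance_metrics <- function(confusion) {
  stopifnot(inherits(confusion, "confusion_summary"))
  pos <- confusion$TP + confusion$FP
  list(accuracy = confusion$TP + confusion$TN,
       precision = if (pos > 0) confusion$TP / pos else NA_real_,
       overall_id_error = confusion$FP + confusion$FN,
       relative_id_error = if (pos > 0) confusion$FP / pos else NA_real_)
}

#' Sweep Best Close Match over a grid of thresholds
#'
#' Evaluates BCM-style confusion classes and performance metrics at each
#' threshold. The default grid is 30 evenly spaced values from 0.15 down to
#' 0.00. Thresholds are processed (and returned) in decreasing order, so the
#' discarded fraction is non-decreasing down the rows.
#'
#' @param dataset a \code{barcode_dataset}.
#' @param dm a \code{k2p_distmat}.
#' @param thresholds numeric vector of thresholds, each >= 0.
#' @param tie_tol tie tolerance passed to the match criteria.
#' @return a \code{sweep_table} data.frame: one row per threshold with
#'   TP/FP/FN/TN proportions, accuracy, precision, overall and relative
#'   identification error, and the discarded fraction.
#' @export
threshold_sweep <- function(dataset, dm,
                            thresholds = seq(0.15, 0, length.out = 30),
                            tie_tol = 1e-12) {
  if (!length(thresholds)) stop("thresholds must be non-empty")
  if (any(thresholds < 0)) stop("thresholds must be >= 0")
  thresholds <- sort(unique(thresholds), decreasing = TRUE)
  bm <- evaluate_dataset(dataset, "BM", dm = dm, tie_tol = tie_tol)
  rows <- lapply(thresholds, function(thr) {
    cs <- classify_confusion(bm$verdicts, thr)
    pm <- performance_metrics(cs)
    data.frame(threshold = thr, TP = cs$TP, FP = cs$FP, FN = cs$FN,
               TN = cs$TN, accuracy = pm$accuracy, precision = pm$precision,
               overall_id_error = pm$overall_id_error,
               relative_id_error = pm$relative_id_error,
               discarded_fraction = cs$FN + cs$TN,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Infer the ad hoc threshold from a sweep by linear regression
#'
#' Ordinary least squares of relative identification error on threshold,
#' over all sweep rows where the error is defined; the ad hoc threshold is
#' the value at which the fitted line reaches \code{max_rel_error}
#' (default 5\%). A non-positive estimate marks the reference library as
#' unreliable for molecular identification at that error level. A
#' zero-variance fit (all errors identical) is degenerate: estimate and
#' reliability are reported as absent.
#'
#' @param sweep a \code{sweep_table}.
#' @param max_rel_error tolerated relative identification error.
#' @return list of class \code{ad_hoc_threshold}: \code{estimate},
#'   \code{r_squared}, \code{reliable}, \code{slope}, \code{intercept},
#'   \code{n_points}, \code{max_rel_error}.
#' @export
ad_hoc_threshold <- function(sweep, max_rel_error = 0.05) {
  stopifnot(is.data.frame(sweep),
            all(c("threshold", "relative_id_error") %in% names(sweep)))
  ok <- !is.na(sweep$relative_id_error)
  if (sum(ok) < 2L) stop("need at least 2 sweep rows with a defined ",
                         "relative identification error")
  x <- sweep$threshold[ok]; y <- sweep$relative_id_error[ok]
  if (stats::var(y) < .Machine$double.eps || stats::var(x) < .Machine$double.eps) {
    return(structure(list(estimate = NA_real_, r_squared = NA_real_,
                          reliable = NA, slope = NA_real_,
                          intercept = NA_real_, n_points = sum(ok),
                          max_rel_error = max_rel_error),
                     class = "ad_hoc_threshold"))
  }
  fit <- stats::lm(y ~ x)
  b <- unname(stats::coef(fit)[2L]); a <- unname(stats::coef(fit)[1L])
  est <- (max_rel_error - a) / b
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(estimate = est, r_squared = r2,
                 reliable = est > 0, slope = b, intercept = a,
                 n_points = sum(ok), max_rel_error = max_rel_error),
            class = "ad_hoc_threshold")
}

#' @export
print.ad_hoc_threshold <- function(x, ...) {
  if (is.na(x$estimate)) {
    cat("ad hoc threshold: degenerate regression (estimate absent)\n")
  } else {
    cat(sprintf("ad hoc threshold at relative ID error %.0f%%: %.4g (R-square %.2f)\n",
                100 * x$max_rel_error, x$estimate, x$r_squared))
    cat(if (isTRUE(x$reliable))
      "  positive estimate: library usable at this error level\n"
      else "  non-positive estimate: library unreliable for identification\n")
  }
  invisible(x)
}

#' Strip singletons and/or named taxa from a dataset
#'
#' Used for the "perfect-world" experiments: named taxa (species or whole
#' genera) are removed first, then singletons -- species left with exactly
#' one ingroup sequence -- if requested. The outgroup is never removed.
#'
#' @param dataset a \code{barcode_dataset}.
#' @param drop_singletons drop all singleton species?
#' @param drop_taxa character vector of species or genus names to drop (a
#'   genus name removes all its species; unknown names are an error).
#' @return a new \code{barcode_dataset}; attributes
#'   \code{n_removed_taxa}, \code{n_removed_singletons} and
#'   \code{removed_species} record the bookkeeping.
#' @export
strip_dataset <- function(dataset, drop_singletons = FALSE,
                          drop_taxa = character()) {
  stopifnot(inherits(dataset, "barcode_dataset"))
  r <- dataset$records
  ing <- !r$specimen_id %in% dataset$outgroup_ids
  unknown <- setdiff(drop_taxa, c(r$species, r$genus))
  if (length(unknown))
    stop("unknown taxon name(s): ", paste(unknown, collapse = ", "))
  drop <- ing & (r$species %in% drop_taxa | r$genus %in% drop_taxa)
  n_taxa_removed <- sum(drop)
  keep <- r[!drop, , drop = FALSE]
  n_singleton_removed <- 0L
  removed_species <- unique(r$species[drop])
  if (drop_singletons) {
    king <- !keep$specimen_id %in% dataset$outgroup_ids
    tab <- table(keep$species[king])
    singles <- names(tab)[tab == 1L]
    sdrop <- king & keep$species %in% singles
    n_singleton_removed <- sum(sdrop)
    removed_species <- c(removed_species, singles)
    keep <- keep[!sdrop, , drop = FALSE]
  }
  out <- barcode_dataset(keep,
                         outgroup_ids = intersect(dataset$outgroup_ids,
                                                  keep$specimen_id))
  attr(out, "n_removed_taxa") <- n_taxa_removed
  attr(out, "n_removed_singletons") <- n_singleton_removed
  attr(out, "removed_species") <- removed_species
  out
}

#' Flag species and genera that resist molecular identification
#'
#' Aggregates leave-one-out reports per species and per genus and flags a
#' taxon when the fraction of its queries that are not correctly identified
#' exceeds a cutoff, or when any of its sequences has a zero-distance
#' allospecific match (an identical barcode in another species -- the
#' clearest symptom of shared or overlapping haplotypes). Flagged taxa are
#' candidates for alternative identification markers.
#'
#' @param reports an \code{identification_report} or a list of them.
#' @param dataset the \code{barcode_dataset} the reports were computed on.
#' @param dm the \code{k2p_distmat}; used to enumerate zero-distance
#'   allospecific pairs exactly (the relation is symmetric by construction).
#' @param noncorrect_cutoff flag when the non-correct fraction exceeds this.
#' @param zero_tol distances at or below this count as zero.
#' @return data.frame with one row per species and per genus: \code{level},
#'   \code{name}, \code{n_queries}, \code{frac_noncorrect},
#'   \code{n_zero_allospecific} (sequences with an identical allospecific
#'   match), \code{flagged}, \code{reason}.
#' @export
flag_problem_taxa <- function(reports, dataset, dm, noncorrect_cutoff = 0.5,
                              zero_tol = 1e-12) {
  if (inherits(reports, "identification_report")) reports <- list(reports)
  if (!length(reports)) stop("need at least one identification report")
  v <- do.call(rbind, lapply(reports, function(rep) {
    stopifnot(inherits(rep, "identification_report"))
    rep$verdicts[, c("query_id", "species", "outcome")]
  }))
  r <- dataset$records
  genus_of <- stats::setNames(r$genus, r$species)
  v$genus <- unname(genus_of[v$species])

  # identical allospecific matches, enumerated over the matrix
  ing <- !dm$ids %in% dataset$outgroup_ids
  sp <- r$species[match(dm$ids, r$specimen_id)]
  zero <- !is.na(dm$d) & dm$d <= zero_tol
  allo <- outer(sp, sp, `!=`)
  zmat <- zero & allo & outer(ing, ing, `&`)
  diag(zmat) <- FALSE
  has_zero_allo <- rowSums(zmat) > 0
  zcount_species <- tapply(has_zero_allo[ing], sp[ing], sum)

  one_level <- function(level, key) {
    agg_n <- tapply(v$outcome, v[[key]], length)
    agg_bad <- tapply(v$outcome != "correct", v[[key]], mean)
    nm <- names(agg_n)
    nz <- if (key == "species") {
      ifelse(nm %in% names(zcount_species), zcount_species[nm], 0L)
    } else {
      vapply(nm, function(g) {
        spg <- unique(r$species[r$genus == g])
        sum(zcount_species[intersect(spg, names(zcount_species))])
      }, numeric(1))
    }
    data.frame(level = level, name = nm, n_queries = as.integer(agg_n),
               frac_noncorrect = as.numeric(agg_bad),
               n_zero_allospecific = as.integer(nz),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_level("species", "species"), one_level("genus", "genus"))
  out$flagged <- out$frac_noncorrect > noncorrect_cutoff |
    out$n_zero_allospecific > 0L
  out$reason <- ifelse(!out$flagged, "",
    ifelse(out$n_zero_allospecific > 0L & out$frac_noncorrect > noncorrect_cutoff,
           "identical allospecific barcodes; mostly not correct",
    ifelse(out$n_zero_allospecific > 0L, "identical allospecific barcodes",
           "mostly not correct")))
  rownames(out) <- NULL
  out
}
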