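# Leave-one-out identification of every ingroup sequence under the five
# criteria: NJT and NJT_M (tree-based), BM, BCM and ASB (similarity-based).
#
# Outcome vocabulary: "correct", "ambiguous", "incorrect", "no_match"
# (no_match only for the threshold-using criteria BCM and ASB). Outgroup
# sequences are never queries and never candidate matches. Singleton species
# can never be "correct" under any criterion.

.OUTCOMES <- c("correct", "ambiguous", "incorrect", "no_match")

# shared context for the similarity criteria
.sim_context <- function(dm, dataset) {
  r <- dataset$records
  idx <- match(dm$ids, r$specimen_id)
  if (anyNA(idx)) stop("distance matrix ids do not match the dataset")
  list(D = dm$d, ids = dm$ids, sp = r$species[idx],
       ing = !dm$ids %in% dataset$outgroup_ids)
}

# Best-Match core for one query index. Tie table (ties = equal distances
# within tie_tol): all tied conspecific -> correct; tie spans the query's
# species plus others -> ambiguous; >= 2 foreign species only -> ambiguous;
# a single foreign species only -> incorrect.
.bm_core <- function(q, ctx, tie_tol) {
  d <- ctx$D[q, ]
  d[q] <- NA; d[!ctx$ing] <- NA
  if (all(is.na(d)))
    return(list(outcome = NA_character_, best_distance = NA_real_,
                matched_species = character()))
  bd <- min(d, na.rm = TRUE)
  tied <- which(!is.na(d) & d <= bd + tie_tol)
  tsp <- unique(ctx$sp[tied])
  qs <- ctx$sp[q]
  outcome <- if (all(tsp == qs)) "correct"
             else if (qs %in% tsp) "ambiguous"
             else if (length(tsp) >= 2L) "ambiguous"
             else "incorrect"
  list(outcome = outcome, best_distance = bd, matched_species = tsp)
}

# All-Species-Barcodes core: correct iff every conspecific outranks every
# allospecific; incorrect iff some single foreign species is entirely closer
# than the closest conspecific; otherwise (interleaving, boundary ties, or a
# singleton query) ambiguous.
.asb_core <- function(q, ctx, threshold, tie_tol) {
  d <- ctx$D[q, ]
  d[q] <- NA; d[!ctx$ing] <- NA
  if (all(is.na(d)))
    return(list(outcome = NA_character_, best_distance = NA_real_,
                matched_species = character()))
  bd <- min(d, na.rm = TRUE)
  qs <- ctx$sp[q]
  tied <- which(!is.na(d) & d <= bd + tie_tol)
  tsp <- unique(ctx$sp[tied])
  if (bd > threshold)
    return(list(outcome = "no_match", best_distance = bd,
                matched_species = character()))
  ref <- which(!is.na(d))
  con <- ref[ctx$sp[ref] == qs]
  allo <- ref[ctx$sp[ref] != qs]
  if (!length(con))   # singleton query with an in-threshold match
    return(list(outcome = "ambiguous", best_distance = bd,
                matched_species = tsp))
  if (!length(allo))
    return(list(outcome = "correct", best_distance = bd,
                matched_species = qs))
  min_con <- min(d[con]); max_con <- max(d[con])
  allo_sp <- split(d[allo], ctx$sp[allo])
  if (any(vapply(allo_sp, max, numeric(1)) < min_con - tie_tol))
    return(list(outcome = "incorrect", best_distance = bd,
                matched_species = tsp))
  outcome <- if (max_con < min(d[allo]) - tie_tol) "correct" else "ambiguous"
  list(outcome = outcome, best_distance = bd, matched_species = tsp)
}

.verdict_row <- function(id, species, criterion, core) {
  data.frame(query_id = id, species = species, criterion = criterion,
             outcome = core$outcome, best_distance = core$best_distance,
             matched_species = paste(core$matched_species, collapse = ","),
             stringsAsFactors = FALSE)
}

.query_index <- function(query_id, ctx) {
  q <- match(query_id, ctx$ids)
  if (is.na(q)) stop("unknown query '", query_id, "'")
  if (!ctx$ing[q]) stop("'", query_id, "' is an outgroup sequence, not a query")
  q
}

#' Best Match (BM) verdict for one query
#'
#' The query is identified by its nearest neighbour among all other ingroup
#' sequences: correct when all equally-nearest matches are conspecific,
#' incorrect when they all belong to one other species, ambiguous when the
#' tie spans more than one species.
#'
#' @param query_id an ingroup specimen id.
#' @param dm a \code{k2p_distmat}.
#' @param dataset the matching \code{barcode_dataset}.
#' @param tie_tol distances within \code{tie_tol} of the minimum count as
#'   equally good matches (absolute; guards against representation noise in
#'   rational distances).
#' @return one-row verdict data.frame (\code{query_id}, \code{species},
#'   \code{criterion}, \code{outcome}, \code{best_distance},
#'   \code{matched_species}).
#' @export
best_match <- function(query_id, dm, dataset, tie_tol = 1e-12) {
  ctx <- .sim_context(dm, dataset)
  q <- .query_index(query_id, ctx)
  core <- .bm_core(q, ctx, tie_tol)
  if (is.na(core$outcome)) warning("query '", query_id,
                                   "' has no defined distances")
  .verdict_row(query_id, ctx$sp[q], "BM", core)
}

#' Best Close Match (BCM) verdict for one query
#'
#' As \code{\link{best_match}}, but the best distance must fall within the
#' threshold (conventionally the 95th percentile of intraspecific
#' distances); otherwise the query has no match.
#'
#' @inheritParams best_match
#' @param threshold distance threshold (proportion, >= 0).
#' @return one-row verdict data.frame.
#' @export
best_close_match <- function(query_id, dm, dataset, threshold,
                             tie_tol = 1e-12) {
  if (threshold < 0) stop("threshold must be >= 0")
  ctx <- .sim_context(dm, dataset)
  q <- .query_index(query_id, ctx)
  core <- .bm_core(q, ctx, tie_tol)
  if (!is.na(core$outcome) && core$best_distance > threshold) {
    core$outcome <- "no_match"; core$matched_species <- character()
  }
  .verdict_row(query_id, ctx$sp[q], "BCM", core)
}

#' All Species Barcodes (ASB) verdict for one query
#'
#' The strictest similarity criterion: within the threshold, identification
#' succeeds only when every conspecific sequence tops the ranked list of
#' matches. An allospecific sequence interleaving before the least similar
#' conspecific makes the query ambiguous; a foreign species entirely closer
#' than all conspecifics makes it a misidentification. A singleton query
#' with an in-threshold match is ambiguous (its "all conspecifics" condition
#' is vacuous and cannot support a positive identification).
#'
#' @inheritParams best_close_match
#' @return one-row verdict data.frame.
#' @export
all_species_barcodes <- function(query_id, dm, dataset, threshold,
                                 tie_tol = 1e-12) {
  if (threshold < 0) stop("threshold must be >= 0")
  ctx <- .sim_context(dm, dataset)
  q <- .query_index(query_id, ctx)
  core <- .asb_core(q, ctx, threshold, tie_tol)
  .verdict_row(query_id, ctx$sp[q], "ASB", core)
}

# tips-below-node lists for a phylo, computed once
.tips_below <- function(tree) {
  phangorn::Descendants(tree, seq_len(ape::Ntip(tree) + tree$Nnode), "tips")
}

# trees are read as rooted at their root node; a basal polytomy (e.g. after
# collapsing) is fine, but the caller is expected to have placed the root
# meaningfully (root_with_outgroup)
.check_tree_dataset <- function(tree, dataset) {
  want <- dataset$records$specimen_id
  if (!setequal(tree$tip.label, want))
    stop("tree leaves do not match the dataset's specimen ids")
}

#' Tree-based identification, species-cluster criterion (NJT)
#'
#' A species is successfully identified when its sequences form an exclusive
#' cluster: the minimal spanning clade of its leaves contains no foreign
#' leaf. Species whose sequences sit at multiple positions in the tree are
#' misidentified; singletons are ambiguous. All sequences of a species share
#' its outcome.
#'
#' @param tree a rooted \code{phylo} whose leaves are the dataset's
#'   specimen ids.
#' @param dataset the matching \code{barcode_dataset}.
#' @return verdict data.frame, one row per ingroup sequence.
#' @export
njt_classify <- function(tree, dataset) {
  .check_tree_dataset(tree, dataset)
  r <- dataset$records
  ing <- !r$specimen_id %in% dataset$outgroup_ids
  below <- .tips_below(tree)
  tipno <- stats::setNames(seq_along(tree$tip.label), tree$tip.label)
  rows <- list()
  for (spname in unique(r$species[ing])) {
    ids <- r$specimen_id[ing & r$species == spname]
    if (length(ids) == 1L) {
      outcome <- "ambiguous"
    } else {
      mrca <- ape::getMRCA(tree, unname(tipno[ids]))
      clade_tips <- tree$tip.label[below[[mrca]]]
      outcome <- if (setequal(clade_tips, ids)) "correct" else "incorrect"
    }
    rows[[spname]] <- data.frame(query_id = ids, species = spname,
                                 criterion = "NJT", outcome = outcome,
                                 best_distance = NA_real_,
                                 matched_species = "",
                                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, unname(rows))
  out <- out[match(r$specimen_id[ing], out$query_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# the deliberately isolated reading of "a sequence sister to conspecifics":
# a single conspecific sibling leaf is treated as ambiguous, not correct
.single_conspecific_sister_outcome <- function() "ambiguous"

#' Tree-based identification, node-level criterion (NJT_M)
#'
#' Refines NJT by judging each leaf from its position one node into the
#' tree. With v the leaf's parent and S(v) the other leaves below v:
#' all of S(v) conspecific and |S(v)| >= 2 (a conspecific cluster or
#' polytomy) is correct; all allospecific and |S(v)| >= 2 is a
#' misidentification; singletons, a single sibling leaf (the sister-group
#' cases) and mixed polytomies are ambiguous. Meant to run on a
#' polytomy-collapsed, rooted tree (see
#' \code{\link{collapse_short_branches}}).
#'
#' @inheritParams njt_classify
#' @return verdict data.frame, one row per ingroup sequence.
#' @export
njt_m_classify <- function(tree, dataset) {
  .check_tree_dataset(tree, dataset)
  r <- dataset$records
  ing <- !r$specimen_id %in% dataset$outgroup_ids
  sp_of <- stats::setNames(r$species, r$specimen_id)
  n_per_sp <- table(r$species[ing])
  below <- .tips_below(tree)
  tipno <- stats::setNames(seq_along(tree$tip.label), tree$tip.label)
  parent_of <- stats::setNames(tree$edge[, 1L], tree$edge[, 2L])
  rows <- lapply(r$specimen_id[ing], function(id) {
    qs <- sp_of[[id]]
    if (n_per_sp[[qs]] == 1L) {
      outcome <- "ambiguous"
    } else {
      tip <- unname(tipno[id])
      v <- unname(parent_of[as.character(tip)])
      sibs <- setdiff(below[[v]], tip)
      sib_sp <- sp_of[tree$tip.label[sibs]]
      consp <- sib_sp == qs   # outgroup leaves are simply allospecific
      outcome <- if (all(consp)) {
        if (length(sibs) >= 2L) "correct" else .single_conspecific_sister_outcome()
      } else if (!any(consp)) {
        if (length(sibs) >= 2L) "incorrect" else "ambiguous"
      } else "ambiguous"
    }
    data.frame(query_id = id, species = qs, criterion = "NJT_M",
               outcome = outcome, best_distance = NA_real_,
               matched_species = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tally identification outcomes into a Table-style summary
#'
#' The reporting layer shared by all criteria: counts per outcome,
#' percentages of all queries (rounded half-up to 2 decimals), and the
#' success rate among non-discarded queries.
#'
#' @param counts named vector or table with entries \code{correct},
#'   \code{ambiguous}, \code{incorrect}, \code{no_match} (missing entries
#'   count as zero).
#' @param n_queries total number of queries.
#' @return list with \code{counts}, \code{pct} (both in fixed outcome
#'   order), and \code{pct_correct_of_nondiscarded}.
#' @export
tally_verdicts <- function(counts, n_queries) {
  full <- stats::setNames(rep(0L, 4L), .OUTCOMES)
  full[names(counts)] <- as.integer(counts)
  if (sum(full) != n_queries)
    stop("counts sum to ", sum(full), ", expected n_queries = ", n_queries)
  pct <- round_half_up(100 * full / n_queries, 2)
  nondisc <- n_queries - full[["no_match"]]
  list(counts = full, pct = pct,
       pct_correct_of_nondiscarded =
         if (nondisc > 0) round_half_up(100 * full[["correct"]] / nondisc, 2)
         else NA_real_)
}

#' Leave-one-out evaluation of a dataset under one criterion
#'
#' Runs every ingroup sequence as a query against all others and tallies the
#' outcomes. Similarity criteria (BM, BCM, ASB) need a distance matrix;
#' tree criteria (NJT, NJT_M) need a rooted tree (for NJT_M, a
#' polytomy-collapsed one); BCM and ASB need a threshold.
#'
#' @param dataset a \code{barcode_dataset}.
#' @param criterion one of \code{"BM"}, \code{"BCM"}, \code{"ASB"},
#'   \code{"NJT"}, \code{"NJT_M"}.
#' @param dm a \code{k2p_distmat} (similarity criteria).
#' @param tree a rooted \code{phylo} (tree criteria).
#' @param threshold distance threshold (BCM/ASB).
#' @param tie_tol tie tolerance for equally good matches.
#' @return an \code{identification_report}: list with \code{criterion},
#'   \code{threshold}, \code{n_queries}, \code{verdicts} (data.frame) and
#'   \code{tallies} (see \code{\link{tally_verdicts}}).
#' @export
evaluate_dataset <- function(dataset,
                             criterion = c("BM", "BCM", "ASB", "NJT", "NJT_M"),
                             dm = NULL, tree = NULL, threshold = NULL,
                             tie_tol = 1e-12) {
  criterion <- match.arg(criterion)
  similarity <- criterion %in% c("BM", "BCM", "ASB")
  if (similarity && is.null(dm))
    stop(criterion, " needs a distance matrix")
  if (!similarity && is.null(tree))
    stop(criterion, " needs a tree")
  if (criterion %in% c("BCM", "ASB")) {
    if (is.null(threshold)) stop(criterion, " needs a threshold")
    if (threshold < 0) stop("threshold must be >= 0")
  } else threshold <- NA_real_

  if (similarity) {
    ctx <- .sim_context(dm, dataset)
    queries <- which(ctx$ing)
    rows <- lapply(queries, function(q) {
      core <- if (criterion == "ASB") .asb_core(q, ctx, threshold, tie_tol)
              else .bm_core(q, ctx, tie_tol)
      if (criterion == "BCM" && !is.na(core$outcome) &&
          core$best_distance > threshold) {
        core$outcome <- "no_match"; core$matched_species <- character()
      }
      .verdict_row(ctx$ids[q], ctx$sp[q], criterion, core)
    })
    verdicts <- do.call(rbind, rows)
  } else {
    verdicts <- if (criterion == "NJT") njt_classify(tree, dataset)
                else njt_m_classify(tree, dataset)
  }
  n <- nrow(verdicts)
  if (anyNA(verdicts$outcome))
    warning(sum(is.na(verdicts$outcome)),
            " quer(ies) had no defined distances and no verdict")
  tallies <- tally_verdicts(table(factor(verdicts$outcome, levels = .OUTCOMES)), n)
  structure(list(criterion = criterion, threshold = threshold,
                 n_queries = n, verdicts = verdicts, tallies = tallies),
            class = "identification_report")
}

#' @export
print.identification_report <- function(x, ...) {
  thr <- if (is.na(x$threshold)) "" else sprintf(" (threshold %.4g)", x$threshold)
  cat(sprintf("identification_report: %s%s, %d queries\n", x$criterion, thr,
              x$n_queries))
  t <- x$tallies
  for (o in .OUTCOMES)
    cat(sprintf("  %-10s %5d  %6.2f%%\n", o, t$counts[[o]], t$pct[[o]]))
  if (!is.na(t$pct_correct_of_nondiscarded))
    cat(sprintf("  correct among non-discarded: %.2f%%\n",
                t$pct_correct_of_nondiscarded))
  invisible(x)
}
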