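# Fixtures and independent oracles shared across the test files. All data
# are built in code; the brute-force evaluators deliberately take a
# different route (ranked lists, ape utilities) than the implementation.

BASES <- c("A", "C", "G", "T")

random_seq <- function(L) paste(sample(BASES, L, replace = TRUE), collapse = "")

# substitute given positions of a sequence with a fixed base
mutate_seq <- function(seq, pos, base = "G") {
  v <- strsplit(seq, "")[[1]]
  v[pos] <- base
  paste(v, collapse = "")
}

# n sequences derived from one random base sequence by scattered point
# mutations -- related enough that every K2P distance is defined
related_seqs <- function(n, L, max_mut = max(3L, L %/% 8L)) {
  base <- random_seq(L)
  vapply(seq_len(n), function(i) {
    pos <- sample(L, sample(1:max_mut, 1))
    mutate_seq(base, pos, sample(BASES, length(pos), replace = TRUE))
  }, character(1))
}

# quick dataset from parallel vectors
toy_dataset <- function(ids, species, seqs, genus = NULL, population = NULL,
                        outgroup = character()) {
  genus <- genus %||% vapply(strsplit(species, " "), `[[`, "", 1L)
  barcode_dataset(data.frame(specimen_id = ids, species = species,
                             genus = genus,
                             population = population %||% NA_character_,
                             sequence = seqs, stringsAsFactors = FALSE),
                  outgroup_ids = outgroup)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a dataset whose labels follow an integer species assignment; sequences are
# irrelevant placeholders (analyses use a hand-built distance matrix)
partition_dataset <- function(assign) {
  n <- length(assign)
  toy_dataset(ids = paste0("q", seq_len(n)),
              species = sprintf("Genus sp%02d", assign),
              seqs = rep(strrep("A", 10), n))
}

# random symmetric distance matrix over a discrete value set (forces ties)
random_distmat <- function(n, values = c(0, 0.001, 0.002, 0.005, 0.01, 0.05)) {
  d <- matrix(0, n, n, dimnames = list(paste0("q", 1:n), paste0("q", 1:n)))
  d[upper.tri(d)] <- sample(values, n * (n - 1) / 2, replace = TRUE)
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  k2p_distmat(d)
}

# ---- independent brute-force rule evaluators (similarity criteria) ----

bf_best_match <- function(q, D, sp, tol = 1e-12) {
  d <- D[q, -q]; s <- sp[-q]
  keep <- !is.na(d); d <- d[keep]; s <- s[keep]
  if (!length(d)) return(NA_character_)
  tied_sp <- unique(s[rank(d, ties.method = "min") == 1 |
                      d <= min(d) + tol])
  if (all(tied_sp == sp[q])) "correct"
  else if (length(tied_sp) > 1L) "ambiguous"
  else "incorrect"
}

bf_best_close_match <- function(q, D, sp, thr, tol = 1e-12) {
  d <- D[q, -q]; d <- d[!is.na(d)]
  if (!length(d)) return(NA_character_)
  if (min(d) > thr) "no_match" else bf_best_match(q, D, sp, tol)
}

bf_asb <- function(q, D, sp, thr, tol = 1e-12) {
  d <- D[q, -q]; s <- sp[-q]
  keep <- !is.na(d); d <- d[keep]; s <- s[keep]
  if (!length(d)) return(NA_character_)
  if (min(d) > thr) return("no_match")
  con <- d[s == sp[q]]; allo <- d[s != sp[q]]
  if (!length(con)) return("ambiguous")
  if (!length(allo)) return("correct")
  # ranked-list reading: does any foreign species sit entirely above all
  # conspecifics? does anything interleave before the worst conspecific?
  per_sp_worst <- tapply(allo, s[s != sp[q]], max)
  if (any(per_sp_worst < min(con) - tol)) return("incorrect")
  if (max(con) < min(allo) - tol) "correct" else "ambiguous"
}

# ---- independent tree-criteria evaluators (ape route) ----

bf_njt <- function(tree, dataset) {
  r <- dataset$records
  ing <- !r$specimen_id %in% dataset$outgroup_ids
  out <- setNames(rep(NA_character_, sum(ing)), r$specimen_id[ing])
  for (spname in unique(r$species[ing])) {
    ids <- r$specimen_id[ing & r$species == spname]
    verdict <- if (length(ids) == 1L) "ambiguous"
      else if (ape::is.monophyletic(tree, ids, reroot = FALSE)) "correct"
      else "incorrect"
    out[ids] <- verdict
  }
  out
}

bf_njtm <- function(tree, dataset) {
  r <- dataset$records
  ing <- !r$specimen_id %in% dataset$outgroup_ids
  sp_of <- setNames(r$species, r$specimen_id)
  counts <- table(r$species[ing])
  out <- setNames(rep(NA_character_, sum(ing)), r$specimen_id[ing])
  for (id in r$specimen_id[ing]) {
    if (counts[[sp_of[[id]]]] == 1L) { out[id] <- "ambiguous"; next }
    tip <- which(tree$tip.label == id)
    parent <- tree$edge[tree$edge[, 2] == tip, 1]
    clade <- ape::extract.clade(tree, parent)$tip.label
    sibs <- setdiff(clade, id)
    consp <- sp_of[sibs] == sp_of[[id]]
    out[id] <- if (all(consp)) {
      if (length(sibs) >= 2) "correct" else "ambiguous"
    } else if (!any(consp)) {
      if (length(sibs) >= 2) "incorrect" else "ambiguous"
    } else "ambiguous"
  }
  out
}

# ---- misc ----

# all set partitions of n items, as integer assignment vectors
set_partitions <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in set_partitions(n - 1L)) {
    k <- max(p)
    for (b in seq_len(k + 1L)) out[[length(out) + 1L]] <- c(p, b)
  }
  out
}

# random rooted tree with positive branch lengths (additive by construction)
random_additive_tree <- function(n) {
  t <- ape::rtree(n, rooted = TRUE)
  t$edge.length <- stats::runif(length(t$edge.length), 0.05, 1)
  t
}
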