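# The five leave-one-out identification criteria and their tallies.

# small fixture: distances chosen by hand around query q1 (species sp01)
fixture_dm <- function(d12, d13, d14, rest = 0.2) {
  ids <- paste0("q", 1:4)
  d <- matrix(rest, 4, 4, dimnames = list(ids, ids)); diag(d) <- 0
  d["q1", "q2"] <- d["q2", "q1"] <- d12
  d["q1", "q3"] <- d["q3", "q1"] <- d13
  d["q1", "q4"] <- d["q4", "q1"] <- d14
  k2p_distmat(d)
}

test_that("best match follows the tie table", {
  ds <- partition_dataset(c(1, 1, 2, 3))
  # unique conspecific nearest -> correct
  v <- best_match("q1", fixture_dm(0.001, 0.01, 0.02), ds)
  expect_equal(v$outcome, "correct")
  expect_equal(v$best_distance, 0.001)
  # unique allospecific nearest -> incorrect
  expect_equal(best_match("q1", fixture_dm(0.01, 0.001, 0.02), ds)$outcome,
               "incorrect")
  # tie across two foreign species -> ambiguous
  expect_equal(best_match("q1", fixture_dm(0.01, 0.001, 0.001), ds)$outcome,
               "ambiguous")
  # tie conspecific + allospecific -> ambiguous
  expect_equal(best_match("q1", fixture_dm(0.001, 0.001, 0.02), ds)$outcome,
               "ambiguous")
  # all-tied single foreign species -> incorrect
  ds2 <- partition_dataset(c(1, 2, 2, 3))
  expect_equal(best_match("q1", fixture_dm(0.001, 0.001, 0.02), ds2)$outcome,
               "incorrect")
  # ties are recognised within tolerance, not exact equality
  expect_equal(best_match("q1", fixture_dm(0.001, 0.001 + 1e-14, 0.02), ds)$outcome,
               "ambiguous")
})

test_that("best close match adds only the threshold gate", {
  ds <- partition_dataset(c(1, 1, 2, 3))
  expect_equal(best_close_match("q1", fixture_dm(0.001, 0.01, 0.02), ds,
                                threshold = 0.003)$outcome, "correct")
  # best match above threshold -> no_match regardless of species
  expect_equal(best_close_match("q1", fixture_dm(0.004, 0.01, 0.02), ds,
                                threshold = 0.003)$outcome, "no_match")
  expect_equal(best_close_match("q1", fixture_dm(0.01, 0.004, 0.02), ds,
                                threshold = 0.003)$outcome, "no_match")
  # tie conspecific+allospecific below threshold -> ambiguous, as in BM
  expect_equal(best_close_match("q1", fixture_dm(0.001, 0.001, 0.02), ds,
                                threshold = 0.003)$outcome, "ambiguous")
  # boundary: a distance equal to the threshold is within it
  expect_equal(best_close_match("q1", fixture_dm(0.003, 0.01, 0.02), ds,
                                threshold = 0.003)$outcome, "correct")
})

test_that("all species barcodes demands every conspecific on top", {
  ds <- partition_dataset(c(1, 1, 1, 2))      # q1..q3 conspecific, q4 foreign
  # conspecifics at 0.001/0.002, foreign at 0.01 -> correct
  expect_equal(all_species_barcodes("q1", fixture_dm(0.001, 0.002, 0.01), ds,
                                    threshold = 0.05)$outcome, "correct")
  # foreign interleaves before the worst conspecific -> ambiguous
  expect_equal(all_species_barcodes("q1", fixture_dm(0.001, 0.01, 0.005), ds,
                                    threshold = 0.05)$outcome, "ambiguous")
  # a foreign species entirely closer than all conspecifics -> incorrect
  expect_equal(all_species_barcodes("q1", fixture_dm(0.01, 0.02, 0.001), ds,
                                    threshold = 0.05)$outcome, "incorrect")
  # nothing within the threshold -> no_match
  expect_equal(all_species_barcodes("q1", fixture_dm(0.01, 0.02, 0.005), ds,
                                    threshold = 0.003)$outcome, "no_match")
  # singleton with an in-threshold match -> ambiguous, never correct
  ds3 <- partition_dataset(c(1, 2, 2, 2))
  expect_equal(all_species_barcodes("q1", fixture_dm(0.001, 0.002, 0.003), ds3,
                                    threshold = 0.05)$outcome, "ambiguous")
})

test_that("similarity verdicts agree with a brute-force evaluator on enumerated toys", {
  set.seed(41)
  thr <- 0.004
  for (n in 4:6) {
    parts <- set_partitions(n)
    for (assign in parts) {
      ds <- partition_dataset(assign)
      dm <- random_distmat(n)
      sp <- ds$records$species
      bm <- evaluate_dataset(ds, "BM", dm = dm)
      bcm <- evaluate_dataset(ds, "BCM", dm = dm, threshold = thr)
      asb <- evaluate_dataset(ds, "ASB", dm = dm, threshold = thr)
      for (q in seq_len(n)) {
        expect_identical(bm$verdicts$outcome[q], bf_best_match(q, dm$d, sp),
                         label = paste("BM", n, paste(assign, collapse = "")))
        expect_identical(bcm$verdicts$outcome[q],
                         bf_best_close_match(q, dm$d, sp, thr))
        expect_identical(asb$verdicts$outcome[q], bf_asb(q, dm$d, sp, thr))
      }
    }
  }
})

test_that("criterion interrelations hold on random datasets", {
  set.seed(42)
  thr <- 0.004
  for (rep in 1:30) {
    n <- sample(5:8, 1)
    ds <- partition_dataset(sample(1:3, n, replace = TRUE))
    dm <- random_distmat(n)
    bm <- evaluate_dataset(ds, "BM", dm = dm)$verdicts
    bcm <- evaluate_dataset(ds, "BCM", dm = dm, threshold = thr)$verdicts
    asb <- evaluate_dataset(ds, "ASB", dm = dm, threshold = thr)$verdicts
    below <- bm$best_distance <= thr
    # BM and BCM agree wherever the best distance is inside the threshold
    expect_identical(bcm$outcome[below], bm$outcome[below])
    # BCM's no_match set is exactly the out-of-threshold queries
    expect_identical(bcm$outcome == "no_match", !below)
    # ASB-correct implies BM-correct (strictly stricter criterion)
    expect_true(all(bm$outcome[asb$outcome == "correct"] == "correct"))
    # singletons can never be correct
    singles <- names(table(ds$records$species))[table(ds$records$species) == 1]
    for (crit in list(bm, bcm, asb))
      expect_false(any(crit$outcome[crit$species %in% singles] == "correct"))
  }
})

test_that("NJT judges species-level monophyly on the tree", {
  txt <- "(((A1:1,A2:1):1,(B1:1,B2:1):1):1,((C1:1,A3:1):1,OUT:4):1);"
  tree <- ape::read.tree(text = txt)
  ds <- toy_dataset(c("A1", "A2", "A3", "B1", "B2", "C1", "OUT"),
                    c("G spA", "G spA", "G spA", "G spB", "G spB", "G spC",
                      "Out spO"),
                    rep(strrep("A", 8), 7), outgroup = "OUT")
  v <- njt_classify(tree, ds)
  out <- setNames(v$outcome, v$query_id)
  # spA is split (A3 sits apart) -> all three incorrect
  expect_equal(unname(out[c("A1", "A2", "A3")]), rep("incorrect", 3))
  # spB monophyletic -> correct; singleton spC -> ambiguous
  expect_equal(unname(out[c("B1", "B2")]), rep("correct", 2))
  expect_equal(unname(out["C1"]), "ambiguous")
  # outcome constant within species, outgroup never judged
  expect_false("OUT" %in% v$query_id)
})

test_that("NJT_M judges each sequence one node into the tree", {
  # polytomy of three conspecifics; a cherry with a conspecific; a leaf one
  # node into a foreign pair; a mixed polytomy
  txt <- paste0("(((P1:1,P2:1,P3:1):1,(S1:1,S2:1):1):1,",
                "((F1:0.5,(X1:1,X2:1):1):1,((M1:1,M2:1,Y1:1):1,F2:1):1):1,",
                "OUT:4);")
  tree <- root_with_outgroup(ape::read.tree(text = txt), "OUT")
  ds <- toy_dataset(
    c("P1", "P2", "P3", "S1", "S2", "F1", "F2", "X1", "X2", "M1", "M2", "Y1",
      "OUT"),
    c("G spP", "G spP", "G spP", "G spS", "G spS", "G spF", "G spF", "G spX",
      "G spX", "G spM", "G spM", "G spY", "Out spO"),
    rep(strrep("A", 8), 13), outgroup = "OUT")
  v <- njt_m_classify(tree, ds)
  out <- setNames(v$outcome, v$query_id)
  # polytomy of conspecifics -> correct
  expect_equal(unname(out[c("P1", "P2", "P3")]), rep("correct", 3))
  # sister to a single conspecific (cherry) -> ambiguous reading
  expect_equal(unname(out[c("S1", "S2")]), rep("ambiguous", 2))
  # one node into a foreign cluster or polytomy -> incorrect
  expect_equal(unname(out["F1"]), "incorrect")
  expect_equal(unname(out["F2"]), "incorrect")
  # mixed polytomy (conspecific + foreign) -> ambiguous
  expect_equal(unname(out[c("M1", "M2")]), rep("ambiguous", 2))
  # singleton -> ambiguous even with structure around it
  expect_equal(unname(out["Y1"]), "ambiguous")
})

test_that("tree criteria agree with independent ape-based evaluators", {
  set.seed(43)
  for (rep in 1:25) {
    n <- sample(5:8, 1)
    tree <- ape::rtree(n, rooted = TRUE, tip.label = paste0("q", 1:n))
    # random polytomies
    if (tree$Nnode > 2 && runif(1) < 0.5) {
      internal <- which(tree$edge[, 2] > ape::Ntip(tree))
      kill <- sample(internal, min(2, length(internal)))
      tree$edge.length[kill] <- 0
      tree <- collapse_short_branches(tree)
    }
    ds <- partition_dataset(sample(1:3, n, replace = TRUE))
    v1 <- njt_classify(tree, ds)
    ref1 <- bf_njt(tree, ds)
    expect_identical(setNames(v1$outcome, v1$query_id), ref1[v1$query_id])
    v2 <- njt_m_classify(tree, ds)
    ref2 <- bf_njtm(tree, ds)
    expect_identical(setNames(v2$outcome, v2$query_id), ref2[v2$query_id])
  }
})

test_that("reports tally verdicts exactly and reject inconsistent counts", {
  set.seed(44)
  ds <- partition_dataset(c(1, 1, 2, 2, 3))
  dm <- random_distmat(5)
  rep_ <- evaluate_dataset(ds, "BCM", dm = dm, threshold = 0.004)
  recount <- table(factor(rep_$verdicts$outcome,
                          levels = c("correct", "ambiguous", "incorrect",
                                     "no_match")))
  expect_equal(unname(rep_$tallies$counts), as.integer(recount))
  expect_equal(sum(rep_$tallies$counts), rep_$n_queries)
  expect_equal(sum(rep_$tallies$pct), 100, tolerance = 0.05)
  expect_error(tally_verdicts(c(correct = 3), 5), "n_queries")
  # prerequisites enforced
  expect_error(evaluate_dataset(ds, "BCM", dm = dm), "threshold")
  expect_error(evaluate_dataset(ds, "BM"), "distance matrix")
  expect_error(evaluate_dataset(ds, "NJT"), "tree")
})
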