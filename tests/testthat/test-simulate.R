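# The synthetic reference-library generator: determinism, divergence
# calibration, scenario pathologies and presets.

test_that("zero divergence collapses the library to one haplotype", {
  cfg <- simulation_config(seed = 5, seq_length = 120, n_genera = 2,
                           species_per_genus = c(2, 2),
                           divergence = list(between_genera = 0,
                                             between_species = 0,
                                             between_populations = 0,
                                             within_population = 0),
                           outgroup_divergence = 0)
  tr <- simulate_dataset(cfg)
  expect_equal(length(unique(tr$dataset$records$sequence)), 1L)
  dm <- distance_matrix(tr$dataset)
  expect_true(all(dm$d == 0))
})

test_that("a fixed seed reproduces the dataset byte for byte", {
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_barcode_fasta(simulate_dataset(preset("host_race", seed = 9))$dataset, f1)
  write_barcode_fasta(simulate_dataset(preset("host_race", seed = 9))$dataset, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # and a different seed does not
  f3 <- withr::local_tempfile(fileext = ".fasta")
  write_barcode_fasta(simulate_dataset(preset("host_race", seed = 10))$dataset, f3)
  expect_false(identical(readBin(f1, "raw", file.size(f1)),
                         readBin(f3, "raw", file.size(f3))))
})

test_that("realised divergences track the configured expectations", {
  # divergence ladder: realised mean distance scales linearly
  lvls <- c(0.01, 0.05, 0.1)
  means <- sapply(lvls, function(dv) {
    cfg <- simulation_config(seed = 7, seq_length = 2000, n_genera = 4,
                             species_per_genus = c(2, 2),
                             populations_per_species = c(1, 1),
                             specimens_per_population = c(2, 2),
                             divergence = list(between_genera = dv,
                                               between_species = dv,
                                               between_populations = 0,
                                               within_population = 0))
    tr <- simulate_dataset(cfg)
    s <- summarize_distances(distance_matrix(tr$dataset), tr$dataset)
    s$interspecific[["mean"]]
  })
  fit <- stats::lm(means ~ lvls)
  expect_equal(unname(stats::coef(fit)[2]), 1, tolerance = 0.1)
  expect_equal(unname(stats::coef(fit)[1]), 0, tolerance = 0.005)
  # per-pair expected divergence in the truth matches the realised K2P
  cfg <- preset("clean", seed = 3)
  tr <- simulate_dataset(cfg)
  dm <- distance_matrix(tr$dataset)
  E <- tr$expected_divergence[dm$ids, dm$ids]
  ut <- upper.tri(E)
  expect_equal(mean(dm$d[ut]), mean(E[ut]), tolerance = 0.1)
})

test_that("the transition bias approaches the configured kappa", {
  # with kappa = 4 and short branches, observed ts/tv should approach the
  # rate-matrix expectation; oracle via eigen-decomposition of the K80
  # generator, independent of the sampler's closed form
  kappa <- 4; t <- 0.05; L <- 60000
  beta <- 1 / (kappa + 2); alpha <- kappa * beta
  Q <- matrix(beta, 4, 4)
  Q[cbind(1:4, c(3, 4, 1, 2))] <- alpha   # A<->G, C<->T
  diag(Q) <- 0; diag(Q) <- -rowSums(Q)
  e <- eigen(Q)
  P <- e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors)
  exp_ts <- P[1, 3]                       # by symmetry all ts entries equal
  exp_tv <- P[1, 2] + P[1, 4]
  cfg <- simulation_config(seed = 8, seq_length = L, n_genera = 1,
                           species_per_genus = c(2, 2),
                           populations_per_species = c(1, 1),
                           specimens_per_population = c(1, 1),
                           divergence = list(between_genera = 2 * t,
                                             between_species = 2 * t,
                                             between_populations = 0,
                                             within_population = 0),
                           kappa = kappa)
  tr <- simulate_dataset(cfg)
  r <- tr$dataset$records
  cp <- count_site_pairs(r$sequence[1], r$sequence[2])
  # two branches of length t: compose the one-branch matrix with itself
  P2 <- P %*% P
  expect_equal(cp$P, P2[1, 3], tolerance = 0.05)
  expect_equal(cp$Q, P2[1, 2] + P2[1, 4], tolerance = 0.05)
  expect_gt(cp$n_transitions / cp$n_transversions, 1)  # kappa > 1 shows
})

test_that("the shared-haplotype scenario plants identical foreign barcodes", {
  tr <- simulate_dataset(preset("urophora_like", seed = 2))
  r <- tr$dataset$records
  g1 <- r$genus == "Genus01"
  seqs <- split(r$sequence[g1], r$species[g1])
  shared <- intersect(seqs[[1]], unlist(seqs[-1]))
  expect_gt(length(shared), 0)
  # and the truth table says those pairs are expected at zero divergence
  h <- tr$hierarchy
  rows1 <- which(h$genus_i == 1L)
  E1 <- tr$expected_divergence[rows1, rows1]
  same_hap <- outer(h$haplotype[rows1], h$haplotype[rows1], `==`)
  expect_true(all(E1[same_hap] == 0))
  expect_true(all(E1[!same_hap] ==
                    tr$config$shared_haplotype_divergence))
})

test_that("host-race populations separate at species-level divergence", {
  tr <- simulate_dataset(preset("host_race", seed = 4))
  h <- tr$hierarchy
  # the designated species is the first species of the last genus
  target <- min(h$species_i[h$genus_i == max(h$genus_i)])
  rows <- which(h$species_i == target)
  expect_gte(length(unique(h$pop_i[rows])), 3L)
  E <- tr$expected_divergence
  cross <- E[rows, rows][outer(h$pop_i[rows], h$pop_i[rows], `!=`)]
  expect_true(all(cross == tr$config$divergence$between_species))
})

test_that("presets deliver their advertised shapes", {
  tr <- simulate_dataset(preset("paper_shaped", seed = 1))
  r <- tr$dataset$records
  ing <- !r$specimen_id %in% tr$dataset$outgroup_ids
  tab <- table(r$species[ing])
  expect_equal(length(tab), 135L)
  expect_equal(sum(tab == 1), 41L)
  expect_equal(length(unique(r$genus[ing])), 42L)
  expect_equal(sum(tab > 15), 1L)
  expect_equal(tr$dataset$alignment_length, 658L)
  # clean preset: no singletons, a clean barcode gap
  tr2 <- simulate_dataset(preset("clean", seed = 1))
  dm2 <- distance_matrix(tr2$dataset)
  tab2 <- table(tr2$dataset$records$species)
  expect_false(any(tab2[names(tab2) != "Outgroup sp01"] == 1))
  g <- barcode_gap_overlap(dm2, tr2$dataset)
  expect_equal(g$overlap_fraction, 0)
  expect_error(preset("nope"), "arg")
})

test_that("simulated singletons are exactly the species that can never be correct", {
  tr <- simulate_dataset(preset("singleton_rich", seed = 6))
  ds <- tr$dataset
  dm <- distance_matrix(ds)
  tab <- table(ds$records$species[!ds$records$specimen_id %in% ds$outgroup_ids])
  singles <- names(tab)[tab == 1]
  expect_gt(length(singles), 0)
  bm <- evaluate_dataset(ds, "BM", dm = dm)$verdicts
  expect_false(any(bm$outcome[bm$species %in% singles] == "correct"))
  # multi-specimen species in this clean-structured library are all correct
  expect_true(all(bm$outcome[!bm$species %in% singles] == "correct"))
})

test_that("impossible configurations are refused", {
  expect_error(simulation_config(n_genera = 0), "n_genera")
  expect_error(simulation_config(divergence = list(between_genera = 0.01,
                                                   between_species = 0.05,
                                                   between_populations = 0,
                                                   within_population = 0)),
               "ordered")
  expect_error(simulation_config(kappa = 0), "kappa")
  expect_error(simulation_config(scenario = "shared_haplotype",
                                 shared_haplotype_species = 1), ">= 2")
})

test_that("coding mode keeps simulated barcodes free of internal stops", {
  cfg <- simulation_config(seed = 12, seq_length = 120, n_genera = 2,
                           species_per_genus = c(2, 2), coding = TRUE,
                           divergence = list(between_genera = 0.13,
                                             between_species = 0.05,
                                             between_populations = 0.004,
                                             within_population = 0.001))
  tr <- simulate_dataset(cfg)
  qc <- check_coding_frame(tr$dataset, genetic_code = "5", frame = 0)
  expect_false(any(qc$has_stop))
  expect_false(any(qc$has_gaps))
})
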