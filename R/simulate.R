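# Synthetic barcode reference libraries with the hierarchical structure the
# analysis assumes: genera containing species containing populations
# containing specimens, evolved under a two-parameter (transition/
# transversion) substitution process, plus the pathological scenarios that
# break threshold-based identification (singletons, a genus with haplotypes
# shared across species, host-race substructure).
#
# Branch lengths are in expected substitutions per site, so a configured
# divergence level is also the expected K2P distance between the
# corresponding pair of sequences -- which makes parameter recovery a
# meaningful end-to-end test.

.BASES <- c("A", "C", "G", "T")
.TS_PARTNER <- c(3L, 4L, 1L, 2L)        # A<->G, C<->T
.TV_PARTNER1 <- c(2L, 1L, 2L, 1L)       # A->C, C->A, G->C, T->A
.TV_PARTNER2 <- c(4L, 3L, 4L, 3L)       # A->T, C->G, G->T, T->G

#' Configure a synthetic barcode dataset
#'
#' Divergence levels are expected pairwise substitutions per site between
#' two sequences of the named relationship (e.g. \code{between_species} is
#' the expected divergence of two specimens of different species in the same
#' genus). They must be non-decreasing up the hierarchy; the
#' \code{shared_haplotype} scenario deliberately violates the species-level
#' ordering inside one designated genus.
#'
#' @param seed integer seed; the whole dataset is deterministic given it.
#' @param seq_length alignment length in bp (default 658, the standard COI
#'   barcode fragment).
#' @param n_genera number of ingroup genera (>= 1).
#' @param species_per_genus inclusive integer range \code{c(lo, hi)}.
#' @param n_species optional total species count overriding the range:
#'   species are then spread over the genera (each genus gets at least one).
#' @param populations_per_species inclusive integer range.
#' @param specimens_per_population inclusive integer range.
#' @param specimens_per_species optional integer vector (one entry per
#'   species, shuffled over species) fixing each species' specimen count;
#'   populations then share the specimens round-robin.
#' @param singleton_fraction fraction of species reduced to a single
#'   specimen (never applied to the scenario's designated problem taxa).
#' @param divergence list with \code{between_genera},
#'   \code{between_species}, \code{between_populations},
#'   \code{within_population}.
#' @param kappa transition/transversion rate ratio (> 0).
#' @param scenario \code{"clean"}, \code{"singleton_rich"},
#'   \code{"shared_haplotype"} or \code{"host_race"}.
#' @param shared_haplotype_species species count of the designated
#'   shared-haplotype genus (scenario \code{shared_haplotype}).
#' @param shared_haplotype_divergence expected divergence between distinct
#'   haplotypes inside that genus.
#' @param outgroup_divergence expected divergence between the single
#'   outgroup sequence and the ingroup.
#' @param coding when TRUE, sequences are regenerated until free of internal
#'   stop codons (frame 0, invertebrate mitochondrial code).
#' @return a validated list of class \code{simulation_config}.
#' @export
simulation_config <- function(seed = 1L,
                              seq_length = 658L,
                              n_genera = 8L,
                              species_per_genus = c(2L, 5L),
                              n_species = NULL,
                              populations_per_species = c(1L, 3L),
                              specimens_per_population = c(1L, 3L),
                              specimens_per_species = NULL,
                              singleton_fraction = 0,
                              divergence = list(between_genera = 0.13,
                                                between_species = 0.05,
                                                between_populations = 0.004,
                                                within_population = 0.001),
                              kappa = 4,
                              scenario = c("clean", "singleton_rich",
                                           "shared_haplotype", "host_race"),
                              shared_haplotype_species = 6L,
                              shared_haplotype_divergence = 0.016,
                              outgroup_divergence = 0.21,
                              coding = FALSE) {
  scenario <- match.arg(scenario)
  if (seq_length < 1L) stop("seq_length must be positive")
  if (n_genera < 1L) stop("n_genera must be >= 1")
  if (kappa <= 0) stop("kappa must be > 0")
  dv <- divergence
  need <- c("between_genera", "between_species", "between_populations",
            "within_population")
  if (!all(need %in% names(dv)))
    stop("divergence must name: ", paste(need, collapse = ", "))
  if (any(unlist(dv[need]) < 0)) stop("divergences must be >= 0")
  if (!(dv$within_population <= dv$between_populations &&
        dv$between_populations <= dv$between_species &&
        dv$between_species <= dv$between_genera))
    stop("divergences must be ordered: within_population <= ",
         "between_populations <= between_species <= between_genera")
  if (singleton_fraction < 0 || singleton_fraction > 1)
    stop("singleton_fraction must be in [0, 1]")
  if (scenario == "shared_haplotype" && shared_haplotype_species < 2L)
    stop("shared_haplotype needs >= 2 species in the designated genus")
  structure(list(seed = as.integer(seed), seq_length = as.integer(seq_length),
                 n_genera = as.integer(n_genera),
                 species_per_genus = as.integer(species_per_genus),
                 n_species = if (is.null(n_species)) NULL else as.integer(n_species),
                 populations_per_species = as.integer(populations_per_species),
                 specimens_per_population = as.integer(specimens_per_population),
                 specimens_per_species = specimens_per_species,
                 singleton_fraction = singleton_fraction,
                 divergence = dv[need], kappa = kappa, scenario = scenario,
                 shared_haplotype_species = as.integer(shared_haplotype_species),
                 shared_haplotype_divergence = shared_haplotype_divergence,
                 outgroup_divergence = outgroup_divergence,
                 coding = isTRUE(coding)),
            class = "simulation_config")
}

# K80 substitution probabilities for one branch of length t (expected
# substitutions per site): alpha = transition rate, beta = each-transversion
# rate, normalised so alpha + 2*beta = 1.
.k80_probs <- function(t, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1          # each of the two transversion targets
  c(p_same = 1 - p_ts - 2 * p_tv, p_ts = p_ts, p_tv = p_tv)
}

.has_internal_stop <- function(seq_int) {
  n_codons <- length(seq_int) %/% 3L
  if (n_codons < 2L) return(FALSE)
  starts <- seq.int(1L, by = 3L, length.out = n_codons - 1L)
  codons <- paste0(.BASES[seq_int[starts]], .BASES[seq_int[starts + 1L]],
                   .BASES[seq_int[starts + 2L]])
  any(codons %in% c("TAA", "TAG"))  # invertebrate mitochondrial stops
}

# evolve an integer-coded sequence along a branch of length t
.evolve <- function(seq_int, t, kappa, coding = FALSE) {
  if (t <= 0) return(seq_int)
  p <- .k80_probs(t, kappa)
  for (try in seq_len(100L)) {
    u <- stats::runif(length(seq_int))
    out <- seq_int
    is_ts <- u >= p[["p_same"]] & u < p[["p_same"]] + p[["p_ts"]]
    is_tv <- u >= p[["p_same"]] + p[["p_ts"]]
    out[is_ts] <- .TS_PARTNER[seq_int[is_ts]]
    tv1 <- is_tv & (u - p[["p_same"]] - p[["p_ts"]] < p[["p_tv"]])
    tv2 <- is_tv & !tv1
    out[tv1] <- .TV_PARTNER1[seq_int[tv1]]
    out[tv2] <- .TV_PARTNER2[seq_int[tv2]]
    if (!coding || !.has_internal_stop(out)) return(out)
  }
  stop("could not generate a stop-codon-free sequence in 100 draws")
}

.random_root <- function(L, coding) {
  for (try in seq_len(100L)) {
    s <- sample.int(4L, L, replace = TRUE)
    if (!coding || !.has_internal_stop(s)) return(s)
  }
  stop("could not generate a stop-codon-free root sequence")
}

#' Simulate a barcode reference library
#'
#' Draws a genus/species/population/specimen hierarchy from the configured
#' ranges and evolves sequences down it under the two-parameter model, with
#' per-level branch lengths chosen so each configured divergence equals the
#' expected pairwise divergence at that level. Scenario modifiers are
#' applied last. A single outgroup sequence is always included. Deterministic
#' given \code{config$seed}.
#'
#' Scenarios: \code{singleton_rich} is the clean process with a high
#' singleton fraction; \code{shared_haplotype} designates the first genus as
#' problematic -- its populations carry identical haplotypes reused across
#' species boundaries, at low inter-haplotype divergence; \code{host_race}
#' splits the first species of the last genus into three host populations
#' separated by species-level divergence.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return a \code{simulated_truth}: list with \code{dataset} (a
#'   \code{barcode_dataset}), \code{hierarchy} (per-record genus, species,
#'   population, haplotype assignments), \code{expected_divergence}
#'   (matrix of expected pairwise substitutions per site) and the echoed
#'   \code{config}.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  dv <- config$divergence
  kappa <- config$kappa
  L <- config$seq_length
  t_I <- dv$within_population / 2
  t_P <- (dv$between_populations - dv$within_population) / 2
  t_S <- (dv$between_species - dv$between_populations) / 2
  t_G <- (dv$between_genera - dv$between_species) / 2

  # ---- hierarchy sizes ----
  ng <- config$n_genera
  if (!is.null(config$n_species)) {
    if (config$n_species < ng) stop("n_species must be >= n_genera")
    extra <- stats::rmultinom(1L, config$n_species - ng, rep(1, ng))[, 1L]
    sp_per_genus <- 1L + extra
  } else {
    sp_per_genus <- .rint(ng, config$species_per_genus[1L],
                          config$species_per_genus[2L])
  }
  problem_genus <- 0L
  if (config$scenario == "shared_haplotype") {
    problem_genus <- 1L
    sp_per_genus[1L] <- config$shared_haplotype_species
  }
  host_race_genus <- if (config$scenario == "host_race") ng else 0L

  species <- data.frame(genus_i = rep(seq_len(ng), sp_per_genus))
  species$species_i <- unlist(lapply(sp_per_genus, seq_len))
  nsp <- nrow(species)
  species$genus <- sprintf("Genus%02d", species$genus_i)
  species$name <- sprintf("%s sp%02d", species$genus, species$species_i)
  host_race_species <-
    if (host_race_genus > 0L) which(species$genus_i == host_race_genus)[1L] else 0L

  # specimen counts per species
  if (!is.null(config$specimens_per_species)) {
    cnt <- as.integer(config$specimens_per_species)
    if (length(cnt) != nsp)
      stop("specimens_per_species must have one entry per species (",
           nsp, ")")
    species$n_specimens <- sample(cnt)
  } else {
    npop <- .rint(nsp, config$populations_per_species[1L],
                  config$populations_per_species[2L])
    spp <- .rint(nsp, config$specimens_per_population[1L],
                 config$specimens_per_population[2L])
    species$n_specimens <- npop * spp
  }
  # singleton demotion (protected: problem genus and the host-race species)
  protected <- species$genus_i == problem_genus |
    seq_len(nsp) == host_race_species
  n_single <- round(config$singleton_fraction * nsp)
  eligible <- which(!protected)
  if (n_single > 0L && length(eligible)) {
    demote <- sample(eligible, min(n_single, length(eligible)))
    species$n_specimens[demote] <- 1L
  }
  species$n_specimens <- pmax(species$n_specimens, 1L)
  if (host_race_species > 0L)
    species$n_specimens[host_race_species] <-
      max(species$n_specimens[host_race_species], 6L)

  # populations per species, specimens distributed round-robin
  pop_lo <- config$populations_per_species[1L]
  pop_hi <- config$populations_per_species[2L]
  species$n_pops <- pmin(species$n_specimens, .rint(nsp, pop_lo, pop_hi))
  if (problem_genus > 0L) {
    pg <- species$genus_i == problem_genus   # need >= 2 pops to share across species
    species$n_pops[pg] <- pmin(species$n_specimens[pg],
                               pmax(species$n_pops[pg], 2L))
  }
  if (host_race_species > 0L) species$n_pops[host_race_species] <- 3L

  # ---- sequence evolution ----
  root <- .random_root(L, config$coding)
  genus_seq <- lapply(seq_len(ng), function(g)
    .evolve(root, t_G, kappa, config$coding))

  rec <- list(); hier <- list()
  t_hap <- config$shared_haplotype_divergence / 2
  hap_pool <- NULL
  if (problem_genus > 0L) {
    H <- sp_per_genus[problem_genus]
    hap_pool <- lapply(seq_len(H), function(h)
      .evolve(genus_seq[[problem_genus]], t_hap, kappa, config$coding))
  }
  for (s in seq_len(nsp)) {
    g <- species$genus_i[s]
    in_problem <- g == problem_genus
    is_hr <- s == host_race_species
    sp_seq <- if (in_problem) NULL
              else .evolve(genus_seq[[g]], t_S, kappa, config$coding)
    npop <- species$n_pops[s]
    per_pop <- tabulate(rep(seq_len(npop), length.out = species$n_specimens[s]),
                        nbins = npop)
    k <- 0L
    for (p in seq_len(npop)) {
      if (in_problem) {
        H <- length(hap_pool)
        hap <- ((species$species_i[s] + p - 2L) %% H) + 1L
        pop_seq <- hap_pool[[hap]]
      } else {
        hap <- NA_integer_
        t_pop <- if (is_hr) (dv$between_species - dv$within_population) / 2 else t_P
        pop_seq <- .evolve(sp_seq, t_pop, kappa, config$coding)
      }
      for (i in seq_len(per_pop[p])) {
        k <- k + 1L
        seq_i <- if (in_problem) pop_seq     # population members identical
                 else .evolve(pop_seq, t_I, kappa, config$coding)
        id <- sprintf("G%02dS%02dP%02d-%02d", g, species$species_i[s], p, i)
        rec[[length(rec) + 1L]] <- data.frame(
          specimen_id = id, species = species$name[s],
          genus = species$genus[s], population = sprintf("pop%02d", p),
          sequence = paste(.BASES[seq_i], collapse = ""),
          stringsAsFactors = FALSE)
        hier[[length(hier) + 1L]] <- data.frame(
          specimen_id = id, genus_i = g, species_i = s, pop_i = p,
          haplotype = hap, stringsAsFactors = FALSE)
      }
    }
  }
  # outgroup
  depth <- t_G + t_S + t_P + t_I
  t_O <- max(config$outgroup_divergence - depth, 0)
  out_seq <- .evolve(root, t_O, kappa, config$coding)
  rec[[length(rec) + 1L]] <- data.frame(
    specimen_id = "OUT01", species = "Outgroup sp01", genus = "Outgroup",
    population = NA_character_,
    sequence = paste(.BASES[out_seq], collapse = ""), stringsAsFactors = FALSE)
  hier[[length(hier) + 1L]] <- data.frame(
    specimen_id = "OUT01", genus_i = 0L, species_i = 0L, pop_i = 0L,
    haplotype = NA_integer_, stringsAsFactors = FALSE)

  records <- do.call(rbind, rec)
  hierarchy <- do.call(rbind, hier)
  dataset <- barcode_dataset(records, outgroup_ids = "OUT01")

  # ---- expected pairwise divergences ----
  n <- nrow(hierarchy)
  E <- matrix(0, n, n, dimnames = list(hierarchy$specimen_id,
                                       hierarchy$specimen_id))
  gi <- hierarchy$genus_i; si <- hierarchy$species_i; pi_ <- hierarchy$pop_i
  hp <- hierarchy$haplotype
  for (a in seq_len(n - 1L)) for (b in seq.int(a + 1L, n)) {
    e <- if (gi[a] == 0L || gi[b] == 0L) {
      t_O + depth
    } else if (gi[a] != gi[b]) {
      dv$between_genera
    } else if (gi[a] == problem_genus) {
      if (!is.na(hp[a]) && hp[a] == hp[b]) 0 else config$shared_haplotype_divergence
    } else if (si[a] != si[b]) {
      dv$between_species
    } else if (si[a] == host_race_species && pi_[a] != pi_[b]) {
      dv$between_species
    } else if (pi_[a] != pi_[b]) {
      dv$between_populations
    } else {
      dv$within_population
    }
    E[a, b] <- E[b, a] <- e
  }
  structure(list(dataset = dataset, hierarchy = hierarchy,
                 expected_divergence = E, config = config),
            class = "simulated_truth")
}

#' @export
print.simulated_truth <- function(x, ...) {
  cat(sprintf("simulated_truth (scenario '%s', seed %d):\n",
              x$config$scenario, x$config$seed))
  print(x$dataset)
  invisible(x)
}

#' Ready-made simulation configurations
#'
#' \describe{
#'   \item{clean}{30 species (10 genera x 3), 4 specimens each in one
#'     population; interspecific divergence 0.10, intraspecific 0.002; a
#'     textbook barcode gap and no singletons.}
#'   \item{singleton_rich}{the clean process with 30\% of species reduced
#'     to one specimen.}
#'   \item{urophora_like}{a library with one genus of six species sharing
#'     identical haplotypes across species at low divergence, population
#'     members identical, and 30\% singletons elsewhere -- the combination
#'     that produces identical allospecific matches and an unusable ad hoc
#'     threshold.}
#'   \item{host_race}{a clean-style library whose designated species splits
#'     into three host populations at species-level divergence.}
#'   \item{paper_shaped}{135 species in 42 genera with the specimen
#'     histogram 41 x 1, 78 x 2-8, 15 x 9-15, 1 x 23, population
#'     substructure, and divergences placing the intraspecific mean near
#'     0.25\% and the intergeneric mean near 15\%.}
#' }
#'
#' @param name preset name.
#' @param seed seed stored in the returned config.
#' @return a \code{\link{simulation_config}}.
#' @export
preset <- function(name = c("clean", "singleton_rich", "urophora_like",
                            "host_race", "paper_shaped"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
    clean = simulation_config(
      seed = seed, n_genera = 10L, species_per_genus = c(3L, 3L),
      populations_per_species = c(1L, 1L), specimens_per_population = c(4L, 4L),
      divergence = list(between_genera = 0.15, between_species = 0.10,
                        between_populations = 0.002, within_population = 0.002),
      kappa = 4, scenario = "clean"),
    singleton_rich = simulation_config(
      seed = seed, n_genera = 10L, species_per_genus = c(3L, 3L),
      populations_per_species = c(1L, 1L), specimens_per_population = c(4L, 4L),
      singleton_fraction = 0.3,
      divergence = list(between_genera = 0.15, between_species = 0.10,
                        between_populations = 0.002, within_population = 0.002),
      kappa = 4, scenario = "singleton_rich"),
    urophora_like = simulation_config(
      seed = seed, n_genera = 8L, species_per_genus = c(3L, 5L),
      populations_per_species = c(2L, 3L), specimens_per_population = c(2L, 3L),
      singleton_fraction = 0.3,
      divergence = list(between_genera = 0.13, between_species = 0.05,
                        between_populations = 0.004, within_population = 0),
      kappa = 4, scenario = "shared_haplotype",
      shared_haplotype_species = 6L, shared_haplotype_divergence = 0.016),
    host_race = simulation_config(
      seed = seed, n_genera = 8L, species_per_genus = c(2L, 4L),
      populations_per_species = c(1L, 2L), specimens_per_population = c(2L, 3L),
      divergence = list(between_genera = 0.13, between_species = 0.05,
                        between_populations = 0.004, within_population = 0.001),
      kappa = 4, scenario = "host_race"),
    paper_shaped = simulation_config(
      seed = seed, n_genera = 42L, n_species = 135L,
      populations_per_species = c(2L, 4L),
      specimens_per_species = c(rep(1L, 41L),
                                rep(2:8, length.out = 78L),
                                rep(9:15, length.out = 15L), 23L),
      divergence = list(between_genera = 0.15, between_species = 0.05,
                        between_populations = 0.004, within_population = 0.001),
      kappa = 4, scenario = "clean", outgroup_divergence = 0.21)
  )
}
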