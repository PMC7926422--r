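# Synthetic-data generators: every input the pipeline consumes can be
# simulated with known ground truth, so all stages are testable without any
# external download. All generators are pure functions of the configuration;
# a single global seed fans out to independent per-generator substreams so
# adding a generator does not perturb existing fixtures.

#' Configuration for the synthetic-data generators
#'
#' Defaults emulate the scale of the study the pipeline targets: a 17-motif
#' PLS editing factor with E1/E2 C-terminus screened against a proteome of
#' 205 candidate PLS proteins; dramatic editing loss (95% to 0%) at a
#' handful of sites among hundreds of unchanged ones at several-hundred-fold
#' coverage; and an orthologue panel of ~20 editable plus ~20 non-editable
#' species.
#'
#' @param seed integer master seed; the same seed gives byte-identical
#'   outputs from every generator.
#' @param motif_types motif-type labels the trainer emits.
#' @param n_pairs_per_type distinct aa5/aa_last pairs trained per motif type.
#' @param n_obs_per_pair training observations per pair.
#' @param contrast strength of the planted nucleotide preference: the
#'   preferred base has multinomial weight `exp(contrast)`, the others 1.
#'   0 means no signal.
#' @param n_motifs P/L/S motifs in the planted protein (E1 and E2 are
#'   appended).
#' @param n_decoys random decoy proteins for ranking experiments.
#' @param n_motifs_range motif-count range for decoys.
#' @param n_lost_sites,lost_rates planted differential sites and their
#'   (genotype A, genotype B) editing rates.
#' @param n_stable_sites sites with equal rates in both genotypes.
#' @param stable_rate_range rates for stable sites are drawn uniformly here.
#' @param coverage_range per-site read coverage is drawn uniformly here.
#' @param error_rate symmetric base-miscall rate in the count simulator.
#' @param n_editable,n_noneditable species counts in the orthologue panel.
#' @param divergence_rate per-position substitution probability in
#'   non-editable species' windows.
#' @param conservation_factor fraction of `divergence_rate` still felt by
#'   editable species' windows (binding-site conservation; default 0.1).
#' @return list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             motif_types = c("P1", "L1", "S1", "P2", "L2", "S2"),
                             n_pairs_per_type = 20L,
                             n_obs_per_pair = 40L,
                             contrast = 3,
                             n_motifs = 17L,
                             n_decoys = 204L,
                             n_motifs_range = c(10L, 20L),
                             n_lost_sites = 4L,
                             lost_rates = c(0.95, 0.00),
                             n_stable_sites = 200L,
                             stable_rate_range = c(0.05, 0.95),
                             coverage_range = c(500L, 1000L),
                             error_rate = 0.001,
                             n_editable = 20L,
                             n_noneditable = 20L,
                             divergence_rate = 0.3,
                             conservation_factor = 0.1) {
  cfg <- as.list(environment())
  rates <- c(cfg$lost_rates, cfg$stable_rate_range, cfg$error_rate,
             cfg$divergence_rate, cfg$conservation_factor)
  if (any(rates < 0 | rates > 1)) stopf("all rates must lie in [0,1]")
  if (cfg$contrast < 0) stopf("contrast must be >= 0")
  if (any(cfg$coverage_range < 0)) stopf("coverage must be >= 0")
  structure(cfg, class = "generator_config")
}

sample_pairs <- function(n) {
  # unique aa5/aa_last pairs
  pool <- expand.grid(aa5 = AA_ALPHABET, aa_last = AA_ALPHABET,
                      stringsAsFactors = FALSE)
  pool[sample.int(nrow(pool), n), , drop = FALSE]
}

#' Simulate PPR-code training observations with planted base preferences
#'
#' For each motif type, draws `n_pairs_per_type` amino-acid pairs, assigns
#' each a uniformly chosen preferred base, and samples per-pair nucleotide
#' counts from a multinomial in which the preferred base has weight
#' `exp(contrast)` and the other three weight 1. With `contrast = 0` the
#' counts are uniform in expectation (no signal).
#'
#' @param config a [generator_config()].
#' @return list: `observations` (data frame consumable by
#'   [build_scoring_tables()]) and `preferences` (the ground-truth map:
#'   motif_type, aa5, aa_last, preferred base).
#' @export
simulate_training_observations <- function(config) {
  set.seed(substream_seed(config$seed, "training"))
  obs <- list(); prefs <- list()
  for (mt in config$motif_types) {
    pairs <- sample_pairs(config$n_pairs_per_type)
    pref <- sample(RNA_ALPHABET, nrow(pairs), replace = TRUE)
    w <- exp(config$contrast)
    for (i in seq_len(nrow(pairs))) {
      prob <- rep(1, 4); prob[match(pref[i], RNA_ALPHABET)] <- w
      counts <- stats::rmultinom(1, config$n_obs_per_pair, prob / sum(prob))[, 1]
      obs[[length(obs) + 1L]] <- data.frame(
        motif_type = mt, aa5 = pairs$aa5[i], aa_last = pairs$aa_last[i],
        nucleotide = RNA_ALPHABET, weight = counts, stringsAsFactors = FALSE)
    }
    prefs[[mt]] <- data.frame(motif_type = mt, aa5 = pairs$aa5,
                              aa_last = pairs$aa_last, preferred = pref,
                              stringsAsFactors = FALSE)
  }
  observations <- do.call(rbind, c(obs, list(make.row.names = FALSE)))
  observations <- observations[observations$weight > 0, , drop = FALSE]
  rownames(observations) <- NULL
  list(observations = observations,
       preferences = do.call(rbind, c(prefs, list(make.row.names = FALSE))))
}

random_protein <- function(id, n_motifs, motif_types, pair_pool) {
  types <- sample(motif_types, n_motifs, replace = TRUE)
  rows <- pair_pool[sample.int(nrow(pair_pool), n_motifs, replace = TRUE), ,
                    drop = FALSE]
  ppr_protein(id, data.frame(
    index = seq_len(n_motifs + 2L),
    motif_type = c(types, "E1", "E2"),
    aa5 = c(rows$aa5, "G", "G"),
    aa_last = c(rows$aa_last, "N", "N"),
    stringsAsFactors = FALSE))
}

#' Simulate a planted factor/target pair plus decoy proteins
#'
#' Builds a protein whose code residues match the planted base preferences
#' of its target window position-by-position (a perfect match under the
#' trained code), together with `n_decoys` proteins with random residues.
#'
#' @param config a [generator_config()].
#' @param training optional output of [simulate_training_observations()]
#'   (regenerated deterministically from `config` when omitted).
#' @return list: `protein`, `site`, `decoys`, `training`.
#' @export
simulate_protein_with_target <- function(config, training = NULL) {
  if (is.null(training)) training <- simulate_training_observations(config)
  prefs <- training$preferences
  set.seed(substream_seed(config$seed, "protein"))

  n <- config$n_motifs
  types <- sample(config$motif_types, n, replace = TRUE)
  picks <- lapply(types, function(mt) {
    p <- prefs[prefs$motif_type == mt, , drop = FALSE]
    p[sample.int(nrow(p), 1L), , drop = FALSE]
  })
  picks <- do.call(rbind, picks)
  protein <- ppr_protein("planted", data.frame(
    index = seq_len(n + 2L),
    motif_type = c(types, "E1", "E2"),
    aa5 = c(picks$aa5, "G", "G"),
    aa_last = c(picks$aa_last, "N", "N"),
    stringsAsFactors = FALSE))

  # window: motif i (N->C) faces offset -(n + 3) + (i - 1); E1 at -3, E2 at
  # -2 and the two 3'-most positions are unconstrained; last base is the C.
  len <- n + 4L
  bases <- sample(RNA_ALPHABET, len, replace = TRUE)
  bases[seq_len(n)] <- picks$preferred
  bases[len] <- "C"
  site <- editing_site("planted-site", paste(bases, collapse = ""))

  pair_pool <- unique(prefs[, c("aa5", "aa_last")])
  decoys <- lapply(seq_len(config$n_decoys), function(i)
    random_protein(sprintf("decoy-%03d", i),
                   sample(config$n_motifs_range[1]:config$n_motifs_range[2], 1L),
                   config$motif_types, pair_pool))
  list(protein = protein, site = site, decoys = decoys, training = training)
}

#' Simulate per-position count matrices for two genotypes
#'
#' Plants `n_lost_sites` sites whose editing rate changes between genotypes
#' (default 0.95 to 0.00) among `n_stable_sites` sites edited at the same
#' (uniformly drawn) rate in both. Per site and genotype, coverage is drawn
#' uniformly from `coverage_range` and edited reads binomially at the site's
#' rate; symmetric base miscalls are added at `error_rate`.
#'
#' @param config a [generator_config()].
#' @return list: `matrix_a`, `matrix_b` (`site_count_matrix` data frames)
#'   and `truth` (position, rate per genotype, class `"lost"`/`"stable"`).
#' @export
simulate_count_matrices <- function(config) {
  set.seed(substream_seed(config$seed, "counts"))
  n <- config$n_lost_sites + config$n_stable_sites
  positions <- sort(sample.int(10 * max(n, 1L), n))
  cls <- sample(rep(c("lost", "stable"),
                    c(config$n_lost_sites, config$n_stable_sites)))
  rate_a <- rate_b <- numeric(n)
  stable_rates <- stats::runif(n, config$stable_rate_range[1],
                               config$stable_rate_range[2])
  rate_a[cls == "stable"] <- rate_b[cls == "stable"] <- stable_rates[cls == "stable"]
  rate_a[cls == "lost"] <- config$lost_rates[1]
  rate_b[cls == "lost"] <- config$lost_rates[2]

  sim_one <- function(rates) {
    cov <- if (config$coverage_range[2] > config$coverage_range[1])
      sample(config$coverage_range[1]:config$coverage_range[2], n, replace = TRUE)
    else rep(config$coverage_range[1], n)
    edited <- stats::rbinom(n, cov, rates)
    noise_a <- stats::rbinom(n, cov, config$error_rate)
    noise_g <- stats::rbinom(n, cov, config$error_rate)
    df <- data.frame(position = positions, ref = "C", strand = "+",
                     A = noise_a, C = cov - edited, G = noise_g, T = edited,
                     stringsAsFactors = FALSE)
    class(df) <- c("site_count_matrix", "data.frame")
    df
  }
  list(matrix_a = sim_one(rate_a), matrix_b = sim_one(rate_b),
       truth = data.frame(position = positions, rate_a = rate_a,
                          rate_b = rate_b, class = cls,
                          stringsAsFactors = FALSE))
}

mutate_window <- function(bases, rate, keep_last = TRUE) {
  n <- length(bases)
  idx <- which(stats::runif(n) < rate)
  if (keep_last) idx <- setdiff(idx, n)
  for (i in idx) bases[i] <- sample(setdiff(RNA_ALPHABET, bases[i]), 1L)
  bases
}

#' Simulate an orthologue panel with controlled binding-site conservation
#'
#' Starts from the planted factor/target of [simulate_protein_with_target()]
#' and emits one record per species. Editable species keep the genomic C and
#' drift window positions at `divergence_rate * conservation_factor`
#' (purifying selection on the binding site); non-editable species carry U
#' (genomic T) at the site and drift at the full `divergence_rate` (the
#' binding site is free to decay once editing is no longer needed).
#'
#' @param config a [generator_config()].
#' @param planted optional output of [simulate_protein_with_target()].
#' @return list: `records` (list of [species_site_record()]s) and `planted`.
#' @export
simulate_orthologue_panel <- function(config, planted = NULL) {
  if (is.null(planted)) planted <- simulate_protein_with_target(config)
  set.seed(substream_seed(config$seed, "ortho"))
  base0 <- strsplit(planted$site$window, "", fixed = TRUE)[[1]]
  make <- function(i, editable) {
    b <- base0
    if (editable) {
      b <- mutate_window(b, config$divergence_rate * config$conservation_factor)
    } else {
      b <- mutate_window(b, config$divergence_rate)
      b[length(b)] <- "U"
    }
    species_site_record(
      sprintf("%s-sp-%02d", if (editable) "ed" else "ne", i),
      planted$site$site_id, paste(b, collapse = ""), planted$protein)
  }
  records <- c(lapply(seq_len(config$n_editable), make, editable = TRUE),
               lapply(seq_len(config$n_noneditable), make, editable = FALSE))
  list(records = records, planted = planted)
}
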