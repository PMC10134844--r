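#' Describe the design of a top-down-control dilution experiment
#'
#' The default design mirrors the field protocol this package analyses: two
#' dilution treatments (protists-diluted, where the 0.22-um diluent removes
#' protists but retains viruses, and protists+viruses-diluted, where a 30-kDa
#' diluent removes both), a four-point gradient with 25/50/75/100% of the
#' original top-down-control effect remaining, duplicate bottles, and a 12-h
#' incubation. Composition is sequenced once at T0 (the shared source water)
#' and per bottle at T12; total bacterial density is measured per bottle at
#' both timepoints.
#'
#' @param dilution_factors fractions of the original top-down-control effect
#'   remaining, each in (0, 1].
#' @param treatments subset of `c("protists", "protists_viruses")`.
#' @param n_replicates bottles per treatment x dilution factor.
#' @param duration incubation length in hours.
#' @param read_depth reads per composition sample (multinomial size). The
#'   default matches a rarefaction depth of 3188 reads.
#' @param initial_density total bacterial density of the source water,
#'   cells/mL.
#' @param density_cv coefficient of variation of the flow-cytometry density
#'   measurement (lognormal multiplicative noise); 0 means noise-free.
#' @param exact_proportions if `TRUE`, composition samples carry exact
#'   relative abundances instead of multinomial read counts. This noiseless
#'   mode makes downstream estimates analytically predictable and is used to
#'   separate estimation error from sampling noise.
#' @param dilute_inoculum if `TRUE`, initial bottle densities are scaled by
#'   the dilution factor (the bacterial inoculum is itself diluted along with
#'   its predators). Immaterial to the per-capita analysis; off by default.
#' @param seed master seed for all randomness in the simulated experiment.
#' @return a list of class `"ExperimentDesign"`.
#' @export
#' @examples
#' experimentDesign(seed = 7)
experimentDesign <- function(dilution_factors = c(0.25, 0.5, 0.75, 1),
                             treatments = c("protists", "protists_viruses"),
                             n_replicates = 2L,
                             duration = 12,
                             read_depth = 3188L,
                             initial_density = 1e6,
                             density_cv = 0.05,
                             exact_proportions = FALSE,
                             dilute_inoculum = FALSE,
                             seed = 1L) {
  if (any(dilution_factors <= 0 | dilution_factors > 1))
    stop("dilution factors must lie in (0, 1]")
  if (anyDuplicated(dilution_factors)) stop("dilution factors must be distinct")
  if (!all(treatments %in% c("protists", "protists_viruses")) ||
      !length(treatments))
    stop("treatments must be a subset of c('protists', 'protists_viruses')")
  if (duration <= 0) stop("duration must be positive")
  if (!isCount(read_depth)) stop("read_depth must be a positive integer")
  if (!isCount(n_replicates)) stop("n_replicates must be a positive integer")
  if (initial_density <= 0) stop("initial_density must be positive")
  if (density_cv < 0) stop("density_cv must be non-negative")
  structure(list(dilution_factors = sort(dilution_factors),
                 treatments = treatments,
                 n_replicates = as.integer(n_replicates),
                 duration = duration,
                 read_depth = as.integer(read_depth),
                 initial_density = initial_density,
                 density_cv = density_cv,
                 exact_proportions = isTRUE(exact_proportions),
                 dilute_inoculum = isTRUE(dilute_inoculum),
                 seed = as.integer(seed)),
            class = "ExperimentDesign")
}

#' Draw ground-truth taxon traits with a built-in competition-resistance
#' trade-off
#'
#' Each taxon receives an intrinsic (top-down-control-free) growth rate `g`,
#' a protist-grazing mortality `m_P` and a viral-lysis mortality `m_V` (both
#' at full predator/virus strength, h^-1), and an initial relative abundance
#' `p0`. Mortalities are linear in `g` plus Gaussian noise, so `beta_P` and
#' `beta_V` set the strength of the kill-the-winner trade-off: positive
#' slopes mean faster growers die faster.
#'
#' The default rates emulate a productive coastal bacterioplankton community:
#' mean growth 0.10 h^-1, and grazing/lysis each consuming roughly 40% of
#' production at full strength.
#'
#' @param n_taxa number of taxa (>= 2).
#' @param g_mean,g_sd mean and sd of the growth-rate distribution (normal,
#'   truncated at 0), h^-1.
#' @param alpha_P,beta_P intercept (h^-1) and slope (unitless) of the
#'   grazing-mortality trade-off `m_P = alpha_P + beta_P * g + noise`.
#' @param alpha_V,beta_V same for viral-lysis mortality.
#' @param noise_sd sd of the mortality noise, h^-1.
#' @param abundance_shape lognormal sdlog of initial relative abundances.
#' @param seed integer seed; identical seeds give identical trait tables.
#' @return `data.frame` with columns `taxon_id`, `g`, `m_P`, `m_V`, `p0`.
#' @export
#' @examples
#' tr <- drawTraits(5, seed = 7)
#' stopifnot(all.equal(sum(tr$p0), 1))
drawTraits <- function(n_taxa, g_mean = 0.10, g_sd = 0.05,
                       alpha_P = 0, beta_P = 0.4,
                       alpha_V = 0, beta_V = 0.4,
                       noise_sd = 0.01, abundance_shape = 1.5,
                       seed = 1L) {
  if (!isCount(n_taxa) || n_taxa < 2) stop("n_taxa must be an integer >= 2")
  if (g_sd < 0 || noise_sd < 0 || abundance_shape < 0)
    stop("dispersions must be non-negative")
  set.seed(as.integer(seed))
  g <- pmax(0, stats::rnorm(n_taxa, g_mean, g_sd))
  m_P <- pmax(0, alpha_P + beta_P * g + stats::rnorm(n_taxa, 0, noise_sd))
  m_V <- pmax(0, alpha_V + beta_V * g + stats::rnorm(n_taxa, 0, noise_sd))
  p0 <- stats::rlnorm(n_taxa, 0, abundance_shape)
  data.frame(taxon_id = sprintf("ASV%03d", seq_len(n_taxa)),
             g = g, m_P = m_P, m_V = m_V, p0 = p0 / sum(p0))
}

#' Realised per-capita net growth rate under a dilution treatment
#'
#' Under the protists+viruses-diluted treatment both mortality sources are
#' scaled by the dilution factor `d`: `r = g - d * (m_P + m_V)`. Under the
#' protists-diluted treatment the 0.22-um diluent passes viruses, so viral
#' mortality stays at full strength: `r = g - d * m_P - m_V`. Consequently
#' the regression of `r` on `d` has slope `-(m_P + m_V)` and intercept `g`
#' under protists+viruses, and slope `-m_P` with intercept `g - m_V` under
#' protists alone.
#'
#' @param g,m_P,m_V trait vectors (h^-1), recycled to a common length.
#' @param treatment `"protists"` or `"protists_viruses"`.
#' @param d dilution fraction in (0, 1].
#' @return per-capita net growth rate(s), h^-1.
#' @export
#' @examples
#' netRate(0.10, 0.04, 0.02, "protists", 0.5) # 0.06
netRate <- function(g, m_P, m_V, treatment, d) {
  treatment <- match.arg(treatment, c("protists", "protists_viruses"))
  if (any(d <= 0 | d > 1)) stop("dilution fraction must lie in (0, 1]")
  if (treatment == "protists_viruses") g - d * (m_P + m_V)
  else g - d * m_P - m_V
}

#' Multinomial read sampling of a composition
#'
#' Observation model for 16S sequencing: one multinomial draw of `depth`
#' reads from the true relative abundances.
#'
#' @param p simplex vector of true relative abundances (sums to 1 within
#'   1e-9, non-negative).
#' @param depth total reads (>= 1).
#' @param seed integer seed.
#' @return integer count vector summing exactly to `depth`.
#' @export
sampleReads <- function(p, depth, seed = 1L) {
  if (any(p < 0)) stop("abundances must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) stop("abundances must sum to 1")
  if (!isCount(depth)) stop("depth must be a positive integer")
  set.seed(as.integer(seed))
  as.integer(stats::rmultinom(1, size = depth, prob = p))
}

#' Noisy density measurement
#'
#' Flow-cytometry noise model: lognormal multiplicative error with a given
#' coefficient of variation and unbiased mean, so the expected measurement
#' equals the true density.
#'
#' @param true_density true total density, cells/mL (> 0).
#' @param cv coefficient of variation (>= 0); 0 returns `true_density`
#'   exactly.
#' @param seed integer seed.
#' @return measured density, cells/mL.
#' @export
observeDensity <- function(true_density, cv, seed = 1L) {
  if (any(true_density <= 0)) stop("density must be positive")
  if (cv < 0) stop("cv must be non-negative")
  if (cv == 0) return(true_density)
  set.seed(as.integer(seed))
  sdlog <- sqrt(log(1 + cv^2))
  true_density * stats::rlnorm(length(true_density), -sdlog^2 / 2, sdlog)
}

#' Simulate one full dilution experiment with known ground truth
#'
#' Generates the complete observable record of one experiment: a single T0
#' composition sample from the shared source water, one T12 composition
#' sample per bottle, and density measurements per bottle at both timepoints.
#' Within each bottle every taxon grows exponentially at the rate given by
#' [netRate()] for the bottle's treatment and dilution factor; there is no
#' density dependence over the 12-h incubation.
#'
#' All randomness derives from `design$seed` through per-sample substreams
#' ([childSeed()]), so the dataset is a pure function of `(design, traits)`.
#'
#' @param design an [experimentDesign()] object.
#' @param traits a trait table from [drawTraits()] (or equivalent columns).
#' @param experiment experiment label carried into the metadata.
#' @return a [DilutionExperiment-class] with ground truth attached.
#' @export
#' @examples
#' dex <- simulateExperiment(experimentDesign(seed = 3), drawTraits(8, seed = 3))
#' dim(dex) # 8 taxa x 17 samples
simulateExperiment <- function(design, traits, experiment = "exp1") {
  stopifnot(inherits(design, "ExperimentDesign"))
  need <- c("taxon_id", "g", "m_P", "m_V", "p0")
  if (!all(need %in% names(traits))) stop("traits lacks required columns")
  if (any(traits$m_P < 0) || any(traits$m_V < 0)) stop("mortalities must be >= 0")
  if (any(traits$p0 <= 0) || abs(sum(traits$p0) - 1) > 1e-12)
    stop("p0 must be positive and sum to 1")
  if (anyDuplicated(traits$taxon_id)) stop("taxon_ids must be unique")

  bottles <- expand.grid(replicate = seq_len(design$n_replicates),
                         dilution_factor = design$dilution_factors,
                         treatment = design$treatments,
                         stringsAsFactors = FALSE)
  bottles <- bottles[c("treatment", "dilution_factor", "replicate")]
  nb <- nrow(bottles)
  ntax <- nrow(traits)

  compose <- function(p, stream) {
    if (design$exact_proportions) p
    else sampleReads(p, design$read_depth, childSeed(design$seed, stream))
  }

  counts <- matrix(0, ntax, nb + 1L,
                   dimnames = list(traits$taxon_id, NULL))
  counts[, 1L] <- compose(traits$p0, 1L)
  sample_ids <- c(paste0(experiment, "_T0"), character(nb))
  meta <- data.frame(sample_id = sample_ids, experiment = experiment,
                     treatment = "source", dilution_factor = NA_real_,
                     replicate = NA_integer_, timepoint = "T0",
                     stringsAsFactors = FALSE)
  dens <- vector("list", nb)

  for (i in seq_len(nb)) {
    b <- bottles[i, ]
    n0 <- design$initial_density * traits$p0 *
      if (design$dilute_inoculum) b$dilution_factor else 1
    r <- netRate(traits$g, traits$m_P, traits$m_V, b$treatment,
                 b$dilution_factor)
    n12 <- n0 * exp(r * design$duration)
    counts[, i + 1L] <- compose(n12 / sum(n12), 10L * i)
    sid <- sprintf("%s_%s_d%02d_r%d", experiment,
                   if (b$treatment == "protists") "P" else "PV",
                   round(100 * b$dilution_factor), b$replicate)
    sample_ids[i + 1L] <- sid
    meta[i + 1L, ] <- list(sid, experiment, b$treatment, b$dilution_factor,
                           as.integer(b$replicate), "T12")
    dens[[i]] <- data.frame(
      experiment = experiment, treatment = b$treatment,
      dilution_factor = b$dilution_factor, replicate = as.integer(b$replicate),
      timepoint = c("T0", "T12"),
      cells_per_ml = c(
        observeDensity(sum(n0), design$density_cv, childSeed(design$seed, 10L * i + 1L)),
        observeDensity(sum(n12), design$density_cv, childSeed(design$seed, 10L * i + 2L))),
      stringsAsFactors = FALSE)
  }
  colnames(counts) <- sample_ids
  meta$sample_id <- sample_ids
  DilutionExperiment(counts, meta, do.call(rbind, dens), truth = traits)
}
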