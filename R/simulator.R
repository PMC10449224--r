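#' Simulation scenario configuration
#'
#' Defines the two-population introgression scenario: a recipient population
#' of `N_recipient` diploids and a source (archaic) population of `N_source`
#' diploids evolve in isolation for `isolation_generations`; a
#' single-generation pulse then replaces a fraction `pulse_fraction` of the
#' recipient with source individuals whose female fraction is
#' `female_fraction_pulse` (the sex-bias parameter `p`); the recipient then
#' evolves for `post_pulse_generations` more generations. Defaults are the
#' study conditions: a 25,000-diploid recipient, a 250-diploid source
#' (recipient 100 times the source), 20,000 generations of isolation, a 5%
#' pulse, and 15,000 post-pulse generations.
#'
#' `scaling_factor` Q rescales for tractability: population sizes and
#' generation counts are divided by Q while selection coefficients, the
#' mutation rate and recombination rates are multiplied by Q, preserving the
#' population-scaled parameters 2Ns, 2Nu and 2Nr.
#'
#' @param N_recipient,N_source diploid population sizes at full (nominal) scale.
#' @param isolation_generations,post_pulse_generations generation counts at
#'   full (nominal) scale.
#' @param pulse_fraction fraction of the recipient replaced by the pulse.
#' @param female_fraction_pulse female fraction `p` of the introgressors.
#' @param recipient_female_fraction standing female fraction of the recipient
#'   (and source) population.
#' @param inheritance `"autosomal"` or `"chrX"`.
#' @param dominance_h dominance coefficient applied to every mutation.
#' @param scaling_factor integer rescaling factor Q >= 1.
#' @param pulse_mode `"exact"` (deterministic migrant count and sex split) or
#'   `"stochastic"` (per-individual replacement and per-migrant sex draws).
#' @param sex_assignment `"deterministic"` (exact female count each
#'   generation) or `"bernoulli"`.
#' @param seed integer seed governing the whole run.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(N_recipient = 25000, N_source = 250,
                       isolation_generations = 20000,
                       post_pulse_generations = 15000,
                       pulse_fraction = 0.05, female_fraction_pulse = 0.5,
                       recipient_female_fraction = 0.5,
                       inheritance = c("autosomal", "chrX"),
                       dominance_h = 0.5, scaling_factor = 2,
                       pulse_mode = c("exact", "stochastic"),
                       sex_assignment = c("deterministic", "bernoulli"),
                       seed = 1L) {
  inheritance <- match.arg(inheritance)
  pulse_mode <- match.arg(pulse_mode)
  sex_assignment <- match.arg(sex_assignment)
  stopifnot(pulse_fraction > 0, pulse_fraction < 1,
            female_fraction_pulse >= 0, female_fraction_pulse <= 1,
            recipient_female_fraction > 0, recipient_female_fraction < 1,
            scaling_factor >= 1, dominance_h >= 0, dominance_h <= 1)
  q <- scaling_factor
  cfg <- structure(
    list(N_recipient = N_recipient, N_source = N_source,
         isolation_generations = isolation_generations,
         post_pulse_generations = post_pulse_generations,
         pulse_fraction = pulse_fraction,
         female_fraction_pulse = female_fraction_pulse,
         recipient_female_fraction = recipient_female_fraction,
         inheritance = inheritance, dominance_h = dominance_h,
         scaling_factor = q, pulse_mode = pulse_mode,
         sex_assignment = sex_assignment, seed = as.integer(seed),
         # scaled quantities actually simulated
         N_recipient_scaled = as.integer(round(N_recipient / q)),
         N_source_scaled = as.integer(round(N_source / q)),
         isolation_scaled = as.integer(round(isolation_generations / q)),
         post_pulse_scaled = as.integer(round(post_pulse_generations / q))),
    class = "sim_config"
  )
  if (cfg$N_source_scaled < 2 || cfg$N_recipient_scaled < 2) {
    stop("configuration error: scaled population sizes are too small")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %s, h = %g, p = %g\n  N_r = %d, N_s = %d, isolation %d + post-pulse %d generations (Q = %g: simulated as %d/%d diploids, %d + %d generations)\n  pulse %g (%s), recipient female fraction %g, seed %d\n",
    x$inheritance, x$dominance_h, x$female_fraction_pulse,
    x$N_recipient, x$N_source, x$isolation_generations,
    x$post_pulse_generations, x$scaling_factor, x$N_recipient_scaled,
    x$N_source_scaled, x$isolation_scaled, x$post_pulse_scaled,
    x$pulse_fraction, x$pulse_mode, x$recipient_female_fraction, x$seed))
  invisible(x)
}

sexes_for <- function(n, female_fraction) {
  nf <- round(female_fraction * n)
  c(rep(0L, nf), rep(1L, n - nf))
}

#' Create a simulation world (engine handle)
#'
#' Builds the C++ engine holding the recipient (population `"recipient"`) and
#' source (`"source"`) populations, both initialized mutation-free at
#' generation 0 with deterministic sex counts. The returned handle is a
#' mutable reference: stepping functions modify it in place.
#'
#' @param config a [sim_config].
#' @param map a [chromosome_map]; its inheritance mode must match the config.
#' @param dfe a [dfe_params].
#' @return Object of class `sim_world`.
#' @export
sim_world <- function(config, map, dfe = dfe_params()) {
  stopifnot(inherits(config, "sim_config"), inherits(map, "chromosome_map"),
            inherits(dfe, "dfe_params"))
  if (map$inheritance != config$inheritance) {
    stop("configuration error: map inheritance (", map$inheritance,
         ") does not match config (", config$inheritance, ")")
  }
  q <- config$scaling_factor
  eng <- .engine_new(
    map$length_bp, config$inheritance == "chrX",
    as.numeric(map$exons[, 1]), as.numeric(map$exons[, 2]),
    as.numeric(map$recomb$start), as.numeric(map$recomb$end),
    as.numeric(map$recomb$rate) * q,
    dfe$shape_k, dfe$scale_theta, config$dominance_h,
    dfe$mutation_rate * q, q, 1e-9
  )
  .engine_init_pop(eng, 0L, sexes_for(config$N_recipient_scaled,
                                      config$recipient_female_fraction))
  .engine_init_pop(eng, 1L, sexes_for(config$N_source_scaled,
                                      config$recipient_female_fraction))
  structure(list(engine = eng, config = config, map = map, dfe = dfe),
            class = "sim_world")
}

pop_index <- function(population = c("recipient", "source")) {
  if (match.arg(population) == "recipient") 0L else 1L
}

#' Advance a population by one Wright-Fisher generation
#'
#' Offspring draw a mother from the females and a father from the males with
#' probability proportional to multiplicative fitness; gametes recombine over
#' the map (X: female meiosis only; fathers pass their single X intact to
#' daughters and nothing to sons); new deleterious mutations fall in exons.
#'
#' @param world a [sim_world] (modified in place).
#' @param population `"recipient"` or `"source"`.
#' @param generations number of generations to advance.
#' @return The world, invisibly.
#' @export
wright_fisher_step <- function(world, population = "recipient",
                               generations = 1L) {
  .engine_run(world$engine, pop_index(population), as.integer(generations),
              world$config$recipient_female_fraction,
              world$config$sex_assignment == "bernoulli")
  invisible(world)
}

#' Burn in both populations through the isolation phase
#'
#' Evolves source and recipient independently for the (scaled) isolation
#' period under mutation, selection and drift, then labels every source
#' haplotype 100% archaic so descent from the pulse generation can be tracked
#' exactly.
#'
#' @param world a [sim_world] (modified in place).
#' @return The world, invisibly.
#' @export
burn_in <- function(world) {
  g <- world$config$isolation_scaled
  wright_fisher_step(world, "recipient", g)
  wright_fisher_step(world, "source", g)
  .engine_mark_archaic(world$engine, 1L)
  invisible(world)
}

#' Apply the single-generation introgression pulse
#'
#' Migrant individuals bred from the source population replace recipient
#' individuals (Wright-Fisher migration: each migrant's parents are drawn
#' from the source with replacement, weighted by fitness, so the pulse can
#' exceed the source census size). Every source haplotype is fully
#' archaic-labeled at pulse time, so every migrant haplotype is too. In
#' `"exact"` mode `m = round(pulse_fraction * N_recipient)` migrants with
#' `round(p * m)` females enter; in `"stochastic"` mode each recipient is
#' independently replaced with probability `pulse_fraction` and each migrant
#' is female with probability `p`. The archaic haplotypes entering number
#' `2m` for autosomes and `2 * females + males` for chromosome X.
#'
#' @param world a [sim_world] (modified in place), after [burn_in()].
#' @return Diagnostics list: `n_migrants`, `n_female`, `archaic_haplotypes`,
#'   `realized_pulse_fraction`, `realized_female_fraction`.
#' @export
introgression_pulse <- function(world) {
  d <- .engine_pulse(world$engine, world$config$pulse_fraction,
                     world$config$female_fraction_pulse,
                     world$config$pulse_mode == "exact")
  d$realized_pulse_fraction <- d$n_migrants / world$config$N_recipient_scaled
  d$realized_female_fraction <- if (d$n_migrants > 0) {
    d$n_female / d$n_migrants
  } else {
    NA_real_
  }
  d
}

#' Sample haplotypes from a population
#'
#' Uniform sampling without replacement from all haplotypes present (two per
#' female or autosomal individual, one per chrX male).
#'
#' @param world a [sim_world].
#' @param k number of haplotypes.
#' @param population `"recipient"` or `"source"`.
#' @return List of `k` two-column tract matrices.
#' @export
sample_haplotypes <- function(world, k, population = "recipient") {
  .engine_sample_haps(world$engine, pop_index(population), as.integer(k))
}

#' Inspect a population's state
#'
#' @param world a [sim_world].
#' @param population `"recipient"` or `"source"`.
#' @return List with `generation`, `n` and `individuals`; each individual has
#'   `sex`, `h1` and `h2` (NULL for chrX males), and each haplotype its tract
#'   matrix and mutation positions/coefficients/ids.
#' @export
population_state <- function(world, population = "recipient") {
  .engine_get_pop(world$engine, pop_index(population))
}

#' Overwrite one haplotype of one individual (testing/initialization hook)
#'
#' @param world a [sim_world] (modified in place).
#' @param individual 1-based individual index.
#' @param hap 1 or 2.
#' @param tracts two-column matrix of archaic tracts.
#' @param mut_pos,mut_s positions and (scaled) selection coefficients of
#'   mutations carried by the haplotype; fresh mutation ids are assigned, so
#'   two haplotypes set this way never count as homozygous.
#' @param population `"recipient"` or `"source"`.
#' @return The world, invisibly.
#' @export
set_haplotype <- function(world, individual, hap, tracts,
                          mut_pos = numeric(0), mut_s = numeric(0),
                          population = "recipient") {
  stopifnot(hap %in% c(1, 2))
  tracts <- matrix(as.numeric(as.matrix(tracts)), ncol = 2)
  .engine_set_hap(world$engine, pop_index(population),
                  as.integer(individual) - 1L, as.integer(hap), tracts,
                  as.numeric(mut_pos), as.numeric(mut_s))
  invisible(world)
}

#' Per-individual fitness values
#'
#' @param world a [sim_world].
#' @param population `"recipient"` or `"source"`.
#' @return Numeric vector of multiplicative fitnesses.
#' @export
population_fitness <- function(world, population = "recipient") {
  .engine_fitness(world$engine, pop_index(population))
}

#' Per-individual counts of deleterious mutations above a threshold
#'
#' @param world a [sim_world].
#' @param s_min count mutations with unscaled selection coefficient above
#'   this value.
#' @param population `"recipient"` or `"source"`.
#' @return Integer vector of counts.
#' @export
deleterious_load <- function(world, s_min = 0.01, population = "recipient") {
  .engine_load_counts(world$engine, pop_index(population),
                      s_min * world$config$scaling_factor)
}

default_schedule <- function(post_pulse_scaled) {
  g <- unique(c(1, seq(2, min(40, post_pulse_scaled), by = 2),
                seq(50, post_pulse_scaled, by = 50), post_pulse_scaled))
  sort(g[g >= 1 & g <= post_pulse_scaled])
}

#' Run a complete introgression scenario
#'
#' Orchestrates burn-in, pulse and the post-pulse phase, sampling
#' `sample_size` haplotypes without replacement from the recipient at each
#' scheduled generation (in scaled generations since the pulse) and recording
#' their coverage (tracts of at least `min_tract_bp`) and raw tract sets.
#'
#' @param config a [sim_config].
#' @param map a [chromosome_map].
#' @param dfe a [dfe_params].
#' @param sample_schedule generations since the pulse (scaled units) at which
#'   to sample; default: 1, every 2 generations to 40, every 50 thereafter,
#'   and the final generation.
#' @param sample_size haplotypes per sample.
#' @param min_tract_bp coverage filter passed to [compute_coverage()].
#' @param keep_tracts keep raw tract matrices for each sampled generation
#'   (otherwise only for the final generation).
#' @return Object of class `scenario_result`: `coverage` (data frame of all
#'   coverage records with columns `generation`, `haplotype_id`, `coverage`,
#'   `n_tracts`, `total_tract_bp`; generations counted since the pulse),
#'   `tracts` (list keyed by generation), `pulse` diagnostics, `config`,
#'   `L`, `schedule`.
#' @export
run_scenario <- function(config, map, dfe = dfe_params(),
                         sample_schedule = NULL, sample_size = 1000,
                         min_tract_bp = 500, keep_tracts = FALSE) {
  schedule <- sort(unique(as.integer(
    sample_schedule %||% default_schedule(config$post_pulse_scaled)
  )))
  if (length(schedule) == 0 || min(schedule) < 0 ||
      max(schedule) > config$post_pulse_scaled) {
    stop("sample schedule must lie within [0, post_pulse_scaled]")
  }
  set.seed(config$seed)
  world <- sim_world(config, map, dfe)
  burn_in(world)
  pulse <- introgression_pulse(world)

  final_gen <- config$post_pulse_scaled
  cov_list <- list()
  tract_list <- list()
  take_sample <- function(gen) {
    haps <- sample_haplotypes(world, sample_size)
    recs <- vapply(haps, function(tr) {
      len <- if (nrow(tr) > 0) tr[, 2] - tr[, 1] else numeric(0)
      keep <- len >= min_tract_bp
      c(sum(len[keep]), sum(keep))
    }, numeric(2))
    cov_list[[length(cov_list) + 1]] <<- data.frame(
      generation = gen, haplotype_id = seq_len(sample_size),
      coverage = recs[1, ] / map$length_bp, n_tracts = as.integer(recs[2, ]),
      total_tract_bp = recs[1, ])
    if (keep_tracts || gen == final_gen) {
      tract_list[[as.character(gen)]] <<- haps
    }
  }
  if (0 %in% schedule) take_sample(0)
  for (g in seq_len(final_gen)) {
    wright_fisher_step(world, "recipient")
    if (g %in% schedule) take_sample(g)
  }
  structure(
    list(coverage = do.call(rbind, cov_list), tracts = tract_list,
         pulse = pulse, config = config, L = map$length_bp,
         schedule = schedule, mean_recomb_rate = mean_recombination_rate(map),
         engine_info = .engine_info(world$engine)),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  fin <- x$coverage[x$coverage$generation == max(x$coverage$generation), ]
  cat(sprintf(
    "<scenario_result> %s, h = %g, p = %g: %d sampled generations\n  pulse: %d migrants (%d female); final mean coverage %.4f over %d haplotypes\n",
    x$config$inheritance, x$config$dominance_h,
    x$config$female_fraction_pulse, length(x$schedule),
    x$pulse$n_migrants, x$pulse$n_female, mean(fin$coverage), nrow(fin)))
  invisible(x)
}

#' Final-generation coverage values of a scenario result
#'
#' @param result a `scenario_result`.
#' @return Numeric vector of per-haplotype coverages at the last sampled
#'   generation.
#' @export
final_coverage <- function(result) {
  cov <- result$coverage
  cov$coverage[cov$generation == max(cov$generation)]
}
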