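test_that("pulse arithmetic matches the expected haplotype counts", {
  # scaled N = 1000, 5% pulse: 50 introgressors, 25 female;
  # autosomal archaic haplotypes 100, chrX 75, ratio 4/3
  for (inh in c("autosomal", "chrX")) {
    cfg <- sim_config(N_recipient = 1000, N_source = 100,
                      isolation_generations = 1, post_pulse_generations = 1,
                      pulse_fraction = 0.05, female_fraction_pulse = 0.5,
                      inheritance = inh, scaling_factor = 1, seed = 2)
    map <- synthesize_chromosome_map(1e6, seed = 5, inheritance = inh)
    set.seed(2)
    w <- sim_world(cfg, map, dfe_params(mutation_rate = 0))
    burn_in(w)
    d <- introgression_pulse(w)
    expect_equal(d$n_migrants, 50)
    expect_equal(d$n_female, 25)
    expect_equal(d$archaic_haplotypes, if (inh == "chrX") 75 else 100)
  }
  # p = 1 and p = 0 bracket the 2/(1+p) haplotype-count ratio
  counts <- vapply(c(0, 1), function(p) {
    out <- numeric(2)
    for (i in 1:2) {
      inh <- c("autosomal", "chrX")[i]
      cfg <- sim_config(N_recipient = 1000, N_source = 100,
                        isolation_generations = 1, post_pulse_generations = 1,
                        pulse_fraction = 0.05, female_fraction_pulse = p,
                        inheritance = inh, scaling_factor = 1, seed = 3)
      map <- synthesize_chromosome_map(1e6, seed = 5, inheritance = inh)
      set.seed(3)
      w <- sim_world(cfg, map, dfe_params(mutation_rate = 0))
      burn_in(w)
      out[i] <- introgression_pulse(w)$archaic_haplotypes
    }
    out[1] / out[2]
  }, numeric(1))
  expect_equal(counts, c(2, 1))  # Eq-1 endpoints
})

test_that("ancestry is conserved when everyone is archaic", {
  w <- tiny_world("autosomal", n_rec = 30, mutation_rate = 0)
  st <- population_state(w)
  L <- w$map$length_bp
  for (i in seq_len(st$n)) {
    set_haplotype(w, i, 1, matrix(c(0, L), ncol = 2))
    set_haplotype(w, i, 2, matrix(c(0, L), ncol = 2))
  }
  wright_fisher_step(w)
  st <- population_state(w)
  for (ind in st$individuals) {
    expect_equal(unname(ind$h1$tracts), matrix(c(0, L), ncol = 2))
    expect_equal(unname(ind$h2$tracts), matrix(c(0, L), ncol = 2))
  }
})

test_that("a son never inherits X material from his father", {
  w <- tiny_world("chrX", n_rec = 40, mutation_rate = 0)
  st <- population_state(w)
  L <- w$map$length_bp
  # tag every male X with a full-length tract; females stay blank
  for (i in seq_len(st$n)) {
    if (st$individuals[[i]]$sex == "male") {
      set_haplotype(w, i, 1, matrix(c(0, L), ncol = 2))
    }
  }
  wright_fisher_step(w)
  st <- population_state(w)
  for (ind in st$individuals) {
    if (ind$sex == "male") {
      # sons carry only the (blank) maternal X
      expect_identical(nrow(ind$h1$tracts), 0L)
      expect_null(ind$h2)
    } else {
      # daughters carry the tagged paternal X intact
      expect_equal(unname(ind$h2$tracts), matrix(c(0, L), ncol = 2))
      expect_identical(nrow(ind$h1$tracts), 0L)
    }
  }
})

test_that("neutral transmission keeps the expected archaic fraction", {
  # one generation of drift: over 200 replicates the mean offspring archaic
  # fraction stays within 3 binomial standard errors of the parental fraction
  set.seed(77)
  fracs <- replicate(200, {
    w <- tiny_world("autosomal", n_rec = 50, mutation_rate = 0,
                    seed = sample.int(1e6, 1))
    st <- population_state(w)
    L <- w$map$length_bp
    for (i in 1:25) set_haplotype(w, i, 1, matrix(c(0, L), ncol = 2))
    wright_fisher_step(w)
    st <- population_state(w)
    tot <- 0
    for (ind in st$individuals) {
      for (h in list(ind$h1, ind$h2)) {
        if (nrow(h$tracts) > 0) tot <- tot + sum(h$tracts[, 2] - h$tracts[, 1])
      }
    }
    tot / (100 * L)
  })
  p0 <- 0.25
  se <- sqrt(p0 * (1 - p0) / 100) / sqrt(200)
  expect_lt(abs(mean(fracs) - p0), 3 * se)
})

test_that("runs are reproducible under a fixed seed", {
  cfg <- sim_config(N_recipient = 200, N_source = 20,
                    isolation_generations = 20, post_pulse_generations = 20,
                    pulse_fraction = 0.05, inheritance = "autosomal",
                    scaling_factor = 1, seed = 31)
  map <- synthesize_chromosome_map(1e6, seed = 5)
  r1 <- run_scenario(cfg, map, dfe_params(), sample_schedule = c(1, 20),
                     sample_size = 100)
  r2 <- run_scenario(cfg, map, dfe_params(), sample_schedule = c(1, 20),
                     sample_size = 100)
  expect_identical(r1$coverage, r2$coverage)
  expect_identical(r1$tracts, r2$tracts)
})

test_that("mutation-free burn-in leaves both populations at fitness 1", {
  w <- tiny_world("autosomal", mutation_rate = 0)
  burn_in(w)
  expect_true(all(population_fitness(w, "recipient") == 1))
  expect_true(all(population_fitness(w, "source") == 1))
  st <- population_state(w, "recipient")
  expect_true(all(vapply(st$individuals,
                         function(i) length(i$h1$mut_pos) == 0, logical(1))))
  # source is fully archaic-labeled after burn-in
  ss <- population_state(w, "source")
  L <- w$map$length_bp
  expect_true(all(vapply(ss$individuals, function(i) {
    nrow(i$h1$tracts) == 1 && i$h1$tracts[1, 2] - i$h1$tracts[1, 1] == L
  }, logical(1))))
})

test_that("engine fitness agrees with the R dominance rules", {
  for (h in c(0, 0.5)) {
    w <- tiny_world("chrX", n_rec = 10, mutation_rate = 0, dominance_h = h)
    st <- population_state(w)
    q <- w$config$scaling_factor
    dfe <- dfe_params(dominance_h = h)
    # plant distinct mutations on individual 1 (female under default layout)
    set_haplotype(w, 1, 1, matrix(numeric(0), ncol = 2),
                  mut_pos = c(1000, 2000), mut_s = c(0.1, 0.05) * q)
    set_haplotype(w, 1, 2, matrix(numeric(0), ncol = 2),
                  mut_pos = 3000, mut_s = 0.2 * q)
    fit <- population_fitness(w)
    m1 <- data.frame(id = 1:2, s = c(0.1, 0.05))
    m2 <- data.frame(id = 3L, s = 0.2)
    expect_equal(fit[1], genotype_fitness(m1, m2, dfe))
    # a male X (hemizygous) ignores dominance
    male <- which(vapply(st$individuals, function(i) i$sex == "male",
                         logical(1)))[1]
    set_haplotype(w, male, 1, matrix(numeric(0), ncol = 2),
                  mut_pos = 5000, mut_s = 0.1 * q)
    expect_equal(population_fitness(w)[male],
                 genotype_fitness(data.frame(id = 1L, s = 0.1), NULL, dfe))
  }
})

test_that("source accumulates more deleterious load than the recipient", {
  # the 100x smaller source drifts weakly deleterious variants higher;
  # compare mean per-individual counts of s > 0.01 mutations (sign test
  # over 5 replicate burn-ins at reduced scale)
  wins <- 0
  map <- synthesize_chromosome_map(1e7, seed = 5)
  for (rep in 1:5) {
    cfg <- sim_config(N_recipient = 3000, N_source = 50,
                      isolation_generations = 6000, post_pulse_generations = 1,
                      pulse_fraction = 0.05, inheritance = "autosomal",
                      scaling_factor = 10, seed = 500 + rep)
    set.seed(500 + rep)
    w <- sim_world(cfg, map, dfe_params())
    burn_in(w)
    src <- mean(deleterious_load(w, 0.01, "source"))
    rec <- mean(deleterious_load(w, 0.01, "recipient"))
    wins <- wins + (src > rec)
  }
  expect_gte(wins, 4)
})

test_that("stochastic pulse mode realizes a random size near its target", {
  cfg <- sim_config(N_recipient = 2000, N_source = 200,
                    isolation_generations = 1, post_pulse_generations = 1,
                    pulse_fraction = 0.05, female_fraction_pulse = 0.5,
                    inheritance = "autosomal", scaling_factor = 1,
                    pulse_mode = "stochastic", seed = 9)
  map <- synthesize_chromosome_map(1e6, seed = 5)
  set.seed(9)
  w <- sim_world(cfg, map, dfe_params(mutation_rate = 0))
  burn_in(w)
  d <- introgression_pulse(w)
  # binomial(2000, 0.05): mean 100, sd ~9.7
  expect_gt(d$n_migrants, 100 - 5 * 9.75)
  expect_lt(d$n_migrants, 100 + 5 * 9.75)
  expect_true(d$n_migrants != 100 || d$n_female != 50)  # some stochasticity
})
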