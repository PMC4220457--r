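test_that("default design yields one site per landscape x system x replicate", {
  cfg <- synth_config(seed = 3)
  study <- generate_study(cfg)
  expect_length(study$sites, 32)
  meta <- sites_table(study)
  expect_equal(nrow(unique(meta[, c("landscape", "system")])), 8)
  expect_true(all(table(meta$system) == 8))
  expect_true(all(meta$n_subplots == 3))
  expect_true(all(meta$subplot_area_m2 == 1))
})

test_that("generation is deterministic and order-independent across sites", {
  cfg <- tiny_config(seed = 99)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(individuals_table(s1), individuals_table(s2))
  # re-drawing one site in isolation reproduces the study's site
  pools <- trophicflux:::build_species_pools(cfg)
  site5 <- draw_site_community(cfg, s1$sites[[5]]$system,
                               as.integer(sub("L", "", s1$sites[[5]]$landscape)),
                               seed = trophicflux:::substream_seed(cfg$seed, 5),
                               pools = pools)
  expect_identical(site5$individuals, s1$sites[[5]]$individuals)
})

test_that("every individual belongs to one of the four guilds", {
  ind <- individuals_table(generate_study(tiny_config(seed = 4)))
  expect_true(all(ind$guild %in% c("predator", "omnivore", "detritivore",
                                   "herbivore")))
  expect_true(all(ind$subplot %in% 1:3))
})

test_that("site individual counts scale with the density multiplier", {
  # Monte-Carlo check of E[count] = subplots * area * base_density * multiplier
  cfg <- synth_config(
    seed = 10, base_density_m2 = 30,
    species_pool_size = c(predator = 30, omnivore = 30, detritivore = 30,
                          herbivore = 30),
    density_multiplier = c(forest = 1, jungle_rubber = 1, rubber = 1,
                           oil_palm = 0.5)
  )
  draws <- 300
  counts <- vapply(seq_len(draws), function(i) {
    f <- draw_site_community(cfg, "forest", 1, seed = 1000 + i)
    o <- draw_site_community(cfg, "oil_palm", 1, seed = 50000 + i)
    c(nrow(f$individuals), nrow(o$individuals))
  }, numeric(2))
  mean_f <- mean(counts[1, ]); mean_o <- mean(counts[2, ])
  expect_equal(mean_f, 90, tolerance = 0.05)      # 3 subplots * 30 / m2
  expect_equal(mean_o / mean_f, 0.5, tolerance = 0.05)
})

test_that("a zero density multiplier silences the whole community", {
  cfg <- tiny_config(density_multiplier = c(forest = 1, jungle_rubber = 1,
                                            rubber = 1, oil_palm = 0))
  site <- draw_site_community(cfg, "oil_palm", 1, seed = 5)
  expect_equal(nrow(site$individuals), 0)
})

test_that("no-effect configuration equalizes expected per-system densities", {
  cfg <- tiny_config(
    seed = 21,
    density_multiplier = c(forest = 1, jungle_rubber = 1, rubber = 1, oil_palm = 1),
    richness_retention = c(forest = 1, jungle_rubber = 1, rubber = 1, oil_palm = 1),
    body_mass_multiplier = c(forest = 1, jungle_rubber = 1, rubber = 1, oil_palm = 1)
  )
  counts <- replicate(200, {
    sapply(c("forest", "oil_palm"), function(sys)
      nrow(draw_site_community(cfg, sys, 1,
                               seed = sample.int(1e6, 1))$individuals))
  })
  expect_equal(mean(counts[1, ]) / mean(counts[2, ]), 1, tolerance = 0.06)
})

test_that("true_effect reads back configured factors and rejects unknowns", {
  cfg <- synth_config(density_multiplier = c(forest = 1, jungle_rubber = 0.8,
                                             rubber = 0.9, oil_palm = 0.52))
  expect_identical(true_effect(cfg, "forest", "density"), 1)
  expect_identical(true_effect(cfg, "oil_palm", "density"), 0.52)
  expect_identical(true_effect(cfg, "oil_palm", "richness_retention"), 0.60)
  expect_error(true_effect(cfg, "oil_palm", "colourfulness"), "unknown response")
  expect_error(true_effect(cfg, "wheat", "density"), "unknown system")
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(synth_config(subplots_per_site = 0), "subplots_per_site")
  expect_error(synth_config(density_multiplier = c(
    forest = 2, jungle_rubber = 1, rubber = 1, oil_palm = 1)),
    "density_multiplier")
  expect_error(synth_config(richness_retention = c(
    forest = 1, jungle_rubber = 1.2, rubber = 1, oil_palm = 1)),
    "richness_retention")
  expect_error(synth_config(abundance_model = list(type = "lognormal",
                                                   sdlog = -1)),
               "abundance_model")
  expect_error(synth_config(abundance_model = list(type = "logseries", p = 2)),
               "abundance_model")
  expect_error(synth_config(guild_fractions = c(predator = 1, omnivore = 1,
                                                detritivore = 1, herbivore = 1)),
               "guild_fractions")
  expect_error(draw_site_community(synth_config(), "wheat"), "unknown system")
})

test_that("logseries abundance model is accepted and reproducible", {
  cfg <- tiny_config(abundance_model = list(type = "logseries", p = 0.95,
                                            turnover_sdlog = 0))
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(individuals_table(s1), individuals_table(s2))
})

test_that("write_study / read_study round-trips site data as plain text", {
  study <- generate_study(tiny_config(seed = 8))
  dir <- withr::local_tempdir()
  write_study(study, dir)
  expect_true(all(file.exists(file.path(dir, c("individuals.csv", "sites.csv",
                                               "config.yaml")))))
  back <- read_study(dir)
  expect_length(back, length(study$sites))
  orig <- study$sites[[3]]
  match_id <- which(vapply(back, function(s) s$site_id, "") == orig$site_id)
  expect_equal(back[[match_id]]$individuals$species_id,
               orig$individuals$species_id)
  expect_equal(back[[match_id]]$temperature_C, orig$temperature_C)
})
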