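GU <- c("predator", "omnivore", "detritivore", "herbivore")

test_that("diet matrices carry the contracted proportions", {
  W <- build_diet_matrix("null_model")
  expect_equal(unname(W[c("omnivore", "detritivore", "herbivore"), "predator"]),
               rep(1 / 3, 3))
  expect_equal(unname(W[c("predator", "detritivore", "herbivore"), "omnivore"]),
               rep(0.25, 3))
  expect_equal(unname(W[c("plant", "detritus"), "omnivore"]), c(0.125, 0.125))
  expect_equal(unname(W["detritus", "detritivore"]), 1)
  expect_equal(unname(W["plant", "herbivore"]), 1)

  W2 <- build_diet_matrix("no_animal_omnivory")
  expect_equal(unname(W2[c("plant", "detritus"), "omnivore"]), c(0.5, 0.5))
  expect_equal(W2[, "predator"], W[, "predator"])
  for (M in list(W, W2)) expect_equal(unname(colSums(M)), rep(1, 4))
  expect_true(all(W[, ] >= 0))
  expect_error(build_diet_matrix("gourmet"), "arg")
})

test_that("effective assimilation is the diet-weighted efficiency", {
  at <- assimilation_table(e_animal = 0.9, e_plant = 0.5, e_detritus = 0.2)
  W <- build_diet_matrix("null_model")
  expect_equal(effective_assimilation("detritivore", W, at), 0.2)
  expect_equal(effective_assimilation("herbivore", W, at), 0.5)
  expect_equal(effective_assimilation("omnivore", W, at),
               0.75 * 0.9 + 0.125 * 0.5 + 0.125 * 0.2)  # 0.7625
  expect_equal(effective_assimilation("predator", W, at), 0.9)
  expect_error(assimilation_table(e_animal = 1.2), "\\(0, 1\\]")
})

test_that("solver reproduces hand-solved chain and cycle systems", {
  W <- build_diet_matrix("null_model")
  # single consumer with e = 1 and no predation loss: F = X
  e1 <- setNames(rep(1, 4), GU)
  X <- setNames(c(0, 0, 10, 0), GU)
  sol <- solve_fluxes(X, W, e_a = e1)
  expect_equal(unname(sol$F_J_h_m2[["detritivore"]]), 10)

  # chain: predator (e=1, X=2) eats only detritivore (e=0.5, X=10)
  Wc <- matrix(0, 6, 4, dimnames = list(c("plant", "detritus", GU), GU))
  Wc["detritivore", "predator"] <- 1
  Wc["detritus", "detritivore"] <- 1
  Wc["plant", "herbivore"] <- 1
  Wc["plant", "omnivore"] <- 1
  chain <- solve_fluxes(setNames(c(2, 0, 10, 0), GU), Wc,
                        e_a = setNames(c(1, 1, 0.5, 1), GU))
  expect_equal(unname(chain$F_J_h_m2[["predator"]]), 2)
  expect_equal(unname(chain$L[["detritivore"]]), 2)
  expect_equal(unname(chain$F_J_h_m2[["detritivore"]]), 24)  # (10 + 2) / 0.5

  # cycle: predator(e=1,X=1) with L_pred = 0.25 F_omn; omnivore(e=1,X=1)
  # with L_omn = F_pred  ->  F_pred = 5/3, F_omn = 8/3
  Wx <- matrix(0, 6, 4, dimnames = list(c("plant", "detritus", GU), GU))
  Wx["omnivore", "predator"] <- 1
  Wx["predator", "omnivore"] <- 0.25
  Wx["plant", "omnivore"] <- 0.75
  Wx["detritus", "detritivore"] <- 1
  Wx["plant", "herbivore"] <- 1
  cyc <- solve_fluxes(setNames(c(1, 1, 0, 0), GU), Wx,
                      e_a = setNames(rep(1, 4), GU))
  expect_equal(unname(cyc$F_J_h_m2[["predator"]]), 5 / 3)
  expect_equal(unname(cyc$F_J_h_m2[["omnivore"]]), 8 / 3)
})

test_that("direct solve equals the fixed-point iteration oracle", {
  set.seed(11)
  for (i in 1:50) {
    inst <- random_flux_instance(sample(c("null_model", "no_animal_omnivory"), 1))
    sol <- solve_fluxes(inst$X, inst$W, e_a = inst$e)
    oracle <- iterate_fluxes(inst$X, inst$W, inst$e)
    expect_equal(sol$F_J_h_m2, oracle, tolerance = 1e-9)
    # balance invariant at every node
    expect_equal(unname(inst$e * sol$F_J_h_m2 - sol$X - sol$L), rep(0, 4),
                 tolerance = 1e-9)
  }
})

test_that("zeroing the omnivore's animal diet recovers top-down substitution", {
  W <- build_diet_matrix("no_animal_omnivory")
  at <- assimilation_table()
  e <- vapply(GU, effective_assimilation, numeric(1), W = W, table = at)
  X <- setNames(c(2, 3, 7, 4), GU)
  sol <- solve_fluxes(X, W, e_a = e)
  # acyclic: predators first, then each prey guild explicitly
  f_pred <- X[["predator"]] / e[["predator"]]
  for (g in c("omnivore", "detritivore", "herbivore")) {
    f_g <- (X[[g]] + W[g, "predator"] * f_pred) / e[[g]]
    expect_equal(unname(sol$F_J_h_m2[[g]]), unname(f_g), tolerance = 1e-12)
  }
})

test_that("fluxes respond monotonically to demand and efficiency", {
  W <- build_diet_matrix("null_model")
  at <- assimilation_table()
  X <- setNames(c(1, 1, 5, 2), GU)
  base <- solve_fluxes(X, W, assim = at)
  X2 <- X; X2[["detritivore"]] <- X2[["detritivore"]] + 3
  more <- solve_fluxes(X2, W, assim = at)
  expect_true(all(more$F_J_h_m2 >= base$F_J_h_m2 - 1e-12))
  # lower herbivore efficiency raises its required ingoing flux
  e <- base$e_a; e[["herbivore"]] <- e[["herbivore"]] / 2
  harder <- solve_fluxes(X, W, e_a = e)
  expect_gt(harder$F_J_h_m2[["herbivore"]], base$F_J_h_m2[["herbivore"]])
})

test_that("infeasible systems are rejected with the offending node named", {
  GUn <- GU
  Wbad <- matrix(0, 6, 4, dimnames = list(c("plant", "detritus", GUn), GUn))
  # perfect predator-omnivore loop with efficiencies 1: singular system
  Wbad["omnivore", "predator"] <- 1
  Wbad["predator", "omnivore"] <- 1
  Wbad["detritus", "detritivore"] <- 1
  Wbad["plant", "herbivore"] <- 1
  expect_error(solve_fluxes(setNames(c(1, 1, 1, 1), GUn), Wbad,
                            e_a = setNames(rep(1, 4), GUn)),
               "singular|negative flux")
  expect_error(solve_fluxes(setNames(c(-1, 1, 1, 1), GUn),
                            build_diet_matrix("null_model")),
               "nonnegative")
})

test_that("energy-to-mass conversion is exact and invertible", {
  expect_equal(to_mass_flux(0), 0)
  expect_equal(to_mass_flux(1, energy_per_gram = 7000), 8760 * 1e4 / 7e6)
  f <- c(0.3, 2, 41.7)
  expect_equal(mass_to_energy_flux(to_mass_flux(f, 6500), 6500), f,
               tolerance = 1e-14)
  expect_error(to_mass_flux(1, energy_per_gram = 0), "> 0")
})

test_that("sensitivity comparison is zero for identical or rescaled results", {
  d <- data.frame(site_id = paste0("s", 1:8),
                  system = rep(c("forest", "oil_palm"), each = 4),
                  flux = c(10, 12, 9, 11, 5, 6, 4, 5))
  same <- sensitivity_compare(d, d)
  expect_true(all(same$disparity == 0))
  scaled <- d; scaled$flux <- d$flux * 3.7  # global rescale leaves losses alone
  expect_equal(sensitivity_compare(d, scaled)$disparity, 0, tolerance = 1e-12)
  # brute-force oracle on distinct models
  alt <- d; alt$flux <- d$flux * rep(c(1, 0.9), each = 4)
  out <- sensitivity_compare(d, alt)
  loss_null <- 1 - mean(d$flux[5:8]) / mean(d$flux[1:4])
  loss_alt <- 1 - mean(alt$flux[5:8]) / mean(alt$flux[1:4])
  expect_equal(out$disparity, abs(loss_null - loss_alt), tolerance = 1e-12)
  expect_error(sensitivity_compare(d, alt, reference_system = "savanna"),
               "reference system")
})
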