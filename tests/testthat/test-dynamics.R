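# dynamics_check: simulation closed forms, persistence extraction and
# the organization-membership theorem.

test_that("closed-form solutions are reproduced by the integrator", {
  # inflow/outflow balance: c_A(t) = 1 + (c0 - 1) exp(-t)
  net <- read_reaction_text("in: 0 -> A\nout: A -> 0")
  tr <- mass_action_simulate(net, c(`in` = 1, out = 1), c(A = 0.2),
                             t_end = 10, n_points = 101)
  expect_equal(tr$concentrations[, "A"],
               1 + (0.2 - 1) * exp(-tr$times), tolerance = 1e-6)
  # pure conversion: c_A = exp(-t), c_B = 1 - exp(-t)
  net2 <- read_reaction_text("r: A -> B")
  tr2 <- mass_action_simulate(net2, c(r = 1), c(A = 1), t_end = 10,
                              n_points = 101)
  expect_equal(tr2$concentrations[, "A"], exp(-tr2$times),
               tolerance = 1e-6)
  expect_equal(tr2$concentrations[, "B"], 1 - exp(-tr2$times),
               tolerance = 1e-6)
})

test_that("an unfed network from the zero state stays identically zero", {
  net <- read_reaction_text("r1: A -> B\nr2: 2 B -> A")
  tr <- mass_action_simulate(net, c(r1 = 1, r2 = 1), c(), t_end = 5,
                             n_points = 21)
  expect_true(all(tr$concentrations == 0))
  ps <- persistent_set(tr)
  expect_length(ps$species, 0L)
  expect_length(ps$reactions, 0L)
})

test_that("persistence extraction matches the known limit sets", {
  net <- read_reaction_text("in: 0 -> A\nout: A -> 0")
  tr <- mass_action_simulate(net, c(`in` = 1, out = 1), c(A = 0.2),
                             t_end = 60, n_points = 201)
  ps <- persistent_set(tr)
  expect_identical(ps$species, "A")
  expect_setequal(ps$reactions, c("in", "out"))
  # ... and that set is an organization of the network
  expect_true(paste(sort(ps$reactions), collapse = ",") %in%
                org_reaction_sets(enumerate_organizations(net)))

  # A -> B: A vanishes, B persists inertly; the reaction set is empty
  net2 <- read_reaction_text("r: A -> B")
  tr2 <- mass_action_simulate(net2, c(r = 1), c(A = 1, B = 0),
                              t_end = 60, n_points = 201)
  ps2 <- persistent_set(tr2)
  expect_identical(ps2$species, "B")
  expect_length(ps2$reactions, 0L)
})

test_that("persistent species shrink as the threshold grows", {
  net <- read_reaction_text("in: 0 -> A\nout: A -> 0\nr: A -> B\ns: B -> 0")
  tr <- mass_action_simulate(net, c(`in` = 0.01, out = 1, r = 1, s = 1),
                             c(A = 1, B = 1), t_end = 80, n_points = 201)
  sizes <- vapply(c(1e-8, 1e-4, 1e-1),
                  function(th) length(persistent_set(tr, threshold = th,
                                                     trend_cut = 0)$species),
                  0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("the persistent set of a Tyson simulation is an organization", {
  net <- tyson_fixture()
  k <- structure(rep(1, 9), names = paste0("Reaction", 1:9))
  c0 <- structure(rep(1, 6), names = net$reactive)
  ok <- theorem_check(net, k, c0, t_end = 300, n_points = 201,
                      substeps = 25)
  expect_true(ok)
  ps <- attr(ok, "persistent")
  expect_true(paste(sort(ps$reactions), collapse = ",") %in%
                org_reaction_sets(enumerate_organizations(net)))
})

test_that("the theorem holds across a seeded dissipative random suite", {
  # the acceptance suite runs 50 of these; quick cross-section here
  for (seed in 1:10) {
    cfg <- generator_config(n_species = 4 + seed %% 3,
                            n_reactions = 5 + seed %% 4,
                            p_inflow = 0.2, p_outflow = 0.1,
                            bounded = TRUE, dissipative = TRUE,
                            seed = seed)
    net <- random_network(cfg)
    ok <- theorem_check(net, random_rates(net, seed + 10000),
                        random_initial(net, seed + 20000),
                        t_end = 400, n_points = 201, substeps = 25)
    expect_true(ok, info = paste("seed", seed))
  }
})

test_that("integration failures are reported with context", {
  net <- read_reaction_text("r: 2 A -> 3 A")   # explosive autocatalysis
  expect_error(mass_action_simulate(net, c(r = 5), c(A = 5), t_end = 50,
                                    n_points = 11, substeps = 2),
               "integration failure")
})
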