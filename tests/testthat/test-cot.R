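# cot_engine: closedness, closure, enumeration and the brute-force
# oracle.

test_that("closedness follows the worked Tyson examples", {
  net <- tyson_fixture()
  expect_true(is_closed(net, c("C2", "CP"), c("Reaction2", "Reaction3")))
  S <- c("C2", "CP", "Y")
  expect_false(is_closed(net, S, active_reactions(net, S, "Reaction6")))
  expect_true(is_closed(net, character(), character()))
  # omitting a mandatory active reaction also breaks closedness
  expect_false(is_closed(net, c("C2", "CP"), "Reaction2"))
})

test_that("closure reaches the documented fixpoints", {
  net <- tyson_fixture()
  expect_setequal(closure(net, c("C2", "CP", "Y"), "Reaction6"),
                  net$reactive)
  expect_identical(closure(net, character()), character())
  # Reaction2 adds CP; CP only activates Reaction3, which returns C2
  expect_setequal(closure(net, "C2"), c("C2", "CP"))
  # monotone and idempotent
  for (seed in 1:10) {
    net2 <- random_network(generator_config(seed = seed))
    s1 <- net2$reactive[1L]
    c1 <- closure(net2, s1)
    expect_true(all(c1 %in% closure(net2, net2$reactive[1:2])))
    expect_setequal(closure(net2, c1), c1)
  }
})

test_that("Tyson has exactly the five organizations of the published lattice", {
  net <- tyson_fixture()
  orgs <- enumerate_organizations(net)
  expect_identical(org_reaction_sets(orgs), sort(c(
    "",
    "Reaction6,Reaction7",
    "Reaction2,Reaction3",
    "Reaction2,Reaction3,Reaction6,Reaction7",
    paste(paste0("Reaction", 1:9), collapse = ","))))
  expect_false(attr(orgs, "incomplete"))
  for (o in orgs) expect_true(validate_organization(net, o))
})

test_that("a single consuming reaction admits only the empty organization", {
  net <- read_reaction_text("r: A -> B")
  expect_identical(org_reaction_sets(enumerate_organizations(net)), "")
  expect_identical(org_reaction_sets(brute_force_organizations(net)), "")
})

test_that("the empty organization is always present", {
  for (seed in 1:15) {
    net <- random_network(generator_config(n_species = 5, n_reactions = 6,
                                           p_inflow = 0.2, seed = seed))
    expect_true("" %in% org_reaction_sets(enumerate_organizations(net)))
  }
})

test_that("species-disjoint organizations compose as disjoint unions", {
  for (seed in 1:10) {
    net <- random_network(generator_config(n_species = 6, n_reactions = 7,
                                           p_inflow = 0.2, seed = seed))
    orgs <- enumerate_organizations(net)
    keys <- org_reaction_sets(orgs)
    for (i in seq_along(orgs)) for (j in seq_along(orgs)) {
      if (i < j && !length(intersect(orgs[[i]]$species, orgs[[j]]$species))) {
        u <- paste(sort(union(orgs[[i]]$reactions, orgs[[j]]$reactions)),
                   collapse = ",")
        expect_true(u %in% keys)
      }
    }
  }
})

test_that("enumeration equals the brute-force oracle on random networks", {
  # the acceptance suite runs 200 of these; keep a quick cross-section
  for (seed in 101:130) {
    net <- random_network(generator_config(n_species = 4 + seed %% 3,
                                           n_reactions = 5 + seed %% 4,
                                           p_inflow = 0.15, p_outflow = 0.2,
                                           seed = seed))
    expect_identical(org_sig(enumerate_organizations(net)),
                     org_sig(brute_force_organizations(net)),
                     info = paste("seed", seed))
  }
})

test_that("the oracle guard rejects oversized networks", {
  net <- random_network(generator_config(n_species = 11, n_reactions = 5,
                                         seed = 1))
  expect_error(brute_force_organizations(net), "guard")
})

test_that("a timeout yields a partial result flagged incomplete", {
  net <- markevich_synthetic_fixture()
  ctrl <- cot_control(timeout = 1e-9)
  orgs <- enumerate_organizations(net, ctrl)
  expect_true(attr(orgs, "incomplete"))
  expect_true(length(orgs) <= 5L)
})

test_that("organizations re-validate under exact arithmetic", {
  for (net in list(tyson_fixture(), markevich_synthetic_fixture(),
                   chain4_network(), planted_network(3))) {
    for (o in enumerate_organizations(net))
      expect_true(validate_organization(net, o))
  }
})

test_that("enumeration is independent of reaction and species order", {
  net <- tyson_fixture()
  perm <- c(4L, 9L, 1L, 7L, 2L, 8L, 3L, 6L, 5L)
  net2 <- build_network(
    lapply(rev(seq_len(nrow(net$species))),
           function(i) species(net$species$id[i], net$species$name[i],
                               net$species$is_boundary[i])),
    net$reactions[perm])
  expect_identical(org_sig(enumerate_organizations(net2)),
                   org_sig(enumerate_organizations(net)))
})
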