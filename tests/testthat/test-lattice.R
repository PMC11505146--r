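# lattice_metrics: Hasse construction, height/width, persistence,
# parameter record, DOT export.

tyson_lattice <- function() {
  net <- tyson_fixture()
  orgs <- enumerate_organizations(net)
  list(net = net, orgs = orgs, lat = build_lattice(orgs))
}

test_that("the Tyson lattice has the published edges and layers", {
  tl <- tyson_lattice()
  key <- vapply(tl$orgs, function(o) paste(sort(o$reactions), collapse = ","), "")
  idx <- function(r) which(key == r)
  o0 <- idx(""); o1 <- idx("Reaction6,Reaction7")
  o2 <- idx("Reaction2,Reaction3")
  o3 <- idx("Reaction2,Reaction3,Reaction6,Reaction7")
  o4 <- idx(paste(paste0("Reaction", 1:9), collapse = ","))
  edges <- apply(tl$lat$edges, 1L, paste, collapse = "-")
  expect_setequal(edges, c(paste(o0, o1, sep = "-"), paste(o0, o2, sep = "-"),
                           paste(o1, o3, sep = "-"), paste(o2, o3, sep = "-"),
                           paste(o3, o4, sep = "-")))
  expect_identical(tl$lat$layers[c(o0, o1, o2, o3, o4)],
                   c(0L, 1L, 1L, 2L, 3L))
  expect_identical(lattice_height(tl$lat), 4L)
  expect_identical(lattice_width(tl$lat), 2L)
})

test_that("a four-organization chain gives 3 edges, 4 layers, width 1", {
  net <- chain4_network()
  orgs <- enumerate_organizations(net)
  expect_identical(org_reaction_sets(orgs),
                   sort(c("", "a,b", "a,b,c,d", "a,b,c,d,e,f")))
  expect_identical(org_sig(orgs), org_sig(brute_force_organizations(net)))
  lat <- build_lattice(orgs)
  expect_identical(nrow(lat$edges), 3L)
  expect_identical(lattice_height(lat), 4L)
  expect_identical(lattice_width(lat), 1L)
})

test_that("a single-organization lattice is trivial", {
  net <- read_reaction_text("r: A -> B")
  lat <- build_lattice(enumerate_organizations(net))
  expect_identical(nrow(lat$edges), 0L)
  expect_identical(lattice_height(lat), 1L)
  expect_identical(lattice_width(lat), 1L)
})

test_that("Hasse edges re-verify: no organization strictly between", {
  for (seed in 1:8) {
    net <- random_network(generator_config(n_species = 6, n_reactions = 7,
                                           p_inflow = 0.2, seed = seed))
    orgs <- enumerate_organizations(net)
    lat <- build_lattice(orgs)
    rsets <- lapply(orgs, `[[`, "reactions")
    if (nrow(lat$edges)) for (e in seq_len(nrow(lat$edges))) {
      lo <- rsets[[lat$edges[e, 1L]]]; hi <- rsets[[lat$edges[e, 2L]]]
      expect_true(all(lo %in% hi) && length(lo) < length(hi))
      for (mid in rsets) {
        strictly_between <- all(lo %in% mid) && all(mid %in% hi) &&
          length(mid) > length(lo) && length(mid) < length(hi)
        expect_false(strictly_between)
      }
    }
  }
})

test_that("height and width are invariant under relabeling", {
  net <- tyson_fixture()
  relabeled <- read_reaction_text(gsub("Reaction", "X", gsub(
    "\\b(C2|CP|pM|M|Y|YP)\\b", "sp_\\1", write_reaction_text(net))))
  a <- build_lattice(enumerate_organizations(net))
  b <- build_lattice(enumerate_organizations(relabeled))
  expect_identical(lattice_height(a), lattice_height(b))
  expect_identical(lattice_width(a), lattice_width(b))
})

test_that("reaction-count layering reproduces the Tyson (4, 2) record too", {
  tl <- tyson_lattice()
  lat <- build_lattice(tl$orgs, cot_control(layering = "nreactions"))
  expect_identical(lattice_height(lat), 4L)
  expect_identical(lattice_width(lat), 2L)
})

test_that("persistence follows the published values and its invariant", {
  tl <- tyson_lattice()
  expect_identical(persistence(tl$net, tl$orgs), 1)
  net <- read_reaction_text("r: A -> B")
  expect_identical(persistence(net, enumerate_organizations(net)), 0)
  # persistence == 1 iff the full reaction set is an organization
  for (seed in 1:10) {
    net2 <- random_network(generator_config(n_species = 5, n_reactions = 6,
                                            p_inflow = 0.2, seed = seed))
    orgs <- enumerate_organizations(net2)
    full <- paste(sort(vapply(net2$reactions, `[[`, "", "id")),
                  collapse = ",")
    expect_identical(persistence(net2, orgs) == 1,
                     full %in% org_reaction_sets(orgs))
  }
})

test_that("the Tyson parameter record matches the published summary", {
  p <- compute_parameters(tyson_fixture())
  expect_identical(p$n_species, 6L)    # reactive species; EmptySet excluded
  expect_identical(p$n_reactions, 9L)
  expect_identical(p$n_organizations, 5L)
  expect_identical(p$height, 4L)
  expect_identical(p$width, 2L)
  expect_identical(p$persistence, 1)
  expect_identical(p$fraction_multi_compartment, 1 / 5)
  expect_identical(p$max_compartments, 2L)
  expect_false(p$incomplete)
  expect_true(p$runtime_ms >= 0)
})

test_that("an empty network yields the trivial parameter record", {
  net <- build_network(list(species("A")), list())
  p <- suppressWarnings(compute_parameters(net))
  expect_identical(p$n_reactions, 0L)
  expect_identical(p$n_organizations, 1L)
  expect_identical(p$height, 1L)
  expect_identical(p$width, 1L)
})

test_that("DOT export follows the published drawing conventions", {
  tl <- tyson_lattice()
  dot <- to_dot(tl$lat)
  expect_match(dot, "digraph")
  # O3 label shows the two-compartment split {C2,CP} | {Y}
  expect_match(dot, "C2,CP \\| Y")
  # O3 is the only multi-compartment organization: exactly one ellipse
  expect_identical(lengths(regmatches(dot, gregexpr("shape=ellipse", dot))), 1L)
  expect_match(dot, "shape=box")
  expect_match(dot, "green")   # first-appearing reactions marked
  # empty lattice still renders valid DOT with one node
  net <- read_reaction_text("r: A -> B")
  dot2 <- to_dot(build_lattice(enumerate_organizations(net)))
  expect_match(dot2, "digraph")
  expect_match(dot2, "o1 \\[")
})

test_that("JSON export carries reactions, blocks and witnesses", {
  tl <- tyson_lattice()
  js <- jsonlite::fromJSON(organizations_to_json(tl$orgs),
                           simplifyVector = FALSE)
  expect_false(js$incomplete)
  expect_length(js$organizations, 5L)
  o3 <- Filter(function(o) length(o$reactions) == 4L, js$organizations)[[1]]
  expect_identical(o3$k, 2L)
  expect_length(o3$compartments, 2L)
})
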