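# Shared fixtures and comparison helpers.

# canonical signature of an organization set: reaction set + minimal k
org_sig <- function(os) {
  sort(vapply(os, function(o)
    paste0(paste(sort(o$reactions), collapse = ","), "|k=", o$k), ""))
}

org_reaction_sets <- function(os) {
  sort(vapply(os, function(o) paste(sort(o$reactions), collapse = ","), ""))
}

# a four-level chain: A<->B at the bottom, extended twice through
# catalysts K then L (each extension is closed only with its catalyst
# and product-return reaction).  Organizations: {}, {a,b},
# {a,b,c,d}, {a,b,c,d,e,f} -- a chain, height 4, width 1.
chain4_network <- function() {
  read_reaction_text(paste(
    "a: A -> B",
    "b: B -> A",
    "c: B + K -> C + K",
    "d: C -> B",
    "e: C + L -> D + L",
    "f: D -> C",
    sep = "\n"))
}

# every reaction strictly consumes mass and there is no inflow, so no
# nonempty self-maintaining set exists
consuming_network <- function() {
  read_reaction_text(paste(
    "r1: 2 A -> B",
    "r2: B + C -> A",
    "r3: C -> 0",
    "r4: 2 B -> C",
    sep = "\n"))
}

tyson_eq1_matrix <- function() {
  N <- matrix(c(
     1, -1,  1,  0,  0,  0,  0,  0,  0,
     0,  1, -1, -1,  0,  0,  0,  0,  0,
     0,  0,  0,  1,  1,  0,  0,  0, -1,
    -1,  0,  0,  0, -1,  0,  0,  0,  1,
     0,  0,  0, -1,  0,  1, -1,  0,  0,
     1,  0,  0,  0,  0,  0,  0, -1,  0),
    nrow = 6, byrow = TRUE)
  storage.mode(N) <- "integer"
  dimnames(N) <- list(c("C2", "CP", "pM", "M", "Y", "YP"),
                      paste0("Reaction", 1:9))
  N
}

random_rates <- function(net, seed, lo = 0.5, hi = 2) {
  rid <- vapply(net$reactions, `[[`, "", "id")
  withr::with_seed(seed, structure(runif(length(rid), lo, hi),
                                   names = rid))
}

random_initial <- function(net, seed, lo = 0.5, hi = 1.5) {
  withr::with_seed(seed, structure(runif(length(net$reactive), lo, hi),
                                   names = net$reactive))
}
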