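#' @keywords internal
"_PACKAGE"

# Shared numeric tolerance and search limits.
#
# `tol` is the single "strictly positive" tolerance shared between flux
# checks and the LP (the LP itself is exact; the tolerance only matters
# when classifying user-supplied numeric flux vectors).

#' Control parameters for organization computations
#'
#' @param tol numeric tolerance below which a flux entry counts as zero
#'   (default `1e-9`).
#' @param k_max maximum number of compartments considered when searching
#'   for (minimal) compartmentalizations (default 4; required
#'   compartment numbers above 3 are rare in practice).
#' @param timeout wall-clock budget in seconds for one enumeration
#'   (default 600). On expiry a partial result is returned with its
#'   `incomplete` flag set.
#' @param max_closed_sets guard on the number of closed species sets
#'   enumerated before the result is flagged incomplete.
#' @param layering either `"depth"` (longest-chain Hasse layering, the
#'   default) or `"nreactions"` (layer = number of reactions).
#' @return a named list of class `cot_control`.
#' @export
cot_control <- function(tol = 1e-9, k_max = 4L, timeout = 600,
                        max_closed_sets = 100000L,
                        layering = c("depth", "nreactions")) {
  layering <- match.arg(layering)
  stopifnot(tol > 0, k_max >= 1L, timeout > 0, max_closed_sets > 0L)
  structure(list(tol = tol, k_max = as.integer(k_max), timeout = timeout,
                 max_closed_sets = as.integer(max_closed_sets),
                 layering = layering),
            class = "cot_control")
}

as_cot_control <- function(control) {
  if (is.null(control)) return(cot_control())
  if (inherits(control, "cot_control")) return(control)
  do.call(cot_control, control)
}

# sorted unique integer set helpers ------------------------------------

iset <- function(x) sort.int(unique(as.integer(x)))

iset_union <- function(a, b) sort.int(unique(c(a, b)))

iset_subset <- function(a, b) all(a %in% b)

iset_equal <- function(a, b) length(a) == length(b) && all(a == b)

set_key <- function(idx) paste0("k:", paste(idx, collapse = ","))

# deterministic RNG scope without touching the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

deadline_reached <- function(deadline) {
  !is.null(deadline) && proc.time()[["elapsed"]] > deadline
}
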