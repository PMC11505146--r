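# Plain-text reaction-list dialect.
#
#   id: 2 A + B -> C
#   id: 0 -> Y          (empty side, inflow; "0" denotes the empty set)
#   id: Y ->            (outflow)
#
# Coefficients are optional positive integers ("2 A" or "2A"); lines
# starting with '#' and blank lines are ignored.  Species are declared
# implicitly in order of first appearance; ids matching the boundary
# list (EmptySet etc.) become boundary species.

TERM_RE <- "^([0-9]+)?\\s*([A-Za-z_][A-Za-z0-9_]*)$"

parse_side <- function(txt, line_no) {
  txt <- trimws(txt)
  if (txt == "" || txt == "0") return(structure(integer(), names = character()))
  if (grepl("(^\\+)|(\\+\\s*$)|(\\+\\s*\\+)", txt))
    stop("line ", line_no, ": dangling '+' in '", txt, "'")
  terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1L]])
  counts <- integer(); ids <- character()
  for (tm in terms) {
    mt <- regmatches(tm, regexec(TERM_RE, tm))[[1L]]
    if (length(mt) == 0L)
      stop("line ", line_no, ": malformed term '", tm, "'")
    counts <- c(counts, if (nzchar(mt[2L])) as.integer(mt[2L]) else 1L)
    ids <- c(ids, mt[3L])
  }
  structure(counts, names = ids)
}

#' Parse the plain-text reaction dialect
#'
#' @param text character vector of lines, or a single string with
#'   embedded newlines.
#' @param boundary_ids species ids treated as boundary.
#' @return a `reaction_network`.
#' @export
read_reaction_text <- function(text, boundary_ids = DEFAULT_BOUNDARY_IDS) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  reactions <- list()
  order_seen <- character()
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[[ln]])
    if (raw == "" || startsWith(raw, "#")) next
    colon <- regexpr(":", raw, fixed = TRUE)
    if (colon < 0L) stop("line ", ln, ": missing 'id:' prefix")
    rid <- trimws(substr(raw, 1L, colon - 1L))
    body <- substr(raw, colon + 1L, nchar(raw))
    arrow <- regexpr("->", body, fixed = TRUE)
    if (arrow < 0L) stop("line ", ln, ": missing '->'")
    lhs <- parse_side(substr(body, 1L, arrow - 1L), ln)
    rhs <- parse_side(substr(body, arrow + 2L, nchar(body)), ln)
    if (length(lhs) == 0L && length(rhs) == 0L)
      stop("line ", ln, ": reaction with empty reactants and products")
    reactions[[length(reactions) + 1L]] <- reaction(rid, lhs, rhs)
    order_seen <- c(order_seen, names(lhs), names(rhs))
  }
  ids <- unique(order_seen)
  build_network(lapply(ids, species), reactions,
                boundary_ids = boundary_ids)
}

#' Serialize a network to the plain-text reaction dialect
#'
#' `read_reaction_text(write_reaction_text(net))` reproduces the
#' network (canonical form: coefficients of one omitted, empty side
#' written as `0`, boundary species dropped).
#'
#' @param net a `reaction_network`.
#' @return character scalar.
#' @export
write_reaction_text <- function(net) {
  fmt_side <- function(ms) {
    ms <- ms[names(ms) %in% net$reactive]
    if (length(ms) == 0L) return("0")
    paste(ifelse(ms == 1L, names(ms), paste(ms, names(ms))),
          collapse = " + ")
  }
  paste(vapply(net$reactions, function(r)
    sprintf("%s: %s -> %s", r$id, fmt_side(r$reactants),
            fmt_side(r$products)), ""), collapse = "\n")
}
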