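# Minimal SBML Level 2/3 reader and writer on top of xml2.
#
# Only the constructs relevant to stoichiometric analysis are
# interpreted: species (boundaryCondition/constant/compartment) and
# reactions (reactants, products, reversibility, stoichiometry).
# Kinetic laws, rules, events and modifiers are ignored on purpose —
# organizations are a purely stoichiometric notion.  Reversible
# reactions are split into forward and reverse irreversible reactions
# ("<id>" and "<id>_rev"); all reaction counts downstream refer to the
# post-split list.

#' Read an SBML model into a reaction network
#'
#' @param path path to an SBML L2/L3 file.
#' @param boundary_ids extra species ids/names treated as boundary in
#'   addition to those with `boundaryCondition` or `constant` set.
#' @param fractional how to treat non-integer stoichiometries:
#'   `"error"` (default) or `"scale"` (multiply the reaction by the
#'   smallest integer that clears the denominators).
#' @return a `reaction_network`.  A model with zero reactions yields an
#'   empty network with a warning.
#' @export
read_sbml <- function(path, boundary_ids = DEFAULT_BOUNDARY_IDS,
                      fractional = c("error", "scale")) {
  fractional <- match.arg(fractional)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  root <- xml2::xml_find_first(doc, "/sbml")
  if (inherits(root, "xml_missing")) stop("not an SBML document: ", path)
  level <- suppressWarnings(as.integer(xml2::xml_attr(root, "level")))
  if (is.na(level)) level <- 2L
  model <- xml2::xml_find_first(doc, "/sbml/model")
  if (inherits(model, "xml_missing")) stop("SBML document has no model")

  sp_nodes <- xml2::xml_find_all(model, "./listOfSpecies/species")
  as_flag <- function(x) !is.na(x) & x == "true"
  sp <- lapply(sp_nodes, function(nd) {
    id <- xml2::xml_attr(nd, "id")
    nm <- xml2::xml_attr(nd, "name")
    s <- species(id, name = if (is.na(nm)) id else nm,
                 is_boundary = as_flag(xml2::xml_attr(nd, "boundaryCondition")) ||
                   as_flag(xml2::xml_attr(nd, "constant")))
    s$compartment <- xml2::xml_attr(nd, "compartment")
    s
  })

  rx_nodes <- xml2::xml_find_all(model, "./listOfReactions/reaction")
  if (length(rx_nodes) == 0L) {
    warning("SBML model has no reactions; returning an empty network")
    return(build_network(sp, list(), boundary_ids = boundary_ids))
  }

  side_of <- function(nd, which) {
    refs <- xml2::xml_find_all(
      nd, sprintf("./listOf%ss/speciesReference", which))
    ids <- xml2::xml_attr(refs, "species")
    st <- xml2::xml_attr(refs, "stoichiometry")
    st <- ifelse(is.na(st), 1, as.numeric(st))
    structure(st, names = ids)
  }
  integerize <- function(counts, rid) {
    if (all(counts == round(counts))) return(counts)
    if (fractional == "error")
      stop("reaction '", rid, "' has fractional stoichiometry; use ",
           "fractional = \"scale\" to rescale")
    for (f in 2:10000) {
      if (all(abs(counts * f - round(counts * f)) < 1e-9))
        return(round(counts * f))
    }
    stop("reaction '", rid, "': cannot rationalize stoichiometry")
  }

  reactions <- list()
  for (nd in rx_nodes) {
    rid <- xml2::xml_attr(nd, "id")
    nm <- xml2::xml_attr(nd, "name")
    rev_attr <- xml2::xml_attr(nd, "reversible")
    reversible <- if (is.na(rev_attr)) level < 3L else rev_attr == "true"
    lhs <- side_of(nd, "Reactant")
    rhs <- side_of(nd, "Product")
    both <- integerize(c(lhs, rhs), rid)
    lhs <- both[seq_along(lhs)]
    rhs <- both[seq_along(rhs) + length(lhs)]
    lab <- if (is.na(nm)) rid else nm
    reactions[[length(reactions) + 1L]] <- reaction(rid, lhs, rhs, label = lab)
    if (reversible)
      reactions[[length(reactions) + 1L]] <-
        reaction(paste0(rid, "_rev"), rhs, lhs,
                 label = paste0(lab, " (reverse)"))
  }
  net <- build_network(sp, reactions, boundary_ids = boundary_ids)
  net$species$sbml_compartment <-
    vapply(sp, function(s) s$compartment %||% NA_character_, "")
  net
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Write a reaction network as SBML Level 3 Version 1
#'
#' All reactions are written irreversible (the in-memory network is
#' already split), boundary species carry `boundaryCondition="true"`.
#' Reading the file back reproduces the network exactly.
#'
#' @param net a `reaction_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(net, path) {
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;",
                          gsub('"', "&quot;", x)))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'level="3" version="1">'),
    '  <model id="model">',
    '    <listOfCompartments>',
    '      <compartment id="default" constant="true" size="1"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (i in seq_len(nrow(net$species))) {
    s <- net$species[i, ]
    lines <- c(lines, sprintf(
      paste0('      <species id="%s" name="%s" compartment="default" ',
             'hasOnlySubstanceUnits="false" boundaryCondition="%s" ',
             'constant="false"/>'),
      esc(s$id), esc(s$name), if (s$is_boundary) "true" else "false"))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfReactions>')
  side_xml <- function(ms, tag) {
    if (length(ms) == 0L) return(character())
    c(sprintf('        <listOf%ss>', tag),
      sprintf(paste0('          <speciesReference species="%s" ',
                     'stoichiometry="%d" constant="true"/>'),
              esc(names(ms)), as.integer(ms)),
      sprintf('        </listOf%ss>', tag))
  }
  for (r in net$reactions) {
    lines <- c(lines,
               sprintf(paste0('      <reaction id="%s" name="%s" ',
                              'reversible="false" fast="false">'),
                       esc(r$id), esc(r$label)),
               side_xml(r$reactants, "Reactant"),
               side_xml(r$products, "Product"),
               '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>', '  </model>', '</sbml>')
  writeLines(lines, path)
  invisible(path)
}
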