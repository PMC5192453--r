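#' Default metabolite name synonyms
#'
#' Alias -> canonical network node name, applied case-insensitively. Covers
#' the composite shift-table entries (the glutamine + glutamate resonance is
#' mapped to glutamate, its primary network node) and common alternate names.
#' @return named character vector.
#' @export
default_synonyms <- function() {
  c("glutamine + glutamate" = "glutamate",
    "alpha-ketoglutarate"   = "2-oxoglutarate",
    "α-ketoglutarate"  = "2-oxoglutarate",
    "akg"                   = "2-oxoglutarate",
    "fatty acid"            = "palmitate",
    "fatty acids"           = "palmitate",
    "dopa"                  = "l-dopa",
    "beta-alanine"          = "beta-alanine")
}

normalize_names <- function(x, synonyms) {
  x <- tolower(trimws(x))
  hit <- x %in% names(synonyms)
  x[hit] <- unname(synonyms[x[hit]])
  x
}

new_network <- function(pathways, reactions, synonyms) {
  mets <- unique(unlist(lapply(reactions, function(r) c(r$substrates, r$products))))
  structure(list(pathways = pathways, reactions = reactions,
                 metabolites = mets %||% character(0), synonyms = synonyms),
            class = "metabolic_network")
}

#' Load a metabolic network
#'
#' Reads either a TSV edge list with columns
#' `pathway`, `reaction`, `role` (substrate/product), `metabolite`, or an SBML
#' Level 3 file with `groups` pathway annotations. A reaction lacking a
#' substrate or a product is rejected with its id. A small curated fly
#' network fixture (glycolysis + TCA, starch/maltose hydrolysis, amino-acid
#' and tyrosine/melanization pathways; a stand-in for the genome-scale
#' reconstruction, not a copy of it) ships with the package.
#'
#' @param path file path; default: the packaged fixture.
#' @param synonyms alias table (see [default_synonyms()]).
#' @return object of class `metabolic_network`: `pathways` (name -> reaction
#'   ids), `reactions` (id -> substrates/products), `metabolites`, `synonyms`.
#' @export
load_network <- function(path = system.file("extdata", "fly_network_synthetic.tsv",
                                            package = "flynmr"),
                         synonyms = default_synonyms()) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("<\\?xml|<sbml", first))
    return(load_network_sbml(path, synonyms))
  dt <- data.table::fread(path, sep = "\t", colClasses = "character")
  if (nrow(dt) == 0L)
    return(new_network(list(), list(), synonyms))
  need <- c("pathway", "reaction", "role", "metabolite")
  if (!all(need %in% names(dt)))
    stop_fly("network TSV needs columns: %s", paste(need, collapse = ", "))
  bad <- setdiff(unique(dt$role), c("substrate", "product"))
  if (length(bad)) stop_fly("unknown role(s): %s", paste(bad, collapse = ", "))
  reactions <- list()
  pathways <- list()
  for (i in seq_len(nrow(dt))) {
    rid <- dt$reaction[i]
    if (is.null(reactions[[rid]]))
      reactions[[rid]] <- list(substrates = character(0), products = character(0))
    slot <- if (dt$role[i] == "substrate") "substrates" else "products"
    reactions[[rid]][[slot]] <- unique(c(reactions[[rid]][[slot]], dt$metabolite[i]))
    pw <- dt$pathway[i]
    pathways[[pw]] <- unique(c(pathways[[pw]], rid))
  }
  for (rid in names(reactions)) {
    r <- reactions[[rid]]
    if (!length(r$substrates) || !length(r$products))
      stop_fly("dangling reaction '%s': missing %s", rid,
               if (length(r$substrates)) "products" else "substrates")
  }
  new_network(pathways, reactions, synonyms)
}

# Minimal SBML L3 reader: species/reactions plus groups:group pathway cover.
load_network_sbml <- function(path, synonyms = default_synonyms()) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          g = "http://www.sbml.org/sbml/level3/version1/groups/version1")
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  species <- stats::setNames(xml2::xml_attr(sp, "name"), xml2::xml_attr(sp, "id"))
  species[is.na(species)] <- names(species)[is.na(species)]
  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  reactions <- list()
  for (r in rx) {
    rid <- xml2::xml_attr(r, "id")
    subs <- xml2::xml_attr(
      xml2::xml_find_all(r, ".//s:listOfReactants/s:speciesReference", ns), "species")
    prods <- xml2::xml_attr(
      xml2::xml_find_all(r, ".//s:listOfProducts/s:speciesReference", ns), "species")
    if (!length(subs) || !length(prods))
      stop_fly("dangling reaction '%s': missing %s", rid,
               if (length(subs)) "products" else "substrates")
    unknown <- setdiff(c(subs, prods), names(species))
    if (length(unknown))
      stop_fly("dangling reaction '%s': unknown species %s", rid,
               paste(unknown, collapse = ", "))
    reactions[[rid]] <- list(substrates = unname(species[subs]),
                             products = unname(species[prods]))
  }
  groups <- xml2::xml_find_all(doc, ".//g:group", ns)
  pathways <- list()
  for (gp in groups) {
    nm <- xml2::xml_attr(gp, "name") %||% xml2::xml_attr(gp, "id")
    if (is.na(nm)) nm <- xml2::xml_attr(gp, "id")
    members <- xml2::xml_attr(xml2::xml_find_all(gp, ".//g:member", ns), "idRef")
    pathways[[nm]] <- intersect(members, names(reactions))
  }
  if (!length(pathways) && length(reactions))
    pathways <- list(all = names(reactions))
  new_network(pathways, reactions, synonyms)
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("<metabolic_network> %d pathways, %d reactions, %d metabolites\n",
              length(x$pathways), length(x$reactions), length(x$metabolites)))
  invisible(x)
}

pathway_nodes <- function(net, pw) {
  unique(unlist(lapply(net$reactions[net$pathways[[pw]]],
                       function(r) c(r$substrates, r$products))))
}

#' Map detected and discriminant metabolites onto pathways
#'
#' Matches the two metabolite lists (all detected, and the discriminant subset
#' with |R| above threshold) against network nodes via the synonym table, then
#' ranks pathways by the number of discriminant metabolites they contain (ties
#' broken by detected count, then pathway name) — the count-based ranking the
#' study reports. A hypergeometric enrichment p-value is added as a
#' supplementary column but is not the ranking key. Unmatched input names are
#' reported with a warning, never fatal.
#'
#' @param net a `metabolic_network`.
#' @param detected character vector of all detected metabolites.
#' @param discriminant character vector of discriminant metabolites.
#' @return data.frame (pathway, n_discriminant, n_detected, size,
#'   hypergeom_p), ranked; attribute `node_states` gives per-node status
#'   (`discriminant`, `detected_only`, `absent`), attribute `unmatched` the
#'   input names without a network node.
#' @export
map_metabolites <- function(net, detected, discriminant) {
  stopifnot(inherits(net, "metabolic_network"))
  nodes_norm <- normalize_names(net$metabolites, net$synonyms)
  det <- unique(normalize_names(detected, net$synonyms))
  dis <- unique(normalize_names(discriminant, net$synonyms))
  unmatched <- unique(c(setdiff(det, nodes_norm), setdiff(dis, nodes_norm)))
  if (length(unmatched))
    warn_fly("not in network: %s", paste(unmatched, collapse = ", "))
  state <- ifelse(nodes_norm %in% dis, "discriminant",
                  ifelse(nodes_norm %in% det, "detected_only", "absent"))
  names(state) <- net$metabolites
  N <- length(net$metabolites)
  K <- sum(state == "discriminant")
  rows <- lapply(names(net$pathways), function(pw) {
    nd <- pathway_nodes(net, pw)
    ndn <- normalize_names(nd, net$synonyms)
    k_dis <- length(intersect(ndn, dis))
    k_det <- length(intersect(ndn, det))
    p <- if (N > 0) phyper(k_dis - 1, K, N - K, length(nd), lower.tail = FALSE) else NA_real_
    data.frame(pathway = pw, n_discriminant = k_dis, n_detected = k_det,
               size = length(nd), hypergeom_p = p)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_discriminant, -out$n_detected, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "node_states") <- state
  attr(out, "unmatched") <- unmatched
  out
}

#' Extract the sub-network touched by a metabolite list
#'
#' Keeps every reaction with at least one listed metabolite among its
#' substrates or products, together with all of that reaction's partners;
#' pathway membership is restricted to the retained reactions. Output is
#' monotone in the input list. No overlap yields an empty (still valid)
#' network with a warning.
#'
#' @param net a `metabolic_network`.
#' @param metabolites non-empty character vector.
#' @return a `metabolic_network`.
#' @export
extract_subnetwork <- function(net, metabolites) {
  stopifnot(inherits(net, "metabolic_network"), length(metabolites) >= 1L)
  want <- unique(normalize_names(metabolites, net$synonyms))
  keep <- vapply(net$reactions, function(r)
    any(normalize_names(c(r$substrates, r$products), net$synonyms) %in% want),
    logical(1))
  if (!any(keep)) {
    warn_fly("no reaction touches any listed metabolite; empty sub-network")
    return(new_network(list(), list(), net$synonyms))
  }
  reactions <- net$reactions[keep]
  pathways <- lapply(net$pathways, intersect, names(reactions))
  pathways <- pathways[lengths(pathways) > 0L]
  new_network(pathways, reactions, net$synonyms)
}

#' Render a network to Graphviz DOT
#'
#' Bipartite metabolite/reaction graph; metabolites colored by mapping state
#' (discriminant vs detected-only), matching the published figure convention.
#' @param net a `metabolic_network`.
#' @param node_states optional named state vector from [map_metabolites()].
#' @param path optional output file.
#' @return DOT source as a character scalar (invisibly if written to `path`).
#' @export
network_to_dot <- function(net, node_states = NULL, path = NULL) {
  col <- function(m) {
    st <- if (!is.null(node_states)) node_states[[m]] %||% "absent" else "absent"
    switch(st, discriminant = "red", detected_only = "lightblue", "white")
  }
  q <- function(x) paste0('"', gsub('"', "'", x), '"')
  lines <- c("digraph metabolic_network {", "  rankdir=LR;")
  for (m in net$metabolites)
    lines <- c(lines, sprintf("  %s [shape=ellipse style=filled fillcolor=%s];",
                              q(m), col(m)))
  for (rid in names(net$reactions)) {
    r <- net$reactions[[rid]]
    lines <- c(lines, sprintf("  %s [shape=box style=filled fillcolor=gray90];", q(rid)))
    for (s in r$substrates) lines <- c(lines, sprintf("  %s -> %s;", q(s), q(rid)))
    for (p in r$products) lines <- c(lines, sprintf("  %s -> %s;", q(rid), q(p)))
  }
  lines <- c(lines, "}")
  dot <- paste(lines, collapse = "\n")
  if (!is.null(path)) { writeLines(dot, path); return(invisible(dot)) }
  dot
}
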