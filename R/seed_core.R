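#' @title Seed sets of metabolic networks
#'
#' @description The seed set of a metabolic network is the minimal set of
#' compounds that cannot be synthesized from other compounds of the network
#' and must therefore be acquired exogenously. Operationally: build the
#' directed compound graph (substrate to product per reaction, both
#' directions for reversible reactions), condense it into strongly connected
#' components (SCCs), and take the compounds of the source SCCs — components
#' with no incoming edge in the condensation. Seeds in an interdependent SCC
#' of size k each carry confidence C = 1/k; the remaining compounds form the
#' non-seed set, what the network can produce on its own.
#'
#' @name seed_core
NULL

#' Construct a metabolic network from a reaction list
#'
#' Compartment suffixes on compound identifiers (ModelSEED-style `_c0`,
#' `_e0`, ...) are stripped so a compound is one node regardless of
#' compartment, and biomass/exchange pseudo-reactions are dropped, both
#' configurable.
#'
#' @param network_id identifier for the network (e.g. a genome id).
#' @param reactions data frame with columns `reaction_id`, `substrates`
#'   (list-column of compound id vectors), `products` (list-column),
#'   `reversible` (logical).
#' @param compounds optional character vector of compound ids to include in
#'   addition to those referenced by reactions (isolated compounds with no
#'   producing or consuming reaction are seeds by definition).
#' @param compartment_regex regex stripped from every compound id
#'   (`NULL` disables).
#' @param drop_pattern reactions whose id matches are removed before graph
#'   construction (`NULL` disables).
#' @return object of class `metabolic_network` with fields `network_id`,
#'   `compounds`, `reactions`.
#' @export
metabolic_network <- function(network_id, reactions, compounds = NULL,
                              compartment_regex = "_[a-z][0-9]*$",
                              drop_pattern = "^(bio|EX_|DM_|SK_)") {
  stopifnot(is.data.frame(reactions),
            all(c("reaction_id", "substrates", "products", "reversible") %in%
                  names(reactions)))
  if (anyDuplicated(reactions$reaction_id))
    stop("duplicate reaction ids in network ", network_id, call. = FALSE)
  if (!is.null(drop_pattern) && nrow(reactions) > 0L)
    reactions <- reactions[!grepl(drop_pattern, reactions$reaction_id), ,
                           drop = FALSE]
  strip <- function(x) {
    x <- as.character(x)
    if (!is.null(compartment_regex)) x <- sub(compartment_regex, "", x)
    unique(x)
  }
  reactions$substrates <- lapply(reactions$substrates, strip)
  reactions$products <- lapply(reactions$products, strip)
  compounds <- sort(unique(c(unlist(reactions$substrates),
                             unlist(reactions$products),
                             if (!is.null(compounds)) strip(compounds))))
  structure(list(network_id = network_id, compounds = compounds,
                 reactions = reactions),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network> ", x$network_id, ": ",
      length(x$compounds), " compounds, ", nrow(x$reactions),
      " reactions\n", sep = "")
  invisible(x)
}

#' Read a reaction-list TSV
#'
#' Columns (no header):
#' `reaction_id<TAB>substrates(;-joined)<TAB>products(;-joined)<TAB>reversible(0/1)`.
#'
#' @param path file path.
#' @param network_id network identifier (defaults to the file stem).
#' @param ... passed to [metabolic_network()].
#' @return a `metabolic_network`.
#' @export
read_reaction_tsv <- function(path,
                              network_id = tools::file_path_sans_ext(basename(path)),
                              ...) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 4L)
    stop("reaction TSV needs four tab-separated columns", call. = FALSE)
  rx <- data.frame(reaction_id = as.character(df[[1L]]),
                   reversible = as.integer(df[[4L]]) != 0L,
                   stringsAsFactors = FALSE)
  rx$substrates <- lapply(as.character(df[[2L]]), split_semi)
  rx$products <- lapply(as.character(df[[3L]]), split_semi)
  metabolic_network(network_id, rx, ...)
}

#' Read a minimal SBML model
#'
#' Parses only what seed extraction needs: species identifiers, reactions
#' with their reactant/product species references, and the `reversible`
#' attribute (missing defaults to `TRUE`, the SBML Level 2 default). Levels
#' 2 and 3 are both accepted; everything else in the document is ignored.
#'
#' @param path SBML file path.
#' @param network_id network identifier (defaults to the file stem).
#' @param ... passed to [metabolic_network()].
#' @return a `metabolic_network`.
#' @export
read_sbml <- function(path,
                      network_id = tools::file_path_sans_ext(basename(path)),
                      ...) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (length(rx_nodes) == 0L)
    stop("no reactions found in SBML file ", path, call. = FALSE)
  species_of <- function(node, which) {
    refs <- xml2::xml_find_all(
      node, paste0("./", which, "/speciesReference"))
    xml2::xml_attr(refs, "species")
  }
  rx <- data.frame(
    reaction_id = xml2::xml_attr(rx_nodes, "id"),
    reversible = {
      rev <- xml2::xml_attr(rx_nodes, "reversible")
      is.na(rev) | tolower(rev) == "true"
    },
    stringsAsFactors = FALSE)
  rx$substrates <- lapply(rx_nodes, species_of, which = "listOfReactants")
  rx$products <- lapply(rx_nodes, species_of, which = "listOfProducts")
  metabolic_network(network_id, rx, ...)
}

#' Build the directed compound graph of a metabolic network
#'
#' For each reaction, an edge runs from every substrate to every product;
#' reversible reactions also contribute the opposite edges. Parallel edges
#' are collapsed and self-loops (a compound on both sides of a reaction)
#' dropped. Compounds touched by no surviving edge remain as isolated
#' vertices.
#'
#' @param net a `metabolic_network`.
#' @return an [igraph::igraph] directed graph whose vertex names are
#'   compound ids.
#' @export
build_compound_graph <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  from <- character()
  to <- character()
  for (i in seq_len(nrow(net$reactions))) {
    s <- net$reactions$substrates[[i]]
    p <- net$reactions$products[[i]]
    unknown <- setdiff(c(s, p), net$compounds)
    if (length(unknown))
      stop("reaction ", net$reactions$reaction_id[i],
           " references unknown compound(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (length(s) == 0L || length(p) == 0L) next
    e <- expand.grid(s = s, p = p, stringsAsFactors = FALSE)
    e <- e[e$s != e$p, , drop = FALSE]
    from <- c(from, e$s)
    to <- c(to, e$p)
    if (isTRUE(net$reactions$reversible[i])) {
      from <- c(from, e$p)
      to <- c(to, e$s)
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = net$compounds, stringsAsFactors = FALSE))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Condense a compound graph into strongly connected components
#'
#' @param g directed igraph.
#' @return list with `scc_of` (named integer: compound to SCC id) and `dag`
#'   (the acyclic condensation graph; vertex names are SCC ids).
#' @export
condense_sccs <- function(g) {
  stopifnot(igraph::vcount(g) > 0L)
  comp <- igraph::components(g, mode = "strong")
  scc_of <- stats::setNames(as.integer(comp$membership),
                            names(comp$membership))
  el <- igraph::as_edgelist(g, names = TRUE)
  cf <- scc_of[el[, 1L]]
  ct <- scc_of[el[, 2L]]
  keep <- cf != ct
  dag_edges <- unique(data.frame(from = as.character(cf[keep]),
                                 to = as.character(ct[keep]),
                                 stringsAsFactors = FALSE))
  dag <- igraph::graph_from_data_frame(
    dag_edges, directed = TRUE,
    vertices = data.frame(name = as.character(seq_len(comp$no)),
                          stringsAsFactors = FALSE))
  list(scc_of = scc_of, dag = dag)
}

#' Compute the seed set of a metabolic network
#'
#' Seeds are the compounds of the condensation's source SCCs (zero
#' in-degree); each seed's confidence is 1/(size of its SCC), so confidences
#' within one source SCC are equal and sum to one. All other compounds form
#' the non-seed set.
#'
#' @param net a `metabolic_network`.
#' @return object of class `seed_set`: `network_id`, `seeds` (named numeric
#'   vector of confidences), `non_seeds`, `scc_of`, `source_sccs`,
#'   `compounds`.
#' @export
compute_seed_set <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  if (length(net$compounds) == 0L)
    stop("cannot compute seeds of an empty metabolic network", call. = FALSE)
  g <- build_compound_graph(net)
  cond <- condense_sccs(g)
  indeg <- igraph::degree(cond$dag, mode = "in")
  source_sccs <- as.integer(igraph::V(cond$dag)$name[indeg == 0L])
  scc_sizes <- table(cond$scc_of)
  seed_names <- names(cond$scc_of)[cond$scc_of %in% source_sccs]
  seeds <- vapply(seed_names, function(cp)
    1 / as.numeric(scc_sizes[[as.character(cond$scc_of[[cp]])]]), numeric(1))
  seeds <- seeds[order(names(seeds))]
  structure(
    list(network_id = net$network_id,
         seeds = seeds,
         non_seeds = sort(setdiff(net$compounds, names(seeds))),
         scc_of = cond$scc_of,
         source_sccs = sort(source_sccs),
         compounds = net$compounds),
    class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat("<seed_set> ", x$network_id, ": ", length(x$seeds), " seeds, ",
      length(x$non_seeds), " non-seeds (",
      length(x$source_sccs), " source SCCs)\n", sep = "")
  invisible(x)
}
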