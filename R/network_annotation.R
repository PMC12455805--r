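#' @title Co-occurrence network annotation
#'
#' @description Taxa (nodes) of a microbial co-occurrence network are mapped
#' to reference genomes — by exact lineage match for standard taxonomy
#' dialects, or by fuzzy Levenshtein name matching otherwise — and the
#' network is then annotated: phenotypic trait attributes on nodes, and
#' directed complementarity edges (donor = source, beneficiary = target)
#' carrying pathway-complement tables and seed scores for every ordered
#' genome combination behind an associated taxon pair. Genome mapping is
#' restricted to nodes resolved at species or strain level.
#'
#' @name network_annotation
NULL

#' Construct a co-occurrence network
#'
#' @param nodes data frame with columns `node_id`, `taxonomy` (lineage
#'   string, may be empty) and optionally `level`; a missing `level` is
#'   inferred from the lineage with [infer_taxonomic_level()].
#' @param edges data frame with columns `source`, `target`, `weight`
#'   (signed association score).
#' @return object of class `cooccurrence_network`.
#' @export
cooccurrence_network <- function(nodes, edges) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges),
            all(c("node_id", "taxonomy") %in% names(nodes)),
            all(c("source", "target", "weight") %in% names(edges)))
  nodes$node_id <- as.character(nodes$node_id)
  if (anyDuplicated(nodes$node_id))
    stop("node ids must be unique", call. = FALSE)
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  unknown <- setdiff(c(edges$source, edges$target), nodes$node_id)
  if (length(unknown))
    stop("edge endpoints missing from the node table: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  if (any(edges$source == edges$target))
    stop("self-edges are not allowed in a co-occurrence network", call. = FALSE)
  if (any(!is.finite(edges$weight)))
    stop("edge weights must be finite", call. = FALSE)
  if (is.null(nodes$level))
    nodes$level <- vapply(nodes$taxonomy, infer_taxonomic_level, character(1))
  edges$sign <- ifelse(edges$weight >= 0,
                       "positive co-occurrence", "mutual exclusion")
  structure(list(nodes = nodes, edges = edges),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("<cooccurrence_network> ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Infer the taxonomic level of a lineage string
#'
#' Looks for the deepest populated rank prefix (`d__` through `s__`, plus
#' `t__` for strains) in a GTDB/Silva-style lineage; lineages without rank
#' prefixes are ranked by their number of nonempty `;`-separated fields
#' (7 fields = species, more = strain). A bare binomial name (two words) is
#' taken as species level.
#'
#' @param taxonomy lineage string.
#' @return one of `"domain"`, `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`, `"species"`, `"strain"`, `"unknown"`.
#' @export
infer_taxonomic_level <- function(taxonomy) {
  ranks <- c(d = "domain", p = "phylum", c = "class", o = "order",
             f = "family", g = "genus", s = "species", t = "strain")
  if (is.na(taxonomy) || !nzchar(trimws(taxonomy))) return("unknown")
  hits <- regmatches(taxonomy,
                     gregexpr("([dpcofgst])__([^;]*)", taxonomy))[[1L]]
  if (length(hits)) {
    populated <- hits[nzchar(trimws(sub("^[dpcofgst]__", "", hits)))]
    if (length(populated) == 0L) return("unknown")
    codes <- substr(populated, 1L, 1L)
    return(ranks[[codes[which.max(match(codes, names(ranks)))]]])
  }
  fields <- trimws(strsplit(taxonomy, ";", fixed = TRUE)[[1L]])
  fields <- fields[nzchar(fields)]
  if (length(fields) >= 8L) return("strain")
  if (length(fields) == 7L) return("species")
  if (length(fields) > 1L)
    return(unname(ranks[length(fields)]))
  # single field: a two-word name is a species binomial
  if (length(strsplit(trimws(taxonomy), "\\s+")[[1L]]) >= 2L) return("species")
  "unknown"
}

#' Normalized Levenshtein similarity on a 0-100 scale
#'
#' `100 * (1 - d / max(nchar))` where `d` is the Levenshtein edit distance;
#' comparison is case-insensitive.
#'
#' @param a,b strings.
#' @return numeric in \[0, 100\].
#' @export
levenshtein_similarity <- function(a, b) {
  a <- tolower(a); b <- tolower(b)
  n <- max(nchar(a), nchar(b))
  if (n == 0L) return(100)
  d <- as.numeric(utils::adist(a, b))
  100 * (1 - d / n)
}

#' Fuzzy-match a taxon name against a dictionary
#'
#' Returns the dictionary entry maximizing the Levenshtein similarity ratio,
#' provided it reaches the threshold; ties are broken by the
#' lexicographically smallest dictionary name (and reported via a message).
#'
#' @param query taxon name.
#' @param dictionary named character vector: dictionary taxon name ->
#'   identifier.
#' @param threshold minimal similarity (0-100) for a match to be accepted;
#'   the default of 90 is deliberately strict to avoid false positives.
#' @return list with `query`, `name`, `id`, `score`, or `NULL` when no
#'   entry reaches the threshold (or the query is empty).
#' @export
match_taxon_name <- function(query, dictionary, threshold = 90) {
  stopifnot(length(dictionary) > 0L, !is.null(names(dictionary)))
  if (is.na(query) || !nzchar(trimws(query))) return(NULL)
  scores <- vapply(names(dictionary), levenshtein_similarity, numeric(1),
                   b = query)
  best <- max(scores)
  if (best < threshold) return(NULL)
  cand <- sort(names(dictionary)[scores == best])
  if (length(cand) > 1L)
    message("fuzzy-match tie for '", query, "': ",
            paste(cand, collapse = ", "), "; keeping '", cand[1L], "'")
  list(query = query, name = cand[1L],
       id = unname(dictionary[[cand[1L]]]), score = best)
}

normalize_lineage <- function(x) {
  x <- gsub("[dpcofgst]__", "", x)
  x <- gsub("\\s*;\\s*", ";", trimws(x))
  tolower(x)
}

#' Map network taxa to reference genomes
#'
#' Exact dialects (`"gtdb"`, `"silva"`) match full lineage strings after
#' normalization (rank prefixes stripped, case-insensitive); the `"other"`
#' scheme falls back to fuzzy name matching of the deepest lineage field
#' with [match_taxon_name()]. Nodes resolved above species level map to no
#' genome; one node may map to several genomes.
#'
#' @param network a `cooccurrence_network`.
#' @param genome_index data frame with columns `taxonomy` and `genome_id`
#'   (several rows may share a taxonomy).
#' @param scheme `"gtdb"`, `"silva"` or `"other"`.
#' @param threshold fuzzy similarity threshold (only used for `"other"`).
#' @return named list: node id -> character vector of genome ids (possibly
#'   empty).
#' @export
map_taxa_to_genomes <- function(network, genome_index,
                                scheme = c("gtdb", "silva", "other"),
                                threshold = 90) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(network, "cooccurrence_network"),
            all(c("taxonomy", "genome_id") %in% names(genome_index)))
  by_tax <- split(as.character(genome_index$genome_id),
                  normalize_lineage(genome_index$taxonomy))
  out <- stats::setNames(vector("list", nrow(network$nodes)),
                         network$nodes$node_id)
  deepest_name <- function(tax) {
    fields <- strsplit(gsub("[dpcofgst]__", "", tax), ";", fixed = TRUE)[[1L]]
    fields <- trimws(fields)
    fields <- fields[nzchar(fields)]
    if (length(fields)) fields[length(fields)] else ""
  }
  fuzzy_dict <- NULL
  if (scheme == "other") {
    dict_names <- vapply(names(by_tax), deepest_name, character(1))
    fuzzy_dict <- stats::setNames(names(by_tax), dict_names)
  }
  for (i in seq_len(nrow(network$nodes))) {
    node <- network$nodes$node_id[i]
    out[[node]] <- character(0)
    if (!network$nodes$level[i] %in% c("species", "strain")) next
    if (scheme %in% c("gtdb", "silva")) {
      key <- normalize_lineage(network$nodes$taxonomy[i])
      if (!is.null(by_tax[[key]])) out[[node]] <- sort(by_tax[[key]])
    } else {
      hit <- match_taxon_name(deepest_name(network$nodes$taxonomy[i]),
                              fuzzy_dict, threshold = threshold)
      if (!is.null(hit)) out[[node]] <- sort(by_tax[[hit$id]])
    }
  }
  out
}

#' Construct a phenotypic trait table
#'
#' @param values data frame or matrix, rows = entities (genomes or nodes;
#'   rownames are the ids), columns = traits; entries `TRUE`/`FALSE`/`NA`
#'   (`NA` = unknown, distinct from absent).
#' @param groups named character vector assigning each trait to a group
#'   among `"lifestyle"`, `"biogeochemical"`, `"metabolite"`, `"other"`;
#'   traits left out default to `"other"`.
#' @param scores optional numeric matrix of prediction scores, same shape.
#' @return object of class `trait_table`.
#' @export
trait_table <- function(values, groups = NULL, scores = NULL) {
  values <- as.data.frame(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("trait table needs unique entity rownames", call. = FALSE)
  traits <- colnames(values)
  g <- stats::setNames(rep("other", length(traits)), traits)
  if (!is.null(groups)) {
    bad <- setdiff(names(groups), traits)
    if (length(bad))
      stop("trait group(s) declared for unknown trait(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    allowed <- c("lifestyle", "biogeochemical", "metabolite", "other")
    if (!all(groups %in% allowed))
      stop("trait groups must be one of: ", paste(allowed, collapse = ", "),
           call. = FALSE)
    g[names(groups)] <- groups
  }
  structure(list(values = values, groups = g, scores = scores),
            class = "trait_table")
}

#' Read a trait table from TSV
#'
#' Wide layout with a header: first column the entity id, remaining columns
#' traits with values 1/0/NA.
#'
#' @param path file path.
#' @param groups passed to [trait_table()].
#' @return a `trait_table`.
#' @export
read_traits_tsv <- function(path, groups = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  rownames(df) <- df[[1L]]
  df <- df[, -1L, drop = FALSE]
  for (j in seq_along(df)) df[[j]] <- as.logical(df[[j]])
  trait_table(df, groups = groups)
}

#' Read a co-occurrence network
#'
#' Either an edge-list TSV (`source<TAB>target<TAB>weight`, no header) plus
#' an optional node TSV (`node_id<TAB>taxonomy`), or a GraphML file whose
#' nodes carry the taxonomy in a declared attribute.
#'
#' @param path network file (`.tsv` edge list or `.graphml`).
#' @param nodes_path optional node-table TSV for the edge-list form.
#' @param taxonomy_attr GraphML vertex attribute holding the lineage.
#' @return a `cooccurrence_network`.
#' @export
read_network <- function(path, nodes_path = NULL, taxonomy_attr = "taxonomy") {
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    g <- igraph::read_graph(path, format = "graphml")
    va <- igraph::vertex_attr(g)
    node_id <- va$name %||% as.character(seq_len(igraph::vcount(g)))
    taxonomy <- va[[taxonomy_attr]] %||% rep("", length(node_id))
    el <- igraph::as_edgelist(g, names = TRUE)
    w <- igraph::edge_attr(g, "weight") %||% rep(1, nrow(el))
    return(cooccurrence_network(
      data.frame(node_id = node_id, taxonomy = taxonomy,
                 stringsAsFactors = FALSE),
      data.frame(source = el[, 1L], target = el[, 2L], weight = as.numeric(w),
                 stringsAsFactors = FALSE)))
  }
  ed <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  edges <- data.frame(source = as.character(ed[[1L]]),
                      target = as.character(ed[[2L]]),
                      weight = as.numeric(ed[[3L]]),
                      stringsAsFactors = FALSE)
  if (!is.null(nodes_path)) {
    nd <- utils::read.delim(nodes_path, header = FALSE, sep = "\t", quote = "",
                            comment.char = "#", stringsAsFactors = FALSE)
    nodes <- data.frame(node_id = as.character(nd[[1L]]),
                        taxonomy = as.character(nd[[2L]]),
                        stringsAsFactors = FALSE)
  } else {
    ids <- sort(unique(c(edges$source, edges$target)))
    nodes <- data.frame(node_id = ids, taxonomy = "", stringsAsFactors = FALSE)
  }
  cooccurrence_network(nodes, edges)
}

#' Annotate a co-occurrence network with traits and complementarity edges
#'
#' Original co-occurrence edges are preserved untouched. For every
#' associated node pair where both nodes map to at least one genome, every
#' ordered genome combination is evaluated; one directed complementarity
#' edge per direction (donor = source node, beneficiary = target node) is
#' added when at least one genome pair of that direction has a pathway
#' complement or a seed complement, carrying the per-genome-pair sub-tables
#' and seed scores. Node attributes (trait vector, mapped genomes) are
#' merged in. Annotating an already-annotated network with the same inputs
#' reproduces the same edge set.
#'
#' @param network a `cooccurrence_network` (or an `annotated_network`, whose
#'   underlying co-occurrence network is then re-annotated).
#' @param node_genomes named list node id -> genome ids, from
#'   [map_taxa_to_genomes()].
#' @param traits optional `trait_table` keyed by genome id.
#' @param pathway_complements optional data frame from
#'   [find_pathway_complements()] pooled over ordered genome pairs.
#' @param seed_scores optional data frame with columns `beneficiary`,
#'   `donor`, `mi_complementarity`, `mi_competition` keyed by genome id.
#' @param seed_complement_list optional list of `seed_complement` objects.
#' @param clusters optional named vector node id -> cluster label.
#' @return object of class `annotated_network`: `nodes` (with genome,
#'   trait and cluster attributes), `edges` (the untouched co-occurrence
#'   edges), `complementarity_edges` (directed; list-columns with the
#'   per-genome-pair tables), `node_genomes`, `traits`.
#' @export
annotate_network <- function(network, node_genomes, traits = NULL,
                             pathway_complements = NULL, seed_scores = NULL,
                             seed_complement_list = NULL, clusters = NULL) {
  if (inherits(network, "annotated_network"))
    network <- cooccurrence_network(
      network$nodes[, c("node_id", "taxonomy", "level")], network$edges)
  stopifnot(inherits(network, "cooccurrence_network"))
  nodes <- network$nodes
  mapped <- node_genomes[nodes$node_id]
  mapped <- lapply(mapped, function(x) if (is.null(x)) character(0) else x)
  all_genomes <- unique(unlist(mapped))
  if (!is.null(pathway_complements) && nrow(pathway_complements) > 0L) {
    ref <- unique(c(pathway_complements$beneficiary, pathway_complements$donor))
    bad <- setdiff(ref, all_genomes)
    if (length(bad))
      stop("pathway complements reference genome(s) not mapped to any node: ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  nodes$genomes <- vapply(mapped, join_semi, character(1))
  if (!is.null(clusters))
    nodes$cluster <- as.character(clusters[nodes$node_id])
  node_traits <- NULL
  if (!is.null(traits)) {
    node_traits <- node_trait_values(mapped, traits)
    for (tr in colnames(node_traits))
      nodes[[paste0("trait:", tr)]] <- node_traits[nodes$node_id, tr]
  }
  sc_key <- function(b, d) paste(b, d, sep = "\r")
  sc_index <- list()
  for (sc in seed_complement_list %||% list())
    sc_index[[sc_key(sc$beneficiary_id, sc$donor_id)]] <- sc
  comp_rows <- list()
  for (e in seq_len(nrow(network$edges))) {
    u <- network$edges$source[e]
    v <- network$edges$target[e]
    if (length(mapped[[u]]) == 0L || length(mapped[[v]]) == 0L) next
    for (dir in list(c(u, v), c(v, u))) {
      donor_node <- dir[1L]; benef_node <- dir[2L]
      pc_tables <- list(); sc_tables <- list(); score_rows <- list()
      for (gd in mapped[[donor_node]]) for (gb in mapped[[benef_node]]) {
        pair <- paste(gd, gb, sep = "->")
        if (!is.null(pathway_complements) && nrow(pathway_complements) > 0L) {
          hit <- pathway_complements[
            pathway_complements$donor == gd &
              pathway_complements$beneficiary == gb, , drop = FALSE]
          if (nrow(hit) > 0L) pc_tables[[pair]] <- hit
        }
        sc <- sc_index[[sc_key(gb, gd)]]
        if (!is.null(sc) && nrow(sc$compounds) > 0L) sc_tables[[pair]] <- sc
        if (!is.null(seed_scores)) {
          srow <- seed_scores[seed_scores$beneficiary == gb &
                                seed_scores$donor == gd, , drop = FALSE]
          if (nrow(srow) > 0L) score_rows[[pair]] <- srow
        }
      }
      if (length(pc_tables) == 0L && length(sc_tables) == 0L) next
      comp_rows[[length(comp_rows) + 1L]] <- list(
        source = donor_node, target = benef_node,
        donor = donor_node, beneficiary = benef_node,
        n_genome_pairs = length(unique(c(names(pc_tables), names(sc_tables)))),
        pathway = pc_tables, seed = sc_tables, scores = score_rows)
    }
  }
  comp <- data.frame(source = character(), target = character(),
                     donor = character(), beneficiary = character(),
                     n_genome_pairs = integer(), stringsAsFactors = FALSE)
  comp$pathway <- list(); comp$seed <- list(); comp$scores <- list()
  if (length(comp_rows)) {
    comp <- data.frame(
      source = vapply(comp_rows, `[[`, character(1), "source"),
      target = vapply(comp_rows, `[[`, character(1), "target"),
      donor = vapply(comp_rows, `[[`, character(1), "donor"),
      beneficiary = vapply(comp_rows, `[[`, character(1), "beneficiary"),
      n_genome_pairs = vapply(comp_rows, `[[`, integer(1), "n_genome_pairs"),
      stringsAsFactors = FALSE)
    comp$pathway <- lapply(comp_rows, `[[`, "pathway")
    comp$seed <- lapply(comp_rows, `[[`, "seed")
    comp$scores <- lapply(comp_rows, `[[`, "scores")
    dup <- duplicated(paste(comp$source, comp$target, sep = "\r"))
    comp <- comp[!dup, , drop = FALSE]
  }
  structure(list(nodes = nodes, edges = network$edges,
                 complementarity_edges = comp,
                 node_genomes = mapped, traits = traits,
                 node_traits = node_traits),
            class = "annotated_network")
}

# Fold genome-level traits up to nodes: present if any mapped genome has the
# trait, absent if all mapped genomes lack it, unknown otherwise (or when no
# genome is mapped).
node_trait_values <- function(mapped, traits) {
  trs <- colnames(traits$values)
  out <- matrix(NA, nrow = length(mapped), ncol = length(trs),
                dimnames = list(names(mapped), trs))
  for (nd in names(mapped)) {
    gs <- intersect(mapped[[nd]], rownames(traits$values))
    if (length(gs) == 0L) next
    for (tr in trs) {
      v <- traits$values[gs, tr]
      if (any(v %in% TRUE)) out[nd, tr] <- TRUE
      else if (all(!is.na(v)) && all(!v)) out[nd, tr] <- FALSE
    }
  }
  out
}

#' @export
print.annotated_network <- function(x, ...) {
  cat("<annotated_network> ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " co-occurrence edges, ",
      nrow(x$complementarity_edges), " complementarity edges\n", sep = "")
  invisible(x)
}

#' Filter nodes by phenotypic traits
#'
#' @param net an `annotated_network` annotated with a trait table.
#' @param traits character vector of trait names (must be declared in the
#'   trait table).
#' @param mode `"ANY"` (at least one selected trait present, logical OR) or
#'   `"ALL"` (every selected trait present, AND). Unknown values count as
#'   not-present.
#' @return character vector of node ids.
#' @export
filter_nodes_by_traits <- function(net, traits, mode = c("ANY", "ALL")) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "annotated_network"))
  if (is.null(net$node_traits))
    stop("network was annotated without a trait table", call. = FALSE)
  undeclared <- setdiff(traits, colnames(net$node_traits))
  if (length(undeclared))
    stop("undeclared trait(s): ", paste(undeclared, collapse = ", "),
         call. = FALSE)
  if (length(traits) == 0L) return(character(0))
  m <- net$node_traits[, traits, drop = FALSE]
  m[is.na(m)] <- FALSE
  hit <- if (mode == "ANY") rowSums(m) > 0 else rowSums(m) == length(traits)
  rownames(m)[hit]
}
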