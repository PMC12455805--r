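#' Export an annotated network as a CX2 JSON document
#'
#' CX2 is the Cytoscape exchange format: a JSON array of aspects. The layout
#' emitted here is: a `CXVersion` descriptor, `attributeDeclarations` for
#' node and edge attributes, a `nodes` aspect (integer ids, attributes under
#' `v`), an `edges` aspect (both co-occurrence and complementarity edges,
#' distinguished by the `interaction` attribute; complement sub-tables are
#' serialized as JSON strings), and a terminating `status` aspect.
#'
#' Co-occurrence edges carry `interaction = "co-occurrence"`, their signed
#' `weight` and a `sign` label; complementarity edges carry
#' `interaction = "complementarity"`, run donor (source) to beneficiary
#' (target), and embed the per-genome-pair pathway/seed tables.
#'
#' @param net an `annotated_network`.
#' @param path output file.
#' @param name network name stored in the document.
#' @return `path`, invisibly.
#' @export
write_cx2 <- function(net, path, name = "annotated co-occurrence network") {
  stopifnot(inherits(net, "annotated_network"))
  node_ids <- stats::setNames(seq_len(nrow(net$nodes)) - 1L, net$nodes$node_id)
  node_attr_cols <- setdiff(names(net$nodes), "node_id")
  nodes_aspect <- lapply(seq_len(nrow(net$nodes)), function(i) {
    v <- list(name = net$nodes$node_id[i])
    for (cl in node_attr_cols) {
      val <- net$nodes[[cl]][i]
      if (!is.na(val)) v[[cl]] <- val
    }
    list(id = unname(node_ids[[net$nodes$node_id[i]]]), v = v)
  })
  edges_aspect <- list()
  eid <- 0L
  for (i in seq_len(nrow(net$edges))) {
    edges_aspect[[length(edges_aspect) + 1L]] <- list(
      id = eid,
      s = unname(node_ids[[net$edges$source[i]]]),
      t = unname(node_ids[[net$edges$target[i]]]),
      v = list(interaction = "co-occurrence",
               weight = net$edges$weight[i],
               sign = net$edges$sign[i]))
    eid <- eid + 1L
  }
  ce <- net$complementarity_edges
  for (i in seq_len(nrow(ce))) {
    pathway_json <- jsonlite::toJSON(
      lapply(ce$pathway[[i]], flatten_pathway_table), auto_unbox = TRUE)
    seed_json <- jsonlite::toJSON(
      lapply(ce$seed[[i]], flatten_seed_complement), auto_unbox = TRUE)
    scores_json <- jsonlite::toJSON(
      lapply(ce$scores[[i]], function(s) as.list(s[1, , drop = FALSE])),
      auto_unbox = TRUE)
    edges_aspect[[length(edges_aspect) + 1L]] <- list(
      id = eid,
      s = unname(node_ids[[ce$source[i]]]),
      t = unname(node_ids[[ce$target[i]]]),
      v = list(interaction = "complementarity",
               donor = ce$donor[i], beneficiary = ce$beneficiary[i],
               n_genome_pairs = ce$n_genome_pairs[i],
               pathway_complements = as.character(pathway_json),
               seed_complements = as.character(seed_json),
               seed_scores = as.character(scores_json)))
    eid <- eid + 1L
  }
  doc <- list(
    list(CXVersion = "2.0", hasFragments = FALSE),
    list(attributeDeclarations = list(list(
      networkAttributes = list(name = list(d = "string")),
      nodes = list(name = list(d = "string")),
      edges = list(interaction = list(d = "string"))))),
    list(networkAttributes = list(list(name = name))),
    list(nodes = nodes_aspect),
    list(edges = edges_aspect),
    list(status = list(list(error = "", success = TRUE))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

flatten_pathway_table <- function(df) {
  lapply(seq_len(nrow(df)), function(i) list(
    module = df$module_id[i],
    missing_kos = join_semi(df$missing_kos[[i]]),
    completed_alternative = join_semi(df$completed_alternative[[i]]),
    map_url = df$map_url[i]))
}

flatten_seed_complement <- function(sc) {
  list(compounds = paste(sc$compounds$kegg_compound, collapse = ";"),
       kegg_maps = lapply(sc$kegg_maps, paste, collapse = ";"))
}

#' Export flat node and edge annotation tables
#'
#' Writes `nodes.tsv` (one row per node with its attributes) and
#' `edges.tsv` (co-occurrence and complementarity edges with a `type`
#' column) into a directory.
#'
#' @param net an `annotated_network`.
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_annotation_tables <- function(net, dir) {
  stopifnot(inherits(net, "annotated_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(net$nodes, file.path(dir, "nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  co <- data.frame(type = "co-occurrence",
                   source = net$edges$source, target = net$edges$target,
                   weight = net$edges$weight, sign = net$edges$sign,
                   donor = NA_character_, beneficiary = NA_character_,
                   n_genome_pairs = NA_integer_, stringsAsFactors = FALSE)
  ce <- net$complementarity_edges
  cm <- data.frame(type = character(), source = character(),
                   target = character(), weight = numeric(),
                   sign = character(), donor = character(),
                   beneficiary = character(), n_genome_pairs = integer(),
                   stringsAsFactors = FALSE)
  if (nrow(ce))
    cm <- data.frame(type = "complementarity", source = ce$source,
                     target = ce$target, weight = NA_real_,
                     sign = NA_character_, donor = ce$donor,
                     beneficiary = ce$beneficiary,
                     n_genome_pairs = ce$n_genome_pairs,
                     stringsAsFactors = FALSE)
  utils::write.table(rbind(co, cm), file.path(dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
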