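#' Run the full annotation workflow on files
#'
#' Thin orchestration over the package's building blocks: read the
#' co-occurrence network, genome KO annotations, module definitions,
#' per-genome reaction lists and the compound mapping; map taxa to genomes;
#' enumerate module alternatives; compute pathway complements, seed sets,
#' seed scores and seed complements for every ordered genome pair; and
#' assemble the annotated network, optionally writing the CX2 document and
#' flat annotation tables.
#'
#' @param network_path edge-list TSV or GraphML file.
#' @param nodes_path optional node TSV (`node_id<TAB>taxonomy`).
#' @param genome_index_path TSV `taxonomy<TAB>genome_id` (no header).
#' @param ko_table_path genome-to-KO TSV.
#' @param modules_path module-definition TSV.
#' @param reactions_dir directory of per-genome reaction TSVs named
#'   `<genome_id>.tsv` (or `.sbml`/`.xml` SBML models); optional.
#' @param mapping_path compound mapping TSV; optional (required when
#'   `reactions_dir` is given).
#' @param traits_path optional genome trait TSV (wide, header).
#' @param clusters_path optional node-cluster TSV (no header).
#' @param scheme taxonomy scheme, see [map_taxa_to_genomes()].
#' @param fuzzy_threshold fuzzy-match similarity threshold.
#' @param max_missing complement size cap, `Inf` for unbounded.
#' @param minimal_only drop complements whose missing set strictly contains
#'   another (see [minimal_complements()]).
#' @param cap alternatives-enumeration cap.
#' @param out_dir if non-`NULL`, write `annotated.cx2`, `nodes.tsv`,
#'   `edges.tsv` (and `complements.tsv`) there.
#' @return the `annotated_network`, invisibly if `out_dir` is given; its
#'   attributes `pathway_complements` and `seed_scores` carry the pooled
#'   pairwise tables.
#' @export
run_annotation_pipeline <- function(network_path, nodes_path = NULL,
                                    genome_index_path, ko_table_path,
                                    modules_path, reactions_dir = NULL,
                                    mapping_path = NULL, traits_path = NULL,
                                    clusters_path = NULL,
                                    scheme = "gtdb", fuzzy_threshold = 90,
                                    max_missing = Inf, minimal_only = FALSE,
                                    cap = 50000L, out_dir = NULL) {
  network <- read_network(network_path, nodes_path = nodes_path)
  genome_index <- utils::read.delim(genome_index_path, header = FALSE,
                                    sep = "\t", quote = "",
                                    stringsAsFactors = FALSE)
  names(genome_index)[1:2] <- c("taxonomy", "genome_id")
  genomes <- read_ko_table(ko_table_path)
  defs <- read_module_definitions(modules_path)
  modules <- lapply(defs, function(d)
    list(def = d, alternatives = enumerate_alternatives(d, cap = cap)))
  node_genomes <- map_taxa_to_genomes(network, genome_index, scheme = scheme,
                                      threshold = fuzzy_threshold)
  used <- intersect(unique(unlist(node_genomes)), names(genomes))

  pc <- list()
  for (b in used) for (d in setdiff(used, b)) {
    hit <- find_pathway_complements(genomes[[b]], genomes[[d]], modules,
                                    max_missing = max_missing)
    if (nrow(hit)) pc[[length(pc) + 1L]] <- hit
  }
  pathway_complements <- if (length(pc)) do.call(rbind, pc) else
    find_pathway_complements(genome_annotation("x", character(0)),
                             genome_annotation("y", character(0)), list())
  if (minimal_only) pathway_complements <- minimal_complements(pathway_complements)

  seed_sets <- NULL; seed_scores <- NULL; sc_list <- NULL
  if (!is.null(reactions_dir)) {
    stopifnot(!is.null(mapping_path))
    mapping <- read_compound_mapping(mapping_path)
    files <- list.files(reactions_dir, full.names = TRUE)
    seed_sets <- list()
    for (f in files) {
      gid <- tools::file_path_sans_ext(basename(f))
      if (!gid %in% used) next
      net <- if (grepl("\\.(sbml|xml)$", f, ignore.case = TRUE))
        read_sbml(f, network_id = gid) else read_reaction_tsv(f, network_id = gid)
      seed_sets[[gid]] <- compute_seed_set(net)
    }
    if (length(seed_sets) >= 1L) {
      pairs <- expand.grid(b = names(seed_sets), d = names(seed_sets),
                           stringsAsFactors = FALSE)
      pairs <- pairs[pairs$b != pairs$d, , drop = FALSE]
      seed_scores <- data.frame(
        beneficiary = pairs$b, donor = pairs$d,
        mi_complementarity = mapply(function(b, d)
          mi_complementarity(seed_sets[[b]], seed_sets[[d]]),
          pairs$b, pairs$d),
        mi_competition = mapply(function(b, d)
          mi_competition(seed_sets[[b]], seed_sets[[d]]),
          pairs$b, pairs$d),
        stringsAsFactors = FALSE)
      sc_list <- mapply(function(b, d)
        seed_complements(seed_sets[[b]], seed_sets[[d]], mapping),
        pairs$b, pairs$d, SIMPLIFY = FALSE)
    }
  }

  traits <- if (!is.null(traits_path)) read_traits_tsv(traits_path) else NULL
  clusters <- NULL
  if (!is.null(clusters_path)) {
    cdf <- utils::read.delim(clusters_path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)
    clusters <- stats::setNames(as.character(cdf[[2L]]), cdf[[1L]])
  }

  ann <- annotate_network(network, node_genomes, traits = traits,
                          pathway_complements = pathway_complements,
                          seed_scores = seed_scores,
                          seed_complement_list = sc_list,
                          clusters = clusters)
  attr(ann, "pathway_complements") <- pathway_complements
  attr(ann, "seed_scores") <- seed_scores
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cx2(ann, file.path(out_dir, "annotated.cx2"))
    write_annotation_tables(ann, out_dir)
    write_complements_tsv(pathway_complements,
                          file.path(out_dir, "complements.tsv"))
    return(invisible(ann))
  }
  ann
}
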