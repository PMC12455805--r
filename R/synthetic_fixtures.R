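#' @title Seeded synthetic fixtures with planted ground truth
#'
#' @description Deterministic generators for every input type the pipeline
#' consumes — module definitions with a known alternative count, genome
#' pairs with a planted complement, metabolic networks with a planted
#' DAG-of-SCCs seed structure, and annotated communities with a planted
#' cluster-trait enrichment — so every module is testable end to end with no
#' database download. All randomness flows through one explicitly seeded
#' Mersenne-Twister stream per generator call; the caller's RNG state is
#' untouched.
#'
#' @name synthetic_fixtures
NULL

# KO id ranges: definitions draw from K9xxxx, donor decoys from K7xxxx, so
# planted complements can never collide with decoy KOs.
ko_id <- function(i) sprintf("K9%04d", i)
decoy_id <- function(i) sprintf("K7%04d", i)

#' Generate a module definition with a known alternative count
#'
#' Every KO in the definition is unique, so distinct option choices always
#' yield distinct KO sets and the planted count is exactly the product over
#' steps of each step's realization count. Options are plain KOs, complexes
#' (`+`-joined, occasionally with an optional `-` member, which inflates
#' option size but not count), or two-realization nested sub-expressions.
#'
#' @param n_steps number of steps (>= 1).
#' @param options_per_step integer vector of option counts per step
#'   (recycled); `NULL` draws 1-3 per step.
#' @param complex_prob probability an option is a 2-3 member complex.
#' @param optional_prob probability a complex gains an optional member.
#' @param nested_prob probability an option is a nested `(Ka,Kb) Kc`
#'   sub-expression (counting as two realizations).
#' @param seed RNG seed.
#' @param module_id identifier for the generated module.
#' @param ko_offset offset added to the generated KO identifier counter, so
#'   several generated modules can be given disjoint KO vocabularies.
#' @param cap passed through: projecting more alternatives than this errors.
#' @return list with `module_id`, `definition` (string),
#'   `n_alternatives` (planted count), `def` (parsed `module_definition`).
#' @export
gen_module_definition <- function(n_steps, options_per_step = NULL,
                                  complex_prob = 0.3, optional_prob = 0.2,
                                  nested_prob = 0.15, seed = 1L,
                                  module_id = "MSYN", ko_offset = 0L,
                                  cap = 50000L) {
  stopifnot(n_steps >= 1L)
  with_seed(seed, {
    counter <- as.integer(ko_offset)
    next_ko <- function() {
      counter <<- counter + 1L
      ko_id(counter)
    }
    if (is.null(options_per_step))
      options_per_step <- sample(1:3, n_steps, replace = TRUE)
    options_per_step <- rep_len(options_per_step, n_steps)
    steps <- character(n_steps)
    counts <- numeric(n_steps)
    for (s in seq_len(n_steps)) {
      opts <- character(options_per_step[s])
      opt_counts <- numeric(options_per_step[s])
      for (o in seq_along(opts)) {
        u <- stats::runif(1)
        if (u < nested_prob) {
          opts[o] <- paste0("(", next_ko(), ",", next_ko(), ") ", next_ko())
          opt_counts[o] <- 2
        } else if (u < nested_prob + complex_prob) {
          members <- replicate(sample(2:3, 1L), next_ko())
          opt <- paste(members, collapse = "+")
          if (stats::runif(1) < optional_prob)
            opt <- paste0(opt, "-", next_ko())
          opts[o] <- opt
          opt_counts[o] <- 1
        } else {
          opts[o] <- next_ko()
          opt_counts[o] <- 1
        }
      }
      counts[s] <- sum(opt_counts)
      body <- paste(opts, collapse = ",")
      needs_parens <- length(opts) > 1L ||
        length(split_top(body, " ")$pieces) > 1L
      steps[s] <- if (needs_parens) paste0("(", body, ")") else body
    }
    n_alternatives <- prod(counts)
    if (n_alternatives > cap)
      stop(sprintf("planted definition projects %.0f alternatives, above the cap %d",
                   n_alternatives, as.integer(cap)), call. = FALSE)
    definition <- paste(steps, collapse = " ")
    list(module_id = module_id, definition = definition,
         n_alternatives = n_alternatives,
         def = parse_module_definition(module_id, definition))
  })
}

#' Generate a beneficiary/donor genome pair with a planted complement
#'
#' The beneficiary carries the chosen alternative minus `k_missing` randomly
#' chosen KOs; the donor carries exactly those missing KOs plus decoy KOs
#' drawn from a disjoint identifier range, so the planted complement is
#' recoverable exactly.
#'
#' @param alternative character vector: the KO set of one alternative.
#' @param k_missing number of KOs withheld from the beneficiary
#'   (1 <= k_missing <= length(alternative)).
#' @param n_decoys decoy KOs added to the donor.
#' @param seed RNG seed.
#' @return list with `beneficiary`, `donor` (both `genome_annotation`) and
#'   `missing` (the planted complement).
#' @export
gen_genome_pair <- function(alternative, k_missing, n_decoys = 5L, seed = 1L) {
  stopifnot(k_missing >= 1L, k_missing <= length(alternative))
  with_seed(seed, {
    missing <- sort(sample(alternative, k_missing))
    decoys <- decoy_id(sample.int(9999L, n_decoys))
    list(beneficiary = genome_annotation("beneficiary",
                                         setdiff(alternative, missing)),
         donor = genome_annotation("donor", c(missing, decoys)),
         missing = missing)
  })
}

#' Generate a metabolic network with planted seed structure
#'
#' Builds one strongly connected component per entry of `scc_sizes` (a
#' reversible chain or an irreversible cycle, both exactly one SCC), wires
#' the components with irreversible reactions along a DAG over component
#' indices, and returns the planted truth: the seeds are the members of the
#' DAG-source components, each with confidence 1/size.
#'
#' @param scc_sizes integer vector of component sizes (>= 1).
#' @param dag_edges two-column matrix of component indices (from, to), or
#'   `NULL` to draw random forward edges; must be acyclic.
#' @param dag_density edge probability when `dag_edges` is `NULL`.
#' @param reversible_fraction probability a component is built as a
#'   reversible chain rather than an irreversible cycle.
#' @param seed RNG seed.
#' @param network_id identifier for the network.
#' @return list with `net` (a `metabolic_network`) and `seeds` (named
#'   numeric vector: planted seed compounds with confidences).
#' @export
gen_metabolic_network <- function(scc_sizes, dag_edges = NULL,
                                  dag_density = 0.3,
                                  reversible_fraction = 0.5, seed = 1L,
                                  network_id = "synthetic_net") {
  stopifnot(length(scc_sizes) >= 1L, all(scc_sizes >= 1L))
  with_seed(seed, {
    n_scc <- length(scc_sizes)
    members <- vector("list", n_scc)
    cp <- 0L
    for (i in seq_len(n_scc)) {
      members[[i]] <- sprintf("cpd%05d", cp + seq_len(scc_sizes[i]))
      cp <- cp + scc_sizes[i]
    }
    if (is.null(dag_edges)) {
      from <- integer(); to <- integer()
      if (n_scc > 1L) {
        for (i in seq_len(n_scc - 1L)) for (j in seq(i + 1L, n_scc)) {
          if (stats::runif(1) < dag_density) {
            from <- c(from, i); to <- c(to, j)
          }
        }
      }
      dag_edges <- cbind(from, to)
    }
    dag_edges <- matrix(as.integer(dag_edges), ncol = 2L)
    if (nrow(dag_edges)) {
      dg <- igraph::graph_from_edgelist(
        matrix(as.character(dag_edges), ncol = 2L), directed = TRUE)
      if (!igraph::is_dag(dg))
        stop("the DAG specification over components is cyclic", call. = FALSE)
    }
    rid <- 0L
    rows <- list()
    add_rx <- function(s, p, rev) {
      rid <<- rid + 1L
      rows[[length(rows) + 1L]] <<- list(
        reaction_id = sprintf("rxn%05d", rid),
        substrates = list(s), products = list(p), reversible = rev)
    }
    for (i in seq_len(n_scc)) {
      k <- scc_sizes[i]
      if (k == 1L) next
      mem <- members[[i]]
      if (stats::runif(1) < reversible_fraction) {
        for (j in seq_len(k - 1L)) add_rx(mem[j], mem[j + 1L], TRUE)
      } else {
        for (j in seq_len(k)) add_rx(mem[j], mem[j %% k + 1L], FALSE)
      }
    }
    for (r in seq_len(nrow(dag_edges))) {
      s <- sample(members[[dag_edges[r, 1L]]], 1L)
      p <- sample(members[[dag_edges[r, 2L]]], 1L)
      add_rx(s, p, FALSE)
    }
    rx <- data.frame(
      reaction_id = vapply(rows, `[[`, character(1), "reaction_id"),
      reversible = vapply(rows, `[[`, logical(1), "reversible"),
      stringsAsFactors = FALSE)
    if (length(rows) == 0L)
      rx <- data.frame(reaction_id = character(), reversible = logical(),
                       stringsAsFactors = FALSE)
    rx$substrates <- lapply(rows, function(r) r$substrates[[1L]])
    rx$products <- lapply(rows, function(r) r$products[[1L]])
    net <- metabolic_network(network_id, rx,
                             compounds = unlist(members),
                             compartment_regex = NULL, drop_pattern = NULL)
    source_idx <- setdiff(seq_len(n_scc), unique(dag_edges[, 2L]))
    seeds <- numeric(0)
    for (i in source_idx)
      seeds <- c(seeds, stats::setNames(rep(1 / scc_sizes[i], scc_sizes[i]),
                                        members[[i]]))
    list(net = net, seeds = seeds[order(names(seeds))])
  })
}

#' Generate a clustered community with a planted trait enrichment
#'
#' Nodes are split evenly into clusters; the first trait is drawn with
#' probability `trait_effect` inside the first cluster and
#' `background_prob` elsewhere, all other traits with `background_prob`
#' everywhere. Co-occurrence edges are denser within clusters than between.
#' When `trait_effect == background_prob` the fixture is a null and the
#' planted enrichment list is empty.
#'
#' @param n_nodes number of nodes (>= 2 * n_clusters).
#' @param n_clusters number of clusters.
#' @param n_traits number of traits.
#' @param trait_effect in-cluster probability of the planted trait.
#' @param background_prob background trait probability.
#' @param p_within,p_between edge probabilities inside/between clusters.
#' @param seed RNG seed.
#' @return list with `network` (a `cooccurrence_network`), `traits`
#'   (node-keyed `trait_table`), `clusters` (named vector) and `planted`
#'   (data frame of planted `(cluster, trait, direction)` triples).
#' @export
gen_annotated_community <- function(n_nodes = 100L, n_clusters = 2L,
                                    n_traits = 6L, trait_effect = 0.8,
                                    background_prob = 0.2,
                                    p_within = 0.2, p_between = 0.05,
                                    seed = 1L) {
  stopifnot(n_nodes >= 2L * n_clusters, n_clusters >= 1L, n_traits >= 1L)
  with_seed(seed, {
    ids <- sprintf("n%03d", seq_len(n_nodes))
    cluster_labels <- sprintf("c%d", seq_len(n_clusters) - 1L)
    clusters <- stats::setNames(
      sample(rep_len(cluster_labels, n_nodes)), ids)
    trait_names <- sprintf("trait%d", seq_len(n_traits))
    vals <- matrix(NA, n_nodes, n_traits, dimnames = list(ids, trait_names))
    for (tr in seq_len(n_traits)) {
      p <- rep(background_prob, n_nodes)
      if (tr == 1L) p[clusters == cluster_labels[1L]] <- trait_effect
      vals[, tr] <- stats::runif(n_nodes) < p
    }
    src <- character(); tgt <- character(); w <- numeric()
    for (i in seq_len(n_nodes - 1L)) for (j in seq(i + 1L, n_nodes)) {
      p <- if (clusters[ids[i]] == clusters[ids[j]]) p_within else p_between
      if (stats::runif(1) < p) {
        src <- c(src, ids[i]); tgt <- c(tgt, ids[j])
        w <- c(w, round(sample(c(-1, 1), 1L, prob = c(0.2, 0.8)) *
                          stats::runif(1, 0.1, 1), 4))
      }
    }
    if (length(src) == 0L) {
      src <- ids[1L]; tgt <- ids[2L]; w <- 0.5
    }
    taxonomy <- sprintf(
      "d__Bacteria;p__Synthetica;c__Ficta;o__Fictales;f__Fictaceae;g__Fictus;s__Fictus%s",
      sub("^n", "", ids))
    network <- cooccurrence_network(
      data.frame(node_id = ids, taxonomy = taxonomy, stringsAsFactors = FALSE),
      data.frame(source = src, target = tgt, weight = w,
                 stringsAsFactors = FALSE))
    planted <- if (trait_effect > background_prob) {
      data.frame(cluster = cluster_labels[1L], trait = trait_names[1L],
                 direction = "enriched", stringsAsFactors = FALSE)
    } else if (trait_effect < background_prob) {
      data.frame(cluster = cluster_labels[1L], trait = trait_names[1L],
                 direction = "depleted", stringsAsFactors = FALSE)
    } else {
      data.frame(cluster = character(), trait = character(),
                 direction = character(), stringsAsFactors = FALSE)
    }
    list(network = network,
         traits = trait_table(as.data.frame(vals)),
         clusters = clusters, planted = planted)
  })
}

#' Write a self-contained fixture directory
#'
#' Emits every input format the pipeline reads — `modules.tsv`,
#' `genomes.tsv`, `reactions/*.tsv`, `mapping.tsv`, `network.tsv` +
#' `nodes.tsv`, `traits.tsv`, `clusters.tsv` — together with `truth.json`
#' recording the planted ground truth. The bundle is internally consistent:
#' each network node maps (by exact lineage) to one genome of
#' `genomes.tsv`, whose KOs come from the generated modules and whose
#' metabolic network sits under `reactions/`.
#'
#' @param dir output directory (created).
#' @param seed RNG seed governing the whole bundle.
#' @param n_taxa number of taxa/genomes.
#' @param n_modules number of module definitions.
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(dir, seed = 1L, n_taxa = 4L, n_modules = 3L) {
  dir.create(file.path(dir, "reactions"), showWarnings = FALSE, recursive = TRUE)
  mods <- lapply(seq_len(n_modules), function(i)
    gen_module_definition(n_steps = 2L + i %% 3L, seed = seed * 100L + i,
                          module_id = sprintf("MSYN%03d", i),
                          ko_offset = (i - 1L) * 200L))
  writeLines(vapply(mods, function(m)
    paste(m$module_id, m$definition, paste0("synthetic ", m$module_id),
          "synthetic", sep = "\t"), character(1)),
    file.path(dir, "modules.tsv"))

  truth <- list(seed = seed,
                module_alternative_counts = stats::setNames(
                  lapply(mods, `[[`, "n_alternatives"),
                  vapply(mods, `[[`, character(1), "module_id")))

  # genomes: taxon i carries the full first alternative of every module
  # except module (i mod n_modules)+1, where one KO is withheld; the next
  # taxon carries that missing KO.
  alts <- lapply(mods, function(m) enumerate_alternatives(m$def))
  genomes <- list()
  planted_complements <- list()
  with_seed(seed + 7L, {
    for (i in seq_len(n_taxa)) {
      gid <- sprintf("G%03d", i)
      hole_mod <- (i - 1L) %% n_modules + 1L
      kos <- character(0)
      for (m in seq_len(n_modules)) {
        a <- alts[[m]][[1L]]$ko_set
        if (m == hole_mod && length(a) > 1L) {
          miss <- sample(a, 1L)
          kos <- c(kos, setdiff(a, miss))
          planted_complements[[gid]] <- list(module = mods[[m]]$module_id,
                                             missing = miss)
        } else {
          kos <- c(kos, a)
        }
      }
      genomes[[gid]] <- sort(unique(kos))
    }
    # give each genome's missing KO to the next genome (cyclically)
    gids <- names(genomes)
    for (i in seq_along(gids)) {
      donor <- gids[i %% length(gids) + 1L]
      miss <- planted_complements[[gids[i]]]
      if (!is.null(miss))
        genomes[[donor]] <- sort(unique(c(genomes[[donor]], miss$missing)))
    }
  })
  rows <- unlist(lapply(names(genomes), function(g)
    paste(g, genomes[[g]], sep = "\t")))
  writeLines(rows, file.path(dir, "genomes.tsv"))
  truth$planted_complements <- planted_complements

  # one metabolic network per genome with planted seeds
  planted_seeds <- list()
  for (i in seq_along(genomes)) {
    gid <- names(genomes)[i]
    gm <- gen_metabolic_network(scc_sizes = c(1L, 2L, 3L),
                                dag_edges = cbind(c(1L, 2L), c(2L, 3L)),
                                seed = seed * 10L + i, network_id = gid)
    flat <- data.frame(
      id = gm$net$reactions$reaction_id,
      s = vapply(gm$net$reactions$substrates, join_semi, character(1)),
      p = vapply(gm$net$reactions$products, join_semi, character(1)),
      rev = as.integer(gm$net$reactions$reversible))
    utils::write.table(flat, file.path(dir, "reactions", paste0(gid, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    planted_seeds[[gid]] <- as.list(gm$seeds)
  }
  truth$planted_seeds <- planted_seeds

  # compound mapping: every generated compound, all module-linked
  cps <- sort(unique(unlist(lapply(planted_seeds, names))))
  all_cps <- sprintf("cpd%05d", seq_len(6L))
  map_df <- data.frame(
    internal = all_cps,
    kegg = sprintf("C%05d", seq_along(all_cps)),
    maps = rep(c("map00010", "map00020"), length.out = length(all_cps)),
    linked = 1L)
  utils::write.table(map_df, file.path(dir, "mapping.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  # community: one node per genome, exact-matchable lineages
  comm <- gen_annotated_community(n_nodes = max(2L * n_taxa, 10L),
                                  n_clusters = 2L, seed = seed + 13L)
  nodes <- comm$network$nodes[seq_len(n_taxa), , drop = FALSE]
  edges <- expand.grid(i = seq_len(n_taxa - 1L), j = seq_len(n_taxa),
                       KEEP.OUT.ATTRS = FALSE)
  edges <- edges[edges$i < edges$j, , drop = FALSE]
  net_edges <- data.frame(source = nodes$node_id[edges$i],
                          target = nodes$node_id[edges$j],
                          weight = 0.5, stringsAsFactors = FALSE)
  utils::write.table(net_edges, file.path(dir, "network.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(nodes[, c("node_id", "taxonomy")],
                     file.path(dir, "nodes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  genome_index <- data.frame(taxonomy = nodes$taxonomy,
                             genome_id = names(genomes))
  utils::write.table(genome_index, file.path(dir, "genome_index.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)

  tt <- comm$traits$values
  full_tt <- data.frame(entity = rownames(tt),
                        lapply(tt, as.integer), check.names = FALSE)
  utils::write.table(full_tt, file.path(dir, "traits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(node = names(comm$clusters), cluster = comm$clusters),
    file.path(dir, "clusters.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  truth$planted_enrichment <- comm$planted
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
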