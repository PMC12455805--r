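toy_network <- function() {
  cooccurrence_network(
    data.frame(
      node_id = c("n1", "n2", "n3"),
      taxonomy = c("d__Bacteria;p__P;c__C;o__O;f__F;g__G;s__G alpha",
                   "d__Bacteria;p__P;c__C;o__O;f__F;g__G;s__G beta",
                   "d__Bacteria;p__P;c__C;o__O;f__F;g__G"),
      stringsAsFactors = FALSE),
    data.frame(source = c("n1", "n2"), target = c("n2", "n3"),
               weight = c(0.8, -0.4), stringsAsFactors = FALSE))
}

toy_index <- function() {
  data.frame(
    taxonomy = c("d__Bacteria;p__P;c__C;o__O;f__F;g__G;s__G alpha",
                 "d__Bacteria;p__P;c__C;o__O;f__F;g__G;s__G alpha",
                 "d__Bacteria;p__P;c__C;o__O;f__F;g__G;s__G beta"),
    genome_id = c("GA1", "GA2", "GB1"),
    stringsAsFactors = FALSE)
}

test_that("network construction validates ids, self-edges and weights", {
  expect_error(cooccurrence_network(
    data.frame(node_id = c("a", "a"), taxonomy = ""),
    data.frame(source = "a", target = "a", weight = 1)), "unique")
  expect_error(cooccurrence_network(
    data.frame(node_id = c("a", "b"), taxonomy = ""),
    data.frame(source = "a", target = "a", weight = 1)), "self-edges")
  expect_error(cooccurrence_network(
    data.frame(node_id = c("a", "b"), taxonomy = ""),
    data.frame(source = "a", target = "b", weight = Inf)), "finite")
  net <- toy_network()
  expect_identical(net$edges$sign,
                   c("positive co-occurrence", "mutual exclusion"))
})

test_that("taxonomic level inference reads rank prefixes and field counts", {
  expect_identical(infer_taxonomic_level("d__B;p__P;c__C;o__O;f__F;g__G;s__G a"),
                   "species")
  expect_identical(infer_taxonomic_level("d__B;p__P;c__C;o__O;f__F;g__G;s__"),
                   "genus")
  expect_identical(infer_taxonomic_level("Escherichia coli"), "species")
  expect_identical(infer_taxonomic_level("Bacteria;Proteobacteria"), "phylum")
  expect_identical(infer_taxonomic_level(""), "unknown")
})

test_that("Levenshtein similarity matches the DP oracle and fuzzy matching obeys its threshold", {
  strings <- c("Escherichia coli", "Escherichia albertii", "Bacillus subtilis",
               "Escherichia coli K-12", "Lactobacillus", "escherichia colli")
  for (a in strings) for (b in strings) {
    d <- oracle_levenshtein(a, b)
    expect_equal(levenshtein_similarity(a, b),
                 100 * (1 - d / max(nchar(a), nchar(b))),
                 info = paste(a, "vs", b))
  }

  dict <- c("Escherichia coli" = "t1", "Escherichia albertii" = "t2")
  hit <- match_taxon_name("Escherichia coli K-12", dict, threshold = 0)
  best <- names(dict)[which.max(vapply(names(dict), function(n)
    100 * (1 - oracle_levenshtein(n, "Escherichia coli K-12") /
             max(nchar(n), nchar("Escherichia coli K-12"))), numeric(1)))]
  expect_identical(hit$name, best)
  ratio <- 100 * (1 - oracle_levenshtein(best, "Escherichia coli K-12") /
                    max(nchar(best), nchar("Escherichia coli K-12")))
  expect_equal(hit$score, ratio)
  # accepted iff the ratio reaches the default threshold of 90
  hit90 <- match_taxon_name("Escherichia coli K-12", dict, threshold = 90)
  expect_identical(is.null(hit90), ratio < 90)

  expect_identical(match_taxon_name("Escherichia coli", dict, 100)$score, 100)
  expect_null(match_taxon_name("Escherichia coli", dict, threshold = 101))
  expect_null(match_taxon_name("", dict))
  expect_message(match_taxon_name("Aaa", c(Aab = "1", Aac = "2"), threshold = 0),
                 "tie")
})

test_that("genome mapping is gated at species level and supports multi-genome hits", {
  mp <- map_taxa_to_genomes(toy_network(), toy_index(), scheme = "gtdb")
  expect_setequal(mp$n1, c("GA1", "GA2"))
  expect_identical(mp$n2, "GB1")
  expect_length(mp$n3, 0L)  # genus-level node maps to nothing
  expect_error(map_taxa_to_genomes(toy_network(), toy_index(), scheme = "ncbi"))
})

test_that("fuzzy mapping recovers planted typo-bearing names", {
  withr::with_seed(55L, {
    species <- sprintf("Fictus%s longinamus%03d", letters[1:20], 1:20)
    index <- data.frame(taxonomy = species, genome_id = sprintf("G%02d", 1:20))
    queries <- species
    mutate <- sample(20L, 2L)  # 10% of names get a one-character typo
    for (i in mutate) {
      pos <- sample(nchar(queries[i]), 1L)
      substr(queries[i], pos, pos) <- "z"
    }
    net <- cooccurrence_network(
      data.frame(node_id = sprintf("q%02d", 1:20), taxonomy = queries,
                 stringsAsFactors = FALSE),
      data.frame(source = "q01", target = "q02", weight = 1))
    mp <- map_taxa_to_genomes(net, index, scheme = "other", threshold = 90)
    hits <- vapply(mp, function(x) if (length(x)) x else NA_character_,
                   character(1))
    expect_identical(unname(hits), index$genome_id)  # all recovered
  })
})

annotated_fixture <- function() {
  net <- toy_network()
  node_genomes <- list(n1 = c("GA1", "GA2"), n2 = c("GB1", "GB2", "GB3"),
                       n3 = character(0))
  gm <- gen_module_definition(2L, options_per_step = 1L, seed = 5L)
  alts <- enumerate_alternatives(gm$def)
  modules <- list(list(def = gm$def, alternatives = alts))
  kos <- alts[[1L]]$ko_set
  pc <- list()
  # every GA -> GB and GB -> GA genome pair complements (both directions)
  for (b in c("GB1", "GB2", "GB3")) for (d in c("GA1", "GA2"))
    pc[[length(pc) + 1L]] <- find_pathway_complements(
      genome_annotation(b, kos[-1L]), genome_annotation(d, kos), modules)
  for (b in c("GA1", "GA2")) for (d in c("GB1", "GB2", "GB3"))
    pc[[length(pc) + 1L]] <- find_pathway_complements(
      genome_annotation(b, kos[-2L]), genome_annotation(d, kos), modules)
  traits <- trait_table(
    data.frame(aerobe = c(TRUE, FALSE, TRUE, NA, TRUE),
               halophile = c(FALSE, FALSE, NA, NA, FALSE),
               row.names = c("GA1", "GA2", "GB1", "GB2", "GB3")),
    groups = c(aerobe = "lifestyle", halophile = "lifestyle"))
  list(net = net, node_genomes = node_genomes,
       pathway_complements = do.call(rbind, pc), traits = traits)
}

test_that("annotation preserves the input network and adds directed edges per role", {
  fx <- annotated_fixture()
  ann <- annotate_network(fx$net, fx$node_genomes, traits = fx$traits,
                          pathway_complements = fx$pathway_complements)
  # conservation
  expect_identical(ann$edges$source, fx$net$edges$source)
  expect_identical(ann$edges$weight, fx$net$edges$weight)
  expect_identical(nrow(ann$nodes), nrow(fx$net$nodes))
  # both directions complement -> exactly 2 directed edges on the n1-n2 pair
  ce <- ann$complementarity_edges
  expect_identical(nrow(ce), 2L)
  expect_setequal(paste(ce$source, ce$target), c("n1 n2", "n2 n1"))
  expect_identical(ce$beneficiary, ce$target)
  expect_identical(ce$donor, ce$source)
  # 2 x 3 genome mappings -> 6 genome-pair sub-tables per direction
  expect_identical(sort(unique(ce$n_genome_pairs)), 6L)
  # node trait fold-up: any-present wins; unknown propagates
  expect_true(ann$nodes[ann$nodes$node_id == "n1", "trait:aerobe"])
  expect_true(is.na(ann$nodes[ann$nodes$node_id == "n3", "trait:aerobe"]))
})

test_that("annotation is idempotent and a no-op without complements", {
  fx <- annotated_fixture()
  ann1 <- annotate_network(fx$net, fx$node_genomes, traits = fx$traits,
                           pathway_complements = fx$pathway_complements)
  ann2 <- annotate_network(ann1, fx$node_genomes, traits = fx$traits,
                           pathway_complements = fx$pathway_complements)
  expect_identical(ann2$edges, ann1$edges)
  expect_identical(ann2$complementarity_edges[, 1:5],
                   ann1$complementarity_edges[, 1:5])

  bare <- annotate_network(fx$net, fx$node_genomes)
  expect_identical(nrow(bare$complementarity_edges), 0L)
  expect_identical(bare$edges[, c("source", "target", "weight")],
                   fx$net$edges[, c("source", "target", "weight")])
})

test_that("complements naming unmapped genomes are rejected", {
  fx <- annotated_fixture()
  rogue <- fx$pathway_complements
  rogue$donor[1L] <- "GHOST"
  expect_error(annotate_network(fx$net, fx$node_genomes,
                                pathway_complements = rogue), "not mapped")
})

test_that("trait filters implement OR and ALL semantics with unknown as absent", {
  fx <- annotated_fixture()
  ann <- annotate_network(fx$net, fx$node_genomes, traits = fx$traits,
                          pathway_complements = fx$pathway_complements)
  expect_identical(filter_nodes_by_traits(ann, character(0), "ANY"), character(0))
  any_hit <- filter_nodes_by_traits(ann, c("aerobe", "halophile"), "ANY")
  all_hit <- filter_nodes_by_traits(ann, c("aerobe", "halophile"), "ALL")
  # naive per-node scan
  m <- ann$node_traits
  m[is.na(m)] <- FALSE
  expect_setequal(any_hit, rownames(m)[m[, "aerobe"] | m[, "halophile"]])
  expect_setequal(all_hit, rownames(m)[m[, "aerobe"] & m[, "halophile"]])
  expect_error(filter_nodes_by_traits(ann, "psychrophile"), "undeclared")
})

test_that("CX2 export is valid JSON with the declared aspects", {
  fx <- annotated_fixture()
  ann <- annotate_network(fx$net, fx$node_genomes, traits = fx$traits,
                          pathway_complements = fx$pathway_complements)
  tf <- tempfile(fileext = ".cx2")
  write_cx2(ann, tf)
  doc <- jsonlite::read_json(tf)
  aspects <- vapply(doc, function(a) names(a)[1L], character(1))
  expect_true(all(c("CXVersion", "nodes", "edges", "status") %in% aspects))
  nodes <- doc[[which(aspects == "nodes")]]$nodes
  expect_length(nodes, 3L)
  edges <- doc[[which(aspects == "edges")]]$edges
  kinds <- vapply(edges, function(e) e$v$interaction, character(1))
  expect_identical(sum(kinds == "co-occurrence"), 2L)
  expect_identical(sum(kinds == "complementarity"), 2L)
  comp <- edges[[which(kinds == "complementarity")[1L]]]
  sub <- jsonlite::fromJSON(comp$v$pathway_complements, simplifyVector = FALSE)
  expect_length(sub, 6L)  # one table per genome pair

  out <- tempfile()
  write_annotation_tables(ann, out)
  expect_true(file.exists(file.path(out, "nodes.tsv")))
  edges_tab <- utils::read.delim(file.path(out, "edges.tsv"))
  expect_identical(nrow(edges_tab), 4L)
})

test_that("edge-list TSV and GraphML inputs read to the same network", {
  tf <- tempfile(fileext = ".tsv")
  nf <- tempfile(fileext = ".tsv")
  writeLines(c("a\tb\t0.5", "b\tc\t-0.25"), tf)
  writeLines(c("a\tG sp1", "b\tG sp2", "c\tG sp3"), nf)
  net <- read_network(tf, nodes_path = nf)
  expect_identical(nrow(net$edges), 2L)
  expect_identical(net$nodes$taxonomy[1L], "G sp1")

  g <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "b"), to = c("b", "c")),
    directed = FALSE,
    vertices = data.frame(name = c("a", "b", "c"),
                          taxonomy = c("G sp1", "G sp2", "G sp3")))
  igraph::E(g)$weight <- c(0.5, -0.25)
  gf <- tempfile(fileext = ".graphml")
  igraph::write_graph(g, gf, format = "graphml")
  net2 <- read_network(gf)
  expect_identical(net2$nodes$taxonomy, net$nodes$taxonomy)
  expect_identical(net2$edges$weight, net$edges$weight)
})
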