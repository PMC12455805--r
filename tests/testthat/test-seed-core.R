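rxn_df <- function(...) {
  rows <- list(...)
  df <- data.frame(
    reaction_id = vapply(rows, `[[`, character(1), 1L),
    reversible = vapply(rows, `[[`, logical(1), 4L),
    stringsAsFactors = FALSE)
  df$substrates <- lapply(rows, `[[`, 2L)
  df$products <- lapply(rows, `[[`, 3L)
  df
}

test_that("compound graphs follow substrate-to-product semantics", {
  net <- metabolic_network("n1", rxn_df(list("r1", c("A", "B"), "C", FALSE)))
  g <- build_compound_graph(net)
  el <- apply(igraph::as_edgelist(g), 1L, paste, collapse = ">")
  expect_setequal(el, c("A>C", "B>C"))

  net2 <- metabolic_network("n2", rxn_df(list("r1", "A", "B", TRUE)))
  el2 <- apply(igraph::as_edgelist(build_compound_graph(net2)), 1L,
               paste, collapse = ">")
  expect_setequal(el2, c("A>B", "B>A"))

  # self-loops are dropped, parallel edges collapse
  net3 <- metabolic_network("n3", rxn_df(
    list("r1", c("A"), c("A", "B"), FALSE),
    list("r2", "A", "B", FALSE)))
  g3 <- build_compound_graph(net3)
  expect_identical(igraph::ecount(g3), 1)
})

test_that("random reaction lists reproduce a naive per-reaction edge oracle", {
  withr::with_seed(31L, {
    for (rep in 1:5) {
      cps <- sprintf("c%02d", 1:12)
      rows <- lapply(1:50, function(i) {
        s <- sample(cps, sample(1:2, 1L))
        p <- sample(cps, sample(1:2, 1L))
        list(sprintf("r%02d", i), s, p, runif(1) < 0.4)
      })
      net <- metabolic_network("rand", do.call(rxn_df, rows),
                               compartment_regex = NULL, drop_pattern = NULL)
      g <- build_compound_graph(net)
      # naive oracle
      edges <- character(0)
      for (r in rows) {
        for (s in r[[2]]) for (p in r[[3]]) {
          if (s != p) {
            edges <- c(edges, paste(s, p, sep = ">"))
            if (r[[4]]) edges <- c(edges, paste(p, s, sep = ">"))
          }
        }
      }
      got <- apply(igraph::as_edgelist(g), 1L, paste, collapse = ">")
      expect_setequal(got, unique(edges))
    }
  })
})

test_that("SCC condensation matches a brute-force mutual-reachability oracle", {
  # simple shapes first
  net <- metabolic_network("chain", rxn_df(list("r1", "A", "B", FALSE),
                                           list("r2", "B", "C", FALSE)))
  cond <- condense_sccs(build_compound_graph(net))
  expect_identical(max(cond$scc_of), 3L)

  net2 <- metabolic_network("cycle", rxn_df(list("r1", "A", "B", TRUE)))
  cond2 <- condense_sccs(build_compound_graph(net2))
  expect_identical(max(cond2$scc_of), 1L)
  expect_true(igraph::is_dag(cond$dag))

  withr::with_seed(17L, {
    for (rep in 1:6) {
      n <- sample(10:40, 1L)
      nodes <- sprintf("v%03d", seq_len(n))
      m <- sample(n:(3L * n), 1L)
      from <- sample(nodes, m, replace = TRUE)
      to <- sample(nodes, m, replace = TRUE)
      keep <- from != to
      g <- igraph::simplify(igraph::graph_from_data_frame(
        data.frame(from = from[keep], to = to[keep]),
        vertices = data.frame(name = nodes)))
      cond <- condense_sccs(g)
      oracle <- oracle_scc_partition(nodes, from[keep], to[keep])
      # same partitions up to relabeling
      expect_identical(
        unname(split(nodes, cond$scc_of[nodes])[order(vapply(split(nodes, cond$scc_of[nodes]), `[[`, character(1), 1L))]),
        unname(split(nodes, oracle)[order(vapply(split(nodes, oracle), `[[`, character(1), 1L))]))
      expect_true(igraph::is_dag(cond$dag))
    }
  })
})

test_that("seed sets of simple motifs are exact", {
  chain <- metabolic_network("chain", rxn_df(list("r1", "A", "B", FALSE),
                                             list("r2", "B", "C", FALSE)))
  ss <- compute_seed_set(chain)
  expect_identical(names(ss$seeds), "A")
  expect_identical(unname(ss$seeds), 1)
  expect_identical(ss$non_seeds, c("B", "C"))

  pair <- metabolic_network("pair", rxn_df(list("r1", "A", "B", TRUE)))
  sp <- compute_seed_set(pair)
  expect_identical(unname(sp$seeds[c("A", "B")]), c(0.5, 0.5))
  expect_length(sp$non_seeds, 0L)

  iso <- metabolic_network("iso", rxn_df(list("r1", "A", "B", FALSE)),
                           compounds = "Z")
  si <- compute_seed_set(iso)
  expect_identical(unname(si$seeds["Z"]), 1)

  empty <- metabolic_network("none", rxn_df()[0, ])
  expect_error(compute_seed_set(empty), "empty")
})

test_that("planted DAG-of-SCC networks are recovered exactly with 1/k confidences", {
  for (s in 1:30) {
    sizes <- sample(1:5, sample(2:6, 1L), replace = TRUE)
    gm <- gen_metabolic_network(sizes, seed = 500L + s)
    ss <- compute_seed_set(gm$net)
    expect_identical(names(ss$seeds), names(gm$seeds))
    expect_equal(unname(ss$seeds), unname(gm$seeds))
    # per-SCC normalization: confidences inside each source SCC sum to 1
    by_scc <- split(ss$seeds, ss$scc_of[names(ss$seeds)])
    expect_true(all(abs(vapply(by_scc, sum, numeric(1)) - 1) < 1e-12))
    # reachability closure: every compound reachable from the seed set
    g <- build_compound_graph(gm$net)
    reached <- unique(unlist(lapply(names(ss$seeds), function(sd)
      names(igraph::subcomponent(g, sd, mode = "out")))))
    expect_setequal(reached, gm$net$compounds)
  }
})

test_that("making a reaction reversible never increases the seed count", {
  withr::with_seed(61L, {
    for (rep in 1:8) {
      gm <- gen_metabolic_network(sample(1:4, 4L, replace = TRUE),
                                  seed = 700L + rep)
      net <- gm$net
      irrev <- which(!net$reactions$reversible)
      if (length(irrev) == 0L) next
      flip <- sample(irrev, 1L)
      net2 <- net
      net2$reactions$reversible[flip] <- TRUE
      n_scc_1 <- max(condense_sccs(build_compound_graph(net))$scc_of)
      n_scc_2 <- max(condense_sccs(build_compound_graph(net2))$scc_of)
      expect_lte(n_scc_2, n_scc_1)
      # seed groups (source SCCs) cannot multiply when edges are added
      expect_lte(length(compute_seed_set(net2)$source_sccs),
                 length(compute_seed_set(net)$source_sccs))
    }
  })
})

test_that("compartment suffixes are stripped and pseudo-reactions dropped", {
  net <- metabolic_network("m", rxn_df(
    list("rxn1", "cpd00001_c0", "cpd00002_c0", FALSE),
    list("EX_cpd00002_e0", "cpd00002_e0", "cpd00002_b", FALSE),
    list("bio1", "cpd00002_c0", "cpd99999_c0", FALSE)))
  expect_setequal(net$compounds, c("cpd00001", "cpd00002"))
  expect_identical(net$reactions$reaction_id, "rxn1")
  ss <- compute_seed_set(net)
  expect_identical(names(ss$seeds), "cpd00001")
})

test_that("reaction TSVs and minimal SBML read to the same network", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("r1\tA;B\tC\t0", "r2\tC\tD\t1"), tf)
  net_tsv <- read_reaction_tsv(tf, network_id = "m")

  sbml <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="m"><listOfSpecies>',
    '<species id="A"/><species id="B"/><species id="C"/><species id="D"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="r1" reversible="false"><listOfReactants>',
    '<speciesReference species="A"/><speciesReference species="B"/>',
    '</listOfReactants><listOfProducts><speciesReference species="C"/>',
    '</listOfProducts></reaction>',
    '<reaction id="r2" reversible="true"><listOfReactants>',
    '<speciesReference species="C"/></listOfReactants>',
    '<listOfProducts><speciesReference species="D"/></listOfProducts>',
    '</reaction></listOfReactions></model></sbml>'), sbml)
  net_sbml <- read_sbml(sbml, network_id = "m")
  expect_identical(net_sbml$compounds, net_tsv$compounds)
  expect_identical(net_sbml$reactions$reversible, net_tsv$reactions$reversible)
  expect_identical(compute_seed_set(net_sbml)$seeds,
                   compute_seed_set(net_tsv)$seeds)
})

test_that("unknown compounds in a reaction raise an error", {
  net <- metabolic_network("m", rxn_df(list("r1", "A", "B", FALSE)))
  net$compounds <- "A"  # corrupt on purpose
  expect_error(build_compound_graph(net), "unknown compound")
})
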