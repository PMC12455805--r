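#' @title Cluster-level trait enrichment and depletion
#'
#' @description Each network cluster is tested for enrichment and depletion
#' of each phenotypic trait with one-sided hypergeometric tail tests:
#' drawing the cluster's annotated nodes without replacement from the
#' annotated background, is the number of trait-positive nodes in the
#' cluster surprisingly high (enrichment, upper tail) or low (depletion,
#' lower tail)? All cluster-by-trait-by-direction p-values form one family
#' for Benjamini-Hochberg false-discovery-rate control.
#'
#' @name enrichment
NULL

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: after ascending sort,
#' `q_(i) = min_{j >= i}( p_(j) * m / j )` clipped to 1 and mapped back to
#' the input order (a validated wrapper around [stats::p.adjust()]).
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Test every cluster for trait enrichment and depletion
#'
#' Per (cluster, trait) cell with `X ~ Hypergeometric(N, K, n)`:
#' enrichment `p = P[X >= k]`, depletion `p = P[X <= k]`, where `N` is the
#' annotated background size, `K` the trait-positive background count, `n`
#' the annotated cluster size and `k` the trait-positive cluster count.
#' Nodes with unknown (`NA`) trait status are excluded per-test; traits
#' positive in zero background nodes are skipped with a message. BH
#' adjustment is applied jointly across all cluster x trait x direction
#' tests.
#'
#' @param traits node-level trait values: a `trait_table` keyed by node id,
#'   or a logical matrix (rows = nodes, columns = traits, `NA` = unknown)
#'   such as the `node_traits` slot of an `annotated_network`.
#' @param clusters named vector node id -> cluster label; nodes without a
#'   label are excluded from the tests.
#' @param background node ids forming the annotated background; defaults to
#'   all clustered nodes with at least one known trait value.
#' @return data frame of class `enrichment_result` with columns `cluster`,
#'   `trait`, `direction` (`"enriched"`/`"depleted"`), `k`, `n`, `K`, `N`,
#'   `p_value`, `q_value`.
#' @export
cluster_trait_tests <- function(traits, clusters, background = NULL) {
  m <- if (inherits(traits, "trait_table")) as.matrix(traits$values) else as.matrix(traits)
  stopifnot(!is.null(rownames(m)), !is.null(names(clusters)))
  clusters <- clusters[!is.na(clusters)]
  if (length(unique(clusters)) < 1L)
    stop("at least one cluster is required", call. = FALSE)
  if (is.null(background))
    background <- intersect(names(clusters),
                            rownames(m)[rowSums(!is.na(m)) > 0])
  background <- intersect(background, rownames(m))
  rows <- list()
  for (tr in colnames(m)) {
    known <- background[!is.na(m[background, tr])]
    N <- length(known)
    K <- sum(m[known, tr])
    if (N == 0L || K == 0L) {
      message("trait '", tr, "' is positive in no background node; skipped")
      next
    }
    for (cl in sort(unique(as.character(clusters)))) {
      members <- intersect(names(clusters)[clusters == cl], known)
      n <- length(members)
      k <- sum(m[members, tr])
      p_enr <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      p_dep <- stats::phyper(k, K, N - K, n)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, trait = tr, direction = "enriched",
        k = k, n = n, K = K, N = N, p_value = p_enr,
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, trait = tr, direction = "depleted",
        k = k, n = n, K = K, N = N, p_value = p_dep,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(cluster = character(), trait = character(),
                      direction = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_value = numeric(),
                      q_value = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Write enrichment results to TSV
#'
#' @param results data frame from [cluster_trait_tests()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
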