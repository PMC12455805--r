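#' @title Pairwise seed scores and seed complementarity
#'
#' @description Two indices summarize the metabolic interplay read off the
#' seed sets of a (beneficiary A, donor B) pair. The metabolic
#' complementarity index is the fraction of A's seeds that B can synthesize
#' (i.e. that lie in B's non-seed set) — an upper bound on cross-feeding
#' potential. The metabolic competition index is the confidence-weighted
#' overlap of the two seed sets — a measure of nutritional-profile
#' similarity and hence potential competition. Seed complementarity listings
#' are restricted to compounds linked to KEGG modules through a compound
#' mapping table.
#'
#' @name seed_interactions
NULL

#' Metabolic complementarity index
#'
#' Fraction of the beneficiary's seed compounds found among the donor's
#' non-seeds: `|Seeds_A intersect NonSeeds_B| / |Seeds_A|`. The index is
#' asymmetric; the self-pair value is 0.
#'
#' @param seeds_a beneficiary `seed_set`.
#' @param seeds_b donor `seed_set`.
#' @return numeric in \[0, 1\].
#' @export
mi_complementarity <- function(seeds_a, seeds_b) {
  stopifnot(inherits(seeds_a, "seed_set"), inherits(seeds_b, "seed_set"))
  if (length(seeds_a$seeds) == 0L)
    stop("beneficiary network ", seeds_a$network_id,
         " has an empty seed set; the index is undefined", call. = FALSE)
  length(intersect(names(seeds_a$seeds), seeds_b$non_seeds)) /
    length(seeds_a$seeds)
}

#' Metabolic competition index
#'
#' Confidence-weighted overlap of two seed sets, weighted on the beneficiary
#' side: `sum(C_A over Seeds_A intersect Seeds_B) / sum(C_A over Seeds_A)`.
#' The self-pair value is 1.
#'
#' @inheritParams mi_complementarity
#' @return numeric in \[0, 1\].
#' @export
mi_competition <- function(seeds_a, seeds_b) {
  stopifnot(inherits(seeds_a, "seed_set"), inherits(seeds_b, "seed_set"))
  if (length(seeds_a$seeds) == 0L || sum(seeds_a$seeds) <= 0)
    stop("beneficiary network ", seeds_a$network_id,
         " has an empty seed set; the index is undefined", call. = FALSE)
  shared <- intersect(names(seeds_a$seeds), names(seeds_b$seeds))
  sum(seeds_a$seeds[shared]) / sum(seeds_a$seeds)
}

#' Read a compound-namespace mapping table
#'
#' Columns (no header): `internal_id<TAB>kegg_compound<TAB>kegg_maps
#' (;-joined)<TAB>module_linked(0/1)`. Internal ids must be unique; the
#' module-linked rows form the whitelist used by [seed_complements()].
#'
#' @param path file path.
#' @return object of class `compound_mapping` (a data frame with list-column
#'   `kegg_maps`).
#' @export
read_compound_mapping <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 4L)
    stop("compound mapping needs four tab-separated columns", call. = FALSE)
  compound_mapping(data.frame(
    internal_id = as.character(df[[1L]]),
    kegg_compound = as.character(df[[2L]]),
    kegg_maps_flat = as.character(df[[3L]]),
    module_linked = as.integer(df[[4L]]) != 0L,
    stringsAsFactors = FALSE))
}

#' @rdname read_compound_mapping
#' @param df data frame with columns `internal_id`, `kegg_compound`,
#'   `kegg_maps_flat` (;-joined) or list-column `kegg_maps`, `module_linked`.
#' @export
compound_mapping <- function(df) {
  stopifnot(all(c("internal_id", "kegg_compound", "module_linked") %in% names(df)))
  if (anyDuplicated(df$internal_id))
    stop("internal compound ids in a mapping must be unique", call. = FALSE)
  if (is.null(df[["kegg_maps"]]))
    df[["kegg_maps"]] <- lapply(df[["kegg_maps_flat"]], split_semi)
  df[["kegg_maps_flat"]] <- NULL
  class(df) <- c("compound_mapping", "data.frame")
  df
}

#' Seed complements between a beneficiary and a donor network
#'
#' Compounds that are seeds of the beneficiary, non-seeds of the donor
#' (i.e. producible by the donor), and on the module-linked whitelist of the
#' compound mapping; translated to KEGG compound ids and grouped by KEGG
#' map. A compound linked to several maps appears under each of them.
#' Compounds lacking a KEGG translation or not module-linked are excluded
#' from the listing (they still count in the MI indices, which operate on
#' the raw seed sets).
#'
#' @param beneficiary,donor `seed_set` objects.
#' @param mapping a `compound_mapping`.
#' @param category optional free-text label carried through to the output.
#' @return object of class `seed_complement`: `beneficiary_id`, `donor_id`,
#'   `compounds` (data frame `internal_id`, `kegg_compound`), `kegg_maps`
#'   (named list: map id to KEGG compound ids), `category`.
#' @export
seed_complements <- function(beneficiary, donor, mapping, category = NA_character_) {
  stopifnot(inherits(beneficiary, "seed_set"), inherits(donor, "seed_set"),
            inherits(mapping, "compound_mapping"))
  whitelist <- mapping$internal_id[mapping$module_linked &
                                     nzchar(mapping$kegg_compound)]
  cps <- sort(intersect(intersect(names(beneficiary$seeds), donor$non_seeds),
                        whitelist))
  idx <- match(cps, mapping$internal_id)
  compounds <- data.frame(internal_id = cps,
                          kegg_compound = mapping$kegg_compound[idx],
                          stringsAsFactors = FALSE)
  kegg_maps <- list()
  for (i in seq_along(cps)) {
    for (m in mapping$kegg_maps[[idx[i]]]) {
      kegg_maps[[m]] <- sort(unique(c(kegg_maps[[m]],
                                      mapping$kegg_compound[idx[i]])))
    }
  }
  structure(
    list(beneficiary_id = beneficiary$network_id,
         donor_id = donor$network_id,
         compounds = compounds,
         kegg_maps = if (length(kegg_maps)) kegg_maps[order(names(kegg_maps))] else list(),
         category = category),
    class = "seed_complement")
}

# Compound color tokens on seed maps: cross-fed seeds red, compounds the
# beneficiary produces on its own blue.
SEED_CROSSFED_COLOR <- "%23ff0000"
SEED_BENEF_COLOR <- "%230000ff"

#' Colored KEGG map URL for seed complements
#'
#' Cross-fed seed compounds carry the red color token and
#' beneficiary-produced compounds the blue one; compounds are sorted so the
#' URL is deterministic. A compound in both sets is colored as cross-fed.
#'
#' @param map_id KEGG map identifier.
#' @param beneficiary_related compounds produced by the beneficiary itself.
#' @param seed_complements compounds a donor could cross-feed.
#' @return URL string.
#' @export
build_seed_map_url <- function(map_id, beneficiary_related, seed_complements) {
  stopifnot(is.character(map_id), length(map_id) == 1L)
  beneficiary_related <- setdiff(beneficiary_related, seed_complements)
  cps <- sort(unique(c(beneficiary_related, seed_complements)))
  tokens <- vapply(cps, function(cp) {
    col <- if (cp %in% seed_complements) SEED_CROSSFED_COLOR else SEED_BENEF_COLOR
    paste0(cp, "%09", col)
  }, character(1))
  paste0("https://www.kegg.jp/kegg-bin/show_pathway?", map_id,
         if (length(tokens)) paste0("/", paste(tokens, collapse = "/")) else "")
}

#' Seed-score matrices over a collection of networks
#'
#' @param seed_sets named list of `seed_set` objects.
#' @return list of two matrices (`complementarity`, `competition`), rows =
#'   beneficiary, columns = donor.
#' @export
seed_score_matrices <- function(seed_sets) {
  ids <- vapply(seed_sets, function(s) s$network_id, character(1))
  n <- length(seed_sets)
  comp <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  compet <- comp
  for (i in seq_len(n)) for (j in seq_len(n)) {
    comp[i, j] <- mi_complementarity(seed_sets[[i]], seed_sets[[j]])
    compet[i, j] <- mi_competition(seed_sets[[i]], seed_sets[[j]])
  }
  list(complementarity = comp, competition = compet)
}

#' Flatten seed complements to a long-format data frame
#'
#' @param x a `seed_complement` or list of them.
#' @return data frame `beneficiary`, `donor`, `kegg_map`, `kegg_compound`,
#'   `internal_id`.
#' @export
seed_complements_table <- function(x) {
  if (inherits(x, "seed_complement")) x <- list(x)
  rows <- list()
  for (sc in x) {
    for (m in names(sc$kegg_maps)) {
      for (cp in sc$kegg_maps[[m]]) {
        internal <- sc$compounds$internal_id[sc$compounds$kegg_compound == cp]
        rows[[length(rows) + 1L]] <- data.frame(
          beneficiary = sc$beneficiary_id, donor = sc$donor_id,
          kegg_map = m, kegg_compound = cp,
          internal_id = paste(internal, collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(beneficiary = character(), donor = character(),
                      kegg_map = character(), kegg_compound = character(),
                      internal_id = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
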