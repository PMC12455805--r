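#' @title Pairwise pathway complementarity
#'
#' @description A donor genome *complements* a beneficiary genome for a KEGG
#' module when it carries exactly the KOs the beneficiary is missing to
#' complete one of the module's alternatives. Modules already complete in the
#' beneficiary yield nothing; both directed roles of a genome pair are
#' obtained by scanning the pair in both orders.
#'
#' @name pathway_complementarity
NULL

#' Construct a genome annotation
#'
#' @param genome_id unique genome identifier.
#' @param kos character vector of KO identifiers (may be empty).
#' @param taxon_label optional taxonomy string.
#' @param ncbi_like_id optional external taxon identifier.
#' @return object of class `genome_annotation`.
#' @export
genome_annotation <- function(genome_id, kos, taxon_label = NULL,
                              ncbi_like_id = NULL) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L, nzchar(genome_id))
  kos <- sort(unique(as.character(kos)))
  bad <- kos[!grepl(KO_PATTERN, kos)]
  if (length(bad))
    stop("invalid KO identifier(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  structure(list(genome_id = genome_id, kos = kos,
                 taxon_label = taxon_label, ncbi_like_id = ncbi_like_id),
            class = "genome_annotation")
}

#' Read genome-to-KO annotations from TSV
#'
#' Expects rows `genome_id<TAB>KO`, one pair per row, no header.
#'
#' @param path file path.
#' @return named list of `genome_annotation` objects.
#' @export
read_ko_table <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("genome KO table needs two tab-separated columns", call. = FALSE)
  sp <- split(df[[2L]], df[[1L]])
  out <- lapply(names(sp), function(g) genome_annotation(g, sp[[g]]))
  names(out) <- names(sp)
  out
}

#' Find donor KO sets that complete a beneficiary's incomplete modules
#'
#' For every module not already complete in the beneficiary, and for each of
#' its alternatives, the missing KOs are `setdiff(alternative, beneficiary)`;
#' a complement is emitted iff that set is nonempty, fully contained in the
#' donor's KOs, and no larger than `max_missing`.
#'
#' @param beneficiary,donor `genome_annotation` objects.
#' @param modules named list where each element is a list with components
#'   `def` (a `module_definition`) and `alternatives` (from
#'   [enumerate_alternatives()]).
#' @param max_missing maximum complement size (default unbounded).
#' @return data frame with one row per (module, alternative) complement:
#'   columns `beneficiary`, `donor`, `module_id`, `module_name`, `category`,
#'   `alt_index`, and list-columns `missing_kos`, `completed_alternative`,
#'   plus `map_url` (colored KEGG map link).
#' @export
find_pathway_complements <- function(beneficiary, donor, modules,
                                     max_missing = Inf) {
  stopifnot(inherits(beneficiary, "genome_annotation"),
            inherits(donor, "genome_annotation"))
  rows <- list()
  for (m in modules) {
    def <- m$def
    alts <- m$alternatives
    if (length(alts) == 0L) next
    if (module_is_complete(beneficiary$kos, alts)) next
    for (i in seq_along(alts)) {
      missing <- setdiff(alts[[i]]$ko_set, beneficiary$kos)
      if (length(missing) == 0L || length(missing) > max_missing) next
      if (!all(missing %in% donor$kos)) next
      rows[[length(rows) + 1L]] <- list(
        beneficiary = beneficiary$genome_id,
        donor = donor$genome_id,
        module_id = def$module_id,
        module_name = def$name %||% NA_character_,
        category = def$category %||% NA_character_,
        alt_index = i,
        missing_kos = list(missing),
        completed_alternative = list(alts[[i]]$ko_set),
        map_url = kegg_map_color_url(
          def$module_id,
          beneficiary_kos = setdiff(alts[[i]]$ko_set, missing),
          donor_kos = missing))
    }
  }
  empty <- data.frame(beneficiary = character(), donor = character(),
                      module_id = character(), module_name = character(),
                      category = character(), alt_index = integer(),
                      map_url = character(), stringsAsFactors = FALSE)
  empty$missing_kos <- list()
  empty$completed_alternative <- list()
  if (length(rows) == 0L) return(empty)
  out <- data.frame(
    beneficiary = vapply(rows, `[[`, character(1), "beneficiary"),
    donor = vapply(rows, `[[`, character(1), "donor"),
    module_id = vapply(rows, `[[`, character(1), "module_id"),
    module_name = vapply(rows, `[[`, character(1), "module_name"),
    category = vapply(rows, `[[`, character(1), "category"),
    alt_index = vapply(rows, `[[`, integer(1), "alt_index"),
    map_url = vapply(rows, `[[`, character(1), "map_url"),
    stringsAsFactors = FALSE)
  out$missing_kos <- lapply(rows, function(r) r$missing_kos[[1L]])
  out$completed_alternative <- lapply(rows, function(r) r$completed_alternative[[1L]])
  out
}

#' Drop complements whose missing set strictly contains another's
#'
#' Keeps, per (beneficiary, donor, module), only complements whose missing
#' KO set is not a strict superset of another reported missing set.
#'
#' @param complements data frame from [find_pathway_complements()].
#' @return filtered data frame.
#' @export
minimal_complements <- function(complements) {
  if (nrow(complements) == 0L) return(complements)
  grp <- paste(complements$beneficiary, complements$donor,
               complements$module_id, sep = "\r")
  keep <- logical(nrow(complements))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    sets <- complements$missing_kos[idx]
    for (a in seq_along(idx)) {
      is_strict_superset <- any(vapply(seq_along(idx), function(b) {
        b != a && length(sets[[b]]) < length(sets[[a]]) &&
          all(sets[[b]] %in% sets[[a]])
      }, logical(1)))
      keep[idx[a]] <- !is_strict_superset
    }
  }
  complements[keep, , drop = FALSE]
}

#' Deduplicate complements on (module, missing KO set)
#'
#' Collapses complements that share a module and an identical missing KO set
#' (the same complement may arise from several alternatives or genome
#' pairs); the number of source rows is kept as multiplicity metadata.
#'
#' @param complements data frame from [find_pathway_complements()].
#' @return data frame with `module_id`, list-column `missing_kos`, and
#'   `n_sources` (how many input rows collapsed into the pair).
#' @export
unique_complements <- function(complements) {
  if (nrow(complements) == 0L) {
    out <- data.frame(module_id = character(), n_sources = integer(),
                      stringsAsFactors = FALSE)
    out$missing_kos <- list()
    return(out)
  }
  key <- paste(complements$module_id,
               vapply(complements$missing_kos, set_key, character(1)),
               sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(module_id = complements$module_id[first],
                    n_sources = as.integer(table(key)[key[first]]),
                    stringsAsFactors = FALSE)
  out$missing_kos <- complements$missing_kos[first]
  rownames(out) <- NULL
  out
}

# Hex color tokens used on colored KEGG maps: the beneficiary's own KOs in
# red, the donor-contributed KOs in blue-green.
BENEFICIARY_COLOR <- "%23ff0000"
DONOR_COLOR <- "%2300cccc"

#' Build a colored KEGG pathway-map URL for a complement
#'
#' Assembles a `show_pathway` URL in which each KO carries a color token:
#' KOs contributed by the donor in blue-green, KOs already present in the
#' beneficiary in red. KOs are sorted, so the URL is deterministic; a KO
#' listed on both sides is colored as the beneficiary's.
#'
#' @param map_or_module_id KEGG map or module identifier.
#' @param beneficiary_kos,donor_kos KO character vectors.
#' @return URL string.
#' @export
kegg_map_color_url <- function(map_or_module_id, beneficiary_kos, donor_kos) {
  stopifnot(is.character(map_or_module_id), length(map_or_module_id) == 1L)
  donor_kos <- setdiff(donor_kos, beneficiary_kos)
  kos <- sort(unique(c(beneficiary_kos, donor_kos)))
  tokens <- vapply(kos, function(k) {
    col <- if (k %in% beneficiary_kos) BENEFICIARY_COLOR else DONOR_COLOR
    paste0(k, "%09", col)
  }, character(1))
  paste0("https://www.kegg.jp/kegg-bin/show_pathway?", map_or_module_id,
         if (length(tokens)) paste0("/", paste(tokens, collapse = "/")) else "")
}

#' Write a complements table to TSV
#'
#' Flattens the list-columns with semicolon joins, giving the six-column
#' layout `beneficiary, donor, module, category, missing_kos,
#' completed_alternative, map_url`.
#'
#' @param complements data frame from [find_pathway_complements()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_complements_tsv <- function(complements, path) {
  flat <- data.frame(
    beneficiary = complements$beneficiary,
    donor = complements$donor,
    module = complements$module_id,
    category = complements$category,
    missing_kos = vapply(complements$missing_kos, join_semi, character(1)),
    completed_alternative = vapply(complements$completed_alternative,
                                   join_semi, character(1)),
    map_url = complements$map_url,
    stringsAsFactors = FALSE)
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
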