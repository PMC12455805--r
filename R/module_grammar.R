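#' @title KEGG MODULE definition grammar
#'
#' @description A KEGG module is a functional unit of enzymes described by a
#' logical DEFINITION expression over KEGG ORTHOLOGY (KO) terms. The grammar
#' couples KOs in four ways: consecutive steps of the pathway (whitespace,
#' logical AND), members of a molecular complex (`+`, AND), alternative ways
#' to perform the same step (`,`, OR), and optional complex components (`-`).
#' The token `--` marks a step whose enzymes are not defined.
#'
#' An *alternative* of a module is a KO set that performs every step in
#' exactly one way; a genome has a *complete* module if it carries all KOs of
#' at least one alternative.
#'
#' @name module_grammar
NULL

KO_PATTERN <- "^K[0-9]{5}$"
GAP_TOKEN <- "--"

node_ko <- function(ko) list(kind = "ko", ko = ko)
node_gap <- function() list(kind = "gap")
node_or <- function(options) list(kind = "or", options = options)
node_and <- function(parts, joiner) list(kind = "and", parts = parts, joiner = joiner)
node_opt <- function(child) list(kind = "opt", child = child)

check_balanced <- function(raw) {
  chars <- strsplit(raw, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("unbalanced ')' at position %d in definition '%s'", i, raw),
             call. = FALSE)
    }
  }
  if (depth > 0L)
    stop(sprintf("unbalanced '(': %d unclosed in definition '%s'", depth, raw),
         call. = FALSE)
  invisible(TRUE)
}

# OR (comma) has the lowest precedence inside an expression, then whitespace
# (AND across sub-steps), then +/- (complex membership). At the top level of a
# definition, whitespace-separated terms are the module's steps; a step
# containing internal whitespace is always parenthesized in KEGG flat files,
# so the two readings never collide.
parse_expr <- function(s) {
  s <- trimws(s)
  if (!nzchar(s)) stop("empty (sub)expression in module definition", call. = FALSE)
  sp <- split_top(s, ",")
  if (length(sp$pieces) > 1L)
    return(node_or(lapply(sp$pieces, parse_and_space)))
  parse_and_space(s)
}

parse_and_space <- function(s) {
  s <- trimws(s)
  pieces <- split_top(s, " ")$pieces
  pieces <- pieces[nzchar(pieces)]
  if (length(pieces) == 0L)
    stop("empty (sub)expression in module definition", call. = FALSE)
  if (length(pieces) > 1L)
    return(node_and(lapply(pieces, parse_complex), joiner = "space"))
  parse_complex(pieces[[1L]])
}

parse_complex <- function(s) {
  s <- trimws(s)
  if (s == GAP_TOKEN) return(node_gap())
  sp <- split_top(s, c("+", "-"))
  pieces <- sp$pieces
  seps <- sp$seps
  if (length(pieces) == 1L) return(parse_unit(s))
  # A leading '-' yields an empty first piece: the first real component is
  # optional on its own.
  optional <- c(FALSE, seps == "-")
  if (!nzchar(pieces[1L])) {
    if (length(pieces) < 2L || seps[1L] != "-")
      stop(sprintf("malformed complex expression '%s'", s), call. = FALSE)
    pieces <- pieces[-1L]
    optional <- optional[-1L]
    optional[1L] <- TRUE
  }
  if (any(!nzchar(pieces)))
    stop(sprintf("malformed complex expression '%s'", s), call. = FALSE)
  parts <- lapply(seq_along(pieces), function(i) {
    u <- parse_unit(pieces[[i]])
    if (optional[i]) node_opt(u) else u
  })
  if (length(parts) == 1L) return(parts[[1L]])
  node_and(parts, joiner = "plus")
}

parse_unit <- function(s) {
  s <- trimws(s)
  if (startsWith(s, "(")) {
    # verify the opening parenthesis wraps the whole token
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    depth <- 0L
    for (i in seq_along(chars)) {
      if (chars[i] == "(") depth <- depth + 1L
      else if (chars[i] == ")") depth <- depth - 1L
      if (depth == 0L && i < length(chars))
        stop(sprintf("invalid token '%s' in module definition", s), call. = FALSE)
    }
    if (!endsWith(s, ")"))
      stop(sprintf("invalid token '%s' in module definition", s), call. = FALSE)
    return(parse_expr(substr(s, 2L, nchar(s) - 1L)))
  }
  if (s == GAP_TOKEN) return(node_gap())
  if (!grepl(KO_PATTERN, s))
    stop(sprintf("token '%s' does not match the KO (K#####) or gap (--) pattern", s),
         call. = FALSE)
  node_ko(s)
}

deparse_node <- function(node) {
  switch(node$kind,
    ko = node$ko,
    gap = GAP_TOKEN,
    opt = {
      inner <- deparse_node(node$child)
      if (node$child$kind %in% c("or", "and")) inner <- paste0("(", inner, ")")
      paste0("-", inner)
    },
    or = paste(vapply(node$options, function(o) {
      d <- deparse_node(o)
      d
    }, character(1)), collapse = ","),
    and = {
      if (node$joiner == "space") {
        paste(vapply(node$parts, function(p) {
          d <- deparse_node(p)
          if (p$kind == "or") d <- paste0("(", d, ")")
          d
        }, character(1)), collapse = " ")
      } else {
        out <- character(length(node$parts))
        for (i in seq_along(node$parts)) {
          p <- node$parts[[i]]
          if (p$kind == "opt") {
            inner <- deparse_node(p$child)
            if (p$child$kind %in% c("or", "and"))
              inner <- paste0("(", inner, ")")
            out[i] <- paste0("-", inner)
          } else {
            d <- deparse_node(p)
            if (p$kind %in% c("or", "and")) d <- paste0("(", d, ")")
            out[i] <- if (i == 1L) d else paste0("+", d)
          }
        }
        paste(out, collapse = "")
      }
    },
    stop("unknown node kind"))
}

#' Parse a KEGG MODULE definition expression
#'
#' Builds the logical tree of a module definition. Top-level
#' whitespace-separated terms become the module's steps (AND); within an
#' expression, commas separate alternative options (OR), `+` joins required
#' members of a complex (AND), a `-` prefix marks the following component
#' optional, and parenthesized sub-expressions recurse. The gap token `--`
#' denotes an undefined step. Definitions spanning several lines are joined
#' with a single space before parsing.
#'
#' @param module_id module identifier (e.g. `"M00002"`).
#' @param raw the definition string.
#' @param name optional human-readable module name.
#' @param category optional module category/class string.
#' @return an object of class `module_definition` with fields `module_id`,
#'   `raw`, `steps` (list of parsed step trees), `normalized` (the canonical
#'   re-serialized definition), `name` and `category`.
#' @examples
#' d <- parse_module_definition("MX", "(K00001,K00002) K00003+K00004")
#' length(d$steps)
#' @export
parse_module_definition <- function(module_id, raw, name = NULL, category = NULL) {
  stopifnot(is.character(module_id), length(module_id) == 1L)
  if (is.null(raw) || is.na(raw) || !nzchar(trimws(raw)))
    stop("empty module definition for ", module_id, call. = FALSE)
  raw <- gsub("\\s+", " ", trimws(raw))
  check_balanced(raw)
  step_strings <- split_top(raw, " ")$pieces
  step_strings <- step_strings[nzchar(step_strings)]
  steps <- lapply(step_strings, parse_expr)
  normalized <- paste(vapply(steps, function(s) {
    d <- deparse_node(s)
    if (length(split_top(d, " ")$pieces) > 1L) d <- paste0("(", d, ")")
    d
  }, character(1)), collapse = " ")
  structure(
    list(module_id = module_id, raw = raw, steps = steps,
         normalized = normalized, name = name, category = category),
    class = "module_definition")
}

#' @export
print.module_definition <- function(x, ...) {
  cat("<module_definition> ", x$module_id,
      if (!is.null(x$name)) paste0(" (", x$name, ")"), "\n", sep = "")
  cat("  ", length(x$steps), " step(s): ", x$normalized, "\n", sep = "")
  invisible(x)
}

# Number of distinct realizations of a subtree (before deduplication).
count_node <- function(node) {
  switch(node$kind,
    ko = 1,
    gap = 1,
    opt = 1,
    or = sum(vapply(node$options, count_node, numeric(1))),
    and = prod(vapply(node$parts, count_node, numeric(1))))
}

# Expand a subtree into its list of KO sets (deduplicated, deterministically
# ordered). Optional components and gap steps expand to the empty set.
expand_node <- function(node) {
  out <- switch(node$kind,
    ko = list(node$ko),
    gap = list(character(0)),
    opt = list(character(0)),
    or = unlist(lapply(node$options, expand_node), recursive = FALSE),
    and = Reduce(function(acc, part) {
      px <- expand_node(part)
      res <- vector("list", length(acc) * length(px))
      k <- 0L
      for (a in acc) for (p in px) {
        k <- k + 1L
        res[[k]] <- union(a, p)
      }
      res
    }, node$parts, accumulate = FALSE, init = list(character(0))))
  out <- lapply(out, function(s) sort(unique(s)))
  keys <- vapply(out, set_key, character(1))
  out <- out[!duplicated(keys)]
  out[order(vapply(out, set_key, character(1)))]
}

#' Enumerate the alternatives of a module definition
#'
#' An alternative is a KO set that realizes every step of the module in
#' exactly one way: the Cartesian product of each step's options. Within a
#' chosen option all required complex members are included and
#' optional-marked members are excluded; options left empty after the
#' optional drop still count as a valid (KO-free) choice. Duplicate KO sets
#' arising from different choices are collapsed.
#'
#' @param def a `module_definition`.
#' @param cap maximum number of alternatives to expand; exceeding it raises
#'   an error rather than exhausting memory. The default comfortably exceeds
#'   the largest known module (13,440 alternatives for glycolysis).
#' @return a list of `alternative` objects, each with `module_id`, `ko_set`
#'   (sorted KO character vector) and `step_choices` (per-step option index,
#'   provenance of the first realization of that KO set).
#' @examples
#' d <- parse_module_definition("MX", "(K00001,K00002) (K00003,K00004)")
#' length(enumerate_alternatives(d))  # 4
#' @export
enumerate_alternatives <- function(def, cap = 50000L) {
  stopifnot(inherits(def, "module_definition"), cap >= 1)
  projected <- prod(vapply(def$steps, count_node, numeric(1)))
  if (projected > cap)
    stop(sprintf("module %s projects %.0f alternatives, exceeding the cap of %d",
                 def$module_id, projected, as.integer(cap)), call. = FALSE)
  per_step <- lapply(def$steps, expand_node)
  n_opts <- vapply(per_step, length, integer(1))
  grid <- do.call(expand.grid, c(lapply(n_opts, seq_len), KEEP.OUT.ATTRS = FALSE))
  alts <- vector("list", nrow(grid))
  keys <- character(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    choice <- as.integer(grid[r, ])
    ko <- sort(unique(unlist(lapply(seq_along(per_step), function(i)
      per_step[[i]][[choice[i]]]))))
    keys[r] <- set_key(ko)
    alts[[r]] <- structure(
      list(module_id = def$module_id, ko_set = ko, step_choices = choice),
      class = "alternative")
  }
  alts <- alts[!duplicated(keys)]
  alts[order(vapply(alts, function(a) set_key(a$ko_set), character(1)))]
}

#' Alternatives of a module completed by a genome
#'
#' Returns the alternatives whose KO set is fully contained in the genome's
#' KO annotation; the module is *complete* in the genome iff the result is
#' nonempty.
#'
#' @param genome_kos character vector of KO identifiers (may be empty).
#' @param alts list of alternatives from [enumerate_alternatives()].
#' @return sub-list of `alts` completed by the genome.
#' @export
completed_alternatives <- function(genome_kos, alts) {
  Filter(function(a) all(a$ko_set %in% genome_kos), alts)
}

#' @rdname completed_alternatives
#' @return `module_is_complete()`: logical scalar.
#' @export
module_is_complete <- function(genome_kos, alts) {
  length(completed_alternatives(genome_kos, alts)) > 0L
}

#' Read module definitions from a flat TSV file
#'
#' Expects columns `module_id<TAB>definition[<TAB>name[<TAB>category]]`, one
#' module per row, without a header.
#'
#' @param path file path.
#' @return named list of `module_definition` objects.
#' @export
read_module_definitions <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          quote = "", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("module definition file needs at least two tab-separated columns",
         call. = FALSE)
  defs <- lapply(seq_len(nrow(df)), function(i) {
    parse_module_definition(
      df[i, 1L], df[i, 2L],
      name = if (ncol(df) >= 3L) df[i, 3L] else NULL,
      category = if (ncol(df) >= 4L) df[i, 4L] else NULL)
  })
  names(defs) <- df[[1L]]
  defs
}

#' Parse the DEFINITION field out of a KEGG flat-file entry
#'
#' Handles multi-line DEFINITION blocks (continuation lines are indented) by
#' joining them with a single space. Also extracts NAME and CLASS when
#' present.
#'
#' @param text character vector of flat-file lines, or a single string with
#'   embedded newlines.
#' @return list with `definition`, `name`, `category` (may be `NA`).
#' @export
parse_kegg_flat_entry <- function(text) {
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  grab <- function(field) {
    i <- grep(paste0("^", field, "\\s"), text)
    if (length(i) == 0L) return(NA_character_)
    i <- i[1L]
    vals <- sub(paste0("^", field, "\\s+"), "", text[i])
    j <- i + 1L
    while (j <= length(text) && grepl("^\\s", text[j])) {
      vals <- c(vals, trimws(text[j]))
      j <- j + 1L
    }
    paste(vals, collapse = " ")
  }
  list(definition = grab("DEFINITION"), name = grab("NAME"),
       category = grab("CLASS"))
}

#' Fetch a module definition from the KEGG REST API
#'
#' Retrieves `GET <base_url>/get/<module_id>` and parses its DEFINITION
#' field. Requires network access; all offline workflows read definitions
#' from flat files instead (see [read_module_definitions()]).
#'
#' @param module_id KEGG module identifier, e.g. `"M00002"`.
#' @param base_url API root.
#' @return a `module_definition`.
#' @export
kegg_fetch_module_definition <- function(module_id,
                                         base_url = "https://rest.kegg.jp") {
  url <- paste0(base_url, "/get/", module_id)
  lines <- readLines(url, warn = FALSE)
  entry <- parse_kegg_flat_entry(lines)
  if (is.na(entry$definition))
    stop("no DEFINITION field in KEGG entry for ", module_id, call. = FALSE)
  parse_module_definition(module_id, entry$definition,
                          name = entry$name, category = entry$category)
}
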