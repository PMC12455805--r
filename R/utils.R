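#' Evaluate code with a temporary, explicitly seeded RNG stream
#'
#' All fixture generators route their randomness through this helper so that a
#' given seed yields byte-identical output regardless of the caller's RNG
#' state, which is saved and restored. The Mersenne-Twister generator with
#' "Rejection" sampling is pinned so results are stable across platforms.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", sample.kind = "Rejection")
  force(code)
}

# Split a string on single-character delimiters occurring at parenthesis depth
# zero. Returns the pieces and the delimiter preceding pieces 2..n.
split_top <- function(s, delims) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  depth <- 0L
  pieces <- character()
  seps <- character()
  buf <- character()
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") depth <- depth - 1L
    if (depth == 0L && ch %in% delims && ch != ")") {
      pieces <- c(pieces, paste(buf, collapse = ""))
      seps <- c(seps, ch)
      buf <- character()
    } else {
      buf <- c(buf, ch)
    }
  }
  list(pieces = c(pieces, paste(buf, collapse = "")), seps = seps)
}

# Canonical key for a KO set (used to deduplicate alternatives/complements).
set_key <- function(x) paste(sort(unique(x)), collapse = "|")

# Collapse a character vector with ";" for flat TSV export.
join_semi <- function(x) paste(sort(unique(x)), collapse = ";")

split_semi <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, ";", fixed = TRUE)[[1L]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
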