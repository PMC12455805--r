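# Independent brute-force oracles used to cross-check the implementation.
# They deliberately take the naive route (full enumeration, quadratic scans,
# textbook dynamic programming) so they share no code path with the package.

# All realizations of a parsed definition tree, enumerated without any
# set-union or per-level deduplication: concatenate everything, deduplicate
# sorted sets only at the very end.
oracle_realizations <- function(node) {
  switch(node$kind,
    ko = list(node$ko),
    gap = list(character(0)),
    opt = list(character(0)),
    or = unlist(lapply(node$options, oracle_realizations), recursive = FALSE),
    and = Reduce(function(acc, part) {
      px <- oracle_realizations(part)
      out <- list()
      for (a in acc) for (p in px) out[[length(out) + 1L]] <- c(a, p)
      out
    }, node$parts, init = list(character(0))))
}

oracle_alternative_sets <- function(def) {
  real <- Reduce(function(acc, step) {
    px <- oracle_realizations(step)
    out <- list()
    for (a in acc) for (p in px) out[[length(out) + 1L]] <- c(a, p)
    out
  }, def$steps, init = list(character(0)))
  sets <- lapply(real, function(x) sort(unique(x)))
  keys <- vapply(sets, paste, character(1), collapse = "|")
  sets[!duplicated(keys)]
}

sorted_keys <- function(sets) {
  sort(vapply(sets, function(s) paste(sort(s), collapse = "|"), character(1)))
}

# Quadratic mutual-reachability partition of a directed edge list.
oracle_scc_partition <- function(nodes, from, to) {
  reach <- matrix(FALSE, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes))
  diag(reach) <- TRUE
  for (k in seq_along(from)) reach[from[k], to[k]] <- TRUE
  repeat {
    nxt <- reach | (reach %*% reach > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  mutual <- reach & t(reach)
  comp <- integer(length(nodes))
  names(comp) <- nodes
  cid <- 0L
  for (n in nodes) {
    if (comp[n] == 0L) {
      cid <- cid + 1L
      comp[mutual[n, ]] <- cid
    }
  }
  comp
}

# Textbook Levenshtein distance by dynamic programming.
oracle_levenshtein <- function(a, b) {
  a <- strsplit(tolower(a), "")[[1L]]
  b <- strsplit(tolower(b), "")[[1L]]
  d <- matrix(0L, length(a) + 1L, length(b) + 1L)
  d[, 1L] <- 0:length(a)
  d[1L, ] <- 0:length(b)
  for (i in seq_along(a)) for (j in seq_along(b)) {
    d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                             d[i, j] + (a[i] != b[j]))
  }
  d[length(a) + 1L, length(b) + 1L]
}

# Exhaustive hypergeometric tail: sum C(K,x) C(N-K, n-x) / C(N, n).
oracle_hyper_upper <- function(k, K, N, n) {
  xs <- k:min(n, K)
  xs <- xs[xs >= max(0, n + K - N)]
  if (length(xs) == 0L) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

oracle_hyper_lower <- function(k, K, N, n) {
  lo <- max(0, n + K - N)
  if (k < lo) return(0)
  xs <- lo:min(k, n, K)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Naive per-(module, alternative) complement scan using only set algebra.
oracle_complements <- function(beneficiary, donor, modules, max_missing = Inf) {
  out <- list()
  for (m in modules) {
    complete <- any(vapply(m$alternatives, function(a)
      all(a$ko_set %in% beneficiary$kos), logical(1)))
    if (complete) next
    for (i in seq_along(m$alternatives)) {
      missing <- setdiff(m$alternatives[[i]]$ko_set, beneficiary$kos)
      if (length(missing) >= 1L && length(missing) <= max_missing &&
          all(missing %in% donor$kos)) {
        out[[length(out) + 1L]] <- list(module_id = m$def$module_id,
                                        alt_index = i,
                                        missing = sort(missing))
      }
    }
  }
  out
}

fixture_path <- function(...) {
  system.file("extdata", ..., package = "crossnet", mustWork = TRUE)
}
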