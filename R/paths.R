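#' Enumerate simple paths of a pathway graph
#'
#' A simple path is a chain of reactions of length at most `N` connecting an
#' ordered pair of species, with three properties: the chain ids are
#' pairwise distinct (non-overlapping), the chain is of minimal length for
#' its (start, end) pair, and a path may start and end at the same species
#' (a cycle path). All distinct minimal chains for a pair are returned, so a
#' pair can own several paths. Path length is counted in reactions, not in
#' species hops; intermediate species may repeat as long as reaction ids do
#' not. Interior species are recorded because the matching stage needs them.
#'
#' @param graph A `pathway_graph`.
#' @param N Maximum chain length (positive integer).
#' @return A list of `simple_path` records: `start`, `end`, `chain`
#'   (character vector of reaction ids), `reversed` (logical vector, one
#'   flag per step), `interior` (character vector, length `length(chain)-1`).
#' @export
enumerate_simple_paths <- function(graph, N) {
  stopifnot(is.numeric(N), length(N) == 1, N >= 1)
  N <- as.integer(N)
  edges <- graph$edges
  if (!nrow(edges)) return(list())

  # outgoing adjacency, indexed by source species
  adj <- split(seq_len(nrow(edges)), edges$from)

  paths <- list()
  for (src in sort(graph$vertices)) {
    # best (minimal) chain length found so far per target species
    best <- integer(0)
    # frontier: partial walks with pairwise-distinct reaction ids
    frontier <- list(list(at = src, chain = character(0),
                          reversed = logical(0), visited = character(0)))
    for (depth in seq_len(N)) {
      nxt <- list()
      for (w in frontier) {
        out <- adj[[w$at]]
        if (is.null(out)) next
        for (e in out) {
          rid <- edges$reaction[e]
          if (rid %in% w$chain) next
          to <- edges$to[e]
          chain <- c(w$chain, rid)
          reversed <- c(w$reversed, edges$reversed[e])
          interior <- w$visited
          b <- best[to]
          if (is.na(b) || b == depth) {
            if (is.na(b)) best[to] <- depth
            paths[[length(paths) + 1L]] <- structure(
              list(start = src, end = to, chain = chain,
                   reversed = reversed, interior = interior),
              class = "simple_path"
            )
          }
          if (depth < N) {
            nxt[[length(nxt) + 1L]] <- list(
              at = to, chain = chain, reversed = reversed,
              visited = c(w$visited, to)
            )
          }
        }
      }
      if (!length(nxt)) break
      frontier <- nxt
    }
  }

  dedup_paths(paths)
}

# Distinct walks can realise the same (start, end, chain, interior,
# orientation) record; keep one representative of each.
dedup_paths <- function(paths) {
  if (!length(paths)) return(list())
  keys <- vapply(paths, path_key, "")
  paths[!duplicated(keys)]
}

path_key <- function(p) {
  paste(p$start, p$end,
        paste(p$chain, collapse = ","),
        paste(as.integer(p$reversed), collapse = ""),
        paste(p$interior, collapse = ","),
        sep = "|")
}

#' @export
print.simple_path <- function(x, ...) {
  cat(x$start, " ..[", paste(x$chain, collapse = ","), "].. ", x$end, "\n",
      sep = "")
  invisible(x)
}
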