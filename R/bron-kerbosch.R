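#' Solver limits
#'
#' Bounds on the maximal-clique enumeration: a maximum number of enumerated
#' cliques and/or a wall-clock budget in seconds. `Inf` means unbounded.
#' In the staged solver the time budget is split equally across the stages.
#'
#' @param max_solutions Maximum number of maximal cliques to enumerate
#'   (per stage), or `Inf`.
#' @param max_time Wall-clock budget in seconds, or `Inf`.
#' @return An object of class `solver_limits`.
#' @export
solver_limits <- function(max_solutions = Inf, max_time = Inf) {
  stopifnot(max_solutions >= 0, max_time >= 0)
  structure(list(max_solutions = max_solutions, max_time = max_time),
            class = "solver_limits")
}

#' Enumerate maximal cliques with pivoting Bron-Kerbosch
#'
#' The classical Bron-Kerbosch algorithm in its pivoting variant: at each
#' recursion the pivot is the vertex of P union X with the most neighbours
#' in P, and only non-neighbours of the pivot are branched on, in fixed
#' index order for determinism. Without limits the enumeration is exact;
#' with limits a prefix of it is returned (every returned clique is still
#' maximal) and truncation is flagged.
#'
#' @param graph A `compatibility_graph`, or a logical adjacency matrix.
#' @param limits A [solver_limits()].
#' @return A list of integer vertex vectors (sorted within each clique),
#'   with attribute `truncated` set to `TRUE` when a bound was hit.
#' @export
bron_kerbosch_v2 <- function(graph, limits = solver_limits()) {
  adj <- if (inherits(graph, "compatibility_graph")) graph$adj else graph
  n <- nrow(adj)
  cliques <- list()
  truncated <- FALSE
  if (n == 0) return(structure(cliques, truncated = FALSE))
  deadline <- if (is.finite(limits$max_time)) {
    Sys.time() + limits$max_time
  } else NULL

  neighbours <- lapply(seq_len(n), function(i) which(adj[i, ]))

  recurse <- function(R, P, X) {
    if (truncated) return()
    if (!is.null(deadline) && Sys.time() > deadline) {
      truncated <<- TRUE
      return()
    }
    if (!length(P) && !length(X)) {
      cliques[[length(cliques) + 1L]] <<- sort(R)
      if (length(cliques) >= limits$max_solutions) truncated <<- TRUE
      return()
    }
    # Tomita pivot: maximise |P intersect N(u)|
    cand_pool <- c(P, X)
    gains <- vapply(cand_pool, function(u) {
      length(intersect(P, neighbours[[u]]))
    }, integer(1))
    pivot <- cand_pool[which.max(gains)]
    for (v in setdiff(P, neighbours[[pivot]])) {
      if (truncated) return()
      Nv <- neighbours[[v]]
      recurse(c(R, v), intersect(P, Nv), intersect(X, Nv))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }

  recurse(integer(0), seq_len(n), integer(0))
  structure(cliques, truncated = truncated)
}
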