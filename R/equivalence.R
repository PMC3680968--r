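#' Construct an equivalence specification
#'
#' Holds the user-supplied lists of allowed and forbidden matches between
#' species of the two documents and between reaction chains. By default two
#' species are equivalent when they share the same name attribute; these
#' lists extend (allow) or restrict (forbid) that default.
#'
#' @param allowed_species,forbidden_species Two-column matrices or
#'   data.frames (doc1 id, doc2 id), or `NULL`.
#' @param allowed_chains,forbidden_chains Two-column matrices or data.frames
#'   of chains written as comma-separated reaction ids (doc1 chain, doc2
#'   chain), or `NULL`.
#' @return An object of class `equivalence_spec`.
#' @export
equivalence_spec <- function(allowed_species = NULL, forbidden_species = NULL,
                             allowed_chains = NULL, forbidden_chains = NULL) {
  norm_pairs <- function(x) {
    if (is.null(x) || !length(x)) {
      return(matrix(character(0), ncol = 2,
                    dimnames = list(NULL, c("doc1", "doc2"))))
    }
    m <- as.matrix(x)
    stopifnot(ncol(m) == 2)
    dimnames(m) <- list(NULL, c("doc1", "doc2"))
    m
  }
  spec <- structure(
    list(
      allowed_species = norm_pairs(allowed_species),
      forbidden_species = norm_pairs(forbidden_species),
      allowed_chains = norm_pairs(allowed_chains),
      forbidden_chains = norm_pairs(forbidden_chains)
    ),
    class = "equivalence_spec"
  )
  overlap_sp <- intersect(pair_keys(spec$allowed_species),
                          pair_keys(spec$forbidden_species))
  overlap_ch <- intersect(pair_keys(spec$allowed_chains),
                          pair_keys(spec$forbidden_chains))
  if (length(overlap_sp) || length(overlap_ch)) {
    stop("equivalence spec lists the same pair as both allowed and ",
         "forbidden: ", c(overlap_sp, overlap_ch)[1], call. = FALSE)
  }
  spec
}

pair_keys <- function(m) {
  if (!nrow(m)) return(character(0))
  paste(m[, 1], m[, 2], sep = "\r")
}

has_pair <- function(m, a, b) {
  any(m[, 1] == a & m[, 2] == b)
}

#' Read an equivalence specification from a TSV file
#'
#' One rule per line, four whitespace-separated fields:
#' `<species|chain> <allow|forbid> <id_or_chain_doc1> <id_or_chain_doc2>`.
#' Chains are written as comma-separated reaction ids. Blank lines and lines
#' starting with `#` are ignored.
#'
#' @param path Path to the rules file.
#' @return An `equivalence_spec`.
#' @export
read_equivalence_spec <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(equivalence_spec())
  fields <- strsplit(lines, "[ \t]+")
  bad <- which(lengths(fields) != 4)
  if (length(bad)) {
    stop("malformed rule on line ", bad[1], " of ", path,
         " (expected 4 fields)", call. = FALSE)
  }
  m <- do.call(rbind, fields)
  pick <- function(kind, verb) {
    sel <- m[, 1] == kind & m[, 2] == verb
    if (!any(sel)) NULL else m[sel, 3:4, drop = FALSE]
  }
  unknown <- !(m[, 1] %in% c("species", "chain")) |
    !(m[, 2] %in% c("allow", "forbid"))
  if (any(unknown)) {
    stop("unknown rule kind/verb on line ", which(unknown)[1], " of ", path,
         call. = FALSE)
  }
  equivalence_spec(
    allowed_species = pick("species", "allow"),
    forbidden_species = pick("species", "forbid"),
    allowed_chains = pick("chain", "allow"),
    forbidden_chains = pick("chain", "forbid")
  )
}

#' Decide whether two species are equivalent
#'
#' The default rule compares the name attributes for exact (case-sensitive,
#' whitespace-trimmed) equality. A pair in `allowed_species` is equivalent
#' regardless of names; a pair in `forbidden_species` never is. Species
#' without a name can only be equivalent through `allowed_species`.
#'
#' @param s1,s2 Single-row species records (lists or one-row data.frames with
#'   `id` and `name`), `s1` from document 1 and `s2` from document 2.
#' @param spec An `equivalence_spec`.
#' @return Logical scalar.
#' @export
species_equivalent <- function(s1, s2, spec = equivalence_spec()) {
  if (has_pair(spec$forbidden_species, s1$id, s2$id)) return(FALSE)
  if (has_pair(spec$allowed_species, s1$id, s2$id)) return(TRUE)
  n1 <- s1$name
  n2 <- s2$name
  if (is.na(n1) || is.na(n2)) return(FALSE)
  trimws(n1) == trimws(n2)
}
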