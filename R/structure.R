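#' Preference structures (sets of preference states)
#'
#' A preference structure is a nonempty set of distinct preference states
#' (relations over a common universe), optionally carrying occurrence
#' probabilities that sum to 1.
#'
#' @param universe a [pair_universe()] or [two_component_design()].
#' @param states a list of [relation()]s, or a 0/1 bit matrix with one row
#'   per state (columns = canonical pairs).
#' @param probs optional numeric vector of state probabilities (nonnegative,
#'   summing to 1 within `1e-9`).
#'
#' @return An object of class `preference_structure` with fields `universe`,
#'   `bits` (k-by-m integer matrix of distinct rows) and `probs` (or NULL).
#' @export
preference_structure <- function(universe, states, probs = NULL) {
  universe <- as_universe(universe)
  if (inherits(states, "relation")) states <- list(states)
  if (is.list(states)) {
    if (length(states) == 0L) stop("a preference structure must be nonempty")
    bits <- do.call(rbind, lapply(states, function(r) {
      stopifnot(inherits(r, "relation"))
      check_same_universe(r$universe, universe)
      r$bits
    }))
  } else {
    bits <- if (is.matrix(states)) states else matrix(states, nrow = 1L)
    storage.mode(bits) <- "integer"
  }
  if (nrow(bits) == 0L) stop("a preference structure must be nonempty")
  if (ncol(bits) != universe$m || !all(bits %in% c(0L, 1L)))
    stop("state bits must be 0/1 with one column per canonical pair")
  if (anyDuplicated(apply(bits, 1L, paste, collapse = "")))
    stop("duplicate states are not allowed in a preference structure")
  if (!is.null(probs)) {
    probs <- as.numeric(probs)
    if (length(probs) != nrow(bits) || any(probs < 0) ||
        abs(sum(probs) - 1) > 1e-9)
      stop("'probs' must be nonnegative, one per state, and sum to 1")
  }
  dimnames(bits) <- NULL
  structure(list(universe = universe, bits = bits, probs = probs),
            class = "preference_structure")
}

#' @export
print.preference_structure <- function(x, ...) {
  cat("Preference structure:", nrow(x$bits), "states on", x$universe$n,
      "options", if (!is.null(x$probs)) "(with probabilities)" else "", "\n")
  invisible(x)
}

#' Number of states of a preference structure
#' @param structure a [preference_structure()].
#' @return Integer state count.
#' @export
structure_size <- function(structure) {
  stopifnot(inherits(structure, "preference_structure"))
  nrow(structure$bits)
}

#' Extract the states of a structure as relations
#' @param structure a [preference_structure()].
#' @return List of [relation()]s.
#' @export
structure_states <- function(structure) {
  stopifnot(inherits(structure, "preference_structure"))
  lapply(seq_len(nrow(structure$bits)),
         function(i) relation(structure$universe, structure$bits[i, ]))
}

#' Does a structure contain a given relation as a state?
#' @param structure a [preference_structure()].
#' @param rel a [relation()].
#' @return `TRUE` or `FALSE`.
#' @export
structure_contains <- function(structure, rel) {
  stopifnot(inherits(structure, "preference_structure"), inherits(rel, "relation"))
  check_same_universe(structure$universe, rel$universe)
  any(colSums(t(structure$bits) != rel$bits) == 0L)
}

bits_key <- function(bits) {
  if (is.matrix(bits)) apply(bits, 1L, paste, collapse = "")
  else paste(bits, collapse = "")
}

#' Write a preference structure to JSON
#'
#' The JSON carries the option list, each state as an array of ordered
#' option pairs, and the optional probabilities:
#' `{"options": [...], "states": [[["a","b"], ...], ...], "probs": [...]}`.
#'
#' @param structure a [preference_structure()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_structure_json <- function(structure, path) {
  stopifnot(inherits(structure, "preference_structure"))
  states <- lapply(structure_states(structure), function(r) {
    p <- relation_pairs(r)
    lapply(seq_len(nrow(p)), function(i) c(p[i, 1L], p[i, 2L]))
  })
  obj <- list(options = structure$universe$options, states = states)
  if (!is.null(structure$probs)) obj$probs <- structure$probs
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a preference structure from JSON
#'
#' @param path file path written by [write_structure_json()] (or following
#'   the same layout).
#' @return A [preference_structure()].
#' @export
read_structure_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  universe <- pair_universe(unlist(obj$options))
  states <- lapply(obj$states, function(s) {
    pairs <- do.call(rbind, lapply(s, function(pr) unlist(pr)[1:2]))
    relation_from_pairs(universe, pairs)
  })
  probs <- if (!is.null(obj$probs)) as.numeric(unlist(obj$probs)) else NULL
  preference_structure(universe, states, probs = probs)
}

#' Neighbor graph of a preference structure
#'
#' Undirected graph with one vertex per state and an edge between two states
#' exactly when their canonical distance is 2 (single inverted pair); the
#' structure of all six linear orders on three options, for instance, is a
#' 6-cycle. State probabilities, when present, are attached as the vertex
#' attribute `pi`; `health_count` may be supplied for two-component
#' applications (number of non-monotone stimuli resolved in favor of the
#' less severe health option).
#'
#' @param structure a [preference_structure()].
#' @param health_count optional numeric vertex attribute, one per state.
#' @return An `igraph` graph.
#' @export
structure_graph <- function(structure, health_count = NULL) {
  stopifnot(inherits(structure, "preference_structure"))
  k <- nrow(structure$bits)
  H <- hamming_matrix(structure$bits, structure$bits)
  edges <- which(upper.tri(H) & H == 1L, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = k, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = paste0("S", seq_len(k)))
  if (nrow(edges) > 0L)
    g <- igraph::add_edges(g, as.vector(t(edges)))
  if (!is.null(structure$probs))
    g <- igraph::set_vertex_attr(g, "pi", value = structure$probs)
  if (!is.null(health_count))
    g <- igraph::set_vertex_attr(g, "health_count", value = health_count)
  g
}

#' Export the neighbor graph of a structure to DOT or GraphML
#'
#' @param structure a [preference_structure()].
#' @param path output file path.
#' @param format `"dot"` or `"graphml"`.
#' @param health_count optional vertex attribute (see [structure_graph()]).
#' @return `path`, invisibly.
#' @export
export_structure_graph <- function(structure, path,
                                   format = c("dot", "graphml"),
                                   health_count = NULL) {
  format <- match.arg(format)
  g <- structure_graph(structure, health_count = health_count)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
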