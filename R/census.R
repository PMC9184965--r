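# Enumeration of decision topologies: non-isomorphic connected simple
# graphs on a small number of unlabelled nodes.

edge_pairs <- function(n) {
  if (n < 2L) return(matrix(integer(0), 0L, 2L))
  t(utils::combn(n, 2L))
}

edges_connected <- function(n, E) {
  if (n == 1L) return(TRUE)
  if (!nrow(E)) return(FALSE)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(E))) {
      ci <- comp[E[r, 1]]; cj <- comp[E[r, 2]]
      if (ci != cj) {
        comp[comp == max(ci, cj)] <- min(ci, cj)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  all(comp == 1L)
}

canonical_key <- function(n, E) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(E)) g <- igraph::add_edges(g, t(E))
  p <- igraph::canonical_permutation(g)$labeling
  E2 <- cbind(p[E[, 1]], p[E[, 2]])
  if (!nrow(E2)) return(paste0("n", n))
  E2 <- t(apply(E2, 1L, sort))
  E2 <- E2[order(E2[, 1], E2[, 2]), , drop = FALSE]
  paste(paste(E2[, 1], E2[, 2], sep = "-"), collapse = ",")
}

# All simple graphs (connected or not) on n unlabelled nodes, as edge
# matrices. Direct edge-subset enumeration for n <= 5; for larger n each
# graph is grown by attaching a new vertex to every graph on n-1 nodes in
# every possible way (every n-node graph arises this way), followed by
# canonical-form deduplication.
all_graphs_unlabelled <- function(n) {
  if (n == 1L) return(list(matrix(integer(0), 0L, 2L)))
  if (n <= 5L) {
    EP <- edge_pairs(n)
    ne <- nrow(EP)
    seen <- new.env(hash = TRUE)
    out <- list()
    for (code in 0:(2^ne - 1L)) {
      sel <- bitwAnd(bitwShiftR(code, 0:(ne - 1L)), 1L) == 1L
      E <- EP[sel, , drop = FALSE]
      key <- canonical_key(n, E)
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <- E
      }
    }
    return(out)
  }
  base <- all_graphs_unlabelled(n - 1L)
  seen <- new.env(hash = TRUE)
  out <- list()
  for (B in base) {
    for (code in 0:(2^(n - 1L) - 1L)) {
      nbrs <- which(bitwAnd(bitwShiftR(code, 0:(n - 2L)), 1L) == 1L)
      E <- rbind(B, cbind(nbrs, rep(n, length(nbrs))))
      colnames(E) <- NULL
      key <- canonical_key(n, E)
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <- E
      }
    }
  }
  out
}

# Human-readable names for small connected graphs, from the degree
# sequence (unique within n <= 4).
small_graph_label <- function(n, E) {
  if (n == 1L) return("singleton")
  deg <- tabulate(c(E), nbins = n)
  key <- paste(sort(deg), collapse = "")
  labels <- c("11" = "edge",
              "112" = "path", "222" = "triangle",
              "1122" = "path", "1113" = "star", "1223" = "paw",
              "2222" = "cycle", "2233" = "diamond", "3333" = "complete")
  if (key %in% names(labels)) unname(labels[key]) else key
}

#' Enumerate all decision topologies on n attractors
#'
#' A decision topology is a connected simple graph whose nodes are
#' attractors and whose edges are (deduplicated) index-1 saddle
#' connections. This enumerates all non-isomorphic such graphs on `n`
#' unlabelled nodes by exhaustive edge-subset generation with
#' canonical-form deduplication. For systems with four attractors there
#' are six possible arrangements.
#'
#' @param n number of attractors (1 to 7)
#' @return object of class `topology_census`: list with `n_attractors`,
#'   `graphs` (list of edge matrices), `keys` (canonical codes), `labels`
#'   (human-readable names where n <= 4)
#' @export
#' @examples
#' length(enumerate_topologies(4)$graphs)  # 6
enumerate_topologies <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1L) {
    stop("n must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  if (n > 7L) {
    stop("census is limited to at most 7 attractors", call. = FALSE)
  }
  graphs <- Filter(function(E) edges_connected(n, E),
                   all_graphs_unlabelled(n))
  # order by edge count, then canonical key, for a stable census
  keys <- vapply(graphs, function(E) canonical_key(n, E), character(1))
  o <- order(vapply(graphs, nrow, integer(1)), keys)
  graphs <- graphs[o]; keys <- keys[o]
  labels <- if (n <= 4L) {
    vapply(graphs, function(E) small_graph_label(n, E), character(1))
  } else keys
  structure(list(n_attractors = n, graphs = graphs, keys = keys,
                 labels = labels),
            class = "topology_census")
}

#' @export
print.topology_census <- function(x, ...) {
  cat(sprintf("<topology_census: %d graph(s) on %d attractor(s)>\n",
              length(x$graphs), x$n_attractors))
  for (i in seq_along(x$graphs)) {
    cat(sprintf("  %d: %s (%d edges)\n", i, x$labels[i], nrow(x$graphs[[i]])))
  }
  invisible(x)
}

#' Match a decision graph against a census
#'
#' Tests the (connected) decision graph for isomorphism against every
#' census entry; by completeness of the census exactly one entry matches.
#'
#' @param graph a `decision_graph`, an igraph object, or an edge matrix
#' @param census a `topology_census` with matching node count
#' @return list with `index`, `key`, `label`; index `NA` with an
#'   explanatory `reason` for disconnected graphs
#' @export
match_topology <- function(graph, census) {
  ig <- if (inherits(graph, "decision_graph")) {
    dg_as_igraph(graph)
  } else if (igraph::is_igraph(graph)) {
    graph
  } else {
    g <- igraph::make_empty_graph(census$n_attractors, directed = FALSE)
    if (nrow(graph)) g <- igraph::add_edges(g, t(graph))
    g
  }
  n <- igraph::vcount(ig)
  if (n != census$n_attractors) {
    stop(sprintf("graph has %d nodes but census is for %d", n,
                 census$n_attractors), call. = FALSE)
  }
  if (!igraph::is_connected(ig)) {
    return(list(index = NA_integer_, key = NA_character_,
                label = NA_character_,
                reason = "graph is disconnected; no census entry matches"))
  }
  for (i in seq_along(census$graphs)) {
    E <- census$graphs[[i]]
    h <- igraph::make_empty_graph(n, directed = FALSE)
    if (nrow(E)) h <- igraph::add_edges(h, t(E))
    if (igraph::isomorphic(ig, h)) {
      return(list(index = i, key = census$keys[i],
                  label = census$labels[i]))
    }
  }
  stop("no census entry matched a connected graph; census incomplete?",
       call. = FALSE)
}

#' Export a census as JSON edge lists
#' @param census a `topology_census`
#' @param path output file
#' @export
write_census <- function(census, path) {
  obj <- list(n_attractors = census$n_attractors,
              graphs = lapply(census$graphs, function(E) {
                if (!nrow(E)) list()
                else unname(apply(E, 1, function(r) as.list(as.integer(r))))
              }),
              labels = census$labels)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
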