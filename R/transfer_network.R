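# Chromophore transfer network: nodes are chromophores, edges are
# distance-gated pairs weighted by the rate proxy kappa^2 / r^6, and sinks are
# the terminal emitters. Candidate pathways are ranked by the product of edge
# weights along simple paths (additive on -log weight), a declared
# formalisation of qualitative hop sequences under independent sequential
# transfers; it is not a kinetic model.

#' Build a transfer graph from a pair table
#'
#' One node per chromophore appearing in the pairs or the sink list, one
#' undirected edge per pair. Sinks are recorded even when isolated. Duplicate
#' edges (same unordered ID pair) are an error: upstream must deduplicate.
#'
#' @param pairs Pair table from [all_pairs()] (already cutoff-gated).
#' @param sinks Character vector of rendered chromophore IDs designated as
#'   terminal emitters (see [find_terminal_emitters()]).
#' @return A `transfer_graph`: list with `nodes` (data.frame `id`, `cylinder`,
#'   `sink`), `edges` (the pair table) and `sinks`.
#' @export
build_graph <- function(pairs, sinks = character()) {
  if (is.null(pairs)) pairs <- pair_table_skeleton()
  if (nrow(pairs) > 0L) {
    key <- ifelse(pairs$donor_id <= pairs$acceptor_id,
                  paste(pairs$donor_id, pairs$acceptor_id, sep = "\r"),
                  paste(pairs$acceptor_id, pairs$donor_id, sep = "\r"))
    if (anyDuplicated(key))
      stop("duplicate edge(s): ",
           paste(gsub("\r", " -- ", key[duplicated(key)]), collapse = "; "))
    if (any(pairs$weight <= 0)) stop("all edge weights must be > 0")
  }
  ids <- c(pairs$donor_id, pairs$acceptor_id)
  cyl <- c(pairs$donor_cylinder, pairs$acceptor_cylinder)
  first <- !duplicated(ids)
  nodes <- data.frame(id = ids[first], cylinder = cyl[first],
                      stringsAsFactors = FALSE)
  extra <- setdiff(sinks, nodes$id)
  if (length(extra))
    nodes <- rbind(nodes, data.frame(id = extra, cylinder = NA_character_,
                                     stringsAsFactors = FALSE))
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  nodes$sink <- nodes$id %in% sinks
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = pairs, sinks = sinks),
            class = "transfer_graph")
}

#' @export
print.transfer_graph <- function(x, ...) {
  cat(sprintf("<transfer_graph> %d nodes, %d edges, %d sink(s)\n",
              nrow(x$nodes), nrow(x$edges), length(x$sinks)))
  invisible(x)
}

#' Inter-cylinder bridging pairs
#'
#' Edges whose endpoints lie in different cylinders — the candidate conduits
#' for energy transfer between core cylinders — sorted by ascending distance,
#' ties by descending weight.
#'
#' @param graph A `transfer_graph` whose nodes carry cylinder annotations.
#' @return Subset of the edge table.
#' @export
bridging_pairs <- function(graph) {
  e <- graph$edges
  if (nrow(e) == 0L) return(e)
  ann <- c(e$donor_cylinder, e$acceptor_cylinder)
  bad <- c(e$donor_id, e$acceptor_id)[is.na(ann) | !nzchar(ann)]
  if (length(bad))
    stop("node(s) without cylinder annotation: ",
         paste(unique(bad), collapse = ", "))
  out <- e[e$donor_cylinder != e$acceptor_cylinder, , drop = FALSE]
  out <- out[order(out$r, -out$weight), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# TRUE when path a precedes path b lexicographically (element-wise; a proper
# prefix precedes its extensions).
lex_less <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Strongest candidate pathway from a source to the terminal emitters
#'
#' The simple path maximising the product of edge weights from `source` to
#' the best-reachable sink (equivalently minimising the sum of -log weights;
#' weights are normalised by their maximum first, so the search is a
#' non-negative shortest path and the optimum is automatically simple). Exact
#' cost ties are broken by the lexicographically smallest node sequence.
#'
#' @param graph A `transfer_graph` with at least one sink.
#' @param source Rendered chromophore ID present in the graph.
#' @return List with `status` (`"ok"` or `"disconnected"`), `path` (character
#'   vector of node IDs, empty when disconnected), `sink`, `product` (product
#'   of edge weights along the path) and `log10_product`.
#' @export
strongest_path <- function(graph, source) {
  nodes <- graph$nodes$id
  if (!source %in% nodes) stop("source '", source, "' not in graph")
  if (length(graph$sinks) == 0L) stop("graph has no sinks")
  e <- graph$edges

  disconnected <- list(status = "disconnected", path = character(),
                       sink = NA_character_, product = NA_real_,
                       log10_product = NA_real_)
  if (source %in% graph$sinks)
    return(list(status = "ok", path = source, sink = source,
                product = 1, log10_product = 0))
  if (nrow(e) == 0L) return(disconnected)

  # With all weights <= 1 every -log weight is non-negative, the label-setting
  # search below is exact, and its optimum is automatically a simple path.
  # Weights above 1 (possible only for synthetic inputs; the physical rate
  # proxy kappa^2/r^6 is far below 1 at chromophore distances) make -log
  # negative, so fall back to exhaustive simple-path enumeration.
  if (any(e$weight > 1))
    return(search_paths_exhaustive(graph, source))
  cost <- -log(e$weight)
  adj <- vector("list", length(nodes))
  names(adj) <- nodes
  for (k in seq_len(nrow(e))) {
    a <- e$donor_id[k]; b <- e$acceptor_id[k]
    adj[[a]] <- rbind(adj[[a]], data.frame(to = b, cost = cost[k], edge = k))
    adj[[b]] <- rbind(adj[[b]], data.frame(to = a, cost = cost[k], edge = k))
  }

  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  paths <- stats::setNames(vector("list", length(nodes)), nodes)
  done <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  dist[source] <- 0
  paths[[source]] <- source

  repeat {
    open <- which(!done & is.finite(dist))
    if (length(open) == 0L) break
    # settle the open node with minimal cost; exact ties -> lex-smallest path
    u <- names(open)[1]
    for (v in names(open)[-1]) {
      if (dist[v] < dist[u] ||
          (dist[v] == dist[u] && lex_less(paths[[v]], paths[[u]]))) u <- v
    }
    done[u] <- TRUE
    nb <- adj[[u]]
    if (!is.null(nb)) for (k in seq_len(nrow(nb))) {
      v <- nb$to[k]
      if (done[v]) next
      cand <- dist[u] + nb$cost[k]
      cand_path <- c(paths[[u]], v)
      if (cand < dist[v] ||
          (cand == dist[v] && lex_less(cand_path, paths[[v]]))) {
        dist[v] <- cand
        paths[[v]] <- cand_path
      }
    }
  }

  reach <- graph$sinks[is.finite(dist[graph$sinks])]
  if (length(reach) == 0L) return(disconnected)
  best <- reach[1]
  for (s in reach[-1]) {
    if (dist[s] < dist[best] ||
        (dist[s] == dist[best] && lex_less(paths[[s]], paths[[best]]))) best <- s
  }
  path <- paths[[best]]
  idx <- match_edges(e, path)
  prod_w <- prod(e$weight[idx])
  list(status = "ok", path = path, sink = best, product = prod_w,
       log10_product = sum(log10(e$weight[idx])))
}

# Exhaustive depth-first enumeration of simple paths from source to the best
# sink (used when edge weights exceed 1). Same objective and tie-break as the
# label-setting search.
search_paths_exhaustive <- function(graph, source) {
  e <- graph$edges
  sinks <- graph$sinks
  best <- list(cost = Inf, path = NULL)
  nbr <- function(u) {
    k <- which(e$donor_id == u | e$acceptor_id == u)
    list(v = ifelse(e$donor_id[k] == u, e$acceptor_id[k], e$donor_id[k]),
         cost = -log(e$weight[k]))
  }
  walk <- function(u, visited, cost_sum) {
    if (u %in% sinks) {
      if (cost_sum < best$cost ||
          (cost_sum == best$cost && lex_less(visited, best$path)))
        best <<- list(cost = cost_sum, path = visited)
      return(invisible())
    }
    nb <- nbr(u)
    for (k in seq_along(nb$v)) {
      v <- nb$v[k]
      if (v %in% visited) next
      walk(v, c(visited, v), cost_sum + nb$cost[k])
    }
  }
  walk(source, source, 0)
  if (is.null(best$path))
    return(list(status = "disconnected", path = character(),
                sink = NA_character_, product = NA_real_,
                log10_product = NA_real_))
  idx <- match_edges(e, best$path)
  list(status = "ok", path = best$path, sink = best$path[length(best$path)],
       product = prod(e$weight[idx]),
       log10_product = sum(log10(e$weight[idx])))
}

match_edges <- function(e, path) {
  if (length(path) < 2L) return(integer())
  key <- ifelse(e$donor_id <= e$acceptor_id,
                paste(e$donor_id, e$acceptor_id, sep = "\r"),
                paste(e$acceptor_id, e$donor_id, sep = "\r"))
  a <- path[-length(path)]; b <- path[-1]
  want <- ifelse(a <= b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  match(want, key)
}

#' Export a transfer graph as an edge-list TSV
#'
#' Columns: `node_a`, `node_b`, `r`, `kappa_sq`, `weight`.
#'
#' @param graph A `transfer_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  e <- graph$edges
  out <- data.frame(node_a = e$donor_id, node_b = e$acceptor_id,
                    r = e$r, kappa_sq = e$kappa_sq, weight = e$weight,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a transfer graph as GraphML
#'
#' Node attributes: `cylinder`, `sink`; edge attributes: `r`, `kappa_sq`,
#' `weight`. Suitable for Cytoscape/Gephi-style visualisation.
#'
#' @param graph A `transfer_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  g <- as_igraph(graph)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Convert a transfer graph to an igraph object
#' @param graph A `transfer_graph`.
#' @return An undirected `igraph` graph with node/edge attributes.
#' @export
as_igraph <- function(graph) {
  n <- graph$nodes
  v <- data.frame(name = n$id,
                  cylinder = ifelse(is.na(n$cylinder), "", n$cylinder),
                  sink = n$sink, stringsAsFactors = FALSE)
  e <- graph$edges
  ed <- data.frame(from = e$donor_id, to = e$acceptor_id,
                   r = e$r, kappa_sq = e$kappa_sq, weight = e$weight,
                   stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = v)
}
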