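#' Read a network from a SIF or two-column edge-list file
#'
#' SIF lines are `nodeA<TAB>interaction<TAB>nodeB`; edge lists are
#' `nodeA<TAB>nodeB` with an optional header. The result is an undirected
#' simple graph (self-loops and duplicate edges removed).
#'
#' @param path File path.
#' @param format `"auto"` (default; decided by column count), `"sif"`, or
#'   `"edges"`.
#' @return An `igraph` undirected graph.
#' @export
read_network <- function(path, format = c("auto", "sif", "edges")) {
  format <- match.arg(format)
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  header <- identical(tolower(first[1]), "source") ||
    identical(tolower(first[1]), "nodea")
  df <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  if (format == "auto") format <- if (ncol(df) >= 3) "sif" else "edges"
  edges <- if (format == "sif") df[, c(1, 3)] else df[, c(1, 2)]
  names(edges) <- c("from", "to")
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::simplify(g)
}

#' Write a network to a SIF file
#'
#' @param net An `igraph` graph.
#' @param path Output path.
#' @param interaction Interaction label for the middle column; default "pp".
#' @return Invisibly, `net`.
#' @export
write_sif <- function(net, path, interaction = "pp") {
  el <- igraph::as_edgelist(net)
  writeLines(paste(el[, 1], interaction, el[, 2], sep = "\t"), path)
  invisible(net)
}

#' Induce the seed-gene subnetwork
#'
#' Extracts the subgraph around a seed gene set (typically DEG-encoded
#' proteins): the induced subgraph on the seeds, optionally extended by
#' their first neighbors. Nodes left without any retained edge are
#' dropped.
#'
#' @param net An undirected `igraph` graph.
#' @param seeds Character vector of seed node names.
#' @param neighbors `1` (default) to include first neighbors, `0` for the
#'   seed-induced subgraph only.
#' @return An `igraph` subgraph.
#' @export
induce_subnetwork <- function(net, seeds, neighbors = 1) {
  stopifnot(neighbors %in% c(0, 1))
  present <- intersect(as.character(seeds), igraph::V(net)$name)
  if (length(present) == 0) stop_input("no seed gene present in the network")
  keep <- present
  if (neighbors == 1) {
    nb <- unlist(igraph::adjacent_vertices(net, present), use.names = FALSE)
    keep <- union(present, igraph::V(net)$name[unique(nb)])
  }
  sub <- igraph::induced_subgraph(net, keep)
  iso <- igraph::degree(sub) == 0
  sub <- igraph::delete_vertices(sub, which(iso))
  if (igraph::vcount(sub) == 0) {
    stop_input("seed genes induce an empty network (no retained edges)")
  }
  sub
}

#' Node degree and betweenness centrality
#'
#' Exact (Brandes) shortest-path betweenness, unnormalized and fractional
#' over tied geodesics, alongside the degree of every node.
#'
#' @param net An undirected `igraph` graph.
#' @return A `data.frame`: `node`, `degree`, `betweenness`.
#' @export
centralities <- function(net) {
  if (igraph::vcount(net) == 0) stop_input("empty network")
  data.frame(node = igraph::V(net)$name,
             degree = unname(igraph::degree(net)),
             betweenness = unname(igraph::betweenness(net, directed = FALSE,
                                                      weights = NA)),
             stringsAsFactors = FALSE)
}

# Deterministic top-m list for one metric: metric descending, node id
# ascending as tie-break.
top_m <- function(metrics, col, m) {
  ord <- order(-metrics[[col]], metrics$node)
  metrics$node[ord[seq_len(min(m, nrow(metrics)))]]
}

#' Dual-metric hub selection
#'
#' Ranks nodes independently by degree (local metric) and betweenness
#' centrality (global metric) and defines hubs as the intersection of the
#' two top lists, growing the list length from `n_hubs` until the
#' intersection holds `n_hubs` nodes. The final order is by degree rank,
#' with ties broken by betweenness rank and then node id. A rank-sum
#' variant is available.
#'
#' @param metrics Output of [centralities()].
#' @param n_hubs Number of hubs requested; default 10.
#' @param method `"intersection"` (default) or `"ranksum"`.
#' @return Character vector of hub node ids, highest-ranking first. If the
#'   intersection cannot reach `n_hubs`, all intersecting nodes are
#'   returned with a warning.
#' @export
select_hubs <- function(metrics, n_hubs = 10,
                        method = c("intersection", "ranksum")) {
  method <- match.arg(method)
  n_hubs <- check_count(n_hubs, "n_hubs")
  if (n_hubs > nrow(metrics)) stop_input("'n_hubs' exceeds the node count")
  ord_deg <- order(-metrics$degree, metrics$node)
  ord_bet <- order(-metrics$betweenness, metrics$node)
  rank_deg <- match(metrics$node, metrics$node[ord_deg])
  rank_bet <- match(metrics$node, metrics$node[ord_bet])
  if (method == "ranksum") {
    ord <- order(rank_deg + rank_bet, rank_deg, metrics$node)
    return(metrics$node[ord][seq_len(n_hubs)])
  }
  hubs <- character(0)
  for (m in seq(n_hubs, nrow(metrics))) {
    hubs <- intersect(metrics$node[ord_deg][seq_len(m)],
                      metrics$node[ord_bet][seq_len(m)])
    if (length(hubs) >= n_hubs) break
  }
  idx <- match(hubs, metrics$node)
  hubs <- hubs[order(rank_deg[idx], rank_bet[idx], hubs)]
  if (length(hubs) > n_hubs) hubs <- hubs[seq_len(n_hubs)]
  if (length(hubs) < n_hubs) {
    warning(sprintf("dual-metric intersection reaches only %d of %d requested hubs",
                    length(hubs), n_hubs))
  }
  hubs
}

# MCODE vertex weight: highest-k-core number of the node's closed
# neighborhood times the density of that highest k-core (the
# core-clustering coefficient).
mcode_vertex_weights <- function(net) {
  adj <- igraph::adjacent_vertices(net, igraph::V(net))
  vapply(seq_len(igraph::vcount(net)), function(i) {
    nb <- union(i, as.integer(adj[[i]]))
    if (length(nb) < 2) return(0)
    sub <- igraph::induced_subgraph(net, nb)
    if (igraph::ecount(sub) == 0) return(0)
    core <- igraph::coreness(sub)
    k <- max(core)
    kc_nodes <- which(core >= k)
    kc <- igraph::induced_subgraph(sub, kc_nodes)
    nn <- igraph::vcount(kc)
    dens <- if (nn > 1) 2 * igraph::ecount(kc) / (nn * (nn - 1)) else 0
    k * dens
  }, numeric(1))
}

#' MCODE-style dense-module detection
#'
#' Detects densely connected modules by core-clustering-coefficient vertex
#' weighting and greedy seed expansion: nodes are weighted by the highest
#' k-core of their closed neighborhood (core number times core density),
#' seeds are processed in descending weight, and neighbors are recruited
#' while their weight is at least `(1 - vwp)` times the seed weight. Each
#' node belongs to at most one module. Post-processing discards modules
#' without a 2-core, optionally trims singly connected members (haircut)
#' and optionally adds dense neighbors (fluff). Modules are scored by
#' subgraph density times size and returned in descending score.
#'
#' @param net An undirected simple `igraph` graph.
#' @param vwp Vertex weight percentage in `[0, 1]`; default 0.2.
#' @param haircut Iteratively remove module members with intra-module
#'   degree below 2; default `TRUE`.
#' @param fluff Add neighbors whose closed-neighborhood density exceeds
#'   `fluff_density`; fluffed nodes may appear in several modules.
#'   Default `FALSE`.
#' @param fluff_density Density threshold used when `fluff = TRUE`.
#' @param min_size Minimum module size; default 3.
#' @return An object of class `module_set`: list with `modules` (list of
#'   character vectors), `scores`, and `params`.
#' @export
mcode_modules <- function(net, vwp = 0.2, haircut = TRUE, fluff = FALSE,
                          fluff_density = 0.2, min_size = 3) {
  if (!is.numeric(vwp) || vwp < 0 || vwp > 1) stop_input("'vwp' must be in [0, 1]")
  n <- igraph::vcount(net)
  params <- list(vwp = vwp, haircut = haircut, fluff = fluff,
                 min_size = min_size)
  empty <- structure(list(modules = list(), scores = numeric(0),
                          params = params), class = "module_set")
  if (n == 0 || igraph::ecount(net) == 0) return(empty)
  if (is.null(igraph::V(net)$name)) {
    net <- igraph::set_vertex_attr(net, "name",
                                   value = as.character(seq_len(n)))
  }
  w <- mcode_vertex_weights(net)
  names_v <- igraph::V(net)$name
  adj <- lapply(igraph::adjacent_vertices(net, igraph::V(net)), as.integer)
  used <- rep(FALSE, n)
  seed_order <- order(-w, names_v)
  raw_modules <- list()
  for (s in seed_order) {
    if (used[s] || w[s] <= 0) next
    threshold <- (1 - vwp) * w[s]
    members <- s
    used[s] <- TRUE
    frontier <- s
    while (length(frontier) > 0) {
      cand <- unique(unlist(adj[frontier], use.names = FALSE))
      cand <- cand[!used[cand] & w[cand] >= threshold]
      if (length(cand) == 0) break
      used[cand] <- TRUE
      members <- c(members, cand)
      frontier <- cand
    }
    raw_modules <- c(raw_modules, list(members))
  }
  modules <- list()
  scores <- numeric(0)
  for (members in raw_modules) {
    sub <- igraph::induced_subgraph(net, members)
    core <- if (igraph::ecount(sub) > 0) igraph::coreness(sub) else 0
    if (max(core) < 2) next   # must contain a 2-core
    if (haircut) {
      repeat {
        deg <- igraph::degree(sub)
        drop <- which(deg < 2)
        if (length(drop) == 0 || igraph::vcount(sub) - length(drop) < 2) break
        sub <- igraph::delete_vertices(sub, drop)
      }
    }
    member_names <- igraph::V(sub)$name
    if (fluff) {
      idx <- match(member_names, names_v)
      nb <- unique(unlist(adj[idx], use.names = FALSE))
      nb <- setdiff(nb, idx)
      dens_ok <- vapply(nb, function(v) {
        cn <- union(v, adj[[v]])
        subv <- igraph::induced_subgraph(net, cn)
        nn <- igraph::vcount(subv)
        if (nn < 2) return(FALSE)
        2 * igraph::ecount(subv) / (nn * (nn - 1)) > fluff_density
      }, logical(1))
      member_names <- union(member_names, names_v[nb[dens_ok]])
      sub <- igraph::induced_subgraph(net, match(member_names, names_v))
    }
    size <- igraph::vcount(sub)
    if (size < min_size) next
    dens <- 2 * igraph::ecount(sub) / (size * (size - 1))
    modules <- c(modules, list(sort(igraph::V(sub)$name)))
    scores <- c(scores, dens * size)
  }
  ord <- order(-scores, vapply(modules, `[[`, "", 1L))
  structure(list(modules = modules[ord], scores = scores[ord],
                 params = params),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set: %d module(s)\n", length(x$modules)))
  for (i in seq_along(x$modules)) {
    cat(sprintf("  [%d] score %.3f, %d nodes: %s\n", i, x$scores[i],
                length(x$modules[[i]]),
                paste(utils::head(x$modules[[i]], 8), collapse = " ")))
  }
  invisible(x)
}
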