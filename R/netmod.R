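#' Normalize gene symbols for cross-species matching
#'
#' Uppercases and trims symbols so mouse protein symbols match human
#' gene-list symbols.
#'
#' @param x character vector of gene symbols.
#' @return normalized character vector.
#' @export
normalize_symbols <- function(x) toupper(trimws(as.character(x)))

#' Read a SIF or 2/3-column edge list
#'
#' SIF lines are "A <interaction> B"; plain TSV may have 2 columns
#' (A, B) or 3 (A, type, B / A, B, type — the 3-column form is read as
#' SIF order: source, type, target).
#'
#' @param path file path.
#' @return data.frame with columns `from`, `to` (symbols normalized).
#' @export
read_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[\t ]+")
  from <- character(length(parts)); to <- character(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) == 2) { from[i] <- p[1]; to[i] <- p[2] }
    else if (length(p) >= 3) { from[i] <- p[1]; to[i] <- p[3] }
    else stop("read_sif: malformed line ", i)
  }
  data.frame(from = normalize_symbols(from), to = normalize_symbols(to),
             stringsAsFactors = FALSE)
}

#' Write an edge list as SIF
#'
#' @param edges data.frame with `from`, `to` (optional `type`, default
#'   "pp" for physical protein interaction).
#' @param path file path.
#' @export
write_sif <- function(edges, path) {
  type <- if ("type" %in% names(edges)) edges$type else "pp"
  writeLines(paste(edges$from, type, edges$to, sep = "\t"), path)
}

#' Write a network as GraphML
#'
#' GraphML keeps node names and edge source tags, so merged networks can
#' be loaded into graph viewers with their provenance.
#'
#' @param g igraph.
#' @param path file path.
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
}

# coerce an edge list (data.frame) or igraph to a simple undirected igraph
.as_interaction_graph <- function(edges) {
  if (inherits(edges, "igraph")) {
    g <- igraph::as.undirected(edges, mode = "collapse")
  } else {
    stopifnot(all(c("from", "to") %in% names(edges)))
    g <- igraph::graph_from_data_frame(
      data.frame(from = normalize_symbols(edges$from),
                 to = normalize_symbols(edges$to)),
      directed = FALSE)
  }
  igraph::simplify(g)
}

#' Build a seeded disease subnetwork
#'
#' Induces the subgraph of the interaction database on a set of seed
#' proteins. Optionally expands the node set with up to `expansion_k`
#' non-seed neighbours of highest degree (degree within the database,
#' ties broken lexicographically) — a simple stand-in for association-
#' weighted neighbour retrieval, which is an external service. Every
#' edge carries source tag `"database"`.
#'
#' @param seeds character vector of seed gene symbols.
#' @param database_edges data.frame (`from`, `to`) or igraph of physical
#'   interactions.
#' @param expansion_k number of extra neighbours to add; default 0.
#' @return igraph with graph attributes `n_components`,
#'   `component_sizes`, `n_isolated_seeds`; edge attribute `source`.
#' @export
build_subnetwork <- function(seeds, database_edges, expansion_k = 0) {
  stopifnot(length(seeds) > 0)
  seeds <- unique(normalize_symbols(seeds))
  db <- .as_interaction_graph(database_edges)
  present <- intersect(seeds, igraph::V(db)$name)
  if (length(present) == 0)
    stop("build_subnetwork: no seed appears in the interaction database")
  nodes <- present
  if (expansion_k > 0) {
    nbrs <- setdiff(unique(unlist(lapply(present, function(s)
      igraph::V(db)$name[as.integer(igraph::neighbors(db, s))]))), seeds)
    if (length(nbrs) > 0) {
      deg <- igraph::degree(db, v = nbrs)
      ord <- order(-deg, names(deg))
      nodes <- c(nodes, names(deg)[ord][seq_len(min(expansion_k,
                                                    length(nbrs)))])
    }
  }
  g <- igraph::induced_subgraph(db, nodes)
  # seeds absent from the database are isolated by definition
  missing_seeds <- setdiff(seeds, igraph::V(db)$name)
  if (length(missing_seeds) > 0)
    g <- igraph::add_vertices(g, length(missing_seeds),
                              name = missing_seeds)
  igraph::E(g)$source <- "database"
  comp <- igraph::components(g)
  g <- igraph::set_graph_attr(g, "n_components", comp$no)
  g <- igraph::set_graph_attr(g, "component_sizes",
                              as.integer(comp$csize))
  g <- igraph::set_graph_attr(g, "n_isolated_seeds",
                              sum(igraph::degree(g) == 0))
  g
}

#' Merge bait interactome edges into a subnetwork
#'
#' Adds the bait node (if absent) and one edge bait-partner per partner.
#' Partners not already in the graph are added as new nodes when
#' `add_new_nodes = TRUE` (default); otherwise only partners already
#' present are linked. New edges carry source tag `"iap"`; an edge that
#' already exists from the database keeps one copy with both tags
#' (`"database;iap"`).
#'
#' @param g igraph subnetwork (edge attribute `source`).
#' @param bait bait gene symbol.
#' @param iap_partners character vector of partner symbols.
#' @param add_new_nodes add partners absent from `g`; default TRUE.
#' @return merged igraph.
#' @export
merge_interactome <- function(g, bait, iap_partners,
                              add_new_nodes = TRUE) {
  stopifnot(nzchar(bait))
  bait <- normalize_symbols(bait)
  partners <- setdiff(unique(normalize_symbols(iap_partners)), bait)
  if (is.null(igraph::E(g)$source) && igraph::ecount(g) > 0)
    igraph::E(g)$source <- "database"
  if (!(bait %in% igraph::V(g)$name))
    g <- igraph::add_vertices(g, 1, name = bait)
  if (!add_new_nodes)
    partners <- intersect(partners, igraph::V(g)$name)
  new_nodes <- setdiff(partners, igraph::V(g)$name)
  if (length(new_nodes) > 0)
    g <- igraph::add_vertices(g, length(new_nodes), name = new_nodes)
  for (p in partners) {
    eid <- suppressWarnings(igraph::get_edge_ids(g, c(bait, p)))
    if (eid > 0) {
      src <- igraph::E(g)$source[eid]
      if (!grepl("iap", src))
        igraph::E(g)$source[eid] <- paste(src, "iap", sep = ";")
    } else {
      g <- igraph::add_edges(g, c(bait, p), source = "iap")
    }
  }
  g
}

#' Degree and betweenness hub report
#'
#' Exact shortest-path betweenness centrality normalized by
#' `(n-1)(n-2)/2` (undirected), so a star centre scores 1. Unreachable
#' pairs in disconnected graphs contribute 0. Ranking ties are broken
#' lexicographically by node name.
#'
#' @param g igraph (at least 3 nodes for betweenness).
#' @return data.frame: node, degree, betweenness, rank_by_degree,
#'   rank_by_betweenness; sorted by betweenness rank.
#' @export
centrality <- function(g) {
  n <- igraph::vcount(g)
  if (n < 3) stop("centrality: need at least 3 nodes")
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  rd <- order(-deg, nodes)
  rb <- order(-btw, nodes)
  out <- data.frame(node = nodes, degree = as.integer(deg),
                    betweenness = unname(btw),
                    stringsAsFactors = FALSE)
  out$rank_by_degree <- match(out$node, nodes[rd])
  out$rank_by_betweenness <- match(out$node, nodes[rb])
  out <- out[order(out$rank_by_betweenness), ]
  rownames(out) <- NULL
  out
}

#' Hub prioritization by co-expression overlap with a subnetwork
#'
#' For each candidate locus gene, tests whether its co-expression set is
#' over-represented among the subnetwork's proteins (hypergeometric,
#' upper tail) and attaches constraint (pLI), disease flags and
#' proteome Z-ratio annotations verbatim. No composite score is
#' computed; evidence lines are reported side by side.
#'
#' @param locus_genes character vector of candidate gene symbols.
#' @param coexpr_sets a `"gene_set_collection"` keyed by locus gene.
#' @param subnetwork_proteins character vector of subnetwork members.
#' @param universe background gene universe.
#' @param annotations optional data.frame with columns `gene`, `pli`,
#'   `disease_flags`, `z_ratio`.
#' @return data.frame (one row per locus gene) sorted by p; genes with
#'   no co-expression set are flagged, not dropped.
#' @export
hub_prediction <- function(locus_genes, coexpr_sets, subnetwork_proteins,
                           universe, annotations = NULL) {
  stopifnot(inherits(coexpr_sets, "gene_set_collection"))
  locus_genes <- normalize_symbols(locus_genes)
  subnetwork_proteins <- normalize_symbols(subnetwork_proteins)
  rows <- lapply(locus_genes, function(gene) {
    cset <- coexpr_sets$sets[[gene]]
    if (is.null(cset) || length(intersect(cset, universe)) == 0)
      return(data.frame(locus_gene = gene, coexpr_set_size = NA_integer_,
                        overlap_with_subnetwork = NA_integer_,
                        fold = NA_real_, p = NA_real_,
                        flag = "missing_coexpression_set",
                        stringsAsFactors = FALSE))
    enr <- hypergeom_enrich(normalize_symbols(cset), subnetwork_proteins,
                            universe, alternative = "greater")
    data.frame(locus_gene = gene, coexpr_set_size = enr$n_query,
               overlap_with_subnetwork = enr$k, fold = enr$fold,
               p = enr$p, flag = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(annotations)) {
    idx <- match(out$locus_gene, normalize_symbols(annotations$gene))
    for (col in setdiff(names(annotations), "gene"))
      out[[col]] <- annotations[[col]][idx]
  }
  out <- out[order(out$p, out$locus_gene, na.last = TRUE), ]
  rownames(out) <- NULL
  out
}
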