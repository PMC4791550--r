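#' Build a directed gene network from learned parent sets
#'
#' One arc per (parent, child) pair. The node set includes every variable,
#' also isolated ones. Self-loops are rejected (a variable is never its own
#' parent); duplicate arcs are collapsed with a warning.
#'
#' @param parent_sets Named list (variable -> parents), a `ctbn_fit`, or an
#'   arc tibble with columns `from` and `to`.
#' @param nodes Optional character vector fixing the node universe (must
#'   cover every arc endpoint); defaults to the variables present.
#' @return A `gene_network`: list with `nodes` (tibble `gene`, `out_degree`,
#'   `in_degree`, `hierarchy_class`) and `arcs` (tibble `from`, `to`).
#' @export
build_graph <- function(parent_sets, nodes = NULL) {
  if (inherits(parent_sets, "ctbn_fit")) {
    arcs <- tidy.ctbn_fit(parent_sets)[c("from", "to")]
    nodes <- nodes %||% parent_sets$variables
  } else if (is.data.frame(parent_sets)) {
    stopifnot(all(c("from", "to") %in% names(parent_sets)))
    arcs <- tibble::as_tibble(parent_sets[c("from", "to")])
  } else {
    nodes <- nodes %||% union(names(parent_sets),
                              unlist(parent_sets, use.names = FALSE))
    arcs <- purrr::imap(parent_sets, function(ps, child) {
      tibble::tibble(from = as.character(ps), to = rep(child, length(ps)))
    }) |> dplyr::bind_rows()
  }
  if (!all(c("from", "to") %in% names(arcs))) {
    arcs <- tibble::tibble(from = character(), to = character())
  }
  nodes <- sort(unique(nodes %||% union(arcs$from, arcs$to)))
  if (!all(c(arcs$from, arcs$to) %in% nodes)) {
    rlang::abort("arcs reference genes outside the node universe")
  }
  if (any(arcs$from == arcs$to)) rlang::abort("self-loops are not allowed")
  n_before <- nrow(arcs)
  arcs <- dplyr::distinct(arcs) |> dplyr::arrange(.data$from, .data$to)
  if (nrow(arcs) < n_before) {
    warning(sprintf("collapsed %d duplicate arc(s)", n_before - nrow(arcs)))
  }
  node_tbl <- tibble::tibble(
    gene = nodes,
    out_degree = tabulate(factor(arcs$from, levels = nodes), length(nodes)),
    in_degree = tabulate(factor(arcs$to, levels = nodes), length(nodes)))
  node_tbl$hierarchy_class <- hierarchy_class(node_tbl$out_degree, node_tbl$in_degree)
  structure(list(nodes = node_tbl, arcs = arcs), class = "gene_network")
}

hierarchy_class <- function(out_deg, in_deg) {
  dplyr::case_when(
    out_deg >= 1 & in_deg == 0 ~ "root",
    out_deg == 0 & in_deg >= 1 ~ "leaf",
    out_deg >= 1 & in_deg >= 1 ~ "intermediate",
    TRUE ~ "isolated")
}

#' @export
print.gene_network <- function(x, ...) {
  cls <- table(x$nodes$hierarchy_class)
  cat("<gene_network> ", nrow(x$nodes), " nodes, ", nrow(x$arcs), " arcs (",
      paste(names(cls), unname(cls), sep = ": ", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Node table of a gene network
#'
#' @param x A `gene_network`.
#' @param ... Unused.
#' @return The node tibble with `hub_rank` added (see [rank_hubs()]).
#' @method tidy gene_network
#' @export
tidy.gene_network <- function(x, ...) {
  ranking <- rank_hubs(x)
  dplyr::left_join(x$nodes, ranking[c("gene", "hub_rank")], by = "gene")
}

#' @rdname tidy.gene_network
#' @return For `glance()`: one-row tibble of node/arc/class counts.
#' @method glance gene_network
#' @export
glance.gene_network <- function(x, ...) {
  cls <- x$nodes$hierarchy_class
  tibble::tibble(n_nodes = nrow(x$nodes), n_arcs = nrow(x$arcs),
                 n_root = sum(cls == "root"),
                 n_intermediate = sum(cls == "intermediate"),
                 n_leaf = sum(cls == "leaf"),
                 n_isolated = sum(cls == "isolated"),
                 max_out_degree = max(c(0L, x$nodes$out_degree)),
                 max_in_degree = max(c(0L, x$nodes$in_degree)))
}

#' Rank genes as regulatory hubs
#'
#' Orders nodes by descending out-degree (number of outgoing arcs, i.e.
#' number of genes the node is a learned parent of), ties broken by gene id
#' for a stable, deterministic total order. The first row is the network's
#' major hub.
#'
#' @param net A `gene_network`.
#' @return A tibble `gene`, `out_degree`, `in_degree`, `hierarchy_class`,
#'   `hub_rank` ordered by rank.
#' @export
rank_hubs <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  net$nodes |>
    dplyr::arrange(dplyr::desc(.data$out_degree), .data$gene) |>
    dplyr::mutate(hub_rank = dplyr::row_number())
}

#' Classify nodes into the regulatory hierarchy
#'
#' Roots have outgoing arcs only (putative upstream regulators),
#' leaves incoming arcs only (terminal effectors, e.g. cytokines),
#' intermediates both, isolated nodes neither.
#'
#' @param net A `gene_network`.
#' @return A tibble `gene`, `hierarchy_class`.
#' @export
classify_hierarchy <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  net$nodes[c("gene", "hierarchy_class")]
}

#' Extract a neighborhood subnetwork
#'
#' Induced subgraph on the requested genes plus all nodes within `radius`
#' arcs (either direction); node attributes are recomputed on the subgraph.
#'
#' @param net A `gene_network`.
#' @param genes Character vector of seed genes; ids missing from the network
#'   are reported with a warning, not an error.
#' @param radius Non-negative integer neighborhood radius (0 = induced
#'   subgraph on the seeds only).
#' @return A `gene_network` on the neighborhood.
#' @export
extract_subnetwork <- function(net, genes, radius = 1L) {
  stopifnot(inherits(net, "gene_network"), radius >= 0)
  missing <- setdiff(genes, net$nodes$gene)
  if (length(missing)) {
    warning(paste0("gene(s) not in network: ", paste(missing, collapse = ", ")))
  }
  seeds <- intersect(genes, net$nodes$gene)
  if (!length(seeds)) return(build_graph(list(), nodes = character()))
  g <- to_igraph(net)
  hood <- igraph::ego(g, order = radius, nodes = seeds, mode = "all")
  keep <- sort(unique(names(unlist(hood))))
  sub_arcs <- dplyr::filter(net$arcs, .data$from %in% keep & .data$to %in% keep)
  build_graph(sub_arcs, nodes = keep)
}

#' Score an inferred network against a ground truth
#'
#' Direction-sensitive confusion counts over directed arcs on a shared node
#' universe. Conventions for degenerate cases: empty truth gives recall 1,
#' an empty inferred arc set gives precision 1, and F1 is 0 when undefined.
#'
#' @param inferred,truth `gene_network` objects on the same node set.
#' @return A one-row tibble `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
evaluate_structure <- function(inferred, truth) {
  stopifnot(inherits(inferred, "gene_network"), inherits(truth, "gene_network"))
  if (!setequal(inferred$nodes$gene, truth$nodes$gene)) {
    only_inf <- setdiff(inferred$nodes$gene, truth$nodes$gene)
    only_tru <- setdiff(truth$nodes$gene, inferred$nodes$gene)
    rlang::abort(c("node universes differ",
                   paste0("only in inferred: ", paste(utils::head(only_inf, 5), collapse = ", ")),
                   paste0("only in truth: ", paste(utils::head(only_tru, 5), collapse = ", "))))
  }
  key <- function(a) paste(a$from, a$to, sep = "\r")
  inf <- key(inferred$arcs); tru <- key(truth$arcs)
  tp <- length(intersect(inf, tru))
  fp <- length(setdiff(inf, tru))
  fn <- length(setdiff(tru, inf))
  precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  tibble::tibble(tp = tp, fp = fp, fn = fn,
                 precision = precision, recall = recall, f1 = f1)
}

#' Convert a gene network to an igraph object
#'
#' @param net A `gene_network`.
#' @return A directed `igraph` graph with node attributes.
#' @export
to_igraph <- function(net) {
  igraph::graph_from_data_frame(net$arcs, directed = TRUE,
                                vertices = as.data.frame(net$nodes))
}

#' Write / read simple interaction format (SIF)
#'
#' Lines of the form `parent ctbn child`, the exchange format for learned
#' and ground-truth structures.
#'
#' @param arcs A tibble with `from` and `to` (or a `gene_network`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sif <- function(arcs, path) {
  if (inherits(arcs, "gene_network")) arcs <- arcs$arcs
  lines <- sprintf("%s\tctbn\t%s", arcs$from, arcs$to)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sif
#' @return For `read_sif()`: a tibble `from`, `to`.
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(tibble::tibble(from = character(), to = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(from = vapply(parts, `[[`, "", 1),
                 to = vapply(parts, `[[`, "", 3))
}

#' Write a gene network to GraphML and a node-attribute TSV
#'
#' @param net A `gene_network`.
#' @param graphml_path Path for the GraphML file (skipped when `NULL`).
#' @param nodes_path Path for the node-attribute TSV (gene, out_degree,
#'   in_degree, hierarchy_class, hub_rank; skipped when `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_network <- function(net, graphml_path = NULL, nodes_path = NULL) {
  if (!is.null(graphml_path)) {
    igraph::write_graph(to_igraph(net), graphml_path, format = "graphml")
  }
  if (!is.null(nodes_path)) {
    utils::write.table(tidy.gene_network(net), nodes_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(c(graphml_path, nodes_path))
}
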