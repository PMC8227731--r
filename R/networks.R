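#' Build a phenotype cooperation network
#'
#' Nodes are the TFs appearing in significant pairs; each significant
#' pair contributes one undirected edge weighted by its z-score.
#'
#' @param sig `pair_statistics` of significant pairs (from
#'   [significant_pairs]).
#' @param phenotype Label for the network (e.g. `"sex"`, `"colour"`).
#' @return Object of class `coop_network` with fields `phenotype`,
#'   `nodes` (character) and `edges` (data frame `tf_a`, `tf_b`, `z`).
#' @export
build_network <- function(sig, phenotype = "phenotype") {
  edges <- data.frame(tf_a = character(), tf_b = character(), z = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(sig) > 0L) {
    pk <- pair_key(sig$tf_a, sig$tf_b)
    edges <- data.frame(tf_a = pk$tf_a, tf_b = pk$tf_b, z = sig$z,
                        stringsAsFactors = FALSE)
    edges <- edges[!duplicated(paste(edges$tf_a, edges$tf_b, sep = "\t")), ,
                   drop = FALSE]
    if (any(edges$tf_a == edges$tf_b))
      stop("self-loop edge in cooperation network")
    edges <- edges[order(edges$tf_a, edges$tf_b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(phenotype = phenotype,
                 nodes = sort(unique(c(edges$tf_a, edges$tf_b))),
                 edges = edges),
            class = "coop_network")
}

#' @export
print.coop_network <- function(x, ...) {
  cat(sprintf("Cooperation network '%s': %d TFs, %d significant pairs\n",
              x$phenotype, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Top hub TFs of a cooperation network
#'
#' Nodes ranked by degree (number of incident cooperation edges),
#' descending; ties broken first by the summed absolute z of incident
#' edges (descending), then lexicographically — a total order, so the
#' ranking is deterministic.
#'
#' @param net A `coop_network`.
#' @param k How many hubs to return (default 3, the conventional
#'   "top three"); fewer if the network is smaller.
#' @return Character vector of TF names.
#' @export
hubs <- function(net, k = 3L) {
  stopifnot(k >= 1L)
  if (length(net$nodes) == 0L) return(character(0))
  deg <- vapply(net$nodes, function(v)
    sum(net$edges$tf_a == v | net$edges$tf_b == v), 0L)
  zsum <- vapply(net$nodes, function(v)
    sum(abs(net$edges$z[net$edges$tf_a == v | net$edges$tf_b == v])), 0)
  ord <- order(-deg, -zsum, net$nodes)
  net$nodes[ord][seq_len(min(k, length(net$nodes)))]
}

edge_keys <- function(net) {
  if (nrow(net$edges) == 0L) return(character(0))
  paste(net$edges$tf_a, net$edges$tf_b, sep = "\t")
}

#' Compare two phenotype cooperation networks
#'
#' Partitions the edge sets into common edges (present in both networks)
#' and phenotype-specific edges, and identifies partner-switching TFs:
#' nodes present in both networks but with no incident common edge —
#' factors that cooperate in both phenotypes yet with different partners
#' in each.
#'
#' @param a,b `coop_network` objects.
#' @return Object of class `network_comparison` with fields
#'   `common_edges`, `specific_edges_a`, `specific_edges_b` (data frames
#'   `tf_a`, `tf_b`, plus per-network z columns where applicable),
#'   `shared_nodes`, `switching_nodes`, `phenotype_a`, `phenotype_b`.
#' @export
compare_networks <- function(a, b) {
  ka <- edge_keys(a); kb <- edge_keys(b)
  common_k <- intersect(ka, kb)
  spec_a <- a$edges[!(ka %in% kb), , drop = FALSE]
  spec_b <- b$edges[!(kb %in% ka), , drop = FALSE]
  common <- a$edges[ka %in% common_k, c("tf_a", "tf_b"), drop = FALSE]
  if (nrow(common) > 0L) {
    common$z_a <- a$edges$z[match(paste(common$tf_a, common$tf_b, sep = "\t"), ka)]
    common$z_b <- b$edges$z[match(paste(common$tf_a, common$tf_b, sep = "\t"), kb)]
  } else {
    common$z_a <- numeric(0); common$z_b <- numeric(0)
  }
  shared <- intersect(a$nodes, b$nodes)
  common_nodes <- unique(c(common$tf_a, common$tf_b))
  switching <- setdiff(shared, common_nodes)
  rownames(common) <- NULL; rownames(spec_a) <- NULL; rownames(spec_b) <- NULL
  structure(list(common_edges = common,
                 specific_edges_a = spec_a, specific_edges_b = spec_b,
                 shared_nodes = sort(shared),
                 switching_nodes = sort(switching),
                 phenotype_a = a$phenotype, phenotype_b = b$phenotype),
            class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf(paste0("Network comparison %s vs %s: %d common, ",
                     "%d + %d specific edges; %d shared TFs ",
                     "(%d partner-switching)\n"),
              x$phenotype_a, x$phenotype_b, nrow(x$common_edges),
              nrow(x$specific_edges_a), nrow(x$specific_edges_b),
              length(x$shared_nodes), length(x$switching_nodes)))
  invisible(x)
}

as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("tf_a", "tf_b"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE))
  igraph::E(g)$z <- net$edges$z
  g
}

#' Export a network or comparison to GraphML or TSV
#'
#' Networks carry z as an edge attribute; comparison exports label every
#' edge with exactly one category (`common`, `specific_a`, `specific_b`).
#' TSV edge lists print z at full precision so the edge set round-trips
#' bit-exactly through [read_network_tsv].
#'
#' @param x A `coop_network` or `network_comparison`.
#' @param path Output path.
#' @param format `"graphml"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(x, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (inherits(x, "coop_network")) {
    if (format == "graphml") {
      igraph::write_graph(as_igraph(x), path, format = "graphml")
    } else {
      out <- x$edges
      out$z <- sprintf("%.17g", out$z)
      utils::write.table(out, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  } else if (inherits(x, "network_comparison")) {
    lab <- function(df, category) {
      if (nrow(df) == 0L)
        return(data.frame(tf_a = character(), tf_b = character(),
                          category = character(), stringsAsFactors = FALSE))
      data.frame(tf_a = df$tf_a, tf_b = df$tf_b, category = category,
                 stringsAsFactors = FALSE)
    }
    edges <- rbind(lab(x$common_edges, "common"),
                   lab(x$specific_edges_a, "specific_a"),
                   lab(x$specific_edges_b, "specific_b"))
    if (format == "tsv") {
      utils::write.table(edges, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    } else {
      nodes <- sort(unique(c(edges$tf_a, edges$tf_b)))
      g <- igraph::graph_from_data_frame(
        edges[, c("tf_a", "tf_b")], directed = FALSE,
        vertices = data.frame(name = nodes))
      igraph::E(g)$category <- edges$category
      igraph::write_graph(g, path, format = "graphml")
    }
  } else {
    stop("cannot export object of class ", paste(class(x), collapse = "/"))
  }
  invisible(path)
}

#' Read a network TSV edge list written by [export_network]
#'
#' @param path TSV path.
#' @param phenotype Label for the reconstructed network.
#' @return A `coop_network`.
#' @export
read_network_tsv <- function(path, phenotype = "phenotype") {
  edges <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE,
                             colClasses = c(tf_a = "character",
                                            tf_b = "character"))
  fake <- data.frame(tf_a = edges$tf_a, tf_b = edges$tf_b, z = edges$z,
                     significant = rep(TRUE, nrow(edges)),
                     stringsAsFactors = FALSE)
  build_network(fake, phenotype)
}
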