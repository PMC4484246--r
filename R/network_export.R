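# Network serialization: a round-trippable long edge TSV, GraphML (weights
# as per-sample edge attributes) and Graphviz DOT (penwidth proportional to
# relative abundance).

# DOT penwidth per percent relative abundance (linear; 0.1% -> width 1)
DOT_PENWIDTH_PER_PERCENT <- 10

#' Export a meta-network
#'
#' * `edge_tsv` — long table, one row per edge x sample
#'   (`substrate_code`, `product_code`, `family_id`, `sample_id`, `weight`);
#'   exact round trip via [read_network_tsv()].
#' * `graphml` — via igraph; each sample's weights stored as an edge
#'   attribute named `w_<sample_id>`.
#' * `dot` — one graph per call; line thickness `penwidth` is linear in
#'   relative abundance, 10 width units per percent
#'   (`DOT_PENWIDTH_PER_PERCENT`). With `sample = NULL` the per-edge maximum
#'   across samples is drawn.
#'
#' @param net A `meta_network`.
#' @param path Output file.
#' @param format `"edge_tsv"`, `"graphml"` or `"dot"`.
#' @param sample For DOT: which sample's weights to draw (default: per-edge
#'   max across samples).
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("edge_tsv", "graphml", "dot"),
                           sample = NULL) {
  format <- tryCatch(match.arg(format), error = function(e) {
    stop("unknown export format: ", format[1], call. = FALSE)
  })
  switch(format,
    edge_tsv = {
      n_e <- nrow(net$edges)
      tab <- data.frame(
        substrate_code = rep(net$edges$substrate_code, times = length(net$samples)),
        product_code = rep(net$edges$product_code, times = length(net$samples)),
        family_id = rep(net$edges$family_id, times = length(net$samples)),
        sample_id = rep(net$samples, each = n_e),
        weight = as.vector(net$weights)
      )
      write_tsv_strict(tab, path)
    },
    graphml = {
      g <- as_igraph(net)
      igraph::write_graph(g, path, format = "graphml")
    },
    dot = {
      w <- if (is.null(sample)) {
        if (nrow(net$edges) > 0) apply(net$weights, 1, max) else numeric(0)
      } else {
        if (!sample %in% net$samples) stop("unknown sample: ", sample, call. = FALSE)
        net$weights[, sample]
      }
      lines <- c(
        "digraph metaweb {",
        sprintf("  \"%s\";", net$nodes),
        sprintf(
          "  \"%s\" -> \"%s\" [label=\"%s\", penwidth=%g];",
          net$edges$substrate_code, net$edges$product_code,
          net$edges$family_id, w * DOT_PENWIDTH_PER_PERCENT
        ),
        "}"
      )
      writeLines(lines, path)
    }
  )
  invisible(path)
}

#' Convert a meta-network to an igraph object
#'
#' Edge attributes: `family_id` plus one `w_<sample>` weight per sample.
#'
#' @param net A `meta_network`.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    data.frame(
      from = net$edges$substrate_code, to = net$edges$product_code,
      family_id = net$edges$family_id
    ),
    directed = TRUE, vertices = net$nodes
  )
  for (s in net$samples) {
    g <- igraph::set_edge_attr(g, paste0("w_", s), value = net$weights[, s])
  }
  g
}

#' Read a meta-network back from its long edge TSV
#'
#' Exact inverse of `export_network(format = "edge_tsv")`.
#'
#' @param path Edge TSV path.
#' @return A `meta_network`.
#' @export
read_network_tsv <- function(path) {
  df <- read_tsv_strict(path,
    required = c("substrate_code", "product_code", "family_id", "sample_id", "weight"),
    numeric_cols = "weight"
  )
  samples <- unique(df$sample_id)
  if (nrow(df) == 0) {
    return(meta_network(
      data.frame(
        substrate_code = character(), product_code = character(),
        family_id = character()
      ),
      matrix(0, 0, 0), character(0)
    ))
  }
  ekey <- unique(paste(df$substrate_code, df$product_code, df$family_id, sep = "\r"))
  parts <- do.call(rbind, strsplit(ekey, "\r", fixed = TRUE))
  edges <- data.frame(
    substrate_code = parts[, 1], product_code = parts[, 2], family_id = parts[, 3],
    stringsAsFactors = FALSE
  )
  w <- matrix(0, nrow(edges), length(samples), dimnames = list(NULL, samples))
  row_i <- match(paste(df$substrate_code, df$product_code, df$family_id, sep = "\r"), ekey)
  col_i <- match(df$sample_id, samples)
  w[cbind(row_i, col_i)] <- df$weight
  meta_network(edges, w, samples)
}
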