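# Meta-network reconstruction: substrate -> product edges supported by
# detected catabolic families, weighted per sample by gene relative
# abundance; plus the metabolomics-calibrated degradation-confidence model.

#' Build a weighted degradation meta-network
#'
#' For every catalog reaction whose family has positive relative abundance
#' in at least one profile, an edge (substrate_code -> product_code,
#' family_id) is created; its weight in each sample is that family's
#' percentage there. Each reaction carries its family's full percentage (one
#' line per reaction, thickness by gene abundance — no splitting across a
#' family's reactions). Nodes are exactly the codes incident to included
#' edges.
#'
#' @param profiles Named list of `catabolic_profile`.
#' @param catalog A `deg_catalog`.
#' @return A `meta_network`: `nodes`, `edges` (data.frame with
#'   `substrate_code`, `product_code`, `family_id`), `weights` (edges x
#'   samples matrix, percent), `samples`.
#' @export
build_network <- function(profiles, catalog) {
  stopifnot(inherits(catalog, "deg_catalog"))
  samples <- vapply(profiles, `[[`, "", "sample_id")
  known <- catalog$families$family_id
  for (p in profiles) {
    bad <- setdiff(names(p$family_percent), known)
    if (length(bad) > 0) {
      stop("profile ", p$sample_id, " references family absent from catalog: ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
  }
  rx <- catalog$reactions
  w <- matrix(0, nrow(rx), length(samples),
    dimnames = list(NULL, samples)
  )
  for (j in seq_along(profiles)) {
    p <- profiles[[j]]
    idx <- match(rx$family_id, names(p$family_percent))
    w[, j] <- ifelse(is.na(idx), 0, p$family_percent[idx])
  }
  keep <- rowSums(w > 0) > 0
  edges <- rx[keep, c("substrate_code", "product_code", "family_id"), drop = FALSE]
  rownames(edges) <- NULL
  w <- w[keep, , drop = FALSE]
  meta_network(edges, w, samples)
}

#' Construct a meta-network from an edge table and weight matrix
#'
#' @param edges data.frame with `substrate_code`, `product_code`,
#'   `family_id`.
#' @param weights Numeric matrix, one row per edge, one named column per
#'   sample; percentages, all `>= 0`.
#' @param samples Sample ids (defaults to the weight column names).
#' @export
meta_network <- function(edges, weights, samples = colnames(weights)) {
  stopifnot(nrow(edges) == nrow(weights))
  if (any(weights < 0)) stop("negative edge weight", call. = FALSE)
  if (nrow(edges) > 0 && any(rowSums(weights > 0) == 0)) {
    stop("edge with zero weight in every sample", call. = FALSE)
  }
  colnames(weights) <- samples
  nodes <- sort(unique(c(edges$substrate_code, edges$product_code)))
  structure(list(
    nodes = nodes, edges = edges, weights = weights, samples = samples
  ), class = "meta_network")
}

#' @export
print.meta_network <- function(x, ...) {
  cat(sprintf(
    "<meta_network> %d nodes, %d edges, %d samples\n",
    length(x$nodes), nrow(x$edges), length(x$samples)
  ))
  invisible(x)
}

#' Count catabolic genes supporting degradation of each chemical
#'
#' For each (sample, chemical) pair, the number of retained gene-equivalents
#' whose family consumes that chemical (i.e. has a catalog reaction with the
#' chemical as substrate). This is the "minimum number of catabolic genes"
#' axis of the confidence model.
#'
#' @param anns Named list of screened `sample_annotation`.
#' @param catalog A `deg_catalog`.
#' @return data.frame with `sample_id`, `chemical_code`, `k`.
#' @export
chemical_gene_counts <- function(anns, catalog) {
  chems <- sort(unique(catalog$reactions$substrate_code))
  rows <- lapply(anns, function(a) {
    fam_n <- if (nrow(a$hits) == 0) numeric(0) else tapply(a$hits$n, a$hits$family_id, sum)
    k <- vapply(chems, function(ch) {
      fams <- catalog$reactions$family_id[catalog$reactions$substrate_code == ch]
      sum(fam_n[intersect(names(fam_n), fams)])
    }, 0)
    data.frame(sample_id = a$sample_id, chemical_code = chems, k = as.numeric(k))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# weighted pool-adjacent-violators: least-squares monotone (non-decreasing) fit
pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (n == 0) {
    return(numeric(0))
  }
  val <- y
  wt <- w
  len <- rep(1L, n)
  m <- 0L
  for (i in seq_len(n)) {
    m <- m + 1L
    val[m] <- y[i]
    wt[m] <- w[i]
    len[m] <- 1L
    while (m > 1L && val[m - 1L] > val[m]) {
      tot <- wt[m - 1L] + wt[m]
      val[m - 1L] <- (wt[m - 1L] * val[m - 1L] + wt[m] * val[m]) / tot
      wt[m - 1L] <- tot
      len[m - 1L] <- len[m - 1L] + len[m]
      m <- m - 1L
    }
  }
  rep(val[seq_len(m)], len[seq_len(m)])
}

#' Fit a metabolomics-calibrated degradation-confidence model
#'
#' For each chemical with evidence rows, estimates the probability that the
#' chemical is actually degraded as a function of the number of supporting
#' catabolic genes k: the empirical frequency of `status == "degraded"`
#' among evidence rows at each k, Laplace-smoothed
#' (`(degraded + 1) / (rows + 2)`), then monotonized (non-decreasing in k)
#' by pool-adjacent-violators. Chemicals without evidence inherit a global
#' model pooled over all chemicals.
#'
#' Conditioning defaults to the exact gene count (`P(degraded | K = k)`),
#' which is what the planted-curve recovery property measures; the
#' `"geq"` variant conditions on `K >= k` ("at least k genes"). Only count
#' values actually observed in the evidence form estimation bins; the step
#' function carries each fitted value rightward across unobserved counts,
#' which preserves monotonicity.
#'
#' @param evidence data.frame with `sample_id`, `chemical_code`, `status`
#'   (`degraded`/`not_degraded`).
#' @param gene_counts data.frame with `sample_id`, `chemical_code`, `k`
#'   (from [chemical_gene_counts()]); every evidence row must have one.
#' @param catalog Optional `deg_catalog`; evidence chemicals are validated
#'   against its substrate codes when given.
#' @param conditioning `"exact"` or `"geq"`.
#' @param threshold Stored default confidence threshold (0.90).
#' @param k_cap Counts above `k_cap` are pooled into the top bin (useful
#'   when gene-equivalent counts are large but the curve saturates early);
#'   default `NULL`, no cap.
#' @return A `confidence_model`: per-chemical step functions `curves` over
#'   k = 0..K, `support` (evidence rows per chemical), pooled `global`
#'   curve, `threshold`, `conditioning`.
#' @export
fit_confidence <- function(evidence, gene_counts, catalog = NULL,
                           conditioning = c("exact", "geq"), threshold = 0.90,
                           k_cap = NULL) {
  conditioning <- match.arg(conditioning)
  if (!is.null(catalog)) {
    chems <- unique(catalog$reactions$substrate_code)
    bad <- setdiff(unique(evidence$chemical_code), chems)
    if (length(bad) > 0) {
      stop("evidence chemical absent from catalog: ", paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
  }
  key <- paste(evidence$sample_id, evidence$chemical_code)
  ckey <- paste(gene_counts$sample_id, gene_counts$chemical_code)
  idx <- match(key, ckey)
  if (anyNA(idx)) {
    stop("evidence row without a gene count: ", key[which(is.na(idx))[1]],
      call. = FALSE
    )
  }
  ev <- data.frame(
    chemical_code = evidence$chemical_code,
    degraded = evidence$status == "degraded",
    k = floor(gene_counts$k[idx])
  )
  if (!is.null(k_cap)) ev$k <- pmin(ev$k, k_cap)
  k_max <- max(ev$k, 0)
  fit_one <- function(rows) {
    ks <- sort(unique(rows$k))
    if (conditioning == "exact") {
      n_k <- vapply(ks, function(k) sum(rows$k == k), 0)
      d_k <- vapply(ks, function(k) sum(rows$degraded[rows$k == k]), 0)
    } else {
      n_k <- vapply(ks, function(k) sum(rows$k >= k), 0)
      d_k <- vapply(ks, function(k) sum(rows$degraded[rows$k >= k]), 0)
    }
    fit <- pava((d_k + 1) / (n_k + 2), w = n_k + 2)
    full <- if (length(ks) == 1) {
      rep(fit, k_max + 1)
    } else {
      stats::approx(ks, fit, xout = 0:k_max, method = "constant", rule = 2, f = 0)$y
    }
    stats::setNames(full, 0:k_max)
  }
  curves <- lapply(split(ev, ev$chemical_code), fit_one)
  support <- vapply(split(ev, ev$chemical_code), nrow, 0L)
  structure(list(
    curves = curves,
    support = support,
    global = fit_one(ev),
    k_max = k_max,
    threshold = threshold,
    conditioning = conditioning
  ), class = "confidence_model")
}

#' @export
print.confidence_model <- function(x, ...) {
  cat(sprintf(
    "<confidence_model> %d chemical-specific curves (%s conditioning), k = 0..%d, threshold %.2f\n",
    length(x$curves), x$conditioning, x$k_max, x$threshold
  ))
  invisible(x)
}

#' Evaluate fitted degradation confidence
#'
#' Step-function evaluation: counts beyond the fitted range are clamped to
#' the last step. Chemicals the model never saw evidence for fall back to
#' the pooled global curve.
#'
#' @param model A `confidence_model`.
#' @param chemical_code Chemical code (scalar).
#' @param k Gene count(s).
#' @return Confidence value(s) in `[0, 1]`.
#' @export
confidence_at <- function(model, chemical_code, k) {
  curve <- model$curves[[chemical_code]] %||% model$global
  idx <- pmin(pmax(floor(k), 0), length(curve) - 1) + 1
  as.numeric(curve[idx])
}

#' Chemicals degradable with at least a given confidence
#'
#' A chemical belongs to a sample's degradable set iff (i) it has at least
#' one outgoing edge with positive weight in that sample (some detected
#' family consumes it there) and (ii) its fitted confidence at the sample's
#' gene count is `>= threshold` ("at least 90%" is a closed bound).
#'
#' @param net A `meta_network`.
#' @param model A `confidence_model`.
#' @param gene_counts data.frame `sample_id`, `chemical_code`, `k`.
#' @param threshold Confidence threshold in (0, 1]; default 0.90.
#' @return A `degradable_set`: `per_sample` (named list of code vectors),
#'   `union` (codes degradable somewhere), `threshold`.
#' @export
degradable_set <- function(net, model, gene_counts, threshold = 0.90) {
  stopifnot(threshold > 0, threshold <= 1)
  per_sample <- lapply(net$samples, function(s) {
    out <- character(0)
    gc_s <- gene_counts[gene_counts$sample_id == s, , drop = FALSE]
    for (i in seq_len(nrow(gc_s))) {
      ch <- gc_s$chemical_code[i]
      has_edge <- any(net$edges$substrate_code == ch & net$weights[, s] > 0)
      if (has_edge &&
        confidence_at(model, ch, gc_s$k[i]) >= threshold) {
        out <- c(out, ch)
      }
    }
    sort(out)
  })
  names(per_sample) <- net$samples
  structure(list(
    per_sample = per_sample,
    union = sort(unique(unlist(per_sample))),
    threshold = threshold
  ), class = "degradable_set")
}

#' @export
print.degradable_set <- function(x, ...) {
  cat(sprintf(
    "<degradable_set> threshold %.2f: %d chemicals in the union; per sample: %s\n",
    x$threshold, length(x$union),
    paste(sprintf("%s=%d", names(x$per_sample), lengths(x$per_sample)), collapse = ", ")
  ))
  invisible(x)
}

#' Products reachable from source chemicals in one sample
#'
#' Directed breadth-first traversal over the edges with positive weight in
#' the given sample. Sources themselves are excluded unless re-reached
#' through an edge.
#'
#' @param net A `meta_network`.
#' @param sample_id Sample to evaluate.
#' @param sources Chemical codes; must all be network nodes.
#' @return Sorted character vector of reachable codes.
#' @export
reachable_products <- function(net, sample_id, sources) {
  if (!sample_id %in% net$samples) stop("unknown sample: ", sample_id, call. = FALSE)
  bad <- setdiff(sources, net$nodes)
  if (length(bad) > 0) {
    stop("unknown source code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  act <- net$weights[, sample_id] > 0
  from <- net$edges$substrate_code[act]
  to <- net$edges$product_code[act]
  seen <- character(0)
  frontier <- sources
  while (length(frontier) > 0) {
    nxt <- unique(to[from %in% frontier])
    nxt_new <- setdiff(nxt, seen)
    seen <- union(seen, nxt_new)
    frontier <- nxt_new
  }
  sort(seen)
}

#' Compare two meta-networks
#'
#' Reports edges shared and unique to each network (keyed by substrate,
#' product, family), the ratio of mean per-sample weights for families
#' present in both, and the number of distinct substrates per network —
#' the comparison used to contrast degradation webs between sites.
#'
#' @param a,b `meta_network` objects over a shared catalog.
#' @return A `network_comparison`: `shared`, `only_a`, `only_b` edge
#'   data.frames, `family_ratio` data.frame (`family_id`, `mean_a`,
#'   `mean_b`, `ratio`), `n_substrates` (named length-2 vector).
#' @export
compare_networks <- function(a, b) {
  key <- function(n) paste(n$edges$substrate_code, n$edges$product_code, n$edges$family_id)
  ka <- key(a)
  kb <- key(b)
  fams <- intersect(unique(a$edges$family_id), unique(b$edges$family_id))
  fam_mean <- function(net, f) {
    rows <- net$edges$family_id == f
    mean(net$weights[rows, , drop = FALSE])
  }
  ratio <- data.frame(
    family_id = fams,
    mean_a = vapply(fams, fam_mean, 0, net = a),
    mean_b = vapply(fams, fam_mean, 0, net = b)
  )
  ratio$ratio <- ifelse(ratio$mean_b > 0, ratio$mean_a / ratio$mean_b, Inf)
  rownames(ratio) <- NULL
  structure(list(
    shared = a$edges[ka %in% kb, , drop = FALSE],
    only_a = a$edges[!ka %in% kb, , drop = FALSE],
    only_b = b$edges[!kb %in% ka, , drop = FALSE],
    family_ratio = ratio,
    n_substrates = c(
      a = length(unique(a$edges$substrate_code)),
      b = length(unique(b$edges$substrate_code))
    )
  ), class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf(
    "<network_comparison> %d shared edges, %d only in a, %d only in b; substrates a=%d b=%d\n",
    nrow(x$shared), nrow(x$only_a), nrow(x$only_b),
    x$n_substrates[["a"]], x$n_substrates[["b"]]
  ))
  invisible(x)
}
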