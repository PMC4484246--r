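# Screening, relative abundance (DEGgp), taxonomy-based imputation, and
# merging of DNA-derived with 16S-imputed evidence.

#' Screen annotation hits by bit score and e-value
#'
#' Keeps exactly the hits with `bit_score > min_score` and
#' `e_value < max_evalue` (both strict, the convention of homology-search
#' screens). Imputed hits carry sentinel scores chosen to always pass. The
#' sample's `total_gene_count` is untouched: screening selects catabolic
#' hits, it does not change the denominator.
#'
#' @param ann A `sample_annotation` (or named list of them, screened
#'   elementwise).
#' @param min_score Minimum bit score, exclusive. Default 45.
#' @param max_evalue Maximum e-value, exclusive. Default 1e-3.
#' @return A `sample_annotation` containing only the passing hits.
#' @export
screen_hits <- function(ann, min_score = 45, max_evalue = 1e-3) {
  if (!inherits(ann, "sample_annotation")) {
    return(lapply(ann, screen_hits, min_score = min_score, max_evalue = max_evalue))
  }
  stopifnot(is.finite(min_score), is.finite(max_evalue))
  keep <- ann$hits$bit_score > min_score & ann$hits$e_value < max_evalue
  out <- ann
  out$hits <- ann$hits[keep, , drop = FALSE]
  rownames(out$hits) <- NULL
  out
}

#' Family-level relative abundance profile (DEGgp)
#'
#' Converts a (screened) annotation into per-family percentages of the
#' sample's total predicted genes, plus their sum `degp_total` — the DEGgp
#' aggregate. Referring counts to the total gene number makes samples of
#' different sequencing depth comparable.
#'
#' @param ann A screened `sample_annotation` with `total_gene_count > 0`.
#' @return A `catabolic_profile`: `family_percent` (named, percent),
#'   `degp_total` (percent), `source_mix` (`dna`/`imputed`/`combined`),
#'   `denominators` and internal `family_counts` (gene-equivalents, kept at
#'   full precision for pooling).
#' @export
catabolic_profile <- function(ann) {
  if (!inherits(ann, "sample_annotation")) {
    return(lapply(ann, catabolic_profile))
  }
  if (ann$total_gene_count <= 0) {
    if (nrow(ann$hits) > 0) {
      stop("sample ", ann$sample_id, ": total_gene_count is 0, DEGgp undefined",
        call. = FALSE
      )
    }
    # fully empty route (e.g. no OTU mapped to any genome): a valid
    # zero-denominator profile that merging treats as absent
    mix <- "imputed"
    return(structure(list(
      sample_id = ann$sample_id,
      family_percent = stats::setNames(numeric(0), character(0)),
      family_counts = stats::setNames(numeric(0), character(0)),
      degp_total = 0,
      source_mix = mix,
      denominators = c(dna = 0, imputed = 0)
    ), class = "catabolic_profile"))
  }
  counts <- if (nrow(ann$hits) == 0) {
    stats::setNames(numeric(0), character(0))
  } else {
    tapply(ann$hits$n, ann$hits$family_id, sum)
  }
  counts <- stats::setNames(as.numeric(counts), names(counts))
  src <- unique(ann$hits$source)
  mix <- if (length(src) == 0 || identical(src, "dna")) "dna" else if (identical(src, "imputed")) "imputed" else "combined"
  denom <- c(dna = 0, imputed = 0)
  denom[[if (mix == "imputed") "imputed" else "dna"]] <- ann$total_gene_count
  new_profile(ann$sample_id, counts, denom, mix)
}

new_profile <- function(sample_id, family_counts, denominators, source_mix) {
  total <- sum(denominators)
  fp <- 100 * family_counts / total
  structure(list(
    sample_id = sample_id,
    family_percent = fp,
    family_counts = family_counts,
    degp_total = sum(fp),
    source_mix = source_mix,
    denominators = denominators
  ), class = "catabolic_profile")
}

#' @export
print.catabolic_profile <- function(x, ...) {
  cat(sprintf(
    "<catabolic_profile> %s [%s]: DEGgp = %.2f%% over %d families (denominator %g genes)\n",
    x$sample_id, x$source_mix, x$degp_total, length(x$family_percent),
    sum(x$denominators)
  ))
  invisible(x)
}

# sentinels for imputed gene-equivalents: always pass screening
IMPUTED_SCORE <- 1e6
IMPUTED_EVALUE <- 0

#' Impute catabolic gene content from 16S taxonomy
#'
#' Fills annotation gaps left by shallow metagenome sequencing: each OTU
#' mapped to a reference genome contributes `count x` that genome's
#' per-family gene counts as imputed gene-equivalents, and `count x` the
#' genome's total genes to the imputed denominator. Unmapped OTUs contribute
#' nothing and are reported in a warning. Multiplicities are materialized as
#' counts (one row per family with `n` gene-equivalents), not replicated
#' rows, and imputed rows carry sentinel scores that always pass
#' [screen_hits()].
#'
#' @param otus An `otu_table`.
#' @param map OTU-to-genome map data.frame (`otu_id`, `genome_id`,
#'   `identity_percent`), one genome per OTU.
#' @param genomes Named list of genome annotations as from
#'   [read_genome_annotations()].
#' @param sample_id Which sample column of `otus` to impute.
#' @return A `sample_annotation` with `source = "imputed"` whose
#'   `total_gene_count` is the imputed denominator (0 if nothing mapped).
#' @export
impute_from_taxonomy <- function(otus, map, genomes, sample_id) {
  stopifnot(inherits(otus, "otu_table"))
  if (!sample_id %in% otus$sample_ids) {
    stop("unknown sample: ", sample_id, call. = FALSE)
  }
  missing_g <- setdiff(unique(map$genome_id), names(genomes))
  if (length(missing_g) > 0) {
    stop("map references missing genome(s): ", paste(missing_g, collapse = ", "),
      call. = FALSE
    )
  }
  counts <- otus$counts[, sample_id]
  present <- names(counts)[counts > 0]
  mapped <- intersect(present, map$otu_id)
  unmapped <- setdiff(present, map$otu_id)
  if (length(unmapped) > 0) {
    warning(
      length(unmapped), " of ", length(present),
      " OTUs in sample ", sample_id, " have no genome affiliation and were skipped",
      call. = FALSE
    )
  }
  fam_eq <- list()
  denom <- 0
  for (o in mapped) {
    g <- genomes[[map$genome_id[map$otu_id == o]]]
    c_o <- counts[[o]]
    denom <- denom + c_o * g$total_genes
    for (f in names(g$family_counts)) {
      fam_eq[[f]] <- (fam_eq[[f]] %||% 0) + c_o * g$family_counts[[f]]
    }
  }
  fams <- names(fam_eq)
  hits <- if (length(fams) == 0) {
    empty_hits()
  } else {
    data.frame(
      gene_id = paste0("imp|", sample_id, "|", fams),
      family_id = fams,
      bit_score = rep(IMPUTED_SCORE, length(fams)),
      e_value = rep(IMPUTED_EVALUE, length(fams)),
      source = rep("imputed", length(fams)),
      n = as.numeric(unlist(fam_eq)),
      stringsAsFactors = FALSE
    )
  }
  sample_annotation(sample_id, total_gene_count = denom, hits = hits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Merge DNA-derived and imputed profiles by count pooling
#'
#' Combined percentage of family f is
#' `100 * (dna_count_f + imputed_count_f) / (dna_total + imputed_total)` —
#' a denominator-weighted mean of the two inputs, so the combined value
#' always lies between them. An `"average"` mode (unweighted mean of the two
#' percentages) is exposed for sensitivity comparison.
#'
#' @param dna,imputed `catabolic_profile` objects for the same sample.
#' @param mode `"pool"` (default, pooled counts) or `"average"`.
#' @return A `catabolic_profile` with `source_mix = "combined"`.
#' @export
merge_profiles <- function(dna, imputed, mode = c("pool", "average")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dna, "catabolic_profile"), inherits(imputed, "catabolic_profile"))
  if (!identical(dna$sample_id, imputed$sample_id)) {
    stop("sample ids differ: ", dna$sample_id, " vs ", imputed$sample_id, call. = FALSE)
  }
  fams <- union(names(dna$family_counts), names(imputed$family_counts))
  get <- function(p, f) if (f %in% names(p$family_counts)) p$family_counts[[f]] else 0
  denom <- c(
    dna = sum(dna$denominators),
    imputed = sum(imputed$denominators)
  )
  if (mode == "pool") {
    counts <- stats::setNames(
      vapply(fams, function(f) get(dna, f) + get(imputed, f), 0), fams
    )
    new_profile(dna$sample_id, counts, denom, "combined")
  } else {
    pct <- function(p, f) if (f %in% names(p$family_percent)) p$family_percent[[f]] else 0
    fp <- stats::setNames(
      vapply(fams, function(f) (pct(dna, f) + pct(imputed, f)) / 2, 0), fams
    )
    # represent averaged percentages over the pooled denominator
    total <- sum(denom)
    new_profile(dna$sample_id, fp / 100 * total, denom, "combined")
  }
}

#' Aggregate DEGgp and family classes across profiles
#'
#' Convenience summary used by the `report` CLI stage: per-sample DEGgp and,
#' when a catalog is given, the percentage per pathway class.
#'
#' @param profiles Named list of `catabolic_profile`.
#' @param catalog Optional `deg_catalog` for class aggregation.
#' @return data.frame with one row per sample.
#' @export
profile_summary <- function(profiles, catalog = NULL) {
  out <- data.frame(
    sample_id = vapply(profiles, `[[`, "", "sample_id"),
    source_mix = vapply(profiles, `[[`, "", "source_mix"),
    degp_total = vapply(profiles, `[[`, 0, "degp_total")
  )
  if (!is.null(catalog)) {
    tags <- unique(catalog$families$class_tag)
    for (tag in tags) {
      fams <- catalog$families$family_id[catalog$families$class_tag == tag]
      out[[tag]] <- vapply(profiles, function(p) {
        sum(p$family_percent[intersect(names(p$family_percent), fams)])
      }, 0)
    }
  }
  rownames(out) <- NULL
  out
}
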