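# Tabular I/O. One dialect everywhere: TSV, mandatory header, "NA" missing.
# Identifiers are preserved verbatim (no case folding, no trimming beyond
# the tab delimiter), so all readers run with quote = "" and
# check.names = FALSE, and all writers quote nothing.

#' Read a strict TSV table
#'
#' Internal workhorse behind every reader: tab-separated, mandatory header,
#' `"NA"` is the only missing-value token, no quoting, identifiers kept
#' verbatim. Fails with the offending column name when a required column is
#' absent, and with a line number when a declared-numeric field does not
#' parse.
#'
#' @param path Path to a TSV file.
#' @param required Character vector of column names that must be present.
#' @param numeric_cols Columns converted to numeric with per-row validation.
#' @return A data.frame of character/numeric columns.
#' @keywords internal
read_tsv_strict <- function(path, required = character(), numeric_cols = character()) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path,
    colClasses = "character", check.names = FALSE,
    quote = "", comment.char = "", na.strings = "NA",
    stringsAsFactors = FALSE
  )
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s) in ", path, ": ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  for (col in intersect(numeric_cols, names(df))) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(val))
    if (length(bad) > 0) {
      # +1 for the header line
      stop(sprintf(
        "non-numeric value '%s' in column '%s' at line %d of %s",
        raw[bad[1]], col, bad[1] + 1L, path
      ), call. = FALSE)
    }
    df[[col]] <- val
  }
  df
}

write_tsv_strict <- function(df, path) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE, na = "NA"
  )
  invisible(path)
}

#' Read a gene-annotation hit table
#'
#' Parses a per-gene annotation table (one row per match of a predicted gene
#' to a catabolic family) together with its companion totals table giving the
#' number of predicted protein-coding genes per sample, and assembles one
#' [sample_annotation()] per sample. Samples present only in the totals table
#' yield annotations with zero hits.
#'
#' @param path TSV with columns `sample_id`, `gene_id`, `family_id`,
#'   `bit_score`, `e_value`.
#' @param totals_path TSV with columns `sample_id`, `total_gene_count`.
#' @param source_label `"dna"` for metagenome-derived hits, `"imputed"` for
#'   hits inferred from 16S rRNA taxonomic affiliation.
#' @return Named list of `sample_annotation` objects, one per sample.
#' @export
read_hit_table <- function(path, totals_path, source_label = c("dna", "imputed")) {
  source_label <- match.arg(source_label)
  hits <- read_tsv_strict(path,
    required = c("sample_id", "gene_id", "family_id", "bit_score", "e_value"),
    numeric_cols = c("bit_score", "e_value")
  )
  totals <- read_tsv_strict(totals_path,
    required = c("sample_id", "total_gene_count"),
    numeric_cols = "total_gene_count"
  )
  if (nrow(hits) == 0) {
    warning("hit table ", path, " has a header but no rows", call. = FALSE)
  }
  unknown <- setdiff(unique(hits$sample_id), totals$sample_id)
  if (length(unknown) > 0) {
    stop("sample(s) in hit table missing from totals table: ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  out <- lapply(seq_len(nrow(totals)), function(i) {
    sid <- totals$sample_id[i]
    h <- hits[hits$sample_id == sid, , drop = FALSE]
    sample_annotation(
      sample_id = sid,
      total_gene_count = totals$total_gene_count[i],
      hits = data.frame(
        gene_id = h$gene_id, family_id = h$family_id,
        bit_score = h$bit_score, e_value = h$e_value,
        source = rep(source_label, nrow(h)),
        n = rep(1, nrow(h)),
        stringsAsFactors = FALSE
      )
    )
  })
  names(out) <- totals$sample_id
  out
}

#' Write a collection of sample annotations as hit + totals TSVs
#'
#' Inverse of [read_hit_table()]. Hits with multiplicity `n > 1` (imputed
#' gene-equivalents materialized as counts) are written with an `n` column
#' and are expanded back on read only by [read_hit_table()]'s companion
#' [read_hit_table_counts()].
#'
#' @param anns Named list of `sample_annotation`.
#' @param path,totals_path Output TSV paths.
#' @export
write_hit_table <- function(anns, path, totals_path) {
  rows <- lapply(anns, function(a) {
    if (nrow(a$hits) == 0) {
      return(NULL)
    }
    cbind(sample_id = a$sample_id, a$hits[c("gene_id", "family_id", "bit_score", "e_value", "n")])
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(
      sample_id = character(), gene_id = character(), family_id = character(),
      bit_score = numeric(), e_value = numeric(), n = numeric()
    )
  }
  write_tsv_strict(tab, path)
  totals <- data.frame(
    sample_id = vapply(anns, `[[`, "", "sample_id"),
    total_gene_count = vapply(anns, `[[`, 0, "total_gene_count")
  )
  write_tsv_strict(totals, totals_path)
  invisible(path)
}

#' Read a hit table that carries a multiplicity column
#'
#' Like [read_hit_table()] but honours an optional `n` column of
#' gene-equivalent multiplicities (used for taxonomy-imputed hits, which are
#' materialized as counts rather than replicated rows).
#'
#' @inheritParams read_hit_table
#' @return Named list of `sample_annotation`.
#' @export
read_hit_table_counts <- function(path, totals_path, source_label = c("dna", "imputed")) {
  source_label <- match.arg(source_label)
  hits <- read_tsv_strict(path,
    required = c("sample_id", "gene_id", "family_id", "bit_score", "e_value"),
    numeric_cols = c("bit_score", "e_value", "n")
  )
  if (is.null(hits$n)) hits$n <- rep(1, nrow(hits))
  totals <- read_tsv_strict(totals_path,
    required = c("sample_id", "total_gene_count"),
    numeric_cols = "total_gene_count"
  )
  out <- lapply(seq_len(nrow(totals)), function(i) {
    sid <- totals$sample_id[i]
    h <- hits[hits$sample_id == sid, , drop = FALSE]
    sample_annotation(
      sample_id = sid,
      total_gene_count = totals$total_gene_count[i],
      hits = data.frame(
        gene_id = h$gene_id, family_id = h$family_id,
        bit_score = h$bit_score, e_value = h$e_value,
        source = rep(source_label, nrow(h)), n = h$n,
        stringsAsFactors = FALSE
      )
    )
  })
  names(out) <- totals$sample_id
  out
}

#' Read an OTU-by-sample count table
#'
#' @param path TSV whose first column is `otu_id` and whose remaining columns
#'   are sample counts (nonnegative integers).
#' @return List with `counts` (integer matrix, OTUs x samples), `otu_ids`,
#'   `sample_ids`.
#' @export
read_otu_table <- function(path) {
  df <- read_tsv_strict(path, required = "otu_id")
  sample_ids <- setdiff(names(df), "otu_id")
  if (anyDuplicated(df$otu_id)) stop("duplicate otu_id values", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("duplicate sample columns", call. = FALSE)
  m <- matrix(0L, nrow(df), length(sample_ids),
    dimnames = list(df$otu_id, sample_ids)
  )
  for (s in sample_ids) {
    v <- suppressWarnings(as.numeric(df[[s]]))
    if (anyNA(v)) stop("non-numeric count in column ", s, call. = FALSE)
    if (any(v < 0)) stop("negative count in column ", s, call. = FALSE)
    m[, s] <- as.integer(round(v))
  }
  otu_table(m)
}

#' Construct an OTU table from a count matrix
#'
#' @param counts Nonnegative integer matrix, OTUs in rows, samples in columns,
#'   both dimensions named.
#' @export
otu_table <- function(counts) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)), !is.null(colnames(counts)))
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("row/column labels must be unique", call. = FALSE)
  }
  structure(list(
    counts = counts,
    otu_ids = rownames(counts), sample_ids = colnames(counts)
  ), class = "otu_table")
}

#' @export
write_otu_table <- function(tab, path) {
  df <- data.frame(otu_id = tab$otu_ids, tab$counts, check.names = FALSE)
  write_tsv_strict(df, path)
}

#' Read reference-genome catabolic annotation summaries
#'
#' @param path TSV with columns `genome_id`, `total_genes`, `family_id`,
#'   `count` (one row per genome x family; families absent from a genome are
#'   simply omitted).
#' @return Named list of genome annotations: `genome_id`, `total_genes`,
#'   `family_counts` (named numeric).
#' @export
read_genome_annotations <- function(path) {
  df <- read_tsv_strict(path,
    required = c("genome_id", "total_genes", "family_id", "count"),
    numeric_cols = c("total_genes", "count")
  )
  out <- lapply(split(df, df$genome_id), function(g) {
    fc <- stats::setNames(g$count, g$family_id)
    if (sum(fc) > g$total_genes[1]) {
      stop("genome ", g$genome_id[1], ": family counts exceed total_genes",
        call. = FALSE
      )
    }
    list(
      genome_id = g$genome_id[1], total_genes = g$total_genes[1],
      family_counts = fc
    )
  })
  out[order(names(out))]
}

#' @export
write_genome_annotations <- function(genomes, path) {
  rows <- lapply(genomes, function(g) {
    data.frame(
      genome_id = g$genome_id, total_genes = g$total_genes,
      family_id = names(g$family_counts), count = as.numeric(g$family_counts)
    )
  })
  write_tsv_strict(do.call(rbind, rows), path)
}

#' Read an OTU-to-reference-genome map
#'
#' @param path TSV with columns `otu_id`, `genome_id`, `identity_percent`.
#' @return data.frame; at most one genome per OTU is enforced.
#' @export
read_otu_genome_map <- function(path) {
  df <- read_tsv_strict(path,
    required = c("otu_id", "genome_id", "identity_percent"),
    numeric_cols = "identity_percent"
  )
  if (anyDuplicated(df$otu_id)) stop("an OTU maps to more than one genome", call. = FALSE)
  if (any(df$identity_percent < 0 | df$identity_percent > 100)) {
    stop("identity_percent outside [0,100]", call. = FALSE)
  }
  df
}

#' Read per-sample environmental metadata
#'
#' Expected columns: `sample_id`, `temperature` (deg C), `tph` (mg
#' hydrocarbons per kg sediment), `o2` (mg/L, may be NA), `latitude`,
#' `longitude`; extra columns are carried through untouched.
#'
#' @param path TSV path.
#' @export
read_sample_metadata <- function(path) {
  df <- read_tsv_strict(path,
    required = c("sample_id", "temperature"),
    numeric_cols = c("temperature", "tph", "o2", "latitude", "longitude")
  )
  if (anyNA(df$temperature) || any(!is.finite(df$temperature))) {
    stop("temperature must be finite for every sample", call. = FALSE)
  }
  if (!is.null(df$tph) && any(df$tph < 0, na.rm = TRUE)) {
    stop("tph must be >= 0", call. = FALSE)
  }
  df
}

#' Read metabolite-evidence rows from enrichment validations
#'
#' @param path TSV with columns `sample_id`, `chemical_code`, `status`
#'   (`degraded`/`not_degraded`), `evidence_kind` (`substrate_depleted`/
#'   `intermediate_detected`).
#' @export
read_metabolite_evidence <- function(path) {
  df <- read_tsv_strict(path,
    required = c("sample_id", "chemical_code", "status", "evidence_kind")
  )
  bad <- setdiff(unique(df$status), c("degraded", "not_degraded"))
  if (length(bad) > 0) stop("invalid status value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(df$evidence_kind), c("substrate_depleted", "intermediate_detected"))
  if (length(bad) > 0) stop("invalid evidence_kind value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  df
}

#' Read/write catabolic profiles as a sample x family percentage matrix
#'
#' The TSV carries one row per sample: `sample_id`, `source_mix`,
#' `dna_total_genes`, `imputed_total_genes`, `degp_total`, then one column
#' per family (percent of total genes).
#'
#' @param profiles Named list of `catabolic_profile`.
#' @param path TSV path.
#' @export
write_profiles <- function(profiles, path) {
  fams <- sort(unique(unlist(lapply(profiles, function(p) names(p$family_percent)))))
  rows <- lapply(profiles, function(p) {
    v <- stats::setNames(rep(0, length(fams)), fams)
    v[names(p$family_percent)] <- p$family_percent
    data.frame(
      sample_id = p$sample_id, source_mix = p$source_mix,
      dna_total_genes = p$denominators[["dna"]],
      imputed_total_genes = p$denominators[["imputed"]],
      degp_total = p$degp_total, t(v), check.names = FALSE
    )
  })
  write_tsv_strict(do.call(rbind, rows), path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- read_tsv_strict(path,
    required = c(
      "sample_id", "source_mix", "dna_total_genes",
      "imputed_total_genes", "degp_total"
    ),
    numeric_cols = c("dna_total_genes", "imputed_total_genes", "degp_total")
  )
  fams <- setdiff(names(df), c(
    "sample_id", "source_mix", "dna_total_genes",
    "imputed_total_genes", "degp_total"
  ))
  out <- lapply(seq_len(nrow(df)), function(i) {
    fp <- vapply(fams, function(f) as.numeric(df[[f]][i]), 0)
    denom <- c(dna = df$dna_total_genes[i], imputed = df$imputed_total_genes[i])
    total <- sum(denom)
    structure(list(
      sample_id = df$sample_id[i],
      family_percent = fp,
      family_counts = fp / 100 * total,
      degp_total = df$degp_total[i],
      source_mix = df$source_mix[i],
      denominators = denom
    ), class = "catabolic_profile")
  })
  names(out) <- df$sample_id
  out
}
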