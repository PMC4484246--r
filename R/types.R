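# Core value types. Deliberately light-weight S3: lists + data.frames,
# validated at construction, in the style of vegan/ape rather than S4.

CLASS_TAGS <- c(
  "alkane", "monoaromatic", "polyaromatic",
  "ring_cleavage_extradiol", "ring_cleavage_intradiol", "other"
)

#' Construct a per-sample gene annotation
#'
#' Bundles a sample's predicted-gene total with its catabolic-family hit
#' rows. Each hit row carries a `bit_score`, an `e_value`, a `source`
#' (`"dna"` for metagenome-derived, `"imputed"` for 16S-derived) and a
#' multiplicity `n` (gene-equivalents; 1 for real annotation rows, possibly
#' large for taxonomy-imputed content).
#'
#' @param sample_id Sample token.
#' @param total_gene_count Number of predicted protein-coding genes in the
#'   sample (the denominator for all relative abundances).
#' @param hits data.frame with columns `gene_id`, `family_id`, `bit_score`,
#'   `e_value`, `source`, `n`.
#' @return Object of class `sample_annotation`.
#' @export
sample_annotation <- function(sample_id, total_gene_count, hits = empty_hits()) {
  stopifnot(is.character(sample_id), length(sample_id) == 1)
  if (is.na(total_gene_count) || total_gene_count < 0) {
    stop("total_gene_count must be a nonnegative number", call. = FALSE)
  }
  needed <- c("gene_id", "family_id", "bit_score", "e_value", "source", "n")
  missing <- setdiff(needed, names(hits))
  if (length(missing) > 0) {
    stop("hits is missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(hits$source), c("dna", "imputed"))
  if (length(bad) > 0) stop("invalid hit source: ", paste(bad, collapse = ", "), call. = FALSE)
  neg <- which(hits$e_value < 0)
  if (length(neg) > 0) {
    stop("negative e-value for gene ", hits$gene_id[neg[1]], call. = FALSE)
  }
  dna_equiv <- sum(hits$n[hits$source == "dna"])
  if (dna_equiv > total_gene_count) {
    stop(
      "sample ", sample_id, ": more DNA hits (", dna_equiv,
      ") than total genes (", total_gene_count, ")",
      call. = FALSE
    )
  }
  structure(list(
    sample_id = sample_id,
    total_gene_count = total_gene_count,
    hits = hits[needed]
  ), class = "sample_annotation")
}

empty_hits <- function() {
  data.frame(
    gene_id = character(), family_id = character(),
    bit_score = numeric(), e_value = numeric(),
    source = character(), n = numeric(),
    stringsAsFactors = FALSE
  )
}

#' @export
print.sample_annotation <- function(x, ...) {
  cat(sprintf(
    "<sample_annotation> %s: %d hit rows (%.0f gene-equivalents) / %g total genes\n",
    x$sample_id, nrow(x$hits), sum(x$hits$n), x$total_gene_count
  ))
  invisible(x)
}

#' Read a reaction catalog
#'
#' A catalog names the catabolic gene families screened for (with a pathway
#' class tag) and the substrate -> product reaction each family mediates,
#' using opaque 3-character chemical codes (e.g. catechol "CAT" -> ring
#' fission product "124"). Families are deduplicated; reactions are
#' validated against the family list.
#'
#' @param path TSV with columns `family_id`, `class_tag`, `substrate_code`,
#'   `substrate_name`, `product_code`, `product_name` (one row per reaction;
#'   `description` optional).
#' @return Object of class `deg_catalog`: list with `families` and
#'   `reactions` data.frames.
#' @export
read_catalog <- function(path) {
  df <- read_tsv_strict(path, required = c(
    "family_id", "class_tag", "substrate_code", "substrate_name",
    "product_code", "product_name"
  ))
  if (is.null(df$description)) df$description <- rep("", nrow(df))
  deg_catalog(
    families = unique(df[c("family_id", "description", "class_tag")]),
    reactions = df[c(
      "family_id", "substrate_code", "substrate_name",
      "product_code", "product_name"
    )]
  )
}

#' Construct a validated reaction catalog
#'
#' @param families data.frame with `family_id`, `description`, `class_tag`.
#' @param reactions data.frame with `family_id`, `substrate_code`,
#'   `substrate_name`, `product_code`, `product_name`.
#' @export
deg_catalog <- function(families, reactions) {
  families <- unique(families)
  if (anyDuplicated(families$family_id)) {
    dup <- families$family_id[duplicated(families$family_id)]
    stop("family_id not unique: ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(families$class_tag), CLASS_TAGS)
  if (length(bad) > 0) {
    stop("class_tag not in the closed set: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(reactions$family_id, families$family_id)
  if (length(unknown) > 0) {
    stop("reaction references unknown family: ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  same <- reactions$substrate_code == reactions$product_code
  if (any(same)) {
    stop("substrate_code equals product_code for family ",
      paste(reactions$family_id[same], collapse = ", "),
      call. = FALSE
    )
  }
  key <- paste(reactions$family_id, reactions$substrate_code, reactions$product_code)
  if (anyDuplicated(key)) {
    stop("duplicate (family, substrate, product) reaction: ",
      key[duplicated(key)][1],
      call. = FALSE
    )
  }
  rownames(families) <- NULL
  rownames(reactions) <- NULL
  structure(list(families = families, reactions = reactions), class = "deg_catalog")
}

#' @export
print.deg_catalog <- function(x, ...) {
  cat(sprintf(
    "<deg_catalog> %d families, %d reactions, %d chemical codes\n",
    nrow(x$families), nrow(x$reactions),
    length(unique(c(x$reactions$substrate_code, x$reactions$product_code)))
  ))
  invisible(x)
}

#' @export
write_catalog <- function(catalog, path) {
  fam <- catalog$families
  df <- merge(catalog$reactions, fam, by = "family_id", sort = FALSE)
  write_tsv_strict(df[c(
    "family_id", "class_tag", "description", "substrate_code",
    "substrate_name", "product_code", "product_name"
  )], path)
}

#' Built-in desk-scale reaction catalog
#'
#' A compact catalog of well-known hydrocarbon-degradation gene families and
#' the reactions they mediate: alkane hydroxylation (AlkB, P450), aromatic
#' ring activation (Ndo, Bph, Ben, PhO, OphA, IphA), the salicylate branch
#' point (Sal1 to catechol vs NahGH to gentisate), and ring cleavage
#' (extradiol XylE, intradiol CatA, protocatechuate 3,4- and
#' 4,5-dioxygenases). Chemical codes are opaque 3-character tokens; numeric
#' codes follow the convention for ring-fission products (catechol -> "124"
#' extradiol / "109" intradiol, protocatechuate -> "104" / "099", biphenyl
#' dihydrodiol "051").
#'
#' @return A `deg_catalog`.
#' @export
default_catalog <- function() {
  r <- function(fam, tag, sc, sn, pc, pn) {
    data.frame(
      family_id = fam, class_tag = tag, substrate_code = sc,
      substrate_name = sn, product_code = pc, product_name = pn
    )
  }
  rx <- rbind(
    r("AlkB", "alkane", "ALK", "n-alkanes", "FAL", "fatty alcohols"),
    r("P450", "alkane", "ALK", "n-alkanes", "FAL", "fatty alcohols"),
    r("FaH", "alkane", "FAL", "fatty alcohols", "FAC", "fatty acids"),
    r("Ndo", "polyaromatic", "NAP", "naphthalene", "SAL", "salicylate"),
    r("PhdA", "polyaromatic", "PHN", "phenanthrene", "HNA", "1-hydroxy-2-naphthoate"),
    r("Dfd", "polyaromatic", "DBF", "dibenzofuran", "SAL", "salicylate"),
    r("Sal1", "monoaromatic", "SAL", "salicylate", "CAT", "catechol"),
    r("NahGH", "monoaromatic", "SAL", "salicylate", "GEN", "gentisate"),
    r("PhO", "monoaromatic", "PHE", "phenol", "CAT", "catechol"),
    r("Ben", "monoaromatic", "BEN", "benzoate", "CAT", "catechol"),
    r("Bph", "monoaromatic", "BPH", "biphenyl", "051", "biphenyl-2,3-diol"),
    r("BphC", "ring_cleavage_extradiol", "051", "biphenyl-2,3-diol", "CAT", "catechol"),
    r("OphA", "monoaromatic", "PHT", "phthalate", "PCA", "protocatechuate"),
    r("IphA", "monoaromatic", "IPH", "isophthalate", "PCA", "protocatechuate"),
    r("PobA", "monoaromatic", "4HB", "4-hydroxybenzoate", "PCA", "protocatechuate"),
    r("XylE", "ring_cleavage_extradiol", "CAT", "catechol", "124", "2-hydroxy-6-oxohexa-2,4-dienoate"),
    r("CatA", "ring_cleavage_intradiol", "CAT", "catechol", "109", "cis,cis-muconate"),
    r("PcaHG", "ring_cleavage_intradiol", "PCA", "protocatechuate", "104", "3-carboxy-cis,cis-muconate"),
    r("LigAB", "ring_cleavage_extradiol", "PCA", "protocatechuate", "099", "2-hydroxy-4-carboxymuconate semialdehyde"),
    r("GtdA", "ring_cleavage_extradiol", "GEN", "gentisate", "MAL", "maleylpyruvate")
  )
  fams <- unique(rx[c("family_id", "class_tag")])
  fams$description <- fams$family_id
  deg_catalog(fams[c("family_id", "description", "class_tag")], rx[c(
    "family_id", "substrate_code", "substrate_name", "product_code", "product_name"
  )])
}
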