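# Synthetic-study generator. Emulates a multi-site polluted-sediment survey
# with planted, recoverable structure: a linear temperature -> DEGgp
# relationship, richness decreasing with temperature, two-cluster community
# composition, and a known gene-count -> degradation-probability curve
# behind the metabolite evidence.

# run code under a private RNG stream without touching global state
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister")
  force(code)
}

eval_curve <- function(curve, k) {
  idx <- pmin(pmax(floor(k), 0), length(curve) - 1) + 1
  as.numeric(curve[idx])
}

#' Describe a synthetic study design
#'
#' Defaults mirror the desk-scale world the package validates against:
#' 8 samples evenly spaced over 13.0-26.5 degrees C, with the planted DEGgp
#' line running from 1.8% at the cold end to 4.21% at the warm end
#' (slope 0.17852 %/degC, intercept -0.52074%). The noise SD (0.45%) was
#' calibrated once by Monte-Carlo so that the DEGgp~temperature OLS r^2
#' averages ~0.8 over replicate studies. Richness decreases with
#' temperature; community compositions come from two cluster centroids
#' separated by `cluster_gap`; metabolite evidence is drawn from
#' `confidence_curve` evaluated at each sample's per-chemical gene count.
#'
#' @param n_samples Number of samples (>= 4).
#' @param temperature_range `c(t_min, t_max)` in degrees C.
#' @param degp_slope Planted DEGgp slope, percent per degree C.
#' @param degp_intercept Planted DEGgp intercept, percent.
#' @param degp_noise_sd SD of per-sample Gaussian noise on DEGgp, percent.
#' @param richness_slope OTUs per degree C (negative).
#' @param richness_max Richness at the coldest site.
#' @param cluster_gap Effect size separating the two community centroids
#'   (log-abundance units; ARI-1.0 recovery holds for `cluster_gap >= 1`).
#' @param genes_per_sample Predicted protein-coding genes per sample (the
#'   DEGgp denominator; planted DEGgp values are quantized to integer hit
#'   counts out of this total).
#' @param otu_pool Size of the shared OTU pool.
#' @param sequencing_depth Reads per sample for the OTU count table.
#' @param confidence_curve Named numeric over gene counts k = 0, 1, ...:
#'   true degradation probability; must be non-decreasing in `[0, 1]`.
#' @param evidence_replicates Evidence rows per (sample, chemical).
#' @param seed Integer seed; all randomness flows from it.
#' @return A `study_design` list.
#' @export
study_design <- function(n_samples = 8,
                         temperature_range = c(13, 26.5),
                         degp_slope = 0.17852,
                         degp_intercept = -0.52074,
                         degp_noise_sd = 0.45,
                         richness_slope = -4,
                         richness_max = 120,
                         cluster_gap = 2,
                         genes_per_sample = 20000,
                         otu_pool = 240,
                         sequencing_depth = 20000,
                         confidence_curve = stats::setNames(
                           stats::plogis(-2 + 1.2 * (0:8)), 0:8
                         ),
                         evidence_replicates = 1,
                         seed = 1) {
  if (n_samples < 4) stop("n_samples must be >= 4", call. = FALSE)
  if (temperature_range[1] >= temperature_range[2]) {
    stop("temperature_range must satisfy t_min < t_max", call. = FALSE)
  }
  if (any(diff(confidence_curve) < 0) ||
    any(confidence_curve < 0 | confidence_curve > 1)) {
    stop("confidence_curve must be non-decreasing within [0,1]", call. = FALSE)
  }
  temps <- seq(temperature_range[1], temperature_range[2], length.out = n_samples)
  line <- degp_intercept + degp_slope * temps
  if (any(line <= 0 | line >= 100)) {
    stop("design implies DEGgp <= 0 or >= 100 for some sample", call. = FALSE)
  }
  rich <- round(richness_max + richness_slope * (temps - temperature_range[1]))
  if (any(rich < 2) || any(rich > otu_pool)) {
    stop("richness outside [2, otu_pool] for some sample", call. = FALSE)
  }
  structure(as.list(environment()), class = "study_design")
}

# fixed family mix for planted catabolic hits; ratios echo the field's
# typical over-representation of alkane hydroxylases and extradiol cleavage
family_mix <- function(catalog) {
  w <- c(
    AlkB = 7.93, P450 = 1, FaH = 0.8, Ndo = 0.45, PhdA = 0.45, Dfd = 0.45,
    Sal1 = 0.5, NahGH = 0.9, PhO = 0.6, Ben = 0.6, Bph = 0.5, BphC = 0.4,
    OphA = 0.7, IphA = 0.4, PobA = 0.4, XylE = 5.93, CatA = 0.3,
    PcaHG = 0.5, LigAB = 0.8, GtdA = 0.5
  )
  fams <- catalog$families$family_id
  out <- w[intersect(names(w), fams)]
  extra <- setdiff(fams, names(out))
  if (length(extra) > 0) out <- c(out, stats::setNames(rep(0.5, length(extra)), extra))
  out / sum(out)
}

#' Generate a complete synthetic study
#'
#' Produces every input the pipeline consumes — gene annotations (with
#' decoy hits that fail screening), OTU table, reference-genome annotations,
#' OTU-genome map, sample metadata, metabolite evidence — plus the planted
#' truth needed for recovery testing. Byte-identical for a fixed seed.
#'
#' @param design A [study_design()].
#' @param catalog Reaction catalog; defaults to [default_catalog()].
#' @return A `synthetic_study` list: `annotations` (named list of
#'   `sample_annotation`, decoys included), `otus`, `genomes`, `otu_map`,
#'   `metadata`, `evidence`, `catalog`, `design` and `truth`
#'   (`degp_line`, `degp_true` quantized, `cluster`, `otu_probs`,
#'   `degraded_prob`, `degraded`).
#' @export
generate_study <- function(design = study_design(), catalog = default_catalog()) {
  stopifnot(inherits(design, "study_design"))
  with_local_seed(design$seed, {
    n <- design$n_samples
    ids <- sprintf("S%02d", seq_len(n))
    temps <- design$temps
    degp <- design$line + stats::rnorm(n, 0, design$degp_noise_sd)
    if (any(degp <= 0 | degp >= 100)) {
      stop("noise draw pushed DEGgp outside (0, 100); lower degp_noise_sd",
        call. = FALSE
      )
    }
    k_hits <- round(degp / 100 * design$genes_per_sample)
    degp_true <- 100 * k_hits / design$genes_per_sample
    mix <- family_mix(catalog)

    annotations <- list()
    for (i in seq_len(n)) {
      fam_counts <- stats::rmultinom(1, k_hits[i], mix)[, 1]
      fam <- rep(names(fam_counts), fam_counts)
      n_true <- length(fam)
      n_decoy <- round(0.1 * n_true)
      decoy_fam <- sample(names(mix), n_decoy, replace = TRUE)
      half <- n_decoy %/% 2
      hits <- data.frame(
        gene_id = sprintf("%s_g%05d", ids[i], seq_len(n_true + n_decoy)),
        family_id = c(fam, decoy_fam),
        bit_score = c(
          stats::runif(n_true, 50, 300),
          stats::runif(half, 5, 45), # decoys: fail the score screen
          stats::runif(n_decoy - half, 50, 300)
        ),
        e_value = c(
          10^stats::runif(n_true, -30, -5),
          10^stats::runif(half, -30, -5),
          10^stats::runif(n_decoy - half, -2.9, -1) # decoys: fail the e-value screen
        ),
        source = "dna",
        n = 1,
        stringsAsFactors = FALSE
      )
      annotations[[ids[i]]] <- sample_annotation(
        ids[i], design$genes_per_sample, hits
      )
    }

    # community structure: shared log-normal rank-abundance base, two
    # centroids pushed apart by cluster_gap along a fixed random direction
    pool <- sprintf("OTU%04d", seq_len(design$otu_pool))
    base <- sort(stats::rnorm(design$otu_pool, 0, 1), decreasing = TRUE)
    direction <- stats::rnorm(design$otu_pool, 0, 1)
    centroid <- rbind(
      base + design$cluster_gap / 2 * direction,
      base - design$cluster_gap / 2 * direction
    )
    cluster <- ifelse(temps <= mean(design$temperature_range), 1L, 2L)
    counts <- matrix(0L, design$otu_pool, n, dimnames = list(pool, ids))
    otu_probs <- matrix(0, design$otu_pool, n, dimnames = list(pool, ids))
    for (i in seq_len(n)) {
      logw <- centroid[cluster[i], ] + stats::rnorm(design$otu_pool, 0, 0.3)
      keep <- rank(-logw, ties.method = "first") <= design$rich[i]
      p <- ifelse(keep, exp(logw), 0)
      p <- p / sum(p)
      otu_probs[, i] <- p
      counts[, i] <- stats::rmultinom(1, design$sequencing_depth, p)[, 1]
    }
    otus <- otu_table(counts)

    # reference genomes + OTU affiliations for the imputation route
    fams <- catalog$families$family_id
    genomes <- lapply(seq_len(6), function(g) {
      fc <- stats::rpois(length(fams), 0.8)
      names(fc) <- fams
      list(
        genome_id = sprintf("genome%02d", g), total_genes = 3000,
        family_counts = fc[fc > 0]
      )
    })
    names(genomes) <- vapply(genomes, `[[`, "", "genome_id")
    mapped <- sample(pool, round(0.8 * length(pool)))
    otu_map <- data.frame(
      otu_id = mapped,
      genome_id = sample(names(genomes), length(mapped), replace = TRUE),
      identity_percent = stats::runif(length(mapped), 97, 100)
    )

    metadata <- data.frame(
      sample_id = ids,
      temperature = temps,
      tph = round(10^stats::runif(n, 2.1, 5.4)),
      o2 = ifelse(stats::runif(n) < 0.2, NA, round(stats::runif(n, 0, 22), 1)),
      latitude = round(stats::runif(n, 29, 44), 4),
      longitude = round(stats::runif(n, -6, 36), 4)
    )

    # metabolite evidence drawn from the planted confidence curve at each
    # sample's screened gene count per chemical
    screened <- screen_hits(annotations)
    gc_tab <- chemical_gene_counts(screened, catalog)
    reps <- design$evidence_replicates
    ev_rows <- gc_tab[rep(seq_len(nrow(gc_tab)), each = reps), , drop = FALSE]
    p_deg <- eval_curve(design$confidence_curve, ev_rows$k)
    degraded <- stats::runif(nrow(ev_rows)) < p_deg
    evidence <- data.frame(
      sample_id = ev_rows$sample_id,
      chemical_code = ev_rows$chemical_code,
      status = ifelse(degraded, "degraded", "not_degraded"),
      evidence_kind = sample(c("substrate_depleted", "intermediate_detected"),
        nrow(ev_rows),
        replace = TRUE
      ),
      row.names = NULL
    )

    structure(list(
      annotations = annotations,
      otus = otus,
      genomes = genomes,
      otu_map = otu_map,
      metadata = metadata,
      evidence = evidence,
      catalog = catalog,
      design = design,
      truth = list(
        sample_ids = ids,
        temperature = temps,
        degp_line = design$line,
        degp_true = degp_true,
        cluster = cluster,
        otu_probs = otu_probs,
        gene_counts = gc_tab,
        degraded_prob = p_deg,
        degraded = degraded,
        confidence_curve = design$confidence_curve
      )
    ), class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> %d samples, %d OTUs, %d evidence rows (seed %d)\n",
    length(x$annotations), length(x$otus$otu_ids), nrow(x$evidence),
    x$design$seed
  ))
  invisible(x)
}

#' Generate a synthetic LC-MS feature matrix with planted signal
#'
#' `n_signal` features get a between-group mean shift of `shift_sd` standard
#' deviations and full within-group presence; the remaining features are
#' null, with random dropout (zeros) at rate `dropout`.
#'
#' @param n_features Total features.
#' @param groups Group label per replicate column (two groups, >= 2
#'   replicates each).
#' @param n_signal Number of features with planted signal
#'   (`<= n_features`).
#' @param seed Integer seed.
#' @param shift_sd Planted shift in within-group SD units. Default 3.
#' @param dropout Dropout probability for null features. Default 0.3.
#' @return List: `matrix` (features x replicates), `signal` (logical truth
#'   per feature).
#' @export
generate_mass_features <- function(n_features, groups, n_signal, seed,
                                   shift_sd = 3, dropout = 0.3) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required", call. = FALSE)
  if (any(table(groups) < 2)) stop("each group needs at least 2 replicates", call. = FALSE)
  if (n_signal > n_features) stop("n_signal must be <= n_features", call. = FALSE)
  with_local_seed(seed, {
    m <- length(groups)
    base_sd <- 10
    mat <- matrix(stats::rnorm(n_features * m, 100, base_sd), n_features, m)
    signal <- seq_len(n_features) <= n_signal
    g2 <- groups == levels(groups)[2]
    mat[signal, g2] <- mat[signal, g2] + shift_sd * base_sd
    drop_mask <- matrix(stats::runif(n_features * m) < dropout, n_features, m)
    drop_mask[signal, ] <- FALSE # planted features are always detected
    mat[drop_mask] <- 0
    mat[mat < 0] <- 0
    rownames(mat) <- sprintf("m%05d", seq_len(n_features))
    colnames(mat) <- sprintf("%s_r%d", groups, stats::ave(seq_len(m), groups, FUN = seq_along))
    list(matrix = mat, signal = signal)
  })
}

#' Write every artifact of a synthetic study to a directory
#'
#' Emits the full set of pipeline inputs in the package's TSV formats plus
#' `truth.json`: `hits.tsv` + `totals.tsv`, `otus.tsv`, `genomes.tsv`,
#' `otu_map.tsv`, `metadata.tsv`, `evidence.tsv`, `catalog.tsv`.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_hit_table(study$annotations, p("hits.tsv"), p("totals.tsv"))
  write_otu_table(study$otus, p("otus.tsv"))
  write_genome_annotations(study$genomes, p("genomes.tsv"))
  write_tsv_strict(study$otu_map, p("otu_map.tsv"))
  write_tsv_strict(study$metadata, p("metadata.tsv"))
  write_tsv_strict(study$evidence, p("evidence.tsv"))
  write_catalog(study$catalog, p("catalog.tsv"))
  truth <- study$truth
  truth$otu_probs <- NULL # large; regenerate from the seed when needed
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
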