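# Shared fixtures (built in code) and independent oracles. Oracles stay
# deliberately naive - loops, set comprehensions, textbook formulas - and
# never call the code paths they check.

toy_catalog <- function() {
  deg_catalog(
    families = data.frame(
      family_id = c("XylE", "CatA", "AlkB", "Sal1"),
      description = c("catechol 2,3-dioxygenase", "catechol 1,2-dioxygenase",
                      "alkane hydroxylase", "salicylate 1-hydroxylase"),
      class_tag = c("ring_cleavage_extradiol", "ring_cleavage_intradiol",
                    "alkane", "monoaromatic")
    ),
    reactions = data.frame(
      family_id = c("XylE", "CatA", "AlkB", "Sal1"),
      substrate_code = c("CAT", "CAT", "ALK", "SAL"),
      substrate_name = c("catechol", "catechol", "n-alkanes", "salicylate"),
      product_code = c("124", "109", "FAL", "CAT"),
      product_name = c("2-hydroxy-6-oxohexa-2,4-dienoate", "cis,cis-muconate",
                       "fatty alcohols", "catechol")
    )
  )
}

toy_hits <- function(family_id, bit_score, e_value, source = "dna", n = 1) {
  m <- length(family_id)
  data.frame(
    gene_id = sprintf("g%03d", seq_len(m)),
    family_id = family_id,
    bit_score = rep_len(bit_score, m),
    e_value = rep_len(e_value, m),
    source = rep_len(source, m),
    n = rep_len(n, m),
    stringsAsFactors = FALSE
  )
}

random_annotation <- function(sample_id, n_hits, total = 10000,
                              families = c("XylE", "CatA", "AlkB", "Sal1")) {
  sample_annotation(
    sample_id, total,
    toy_hits(
      family_id = sample(families, n_hits, replace = TRUE),
      bit_score = stats::runif(n_hits, 10, 300),
      e_value = 10^stats::runif(n_hits, -30, 0)
    )
  )
}

# independent unweighted/weighted pool-adjacent-violators, recursive form
oracle_pava <- function(y, w = rep(1, length(y))) {
  if (length(y) <= 1) return(y)
  for (i in seq_len(length(y) - 1)) {
    if (y[i] > y[i + 1]) {
      pooled <- sum(w[i:(i + 1)] * y[i:(i + 1)]) / sum(w[i:(i + 1)])
      y2 <- c(y[seq_len(i - 1)], pooled, y[-seq_len(i + 1)])
      w2 <- c(w[seq_len(i - 1)], sum(w[i:(i + 1)]), w[-seq_len(i + 1)])
      fit <- oracle_pava(y2, w2)
      return(c(fit[seq_len(i)], fit[i], fit[-seq_len(i)])[seq_along(y)])
    }
  }
  y
}

# textbook Welch two-sample t-test
oracle_welch <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# normal-equations simple OLS with slope t-test
oracle_ols <- function(y, x) {
  n <- length(y)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  sse <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  se <- sqrt(sse / (n - 2) / sxx)
  t <- slope / se
  list(
    slope = slope, intercept = intercept, r2 = 1 - sse / sst,
    se = se, p = 2 * stats::pt(-abs(t), n - 2)
  )
}

# transitive closure by boolean matrix powers; reachable set from sources
oracle_reachable <- function(edges_from, edges_to, nodes, sources) {
  n <- length(nodes)
  a <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  a[cbind(edges_from, edges_to)] <- TRUE
  reach <- a
  for (i in seq_len(n)) reach <- reach | (reach %*% a > 0)
  hit <- rep(FALSE, n)
  for (s in sources) hit <- hit | reach[s, ]
  sort(nodes[hit])
}

# orthogonal Procrustes residual (rotation/reflection + translation only)
procrustes_error <- function(x, y) {
  x <- scale(x, scale = FALSE)
  y <- scale(y, scale = FALSE)
  s <- svd(t(y) %*% x)
  rot <- s$u %*% t(s$v)
  max(abs(y %*% rot - x))
}

# elementwise Bray-Curtis
oracle_bray <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
    }
  }
  d
}
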