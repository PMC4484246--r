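# Network reconstruction, confidence calibration, degradable sets,
# reachability, network comparison.

test_that("build_network wires one edge per supported reaction with per-sample weights", {
  cat <- toy_catalog()
  p <- catabolic_profile(
    sample_annotation("A", 10000, toy_hits("XylE", 100, 1e-9, n = 5))
  )
  net <- build_network(list(A = p), cat)
  expect_equal(sort(net$nodes), c("124", "CAT"))
  expect_equal(nrow(net$edges), 1)
  expect_equal(unname(net$weights[1, "A"]), 0.05)

  # all-zero profiles give the empty network
  p0 <- catabolic_profile(sample_annotation("A", 100))
  net0 <- build_network(list(A = p0), cat)
  expect_equal(nrow(net0$edges), 0)
  expect_length(net0$nodes, 0)

  bad <- p
  names(bad$family_percent) <- "NotAFamily"
  expect_error(build_network(list(A = bad), cat), "NotAFamily")
})

test_that("node and edge sets equal a set-comprehension oracle on random instances", {
  set.seed(12)
  fams <- sprintf("F%02d", 1:20)
  codes <- sprintf("C%02d", 1:25)
  rx <- unique(data.frame(
    family_id = sample(fams, 40, replace = TRUE),
    substrate_code = sample(codes, 40, replace = TRUE),
    product_code = sample(codes, 40, replace = TRUE)
  ))
  rx <- rx[rx$substrate_code != rx$product_code, ]
  catalog <- deg_catalog(
    data.frame(family_id = fams, description = "", class_tag = "other"),
    data.frame(rx[c("family_id", "substrate_code")],
      substrate_name = "s", product_code = rx$product_code, product_name = "p")
  )
  profiles <- lapply(sprintf("s%d", 1:6), function(s) {
    n_hit <- rpois(1, 30)
    catabolic_profile(screen_hits(random_annotation(s, n_hit, families = fams)))
  })
  names(profiles) <- sprintf("s%d", 1:6)
  net <- build_network(profiles, catalog)

  # oracle: comprehension over reactions x samples
  pct <- function(p, f) if (f %in% names(p$family_percent)) p$family_percent[[f]] else 0
  exp_edges <- character(0)
  for (i in seq_len(nrow(catalog$reactions))) {
    f <- catalog$reactions$family_id[i]
    if (any(vapply(profiles, pct, 0, f = f) > 0)) {
      exp_edges <- c(exp_edges, paste(
        catalog$reactions$substrate_code[i],
        catalog$reactions$product_code[i], f
      ))
    }
  }
  got_edges <- paste(net$edges$substrate_code, net$edges$product_code, net$edges$family_id)
  expect_setequal(got_edges, exp_edges)
  exp_nodes <- unique(unlist(strsplit(exp_edges, " "))[c(TRUE, TRUE, FALSE)])
  expect_setequal(net$nodes, exp_nodes)
  # weights: each edge carries its family's full percentage in each sample
  for (j in seq_along(profiles)) {
    expect_equal(
      unname(net$weights[, j]),
      vapply(net$edges$family_id, pct, 0, p = profiles[[j]]),
      ignore_attr = TRUE
    )
  }
})

test_that("confidence fit: smoothing limit, PAVA oracle, monotonicity", {
  # every row degraded at one count: conf(k) = (n+1)/(n+2) everywhere
  n <- 18
  ev <- data.frame(
    sample_id = sprintf("s%02d", 1:n), chemical_code = "CAT",
    status = "degraded", evidence_kind = "substrate_depleted"
  )
  gc <- data.frame(sample_id = ev$sample_id, chemical_code = "CAT", k = 3)
  m <- fit_confidence(ev, gc)
  expect_equal(unname(m$curves$CAT), rep((n + 1) / (n + 2), 4))

  # weighted PAVA equals the independent recursive oracle
  set.seed(13)
  for (rep in 1:20) {
    y <- runif(8)
    w <- sample(1:5, 8, replace = TRUE)
    expect_equal(degnet:::pava(y, w), oracle_pava(y, w), tolerance = 1e-12)
  }
  # and the unweighted case matches stats::isoreg
  y <- runif(15)
  expect_equal(degnet:::pava(y), isoreg(y)$yf, tolerance = 1e-12)

  # spec's raw-proportion example: (0.9, 0.7, 0.95) -> (0.8, 0.8, 0.95)
  expect_equal(degnet:::pava(c(0.9, 0.7, 0.95)), c(0.8, 0.8, 0.95))

  # monotone non-decreasing on every fitted curve, random evidence
  ev2 <- data.frame(
    sample_id = rep(sprintf("s%d", 1:40), each = 2),
    chemical_code = rep(c("CAT", "ALK"), 40),
    status = sample(c("degraded", "not_degraded"), 80, replace = TRUE),
    evidence_kind = "substrate_depleted"
  )
  gc2 <- data.frame(
    sample_id = ev2$sample_id, chemical_code = ev2$chemical_code,
    k = sample(0:6, 80, replace = TRUE)
  )
  m2 <- fit_confidence(unique(ev2), unique(gc2))
  for (cv in c(m2$curves, list(m2$global))) {
    expect_true(all(diff(cv) >= -1e-12))
    expect_true(all(cv >= 0 & cv <= 1))
  }
})

test_that("planted logistic curve is recovered within 0.1 sup-norm", {
  set.seed(14)
  curve <- plogis(-2 + 1.2 * (0:8))
  n <- 2000
  k <- sample(0:8, n, replace = TRUE)
  status <- ifelse(runif(n) < curve[k + 1], "degraded", "not_degraded")
  ev <- data.frame(
    sample_id = sprintf("r%04d", 1:n), chemical_code = "CAT",
    status = status, evidence_kind = "substrate_depleted"
  )
  gc <- data.frame(sample_id = ev$sample_id, chemical_code = "CAT", k = k)
  m <- fit_confidence(ev, gc)
  expect_lt(max(abs(m$curves$CAT - curve)), 0.1)
})

test_that("degradable set honours the closed >= 0.90 bound and edge requirement", {
  cat <- toy_catalog()
  profs <- list(
    A = catabolic_profile(sample_annotation("A", 1000, toy_hits("XylE", 100, 1e-9, n = 2)))
  )
  net <- build_network(profs, cat)
  model <- structure(list(
    curves = list(CAT = setNames(c(0.5, 0.9), 0:1)),
    support = c(CAT = 10), global = setNames(c(0.2, 0.2), 0:1),
    k_max = 1, threshold = 0.9, conditioning = "exact"
  ), class = "confidence_model")

  gc <- data.frame(sample_id = "A", chemical_code = "CAT", k = c(1))
  ds <- degradable_set(net, model, gc)
  expect_equal(ds$per_sample$A, "CAT") # conf exactly 0.90 -> included

  gc0 <- data.frame(sample_id = "A", chemical_code = "CAT", k = 0)
  expect_length(degradable_set(net, model, gc0)$per_sample$A, 0) # conf(0)=0.5 < 0.9

  # no outgoing edge in the sample excludes even confident chemicals
  gc_alk <- data.frame(sample_id = "A", chemical_code = c("CAT", "ALK"), k = 1)
  ds2 <- degradable_set(net, model, gc_alk)
  expect_false("ALK" %in% ds2$per_sample$A)
})

test_that("degradable set equals per-chemical re-evaluation and is monotone in threshold", {
  set.seed(15)
  st <- generate_study(study_design(seed = 3, evidence_replicates = 2))
  scr <- screen_hits(st$annotations)
  counts <- chemical_gene_counts(scr, st$catalog)
  model <- fit_confidence(st$evidence, counts, st$catalog, k_cap = 8)
  net <- build_network(catabolic_profile(scr), st$catalog)

  ds <- degradable_set(net, model, counts, threshold = 0.8)
  for (s in net$samples) {
    for (ch in unique(counts$chemical_code)) {
      k <- counts$k[counts$sample_id == s & counts$chemical_code == ch]
      has_edge <- any(net$edges$substrate_code == ch & net$weights[, s] > 0)
      in_set <- ch %in% ds$per_sample[[s]]
      expect_identical(
        in_set,
        has_edge && confidence_at(model, ch, k) >= 0.8,
        info = paste(s, ch)
      )
    }
  }
  # lowering the threshold never shrinks any per-sample set
  thresholds <- c(0.95, 0.9, 0.7, 0.5, 0.2)
  sets <- lapply(thresholds, function(th) degradable_set(net, model, counts, th))
  for (i in seq_len(length(sets) - 1)) {
    for (s in net$samples) {
      expect_true(all(sets[[i]]$per_sample[[s]] %in% sets[[i + 1]]$per_sample[[s]]))
    }
  }
})

test_that("reachability: chains, weight-zero breaks, random DAG vs closure oracle", {
  edges <- data.frame(
    substrate_code = c("a", "b"), product_code = c("b", "c"),
    family_id = c("F1", "F2")
  )
  w <- matrix(c(1, 1, 1, 0), 2, 2, dimnames = list(NULL, c("s1", "s2")))
  net <- meta_network(edges, w)
  expect_equal(reachable_products(net, "s1", "a"), c("b", "c"))
  expect_equal(reachable_products(net, "s2", "a"), "b") # a->b only; b->c has weight 0
  expect_error(reachable_products(net, "s1", "zzz"), "unknown source")

  set.seed(16)
  nodes <- sprintf("n%02d", 1:30)
  from_i <- sample(1:29, 60, replace = TRUE)
  to_i <- pmin(from_i + sample(1:5, 60, replace = TRUE), 30) # forward edges: a DAG
  keep <- from_i != to_i
  edges2 <- unique(data.frame(
    substrate_code = nodes[from_i[keep]], product_code = nodes[to_i[keep]],
    family_id = "F"
  ))
  net2 <- meta_network(edges2, matrix(1, nrow(edges2), 1, dimnames = list(NULL, "s")))
  src <- sample(nodes[1:5], 2)
  expect_equal(
    reachable_products(net2, "s", src),
    setdiff(oracle_reachable(edges2$substrate_code, edges2$product_code, nodes, src),
      character(0))
  )
})

test_that("network comparison mirrors the missing-family contrast", {
  cat <- toy_catalog()
  mk <- function(fams, n, sid) {
    build_network(list(catabolic_profile(
      sample_annotation(sid, 1000, toy_hits(fams, 100, 1e-9, n = n))
    )), cat)
  }
  a <- mk(c("XylE", "AlkB"), c(4, 6), "OV011")
  b <- mk(c("XylE", "AlkB"), c(4, 6), "OV011")
  cmp <- compare_networks(a, b)
  expect_equal(nrow(cmp$only_a), 0)
  expect_equal(nrow(cmp$only_b), 0)
  expect_true(all(cmp$family_ratio$ratio == 1))

  # family present in a only shows up as absent from b
  b2 <- mk("AlkB", 6, "BM058")
  cmp2 <- compare_networks(a, b2)
  expect_true("XylE" %in% cmp2$only_a$family_id)
  expect_false("XylE" %in% cmp2$family_ratio$family_id)

  # random pair agrees with plain set algebra on edge keys
  set.seed(17)
  fams <- c("XylE", "CatA", "AlkB", "Sal1")
  pa <- catabolic_profile(screen_hits(random_annotation("x", 30, families = fams)))
  pb <- catabolic_profile(screen_hits(random_annotation("y", 30, families = fams)))
  na_ <- build_network(list(x = pa), cat)
  nb_ <- build_network(list(y = pb), cat)
  cmp3 <- compare_networks(na_, nb_)
  key <- function(e) paste(e$substrate_code, e$product_code, e$family_id)
  expect_setequal(key(cmp3$shared), intersect(key(na_$edges), key(nb_$edges)))
  expect_setequal(key(cmp3$only_a), setdiff(key(na_$edges), key(nb_$edges)))
  expect_setequal(key(cmp3$only_b), setdiff(key(nb_$edges), key(na_$edges)))
})

test_that("combined-evidence network contains every DNA-only edge", {
  st <- generate_study(study_design(seed = 21))
  scr <- screen_hits(st$annotations)
  dna_p <- catabolic_profile(scr)
  imp <- suppressWarnings(lapply(
    st$metadata$sample_id,
    function(s) impute_from_taxonomy(st$otus, st$otu_map, st$genomes, s)
  ))
  names(imp) <- st$metadata$sample_id
  imp_p <- catabolic_profile(screen_hits(imp))
  comb_p <- mapply(merge_profiles, dna_p, imp_p, SIMPLIFY = FALSE)
  net_dna <- build_network(dna_p, st$catalog)
  net_comb <- build_network(comb_p, st$catalog)
  key <- function(e) paste(e$substrate_code, e$product_code, e$family_id)
  expect_true(all(key(net_dna$edges) %in% key(net_comb$edges)))
  # combined weights positive wherever DNA weights are positive
  idx <- match(key(net_dna$edges), key(net_comb$edges))
  for (s in net_dna$samples) {
    pos <- net_dna$weights[, s] > 0
    expect_true(all(net_comb$weights[idx[pos], s] > 0))
  }
})
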