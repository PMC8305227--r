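class_submatrix <- function(m, cl) {
  subset_features(m, names(which(feature_classes(m) == cl)))
}

pair_tables_from <- function(m) {
  list(mi_lnc = pearson_pairs(class_submatrix(m, "miRNA"), class_submatrix(m, "lncRNA")),
       mi_m = pearson_pairs(class_submatrix(m, "miRNA"), class_submatrix(m, "mRNA")),
       lnc_m = pearson_pairs(class_submatrix(m, "lncRNA"), class_submatrix(m, "mRNA")))
}

test_that("the same seed reproduces bit-identical matrices; seeds differ otherwise", {
  g1 <- make_expression(seed = 42)
  g2 <- make_expression(seed = 42)
  g3 <- make_expression(seed = 43)
  expect_identical(expr_values(g1$matrix), expr_values(g2$matrix))
  expect_identical(g1$truth$triangles, g2$truth$triangles)
  expect_false(identical(expr_values(g1$matrix), expr_values(g3$matrix)))
})

test_that("planted edge correlations land within 3 Fisher-z standard errors", {
  gen <- make_expression(n_samples = 80, a = 1, b = 1, c = 1, sigma = 0.5,
                         seed = 19)
  expect_equal(gen$truth$triangles$expected_r_lnc_m[1], 0.8)  # 1 / 1.25
  pt <- pair_tables_from(gen$matrix)
  se_r <- (1 - 0.8^2) / sqrt(80 - 1)  # sampling sd of r near |r| = 0.8
  for (i in seq_len(nrow(gen$truth$triangles))) {
    tri <- gen$truth$triangles[i, ]
    r_lm <- pt$lnc_m$r[pt$lnc_m$a_id == tri$lnc_id & pt$lnc_m$b_id == tri$m_id]
    r_ml <- pt$mi_lnc$r[pt$mi_lnc$a_id == tri$mi_id & pt$mi_lnc$b_id == tri$lnc_id]
    r_mm <- pt$mi_m$r[pt$mi_m$a_id == tri$mi_id & pt$mi_m$b_id == tri$m_id]
    expect_lt(abs(r_lm - 0.8), 3 * se_r)
    expect_lt(abs(r_ml - (-0.8)), 3 * se_r)
    expect_lt(abs(r_mm - (-0.8)), 3 * se_r)
  }
})

test_that("expected correlation shrinks toward zero as noise grows", {
  gen <- make_expression(sigma = 50, seed = 23, n_mrna = 10, n_lncrna = 10,
                         n_mirna = 10, n_triangles = 3)
  expect_lt(max(abs(gen$truth$triangles$expected_r_lnc_m)), 0.01)
  pt <- pair_tables_from(gen$matrix)
  planted <- paste(gen$truth$triangles$lnc_id, gen$truth$triangles$mi_id,
                   gen$truth$triangles$m_id)
  found <- motif_keys(find_motifs(pt$mi_lnc, pt$mi_m, pt$lnc_m, threshold = 0.6))
  expect_false(any(planted %in% found))
})

test_that("generated values pass the expression filter", {
  gen <- make_expression(seed = 31)
  kept <- filter_expressed(gen$matrix, 0.75)
  expect_equal(nrow(expr_values(kept)), nrow(expr_values(gen$matrix)))
  expect_error(make_expression(n_triangles = 50, n_mirna = 10))
  expect_error(make_expression(sigma = 0))
})

test_that("planted triangles are recovered at threshold 0.6 with few false positives", {
  # study conditions: expected |r| = 0.8 (a = b = c = 1, sigma = 0.5), n = 80
  n_seeds <- 20
  recalls <- numeric(n_seeds)
  fp_rates <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    gen <- make_expression(n_samples = 80, n_mrna = 30, n_lncrna = 15,
                           n_mirna = 15, n_triangles = 5, sigma = 0.5, seed = s)
    pt <- pair_tables_from(gen$matrix)
    found <- motif_keys(find_motifs(pt$mi_lnc, pt$mi_m, pt$lnc_m, threshold = 0.6))
    planted <- paste(gen$truth$triangles$lnc_id, gen$truth$triangles$mi_id,
                     gen$truth$triangles$m_id)
    recalls[s] <- mean(planted %in% found)
    n_triples <- 15 * 15 * 30
    fp_rates[s] <- sum(!(found %in% planted)) / (n_triples - length(planted))
  }
  expect_gte(mean(recalls), 0.95)
  expect_lte(mean(fp_rates), 0.01)
})

test_that("planted loci classes are recovered by the overlap classifier", {
  req <- c(convergent = 3, divergent = 2, lncRNA_within_mRNA = 2,
           mRNA_within_lncRNA = 1)
  loci <- make_loci(planted = req, n_decoys = 4, seed = 11)
  got <- find_antisense_overlaps(loci$lnc_loci, loci$mrna_loci)
  joined <- dplyr::inner_join(got, loci$truth, by = c("lnc_id", "m_id"))
  expect_equal(nrow(joined), sum(req))
  expect_equal(joined$overlap_class, joined$class)
  expect_equal(nrow(got), sum(req))  # decoys contribute nothing
  # no planted overlaps -> empty output
  none <- make_loci(planted = c(convergent = 0), n_decoys = 5, seed = 12)
  expect_equal(nrow(find_antisense_overlaps(none$lnc_loci, none$mrna_loci)), 0L)
})

test_that("multi-isoform planted pairs produce spread overlap lengths", {
  loci <- make_loci(planted = c(convergent = 4), n_decoys = 0, n_isoforms = 2,
                    seed = 13)
  got <- find_antisense_overlaps(loci$lnc_loci, loci$mrna_loci)
  # recompute per-isoform overlaps directly; where they differ min < max
  for (i in seq_len(nrow(got))) {
    li <- loci$lnc_loci[loci$lnc_loci$gene_id == got$lnc_id[i], ]
    mi <- loci$mrna_loci[loci$mrna_loci$gene_id == got$m_id[i], ]
    ovs <- c()
    for (a in seq_len(nrow(li))) for (b in seq_len(nrow(mi))) {
      w <- min(li$end[a], mi$end[b]) - max(li$start[a], mi$start[b])
      if (w >= 1) ovs <- c(ovs, w)
    }
    expect_equal(got$overlap_min[i], min(ovs))
    expect_equal(got$overlap_max[i], max(ovs))
    expect_equal(got$overlap_mean[i], mean(ovs))
    if (length(unique(ovs)) > 1) expect_lt(got$overlap_min[i], got$overlap_max[i])
  }
})

test_that("planted TF regulons are fully recovered under binding gating at coverage 1", {
  regs <- make_tf_regulons(n_tfs = 5, targets_per_tf = 4, binding_coverage = 1,
                           seed = 17)
  pairs <- pearson_pairs(regs$tf_matrix, regs$target_matrix)
  loose <- c(mRNA = -0.5, miRNA = -0.5, lncRNA = -0.5)
  got <- tf_target_search(pairs, binding = regs$binding,
                          neg_cut = loose, pos_cut = -loose,
                          require_binding = TRUE)
  expect_setequal(paste(got$tf_id, got$target_id),
                  paste(regs$truth$tf_id, regs$truth$target_id))
  # recovered signs match the planted regulation direction
  joined <- dplyr::inner_join(got, regs$truth, by = c("tf_id", "target_id"))
  expect_equal(joined$sign_label == "(-)", joined$sign == -1)
})

test_that("coverage 0 with binding required yields nothing; all-negative mixes label (-)", {
  regs0 <- make_tf_regulons(binding_coverage = 0, seed = 18)
  pairs <- pearson_pairs(regs0$tf_matrix, regs0$target_matrix)
  loose <- c(mRNA = -0.5, miRNA = -0.5, lncRNA = -0.5)
  expect_equal(nrow(tf_target_search(pairs, binding = regs0$binding,
                                     neg_cut = loose, pos_cut = -loose,
                                     require_binding = TRUE)), 0L)
  negs <- make_tf_regulons(prop_negative = 1, binding_coverage = 1, seed = 19)
  pairs_n <- pearson_pairs(negs$tf_matrix, negs$target_matrix)
  rec <- tf_target_search(pairs_n, binding = negs$binding, neg_cut = loose,
                          pos_cut = -loose, require_binding = TRUE)
  expect_true(all(rec$sign_label == "(-)"))
  expect_error(make_tf_regulons(binding_coverage = 2))
})

test_that("the simulate bundle writes a coherent, re-loadable input set", {
  dir <- withr::local_tempdir()
  paths <- simulate_bundle(dir, seed = 3)
  expect_true(all(file.exists(unlist(paths))))
  mat <- read_expression(paths$expression, paths$annotation)
  inter <- read_interactions(paths$interactions)
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_equal(ncol(expr_values(mat)), 80L)
  expect_true(all(truth$triangles$lnc_id %in% feature_ids(mat)))
  expect_true(all(inter$mirna_id %in% feature_ids(mat)))
  lnc <- read_loci(paths$lnc_bed, "bed")
  expect_true(all(lnc$gene_id %in% feature_ids(mat)))
  clin <- read_clinical(paths$clinical)
  expect_setequal(clin$data$sample_id, sample_ids(mat))
  expect_equal(unname(clin$kinds["thickness_mm"]), "numeric")
  tfs <- readLines(paths$tf_list)
  expect_true(all(tfs %in% feature_ids(mat)))
})
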