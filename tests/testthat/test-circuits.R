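# pair tables for a random instance, by correlating random expression
random_pair_tables <- function(n_lnc, n_mi, n_m, n_samp = 20, seed = 1) {
  lnc <- random_class_matrix(n_lnc, n_samp, "lncRNA", "l", seed = seed)
  mi <- random_class_matrix(n_mi, n_samp, "miRNA", "mi", seed = seed + 1)
  m <- random_class_matrix(n_m, n_samp, "mRNA", "g", seed = seed + 2)
  list(mi_lnc = pearson_pairs(mi, lnc),
       mi_m = pearson_pairs(mi, m),
       lnc_m = pearson_pairs(lnc, m))
}

test_that("motif enumeration equals the exhaustive triple scan", {
  shapes <- list(c(5, 5, 5), c(8, 6, 10), c(15, 15, 15))
  for (s in shapes) {
    pt <- random_pair_tables(s[1], s[2], s[3], seed = sum(s))
    for (th in c(0, 0.2, 0.4)) {
      got <- find_motifs(pt$mi_lnc, pt$mi_m, pt$lnc_m, threshold = th)
      want <- brute_force_motifs(pt$mi_lnc, pt$mi_m, pt$lnc_m, threshold = th)
      expect_equal(motif_keys(got), want)
    }
  }
})

test_that("evidence gating matches the oracle and is AND across the two miRNA axes", {
  pt <- random_pair_tables(6, 6, 6, seed = 99)
  set.seed(100)
  inter <- dplyr::bind_rows(
    tibble::tibble(mirna_id = sample(sprintf("mi%02d", 1:6), 8, TRUE),
                   partner_id = sample(sprintf("g%02d", 1:6), 8, TRUE),
                   partner_class = "mRNA", source = "TarBase", flag = 1L),
    tibble::tibble(mirna_id = sample(sprintf("mi%02d", 1:6), 8, TRUE),
                   partner_id = sample(sprintf("l%02d", 1:6), 8, TRUE),
                   partner_class = "lncRNA", source = "miRcode", flag = 1L)
  )
  inter <- dplyr::distinct(inter, mirna_id, partner_id, source, .keep_all = TRUE)
  got <- find_motifs(pt$mi_lnc, pt$mi_m, pt$lnc_m, interactions = inter,
                     threshold = 0.1, require_evidence = TRUE)
  want <- brute_force_motifs(pt$mi_lnc, pt$mi_m, pt$lnc_m, interactions = inter,
                             threshold = 0.1, require_evidence = TRUE)
  expect_equal(motif_keys(got), want)
  # gated output is a subset of the ungated output
  ungated <- find_motifs(pt$mi_lnc, pt$mi_m, pt$lnc_m, threshold = 0.1)
  expect_true(all(motif_keys(got) %in% motif_keys(ungated)))
})

test_that("emitted motifs always satisfy the sponge sign pattern", {
  for (seed in c(3, 17, 23)) {
    pt <- random_pair_tables(10, 10, 10, seed = seed)
    got <- find_motifs(pt$mi_lnc, pt$mi_m, pt$lnc_m, threshold = 0.05)
    expect_true(all(got$r_mi_lnc <= -0.05))
    expect_true(all(got$r_mi_m <= -0.05))
    expect_true(all(got$r_lnc_m >= 0.05))
  }
  # a triple with all three correlations positive is never emitted
  all_pos <- function(tbl) { tbl$r <- abs(tbl$r); tbl }
  pt <- random_pair_tables(5, 5, 5, seed = 4)
  got <- find_motifs(all_pos(pt$mi_lnc), all_pos(pt$mi_m), all_pos(pt$lnc_m),
                     threshold = 0)
  expect_equal(nrow(got), 0L)
})

test_that("raising the threshold never adds a motif", {
  pt <- random_pair_tables(12, 8, 12, seed = 7)
  prev <- NULL
  for (th in c(0.1, 0.2, 0.3, 0.4, 0.5)) {
    keys <- motif_keys(find_motifs(pt$mi_lnc, pt$mi_m, pt$lnc_m, threshold = th))
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
})

test_that("p_max filters all three edges conjunctively", {
  pt <- random_pair_tables(8, 8, 8, seed = 13)
  got <- find_motifs(pt$mi_lnc, pt$mi_m, pt$lnc_m, threshold = 0, p_max = 0.05)
  expect_true(all(got$p_mi_lnc <= 0.05 & got$p_mi_m <= 0.05 & got$p_lnc_m <= 0.05))
  loose <- find_motifs(pt$mi_lnc, pt$mi_m, pt$lnc_m, threshold = 0)
  expect_true(all(motif_keys(got) %in% motif_keys(loose)))
})

test_that("ranking is by strongest weakest-edge with deterministic ties", {
  motifs <- tibble::tibble(
    lnc_id = c("l2", "l1", "l3"), mi_id = c("mi1", "mi1", "mi1"),
    m_id = c("g1", "g1", "g1"),
    r_mi_lnc = c(-0.65, -0.61, -0.61), r_mi_m = c(-0.9, -0.9, -0.9),
    r_lnc_m = c(0.9, 0.9, 0.9),
    p_mi_lnc = 0, p_mi_m = 0, p_lnc_m = 0,
    evidence_mi_lnc = list(character(0), character(0), character(0)),
    evidence_mi_m = list(character(0), character(0), character(0))
  )
  ranked <- rank_motifs(motifs, 3)
  expect_equal(ranked$lnc_id, c("l2", "l1", "l3"))  # 0.65 first, then lex
  expect_equal(nrow(rank_motifs(motifs, 10)), 3L)   # top_n beyond count -> all
  # permutation of the input leaves the ordering unchanged
  for (i in 1:3) {
    shuf <- motifs[sample(3), ]
    expect_equal(rank_motifs(shuf, 3)$lnc_id, ranked$lnc_id)
  }
})

test_that("anchor restricts motifs and unknown anchors error by name", {
  pt <- random_pair_tables(8, 8, 8, seed = 19)
  all_m <- find_motifs(pt$mi_lnc, pt$mi_m, pt$lnc_m, threshold = 0)
  anchor <- all_m$mi_id[1]
  got <- find_motifs(pt$mi_lnc, pt$mi_m, pt$lnc_m, threshold = 0, anchor = anchor)
  expect_true(all(got$mi_id == anchor | got$lnc_id == anchor | got$m_id == anchor))
  expect_equal(motif_keys(got),
               motif_keys(all_m[all_m$mi_id == anchor | all_m$lnc_id == anchor |
                                  all_m$m_id == anchor, ]))
  expect_error(find_motifs(pt$mi_lnc, pt$mi_m, pt$lnc_m, anchor = "nosuchgene"),
               "nosuchgene")
  expect_error(find_motifs(pt$mi_lnc, pt$mi_m, pt$lnc_m, threshold = -0.2))
})

test_that("threshold sweep counts are monotone and evidence-gated <= ungated", {
  gen <- make_expression(n_mrna = 20, n_lncrna = 15, n_mirna = 10,
                         n_triangles = 4, seed = 29)
  cl <- function(c) subset_features(gen$matrix,
                                    names(which(feature_classes(gen$matrix) == c)))
  pt <- list(mi_lnc = pearson_pairs(cl("miRNA"), cl("lncRNA")),
             mi_m = pearson_pairs(cl("miRNA"), cl("mRNA")),
             lnc_m = pearson_pairs(cl("lncRNA"), cl("mRNA")))
  inter <- truth_interactions(gen$truth)
  ths <- seq(0.2, 0.7, by = 0.1)
  sweep <- threshold_sweep(pt$mi_lnc, pt$mi_m, pt$lnc_m, interactions = inter,
                           thresholds = ths)
  expect_equal(sweep$threshold, ths)
  expect_true(all(diff(sweep$motif_count) <= 0))
  expect_true(all(diff(sweep$evidence_gated_count) <= 0))
  expect_true(all(sweep$evidence_gated_count <= sweep$motif_count))
  # planted motifs are recovered at every threshold below the planted |r|
  for (th in c(0.2, 0.3, 0.4, 0.5, 0.6)) {
    keys <- motif_keys(find_motifs(pt$mi_lnc, pt$mi_m, pt$lnc_m, threshold = th))
    planted <- paste(gen$truth$triangles$lnc_id, gen$truth$triangles$mi_id,
                     gen$truth$triangles$m_id)
    expect_true(all(planted %in% keys), label = paste("recovery at", th))
  }
  # empty interaction table -> all gated counts zero
  none <- threshold_sweep(pt$mi_lnc, pt$mi_m, pt$lnc_m,
                          interactions = inter[0, ], thresholds = c(0.2, 0.4))
  expect_equal(none$evidence_gated_count, c(0L, 0L))
  expect_error(threshold_sweep(pt$mi_lnc, pt$mi_m, pt$lnc_m,
                               thresholds = c(0.4, 0.2)), "ascending")
})
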