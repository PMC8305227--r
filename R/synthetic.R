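# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate an expression matrix with planted ceRNA triangles
#'
#' Each planted triangle shares a latent standard-normal sample vector `z`:
#' its lncRNA is `a*z + e`, its mRNA `b*z + e'` and its miRNA `-c*z + e''`
#' with independent Gaussian noise of scale `sigma`, so the expected
#' pairwise correlations have closed form — e.g.
#' `r(lnc, mRNA) = a*b / sqrt((a^2 + sigma^2) * (b^2 + sigma^2))`, which is
#' 0.8 at the defaults `a = b = c = 1`, `sigma = 0.5` — negative on both
#' miRNA edges and positive on the lncRNA-mRNA edge. All other features
#' are independent noise. A constant `shift` keeps values predominantly
#' positive (so the expression filter retains them) without changing any
#' correlation.
#'
#' @param n_samples number of samples (default 80, a typical tumor-cohort
#'   size).
#' @param n_mrna,n_lncrna,n_mirna features per class.
#' @param n_triangles number of planted triangles (uses the first
#'   `n_triangles` feature of each class); must not exceed any class count.
#' @param a,b,c latent-factor loadings of lncRNA, mRNA and miRNA.
#' @param sigma independent noise scale (> 0).
#' @param shift constant added to every value.
#' @param seed RNG seed; fully determines the output.
#' @return a list with `matrix` (an [expression_matrix()]) and `truth`
#'   (list: `triangles` tibble with ids and expected edge correlations,
#'   plus the generator parameters).
#' @export
make_expression <- function(n_samples = 80, n_mrna = 100, n_lncrna = 40,
                            n_mirna = 30, n_triangles = 5, a = 1, b = 1,
                            c = 1, sigma = 0.5, shift = 6, seed = 1) {
  if (sigma <= 0) abort("`sigma` must be > 0.")
  if (n_triangles > min(n_mrna, n_lncrna, n_mirna)) {
    abort("more planted triangles than features in some class.")
  }
  with_seed(seed, {
    lnc_ids <- sprintf("LNC%03d", seq_len(n_lncrna))
    mi_ids <- sprintf("MIR%03d", seq_len(n_mirna))
    m_ids <- sprintf("GENE%03d", seq_len(n_mrna))
    smp <- sprintf("S%02d", seq_len(n_samples))
    mk_noise <- function(n) matrix(rnorm(n * n_samples, sd = sqrt(1 + sigma^2)),
                                   nrow = n)
    lnc <- mk_noise(n_lncrna); rownames(lnc) <- lnc_ids
    mi <- mk_noise(n_mirna); rownames(mi) <- mi_ids
    m <- mk_noise(n_mrna); rownames(m) <- m_ids
    exp_r <- function(u, v) (u * v) / sqrt((u^2 + sigma^2) * (v^2 + sigma^2))
    tri <- tibble(
      lnc_id = lnc_ids[seq_len(n_triangles)],
      mi_id = mi_ids[seq_len(n_triangles)],
      m_id = m_ids[seq_len(n_triangles)],
      expected_r_mi_lnc = -exp_r(c, a),
      expected_r_mi_m = -exp_r(c, b),
      expected_r_lnc_m = exp_r(a, b)
    )
    for (i in seq_len(n_triangles)) {
      z <- rnorm(n_samples)
      lnc[i, ] <- a * z + rnorm(n_samples, sd = sigma)
      m[i, ] <- b * z + rnorm(n_samples, sd = sigma)
      mi[i, ] <- -c * z + rnorm(n_samples, sd = sigma)
    }
    values <- rbind(lnc, mi, m) + shift
    colnames(values) <- smp
    fc <- setNames(c(rep("lncRNA", n_lncrna), rep("miRNA", n_mirna),
                     rep("mRNA", n_mrna)),
                   c(lnc_ids, mi_ids, m_ids))
    mat <- expression_matrix(values, fc,
                             units = c(miRNA = "log2(RPM+1)",
                                       mRNA = "log2(norm_count+1)",
                                       lncRNA = "log2(norm_count+1)"))
    list(matrix = mat,
         truth = list(triangles = tri, seed = seed, sigma = sigma,
                      n_samples = n_samples, a = a, b = b, c = c,
                      shift = shift))
  })
}

#' Interaction records supporting planted triangles
#'
#' One miRNA-mRNA record (source `"TarBase"`) and one miRNA-lncRNA record
#' (source `"miRcode"`) per planted triangle, all flags 1, so evidence
#' gating keeps exactly the planted motifs.
#'
#' @param truth the `truth` element returned by [make_expression()].
#' @return an interaction tibble (see [read_interactions()]).
#' @export
truth_interactions <- function(truth) {
  tri <- truth$triangles
  bind_rows(
    tibble(mirna_id = tri$mi_id, partner_id = tri$m_id,
           partner_class = "mRNA", source = "TarBase", flag = 1L),
    tibble(mirna_id = tri$mi_id, partner_id = tri$lnc_id,
           partner_class = "lncRNA", source = "miRcode", flag = 1L)
  )
}

# one planted opposite-strand pair of the requested class; coordinates are
# 0-based half-open within [offset, offset + window)
plant_pair_geometry <- function(class, offset, window) {
  len_l <- sample(2000:8000, 1)
  len_m <- sample(2000:8000, 1)
  ov <- sample(200:1500, 1)
  s <- offset + sample(0:1000, 1)
  if (class == "convergent") {
    # mRNA '+' left, lncRNA '-' right; shared region holds both 3' ends
    m <- c(s, s + len_m)
    l <- c(s + len_m - ov, s + len_m - ov + len_l)
  } else if (class == "divergent") {
    # lncRNA '-' left, mRNA '+' right; shared region holds both 5' ends
    l <- c(s, s + len_l)
    m <- c(s + len_l - ov, s + len_l - ov + len_m)
  } else if (class == "lncRNA_within_mRNA") {
    len_l <- min(len_l, len_m - 200)
    m <- c(s, s + len_m)
    inset <- sample(50:(len_m - len_l - 50), 1)
    l <- c(s + inset, s + inset + len_l)
  } else if (class == "mRNA_within_lncRNA") {
    len_m <- min(len_m, len_l - 200)
    l <- c(s, s + len_l)
    inset <- sample(50:(len_l - len_m - 50), 1)
    m <- c(l[1] + inset, l[1] + inset + len_m)
  } else {
    abort(paste0("unknown overlap class: ", class))
  }
  list(lnc = l, m = m, lnc_strand = "-", m_strand = "+")
}

#' Generate gene loci with planted sense-antisense overlap classes
#'
#' Builds opposite-strand lncRNA/mRNA gene pairs realising each requested
#' overlap class, plus non-overlapping decoy genes, all on one synthetic
#' chromosome. With `n_isoforms = 2` each planted gene gets a second,
#' truncated isoform so per-isoform overlap lengths differ.
#'
#' @param planted named integer vector of pair counts per class
#'   (names among `convergent`, `divergent`, `lncRNA_within_mRNA`,
#'   `mRNA_within_lncRNA`).
#' @param n_decoys non-overlapping genes added per side.
#' @param n_isoforms isoforms per planted gene (1 or 2).
#' @param lnc_ids,m_ids optional id pools to draw gene names from (e.g.
#'   feature ids of an expression matrix); auto-generated when NULL.
#' @param chrom chromosome name.
#' @param seed RNG seed.
#' @return a list with `lnc_loci`, `mrna_loci` (tibbles as from
#'   [read_loci()]) and `truth` (tibble `lnc_id`, `m_id`, `class`).
#' @export
make_loci <- function(planted = c(convergent = 3, divergent = 3,
                                  lncRNA_within_mRNA = 2, mRNA_within_lncRNA = 2),
                      n_decoys = 5, n_isoforms = 1, lnc_ids = NULL,
                      m_ids = NULL, chrom = "chrS", seed = 1) {
  n_pairs <- sum(planted)
  if (is.null(lnc_ids)) lnc_ids <- sprintf("LNC%03d", seq_len(n_pairs + n_decoys))
  if (is.null(m_ids)) m_ids <- sprintf("GENE%03d", seq_len(n_pairs + n_decoys))
  if (length(lnc_ids) < n_pairs + n_decoys || length(m_ids) < n_pairs + n_decoys) {
    abort("not enough ids for the requested pairs and decoys.")
  }
  with_seed(seed, {
    window <- 50000L
    classes <- rep(names(planted), times = planted)
    lnc_rows <- list(); m_rows <- list(); truth_rows <- list()
    add_iso <- function(id, class, strand, iv) {
      rows <- tibble(gene_id = id, class = class, chrom = chrom,
                     strand = strand, start = iv[1], end = iv[2], isoform = 1L)
      if (n_isoforms >= 2) {
        # truncated second isoform anchored at the 5' end of the gene
        cut <- floor((iv[2] - iv[1]) * runif(1, 0.3, 0.7))
        iv2 <- if (strand == "+") c(iv[1], iv[2] - cut) else c(iv[1] + cut, iv[2])
        rows <- bind_rows(rows, tibble(gene_id = id, class = class,
                                       chrom = chrom, strand = strand,
                                       start = iv2[1], end = iv2[2],
                                       isoform = 2L))
      }
      rows
    }
    for (i in seq_along(classes)) {
      g <- plant_pair_geometry(classes[i], offset = (i - 1L) * window, window)
      lnc_rows[[i]] <- add_iso(lnc_ids[i], "lncRNA", g$lnc_strand, g$lnc)
      m_rows[[i]] <- add_iso(m_ids[i], "mRNA", g$m_strand, g$m)
      truth_rows[[i]] <- tibble(lnc_id = lnc_ids[i], m_id = m_ids[i],
                                class = classes[i])
    }
    base <- length(classes) * window
    for (j in seq_len(n_decoys)) {
      off <- base + (j - 1L) * window
      s1 <- off + sample(0:1000, 1)
      lnc_rows[[length(classes) + j]] <- tibble(
        gene_id = lnc_ids[n_pairs + j], class = "lncRNA", chrom = chrom,
        strand = sample(c("+", "-"), 1), start = s1, end = s1 + sample(1000:4000, 1),
        isoform = 1L)
      s2 <- off + 20000L + sample(0:1000, 1)
      m_rows[[length(classes) + j]] <- tibble(
        gene_id = m_ids[n_pairs + j], class = "mRNA", chrom = chrom,
        strand = sample(c("+", "-"), 1), start = s2, end = s2 + sample(1000:4000, 1),
        isoform = 1L)
    }
    list(lnc_loci = bind_rows(lnc_rows), mrna_loci = bind_rows(m_rows),
         truth = bind_rows(truth_rows))
  })
}

#' Generate planted TF regulons with ChIP-seq binding flags
#'
#' Each TF gets an expression vector `z + e`; each of its targets follows
#' `sign * z + e'` with noise scale `sigma`, giving strong planted
#' correlations of the requested sign. Binding flags (source `"ENCODE"`)
#' are set for each planted pair independently with probability
#' `binding_coverage`.
#'
#' @param n_tfs number of TFs.
#' @param targets_per_tf targets per TF, spread across the three RNA
#'   classes round-robin.
#' @param prop_negative proportion of negatively regulated targets.
#' @param binding_coverage probability in \[0, 1\] that a planted pair gets
#'   a binding flag.
#' @param n_samples,sigma,shift,seed as in [make_expression()].
#' @return a list with `tf_matrix` (TF rows, class mRNA), `target_matrix`
#'   (target rows with their classes), `tf_list`, `binding` (tibble, see
#'   [read_binding()]) and `truth` (tibble `tf_id`, `target_id`,
#'   `target_class`, `sign`, `bound`).
#' @export
make_tf_regulons <- function(n_tfs = 4, targets_per_tf = 3, prop_negative = 0.5,
                             binding_coverage = 1, n_samples = 80, sigma = 0.5,
                             shift = 6, seed = 1) {
  if (binding_coverage < 0 || binding_coverage > 1) {
    abort("`binding_coverage` must be in [0, 1].")
  }
  with_seed(seed, {
    tf_ids <- sprintf("TF%02d", seq_len(n_tfs))
    classes <- rep(c("mRNA", "miRNA", "lncRNA"), length.out = targets_per_tf)
    tf_vals <- matrix(0, nrow = n_tfs, ncol = n_samples,
                      dimnames = list(tf_ids, sprintf("S%02d", seq_len(n_samples))))
    tgt_rows <- list(); truth_rows <- list(); tgt_vals <- list()
    k <- 0L
    for (i in seq_len(n_tfs)) {
      z <- rnorm(n_samples)
      tf_vals[i, ] <- z + rnorm(n_samples, sd = sigma)
      for (j in seq_len(targets_per_tf)) {
        k <- k + 1L
        sgn <- if (runif(1) < prop_negative) -1 else 1
        id <- sprintf("TGT%03d", k)
        tgt_vals[[k]] <- sgn * z + rnorm(n_samples, sd = sigma)
        truth_rows[[k]] <- tibble(
          tf_id = tf_ids[i], target_id = id, target_class = classes[j],
          sign = sgn, bound = runif(1) <= binding_coverage)
        tgt_rows[[k]] <- tibble(id = id, class = classes[j])
      }
    }
    truth <- bind_rows(truth_rows)
    tgt <- bind_rows(tgt_rows)
    tmat <- do.call(rbind, tgt_vals) + shift
    rownames(tmat) <- tgt$id
    colnames(tmat) <- colnames(tf_vals)
    binding <- truth %>%
      filter(bound) %>%
      mutate(source = "ENCODE", flag = 1L) %>%
      select(tf_id, target_id, source, flag)
    list(
      tf_matrix = expression_matrix(tf_vals + shift,
                                    setNames(rep("mRNA", n_tfs), tf_ids)),
      target_matrix = expression_matrix(tmat, setNames(tgt$class, tgt$id)),
      tf_list = tf_ids,
      binding = binding,
      truth = truth
    )
  })
}

#' Write loci to a BED6 file
#' @param loci isoform tibble (see [read_loci()]).
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_loci_bed <- function(loci, path) {
  bed <- loci %>%
    mutate(name = gene_id, score = 0L) %>%
    select(chrom, start, end, name, score, strand)
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write a complete synthetic input bundle
#'
#' Emulates the shape of a tumor-cohort study: an expression TSV (three
#' RNA classes, planted triangles), its class annotation, interaction
#' records for the planted triangles, BED loci with planted overlap
#' geometries, a TF block with a ChIP-seq binding table, a clinical table
#' (stage, thickness, metastasis) and a `truth.json` recording everything
#' that was planted.
#'
#' @param dir output directory (created if needed).
#' @param seed master RNG seed.
#' @param ... passed to [make_expression()].
#' @return invisibly, a named list of the written paths.
#' @export
simulate_bundle <- function(dir, seed = 1, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- make_expression(seed = seed, ...)
  regs <- make_tf_regulons(seed = seed + 1L,
                           n_samples = ncol(gen$matrix$values))
  loci <- make_loci(seed = seed + 2L,
                    lnc_ids = names(which(feature_classes(gen$matrix) == "lncRNA")),
                    m_ids = names(which(feature_classes(gen$matrix) == "mRNA")))
  values <- rbind(expr_values(gen$matrix), expr_values(regs$tf_matrix),
                  expr_values(regs$target_matrix))
  fc <- c(feature_classes(gen$matrix), feature_classes(regs$tf_matrix),
          feature_classes(regs$target_matrix))
  full <- expression_matrix(values, fc, units = gen$matrix$units)
  smp <- sample_ids(full)
  clinical <- with_seed(seed + 3L, tibble(
    sample_id = smp,
    stage = sample(c("II", "III", "IV"), length(smp), replace = TRUE),
    thickness_mm = round(runif(length(smp), 2, 12), 1),
    metastasis = sample(c("yes", "no"), length(smp), replace = TRUE)
  ))
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    interactions = file.path(dir, "interactions.tsv"),
    lnc_bed = file.path(dir, "lncrna_loci.bed"),
    mrna_bed = file.path(dir, "mrna_loci.bed"),
    binding = file.path(dir, "binding.tsv"),
    tf_list = file.path(dir, "tf_list.txt"),
    clinical = file.path(dir, "clinical.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_expression(full, paths$expression, paths$annotation)
  readr::write_tsv(truth_interactions(gen$truth), paths$interactions, progress = FALSE)
  write_loci_bed(loci$lnc_loci, paths$lnc_bed)
  write_loci_bed(loci$mrna_loci, paths$mrna_bed)
  readr::write_tsv(regs$binding, paths$binding, progress = FALSE)
  writeLines(regs$tf_list, paths$tf_list)
  readr::write_tsv(clinical, paths$clinical, progress = FALSE)
  jsonlite::write_json(list(
    seed = seed,
    triangles = gen$truth$triangles,
    generator = gen$truth[c("sigma", "n_samples", "a", "b", "c", "shift")],
    overlap_pairs = loci$truth,
    tf_regulons = regs$truth
  ), paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
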