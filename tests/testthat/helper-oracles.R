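# Independent brute-force oracles and tiny fixture builders used across the
# suite. These deliberately avoid the package's own computation paths.

# naive two-pass Pearson: means, then covariance / sd product
naive_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# permutation p-value for the correlation of x and y
permutation_pvalue <- function(x, y, n_perm = 100000, seed = 42) {
  set.seed(seed)
  n <- length(x)
  robs <- abs(naive_pearson(x, y))
  xs <- (x - mean(x)) / sd(x)
  ys <- (y - mean(y)) / sd(y)
  perm_idx <- matrix(replicate(n_perm, sample.int(n)), nrow = n)
  yp <- matrix(ys[perm_idx], nrow = n)
  rp <- abs(as.vector(crossprod(xs, yp)) / (n - 1))
  (1 + sum(rp >= robs)) / (n_perm + 1)
}

# tiny ExpressionMatrix from a plain matrix + one class for all rows
toy_matrix <- function(values, class = "mRNA", ids = NULL, samples = NULL) {
  if (is.null(ids)) ids <- sprintf("f%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  rownames(values) <- ids
  colnames(values) <- samples
  expression_matrix(values, stats::setNames(rep(class, nrow(values)), ids))
}

random_class_matrix <- function(n_feat, n_samp, class, prefix, seed) {
  set.seed(seed)
  toy_matrix(matrix(rnorm(n_feat * n_samp), nrow = n_feat), class = class,
             ids = sprintf("%s%02d", prefix, seq_len(n_feat)))
}

# exhaustive triple scan implementing the motif predicate directly on the
# pair tables (named-lookup based, independent of the join implementation)
brute_force_motifs <- function(pairs_mi_lnc, pairs_mi_m, pairs_lnc_m,
                               interactions = NULL, threshold = 0,
                               require_evidence = FALSE) {
  key <- function(a, b) paste(a, b, sep = "\r")
  r_ml <- stats::setNames(pairs_mi_lnc$r, key(pairs_mi_lnc$a_id, pairs_mi_lnc$b_id))
  r_mm <- stats::setNames(pairs_mi_m$r, key(pairs_mi_m$a_id, pairs_mi_m$b_id))
  r_lm <- stats::setNames(pairs_lnc_m$r, key(pairs_lnc_m$a_id, pairs_lnc_m$b_id))
  has_ev <- function(mi, partner) {
    if (is.null(interactions)) return(FALSE)
    any(interactions$mirna_id == mi & interactions$partner_id == partner &
          interactions$flag == 1L)
  }
  mis <- unique(pairs_mi_lnc$a_id)
  lncs <- unique(pairs_mi_lnc$b_id)
  ms <- unique(pairs_mi_m$b_id)
  out <- character(0)
  for (mi in mis) for (l in lncs) for (m in ms) {
    rml <- r_ml[key(mi, l)]; rmm <- r_mm[key(mi, m)]; rlm <- r_lm[key(l, m)]
    if (anyNA(c(rml, rmm, rlm))) next
    ok <- rml <= -threshold && rmm <= -threshold && rlm >= threshold
    if (ok && require_evidence) ok <- has_ev(mi, l) && has_ev(mi, m)
    if (ok) out <- c(out, paste(l, mi, m))
  }
  sort(out)
}

motif_keys <- function(motifs) sort(paste(motifs$lnc_id, motifs$mi_id, motifs$m_id))

# O(n^2) all-pairs interval oracle for strand-opposed gene overlap
brute_force_overlaps <- function(lnc_loci, mrna_loci) {
  lnc_genes <- split(lnc_loci, lnc_loci$gene_id)
  m_genes <- split(mrna_loci, mrna_loci$gene_id)
  out <- character(0)
  for (l in lnc_genes) for (m in m_genes) {
    if (l$chrom[1] != m$chrom[1] || l$strand[1] == m$strand[1]) next
    hit <- FALSE
    for (i in seq_len(nrow(l))) for (j in seq_len(nrow(m))) {
      if (min(l$end[i], m$end[j]) - max(l$start[i], m$start[j]) >= 1) hit <- TRUE
    }
    if (hit) out <- c(out, paste(l$gene_id[1], m$gene_id[1]))
  }
  sort(out)
}

# terminus-location oracle for overlap classification on union spans
oracle_classify <- function(ls, le, l_strand, ms, me, m_strand) {
  if (ls >= ms && le <= me) return("lncRNA_within_mRNA")
  if (ms >= ls && me <= le) return("mRNA_within_lncRNA")
  five <- function(s, e, st) if (st == "+") s else e - 1
  three <- function(s, e, st) if (st == "+") e - 1 else s
  lo <- max(ls, ms); hi <- min(le, me) - 1
  inov <- function(p) p >= lo && p <= hi
  if (inov(three(ls, le, l_strand)) && inov(three(ms, me, m_strand))) return("convergent")
  if (inov(five(ls, le, l_strand)) && inov(five(ms, me, m_strand))) return("divergent")
  stop("unclassifiable geometry")
}

# random opposite-strand overlapping span pair (union spans only)
random_overlap_geometry <- function() {
  repeat {
    ls <- sample(0:5000, 1); le <- ls + sample(100:4000, 1)
    ms <- sample(0:5000, 1); me <- ms + sample(100:4000, 1)
    if (min(le, me) - max(ls, ms) >= 1) {
      return(tibble::tibble(lnc_start = ls, lnc_end = le, lnc_strand = "-",
                            m_start = ms, m_end = me, m_strand = "+"))
    }
  }
}
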