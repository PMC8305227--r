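loci_to_granges <- function(loci) {
  GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end),
    strand = loci$strand,
    gene_id = loci$gene_id,
    isoform = loci$isoform
  )
}

#' Find strand-opposed (sense-antisense) lncRNA/mRNA overlapping gene pairs
#'
#' Emits every (lncRNA gene, mRNA gene) pair on the same chromosome and
#' opposite strands with at least one base of overlap between any isoform
#' combination. Overlap lengths are summarised as mean/min/max over the
#' isoform combinations that do overlap; classification (see
#' [classify_overlap()]) uses the per-gene union span of isoforms so each
#' gene pair gets exactly one class.
#'
#' @param lnc_loci,mrna_loci isoform tibbles as returned by [read_loci()]
#'   (columns `gene_id`, `chrom`, `strand`, `start`, `end`, `isoform`;
#'   coordinates 0-based half-open).
#' @param same_strand also report same-strand overlapping pairs, attached
#'   (unclassified) as attribute `"same_strand_pairs"`. They are never part
#'   of the sense-antisense output.
#' @return a tibble of overlap pairs with union spans, per-isoform overlap
#'   statistics (`overlap_mean`, `overlap_min`, `overlap_max`), the
#'   four-way `overlap_class`, a `containment` column (`"partial"` or
#'   `"total"`) and a `degenerate` flag for identical spans.
#' @export
find_antisense_overlaps <- function(lnc_loci, mrna_loci, same_strand = FALSE) {
  gr_l <- loci_to_granges(lnc_loci)
  gr_m <- loci_to_granges(mrna_loci)
  hits <- GenomicRanges::findOverlaps(gr_l, gr_m, minoverlap = 1L,
                                      ignore.strand = TRUE)
  if (length(hits) == 0) {
    empty <- empty_overlap_tbl()
    if (same_strand) attr(empty, "same_strand_pairs") <- empty_overlap_tbl()
    return(empty)
  }
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov_w <- GenomicRanges::width(GenomicRanges::pintersect(
    gr_l[qi], gr_m[si], ignore.strand = TRUE))
  iso <- tibble(
    lnc_id = gr_l$gene_id[qi],
    m_id = gr_m$gene_id[si],
    lnc_strand = as.character(GenomicRanges::strand(gr_l))[qi],
    m_strand = as.character(GenomicRanges::strand(gr_m))[si],
    overlap = ov_w
  )
  opposite <- iso$lnc_strand != iso$m_strand
  build <- function(iso_sub) {
    if (nrow(iso_sub) == 0) return(empty_overlap_tbl())
    per_pair <- iso_sub %>%
      group_by(lnc_id, m_id, lnc_strand, m_strand) %>%
      summarise(overlap_mean = mean(overlap), overlap_min = min(overlap),
                overlap_max = max(overlap), n_isoform_overlaps = n(),
                .groups = "drop")
    spans_l <- lnc_loci %>% group_by(gene_id) %>%
      summarise(chrom = first(chrom), lnc_start = min(start),
                lnc_end = max(end), .groups = "drop")
    spans_m <- mrna_loci %>% group_by(gene_id) %>%
      summarise(m_start = min(start), m_end = max(end), .groups = "drop")
    per_pair %>%
      left_join(spans_l, by = c(lnc_id = "gene_id")) %>%
      left_join(spans_m, by = c(m_id = "gene_id")) %>%
      relocate(chrom, .after = m_id)
  }
  out <- build(iso[opposite, , drop = FALSE])
  if (nrow(out)) {
    cls <- classify_overlap(out)
    out$overlap_class <- cls$class
    out$containment <- cls$containment
    out$degenerate <- cls$degenerate
  }
  if (same_strand) {
    attr(out, "same_strand_pairs") <- build(iso[!opposite, , drop = FALSE])
  }
  out
}

empty_overlap_tbl <- function() {
  tibble(
    lnc_id = character(0), m_id = character(0), chrom = character(0),
    lnc_strand = character(0), m_strand = character(0),
    overlap_mean = numeric(0), overlap_min = numeric(0),
    overlap_max = numeric(0), n_isoform_overlaps = integer(0),
    lnc_start = integer(0), lnc_end = integer(0),
    m_start = integer(0), m_end = integer(0)
  )
}

#' Classify a strand-opposed overlapping gene pair
#'
#' Four mutually exclusive classes on the union spans of the two genes:
#' containment takes precedence (`lncRNA_within_mRNA` when the lncRNA span
#' lies inside the mRNA span, `mRNA_within_lncRNA` for the converse;
#' identical spans are the degenerate double containment and are assigned
#' `lncRNA_within_mRNA` with `degenerate = TRUE`). Partial overlaps are
#' `convergent` when the shared region contains both genes' 3' termini
#' (tail-to-tail) and `divergent` when it contains both 5' termini
#' (head-to-head). The 5' terminus of a minus-strand gene is its highest
#' coordinate; half-open ends are decremented before terminus comparison.
#'
#' @param pairs tibble with columns `lnc_start`, `lnc_end`, `lnc_strand`,
#'   `m_start`, `m_end`, `m_strand` (union spans, 0-based half-open,
#'   opposite strands, overlapping).
#' @return a tibble with columns `class`, `containment`
#'   (`"partial"`/`"total"`), `degenerate`.
#' @export
classify_overlap <- function(pairs) {
  n <- nrow(pairs)
  if (any(pairs$lnc_strand == pairs$m_strand)) {
    abort("classify_overlap() is defined for opposite-strand pairs only.")
  }
  cls <- character(n)
  containment <- character(n)
  degenerate <- logical(n)
  for (i in seq_len(n)) {
    ls <- pairs$lnc_start[i]; le <- pairs$lnc_end[i]
    ms <- pairs$m_start[i]; me <- pairs$m_end[i]
    if (min(le, me) - max(ls, ms) < 1) {
      abort("classify_overlap() requires >=1 base of span overlap.")
    }
    same_span <- ls == ms && le == me
    if (ls >= ms && le <= me) {
      cls[i] <- "lncRNA_within_mRNA"; containment[i] <- "total"
      degenerate[i] <- same_span
    } else if (ms >= ls && me <= le) {
      cls[i] <- "mRNA_within_lncRNA"; containment[i] <- "total"
    } else {
      ov_lo <- max(ls, ms)
      ov_hi <- min(le, me) - 1L  # highest covered coordinate
      term <- function(start, end, strand) {
        # returns c(five, three) coordinates
        if (strand == "+") c(start, end - 1L) else c(end - 1L, start)
      }
      tl <- term(ls, le, pairs$lnc_strand[i])
      tm <- term(ms, me, pairs$m_strand[i])
      inov <- function(pos) pos >= ov_lo && pos <= ov_hi
      if (inov(tl[2]) && inov(tm[2])) {
        cls[i] <- "convergent"
      } else if (inov(tl[1]) && inov(tm[1])) {
        cls[i] <- "divergent"
      } else {
        abort("partial opposite-strand overlap with mixed 5'/3' termini: coordinate bug.")
      }
      containment[i] <- "partial"
    }
  }
  tibble(class = cls, containment = containment, degenerate = degenerate)
}

#' Summarise overlap classes
#'
#' @param pairs classified pairs from [find_antisense_overlaps()] (columns
#'   `overlap_class`, `containment`).
#' @return a list with `classes` (class, count, percent of total, one
#'   decimal), `containment` (partial/total split with percents) and
#'   `total`.
#' @export
summarize_overlap_classes <- function(pairs) {
  total <- nrow(pairs)
  if (total == 0) {
    return(list(
      classes = tibble(class = character(0), count = integer(0), percent = numeric(0)),
      containment = tibble(containment = character(0), count = integer(0),
                           percent = numeric(0)),
      total = 0L
    ))
  }
  class_levels <- c("convergent", "divergent", "lncRNA_within_mRNA",
                    "mRNA_within_lncRNA")
  classes <- pairs %>%
    count(overlap_class, name = "count") %>%
    rename(class = overlap_class) %>%
    mutate(percent = round(100 * count / total, 1)) %>%
    arrange(match(class, class_levels))
  containment <- pairs %>%
    count(containment, name = "count") %>%
    mutate(percent = round(100 * count / total, 1)) %>%
    arrange(match(containment, c("partial", "total")))
  list(classes = classes, containment = containment, total = total)
}

#' Attach expression correlations to overlap pairs
#'
#' @param pairs overlap pairs from [find_antisense_overlaps()].
#' @param pairs_lnc_m lncRNA-mRNA pair-correlation table from
#'   [pearson_pairs()].
#' @return `pairs` with columns `expression_r` and `expression_p` joined on
#'   (lncRNA, mRNA) id.
#' @export
attach_expression_correlation <- function(pairs, pairs_lnc_m) {
  corr <- orient_pairs(pairs_lnc_m, "lncRNA", "mRNA") %>%
    select(lnc_id = a_id, m_id = b_id, expression_r = r, expression_p = p)
  pairs %>% left_join(corr, by = c("lnc_id", "m_id"))
}

#' Correlate overlap length with expression correlation
#'
#' Pearson coefficients between the per-pair expression correlation and
#' each of the mean, minimum and maximum overlap lengths across pairs. A
#' zero-variance length statistic yields `NA` for that coefficient.
#'
#' @param pairs overlap pairs carrying `expression_r`, `overlap_mean`,
#'   `overlap_min`, `overlap_max` (see
#'   [attach_expression_correlation()]).
#' @return a tibble with columns `statistic` (`mean`/`min`/`max`), `r`, `n`.
#' @export
overlap_length_vs_correlation <- function(pairs) {
  ok <- pairs %>% filter(!is.na(expression_r))
  if (nrow(ok) < 3) abort("need >= 3 pairs with expression correlations.")
  one <- function(len) {
    if (sd(len) == 0 || sd(ok$expression_r) == 0) return(NA_real_)
    cor(ok$expression_r, len)
  }
  tibble(
    statistic = c("mean", "min", "max"),
    r = c(one(ok$overlap_mean), one(ok$overlap_min), one(ok$overlap_max)),
    n = nrow(ok)
  )
}

#' Convert overlap pairs to a node/edge graph
#' @param pairs classified overlap pairs, optionally with `expression_r`.
#' @return list of `nodes` and `edges` tibbles for [export_graph()].
#' @export
overlaps_to_graph <- function(pairs) {
  nodes <- bind_rows(
    tibble(id = pairs$lnc_id, class = "lncRNA"),
    tibble(id = pairs$m_id, class = "mRNA")
  ) %>% distinct()
  r <- if ("expression_r" %in% names(pairs)) pairs$expression_r else rep(NA_real_, nrow(pairs))
  p <- if ("expression_p" %in% names(pairs)) pairs$expression_p else rep(NA_real_, nrow(pairs))
  edges <- tibble(
    from = pairs$lnc_id, to = pairs$m_id, r = r, p = p,
    evidence = lapply(seq_len(nrow(pairs)), function(i) {
      paste0("overlap:", pairs$overlap_class[i])
    })
  )
  list(nodes = nodes, edges = edges)
}
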