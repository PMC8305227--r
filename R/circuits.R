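# Orient a pair table so a_class == want_a and b_class == want_b,
# swapping individual rows when stored the other way round.
orient_pairs <- function(pairs, want_a, want_b) {
  fwd <- pairs$a_class == want_a & pairs$b_class == want_b
  rev <- pairs$a_class == want_b & pairs$b_class == want_a & !fwd
  out <- pairs[fwd | rev, , drop = FALSE]
  sw <- rev[fwd | rev]
  if (any(sw)) {
    tmp_id <- out$a_id[sw]; tmp_cl <- out$a_class[sw]
    out$a_id[sw] <- out$b_id[sw]; out$a_class[sw] <- out$b_class[sw]
    out$b_id[sw] <- tmp_id;       out$b_class[sw] <- tmp_cl
  }
  out
}

# evidence sources with flag == 1 per (miRNA, partner), as a list-column
evidence_lists <- function(interactions, want_class) {
  if (is.null(interactions) || nrow(interactions) == 0) {
    return(tibble(mirna_id = character(0), partner_id = character(0),
                  evidence = list()))
  }
  interactions %>%
    filter(partner_class == want_class, flag == 1L) %>%
    group_by(mirna_id, partner_id) %>%
    summarise(evidence = list(sort(unique(source))), .groups = "drop")
}

#' Enumerate sign-constrained lncRNA-miRNA-mRNA triangle motifs
#'
#' A ceRNA axis is emitted iff its three pairwise correlations match the
#' miRNA-sponge sign pattern at the (inclusive) magnitude threshold:
#' `r(miRNA, lncRNA) <= -threshold`, `r(miRNA, mRNA) <= -threshold` and
#' `r(lncRNA, mRNA) >= +threshold`. With `require_evidence = TRUE` a motif
#' additionally needs at least one interaction-database hit on the
#' miRNA-mRNA axis AND at least one on the miRNA-lncRNA axis (OR across
#' sources within an axis). An optional `p_max` is applied conjunctively to
#' all three edges. Pairs with undefined `r` (zero-variance features) never
#' match.
#'
#' @param pairs_mi_lnc,pairs_mi_m,pairs_lnc_m pair-correlation tables from
#'   [pearson_pairs()] covering the miRNA-lncRNA, miRNA-mRNA and
#'   lncRNA-mRNA class pairs (either orientation).
#' @param interactions miRNA-target interaction table
#'   (see [read_interactions()]); required when `require_evidence = TRUE`.
#' @param threshold minimum correlation magnitude, inclusive; `>= 0`.
#' @param p_max optional maximum p-value for all three edges.
#' @param require_evidence gate motifs on interaction evidence (see above).
#' @param anchor optional feature id(s); keep only motifs containing one.
#' @param top_n optional cap applied via [rank_motifs()].
#' @return a tibble of motifs: `lnc_id`, `mi_id`, `m_id`, `r_mi_lnc`,
#'   `r_mi_m`, `r_lnc_m`, their p-values, and list-columns
#'   `evidence_mi_lnc`, `evidence_mi_m` of supporting sources.
#' @export
find_motifs <- function(pairs_mi_lnc, pairs_mi_m, pairs_lnc_m,
                        interactions = NULL, threshold = 0, p_max = NULL,
                        require_evidence = FALSE, anchor = NULL, top_n = NULL) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0) {
    abort("`threshold` must be a single magnitude >= 0.")
  }
  if (require_evidence && is.null(interactions)) {
    abort("`require_evidence = TRUE` needs an `interactions` table.")
  }
  ml <- orient_pairs(pairs_mi_lnc, "miRNA", "lncRNA") %>%
    filter(!is.na(r), r <= -threshold) %>%
    select(mi_id = a_id, lnc_id = b_id, r_mi_lnc = r, p_mi_lnc = p)
  mm <- orient_pairs(pairs_mi_m, "miRNA", "mRNA") %>%
    filter(!is.na(r), r <= -threshold) %>%
    select(mi_id = a_id, m_id = b_id, r_mi_m = r, p_mi_m = p)
  lm <- orient_pairs(pairs_lnc_m, "lncRNA", "mRNA") %>%
    filter(!is.na(r), r >= threshold) %>%
    select(lnc_id = a_id, m_id = b_id, r_lnc_m = r, p_lnc_m = p)
  if (!is.null(p_max)) {
    ml <- ml %>% filter(p_mi_lnc <= p_max)
    mm <- mm %>% filter(p_mi_m <= p_max)
    lm <- lm %>% filter(p_lnc_m <= p_max)
  }
  motifs <- ml %>%
    inner_join(mm, by = "mi_id", relationship = "many-to-many") %>%
    inner_join(lm, by = c("lnc_id", "m_id"))
  ev_m <- evidence_lists(interactions, "mRNA")
  ev_l <- evidence_lists(interactions, "lncRNA")
  motifs <- motifs %>%
    left_join(ev_l %>% rename(mi_id = mirna_id, lnc_id = partner_id,
                              evidence_mi_lnc = evidence),
              by = c("mi_id", "lnc_id")) %>%
    left_join(ev_m %>% rename(mi_id = mirna_id, m_id = partner_id,
                              evidence_mi_m = evidence),
              by = c("mi_id", "m_id"))
  fill_empty <- function(col) {
    lapply(col, function(e) if (is.null(e)) character(0) else e)
  }
  motifs$evidence_mi_lnc <- fill_empty(motifs$evidence_mi_lnc)
  motifs$evidence_mi_m <- fill_empty(motifs$evidence_mi_m)
  if (require_evidence) {
    motifs <- motifs %>%
      filter(lengths(evidence_mi_lnc) >= 1, lengths(evidence_mi_m) >= 1)
  }
  if (!is.null(anchor)) {
    known <- unique(c(motifs$lnc_id, motifs$mi_id, motifs$m_id,
                      pairs_mi_lnc$a_id, pairs_mi_lnc$b_id,
                      pairs_mi_m$a_id, pairs_mi_m$b_id,
                      pairs_lnc_m$a_id, pairs_lnc_m$b_id))
    bad <- setdiff(anchor, known)
    if (length(bad)) abort(paste0("unknown anchor id(s): ", paste(bad, collapse = ", ")))
    motifs <- motifs %>%
      filter(lnc_id %in% anchor | mi_id %in% anchor | m_id %in% anchor)
  }
  motifs <- motifs %>%
    select(lnc_id, mi_id, m_id, r_mi_lnc, r_mi_m, r_lnc_m,
           p_mi_lnc, p_mi_m, p_lnc_m, evidence_mi_lnc, evidence_mi_m)
  motifs <- rank_motifs(motifs, top_n = if (is.null(top_n)) nrow(motifs) else top_n)
  motifs
}

#' Rank motifs by their weakest edge
#'
#' Motifs are ordered by descending `min(|r_mi_lnc|, |r_mi_m|, |r_lnc_m|)` —
#' a motif is only as strong as its weakest correlation — with ties broken
#' lexicographically by (lncRNA, miRNA, mRNA) id, so the ordering is
#' deterministic under any input permutation.
#'
#' @param motifs tibble from [find_motifs()].
#' @param top_n number of motifs to keep (`>= 1`); more than available
#'   (or the default `Inf`) returns all.
#' @return the first `top_n` motifs in ranked order.
#' @export
rank_motifs <- function(motifs, top_n = Inf) {
  if (nrow(motifs) == 0) return(motifs)
  if (!is.numeric(top_n) || top_n < 1) abort("`top_n` must be >= 1.")
  motifs %>%
    mutate(min_abs_r = pmin(abs(r_mi_lnc), abs(r_mi_m), abs(r_lnc_m))) %>%
    arrange(desc(min_abs_r), lnc_id, mi_id, m_id) %>%
    select(-min_abs_r) %>%
    head(top_n)
}

#' Motif counts across a grid of correlation thresholds
#'
#' For each threshold, counts all sign-pattern motifs and the subset also
#' carrying interaction evidence on both miRNA axes. Both columns are
#' non-increasing in the threshold, and the gated count never exceeds the
#' ungated one.
#'
#' @inheritParams find_motifs
#' @param thresholds ascending numeric vector of magnitude thresholds.
#' @return a tibble with columns `threshold`, `motif_count`,
#'   `evidence_gated_count`.
#' @export
threshold_sweep <- function(pairs_mi_lnc, pairs_mi_m, pairs_lnc_m,
                            interactions = NULL, thresholds) {
  if (is.unsorted(thresholds)) abort("`thresholds` must be sorted ascending.")
  rows <- lapply(thresholds, function(th) {
    all_m <- find_motifs(pairs_mi_lnc, pairs_mi_m, pairs_lnc_m,
                         interactions = interactions, threshold = th)
    gated <- if (is.null(interactions)) {
      all_m[0, ]
    } else {
      all_m %>% filter(lengths(evidence_mi_lnc) >= 1, lengths(evidence_mi_m) >= 1)
    }
    tibble(threshold = th, motif_count = nrow(all_m),
           evidence_gated_count = nrow(gated))
  })
  bind_rows(rows)
}

#' Convert motifs to a node/edge graph
#'
#' @param motifs tibble from [find_motifs()].
#' @return a list with `nodes` (id, class) and `edges` (from, to, r, p,
#'   evidence) tibbles, ready for [export_graph()].
#' @export
motifs_to_graph <- function(motifs) {
  nodes <- bind_rows(
    tibble(id = motifs$lnc_id, class = "lncRNA"),
    tibble(id = motifs$mi_id, class = "miRNA"),
    tibble(id = motifs$m_id, class = "mRNA")
  ) %>% distinct()
  edges <- bind_rows(
    tibble(from = motifs$mi_id, to = motifs$lnc_id,
           r = motifs$r_mi_lnc, p = motifs$p_mi_lnc,
           evidence = motifs$evidence_mi_lnc),
    tibble(from = motifs$mi_id, to = motifs$m_id,
           r = motifs$r_mi_m, p = motifs$p_mi_m,
           evidence = motifs$evidence_mi_m),
    tibble(from = motifs$lnc_id, to = motifs$m_id,
           r = motifs$r_lnc_m, p = motifs$p_lnc_m,
           evidence = rep(list(character(0)), nrow(motifs)))
  ) %>% distinct(from, to, .keep_all = TRUE)
  list(nodes = nodes, edges = edges)
}

#' Flatten motif evidence list-columns for TSV export
#' @param motifs tibble from [find_motifs()].
#' @return a tibble with evidence as comma-joined strings.
#' @export
motifs_to_table <- function(motifs) {
  motifs %>%
    mutate(
      evidence_mi_lnc = vapply(evidence_mi_lnc, paste, character(1), collapse = ","),
      evidence_mi_m = vapply(evidence_mi_m, paste, character(1), collapse = ",")
    )
}
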