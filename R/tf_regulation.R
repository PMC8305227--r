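#' Extract transcription-factor rows from an expression matrix
#'
#' Restricts an mRNA expression matrix to the features named in a TF list
#' (e.g. a curated human TF catalogue) and reports the list members absent
#' from the matrix.
#'
#' @param x an [expression_matrix()].
#' @param tf_list non-empty character vector of TF gene ids.
#' @return the TF sub-matrix, with attribute `"absent"`: the tf_list
#'   members not found.
#' @export
extract_tfs <- function(x, tf_list) {
  if (!length(tf_list)) abort("`tf_list` must be non-empty.")
  present <- intersect(tf_list, feature_ids(x))
  if (!length(present)) abort("no tf_list member found in the expression matrix.")
  out <- subset_features(x, present)
  attr(out, "absent") <- setdiff(tf_list, present)
  out
}

#' Screen TF-target correlations with ChIP-seq binding gating
#'
#' A TF-target record is emitted iff its correlation passes the asymmetric
#' per-class cutoffs (`r <= neg_cut` OR `r >= pos_cut` for the target's
#' class) and, when `require_binding = TRUE`, at least one ChIP-seq source
#' reports a binding flag for the (TF, target) pair (OR across sources).
#' Negative-correlation records carry `sign_label = "(-)"`; positive ones
#' `"(+)"`. Self-pairs (a TF correlated with its own transcript) are
#' permitted.
#'
#' @param pair_tables a single pair-correlation table or a list of them,
#'   with TFs in `a_id` (see [pearson_pairs()] on an [extract_tfs()]
#'   sub-matrix vs each target-class matrix).
#' @param binding a binding table (see [read_binding()]); required when
#'   `require_binding = TRUE`.
#' @param neg_cut,pos_cut named numeric vectors of per-class cutoffs
#'   (names in `mRNA`, `miRNA`, `lncRNA`); `neg_cut <= 0 <= pos_cut`.
#'   Classes absent from the vectors are not screened.
#' @param require_binding gate on ChIP-seq evidence.
#' @return a tibble of records: `tf_id`, `target_id`, `target_class`, `r`,
#'   `p`, `sign_label`, one 0/1 column per binding source, and `gated`
#'   (TRUE iff >=1 binding flag).
#' @export
tf_target_search <- function(pair_tables, binding = NULL,
                             neg_cut = c(mRNA = -0.9, miRNA = -0.6, lncRNA = -0.7),
                             pos_cut = c(mRNA = 0.9, miRNA = 0.7, lncRNA = 0.8),
                             require_binding = FALSE) {
  if (any(neg_cut > 0) || any(pos_cut < 0)) {
    abort("`neg_cut` must be <= 0 and `pos_cut` >= 0 for every class.")
  }
  if (require_binding && is.null(binding)) {
    abort("`require_binding = TRUE` needs a `binding` table.")
  }
  if (is.data.frame(pair_tables)) pair_tables <- list(pair_tables)
  pairs <- bind_rows(pair_tables) %>%
    select(tf_id = a_id, target_id = b_id, target_class = b_class, r, p)
  classes <- intersect(names(neg_cut), names(pos_cut))
  pairs <- pairs %>%
    filter(target_class %in% classes, !is.na(r)) %>%
    filter(r <= neg_cut[target_class] | r >= pos_cut[target_class]) %>%
    mutate(sign_label = ifelse(r < 0, "(-)", "(+)"))
  sources <- if (is.null(binding)) character(0) else sort(unique(binding$source))
  if (length(sources)) {
    wide <- binding %>%
      tidyr::pivot_wider(names_from = source, values_from = flag, values_fill = 0L)
    pairs <- pairs %>% left_join(wide, by = c("tf_id", "target_id"))
    for (s in sources) pairs[[s]][is.na(pairs[[s]])] <- 0L
    pairs$gated <- rowSums(as.matrix(pairs[, sources, drop = FALSE])) >= 1
  } else {
    pairs$gated <- FALSE
  }
  if (require_binding) pairs <- pairs %>% filter(gated)
  pairs %>% arrange(tf_id, target_class, target_id)
}

#' Most frequent TFs by distinct target count
#'
#' Keeps TFs whose distinct targets across all three RNA classes number at
#' least `min_targets`, listing per-class targets with their correlation
#' sign labels, sorted by total target count (descending) then TF id.
#'
#' @param records gated records from [tf_target_search()].
#' @param min_targets minimum number of distinct targets (default 3).
#' @return a tibble with `tf_id`, `n_targets`, and per-class comma-joined
#'   target strings (`mRNA`, `miRNA`, `lncRNA`; negative correlations
#'   suffixed `"(-)"`).
#' @export
frequent_tfs <- function(records, min_targets = 3) {
  if (nrow(records) == 0) {
    return(tibble(tf_id = character(0), n_targets = integer(0),
                  mRNA = character(0), miRNA = character(0), lncRNA = character(0)))
  }
  labelled <- records %>%
    mutate(label = paste0(target_id, ifelse(sign_label == "(-)", "(-)", ""))) %>%
    distinct(tf_id, target_id, target_class, label)
  totals <- labelled %>%
    group_by(tf_id) %>%
    summarise(n_targets = n_distinct(target_id), .groups = "drop") %>%
    filter(n_targets >= min_targets)
  per_class <- labelled %>%
    filter(tf_id %in% totals$tf_id) %>%
    group_by(tf_id, target_class) %>%
    summarise(targets = paste(sort(label), collapse = ", "), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = target_class, values_from = targets)
  for (cl in c("mRNA", "miRNA", "lncRNA")) {
    if (!cl %in% names(per_class)) per_class[[cl]] <- NA_character_
  }
  totals %>%
    left_join(per_class, by = "tf_id") %>%
    select(tf_id, n_targets, mRNA, miRNA, lncRNA) %>%
    arrange(desc(n_targets), tf_id)
}
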