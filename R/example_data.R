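#' Bundled example: stringent-threshold uveal-melanoma ceRNA axes
#'
#' Eleven lncRNA-miRNA-mRNA axes published for the TCGA uveal-melanoma
#' cohort (80 tumors) at the most stringent correlation cutoff
#' (|r| >= 0.6 on every edge) together with their per-database
#' interaction-evidence flags (TarBase, miRTarBase on the miRNA-mRNA axis;
#' miRcode, LncBase validated/predicted, Encori on the miRNA-lncRNA axis).
#' The rows are re-shaped into the pair tables and interaction table the
#' motif query consumes, so the published filtering can be replayed
#' end-to-end.
#'
#' One miRNA-lncRNA pair appears in several axes with printed coefficients
#' differing in the last decimal (rounding in the source); the pair tables
#' deduplicate by pair and take the mean. P-values are recomputed from r at
#' n = 80 via the t-transform.
#'
#' @return a list with `rows` (the axis table as printed), `pairs_mi_lnc`,
#'   `pairs_mi_m`, `pairs_lnc_m` (pair-correlation tibbles) and
#'   `interactions` (see [read_interactions()]).
#' @export
load_stringent_axes <- function() {
  path <- system.file("extdata", "um_stringent_axes.tsv", package = "cernet",
                      mustWork = TRUE)
  rows <- readr::read_tsv(path, col_types = readr::cols(
    mi_id = readr::col_character(), m_id = readr::col_character(),
    lnc_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  n <- 80L
  mk_pairs <- function(a_id, a_class, b_id, b_class, r) {
    tibble(a_id = a_id, a_class = a_class, b_id = b_id, b_class = b_class, r = r) %>%
      group_by(a_id, a_class, b_id, b_class) %>%
      summarise(r = mean(r), .groups = "drop") %>%
      mutate(p = correlation_pvalue(r, n), n = n)
  }
  pairs_mi_m <- mk_pairs(rows$mi_id, "miRNA", rows$m_id, "mRNA", rows$r_mi_m)
  pairs_mi_lnc <- mk_pairs(rows$mi_id, "miRNA", rows$lnc_id, "lncRNA", rows$r_mi_lnc)
  pairs_lnc_m <- mk_pairs(rows$lnc_id, "lncRNA", rows$m_id, "mRNA", rows$r_lnc_m)
  ev <- function(value_cols, partner_id, partner_class) {
    long <- rows %>%
      select(mirna_id = mi_id, partner_id = all_of(partner_id),
             all_of(value_cols)) %>%
      tidyr::pivot_longer(all_of(value_cols), names_to = "source",
                          values_to = "flag") %>%
      mutate(partner_class = partner_class, flag = as.integer(flag)) %>%
      distinct(mirna_id, partner_id, source, .keep_all = TRUE)
    long
  }
  interactions <- bind_rows(
    ev(c("TarBase", "miRTarBase"), "m_id", "mRNA"),
    ev(c("miRcode", "LncBase_V", "LncBase_P", "Encori"), "lnc_id", "lncRNA")
  ) %>% select(mirna_id, partner_id, partner_class, source, flag)
  list(rows = rows, pairs_mi_lnc = pairs_mi_lnc, pairs_mi_m = pairs_mi_m,
       pairs_lnc_m = pairs_lnc_m, interactions = validate_interactions(interactions))
}
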