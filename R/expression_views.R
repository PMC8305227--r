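#' Group or order one feature's expression by a clinical parameter
#'
#' Categorical parameters partition the samples by value (samples missing
#' the parameter go into an explicit `"NA"` group); numeric parameters
#' yield the samples sorted ascending by the parameter, ties broken by
#' sample id, with missing values last.
#'
#' @param x an [expression_matrix()].
#' @param feature a feature id present in `x`.
#' @param clinical a clinical table as returned by [read_clinical()].
#' @param parameter the clinical parameter to group/order by.
#' @return a tibble with columns `sample_id`, `value` (expression),
#'   `parameter` (the parameter's value per sample) and either `group`
#'   (categorical) or `order` (numeric rank); attribute `"kind"` records
#'   the parameter kind and, for categorical parameters, attribute
#'   `"group_sizes"` the per-group counts.
#' @export
group_expression <- function(x, feature, clinical, parameter) {
  if (!feature %in% feature_ids(x)) abort(paste0("unknown feature: ", feature))
  if (!parameter %in% names(clinical$kinds)) {
    abort(paste0("unknown parameter '", parameter, "'; available: ",
                 paste(names(clinical$kinds), collapse = ", ")))
  }
  kind <- clinical$kinds[[parameter]]
  expr <- tibble(sample_id = sample_ids(x),
                 value = as.numeric(expr_values(x)[feature, ]))
  clin <- clinical$data %>% select(sample_id, parameter = all_of(parameter))
  out <- expr %>% left_join(clin, by = "sample_id")
  if (kind == "categorical") {
    out <- out %>%
      mutate(group = ifelse(is.na(parameter) | parameter == "", "NA",
                            as.character(parameter))) %>%
      arrange(group, sample_id)
    attr(out, "group_sizes") <- out %>% count(group, name = "count")
  } else {
    out <- out %>%
      arrange(is.na(parameter), parameter, sample_id) %>%
      mutate(order = row_number())
  }
  attr(out, "kind") <- kind
  out
}

#' Min-median-max scaling of expression values
#'
#' Piecewise-linear per-feature rescaling used for circuit heatmaps: the
#' minimum maps to 0 (green), the median to 0.5 (black) and the maximum to
#' 1 (red). A constant vector maps to all 0.5.
#'
#' @param values numeric vector (one feature's values) or a matrix
#'   (features in rows).
#' @param ref optional reference vector whose min/median/max define the
#'   scale (defaults to `values` itself); only meaningful for vector input.
#' @return rescaled values in \[0, 1\] with the same shape (values beyond
#'   the reference range are clamped).
#' @export
heatmap_scale <- function(values, ref = NULL) {
  scale_one <- function(v, anchor = v) {
    if (!length(v) || !length(anchor)) abort("need at least one value per feature.")
    lo <- min(anchor); mid <- median(anchor); hi <- max(anchor)
    v <- pmin(pmax(v, lo), hi)
    if (hi == lo) return(rep(0.5, length(v)))
    out <- numeric(length(v))
    low <- v <= mid
    if (mid > lo) out[low] <- 0.5 * (v[low] - lo) / (mid - lo) else out[low] <- 0.5
    if (hi > mid) out[!low] <- 0.5 + 0.5 * (v[!low] - mid) / (hi - mid) else out[!low] <- 0.5
    out
  }
  if (is.matrix(values)) {
    t(apply(values, 1, scale_one))
  } else if (is.null(ref)) {
    scale_one(values)
  } else {
    scale_one(values, anchor = ref)
  }
}
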