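#' Drop features with too many non-positive values
#'
#' Retains exactly the features whose expression is strictly positive in at
#' least `ceiling(min_fraction * n_samples)` samples — with the default
#' 0.75 and 80 samples this is the "at least 60 of 80" rule. Zeros that
#' survive the filter are kept in downstream correlation computation.
#'
#' @param x an [expression_matrix()].
#' @param min_fraction minimum fraction of samples with value > 0; in (0, 1].
#' @return the filtered `ExpressionMatrix`, with a `retention` attribute: a
#'   tibble of kept/dropped counts per feature class.
#' @export
filter_expressed <- function(x, min_fraction = 0.75) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1) {
    abort("`min_fraction` must be in (0, 1].")
  }
  v <- expr_values(x)
  if (nrow(v) == 0 || ncol(v) == 0) abort("empty expression matrix.")
  need <- ceiling(min_fraction * ncol(v))
  npos <- rowSums(v > 0)
  keep <- npos >= need
  retention <- tibble(
    class = unname(feature_classes(x)),
    kept = keep
  ) %>%
    count(class, kept) %>%
    tidyr::pivot_wider(names_from = kept, values_from = n, values_fill = 0L)
  names(retention)[names(retention) == "TRUE"] <- "kept"
  names(retention)[names(retention) == "FALSE"] <- "dropped"
  if (!"kept" %in% names(retention)) retention$kept <- 0L
  if (!"dropped" %in% names(retention)) retention$dropped <- 0L
  out <- expression_matrix(v[keep, , drop = FALSE],
                           feature_classes(x)[keep], x$units)
  attr(out, "retention") <- retention
  out
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the exact null distribution of the t-transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, the
#' standard test for a Pearson coefficient. `|r| = 1` returns the smallest
#' representable positive double rather than 0.
#'
#' @param r Pearson coefficient(s) in \[-1, 1\].
#' @param n sample count(s), `n >= 3`.
#' @return two-sided p-value(s) in (0, 1].
#' @export
correlation_pvalue <- function(r, n) {
  if (any(n < 3)) abort("`n` must be >= 3 for a correlation p-value.")
  if (any(abs(r) > 1, na.rm = TRUE)) abort("`r` must lie in [-1, 1].")
  p <- rep(NA_real_, length(r))
  sat <- !is.na(r) & abs(r) >= 1
  ok <- !is.na(r) & !sat
  if (any(ok)) {
    tt <- r[ok] * sqrt((n - 2) / (1 - r[ok]^2))
    p[ok] <- 2 * pt(abs(tt), df = n - 2, lower.tail = FALSE)
  }
  p[sat] <- .Machine$double.xmin
  pmin(p, 1)
}

#' All pairwise Pearson correlations between two expression matrices
#'
#' Computes `r` over all shared samples (zeros included) for every
#' (feature of `a`, feature of `b`) pair — exactly `|A| * |B|` records,
#' minus self-pairs when the same feature id occurs in both inputs and
#' `drop_self = TRUE`. Zero-variance features yield `r = NA` records that
#' downstream thresholds skip.
#'
#' @param a,b `ExpressionMatrix` objects over the same samples, in the same
#'   order.
#' @param drop_self drop pairs where both ids are identical (default TRUE).
#' @param adjust_p apply Benjamini-Hochberg correction across the returned
#'   table (off by default; raw p-values are reported otherwise).
#' @param as_matrix return the raw `|A| x |B|` correlation matrix instead of
#'   a tidy record table (no p-values; useful for count checks at scale).
#' @return a tibble with columns `a_id`, `a_class`, `b_id`, `b_class`, `r`,
#'   `p`, `n`, or a matrix when `as_matrix = TRUE`.
#' @export
pearson_pairs <- function(a, b, drop_self = TRUE, adjust_p = FALSE,
                          as_matrix = FALSE) {
  stopifnot(inherits(a, "ExpressionMatrix"), inherits(b, "ExpressionMatrix"))
  if (!identical(sample_ids(a), sample_ids(b))) {
    abort("`a` and `b` must share the same samples in the same order.")
  }
  va <- expr_values(a)
  vb <- expr_values(b)
  nsmp <- ncol(va)
  if (nsmp < 3) abort("need at least 3 samples to correlate.")
  sda <- apply(va, 1, sd)
  sdb <- apply(vb, 1, sd)
  rmat <- suppressWarnings(cor(t(va), t(vb)))
  rmat[sda == 0, ] <- NA_real_
  if (any(sdb == 0)) rmat[, sdb == 0] <- NA_real_
  # clamp tiny fp excursions beyond +-1
  rmat[] <- pmin(pmax(rmat, -1), 1)
  if (as_matrix) return(rmat)
  out <- tibble(
    a_id = rep(rownames(rmat), times = ncol(rmat)),
    a_class = rep(unname(feature_classes(a)), times = ncol(rmat)),
    b_id = rep(colnames(rmat), each = nrow(rmat)),
    b_class = rep(unname(feature_classes(b)), each = nrow(rmat)),
    r = as.vector(rmat),
    n = nsmp
  )
  if (drop_self) out <- out %>% filter(a_id != b_id)
  # exact-1 self/duplicate correlations keep a representable p
  out$p <- correlation_pvalue(out$r, nsmp)
  if (adjust_p) out$p <- stats::p.adjust(out$p, method = "BH")
  out %>% select(a_id, a_class, b_id, b_class, r, p, n)
}

#' Write or read a pair-correlation table
#'
#' TSV with columns `a_id`, `a_class`, `b_id`, `b_class`, `r`, `p`, `n` —
#' the downloadable artifact of the correlation engine.
#'
#' @param pairs tibble from [pearson_pairs()].
#' @param path destination TSV.
#' @return `path` invisibly (`write_pairs`) or the tibble (`read_pairs`).
#' @export
write_pairs <- function(pairs, path) {
  readr::write_tsv(pairs, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    a_id = readr::col_character(), a_class = readr::col_character(),
    b_id = readr::col_character(), b_class = readr::col_character(),
    r = readr::col_double(), p = readr::col_double(), n = readr::col_integer()
  ), progress = FALSE)
}
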