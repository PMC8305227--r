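#' Construct an ExpressionMatrix
#'
#' A light container for a features x samples expression matrix with a
#' class label (`"mRNA"`, `"lncRNA"`, `"miRNA"`) per feature and a free-text
#' unit tag per class (e.g. `"log2(RPM+1)"` for miRNAs).
#'
#' @param values numeric matrix, features in rows (rownames required),
#'   samples in columns (colnames required). All cells must be finite.
#' @param feature_class named character vector mapping every feature id to
#'   one of `"mRNA"`, `"lncRNA"`, `"miRNA"`.
#' @param units optional named character vector of unit tags per class.
#' @return an object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, feature_class, units = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (features x samples).")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry feature ids as rownames and sample ids as colnames.")
  }
  if (anyDuplicated(rownames(values))) {
    dups <- unique(rownames(values)[duplicated(rownames(values))])
    abort(paste0("duplicate feature ids: ", paste(dups, collapse = ", ")))
  }
  if (any(!is.finite(values))) {
    abort("expression values must be finite; missing cells are not supported.")
  }
  known <- c("mRNA", "lncRNA", "miRNA")
  missing_ann <- setdiff(rownames(values), names(feature_class))
  if (length(missing_ann)) {
    abort(paste0("features without a class annotation: ",
                 paste(head(missing_ann, 10), collapse = ", ")))
  }
  feature_class <- feature_class[rownames(values)]
  bad <- feature_class[!feature_class %in% known]
  if (length(bad)) {
    abort(paste0("unknown feature class(es): ", paste(unique(bad), collapse = ", "),
                 " (expected mRNA, lncRNA or miRNA)"))
  }
  structure(
    list(values = values, feature_class = feature_class, units = units),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cls <- table(x$feature_class)
  cat("ExpressionMatrix: ", nrow(x$values), " features x ", ncol(x$values),
      " samples\n", sep = "")
  cat("  classes: ", paste(names(cls), cls, sep = "=", collapse = ", "), "\n", sep = "")
  if (!is.null(x$units)) {
    cat("  units:   ", paste(names(x$units), x$units, sep = ": ", collapse = "; "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Feature and sample accessors
#' @param x an `ExpressionMatrix`.
#' @return `feature_ids()`/`sample_ids()`: character vectors;
#'   `feature_classes()`: named character vector; `expr_values()`: the
#'   numeric matrix.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' @rdname feature_ids
#' @export
feature_classes <- function(x) x$feature_class

#' @rdname feature_ids
#' @export
expr_values <- function(x) x$values

#' Subset an ExpressionMatrix by feature ids
#' @param x an `ExpressionMatrix`.
#' @param ids feature ids to keep (order preserved).
#' @return an `ExpressionMatrix` restricted to `ids`.
#' @export
subset_features <- function(x, ids) {
  missing <- setdiff(ids, feature_ids(x))
  if (length(missing)) {
    abort(paste0("unknown feature id(s): ", paste(head(missing, 10), collapse = ", ")))
  }
  expression_matrix(x$values[ids, , drop = FALSE], x$feature_class[ids], x$units)
}

#' Read an expression matrix with its class annotation
#'
#' Expression is a TSV whose header row holds sample ids and whose first
#' column holds feature ids; the annotation TSV must contain columns
#' `feature_id` and `class` covering every feature in the matrix.
#'
#' @param path path to the expression TSV.
#' @param annotation_path path to the annotation TSV (`feature_id`, `class`).
#' @param units optional named character vector of unit tags per class.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, annotation_path, units = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("expression TSV needs a feature-id column plus >=1 sample column.")
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate feature ids in ", path, ": ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  num <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(storage <- matrix(as.numeric(num), nrow = nrow(num),
                                     dimnames = list(ids, colnames(num))))
  if (anyNA(storage)) {
    bad <- which(is.na(storage), arr.ind = TRUE)[1, ]
    abort(paste0("non-numeric expression cell at feature '", ids[bad[1]],
                 "', sample '", colnames(num)[bad[2]], "'"))
  }
  ann <- readr::read_tsv(annotation_path,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!all(c("feature_id", "class") %in% names(ann))) {
    abort("annotation TSV must have columns `feature_id` and `class`.")
  }
  fc <- setNames(ann$class, ann$feature_id)
  expression_matrix(storage, fc, units)
}

#' Write an ExpressionMatrix (and its annotation) to TSV
#' @param x an `ExpressionMatrix`.
#' @param path expression TSV destination.
#' @param annotation_path optional annotation TSV destination.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, annotation_path = NULL) {
  df <- tibble(feature_id = feature_ids(x))
  df <- dplyr::bind_cols(df, as_tibble(x$values))
  readr::write_tsv(df, path, progress = FALSE)
  if (!is.null(annotation_path)) {
    readr::write_tsv(tibble(feature_id = feature_ids(x),
                            class = unname(feature_classes(x))),
                     annotation_path, progress = FALSE)
  }
  invisible(path)
}

#' Read a miRNA-target interaction table
#'
#' TSV with columns `mirna_id`, `partner_id`, `partner_class`
#' (`mRNA`/`lncRNA`), `source` (e.g. TarBase, miRTarBase, miRcode,
#' LncBase-validated, LncBase-predicted, Encori) and binary `flag`.
#' Unknown source names are accepted as-is so new databases do not break
#' parsing.
#'
#' @param path path to the TSV.
#' @return a tibble with the five columns above.
#' @export
read_interactions <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    mirna_id = readr::col_character(),
    partner_id = readr::col_character(),
    partner_class = readr::col_character(),
    source = readr::col_character(),
    flag = readr::col_integer()
  ), progress = FALSE)
  validate_interactions(tab)
}

validate_interactions <- function(tab) {
  if (!all(tab$flag %in% c(0L, 1L))) abort("interaction flags must be 0 or 1.")
  if (!all(tab$partner_class %in% c("mRNA", "lncRNA"))) {
    abort("interaction partner_class must be 'mRNA' or 'lncRNA'.")
  }
  key <- paste(tab$mirna_id, tab$partner_id, tab$source)
  if (anyDuplicated(key)) {
    abort("duplicate (miRNA, partner, source) interaction records.")
  }
  as_tibble(tab)
}

#' Read a TF-promoter binding table
#'
#' TSV with columns `tf_id`, `target_id`, `source` (e.g. ENCODE, ChEA,
#' TransmiR) and binary `flag` recording a ChIP-seq binding hit of the TF
#' at the target gene's promoter.
#'
#' @param path path to the TSV.
#' @return a tibble with the four columns above.
#' @export
read_binding <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    tf_id = readr::col_character(),
    target_id = readr::col_character(),
    source = readr::col_character(),
    flag = readr::col_integer()
  ), progress = FALSE)
  validate_binding(tab)
}

validate_binding <- function(tab) {
  if (!all(tab$flag %in% c(0L, 1L))) abort("binding flags must be 0 or 1.")
  key <- paste(tab$tf_id, tab$target_id, tab$source)
  if (anyDuplicated(key)) abort("duplicate (TF, target, source) binding records.")
  as_tibble(tab)
}

#' Read a clinical table
#'
#' TSV with a `sample_id` column plus one column per clinicopathological
#' parameter. Parameter kinds (categorical vs numeric) are taken from
#' `kinds` when supplied, otherwise inferred: a column that parses fully
#' as numeric (ignoring missing values) is numeric, anything else
#' categorical.
#'
#' @param path path to the TSV.
#' @param kinds optional named character vector (`"categorical"` or
#'   `"numeric"`) per parameter.
#' @return a list with `data` (tibble, `sample_id` first) and `kinds`
#'   (named character vector).
#' @export
read_clinical <- function(path, kinds = NULL) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!"sample_id" %in% names(tab)) abort("clinical TSV must have a `sample_id` column.")
  params <- setdiff(names(tab), "sample_id")
  inferred <- vapply(params, function(p) {
    v <- tab[[p]]
    v <- v[!is.na(v) & v != ""]
    if (length(v) && !anyNA(suppressWarnings(as.numeric(v)))) "numeric" else "categorical"
  }, character(1))
  if (!is.null(kinds)) {
    if (!all(kinds %in% c("categorical", "numeric"))) {
      abort("parameter kinds must be 'categorical' or 'numeric'.")
    }
    inferred[names(kinds)] <- kinds
  }
  for (p in params[inferred == "numeric"]) tab[[p]] <- as.numeric(tab[[p]])
  list(data = as_tibble(tab), kinds = inferred)
}

# ---- gene loci ------------------------------------------------------------

#' Read gene loci from GTF or BED into the internal convention
#'
#' Coordinates are normalized to 0-based half-open intervals: BED is kept
#' as-is, GTF (1-based closed) has 1 subtracted from starts. Multiple
#' isoforms (BED lines or GTF transcripts) of one gene id are grouped under
#' that gene.
#'
#' @param path path to the annotation file.
#' @param dialect `"auto"` (by file extension), `"gtf"` or `"bed"`.
#' @param classes optional named character vector mapping gene id to
#'   `"mRNA"` or `"lncRNA"`; genes not named get class `NA`.
#' @return a tibble of isoforms with columns `gene_id`, `class`, `chrom`,
#'   `strand`, `start`, `end` (0-based half-open), `isoform`.
#' @export
read_loci <- function(path, dialect = c("auto", "gtf", "bed"), classes = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gtf"
  }
  if (dialect == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    ids <- gr$name
  } else {
    gr <- rtracklayer::import(path, format = "GTF")
    keep <- if ("type" %in% names(S4Vectors::mcols(gr))) {
      as.character(gr$type) %in% c("transcript", "mRNA", "gene")
    } else rep(TRUE, length(gr))
    # prefer transcript rows when present so isoforms are transcript spans
    if (any(as.character(gr$type) == "transcript")) {
      keep <- as.character(gr$type) == "transcript"
    }
    gr <- gr[keep]
    ids <- gr$gene_id
  }
  if (any(is.na(ids))) abort("locus records without a gene id.")
  strands <- as.character(GenomicRanges::strand(gr))
  if (any(strands == "*")) abort("loci must carry a strand (+ or -).")
  # GRanges is 1-based closed whatever the source format; normalize here
  out <- tibble(
    gene_id = as.character(ids),
    chrom   = as.character(GenomicRanges::seqnames(gr)),
    strand  = strands,
    start   = GenomicRanges::start(gr) - 1L,
    end     = GenomicRanges::end(gr)
  )
  if (any(out$start >= out$end)) abort("empty or inverted locus interval after normalization.")
  multi <- out %>%
    group_by(gene_id) %>%
    summarise(nc = n_distinct(chrom), ns = n_distinct(strand), .groups = "drop") %>%
    filter(nc > 1 | ns > 1)
  if (nrow(multi)) {
    abort(paste0("isoforms of one gene on multiple chromosomes/strands: ",
                 paste(multi$gene_id, collapse = ", ")))
  }
  out <- out %>%
    group_by(gene_id) %>%
    mutate(isoform = row_number()) %>%
    ungroup()
  out$class <- if (is.null(classes)) NA_character_ else unname(classes[out$gene_id])
  out %>% select(gene_id, class, chrom, strand, start, end, isoform)
}

# ---- graph export ---------------------------------------------------------

#' Export a correlation network as JSON (and optionally GraphML)
#'
#' Nodes carry their RNA class; edges carry the correlation `r`, its
#' p-value, a sign attribute (`"correlated"` for r > 0, `"anti-correlated"`
#' for r < 0) and the list of interaction databases supporting the edge.
#' Edges without supporting evidence get style `"dotted"`, evidenced edges
#' `"solid"`, mirroring the convention that only physically supported
#' relationships are drawn solid.
#'
#' @param nodes tibble with columns `id` and `class`.
#' @param edges tibble with columns `from`, `to`, `r`, `p` and a
#'   list-column `evidence` (character vectors, possibly empty).
#' @param path output JSON path.
#' @param graphml_path optional GraphML destination.
#' @return `path`, invisibly.
#' @export
export_graph <- function(nodes, edges, path, graphml_path = NULL) {
  stopifnot(all(c("id", "class") %in% names(nodes)))
  stopifnot(all(c("from", "to", "r", "p") %in% names(edges)))
  unknown <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(unknown)) {
    abort(paste0("edge references unknown node(s): ", paste(unknown, collapse = ", ")))
  }
  if (!"evidence" %in% names(edges)) edges$evidence <- rep(list(character(0)), nrow(edges))
  edge_list <- lapply(seq_len(nrow(edges)), function(i) {
    ev <- edges$evidence[[i]]
    list(
      from = edges$from[i], to = edges$to[i],
      r = edges$r[i], p = edges$p[i],
      sign = if (is.na(edges$r[i])) NA else
        if (edges$r[i] >= 0) "correlated" else "anti-correlated",
      evidence = as.list(ev),
      style = if (length(ev)) "solid" else "dotted"
    )
  })
  node_list <- lapply(seq_len(nrow(nodes)), function(i) {
    list(id = nodes$id[i], class = nodes$class[i])
  })
  jsonlite::write_json(list(nodes = node_list, edges = edge_list), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(
      d = edges %>%
        mutate(evidence = vapply(evidence, paste, character(1), collapse = ",")) %>%
        mutate(sign = ifelse(r >= 0, "correlated", "anti-correlated"),
               style = ifelse(nchar(evidence) > 0, "solid", "dotted")),
      directed = FALSE,
      vertices = nodes
    )
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(path)
}
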