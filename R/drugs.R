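#' Read a drug-target table from TSV
#'
#' Expects columns `drug`, `gene`, and optionally `status`, `atc_class`,
#' `source`. Duplicate (drug, gene) rows within a source are removed.
#'
#' @param path File path.
#' @return A `data.frame`.
#' @export
read_drug_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("drug", "gene") %in% names(df)))
  key <- paste(df$drug, df$gene, df$source %||% "")
  df <- df[!duplicated(key), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Associate drugs to a disease gene set by hypergeometric overlap
#'
#' For every drug, tests whether its target set overlaps the disease gene
#' set more than expected by chance, with the upper-tail hypergeometric
#' probability (the same kernel as [fisher_overrep()]), then BH-adjusts
#' across drugs.
#'
#' @param table Drug-target `data.frame` with columns `drug`, `gene`.
#' @param disease_genes Character vector of disease-associated genes
#'   (e.g. mutual DEGs, or hubs plus reporter TFs).
#' @param universe Background gene ids; default all genes appearing in
#'   `table`.
#' @param alpha Adjusted-p significance level; default 0.05.
#' @param source_tag Optional label recorded in the `supported_by` column.
#' @return A `data.frame` sorted ascending by `p`: `drug`, `k`, `K`, `n`,
#'   `N`, `overlap_genes` (comma-separated), `p`, `adj_p`, `significant`,
#'   `supported_by`.
#' @export
associate_drugs <- function(table, disease_genes, universe = NULL,
                            alpha = 0.05, source_tag = NA_character_) {
  stopifnot(is.data.frame(table), all(c("drug", "gene") %in% names(table)))
  if (nrow(table) == 0) stop_input("empty drug-target table")
  table <- table[!duplicated(table[, c("drug", "gene")]), , drop = FALSE]
  if (is.null(universe)) universe <- unique(table$gene)
  universe <- unique(as.character(universe))
  disease <- unique(intersect(as.character(disease_genes), universe))
  if (length(disease) == 0) stop_input("empty disease gene set after harmonization")
  N <- length(universe)
  n <- length(disease)
  targets <- split(table$gene, table$drug)
  targets <- lapply(targets, intersect, universe)
  targets <- targets[lengths(targets) > 0]
  rows <- lapply(names(targets), function(d) {
    tg <- targets[[d]]
    ov <- intersect(tg, disease)
    data.frame(drug = d, k = length(ov), K = length(tg), n = n, N = N,
               overlap_genes = paste(sort(ov), collapse = ","),
               p = fisher_overrep(length(ov), length(tg), n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out$significant <- out$adj_p < alpha
  out$supported_by <- source_tag
  out <- out[order(out$p, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect drug associations from two evidence sources
#'
#' Keeps the drugs supported by both sources, mirroring the
#' common-drugs-between-databases design. Under the default rule a drug
#' must be significant (`adj_p < alpha`) in both association tables;
#' under `rule = "either"` it must be significant in at least one and
#' present in both.
#'
#' @param assoc_a,assoc_b Association tables from [associate_drugs()],
#'   computed against the same disease gene set.
#' @param alpha Significance level; default 0.05.
#' @param rule `"both"` (default) or `"either"`.
#' @return The rows of `assoc_a` for the surviving drugs, with
#'   `supported_by` recording both source tags and `p_other`/`adj_p_other`
#'   carrying the second source's values.
#' @export
intersect_sources <- function(assoc_a, assoc_b, alpha = 0.05,
                              rule = c("both", "either")) {
  rule <- match.arg(rule)
  shared <- intersect(assoc_a$drug, assoc_b$drug)
  ia <- match(shared, assoc_a$drug)
  ib <- match(shared, assoc_b$drug)
  sig_a <- assoc_a$adj_p[ia] < alpha
  sig_b <- assoc_b$adj_p[ib] < alpha
  keep <- if (rule == "both") sig_a & sig_b else sig_a | sig_b
  out <- assoc_a[ia[keep], , drop = FALSE]
  tag_a <- assoc_a$supported_by[ia[keep]]
  tag_b <- assoc_b$supported_by[ib[keep]]
  out$supported_by <- paste(ifelse(is.na(tag_a), "sourceA", tag_a),
                            ifelse(is.na(tag_b), "sourceB", tag_b),
                            sep = "+")
  out$p_other <- assoc_b$p[ib[keep]]
  out$adj_p_other <- assoc_b$adj_p[ib[keep]]
  out <- out[order(out$p, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tally associated drugs by development status and ATC class
#'
#' Counts unique drugs per development status and per ATC (anatomical)
#' class, with percentages over unique drugs rounded to two decimals.
#' Drugs without an annotation fall in an `"unclassified"` bucket.
#'
#' @param drugs Character vector of drug ids, or a `data.frame` with a
#'   `drug` column (e.g. from [associate_drugs()]).
#' @param annotations `data.frame` with columns `drug`, `status`,
#'   `atc_class` (extra columns ignored; one row per drug is used).
#' @return List of two `data.frame`s, `status` and `atc_class`, each with
#'   columns `label`, `count`, `percent`.
#' @export
classify_drugs <- function(drugs, annotations) {
  if (is.data.frame(drugs)) drugs <- drugs$drug
  drugs <- unique(as.character(drugs))
  stopifnot(is.data.frame(annotations), "drug" %in% names(annotations))
  ann <- annotations[!duplicated(annotations$drug), , drop = FALSE]
  idx <- match(drugs, ann$drug)
  tally <- function(values) {
    values[is.na(values) | !nzchar(values)] <- "unclassified"
    tab <- sort(table(values), decreasing = TRUE)
    data.frame(label = names(tab), count = as.integer(tab),
               percent = round(100 * as.integer(tab) / length(drugs), 2),
               stringsAsFactors = FALSE)
  }
  list(status = tally(as.character(ann$status[idx])),
       atc_class = tally(as.character(ann$atc_class[idx])))
}
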