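#' Construct an expression dataset
#'
#' Bundles a genes x samples log2-expression matrix with its case/control
#' design. This is the unit of input for [gene_statistics()].
#'
#' @param matrix Numeric matrix of log2 expression, one row per gene.
#'   Row names are the gene identifiers (required, unique).
#' @param group Character (or factor) vector of per-sample labels, one per
#'   column, each `"case"` or `"control"`.
#' @return An object of class `expression_dataset`: a list with elements
#'   `matrix` and `group`.
#' @examples
#' m <- matrix(rnorm(20), 4, 5, dimnames = list(paste0("g", 1:4), NULL))
#' ds <- expression_dataset(m, c("case", "case", "case", "control", "control"))
#' @export
expression_dataset <- function(matrix, group) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop_input("'matrix' must be a numeric matrix")
  }
  if (is.null(rownames(matrix))) stop_input("'matrix' must have gene row names")
  if (anyDuplicated(rownames(matrix))) {
    dup <- rownames(matrix)[duplicated(rownames(matrix))][1L]
    stop_input("duplicate gene id: ", dup)
  }
  group <- as.character(group)
  if (length(group) != ncol(matrix)) {
    stop_input("'group' length must equal the number of samples")
  }
  if (!all(group %in% c("case", "control"))) {
    stop_input("group labels must be 'case' or 'control'")
  }
  if (!all(c("case", "control") %in% group)) {
    stop_input("both groups must be non-empty")
  }
  structure(list(matrix = matrix, group = group),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples (%d case, %d control)\n",
              nrow(x$matrix), ncol(x$matrix),
              sum(x$group == "case"), sum(x$group == "control")))
  invisible(x)
}

# Invert the trigamma function by Newton iteration; used to fit the
# inverse-chi-square variance prior by matching moments of log sample
# variances.
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

# Empirical-Bayes shrinkage of gene-wise variances toward a common prior.
# The prior (d0, s0^2) is fitted by method of moments on log variances:
# if s2 ~ s0^2 * F(df, d0) then var(log s2) exceeds trigamma(df/2) by
# trigamma(d0/2), which is inverted to get d0.
squeeze_var <- function(s2, df) {
  stopifnot(df > 0)
  pos <- s2 > 0
  if (!any(pos)) {
    return(list(s2_post = s2, df_prior = 0, s2_prior = 0))
  }
  z <- log(s2[pos])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- if (length(e) > 1) stats::var(e) else 0
  excess <- evar - trigamma(df / 2)
  if (excess > 0) {
    df_prior <- 2 * trigamma_inverse(excess)
    s2_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
    s2_post <- (df_prior * s2_prior + df * s2) / (df_prior + df)
  } else {
    df_prior <- Inf
    s2_prior <- exp(emean)
    s2_post <- rep(s2_prior, length(s2))
  }
  list(s2_post = s2_post, df_prior = df_prior, s2_prior = s2_prior)
}

#' Per-gene differential-expression statistics
#'
#' Computes, for every gene, the case-minus-control log2 fold change and a
#' two-sided p-value for zero group-mean difference. The default statistic
#' is an empirical-Bayes moderated t: gene-wise pooled variances are shrunk
#' toward a common prior fitted by method of moments on the log variances,
#' and the t reference distribution gains the prior degrees of freedom.
#' A plain Welch t is available as a fallback.
#'
#' @param dataset An [expression_dataset()].
#' @param method `"moderated"` (default) or `"welch"`.
#' @return A `data.frame` with one row per gene: `gene_id`, `log_fc`
#'   (case mean minus control mean, log2 units), `t`, `p`.
#' @details Genes with zero variance in both groups and equal means get
#'   `p = 1`. Each group must contain at least two samples.
#' @seealso [call_degs()], [bh_adjust()]
#' @export
gene_statistics <- function(dataset, method = c("moderated", "welch")) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "expression_dataset"))
  x <- dataset$matrix
  case <- dataset$group == "case"
  n1 <- sum(case)
  n2 <- sum(!case)
  if (n1 < 2 || n2 < 2) stop_input("each group needs at least 2 samples")

  m1 <- rowMeans(x[, case, drop = FALSE])
  m2 <- rowMeans(x[, !case, drop = FALSE])
  log_fc <- m1 - m2
  ss1 <- rowSums((x[, case, drop = FALSE] - m1)^2)
  ss2 <- rowSums((x[, !case, drop = FALSE] - m2)^2)

  if (method == "moderated") {
    df <- n1 + n2 - 2
    s2 <- (ss1 + ss2) / df
    sq <- squeeze_var(s2, df)
    se <- sqrt(sq$s2_post * (1 / n1 + 1 / n2))
    df_total <- df + sq$df_prior
    tstat <- ifelse(se > 0, log_fc / se,
                    ifelse(log_fc == 0, 0, sign(log_fc) * Inf))
    p <- 2 * stats::pt(-abs(tstat), df = df_total)
  } else {
    v1 <- ss1 / (n1 - 1)
    v2 <- ss2 / (n2 - 1)
    se2 <- v1 / n1 + v2 / n2
    se <- sqrt(se2)
    tstat <- ifelse(se > 0, log_fc / se,
                    ifelse(log_fc == 0, 0, sign(log_fc) * Inf))
    # Welch-Satterthwaite df; degenerate zero-variance genes fall back to 1
    df_w <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
    df_w[!is.finite(df_w) | df_w <= 0] <- 1
    p <- 2 * stats::pt(-abs(tstat), df = df_w)
  }
  p[tstat == 0] <- 1
  data.frame(gene_id = rownames(x), log_fc = log_fc, t = tstat, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, order-preserving with the input indexing and
#' capped at 1.
#'
#' @param pvals Numeric vector of raw p-values in `[0, 1]`.
#' @return Numeric vector of BH-adjusted p-values, same order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(pvals) {
  check_prob(pvals, "pvals")
  stats::p.adjust(pvals, method = "BH")
}

#' Call differentially expressed genes
#'
#' Applies the adjusted-p and fold-change thresholds to the per-gene
#' statistics and assigns a direction. A gene is `up` when
#' `adj_p < alpha` and `log_fc >= log2(fc_cutoff)`, `down` when
#' `adj_p < alpha` and `log_fc <= -log2(fc_cutoff)`, otherwise `none`.
#' The inequality on `adj_p` is strict.
#'
#' @param stats Output of [gene_statistics()].
#' @param alpha Adjusted-p significance level; default 0.01.
#' @param fc_cutoff Linear fold-change cutoff (>= 1), applied as
#'   `|log_fc| >= log2(fc_cutoff)`; default 2.
#' @return The input `data.frame` with added columns `adj_p` and
#'   `direction` (factor-free character: `"up"`, `"down"`, `"none"`).
#' @export
call_degs <- function(stats, alpha = 0.01, fc_cutoff = 2) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop_input("'alpha' must be in (0, 1)")
  }
  if (!is.numeric(fc_cutoff) || length(fc_cutoff) != 1 || fc_cutoff < 1) {
    stop_input("'fc_cutoff' must be >= 1")
  }
  stopifnot(all(c("gene_id", "log_fc", "p") %in% names(stats)))
  lfc_cut <- log2(fc_cutoff)
  out <- stats
  out$adj_p <- bh_adjust(out$p)
  out$direction <- ifelse(
    out$adj_p < alpha & out$log_fc >= lfc_cut, "up",
    ifelse(out$adj_p < alpha & out$log_fc <= -lfc_cut, "down", "none"))
  out
}

#' Mutual differentially expressed genes across datasets
#'
#' Intersects same-direction DEG calls across two or more datasets: the
#' mutual up set is the intersection of the per-dataset up sets, and
#' likewise for down. A gene called up in one dataset and down in another
#' is in neither output.
#'
#' @param ... Two or more DEG tables from [call_degs()], or a single list
#'   of them.
#' @return List with character vectors `up` and `down`.
#' @export
mutual_degs <- function(...) {
  tables <- list(...)
  if (length(tables) == 1 && is.list(tables[[1]]) &&
      !is.data.frame(tables[[1]])) {
    tables <- tables[[1]]
  }
  if (length(tables) < 2) stop_input("need at least two DEG tables")
  universes <- lapply(tables, function(t) t$gene_id)
  shared <- Reduce(intersect, universes)
  dropped <- length(unique(unlist(universes))) - length(shared)
  if (dropped > 0) {
    message(sprintf("mutual_degs: %d gene(s) absent from at least one dataset dropped", dropped))
  }
  dir_set <- function(t, d) t$gene_id[t$direction == d]
  list(up = sort(Reduce(intersect, lapply(tables, dir_set, "up"))),
       down = sort(Reduce(intersect, lapply(tables, dir_set, "down"))))
}

#' Read an expression dataset from TSV files
#'
#' @param expr_path Genes x samples TSV with gene ids in the first column
#'   and sample ids in the header.
#' @param groups_path Two-column TSV `sample<TAB>group` with group labels
#'   `case`/`control`.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(expr_path, groups_path) {
  expr <- utils::read.delim(expr_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  m <- as.matrix(expr[, -1, drop = FALSE])
  rownames(m) <- as.character(expr[[1]])
  grp <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  idx <- match(colnames(m), grp[[1]])
  if (anyNA(idx)) stop_input("sample ids in expression and group files disagree")
  expression_dataset(m, grp[[2]][idx])
}

#' Write an expression dataset to TSV files
#'
#' @param dataset An [expression_dataset()].
#' @param expr_path,groups_path Output paths (see [read_expression()]).
#' @return Invisibly, `dataset`.
#' @export
write_expression <- function(dataset, expr_path, groups_path) {
  m <- dataset$matrix
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%03d", seq_len(ncol(m)))
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(m), group = dataset$group),
    groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dataset)
}
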