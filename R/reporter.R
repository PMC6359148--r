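#' Construct a typed regulator-target network
#'
#' A bipartite regulatory network of TF-target and miRNA-target edges.
#' Duplicate (regulator, target) pairs are removed.
#'
#' @param edges A `data.frame` with columns `regulator`, `type`
#'   (`"TF"` or `"miRNA"`), and `target`.
#' @return An object of class `regulatory_network` (a cleaned
#'   `data.frame`).
#' @export
regulatory_network <- function(edges) {
  stopifnot(is.data.frame(edges),
            all(c("regulator", "type", "target") %in% names(edges)))
  edges <- edges[, c("regulator", "type", "target")]
  edges[] <- lapply(edges, as.character)
  bad <- !edges$type %in% c("TF", "miRNA")
  if (any(bad)) {
    warning(sprintf("%d edge(s) with unknown regulator type dropped", sum(bad)))
    edges <- edges[!bad, , drop = FALSE]
  }
  edges <- edges[!duplicated(edges[, c("regulator", "target")]), , drop = FALSE]
  if (nrow(edges) == 0) stop_input("empty regulatory network")
  rownames(edges) <- NULL
  class(edges) <- c("regulatory_network", "data.frame")
  edges
}

#' Read a regulator-target table from TSV
#'
#' Expects three columns: regulator, type (`TF`/`miRNA`), target.
#'
#' @param path File path.
#' @return A [regulatory_network()].
#' @export
read_regnet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("regulator", "type", "target")
  regulatory_network(df)
}

#' Inverse-normal transform of a gene-level p-value
#'
#' Converts differential-expression p-values to z-scores by
#' `z = qnorm(1 - p)`, so small p-values map to large positive z.
#' `p = 0` is clamped to the machine floor with a warning; the resulting
#' z is clamped to `[-z_floor, z_floor]`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param z_floor Magnitude at which z-scores are clamped; default 8.
#' @return Numeric vector of z-scores.
#' @examples
#' gene_z(0.5)      # 0
#' gene_z(0.0228)   # ~2
#' @export
gene_z <- function(p, z_floor = 8) {
  check_prob(p, "p")
  if (any(p == 0)) {
    warning("p-value(s) of 0 clamped to the machine floor")
    p[p == 0] <- .Machine$double.xmin
  }
  z <- stats::qnorm(p, lower.tail = FALSE)
  pmin(pmax(z, -z_floor), z_floor)
}

#' Aggregate target z-scores for one regulator
#'
#' The raw reporter score of a regulator with `k` scored targets is
#' `z_raw = sum(z) / sqrt(k)`, a scale-stable aggregate that is standard
#' normal when the targets' z-scores are independent standard normals.
#'
#' @param z Numeric vector of target z-scores.
#' @param min_targets Minimum number of targets required; default 2.
#' @return The aggregate score (scalar).
#' @export
aggregate_z <- function(z, min_targets = 2) {
  k <- length(z)
  if (k < min_targets) {
    stop_input(sprintf("regulator has %d scored target(s); need >= %d",
                       k, min_targets))
  }
  sum(z) / sqrt(k)
}

# Monte-Carlo background moments of the aggregate score for size-k sets
# drawn uniformly without replacement from the gene z pool. Seeded per k
# so results do not depend on regulator processing order.
background_moments <- function(k, gene_z_pool, n_samples, seed) {
  npool <- length(gene_z_pool)
  if (npool < k) stop_input("background pool smaller than target count")
  agg <- with_seed(child_seed(seed, k), {
    vapply(seq_len(n_samples),
           function(i) sum(gene_z_pool[sample.int(npool, k)]),
           numeric(1)) / sqrt(k)
  })
  c(mu = mean(agg), sigma = stats::sd(agg))
}

#' Background-correct a raw reporter score
#'
#' Standardizes `z_raw` against the Monte-Carlo null of uniformly drawn
#' size-`k` gene sets from the scored universe:
#' `z_corr = (z_raw - mu_k) / sigma_k`, with `mu_k` and `sigma_k` the mean
#' and standard deviation of the aggregate score over `n_samples` random
#' sets. The p-value is the upper normal tail of `z_corr`.
#'
#' @param z_raw Raw aggregate score from [aggregate_z()].
#' @param k Number of scored targets.
#' @param gene_z_pool z-scores of the whole scored gene universe.
#' @param n_samples Number of Monte-Carlo draws; default 10000.
#' @param seed Integer RNG seed.
#' @return List with `z_corr`, `p`, `mu_k`, `sigma_k`.
#' @export
background_correct <- function(z_raw, k, gene_z_pool, n_samples = 10000,
                               seed = 1) {
  if (n_samples < 1000) stop_input("'n_samples' must be >= 1000")
  mom <- background_moments(k, gene_z_pool, n_samples, seed)
  if (mom[["sigma"]] == 0) {
    stop_input("degenerate background (constant z pool): sigma_k = 0")
  }
  z_corr <- (z_raw - mom[["mu"]]) / mom[["sigma"]]
  list(z_corr = z_corr, p = stats::pnorm(z_corr, lower.tail = FALSE),
       mu_k = mom[["mu"]], sigma_k = mom[["sigma"]])
}

#' Score reporter regulators over a regulatory network
#'
#' Implements the reporter-features scoring of TFs and miRNAs: each gene's
#' differential-expression p-value is inverse-normal transformed
#' ([gene_z()]), each regulator's targets are aggregated
#' ([aggregate_z()]), and the aggregate is standardized against random
#' same-size gene sets ([background_correct()]). p-values are
#' BH-adjusted within regulator type (TF and miRNA separately), and
#' regulators with `adj_p < alpha` are flagged as reporters.
#'
#' @param deg_stats Per-gene statistics from [gene_statistics()] (raw
#'   p-values are used; see `use_adjusted`).
#' @param regnet A [regulatory_network()].
#' @param alpha Adjusted-p cut-off for the reporter flag; default 0.01.
#' @param min_targets Minimum scored targets per regulator; default 2.
#' @param n_samples Monte-Carlo background draws; default 10000.
#' @param seed Integer RNG seed for the background sampling.
#' @param signed If `TRUE`, target z-scores are multiplied by the sign of
#'   the target's log fold change before aggregation (directional
#'   variant); default `FALSE`.
#' @param use_adjusted Use BH-adjusted instead of raw gene p-values as the
#'   transform input; default `FALSE`.
#' @return A `data.frame` sorted ascending by `p`: `regulator`, `type`,
#'   `k`, `z_raw`, `z_corr`, `p`, `adj_p`, `significant`.
#' @export
reporter_table <- function(deg_stats, regnet, alpha = 0.01, min_targets = 2,
                           n_samples = 10000, seed = 1, signed = FALSE,
                           use_adjusted = FALSE) {
  stopifnot(is.data.frame(deg_stats),
            all(c("gene_id", "p") %in% names(deg_stats)))
  if (!inherits(regnet, "regulatory_network")) regnet <- regulatory_network(regnet)
  p_in <- if (use_adjusted) bh_adjust(deg_stats$p) else deg_stats$p
  z <- gene_z(p_in)
  if (signed) z <- z * sign(deg_stats$log_fc)
  names(z) <- deg_stats$gene_id

  net <- regnet[regnet$target %in% deg_stats$gene_id, , drop = FALSE]
  if (nrow(net) == 0) stop_input("no regulatory edge maps to the scored genes")
  split_targets <- split(net$target, net$regulator)
  types <- vapply(split(net$type, net$regulator), `[[`, "", 1L)

  ks <- lengths(split_targets)
  keep <- ks >= min_targets
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    message(sprintf("reporter_table: %d regulator(s) with < %d scored targets skipped",
                    n_skip, min_targets))
  }
  split_targets <- split_targets[keep]
  if (length(split_targets) == 0) stop_input("no regulator has enough scored targets")
  ks <- ks[keep]
  types <- types[keep]

  moments <- new.env(parent = emptyenv())
  rows <- lapply(names(split_targets), function(reg) {
    zt <- z[split_targets[[reg]]]
    k <- length(zt)
    z_raw <- sum(zt) / sqrt(k)
    key <- as.character(k)
    if (is.null(moments[[key]])) {
      moments[[key]] <- background_moments(k, z, n_samples, seed)
    }
    mom <- moments[[key]]
    if (mom[["sigma"]] == 0) {
      stop_input("degenerate background (constant z pool): sigma_k = 0")
    }
    z_corr <- (z_raw - mom[["mu"]]) / mom[["sigma"]]
    data.frame(regulator = reg, type = types[[reg]], k = k, z_raw = z_raw,
               z_corr = z_corr, p = stats::pnorm(z_corr, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- NA_real_
  for (ty in unique(out$type)) {
    sel <- out$type == ty
    out$adj_p[sel] <- bh_adjust(out$p[sel])
  }
  out$significant <- out$adj_p < alpha
  out <- out[order(out$p, out$regulator), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reporters shared across datasets
#'
#' Intersects the significant reporter sets of several per-dataset
#' reporter tables, within regulator type, mirroring a mutual-reporter
#' design over independent cohorts.
#'
#' @param ... Two or more tables from [reporter_table()], or a single list
#'   of them.
#' @return List with character vectors `TF` and `miRNA`.
#' @export
mutual_reporters <- function(...) {
  tables <- list(...)
  if (length(tables) == 1 && is.list(tables[[1]]) &&
      !is.data.frame(tables[[1]])) {
    tables <- tables[[1]]
  }
  if (length(tables) < 2) stop_input("need at least two reporter tables")
  sig <- function(t, ty) t$regulator[t$significant & t$type == ty]
  list(TF = sort(Reduce(intersect, lapply(tables, sig, "TF"))),
       miRNA = sort(Reduce(intersect, lapply(tables, sig, "miRNA"))))
}
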