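#' Read a gene-set collection from a GMT file
#'
#' One set per tab-separated line: set id, description, then member genes.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection` (see [gene_set_collection()]).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, 1L) < 3L
  if (any(bad)) stop_input("GMT line(s) with fewer than 3 fields: ",
                           paste(which(bad), collapse = ", "))
  ids <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  names(desc) <- ids
  gene_set_collection(sets, descriptions = desc)
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return Invisibly, `collection`.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$descriptions[[id]] %||% "", collection$sets[[id]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(collection)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of member gene ids.
#' @param descriptions Optional named character vector of set descriptions.
#' @param universe Background gene ids; defaults to the union of all set
#'   members (the annotated-gene convention used by enrichment web tools).
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, universe = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop_input("'sets' must be a named list")
  }
  if (anyDuplicated(names(sets))) stop_input("duplicate set ids")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0)) stop_input("every set must be non-empty")
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets, use.names = FALSE)))
  } else {
    universe <- unique(as.character(universe))
    sets <- lapply(sets, intersect, universe)
    sets <- sets[lengths(sets) > 0]
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets,
                 descriptions = descriptions[names(sets)],
                 universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets over %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Upper-tail hypergeometric (one-sided Fisher) overlap probability
#'
#' Probability of observing `k` or more query genes inside a set of size
#' `K`, for a query of size `n` drawn from a universe of size `N`:
#' `P(X >= k)` with `X ~ Hypergeometric(N, K, n)`. This is the one-sided
#' Fisher exact test for overrepresentation.
#'
#' @param k Observed overlap count.
#' @param K Set (category) size.
#' @param n Query size.
#' @param N Universe size.
#' @return The tail probability, a number in `(0, 1]`.
#' @examples
#' fisher_overrep(3, 4, 4, 8)  # 17/70
#' @export
fisher_overrep <- function(k, K, n, N) {
  check_count(c(k, K, n, N) + 1L, "counts")  # allow zeros
  if (k > K || k > n || K > N || n > N) {
    stop_input("inconsistent counts: need k <= min(K, n) and K, n <= N")
  }
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Gene-set overrepresentation analysis
#'
#' Tests every set in the collection for overrepresentation in the query
#' by the one-sided Fisher exact (hypergeometric) test, with BH adjustment
#' across tested sets. Query genes absent from the collection universe are
#' dropped (with a message) before the query size is computed; coverage is
#' the percentage of the mapped query falling in the set.
#'
#' @param query Character vector of gene ids.
#' @param collection A [gene_set_collection()].
#' @param alpha Adjusted-p significance level; default 0.05.
#' @return A `data.frame` sorted ascending by `p`, one row per set with
#'   non-zero overlap: `set_id`, `description`, `k`, `set_size`,
#'   `query_size`, `universe_size`, `coverage` (percent), `p`, `adj_p`,
#'   `significant`.
#' @export
enrich <- function(query, collection, alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(as.character(query))
  mapped <- intersect(query, collection$universe)
  dropped <- length(query) - length(mapped)
  if (dropped > 0) {
    message(sprintf("enrich: %d query gene(s) outside the universe dropped", dropped))
  }
  if (length(mapped) == 0) stop_input("no query gene maps to the universe")
  N <- length(collection$universe)
  n <- length(mapped)
  rows <- lapply(names(collection$sets), function(id) {
    members <- collection$sets[[id]]
    k <- length(intersect(mapped, members))
    if (k == 0) return(NULL)
    data.frame(set_id = id,
               description = unname(collection$descriptions[[id]] %||% ""),
               k = k, set_size = length(members), query_size = n,
               universe_size = N,
               coverage = 100 * k / n,
               p = fisher_overrep(k, length(members), n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop_input("query overlaps no set in the collection")
  }
  out$adj_p <- bh_adjust(out$p)
  out$significant <- out$adj_p < alpha
  out <- out[order(out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
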