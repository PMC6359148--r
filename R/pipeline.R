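#' Pipeline configuration
#'
#' Collects every stage parameter with defaults matching the pipeline's
#' canonical thresholds: DEG calling at adjusted p < 0.01 with fold-change
#' cutoff 2, enrichment at adjusted p < 0.05, reporter regulators at
#' adjusted p < 0.01, survival significance at log-rank p < 0.05, 10 hubs,
#' MCODE vertex weight percentage 0.2 with haircut on.
#'
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "deg", "enrich", "network", "reporter", "survival",
#'   "drugs")`.
#' @param alpha_deg,fc_cutoff DEG thresholds.
#' @param alpha_enrich Enrichment threshold.
#' @param alpha_reporter Reporter threshold.
#' @param alpha_survival Log-rank threshold.
#' @param alpha_drugs Drug-association threshold.
#' @param deg_method Statistic for [gene_statistics()].
#' @param n_hubs,hub_method Hub selection parameters.
#' @param neighbors Subnetwork induction neighborhood (0 or 1).
#' @param vwp,haircut,fluff,min_module_size MCODE parameters.
#' @param min_targets,n_samples,signed_reporter Reporter parameters.
#' @param split Risk-partition split rule.
#' @param sim A [sim_config()] used by the simulate stage.
#' @param seed Global seed (also forwarded to `sim` unless that was set
#'   explicitly).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = c("simulate", "deg", "enrich",
                                       "network", "reporter", "survival",
                                       "drugs"),
                            alpha_deg = 0.01, fc_cutoff = 2,
                            alpha_enrich = 0.05, alpha_reporter = 0.01,
                            alpha_survival = 0.05, alpha_drugs = 0.05,
                            deg_method = "moderated",
                            n_hubs = 10, hub_method = "intersection",
                            neighbors = 1,
                            vwp = 0.2, haircut = TRUE, fluff = FALSE,
                            min_module_size = 3,
                            min_targets = 2, n_samples = 10000,
                            signed_reporter = FALSE,
                            split = "median",
                            sim = NULL, seed = 1) {
  known <- c("simulate", "deg", "enrich", "network", "reporter",
             "survival", "drugs")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) stop_input("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(sim)) sim <- sim_config(seed = seed)
  cfg <- as.list(environment())
  cfg$known <- NULL
  cfg$bad <- NULL
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys are [pipeline_config()] arguments; the optional `sim`
#' mapping holds [sim_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  do.call(pipeline_config, y)
}

#' Validate pipeline input files
#'
#' Per-file format checks with row-level diagnostics. Fatal problems
#' (unreadable file, duplicate gene ids, non-positive survival times,
#' bad event codes) are distinguished from warnings (e.g. regulator rows
#' with an unknown type, which the readers drop).
#'
#' @param paths Named list/vector of file paths; recognized names are
#'   `expression`, `groups`, `network`, `regnet`, `survival`, `drugs`,
#'   `gene_sets` (a name may carry a numeric suffix, e.g.
#'   `expression_1`).
#' @return A `data.frame` report with columns `file`, `level`
#'   (`"fatal"`/`"warning"`/`"ok"`), `message`; attribute `fatal` says
#'   whether any fatal problem was found.
#' @export
validate_inputs <- function(paths) {
  report <- list()
  note <- function(file, level, message) {
    report[[length(report) + 1]] <<- data.frame(
      file = file, level = level, message = message,
      stringsAsFactors = FALSE)
  }
  for (nm in names(paths)) {
    path <- paths[[nm]]
    kind <- sub("_[0-9]+$", "", nm)
    if (!file.exists(path)) {
      note(path, "fatal", "file not found")
      next
    }
    res <- try(switch(
      kind,
      expression = {
        df <- utils::read.delim(path, check.names = FALSE)
        ids <- as.character(df[[1]])
        if (anyDuplicated(ids)) {
          note(path, "fatal", paste("duplicate gene id:",
                                    ids[duplicated(ids)][1]))
        } else if (!all(vapply(df[-1], is.numeric, logical(1)))) {
          note(path, "fatal", "non-numeric expression column")
        } else note(path, "ok", sprintf("%d genes x %d samples",
                                        nrow(df), ncol(df) - 1))
      },
      groups = {
        df <- utils::read.delim(path)
        bad <- !df[[2]] %in% c("case", "control")
        if (any(bad)) {
          note(path, "fatal", paste("unknown group label at row",
                                    which(bad)[1]))
        } else note(path, "ok", sprintf("%d samples", nrow(df)))
      },
      survival = {
        df <- utils::read.delim(path)
        if (any(df$time <= 0)) {
          note(path, "fatal", paste("non-positive time at row",
                                    which(df$time <= 0)[1]))
        } else if (!all(df$event %in% c(0, 1))) {
          note(path, "fatal", paste("bad event code at row",
                                    which(!df$event %in% c(0, 1))[1]))
        } else note(path, "ok", sprintf("%d patients, %d events",
                                        nrow(df), sum(df$event)))
      },
      regnet = {
        df <- utils::read.delim(path)
        bad <- !df[[2]] %in% c("TF", "miRNA")
        if (any(bad)) {
          note(path, "warning",
               sprintf("%d row(s) with unknown regulator type dropped on read",
                       sum(bad)))
        }
        if (!all(bad)) note(path, "ok", sprintf("%d edges", sum(!bad)))
        else note(path, "fatal", "no valid regulatory edge")
      },
      drugs = {
        df <- utils::read.delim(path)
        if (!all(c("drug", "gene") %in% names(df))) {
          note(path, "fatal", "missing drug/gene columns")
        } else note(path, "ok", sprintf("%d rows, %d drugs", nrow(df),
                                        length(unique(df$drug))))
      },
      network = {
        g <- read_network(path)
        note(path, "ok", sprintf("%d nodes, %d edges",
                                 igraph::vcount(g), igraph::ecount(g)))
      },
      gene_sets = {
        gs <- read_gmt(path)
        note(path, "ok", sprintf("%d sets", length(gs$sets)))
      },
      note(path, "warning", "unrecognized input kind; not checked")
    ), silent = TRUE)
    if (inherits(res, "try-error")) {
      note(path, "fatal", paste("unreadable:",
                                trimws(attr(res, "condition")$message)))
    }
  }
  out <- do.call(rbind, report)
  attr(out, "fatal") <- any(out$level == "fatal")
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> differential expression -> mutual DEGs ->
#' enrichment -> network (subnetwork, hubs, modules) -> reporter
#' regulators -> survival stratification -> drug repositioning, writing
#' each stage's tables under `outdir` and recording a run manifest
#' (configuration snapshot, input checksums, per-stage record counts,
#' package version, seed, timestamps). Stages not listed in
#' `config$stages` are skipped; downstream stages abort with a clear
#' error if their inputs were neither produced nor supplied.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory.
#' @param inputs Optional named list of pre-existing input paths (same
#'   names as [write_bundle()] produces); used when the simulate stage is
#'   disabled.
#' @return Invisibly, a list with the manifest and in-memory stage
#'   results.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir,
                         inputs = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    version = as.character(utils::packageVersion("netreporter")),
    seed = config$seed, started = format(Sys.time(), usetz = TRUE),
    config = unclass(config[setdiff(names(config), "sim")]),
    sim_config = unclass(config$sim),
    stages = list())
  results <- list()
  counts <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
    message(sprintf("[%s] %s", stage,
                    paste(names(list(...)), unlist(list(...)),
                          sep = "=", collapse = ", ")))
  }

  indir <- file.path(outdir, "inputs")
  if ("simulate" %in% config$stages) {
    bundle <- simulate_bundle(config$sim)
    paths <- write_bundle(bundle, indir)
    results$bundle <- bundle
    counts("simulate", genes = config$sim$n_genes,
           datasets = config$sim$n_datasets,
           network_nodes = igraph::vcount(bundle$network))
  } else if (length(config$stages) == 0 && is.null(inputs)) {
    bundle <- list()
    paths <- character(0)
  } else {
    if (is.null(inputs)) stop_input("simulate disabled and no 'inputs' given")
    paths <- unlist(inputs)
    n_ds <- sum(grepl("^expression", names(paths)))
    bundle <- list(
      datasets = lapply(seq_len(n_ds), function(d) {
        read_expression(paths[[sprintf("expression_%d", d)]],
                        paths[[sprintf("groups_%d", d)]])
      }),
      network = if ("network" %in% names(paths))
        read_network(paths[["network"]]),
      regnet = if ("regnet" %in% names(paths))
        read_regnet(paths[["regnet"]]),
      survival = if ("survival" %in% names(paths))
        read_survival(paths[["survival"]]),
      drugs = if ("drugs" %in% names(paths))
        read_drug_table(paths[["drugs"]]),
      gene_sets = if ("gene_sets" %in% names(paths))
        read_gmt(paths[["gene_sets"]]))
  }
  manifest$inputs <- as.list(tools::md5sum(
    paths[file.exists(paths)]))

  deg_tables <- NULL
  mutual <- NULL
  if ("deg" %in% config$stages) {
    stats_list <- lapply(bundle$datasets, gene_statistics,
                         method = config$deg_method)
    deg_tables <- lapply(stats_list, call_degs, alpha = config$alpha_deg,
                         fc_cutoff = config$fc_cutoff)
    for (d in seq_along(deg_tables)) {
      write_tsv(deg_tables[[d]], file.path(outdir, sprintf("deg_%d.tsv", d)))
    }
    mutual <- mutual_degs(deg_tables)
    writeLines(mutual$up, file.path(outdir, "mutual_up.txt"))
    writeLines(mutual$down, file.path(outdir, "mutual_down.txt"))
    results$deg <- deg_tables
    results$mutual <- mutual
    counts("deg",
           up = paste(vapply(deg_tables,
                             function(t) sum(t$direction == "up"), 1L),
                      collapse = "/"),
           down = paste(vapply(deg_tables,
                               function(t) sum(t$direction == "down"), 1L),
                        collapse = "/"),
           mutual_up = length(mutual$up), mutual_down = length(mutual$down))
  }

  if ("enrich" %in% config$stages) {
    if (is.null(mutual)) stop_input("enrich stage needs the deg stage")
    if (is.null(bundle$gene_sets)) stop_input("enrich stage needs a gene-set collection")
    for (side in c("up", "down")) {
      q <- mutual[[side]]
      if (length(q) == 0) next
      tab <- enrich(q, bundle$gene_sets, alpha = config$alpha_enrich)
      write_tsv(tab, file.path(outdir, sprintf("enrichment_%s.tsv", side)))
      results$enrichment[[side]] <- tab
    }
    counts("enrich",
           significant_up = if (is.null(results$enrichment$up)) 0L else
             sum(results$enrichment$up$significant),
           significant_down = if (is.null(results$enrichment$down)) 0L else
             sum(results$enrichment$down$significant))
  }

  hubs <- NULL
  if ("network" %in% config$stages) {
    if (is.null(mutual)) stop_input("network stage needs the deg stage")
    if (is.null(bundle$network)) stop_input("network stage needs an interaction network")
    sub <- induce_subnetwork(bundle$network, c(mutual$up, mutual$down),
                             neighbors = config$neighbors)
    metrics <- centralities(sub)
    hubs <- select_hubs(metrics, n_hubs = config$n_hubs,
                        method = config$hub_method)
    metrics$hub_rank <- match(metrics$node, hubs)
    write_tsv(metrics[order(-metrics$degree, metrics$node), ],
              file.path(outdir, "node_metrics.tsv"))
    writeLines(hubs, file.path(outdir, "hubs.txt"))
    modules <- mcode_modules(sub, vwp = config$vwp,
                             haircut = config$haircut,
                             fluff = config$fluff,
                             min_size = config$min_module_size)
    mod_df <- if (length(modules$modules) > 0) {
      data.frame(module = seq_along(modules$modules),
                 score = modules$scores,
                 size = lengths(modules$modules),
                 members = vapply(modules$modules, paste, "",
                                  collapse = ","),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(module = integer(0), score = numeric(0),
                 size = integer(0), members = character(0))
    }
    write_tsv(mod_df, file.path(outdir, "modules.tsv"))
    results$subnetwork <- sub
    results$metrics <- metrics
    results$hubs <- hubs
    results$modules <- modules
    counts("network", subnetwork_nodes = igraph::vcount(sub),
           hubs = length(hubs), modules = length(modules$modules))
  }

  if ("reporter" %in% config$stages) {
    if (is.null(bundle$regnet)) stop_input("reporter stage needs a regulatory network")
    stats_list <- lapply(bundle$datasets, gene_statistics,
                         method = config$deg_method)
    rep_tables <- lapply(seq_along(stats_list), function(d) {
      reporter_table(stats_list[[d]], bundle$regnet,
                     alpha = config$alpha_reporter,
                     min_targets = config$min_targets,
                     n_samples = config$n_samples,
                     seed = child_seed(config$seed, 100 + d),
                     signed = config$signed_reporter)
    })
    for (d in seq_along(rep_tables)) {
      write_tsv(rep_tables[[d]],
                file.path(outdir, sprintf("reporters_%d.tsv", d)))
    }
    results$reporters <- rep_tables
    if (length(rep_tables) >= 2) {
      results$mutual_reporters <- mutual_reporters(rep_tables)
      writeLines(c(results$mutual_reporters$TF,
                   results$mutual_reporters$miRNA),
                 file.path(outdir, "mutual_reporters.txt"))
      counts("reporter",
             mutual_tfs = length(results$mutual_reporters$TF),
             mutual_mirnas = length(results$mutual_reporters$miRNA))
    } else {
      counts("reporter",
             significant = sum(rep_tables[[1]]$significant))
    }
  }

  if ("survival" %in% config$stages) {
    if (is.null(bundle$survival)) stop_input("survival stage needs clinical data")
    covs <- setdiff(names(bundle$survival), c("patient", "time", "event"))
    if (!is.null(hubs)) {
      found <- intersect(hubs, covs)
      if (length(found) > 0) covs <- found
    }
    model <- cox_fit(bundle$survival, covariates = covs)
    write_tsv(data.frame(covariate = model$covariates, beta = model$beta,
                         se = model$se, hr = exp(model$beta)),
              file.path(outdir, "cox_model.tsv"))
    part <- partition_and_test(model, bundle$survival,
                               alpha = config$alpha_survival,
                               split = config$split)
    write_tsv(part$partition, file.path(outdir, "risk_partition.tsv"))
    for (grp in c("low", "high")) {
      sel <- part$partition$group == grp
      write_tsv(km_curve(bundle$survival$time[sel],
                         bundle$survival$event[sel]),
                file.path(outdir, sprintf("km_%s.tsv", grp)))
    }
    write_tsv(part$covariate_tests, file.path(outdir, "risk_ttests.tsv"))
    jsonlite::write_json(
      list(hazard_ratio = part$hazard_ratio, hr_model = part$hr_model,
           log_rank_chi2 = part$log_rank_chi2,
           log_rank_p = part$log_rank_p,
           significant = part$significant),
      file.path(outdir, "survival_summary.json"),
      auto_unbox = TRUE, digits = NA)
    results$cox <- model
    results$risk <- part
    counts("survival", covariates = length(model$covariates),
           hazard_ratio = round(part$hazard_ratio, 3),
           log_rank_p = signif(part$log_rank_p, 3))
  }

  if ("drugs" %in% config$stages) {
    if (is.null(bundle$drugs)) stop_input("drugs stage needs a drug-target table")
    if (is.null(mutual)) stop_input("drugs stage needs the deg stage")
    disease <- c(mutual$up, mutual$down)
    tab <- bundle$drugs
    src <- unique(tab$source %||% "all")
    universe <- unique(tab$gene)
    assoc <- lapply(src, function(s) {
      rows <- if (is.null(tab$source)) tab else tab[tab$source == s, ]
      associate_drugs(rows, disease, universe = universe,
                      alpha = config$alpha_drugs, source_tag = s)
    })
    names(assoc) <- src
    for (s in src) {
      write_tsv(assoc[[s]], file.path(outdir, sprintf("drugs_%s.tsv", s)))
    }
    final <- if (length(assoc) >= 2) {
      intersect_sources(assoc[[1]], assoc[[2]], alpha = config$alpha_drugs)
    } else {
      assoc[[1]][assoc[[1]]$significant, , drop = FALSE]
    }
    write_tsv(final, file.path(outdir, "drugs_common.tsv"))
    tallies <- classify_drugs(final, tab)
    jsonlite::write_json(tallies, file.path(outdir, "drug_classes.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    results$drug_assoc <- assoc
    results$drugs_common <- final
    results$drug_classes <- tallies
    counts("drugs", tested = nrow(assoc[[1]]), common = nrow(final))
  }

  manifest$finished <- format(Sys.time(), usetz = TRUE)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(list(manifest = manifest, results = results))
}
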