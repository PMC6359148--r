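#' Simulation configuration
#'
#' Parameters of the synthetic study: two case/control expression cohorts
#' with planted differential genes, a scale-free protein-interaction
#' network with planted hubs and clique modules, a typed regulatory
#' network with planted reporter regulators, an exponential-hazard
#' survival cohort with a planted prognostic signature, and a two-source
#' drug-target table with planted disease-associated drugs.
#'
#' Defaults mirror the study conditions the pipeline is meant to emulate:
#' two cohorts totalling 206 cases and 14 controls (74/5 and 132/9), a
#' planted log2 fold change of 2 (the fold-change cutoff of the DEG
#' caller), a survival cohort of 467 patients, 10 planted hubs and 10
#' planted reporter TFs plus 10 reporter miRNAs, and a planted risk
#' signature targeting a high/low-risk hazard ratio of 2.5.
#'
#' @param n_genes Number of genes in the universe.
#' @param n_case,n_control Per-dataset group sizes (recycled to
#'   `n_datasets`).
#' @param n_datasets Number of independent expression datasets.
#' @param n_up,n_down Numbers of planted up- and downregulated genes.
#' @param effect_lfc Planted log2 fold-change magnitude.
#' @param noise_sd Per-gene log2 expression standard deviation.
#' @param baseline_range Range of per-gene baseline log2 expression.
#' @param n_nodes Protein-interaction network size.
#' @param pa_edges,pa_power Preferential-attachment parameters (edges per
#'   new node; attachment exponent).
#' @param n_hubs Number of planted hub proteins.
#' @param hub_boost Extra edges wired from each planted hub to
#'   DEG-encoded nodes.
#' @param clique_sizes Sizes of the planted clique modules.
#' @param n_tfs,n_mirnas Numbers of TF and miRNA regulators.
#' @param n_reporter_tfs,n_reporter_mirnas Planted reporters per type.
#' @param targets_per_regulator Targets drawn per regulator.
#' @param reporter_enrichment Fraction of a planted reporter's targets
#'   drawn from planted DEGs.
#' @param n_patients Survival cohort size.
#' @param baseline_hazard Exponential baseline hazard (events per time
#'   unit).
#' @param censoring_rate Expected fraction of censored patients, in
#'   `[0, 1)`.
#' @param signature_hr Target hazard ratio between median-split risk
#'   groups; the per-gene Cox coefficient is derived from it (see
#'   [generate_survival()]).
#' @param survival_expr_sd Standard deviation of the simulated expression
#'   covariates in the survival cohort.
#' @param n_drugs Number of decoy drugs.
#' @param n_planted_drugs Number of planted disease-associated drugs.
#' @param targets_per_drug Target genes per drug.
#' @param drug_overlap Planted drugs' target overlap with the planted DEG
#'   set.
#' @param n_gene_sets,gene_set_size Gene-set collection emitted for the
#'   enrichment stage.
#' @param n_planted_sets Sets enriched in planted DEGs.
#' @param gene_set_enrichment Fraction of a planted set's members drawn
#'   from planted DEGs.
#' @param seed Master RNG seed; every generator derives its own stream
#'   from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000,
                       n_case = c(74, 132), n_control = c(5, 9),
                       n_datasets = 2,
                       n_up = 150, n_down = 50,
                       effect_lfc = 2, noise_sd = 0.5,
                       baseline_range = c(4, 12),
                       n_nodes = 500, pa_edges = 2, pa_power = 1,
                       n_hubs = 10, hub_boost = 80,
                       clique_sizes = c(5, 4, 4),
                       n_tfs = 50, n_mirnas = 30,
                       n_reporter_tfs = 10, n_reporter_mirnas = 10,
                       targets_per_regulator = 20,
                       reporter_enrichment = 0.8,
                       n_patients = 467, baseline_hazard = 0.05,
                       censoring_rate = 0.3,
                       signature_hr = 2.5, survival_expr_sd = 1,
                       n_drugs = 200, n_planted_drugs = 10,
                       targets_per_drug = 10, drug_overlap = 8,
                       n_gene_sets = 50, gene_set_size = 25,
                       n_planted_sets = 3, gene_set_enrichment = 0.8,
                       seed = 1) {
  cfg <- as.list(environment())
  cfg$n_case <- rep_len(n_case, n_datasets)
  cfg$n_control <- rep_len(n_control, n_datasets)
  check_count(cfg$n_genes, "n_genes")
  check_count(cfg$n_case, "n_case")
  check_count(cfg$n_control, "n_control")
  check_count(cfg$n_datasets, "n_datasets")
  check_count(c(cfg$n_nodes, cfg$n_patients, cfg$n_drugs), "sizes")
  check_count(cfg$n_up + 1L, "n_up", positive = TRUE)   # allow zero plants
  check_count(cfg$n_down + 1L, "n_down", positive = TRUE)
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop_input("'noise_sd' must be > 0")
  if (effect_lfc < 0) stop_input("'effect_lfc' must be >= 0")
  if (censoring_rate < 0 || censoring_rate >= 1) {
    stop_input("'censoring_rate' must be in [0, 1)")
  }
  check_prob(reporter_enrichment, "reporter_enrichment")
  check_prob(gene_set_enrichment, "gene_set_enrichment")
  if (n_up + n_down > n_genes) stop_input("more planted DEGs than genes")
  if (any(clique_sizes > n_nodes)) {
    stop_input("clique size exceeds the network size")
  }
  if (n_nodes > n_genes) stop_input("'n_nodes' cannot exceed 'n_genes'")
  if (drug_overlap > targets_per_drug) {
    stop_input("'drug_overlap' cannot exceed 'targets_per_drug'")
  }
  if (n_hubs + sum(clique_sizes) > n_up + n_down && n_up + n_down > 0) {
    stop_input("not enough planted DEGs to host hubs and cliques")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d genes; %d dataset(s) (case/control: %s); ",
                     "%d+%d planted DEGs at lfc %.2g; %d-node network; ",
                     "%d patients; seed %d\n"),
              x$n_genes, x$n_datasets,
              paste(x$n_case, x$n_control, sep = "/", collapse = ", "),
              x$n_up, x$n_down, x$effect_lfc, x$n_nodes, x$n_patients,
              x$seed))
  invisible(x)
}

#' Generate case/control expression datasets with planted DEGs
#'
#' Emits `n_datasets` genes x samples log2-expression matrices sharing one
#' gene universe and one planted truth: planted up (down) genes have their
#' case-group mean shifted by `+effect_lfc` (`-effect_lfc`); all other
#' genes have zero shift. Noise is Gaussian on the log2 scale with
#' dataset-specific baselines and seeds. Deterministic in
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `datasets` (list of [expression_dataset()]) and
#'   `truth` (a `ground_truth` list carrying the planted gene sets and
#'   the seed; later generators extend it).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  planted <- with_seed(child_seed(config$seed, 1), {
    sample(genes, config$n_up + config$n_down)
  })
  up <- planted[seq_len(config$n_up)]
  down <- setdiff(planted, up)
  shift <- stats::setNames(numeric(config$n_genes), genes)
  shift[up] <- config$effect_lfc
  shift[down] <- -config$effect_lfc

  datasets <- lapply(seq_len(config$n_datasets), function(d) {
    n1 <- config$n_case[d]
    n2 <- config$n_control[d]
    with_seed(child_seed(config$seed, 10 + d), {
      baseline <- stats::runif(config$n_genes, config$baseline_range[1],
                               config$baseline_range[2])
      m <- baseline +
        matrix(stats::rnorm(config$n_genes * (n1 + n2), sd = config$noise_sd),
               config$n_genes, n1 + n2)
      m[, seq_len(n1)] <- m[, seq_len(n1)] + shift
      dimnames(m) <- list(genes,
                          sprintf("ds%d_s%03d", d, seq_len(n1 + n2)))
      expression_dataset(m, c(rep("case", n1), rep("control", n2)))
    })
  })
  truth <- structure(
    list(genes = genes, planted_up_genes = sort(up),
         planted_down_genes = sort(down),
         planted_hubs = character(0), planted_modules = list(),
         planted_reporters = character(0), planted_betas = numeric(0),
         planted_drugs = character(0), planted_sets = character(0),
         seed = config$seed),
    class = "ground_truth")
  list(datasets = datasets, truth = truth)
}

#' Generate the interaction and regulatory networks
#'
#' The protein-interaction network is an undirected simple
#' preferential-attachment (scale-free) graph over a sample of the gene
#' universe that contains every planted DEG. Planted hubs occupy the
#' topologically central positions (the highest-degree attachment nodes,
#' renamed to planted upregulated genes) and are wired to `hub_boost`
#' extra DEG-encoded nodes each; planted modules are inserted as cliques
#' on low-degree DEG nodes, with any chance edge between different
#' planted cliques removed so each module is a separate dense unit.
#' The regulatory network draws each planted reporter's targets
#' preferentially from planted DEGs (fraction `reporter_enrichment`) and
#' every decoy regulator's targets uniformly.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [generate_expression()].
#' @return List with `network` (igraph), `regnet`
#'   ([regulatory_network()]) and the extended `truth`.
#' @export
generate_networks <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  genes <- truth$genes
  degs <- c(truth$planted_up_genes, truth$planted_down_genes)
  net <- with_seed(child_seed(config$seed, 2), {
    g <- igraph::sample_pa(config$n_nodes, power = config$pa_power,
                           m = config$pa_edges, directed = FALSE)
    g <- igraph::simplify(g)
    deg0 <- igraph::degree(g)
    ord <- order(-deg0, seq_along(deg0))
    hub_pos <- ord[seq_len(config$n_hubs)]
    # low-degree, non-hub positions host the planted cliques
    clique_pos_pool <- rev(ord)
    clique_pos_pool <- setdiff(clique_pos_pool, hub_pos)
    clique_pos <- list()
    used <- integer(0)
    for (s in config$clique_sizes) {
      pos <- setdiff(clique_pos_pool, used)[seq_len(s)]
      clique_pos <- c(clique_pos, list(pos))
      used <- c(used, pos)
    }
    # name assignment: hubs get planted up genes, cliques planted DEGs,
    # remaining planted DEGs then background genes fill the rest; with no
    # planted DEGs (pure null simulation) hubs and cliques fall back to
    # arbitrary genes
    hub_pool <- if (length(truth$planted_up_genes) >= config$n_hubs) {
      truth$planted_up_genes
    } else genes
    hub_genes <- sample(hub_pool, config$n_hubs)
    clique_gene_pool <- setdiff(if (length(degs) > 0) degs else genes,
                                hub_genes)
    clique_genes <- list()
    taken <- character(0)
    for (s in config$clique_sizes) {
      cg <- sample(setdiff(clique_gene_pool, taken), s)
      clique_genes <- c(clique_genes, list(cg))
      taken <- c(taken, cg)
    }
    rest_degs <- setdiff(degs, c(hub_genes, taken))
    other_pos <- setdiff(seq_len(config$n_nodes), c(hub_pos, used))
    background <- sample(setdiff(genes, degs),
                         length(other_pos) - length(rest_degs))
    name <- character(config$n_nodes)
    name[hub_pos] <- hub_genes
    name[unlist(clique_pos)] <- unlist(clique_genes)
    name[other_pos] <- sample(c(rest_degs, background))
    g <- igraph::set_vertex_attr(g, "name", value = name)
    # wire hubs to extra DEG-encoded nodes, sparing the planted cliques
    # (so the inserted modules stay separate dense units) and the other
    # hubs (hub neighborhoods stay star-like: high degree and
    # betweenness without forming a dense MCODE-detectable core)
    deg_nodes <- setdiff(intersect(degs, name),
                         c(unlist(clique_genes), hub_genes))
    if (length(deg_nodes) == 0) {
      deg_nodes <- setdiff(name, c(unlist(clique_genes), hub_genes))
    }
    for (h in hub_genes) {
      cand <- setdiff(deg_nodes, c(h, igraph::V(g)$name[
        as.integer(igraph::neighbors(g, h))]))
      extra <- sample(cand, min(config$hub_boost, length(cand)))
      g <- igraph::add_edges(g, as.vector(rbind(h, extra)))
    }
    hub_pairs <- igraph::E(g)[igraph::`%--%`(hub_genes, hub_genes)]
    if (length(hub_pairs) > 0) g <- igraph::delete_edges(g, hub_pairs)
    # insert cliques and isolate them from each other
    for (cg in clique_genes) {
      pairs <- utils::combn(cg, 2)
      g <- igraph::add_edges(g, as.vector(pairs))
    }
    g <- igraph::simplify(g)
    # keep each planted clique a separate dense unit: drop chance edges
    # between different cliques and between clique members and external
    # DEG-encoded nodes (the hub-boosted region); edges to background
    # genes remain, so cliques sit in a sparse neighborhood
    if (length(clique_genes) > 0) {
      el <- igraph::as_edgelist(g)
      memb <- rep(seq_along(clique_genes), lengths(clique_genes))
      names(memb) <- unlist(clique_genes)
      m1 <- memb[el[, 1]]
      m2 <- memb[el[, 2]]
      ext_deg1 <- is.na(m1) & el[, 1] %in% degs
      ext_deg2 <- is.na(m2) & el[, 2] %in% degs
      cross <- (!is.na(m1) & !is.na(m2) & m1 != m2) |
        (!is.na(m1) & ext_deg2) | (!is.na(m2) & ext_deg1)
      if (any(cross)) g <- igraph::delete_edges(g, which(cross))
      # cap any external node at a single edge into the planted cliques,
      # so no outside node can complete a dense subgraph with clique
      # members or bridge two cliques
      el <- igraph::as_edgelist(g)
      m1 <- memb[el[, 1]]
      m2 <- memb[el[, 2]]
      bnd <- xor(is.na(m1), is.na(m2))
      ext <- ifelse(is.na(m1), el[, 1], el[, 2])
      drop_e <- which(bnd)[duplicated(ext[bnd])]
      if (length(drop_e) > 0) g <- igraph::delete_edges(g, drop_e)
      # keep per clique a single anchoring edge whose external endpoint
      # sits in a genuinely sparse spot (core-clustering weight <= 2,
      # i.e. below the recruitment threshold of a size-4 clique seed);
      # any denser attachment could chain the clique into a foreign
      # dense region during greedy module expansion
      wts <- mcode_vertex_weights(g)
      names(wts) <- igraph::V(g)$name
      el <- igraph::as_edgelist(g)
      m1 <- memb[el[, 1]]
      m2 <- memb[el[, 2]]
      bnd <- which(xor(is.na(m1), is.na(m2)))
      if (length(bnd) > 0) {
        ext <- ifelse(is.na(m1[bnd]), el[bnd, 1], el[bnd, 2])
        cl <- ifelse(is.na(m1[bnd]), m2[bnd], m1[bnd])
        keep <- unlist(lapply(split(seq_along(bnd), cl), function(idx) {
          ok <- idx[wts[ext[idx]] <= 2]
          if (length(ok) == 0) return(integer(0))
          ok[which.min(wts[ext[ok]])]
        }))
        g <- igraph::delete_edges(g, bnd[setdiff(seq_along(bnd), keep)])
      }
    }
    list(g = g, hub_genes = sort(hub_genes),
         clique_genes = lapply(clique_genes, sort))
  })

  regnet <- with_seed(child_seed(config$seed, 3), {
    regs <- c(sprintf("TF%03d", seq_len(config$n_tfs)),
              sprintf("miR%03d", seq_len(config$n_mirnas)))
    types <- rep(c("TF", "miRNA"), c(config$n_tfs, config$n_mirnas))
    reporters <- c(sample(regs[types == "TF"], config$n_reporter_tfs),
                   sample(regs[types == "miRNA"], config$n_reporter_mirnas))
    nondeg <- setdiff(genes, degs)
    t_per <- config$targets_per_regulator
    n_enr <- round(config$reporter_enrichment * t_per)
    edges <- lapply(seq_along(regs), function(i) {
      targets <- if (regs[i] %in% reporters && length(degs) > 0) {
        c(sample(degs, min(n_enr, length(degs))),
          sample(nondeg, t_per - min(n_enr, length(degs))))
      } else {
        sample(genes, t_per)
      }
      data.frame(regulator = regs[i], type = types[i], target = targets,
                 stringsAsFactors = FALSE)
    })
    list(net = regulatory_network(do.call(rbind, edges)),
         reporters = sort(reporters))
  })

  truth$planted_hubs <- net$hub_genes
  truth$planted_modules <- net$clique_genes
  truth$planted_reporters <- regnet$reporters
  stopifnot(all(truth$planted_hubs %in% igraph::V(net$g)$name))
  list(network = net$g, regnet = regnet$net, truth = truth)
}

#' Generate a survival cohort with a planted prognostic signature
#'
#' Simulates per-patient expression of the signature genes (the planted
#' hubs; independent Gaussians) and draws event times from the
#' exponential proportional-hazards model
#' `h(t | x) = baseline_hazard * exp(sum_g beta_g x_g)`. Censoring is
#' independent and uniform within each patient's follow-up, at the
#' configured expected rate. The common planted coefficient is derived
#' from `signature_hr`: a median split of a Gaussian prognostic index
#' separates group means by `2 * sqrt(2/pi) * sd(PI)` log-hazard units,
#' so `beta = log(signature_hr) / (2 sqrt(2/pi) * survival_expr_sd *
#' sqrt(k))` targets a high/low hazard ratio of `signature_hr`.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth (after [generate_networks()]; if hubs are
#'   not yet planted, the signature falls back to a sample of planted
#'   upregulated genes).
#' @return List with `survival` (a `data.frame`: patient, time, event,
#'   one column per signature gene) and the extended `truth` carrying
#'   `planted_betas`.
#' @export
generate_survival <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  sig <- truth$planted_hubs
  out <- with_seed(child_seed(config$seed, 4), {
    if (length(sig) == 0) {
      sig <- sort(sample(truth$planted_up_genes,
                         min(config$n_hubs,
                             length(truth$planted_up_genes))))
    }
    k <- length(sig)
    beta <- log(config$signature_hr) /
      (2 * sqrt(2 / pi) * config$survival_expr_sd * sqrt(k))
    n <- config$n_patients
    X <- matrix(stats::rnorm(n * k, sd = config$survival_expr_sd), n, k,
                dimnames = list(NULL, sig))
    pi_lin <- drop(X %*% rep(beta, k))
    t_event <- stats::rexp(n, rate = config$baseline_hazard * exp(pi_lin))
    censored <- stats::runif(n) < config$censoring_rate
    time <- ifelse(censored, stats::runif(n) * t_event, t_event)
    time <- pmax(time, .Machine$double.eps)
    df <- data.frame(patient = sprintf("p%04d", seq_len(n)),
                     time = time, event = as.integer(!censored),
                     stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(X))
    list(df = df, beta = stats::setNames(rep(beta, k), sig))
  })
  if (sum(out$df$event) == 0) warning("all patients censored")
  truth$planted_betas <- out$beta
  list(survival = out$df, truth = truth)
}

#' Generate a two-source drug-target table with planted associated drugs
#'
#' Planted drugs overlap the planted DEG set by `drug_overlap` of their
#' `targets_per_drug` targets and appear in both evidence sources; decoy
#' drugs draw targets uniformly from the gene universe and are assigned
#' to one or both sources at random. Every drug carries a development
#' status and an ATC-style anatomical class, sampled at frequencies
#' typical of repositioning screens (roughly half approved, half
#' investigational, a few percent experimental).
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [generate_expression()] or later.
#' @return List with `drugs` (long `data.frame`: drug, gene, status,
#'   atc_class, source) and the extended `truth` carrying
#'   `planted_drugs`.
#' @export
generate_drug_table <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  genes <- truth$genes
  degs <- c(truth$planted_up_genes, truth$planted_down_genes)
  statuses <- c("approved", "investigational", "experimental")
  status_p <- c(0.49, 0.48, 0.03)
  atc <- c("antineoplastic agents",
           "antineoplastic and immunomodulating agents",
           "hormones and contraceptives",
           "alimentary tract and metabolism",
           "nervous system", "cardiovascular system",
           "anti-infectives", "dermatologicals")
  atc_p <- c(0.16, 0.22, 0.10, 0.13, 0.12, 0.11, 0.09, 0.07)
  out <- with_seed(child_seed(config$seed, 5), {
    planted <- sprintf("drugP%02d", seq_len(config$n_planted_drugs))
    decoys <- sprintf("drugD%03d", seq_len(config$n_drugs))
    all_drugs <- c(planted, decoys)
    ann <- data.frame(
      drug = all_drugs,
      status = sample(statuses, length(all_drugs), replace = TRUE,
                      prob = status_p),
      atc_class = sample(atc, length(all_drugs), replace = TRUE,
                         prob = atc_p),
      stringsAsFactors = FALSE)
    nondeg <- setdiff(genes, degs)
    rows <- lapply(all_drugs, function(d) {
      if (d %in% planted) {
        tg <- c(sample(degs, config$drug_overlap),
                sample(nondeg, config$targets_per_drug - config$drug_overlap))
        src <- c("source_a", "source_b")
      } else {
        tg <- sample(genes, config$targets_per_drug)
        u <- stats::runif(1)
        src <- if (u < 0.3) c("source_a", "source_b")
               else if (u < 0.65) "source_a" else "source_b"
      }
      i <- match(d, ann$drug)
      expand.grid(drug = d, gene = tg, status = ann$status[i],
                  atc_class = ann$atc_class[i], source = src,
                  stringsAsFactors = FALSE)
    })
    list(df = do.call(rbind, rows), planted = planted)
  })
  truth$planted_drugs <- out$planted
  rownames(out$df) <- NULL
  list(drugs = out$df, truth = truth)
}

#' Generate a gene-set collection with planted enriched sets
#'
#' Emits the GMT-style collection consumed by the enrichment stage:
#' `n_planted_sets` sets drawing a fraction `gene_set_enrichment` of
#' their members from planted DEGs, plus uniformly drawn decoy sets.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [generate_expression()] or later.
#' @return List with `collection` (a [gene_set_collection()]) and the
#'   extended `truth` carrying `planted_sets`.
#' @export
generate_gene_sets <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  genes <- truth$genes
  degs <- c(truth$planted_up_genes, truth$planted_down_genes)
  out <- with_seed(child_seed(config$seed, 6), {
    n_enr <- round(config$gene_set_enrichment * config$gene_set_size)
    nondeg <- setdiff(genes, degs)
    sets <- lapply(seq_len(config$n_gene_sets), function(i) {
      if (i <= config$n_planted_sets && length(degs) >= n_enr) {
        c(sample(degs, n_enr),
          sample(nondeg, config$gene_set_size - n_enr))
      } else {
        sample(genes, config$gene_set_size)
      }
    })
    names(sets) <- sprintf("set%03d", seq_len(config$n_gene_sets))
    sets
  })
  planted <- if (config$n_planted_sets > 0 && length(degs) > 0) {
    sprintf("set%03d", seq_len(config$n_planted_sets))
  } else character(0)
  truth$planted_sets <- planted
  desc <- stats::setNames(
    ifelse(names(out) %in% planted, "planted disease set", "decoy set"),
    names(out))
  list(collection = gene_set_collection(out, descriptions = desc,
                                        universe = genes),
       truth = truth)
}

#' Generate the full synthetic input bundle
#'
#' Runs every generator in order and returns all pipeline inputs plus the
#' planted ground truth. Deterministic in `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `datasets`, `network`, `regnet`, `survival`,
#'   `drugs`, `gene_sets`, `config`, and `truth`.
#' @export
simulate_bundle <- function(config = sim_config()) {
  expr <- generate_expression(config)
  nets <- generate_networks(config, expr$truth)
  surv <- generate_survival(config, nets$truth)
  drugs <- generate_drug_table(config, surv$truth)
  gsets <- generate_gene_sets(config, drugs$truth)
  list(datasets = expr$datasets, network = nets$network,
       regnet = nets$regnet, survival = surv$survival,
       drugs = drugs$drugs, gene_sets = gsets$collection,
       config = config, truth = gsets$truth)
}

#' Write a synthetic bundle to disk
#'
#' Serializes every input of the pipeline in its standard plain-text
#' format: per-dataset expression and group TSVs, a SIF network, the
#' regulator-target TSV, the survival TSV, the drug-target TSV, a GMT
#' gene-set file, and the ground truth as JSON.
#'
#' @param bundle Output of [simulate_bundle()].
#' @param outdir Output directory (created if absent).
#' @return Invisibly, the named vector of written paths.
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (d in seq_along(bundle$datasets)) {
    e <- file.path(outdir, sprintf("expression_%d.tsv", d))
    g <- file.path(outdir, sprintf("groups_%d.tsv", d))
    write_expression(bundle$datasets[[d]], e, g)
    paths <- c(paths, stats::setNames(c(e, g),
                                      sprintf(c("expression_%d", "groups_%d"), d)))
  }
  p <- file.path(outdir, "network.sif")
  write_sif(bundle$network, p)
  paths <- c(paths, network = p)
  p <- file.path(outdir, "regnet.tsv")
  utils::write.table(bundle$regnet, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, regnet = p)
  p <- file.path(outdir, "survival.tsv")
  utils::write.table(bundle$survival, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, survival = p)
  p <- file.path(outdir, "drugs.tsv")
  utils::write.table(bundle$drugs, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, drugs = p)
  p <- file.path(outdir, "gene_sets.gmt")
  write_gmt(bundle$gene_sets, p)
  paths <- c(paths, gene_sets = p)
  p <- file.path(outdir, "truth.json")
  truth <- bundle$truth
  truth$genes <- NULL   # recoverable from the expression files
  jsonlite::write_json(unclass(truth), p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, truth = p)
  invisible(paths)
}
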