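small_cfg <- function(...) {
  defaults <- list(n_genes = 600, n_case = 10, n_control = 10,
                   n_datasets = 2, n_up = 40, n_down = 20, n_nodes = 200,
                   n_patients = 60, n_drugs = 30, n_planted_drugs = 4)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("generation is a deterministic function of the seed", {
  b1 <- simulate_bundle(small_cfg(seed = 5))
  b2 <- simulate_bundle(small_cfg(seed = 5))
  expect_identical(b1$datasets[[1]]$matrix, b2$datasets[[1]]$matrix)
  expect_identical(igraph::as_edgelist(b1$network),
                   igraph::as_edgelist(b2$network))
  expect_identical(b1$regnet, b2$regnet)
  expect_identical(b1$survival, b2$survival)
  expect_identical(b1$drugs, b2$drugs)
  expect_identical(b1$truth, b2$truth)
  b3 <- simulate_bundle(small_cfg(seed = 6))
  expect_false(identical(b1$datasets[[1]]$matrix, b3$datasets[[1]]$matrix))
})

test_that("planted genes carry the configured mean shift, others none", {
  cfg <- small_cfg(effect_lfc = 2, noise_sd = 0.5, seed = 8)
  ex <- generate_expression(cfg)
  ds <- ex$datasets[[1]]
  diff <- rowMeans(ds$matrix[, ds$group == "case"]) -
    rowMeans(ds$matrix[, ds$group == "control"])
  up <- ex$truth$planted_up_genes
  down <- ex$truth$planted_down_genes
  bg <- setdiff(rownames(ds$matrix), c(up, down))
  # averaging over plants: SE = 0.5 * sqrt(2/10) / sqrt(40) ~ 0.035
  expect_lt(abs(mean(diff[up]) - 2), 0.15)
  expect_lt(abs(mean(diff[down]) + 2), 0.2)
  expect_lt(abs(mean(diff[bg])), 0.1)
  # truth sets are disjoint and shared across datasets
  expect_length(intersect(up, down), 0)
  expect_identical(rownames(ex$datasets[[1]]$matrix),
                   rownames(ex$datasets[[2]]$matrix))
})

test_that("a null simulation yields a calibrated DEG caller", {
  cfg <- small_cfg(effect_lfc = 0, seed = 12)
  ex <- generate_expression(cfg)
  calls <- call_degs(gene_statistics(ex$datasets[[1]]))
  # with no planted effects the discovery count at BH level q has
  # expectation at most q * m
  expect_lte(sum(calls$direction != "none"), 0.01 * nrow(calls) + 3)
})

test_that("planted network structure is inserted as specified", {
  cfg <- small_cfg(seed = 3, clique_sizes = c(4, 4))
  ex <- generate_expression(cfg)
  nets <- generate_networks(cfg, ex$truth)
  g <- nets$network
  expect_true(igraph::is_simple(g))
  # planted modules induce complete subgraphs
  for (cl in nets$truth$planted_modules) {
    sub <- igraph::induced_subgraph(g, cl)
    expect_equal(igraph::ecount(sub), choose(length(cl), 2))
  }
  # every planted hub is present and heavily connected
  deg <- igraph::degree(g)
  expect_true(all(nets$truth$planted_hubs %in% igraph::V(g)$name))
  expect_true(all(deg[nets$truth$planted_hubs] >=
                    max(deg[setdiff(names(deg), nets$truth$planted_hubs)])))
  # heavy-tailed attachment: the maximum degree dwarfs the median
  expect_gt(max(deg), 10 * stats::median(deg))
  expect_error(generate_networks(small_cfg(clique_sizes = 1000), ex$truth),
               "clique size")
})

test_that("reporter target enrichment honors the configured fraction", {
  cfg <- small_cfg(seed = 4, reporter_enrichment = 1)
  ex <- generate_expression(cfg)
  nets <- generate_networks(cfg, ex$truth)
  degs <- c(ex$truth$planted_up_genes, ex$truth$planted_down_genes)
  for (r in nets$truth$planted_reporters) {
    targets <- nets$regnet$target[nets$regnet$regulator == r]
    expect_true(all(targets %in% degs))
  }
  # decoy regulators draw uniformly: overall DEG fraction near |DEG|/|U|
  decoys <- setdiff(unique(nets$regnet$regulator),
                    nets$truth$planted_reporters)
  dt <- nets$regnet$target[nets$regnet$regulator %in% decoys]
  expect_lt(abs(mean(dt %in% degs) - length(degs) / cfg$n_genes), 0.05)
})

test_that("survival generation respects censoring and hazard structure", {
  cfg <- small_cfg(seed = 6, censoring_rate = 0)
  ex <- generate_expression(cfg)
  nets <- generate_networks(cfg, ex$truth)
  sv <- generate_survival(cfg, nets$truth)
  expect_true(all(sv$survival$event == 1))          # no censoring
  expect_true(all(sv$survival$time > 0))
  expect_setequal(names(sv$truth$planted_betas), nets$truth$planted_hubs)
  # planted coefficients are recovered by a Cox fit at scale
  cfg2 <- small_cfg(seed = 7, n_patients = 800)
  sv2 <- generate_survival(cfg2, generate_networks(
    cfg2, generate_expression(cfg2)$truth)$truth)
  fit <- cox_fit(sv2$survival)
  b_true <- sv2$truth$planted_betas
  expect_lt(mean(abs(fit$beta[names(b_true)] - b_true)),
            3 * mean(fit$se))
})

test_that("drug table planting and decoy overlap behave as configured", {
  cfg <- small_cfg(seed = 9, drug_overlap = 10, targets_per_drug = 10)
  ex <- generate_expression(cfg)
  dr <- generate_drug_table(cfg, ex$truth)
  degs <- c(ex$truth$planted_up_genes, ex$truth$planted_down_genes)
  for (d in dr$truth$planted_drugs) {
    tg <- unique(dr$drugs$gene[dr$drugs$drug == d])
    expect_true(all(tg %in% degs))                  # full-overlap boundary
  }
  # decoy overlap matches the hypergeometric mean K*n/N on average
  decoys <- setdiff(unique(dr$drugs$drug), dr$truth$planted_drugs)
  ov <- vapply(decoys, function(d) {
    sum(unique(dr$drugs$gene[dr$drugs$drug == d]) %in% degs)
  }, 0)
  expected <- cfg$targets_per_drug * length(degs) / cfg$n_genes
  expect_lt(abs(mean(ov) - expected), 3 * stats::sd(ov) / sqrt(length(ov)) + 0.3)
  expect_error(small_cfg(drug_overlap = 11, targets_per_drug = 10),
               "drug_overlap")
})

test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(censoring_rate = 1), "censoring_rate")
  expect_error(sim_config(n_up = 3000), "more planted DEGs")
  expect_error(sim_config(n_nodes = 5000), "n_nodes")
})

test_that("a bundle round-trips through its on-disk formats", {
  b <- simulate_bundle(small_cfg(seed = 10))
  out <- tempfile("bundle")
  paths <- write_bundle(b, out)
  expect_true(all(file.exists(paths)))
  ds <- read_expression(paths[["expression_1"]], paths[["groups_1"]])
  expect_equal(unname(ds$matrix), unname(b$datasets[[1]]$matrix),
               tolerance = 1e-9)
  g <- read_network(paths[["network"]])
  expect_equal(igraph::ecount(g), igraph::ecount(b$network))
  expect_setequal(igraph::V(g)$name, igraph::V(b$network)$name)
  rn <- read_regnet(paths[["regnet"]])
  expect_equal(nrow(rn), nrow(b$regnet))
  sv <- read_survival(paths[["survival"]])
  expect_equal(sv$time, b$survival$time, tolerance = 1e-9)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_setequal(truth$planted_hubs, b$truth$planted_hubs)
  unlink(out, recursive = TRUE)
})
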