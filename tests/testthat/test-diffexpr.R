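test_that("degenerate and hand-computable genes get the exact statistics", {
  planted <- rbind(const = rep(5, 6),
                   shift = c(1, 1, 1, 3, 3, 3))
  ds <- toy_expression(n_null = 30, n1 = 3, n2 = 3, planted = planted)
  st <- gene_statistics(ds)
  const_row <- st[st$gene_id == "g0031", ]
  expect_equal(const_row$log_fc, 0)
  expect_equal(const_row$p, 1)
  # cases are the first triple: case mean 1, control mean 3
  shift_row <- st[st$gene_id == "g0032", ]
  expect_equal(shift_row$log_fc, -2)
})

test_that("null data give approximately uniform p-values", {
  ds <- toy_expression(n_null = 1000, n1 = 8, n2 = 8, seed = 7)
  for (method in c("moderated", "welch")) {
    st <- gene_statistics(ds, method = method)
    ks <- suppressWarnings(ks.test(st$p, "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("moderated statistic agrees with an independent empirical-Bayes fit", {
  ds <- toy_expression(n_null = 300, n1 = 4, n2 = 4, seed = 3)
  st <- gene_statistics(ds)
  design <- cbind(1, as.integer(ds$group == "case"))
  fit <- limma::eBayes(limma::lmFit(ds$matrix, design))
  expect_equal(st$log_fc, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(st$t, unname(fit$t[, 2]), tolerance = 1e-3)
  expect_equal(st$p, unname(fit$p.value[, 2]), tolerance = 1e-3)
  expect_equal(order(st$p), order(fit$p.value[, 2]))
})

test_that("input validation rejects malformed datasets", {
  m <- matrix(rnorm(12), 3, 4, dimnames = list(c("a", "b", "a"), NULL))
  expect_error(expression_dataset(m, rep(c("case", "control"), 2)),
               "duplicate gene id")
  m2 <- matrix(rnorm(8), 2, 4, dimnames = list(c("a", "b"), NULL))
  expect_error(expression_dataset(m2, rep("case", 4)), "non-empty")
  ds <- expression_dataset(m2, c("case", "case", "case", "control"))
  expect_error(gene_statistics(ds), "at least 2 samples")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(11)
  for (m in c(1, 2, 17, 400)) {
    p <- runif(m)
    expect_identical(bh_adjust(p), bh_oracle(p))
  }
  expect_error(bh_adjust(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("DEG calling applies strict adj-p and fold-change thresholds", {
  base <- data.frame(gene_id = "g1", log_fc = 1.5, t = 5, p = 0.005)
  expect_equal(call_degs(base, alpha = 0.01, fc_cutoff = 2)$direction, "up")
  base$log_fc <- 0.5
  expect_equal(call_degs(base)$direction, "none")    # fails fold change
  base$log_fc <- -3
  base$p <- 0.02
  expect_equal(call_degs(base)$direction, "none")    # fails alpha
  base$p <- 0.005
  expect_equal(call_degs(base)$direction, "down")
  # boundary: adj_p exactly at alpha is not significant
  base$p <- 0.01
  expect_equal(call_degs(base)$direction, "none")
  expect_error(call_degs(base, alpha = 1.5), "alpha")
  expect_error(call_degs(base, fc_cutoff = 0.5), "fc_cutoff")
})

test_that("mutual DEGs intersect same-direction calls only", {
  # all 9 direction combinations across two datasets
  dirs <- c("up", "down", "none")
  combos <- expand.grid(a = dirs, b = dirs, stringsAsFactors = FALSE)
  genes <- sprintf("g%d", seq_len(nrow(combos)))
  mk <- function(direction) {
    data.frame(gene_id = genes, log_fc = 0, p = 0.5, adj_p = 0.5,
               direction = direction, stringsAsFactors = FALSE)
  }
  mut <- mutual_degs(mk(combos$a), mk(combos$b))
  expect_equal(mut$up, genes[combos$a == "up" & combos$b == "up"])
  expect_equal(mut$down, genes[combos$a == "down" & combos$b == "down"])
  # a gene up in one and down in the other is in neither output
  conflicted <- genes[combos$a == "up" & combos$b == "down"]
  expect_false(any(conflicted %in% c(mut$up, mut$down)))
  # disjoint up sets give an empty intersection
  t1 <- mk(c("up", rep("none", 8)))
  t2 <- mk(c("none", "up", rep("none", 7)))
  expect_length(mutual_degs(t1, t2)$up, 0)
})

test_that("sign flips of the contrast leave p unchanged and flip directions", {
  b <- generate_expression(sim_config(n_case = 10, n_control = 10,
                                      n_datasets = 1, n_genes = 300,
                                      n_nodes = 100, n_up = 20, n_down = 10,
                                      seed = 5))
  ds <- b$datasets[[1]]
  t1 <- call_degs(gene_statistics(ds))
  # negating the expression values flips the contrast
  neg <- expression_dataset(-ds$matrix, ds$group)
  t2 <- call_degs(gene_statistics(neg))
  expect_equal(t1$p, t2$p, tolerance = 1e-12)
  expect_equal(t1$log_fc, -t2$log_fc)
  expect_equal(t1$direction == "up", t2$direction == "down")
  # so does swapping the group labels
  swp <- expression_dataset(ds$matrix,
                            ifelse(ds$group == "case", "control", "case"))
  t3 <- call_degs(gene_statistics(swp))
  expect_equal(t1$p, t3$p, tolerance = 1e-12)
  expect_equal(t1$log_fc, -t3$log_fc)
  expect_equal(t1$direction == "up", t3$direction == "down")
})

test_that("expression datasets round-trip through TSV", {
  ds <- toy_expression(n_null = 10, n1 = 3, n2 = 3)
  ep <- tempfile(fileext = ".tsv")
  gp <- tempfile(fileext = ".tsv")
  write_expression(ds, ep, gp)
  back <- read_expression(ep, gp)
  expect_equal(unname(back$matrix), unname(ds$matrix), tolerance = 1e-12)
  expect_equal(back$group, ds$group)
  expect_equal(rownames(back$matrix), rownames(ds$matrix))
})
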