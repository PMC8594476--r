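test_that("planted abundance-editing associations are recovered", {
  sim <- simulate_dataset(sim_config(n_cells = 800, n_sites = 1500,
                                     n_genes = 60, seed = 55))
  st <- sim$truth$annotation$sites
  gei <- per_cell_indices(sim$matrix[st$site_kind == "edit", ], "GEI")
  assoc <- fit_gene_associations(gei, sim$expression$tpm,
                                 sim$truth$cells, min_cells_expr = 200)
  pl <- assoc[assoc$gene_id %in% c("gene001", "gene002"), ]
  expect_lt(abs(pl$beta[pl$gene_id == "gene001"] - 0.05),
            2 * pl$se[pl$gene_id == "gene001"])
  expect_lt(abs(pl$beta[pl$gene_id == "gene002"] + 0.05),
            2 * pl$se[pl$gene_id == "gene002"])
  expect_true(all(pl$significant))
})

test_that("genes without abundance variance or coverage are skipped", {
  n <- 400
  cells <- data.frame(cell_id = paste0("c", 1:n),
                      phenotype = rep(c("Ex", "In"), n / 2),
                      library_size = 3e6)
  summaries <- data.frame(cell_id = cells$cell_id,
                          index = runif(n, 0.2, 0.4))
  tpm <- rbind(const = rep(5, n), rare = c(rep(1, 10), rep(0, n - 10)),
               ok = runif(n, 1, 100))
  colnames(tpm) <- cells$cell_id
  out <- fit_gene_associations(summaries, tpm, cells,
                               min_cells_expr = 50)
  expect_setequal(attr(out, "skipped"), c("const", "rare"))
  expect_identical(out$gene_id, "ok")
})

test_that("every fitted gene is reported when thresholds are disabled", {
  sim <- small_sim(seed = 56, n_cells = 300, n_sites = 200,
                   n_genes = 25)
  gei <- per_cell_indices(sim$matrix, "GEI")
  out <- fit_gene_associations(gei, sim$expression$tpm,
                               sim$truth$cells, min_cells_expr = 50,
                               fdr = 1, beta_min = 0)
  expect_identical(nrow(out) + length(attr(out, "skipped")), 25L)
  expect_true(all(out$significant))
})

test_that("cells with zero TPM do not influence a gene's fit", {
  set.seed(57)
  n <- 300
  cells <- data.frame(cell_id = paste0("c", 1:n),
                      phenotype = rep(c("Ex", "In"), n / 2),
                      library_size = round(rlnorm(n, log(1e6), 0.2)))
  summaries <- data.frame(cell_id = cells$cell_id,
                          index = runif(n, 0.2, 0.4))
  tpm <- matrix(runif(n, 1, 50), 1, n,
                dimnames = list("g", cells$cell_id))
  base <- fit_gene_associations(summaries, tpm, cells,
                                min_cells_expr = 50, beta_min = 0)
  # add 100 cells where the gene is silent
  extra <- data.frame(cell_id = paste0("x", 1:100),
                      phenotype = "Ex",
                      library_size = 1e6)
  cells2 <- rbind(cells, extra)
  summaries2 <- rbind(summaries,
                      data.frame(cell_id = extra$cell_id, index = 0.9))
  tpm2 <- cbind(tpm, matrix(0, 1, 100,
                            dimnames = list("g", extra$cell_id)))
  out2 <- fit_gene_associations(summaries2, tpm2, cells2,
                                min_cells_expr = 50, beta_min = 0)
  expect_equal(out2$beta, base$beta, tolerance = 1e-12)
  expect_equal(out2$p, base$p, tolerance = 1e-12)
})

test_that("gene beta is invariant to the phenotype reference level", {
  set.seed(58)
  n <- 200
  cells <- data.frame(cell_id = paste0("c", 1:n),
                      phenotype = rep(c("Ex", "In"), n / 2),
                      library_size = round(rlnorm(n, log(1e6), 0.2)))
  summaries <- data.frame(cell_id = cells$cell_id,
                          index = runif(n, 0.2, 0.4))
  tpm <- matrix(runif(n, 1, 50), 1, n,
                dimnames = list("g", cells$cell_id))
  a <- fit_gene_associations(summaries, tpm, cells,
                             min_cells_expr = 50, beta_min = 0)
  cells$phenotype <- factor(cells$phenotype, levels = c("In", "Ex"))
  b <- fit_gene_associations(summaries, tpm, cells,
                             min_cells_expr = 50, beta_min = 0)
  expect_equal(a$beta, b$beta, tolerance = 1e-12)
})

test_that("downsampling leaves small genes untouched and is seeded", {
  sim <- simulate_dataset(sim_config(n_cells = 700, n_sites = 300,
                                     n_genes = 40, seed = 59))
  st <- sim$truth$annotation$sites
  gei <- per_cell_indices(sim$matrix[st$site_kind == "edit", ], "GEI")
  assoc <- fit_gene_associations(gei, sim$expression$tpm,
                                 sim$truth$cells, min_cells_expr = 100)
  ds1 <- downsample_check(assoc, gei, sim$expression$tpm,
                          sim$truth$cells, cap = 500, seed = 4,
                          genes = assoc$gene_id[1:5])
  ds2 <- downsample_check(assoc, gei, sim$expression$tpm,
                          sim$truth$cells, cap = 500, seed = 4,
                          genes = assoc$gene_id[1:5])
  expect_identical(ds1, ds2)
  small <- ds1[!ds1$downsampled, ]
  if (nrow(small))
    expect_equal(small$beta_capped, small$beta_full, tolerance = 1e-12)
})

test_that("cross-data-set beta correlation behaves at its edges", {
  res <- data.frame(gene_id = paste0("g", 1:50),
                    beta = rnorm(50, 0, 0.02))
  same <- cross_dataset_beta_correlation(res, res)
  expect_equal(same$r, 1)
  expect_error(cross_dataset_beta_correlation(res[1:2, ], res[1:2, ]),
               "3 shared genes")
  set.seed(61)
  other <- data.frame(gene_id = paste0("g", 1:50),
                      beta = rnorm(50, 0, 0.02))
  indep <- cross_dataset_beta_correlation(res, other)
  expect_lt(abs(indep$r), 0.35)
})

test_that("a shared planted signal yields positive cross-data-set correlation", {
  cfg <- function(seed) sim_config(n_cells = 800, n_sites = 1000,
                                   n_genes = 40, seed = seed,
                                   assoc_genes = data.frame(
                                     gene = 1:10,
                                     beta = rep(c(0.05, -0.05),
                                                each = 5)))
  fit_one <- function(seed) {
    sim <- simulate_dataset(cfg(seed))
    st <- sim$truth$annotation$sites
    gei <- per_cell_indices(sim$matrix[st$site_kind == "edit", ], "GEI")
    fit_gene_associations(gei, sim$expression$tpm, sim$truth$cells,
                          min_cells_expr = 100, beta_min = 0)
  }
  a <- fit_one(71); b <- fit_one(72)
  out <- cross_dataset_beta_correlation(
    a, b, subset = data.frame(gene_id = sprintf("gene%03d", 1:10),
                              label = rep(c("positive", "negative"),
                                          each = 5)))
  expect_gt(out$r, 0)
  expect_lt(out$p, 0.05)
  expect_gt(out$r_subset, 0)
  expect_lt(out$separation_p_b, 0.05)
})
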