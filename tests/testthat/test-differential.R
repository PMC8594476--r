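test_that("pseudobulk sums counts within groups", {
  depth <- matrix(c(4, 6, 8, 2), 1, 4)
  alt <- matrix(c(1, 2, 3, 1), 1, 4)
  cells <- data.frame(cell_id = paste0("c", 1:4),
                      subgroup = c("A", "A", "B", "B"))
  em <- em_from_dense(alt, depth, cells = cells)
  pb <- build_pseudobulk(em, group_by = "subgroup", var_min = 0)
  expect_identical(unname(pb$edited[1, "A"]), 3)
  expect_identical(unname(pb$unedited[1, "A"]), 7)
  expect_identical(unname(pb$edited[1, "B"]), 4)
  expect_identical(pb$samples$n_cells, c(2L, 2L))
})

test_that("pseudobulk totals equal a per-group loop oracle", {
  sim <- small_sim(seed = 41, n_cells = 90, n_sites = 200, n_genes = 15)
  em <- sim$matrix
  pb <- suppressWarnings(build_pseudobulk(em, group_by = "subgroup",
                                          var_min = -1))
  alt <- as.matrix(em$alt); depth <- as.matrix(em$depth)
  for (g in sample(colnames(pb$edited), 4)) {
    cols <- which(em$cells$subgroup == g)
    expect_equal(unname(pb$edited[, g]), unname(rowSums(alt[, cols,
                                                            drop = FALSE])))
    expect_equal(unname(pb$edited[, g] + pb$unedited[, g]),
                 unname(rowSums(depth[, cols, drop = FALSE])))
  }
})

test_that("variance filter removes flat sites (strict threshold)", {
  depth <- matrix(10, 3, 4)
  alt <- rbind(c(2, 2, 2, 2),   # constant counts: variance 0
               c(2, 2, 3, 3),   # variance 1/3 > 0.2
               c(2, 2, 2, 3))   # variance 0.25 > 0.2
  cells <- data.frame(cell_id = paste0("c", 1:4),
                      subgroup = c("A", "B", "C", "D"))
  em <- em_from_dense(alt, depth, cells = cells)
  pb <- build_pseudobulk(em, group_by = "subgroup", var_min = 0.2)
  expect_identical(nrow(pb$edited), 2L)
  expect_identical(attr(pb, "removed"), 1L)
  # fraction-based variant
  pbf <- build_pseudobulk(em, group_by = "subgroup", var_min = 0,
                          var_on = "fraction")
  expect_identical(nrow(pbf$edited), 2L)
})

test_that("splitting a pseudoreplicate's cells leaves totals unchanged", {
  sim <- small_sim(seed = 43, n_cells = 60, n_sites = 150, n_genes = 10)
  em <- sim$matrix
  em$cells$grp <- rep("all", nrow(em$cells))
  pb1 <- build_pseudobulk(em, group_by = "grp", var_min = -1)
  em$cells$grp <- rep(c("h1", "h2"), length.out = nrow(em$cells))
  pb2 <- build_pseudobulk(em, group_by = "grp", var_min = -1)
  expect_equal(unname(pb1$edited[, "all"]),
               unname(pb2$edited[, "h1"] + pb2$edited[, "h2"]))
})

test_that("a perfectly symmetric site has no editing fold-change", {
  S <- 8
  samples <- data.frame(sample = paste0("s", 1:S),
                        phenotype = rep(c("Ex", "In"), each = 4))
  ed <- matrix(50, 2, S); un <- matrix(50, 2, S)
  ed[2, ] <- c(30, 35, 40, 45, 30, 35, 40, 45)  # varies, but balanced
  pb <- structure(list(edited = ed, unedited = un, samples = samples,
                       sites = data.frame(chrom = "chr1", pos = 1:2)),
                  class = "pseudobulk")
  res <- fit_site_models(pb, adjust = NULL)
  expect_equal(res$logFC[1], 0, tolerance = 1e-8)
  expect_gt(res$p[1], 0.999)
  expect_equal(res$logFC[2], 0, tolerance = 1e-8)
})

test_that("swapping contrast labels negates logFC and keeps p-values", {
  pb <- sim_pb_counts(seed = 51, n_sites = 40, shift = 0.4)
  res <- fit_site_models(pb)
  pb2 <- pb
  pb2$samples$phenotype <- ifelse(pb$samples$phenotype == "Ex", "In",
                                  "Ex")
  res2 <- fit_site_models(pb2)
  expect_equal(res2$logFC, -res$logFC, tolerance = 1e-6)
  expect_equal(res2$p, res$p, tolerance = 1e-6)
})

test_that("an all-zero arm is continuity-handled and flagged", {
  S <- 6
  samples <- data.frame(sample = paste0("s", 1:S),
                        phenotype = rep(c("Ex", "In"), each = 3))
  ed <- matrix(c(0, 0, 0, 5, 6, 7), 1, S)
  un <- matrix(20, 1, S)
  pb <- structure(list(edited = ed, unedited = un, samples = samples,
                       sites = data.frame(chrom = "chr1", pos = 1)),
                  class = "pseudobulk")
  res <- fit_site_models(pb, adjust = NULL)
  expect_true(res$flagged[1])
  expect_true(is.finite(res$logFC[1]))
  expect_gt(res$logFC[1], 0)
})

test_that("site p-values track an exact beta-binomial LRT oracle", {
  set.seed(31)
  S <- 6
  samples <- data.frame(sample = paste0("s", 1:S),
                        phenotype = rep(c("Ex", "In"), each = 3))
  ns <- 150
  tot <- matrix(pmax(1, rnbinom(ns * S, mu = 60, size = 5)), ns, S)
  p_site <- plogis(rnorm(ns, qlogis(0.3), 0.6))
  shift <- rnorm(ns, 0, 0.6)
  ed <- matrix(0L, ns, S)
  is_in <- samples$phenotype == "In"
  rho <- 0.03; a <- (1 - rho) / rho
  for (s in 1:ns) {
    lp <- qlogis(p_site[s]) + ifelse(is_in, shift[s], 0)
    pj <- rbeta(S, plogis(lp) * a, (1 - plogis(lp)) * a)
    ed[s, ] <- rbinom(S, tot[s, ], pj)
  }
  pb <- structure(list(edited = ed, unedited = tot - ed,
                       samples = samples,
                       sites = data.frame(chrom = "chr1", pos = 1:ns)),
                  class = "pseudobulk")
  res <- fit_site_models(pb, adjust = NULL)
  p_oracle <- vapply(1:ns, function(s)
    bb_lrt_p(ed[s, ], tot[s, ], samples$phenotype), numeric(1))
  expect_gte(cor(res$p, p_oracle, method = "spearman"), 0.95)
})

test_that("gene test returns p near 1 for a no-signal gene and validates n_perm", {
  pb <- sim_pb_counts(seed = 61, n_sites = 20, shift = 0,
                      gene_id = rep(c("flat", "g2"), each = 10))
  # make the 'flat' gene truly signal-free: identical counts everywhere
  pb$edited[1:10, ] <- 30
  pb$unedited[1:10, ] <- 70
  gt <- gene_directional_test(pb, n_perm = 500, seed = 2)
  expect_gt(gt$p[gt$gene_id == "flat"], 0.5)
  expect_error(gene_directional_test(pb, n_perm = 50), "n_perm")
})

test_that("gene test is invariant to site order within genes", {
  pb <- sim_pb_counts(seed = 62, n_sites = 30, shift = 0.3,
                      gene_id = rep(c("a", "b", "c"), each = 10))
  gt1 <- gene_directional_test(pb, n_perm = 500, seed = 7)
  perm <- sample(30)
  pb2 <- pb
  pb2$edited <- pb$edited[perm, ]
  pb2$unedited <- pb$unedited[perm, ]
  pb2$sites <- pb$sites[perm, ]
  gt2 <- gene_directional_test(pb2, n_perm = 500, seed = 7)
  m <- match(gt1$gene_id, gt2$gene_id)
  expect_equal(gt1$stat, gt2$stat[m], tolerance = 1e-10)
  expect_equal(gt1$p, gt2$p[m], tolerance = 1e-10)
})

test_that("disease overlap test handles symmetry and degeneracy", {
  sym <- disease_overlap_test(matrix(c(10, 90, 10, 90), 2, 2))
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p, 1)
  # p equals exhaustive hypergeometric enumeration for a 2x2 table
  tab <- matrix(c(8, 2, 2, 8), 2, 2)
  got <- disease_overlap_test(tab)
  # enumerate all tables with the same margins
  k <- 0:10
  probs <- dhyper(k, 10, 10, 10)
  p_exact <- sum(probs[probs <= dhyper(8, 10, 10, 10) + 1e-12])
  expect_equal(got$p, p_exact, tolerance = 1e-10)
  expect_equal(got$odds_ratio, 16)
  # empty disease list flagged degenerate
  universe <- data.frame(chrom = "chr1", pos = 1:20,
                         gene_id = rep(c("g1", "g2"), 10))
  deg <- disease_overlap_test(universe,
                              disease_sites = data.frame(
                                chrom = character(), pos = integer()),
                              de_genes = "g1")
  expect_true(deg$flagged)
  expect_equal(deg$p, 1)
})
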