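test_that("cell QC applies strict mito and complexity thresholds", {
  cells <- data.frame(cell_id = paste0("c", 1:4),
                      mito_frac = c(0.16, 0.15, 0.10, 0.02),
                      complexity = c(5000, 5000, 900, 5000))
  out <- cell_qc(cells)
  expect_identical(out$qc_pass, c(FALSE, TRUE, FALSE, TRUE))
  expect_identical(out$qc_reason[1], "mito")
  expect_identical(out$qc_reason[3], "complexity")
})

test_that("planted QC failures are counted exactly", {
  set.seed(1)
  n <- 100
  cells <- data.frame(cell_id = paste0("c", 1:n),
                      mito_frac = runif(n, 0, 0.14),
                      complexity = round(runif(n, 2000, 6000)))
  bad_m <- sample(n, 4); bad_c <- sample(setdiff(1:n, bad_m), 3)
  cells$mito_frac[bad_m] <- runif(4, 0.16, 0.4)
  cells$complexity[bad_c] <- round(runif(3, 100, 900))
  out <- cell_qc(cells)
  expect_identical(unname(attr(out, "qc_counts")["total_failed"]), 7L)
  expect_identical(sum(out$qc_reason == "mito"), 4L)
  expect_identical(sum(out$qc_reason == "complexity"), 3L)
})

test_that("candidate selection equals an exhaustive per-site scan", {
  set.seed(5)
  ns <- 50; nc <- 30
  depth <- matrix(rpois(ns * nc, 4) * rbinom(ns * nc, 1, 0.5), ns, nc)
  alt <- matrix(0, ns, nc)
  pos <- depth > 0
  alt[pos] <- rbinom(sum(pos), depth[pos], 0.4)
  ref <- sample(c("A", "T", "C"), ns, replace = TRUE,
                prob = c(0.45, 0.45, 0.1))
  altb <- ifelse(ref == "A", "G", ifelse(ref == "T", "C", "T"))
  sites <- data.frame(chrom = "chr1", pos = 1:ns * 10, ref = ref,
                      alt = altb)
  em <- em_from_dense(alt, depth, sites = sites)
  got <- select_candidates(em, min_depth = 3, min_alt = 1,
                           min_cells = 4)
  want <- brute_candidates(alt, depth, ref, altb, 3, 1, 4)
  expect_identical(got$sites$pos, sites$pos[want])
})

test_that("prevalence boundary is inclusive and non-A>G/T>C never qualify", {
  depth <- matrix(10, 3, 12)
  alt <- rbind(c(rep(5, 10), 0, 0),    # qualifies in exactly 10 cells
               c(rep(5, 9), 0, 0, 0),  # 9 cells
               rep(5, 12))             # C>T: wrong class
  sites <- data.frame(chrom = "chr1", pos = c(10, 20, 30),
                      ref = c("A", "A", "C"), alt = c("G", "G", "T"))
  em <- em_from_dense(alt, depth, sites = sites)
  got <- select_candidates(em, min_depth = 5, min_alt = 2,
                           min_cells = 10)
  expect_identical(got$sites$pos, 10)
  expect_error(select_candidates(em, min_cells = 0), "min_cells")
})

test_that("SNP removal matches on full allele identity only", {
  sites <- data.frame(chrom = "chr1", pos = c(100, 200, 300),
                      ref = c("A", "A", "T"), alt = c("G", "G", "C"))
  em <- em_from_dense(matrix(1, 3, 2), matrix(4, 3, 2), sites = sites)
  snps <- data.frame(chrom = "chr1", pos = c(100, 200),
                     ref = c("A", "A"), alt = c("G", "T"))
  out <- remove_common_snps(em, snps)
  # pos 100 matches exactly; pos 200 has a different alt and stays
  expect_setequal(out$sites$pos, c(200, 300))
  expect_identical(attr(out, "n_snps_removed"), 1L)
})

test_that("strand filter keeps cognate singletons, rescues catalog sites", {
  genes <- data.frame(chrom = "chr1",
                      start = c(1000, 5000, 5500),
                      end = c(2000, 6000, 6500),
                      strand = c("-", "+", "-"),
                      gene_id = c("gMinus", "gPlus", "gAnti"),
                      type = "gene")
  sites <- data.frame(chrom = "chr1",
                      pos = c(1500, 5100, 5600, 5700, 9000),
                      ref = c("T", "A", "A", "A", "A"),
                      alt = c("C", "G", "G", "G", "G"))
  # 1500: T>C in minus gene (cognate, single)   -> kept, strand -
  # 5100: A>G in plus gene, no overlap          -> kept, strand +
  # 5600: A>G inside +/- overlap, not cataloged -> dropped
  # 5700: same overlap but cataloged            -> rescued
  # 9000: intergenic, not cataloged             -> dropped
  catalog <- data.frame(chrom = "chr1", pos = 5700, strand = "+")
  em <- em_from_dense(matrix(1, 5, 2), matrix(4, 5, 2), sites = sites)
  out <- strand_filter(em, catalog, genes)
  expect_setequal(out$sites$pos, c(1500, 5100, 5700))
  expect_identical(out$sites$gene_strand[out$sites$pos == 1500], "-")
  expect_identical(out$sites$variant_class[out$sites$pos == 1500],
                   "T>C")
  expect_true(out$sites$rescued[out$sites$pos == 5700])
  expect_false(any(out$sites$rescued[out$sites$pos != 5700]))
})

test_that("context annotation applies Alu precedence and matches brute force", {
  set.seed(6)
  reps <- data.frame(chrom = "chr1",
                     start = c(100, 150, 400), end = c(300, 350, 500),
                     class = c("Alu", "repNonAlu", "repNonAlu"),
                     strand = "+")
  pos <- sample(1:600, 200, replace = FALSE)
  sites <- data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "G")
  got <- annotate_context(sites, reps)
  want <- vapply(pos, function(p) {
    in_alu <- any(p >= reps$start & p <= reps$end &
                    reps$class == "Alu")
    in_any <- any(p >= reps$start & p <= reps$end)
    if (in_alu) "Alu" else if (in_any) "repNonAlu" else "nonrepetitive"
  }, character(1))
  expect_identical(got$context, want)
  # a site in both an Alu and a non-Alu repeat is Alu
  both <- pos >= 150 & pos <= 300
  if (any(both)) expect_true(all(got$context[both] == "Alu"))
})

test_that("feature annotation picks the most specific class", {
  sim <- small_sim(seed = 19, n_cells = 10, n_sites = 500, n_genes = 25)
  ann <- sim$truth$annotation
  got <- annotate_feature(ann$sites, ann$genes)
  # brute-force oracle over the feature table with the same precedence
  feats <- ann$genes
  prec <- c(stop_codon = 5, three_prime_UTR = 4, five_prime_UTR = 3,
            exon = 2, gene = 1)
  lab_map <- c(stop_codon = "stop_codon", three_prime_UTR = "3'UTR",
               five_prime_UTR = "5'UTR", exon = "exon", gene = "intron")
  want <- vapply(ann$sites$pos, function(p) {
    hit <- feats$type[p >= feats$start & p <= feats$end &
                        feats$type %in% names(prec)]
    if (!length(hit)) return("other")
    lab_map[[hit[which.max(prec[hit])]]]
  }, character(1))
  expect_identical(got$feature, want)
  expect_true(any(got$feature == "3'UTR"))
  expect_true(any(got$feature == "intron"))
})

test_that("novelty classification counts all membership combinations", {
  sites <- data.frame(chrom = "chr1", pos = 1:4 * 100,
                      ref = "A", alt = "G")
  catA <- data.frame(chrom = "chr1", pos = c(100, 200))
  catB <- data.frame(chrom = "chr1", pos = c(200, 300))
  out <- classify_novelty(sites, list(A = catA, B = catB))
  expect_identical(out$in_A, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(out$in_B, c(FALSE, TRUE, TRUE, FALSE))
  expect_identical(out$catalog_status,
                   c("cataloged", "cataloged", "cataloged", "novel"))
  cen <- editing_census(out, c("in_A", "in_B"))
  combos <- cen$combinations
  expect_identical(combos$count[combos$in_A & combos$in_B], 1L)
  expect_identical(combos$count[!combos$in_A & !combos$in_B], 1L)
})

test_that("neighbor distances equal an all-pairs brute force", {
  sites <- data.frame(chrom = "chr1", pos = c(100, 112),
                      context = "Alu")
  nd <- neighbor_distances(sites)
  expect_identical(nd$distances$dist, c(12, 12))
  expect_identical(unname(nd$medians["Alu"]), 12)
  # singleton context excluded
  s2 <- rbind(sites, data.frame(chrom = "chr1", pos = 500,
                                context = "nonrepetitive"))
  nd2 <- neighbor_distances(s2)
  expect_false("nonrepetitive" %in% nd2$distances$context)
  expect_identical(attr(nd2, "n_excluded"), 1L)
  # 200 random positions vs brute force
  set.seed(7)
  pos <- sample(1:10000, 200)
  s3 <- data.frame(chrom = "chr1", pos = pos, context = "Alu")
  nd3 <- neighbor_distances(s3)
  want <- vapply(pos, function(p) min(abs(p - setdiff(pos, p))),
                 numeric(1))
  got <- nd3$distances$dist[match(pos, nd3$distances$pos)]
  expect_identical(got, want)
})

test_that("filter cascade is order-stable for SNP removal and strand rule", {
  sim <- small_sim(seed = 23, n_cells = 150, n_sites = 600,
                   n_genes = 30)
  ann <- sim$truth$annotation
  em0 <- select_candidates(sim$matrix, min_cells = 3)
  a <- strand_filter(remove_common_snps(em0, ann$snps), ann$catalog,
                     ann$genes)
  b <- remove_common_snps(strand_filter(em0, ann$catalog, ann$genes),
                          ann$snps)
  expect_setequal(paste(a$sites$chrom, a$sites$pos),
                  paste(b$sites$chrom, b$sites$pos))
})
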