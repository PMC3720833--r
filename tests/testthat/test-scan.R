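scan_fixture <- function() {
  blk <- make_block(120, 30, seed = 200)
  y <- null_pheno(120, seed = 201)
  genes <- simulate_gene_structure(30, c(10, 10), seed = 202,
                                   positions = blk$snps$pos)
  list(blk = blk, y = y, genes = genes)
}

test_that("region restriction reproduces the whole-run rows for that gene", {
  fx <- scan_fixture()
  plan <- permutation_plan(seed = 1, n_perm = 50)
  full <- gene_scan(fx$blk, fx$y, fx$genes, methods = c("vegas", "gates"),
                    plan = plan)
  g2 <- fx$genes[2, ]
  one <- gene_scan(fx$blk, fx$y, fx$genes, methods = c("vegas", "gates"),
                   plan = plan, chrom = "1", from_bp = g2$start,
                   to_bp = g2$start)
  ref <- full$genes[full$genes$gene_id == g2$gene_id, ]
  expect_equal(one$genes$statistic, ref$statistic)
  expect_equal(one$genes$p_value, ref$p_value)
})

test_that("an empty region yields an empty report, not an error", {
  fx <- scan_fixture()
  out <- gene_scan(fx$blk, fx$y, fx$genes, methods = "vegas",
                   plan = permutation_plan(1, 10), chrom = "99")
  expect_equal(nrow(out$genes), 0L)
  expect_s3_class(out, "gene_scan")
})

test_that("mismatched sample counts are a configuration error", {
  fx <- scan_fixture()
  expect_error(gene_scan(fx$blk, rnorm(50), fx$genes, methods = "vegas"),
               "sample counts")
})

test_that("the combined report carries all six methods plus model sizes", {
  fx <- scan_fixture()
  out <- gene_scan(fx$blk, fx$y, fx$genes[1:2, ],
                   plan = permutation_plan(2, 30), gate = FALSE)
  expect_equal(nrow(out$report), 2L)
  for (m in c("gwis", "bimbam", "vegas", "gates", "minsnp", "minsnp_gene"))
    expect_true(all(paste0(m, c("_stat", "_p", "_k")) %in%
                      names(out$report)))
  expect_true(all(out$genes$model_size <= out$genes$snp_count))
  expect_output(print(out), "genotype mode")
})

test_that("scans are deterministic and thread-count invariant", {
  fx <- scan_fixture()
  a <- gene_scan(fx$blk, fx$y, fx$genes[1:2, ], methods = "minsnp_gene",
                 plan = permutation_plan(9, 40, n_threads = 1))
  b <- gene_scan(fx$blk, fx$y, fx$genes[1:2, ], methods = "minsnp_gene",
                 plan = permutation_plan(9, 40, n_threads = 4))
  expect_identical(a$genes$p_value, b$genes$p_value)
})

test_that("the single-SNP scan covers intergenic SNPs too", {
  fx <- scan_fixture()
  genes_partial <- fx$genes[1, , drop = FALSE]  # leaves SNPs 11..30 intergenic
  out <- gene_scan(fx$blk, fx$y, genes_partial,
                   methods = c("vegas", "single_snp"),
                   plan = permutation_plan(1, 10))
  expect_equal(nrow(out$snp), 30L)
})

test_that("the logistic driver produces finite results on a small study", {
  set.seed(210)
  blk <- make_block(150, 6, seed = 210)
  eta <- -0.4 + 0.7 * scale(blk$dosages[, 1])
  y <- rbinom(150, 1, plogis(eta))
  if (var(y) == 0) y[1:2] <- c(0, 1)
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "1",
                      start = c(2000L, 5000L), end = c(4000L, 7000L))
  out <- gene_scan(blk, y, genes, model = "logistic",
                   methods = c("gwis", "vegas", "gates", "minsnp"),
                   plan = permutation_plan(3, 30), gate = FALSE)
  expect_true(all(is.finite(out$genes$statistic)))
  expect_true(all(out$genes$p_value[out$genes$method != "minsnp"] > 0,
                  na.rm = TRUE))
})

test_that("summary-mode scans run through the driver", {
  set.seed(211)
  blk <- make_block(200, 12, seed = 211)
  y <- null_pheno(200, seed = 212)
  scan <- single_snp_scan(blk, y)
  recs <- data.frame(snp_id = scan$snp_id, beta = scan$beta, se = scan$se,
                     maf = blk$snps$maf, n = scan$n)
  pf <- withr::local_tempfile()
  write_panel_files(blk, pf)
  genes <- simulate_gene_structure(12, c(6, 6), seed = 213,
                                   positions = blk$snps$pos)
  out <- gene_scan(genes = genes, summary = recs, panel = read_panel(pf),
                   snp_info = blk$snps,
                   pheno_moments = list(mean = mean(y$values),
                                        variance = var(y$values)),
                   methods = c("vegas", "gates", "minsnp_gene"),
                   plan = permutation_plan(5, 300))
  expect_equal(out$mode, "summary")
  expect_equal(nrow(out$report), 2L)
  expect_true(all(out$genes$p_value > 0 & out$genes$p_value <= 1))
})

test_that("p-value adjustment appends per-method corrected columns", {
  fx <- scan_fixture()
  out <- gene_scan(fx$blk, fx$y, fx$genes, methods = c("vegas", "gates"),
                   plan = permutation_plan(4, 20))
  adj <- adjust_gene_pvalues(out)
  expect_true(all(c("p_bonferroni", "p_BH") %in% names(adj)))
  v <- adj[adj$method == "vegas", ]
  expect_equal(v$p_bonferroni, pmin(v$p_value * nrow(v), 1))
})
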