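ALL_METHODS <- c("gwis", "bimbam", "vegas", "gates", "minsnp", "minsnp_gene")

block_subset <- function(block, idx) {
  structure(list(dosages = block$dosages[, idx, drop = FALSE],
                 snps = block$snps[idx, , drop = FALSE],
                 sample_ids = block$sample_ids),
            class = "genotype_block")
}

# Slow generic permutation path for the logistic model: one logistic scan
# per permutation feeds vegas/minsnp/minsnp-gene; gwis and bimbam refit.
logistic_gene_chi2 <- function(X, yv, covariates) {
  base <- if (is.null(covariates)) matrix(1, nrow(X), 1) else
    cbind(1, as.matrix(covariates))
  vapply(seq_len(ncol(X)), function(j) {
    if (stats::var(X[, j]) == 0) return(NA_real_)
    fit <- logistic_irls(cbind(base, X[, j]), yv)
    if (fit$separated) return(NA_real_)
    k <- ncol(base) + 1L
    (fit$beta[k] / fit$se[k])^2
  }, numeric(1))
}

#' Run gene-based association tests gene-by-gene
#'
#' The driver ties the toolkit together: genes are processed one at a time
#' (memory stays bounded by the largest gene), the per-gene sufficient
#' statistics are computed once and shared by all enabled methods, and all
#' permutation-based methods consume the same seeded Fisher-Yates shuffle
#' stream, so adding or removing methods never changes another method's
#' p-values.
#'
#' Genotype mode takes a [genotype_block()] and phenotype; summary mode
#' takes per-SNP summary records plus a reference panel and replaces
#' permutations with multivariate-normal null z-scores (case-control
#' summary data is approximated with the linear model, with a notice).
#'
#' @param block [genotype_block()] (genotype mode).
#' @param y phenotype (genotype mode).
#' @param genes gene table (`gene_id, chrom, start, end`), with or without
#'   a precomputed `snp_indices` list column.
#' @param methods subset of `r paste0('"', ALL_METHODS, '"', collapse = ", ")`;
#'   `"single_snp"` may be added to also emit the genome-wide single-SNP
#'   scan (all SNPs, genic or not).
#' @param covariates optional covariate matrix, residualized out once
#'   globally.
#' @param model `"linear"` or `"logistic"` (genotype mode; logistic
#'   permutations refit per shuffle and are slow by nature).
#' @param plan a [permutation_plan()].
#' @param summary summary-statistics data frame (summary mode).
#' @param panel [read_panel()] (summary mode).
#' @param snp_info SNP annotation used to map summary records to genes.
#' @param pheno_moments phenotype mean/variance for summary mode.
#' @param flank_bp gene flanking window for SNP assignment.
#' @param chrom,from_bp,to_bp optional region restriction.
#' @param bf a [bf_config()] for BIMBAM.
#' @param maf_switch MinSNP parametric/empirical MAF threshold.
#' @param gate GWiS permutation gate (see [gwis_pvalue()]).
#' @param verbose per-gene progress on stderr.
#' @return object of class `"gene_scan"`: `$genes` (long per-gene result
#'   table), `$report` (wide combined table, one row per gene), `$snp`
#'   (single-SNP scan or `NULL`), plus the run configuration.
#' @export
gene_scan <- function(block = NULL, y = NULL, genes, methods = ALL_METHODS,
                      covariates = NULL, model = c("linear", "logistic"),
                      plan = permutation_plan(),
                      summary = NULL, panel = NULL, snp_info = NULL,
                      pheno_moments = list(mean = 0, variance = 1),
                      flank_bp = 0, chrom = NULL, from_bp = NULL,
                      to_bp = NULL, bf = bf_config(), maf_switch = 0.01,
                      gate = TRUE, verbose = FALSE) {
  model <- match.arg(model)
  mode <- if (is.null(summary)) "genotype" else "summary"
  want_single <- "single_snp" %in% methods
  methods <- setdiff(methods, "single_snp")
  bad <- setdiff(methods, ALL_METHODS)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  if (mode == "summary" && model == "logistic") {
    message("summary mode: using the linear-regression approximation ",
            "for a dichotomous trait")
    model <- "linear"
  }

  # gene -> SNP assignment
  ann <- if (mode == "genotype") block$snps else {
    if (is.null(snp_info)) stop("summary mode needs snp_info to map genes")
    si <- if (is.character(snp_info)) read_snp_info(snp_info) else snp_info
    si[match(summary$snp_id, si$id), , drop = FALSE]
  }
  if (is.null(genes$snp_indices)) genes <- map_snps_to_genes(ann, genes, flank_bp)
  if (!is.null(chrom)) {
    keep <- genes$chrom == chrom
    if (!is.null(from_bp)) keep <- keep & genes$end >= from_bp
    if (!is.null(to_bp)) keep <- keep & genes$start <= to_bp
    genes <- genes[keep, , drop = FALSE]
  }

  rows <- list()
  if (mode == "genotype") {
    yv <- if (inherits(y, "phenotype")) y$values else as.numeric(y)
    if (length(yv) != nrow(block$dosages))
      stop("configuration error: phenotype and genotype sample counts differ")
    N <- nrow(block$dosages)
    perms <- if (length(methods) && nrow(genes))
      shuffle_stream(plan, N) else NULL
    for (g in seq_len(nrow(genes))) {
      idx <- genes$snp_indices[[g]]
      gid <- genes$gene_id[g]
      if (verbose) message("gene ", gid, " (", length(idx), " SNPs)")
      if (!length(idx)) next
      sub <- block_subset(block, idx)
      if (model == "linear") {
        for (m in methods) {
          r <- switch(m,
            gwis = gwis_pvalue(sub, yv, plan, covariates, gate, perms),
            bimbam = bimbam_gene(sub, yv, bf, plan, "linear", perms),
            vegas = vegas_gene(sub, yv, plan, covariates, perms),
            minsnp = minsnp(sub, yv, plan, covariates, maf_switch, perms),
            minsnp_gene = minsnp_gene(sub, yv, plan, covariates, perms),
            gates = {
              st <- compute_sufficient_stats(sub, yv, covariates)
              dg <- diag(st$gg)
              Fst <- f_stats_vec(st$gy, dg, st$yy, st$df_null - 1L)
              p_snp <- stats::pf(Fst, 1, st$df_null - 1L, lower.tail = FALSE)
              s <- sqrt(pmax(dg, .Machine$double.eps))
              pg <- gates_pvalue(p_snp, st$gg / tcrossprod(s))
              gene_result("gates", pg, pg, 0L, length(idx), length(idx))
            })
          r$gene_id <- gid
          rows[[length(rows) + 1L]] <- r
        }
      } else {
        rows <- c(rows, logistic_gene_rows(sub, yv, covariates, methods,
                                           plan, perms, bf, gate, gid))
      }
    }
    snp_tab <- if (want_single) single_snp_scan(block, yv, covariates, model)
               else NULL
  } else {
    ld_parent <- if (inherits(panel, "panel_ld")) panel$panel else panel
    for (g in seq_len(nrow(genes))) {
      idx <- genes$snp_indices[[g]]
      gid <- genes$gene_id[g]
      if (verbose) message("gene ", gid, " (", length(idx), " SNPs)")
      if (!length(idx)) next
      ld <- panel_ld(ld_parent)  # per-gene cache lifetime
      ss <- gene_stats_from_summary(summary[idx, , drop = FALSE], ld,
                                    pheno_moments)
      if (is.null(ss)) next
      r <- summary_gene_tests(ss, methods, n_sims = plan$n_perm,
                              seed = plan$seed + g, bf = bf,
                              maf_switch = maf_switch, gate = gate)
      r$gene_id <- gid
      rows[[length(rows) + 1L]] <- r
    }
    snp_tab <- NULL
  }

  long <- if (length(rows)) do.call(rbind, rows) else
    gene_result(character(0), numeric(0), numeric(0), integer(0),
                integer(0), integer(0), character(0))[0, ]
  rownames(long) <- NULL
  report <- if (nrow(long))
    write_combined_report(split(long, long$method)) else
    data.frame(gene_id = character(0))
  structure(list(genes = long, report = report, snp = snp_tab,
                 methods = methods, mode = mode, model = model,
                 plan = plan, n_genes = nrow(genes), call = match.call()),
            class = "gene_scan")
}

# Logistic-model gene rows with shared permutation refits.
logistic_gene_rows <- function(sub, yv, covariates, methods, plan, perms,
                               bf, gate, gid) {
  rows <- list()
  stats <- compute_sufficient_stats(sub, yv, covariates)
  eff <- effective_tests(stats)
  chi2 <- logistic_gene_chi2(sub$dosages, yv, covariates)
  need_scan_perm <- any(c("vegas", "minsnp", "minsnp_gene") %in% methods)
  B <- if (is.null(perms)) 0L else ncol(perms)
  chi2_null <- NULL
  if (need_scan_perm && B > 0) {
    chi2_null <- vapply(seq_len(B), function(b)
      logistic_gene_chi2(sub$dosages, yv[perms[, b]], covariates),
      numeric(ncol(sub$dosages)))
    if (is.null(dim(chi2_null))) chi2_null <- matrix(chi2_null, nrow = 1)
  }
  M <- ncol(sub$dosages)
  for (m in methods) {
    r <- switch(m,
      vegas = {
        obs <- vegas_statistic(chi2)
        p <- if (is.null(chi2_null)) NA_real_ else
          empirical_p(obs, apply(chi2_null, 2, sum, na.rm = TRUE))
        gene_result("vegas", obs, p, B, M, M)
      },
      minsnp = {
        p_snp <- stats::pchisq(chi2, 1, lower.tail = FALSE)
        best <- which.min(p_snp)
        gene_result("minsnp", chi2[best], p_snp[best], B, 1L, M)
      },
      minsnp_gene = {
        obs <- suppressWarnings(max(chi2, na.rm = TRUE))
        p <- if (is.null(chi2_null)) NA_real_ else
          empirical_p(obs, apply(chi2_null, 2, max, na.rm = TRUE))
        gene_result("minsnp_gene", obs, p, B, 1L, M)
      },
      gates = {
        p_snp <- stats::pchisq(chi2, 1, lower.tail = FALSE)
        s <- sqrt(pmax(diag(stats$gg), .Machine$double.eps))
        pg <- gates_pvalue(p_snp, stats$gg / tcrossprod(s))
        gene_result("gates", pg, pg, 0L, M, M)
      },
      gwis = {
        obs <- gwis_forward_search(stats, eff, model = "logistic",
                                   block = sub, y = yv,
                                   covariates = covariates)
        if ((gate && obs$score <= 0) || B == 0) {
          gene_result("gwis", obs$score,
                      NA_real_, 0L, obs$k, M)
        } else {
          raws <- vapply(seq_len(B), function(b)
            gwis_forward_search(stats, eff, model = "logistic",
                                block = sub, y = yv[perms[, b]],
                                covariates = covariates)$raw, numeric(1))
          gene_result("gwis", obs$score, empirical_p(obs$raw, raws),
                      B, obs$k, M)
        }
      },
      bimbam = bimbam_gene(sub, yv, bf, if (B > 0) plan else NULL,
                           "logistic", perms))
    r$gene_id <- gid
    rows[[length(rows) + 1L]] <- r
  }
  rows
}

#' @export
print.gene_scan <- function(x, ...) {
  cat(sprintf("gene scan (%s mode, %s model): %d genes, methods: %s\n",
              x$mode, x$model, x$n_genes,
              paste(x$methods, collapse = ", ")))
  cat(sprintf("permutations: %d (seed %d)\n", x$plan$n_perm, x$plan$seed))
  if (nrow(x$genes)) {
    sig <- x$genes[!is.na(x$genes$p_value) & x$genes$p_value <= 0.05, ]
    cat(sprintf("%d method-gene results, %d with p <= 0.05\n",
                nrow(x$genes), nrow(sig)))
  }
  invisible(x)
}

#' @export
summary.gene_scan <- function(object, n = 10, ...) {
  g <- object$genes
  g <- g[order(g$p_value), ]
  cat("top gene results:\n")
  print(utils::head(g, n), row.names = FALSE)
  invisible(object)
}

#' Multiple-testing adjustment helper
#'
#' Gene p-values are reported raw by [gene_scan()]; this helper appends
#' Bonferroni- or Benjamini-Hochberg-adjusted columns per method on
#' request.
#'
#' @param scan a [gene_scan()] result (or its `$genes` table).
#' @param method one of `p.adjust.methods` (default both `"bonferroni"`
#'   and `"BH"`).
#' @return the long result table with `p_<method>` columns appended.
#' @export
adjust_gene_pvalues <- function(scan, method = c("bonferroni", "BH")) {
  g <- if (inherits(scan, "gene_scan")) scan$genes else scan
  for (m in method) {
    col <- paste0("p_", m)
    g[[col]] <- NA_real_
    for (meth in unique(g$method)) {
      i <- g$method == meth
      g[[col]][i] <- stats::p.adjust(g$p_value[i], method = m)
    }
  }
  g
}
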