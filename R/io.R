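#' Read a genotype dosage file
#'
#' Two dialects are supported.  `dosage_table` is whitespace-delimited text
#' with a header row (`sample_id` followed by SNP ids) and one row per
#' sample: the sample id then `P` fractional dosages in \[0,2\].
#' `vcf_dosage` is a VCF whose per-sample `DS` FORMAT field carries the
#' dosage; when `DS` is absent the dosage is taken as the alternate-allele
#' count from `GT`.
#'
#' Missing dosages (`NA`, `.`) are imputed to the per-SNP mean dosage and
#' the imputed count is reported via `message()`.  Any dosage outside
#' \[0,2\] is an error naming the offending row and column.
#'
#' @param path input file.
#' @param format_name `"dosage_table"` or `"vcf_dosage"`.
#' @param snp_info optional path to (or data frame of) SNP annotation with
#'   columns `id`, `chrom`, `pos`, `ref`, `alt` for the `dosage_table`
#'   dialect, which carries no positional metadata itself.
#' @return a [genotype_block()].
#' @export
read_genotypes <- function(path, format_name = c("dosage_table", "vcf_dosage"),
                           snp_info = NULL) {
  format_name <- match.arg(format_name)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (format_name == "dosage_table") {
    hdr <- strsplit(readLines(path, n = 1L), "[ \t]+")[[1]]
    snp_ids <- hdr[-1]
    tab <- tryCatch(
      read.table(path, header = TRUE, check.names = FALSE,
                 na.strings = c("NA", "."), stringsAsFactors = FALSE),
      error = function(e) stop("malformed dosage table '", path, "': ",
                               conditionMessage(e)))
    sample_ids <- as.character(tab[[1]])
    X <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(X)) {
      bad <- which(is.na(suppressWarnings(as.numeric(X))) & !is.na(X))[1]
      stop(sprintf("non-numeric dosage near row %d of %s",
                   ((bad - 1) %% nrow(X)) + 2, path))
    }
    storage.mode(X) <- "double"
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fmt <- v@gt[1, 1]
    if (grepl("\\bDS\\b", fmt)) {
      ds <- vcfR::extract.gt(v, element = "DS")
      X <- t(apply(ds, 1, as.numeric))
    } else {
      gt <- vcfR::extract.gt(v, element = "GT")
      cnt <- function(g) {
        ifelse(is.na(g), NA_real_,
               vapply(strsplit(g, "[/|]"), function(a)
                 sum(a == "1"), numeric(1)))
      }
      X <- t(apply(gt, 1, cnt))
    }
    X <- t(X)  # samples x SNPs
    sample_ids <- colnames(v@gt)[-1]
    fx <- vcfR::getFIX(v)
    snp_info <- data.frame(id = fx[, "ID"], chrom = fx[, "CHROM"],
                           pos = as.integer(fx[, "POS"]),
                           ref = fx[, "REF"], alt = fx[, "ALT"],
                           maf = NA_real_, stringsAsFactors = FALSE)
    snp_ids <- snp_info$id
  }
  n_missing <- sum(is.na(X))
  if (n_missing > 0) {
    for (j in which(colSums(is.na(X)) > 0)) {
      m <- mean(X[, j], na.rm = TRUE)
      X[is.na(X[, j]), j] <- m
    }
    message(n_missing, " missing dosage(s) imputed to per-SNP mean")
  }
  bad <- which(X < 0 | X > 2)
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(X)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(X)) + 1L
    stop(sprintf("dosage %g out of [0,2] at data row %d, SNP column %d (%s)",
                 X[bad[1]], i, j, snp_ids[j]))
  }
  if (is.character(snp_info)) snp_info <- read_snp_info(snp_info)
  if (is.null(snp_info)) {
    snp_info <- data.frame(id = snp_ids, chrom = "0",
                           pos = seq_along(snp_ids), ref = "N", alt = "N",
                           maf = NA_real_, stringsAsFactors = FALSE)
  } else {
    snp_info <- snp_info[match(snp_ids, snp_info$id), , drop = FALSE]
    if (anyNA(snp_info$id)) stop("snp_info is missing some dosage-table SNPs")
  }
  genotype_block(X, snp_info, sample_ids)
}

#' @rdname read_genotypes
#' @param block a [genotype_block()] to write.
#' @param digits decimal places for dosages (round-trip is exact for the
#'   default simulator output, which is integer or half-integer).
#' @export
write_dosage_table <- function(block, path, digits = 6) {
  df <- data.frame(sample_id = block$sample_ids,
                   round(block$dosages, digits), check.names = FALSE)
  colnames(df) <- c("sample_id", block$snps$id)
  write.table(df, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read / write SNP annotation
#'
#' Whitespace-delimited text with header `id chrom pos ref alt [maf]`.
#' @param path file path.
#' @export
read_snp_info <- function(path) {
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                    colClasses = NA)
  need <- c("id", "chrom", "pos")
  if (!all(need %in% names(tab)))
    stop("snp info file needs columns: ", paste(need, collapse = ", "))
  if (is.null(tab$ref)) tab$ref <- "N"
  if (is.null(tab$alt)) tab$alt <- "N"
  if (is.null(tab$maf)) tab$maf <- NA_real_
  tab$chrom <- as.character(tab$chrom)
  tab
}

#' @rdname read_snp_info
#' @param snps SNP annotation data frame.
#' @export
write_snp_info <- function(snps, path) {
  write.table(snps, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read a gene annotation table
#'
#' 4+ column whitespace-delimited text: `gene_id chrom start end`, 1-based
#' inclusive bp coordinates.
#' @param path file path.
#' @return data frame `gene_id, chrom, start, end`.
#' @export
read_genes <- function(path) {
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(tab))) {
    # headerless 4-column variant
    tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 4) stop("gene table needs 4 columns (gene_id chrom start end)")
    names(tab)[1:4] <- need
  }
  if (any(tab$start > tab$end)) stop("gene with start > end")
  tab$chrom <- as.character(tab$chrom)
  tab[need]
}

#' @rdname read_genes
#' @param genes gene annotation data frame (list column `snp_indices`, if
#'   present, is dropped on write).
#' @export
write_gene_table <- function(genes, path) {
  write.table(genes[c("gene_id", "chrom", "start", "end")], path,
              quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read a phenotype file
#'
#' Two-column text `sample_id value` (header optional).
#' @param path file path.
#' @param trait_type forwarded to [phenotype_vector()].
#' @export
read_phenotype <- function(path, trait_type = NULL) {
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (!is.numeric(tab[[2]]))
    tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  y <- phenotype_vector(tab[[2]], trait_type)
  names(y$values) <- as.character(tab[[1]])
  y
}

#' @rdname read_phenotype
#' @param y a [phenotype_vector()] with named values.
#' @export
write_phenotype <- function(y, path) {
  ids <- names(y$values)
  if (is.null(ids)) ids <- paste0("s", seq_along(y$values))
  write.table(data.frame(sample_id = ids, value = y$values), path,
              quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Assign SNPs to genes
#'
#' SNP `j` is assigned to gene `g` iff the chromosomes match and
#' `start - flank_bp <= pos <= end + flank_bp` (1-based inclusive).  A SNP
#' may belong to several overlapping genes; genes covering no SNP are kept
#' with empty `snp_indices`.  The assignment is a pure function of
#' `(snps, genes, flank_bp)`.
#'
#' @param snps SNP annotation data frame (`id`, `chrom`, `pos`).
#' @param genes gene table (`gene_id`, `chrom`, `start`, `end`).
#' @param flank_bp symmetric flanking window in bp (default 0).
#' @return `genes` with a list column `snp_indices` of strictly increasing
#'   indices into `snps`.
#' @export
map_snps_to_genes <- function(snps, genes, flank_bp = 0) {
  idx <- vector("list", nrow(genes))
  for (g in seq_len(nrow(genes))) {
    hit <- which(snps$chrom == genes$chrom[g] &
                 snps$pos >= genes$start[g] - flank_bp &
                 snps$pos <= genes$end[g] + flank_bp)
    idx[[g]] <- sort(hit)
  }
  genes$snp_indices <- I(idx)
  genes
}

#' Read a per-SNP summary-statistics file
#'
#' Whitespace-delimited with header `snp_id beta se maf n`.  Records with
#' `se <= 0` or `maf` outside (0, 0.5] are rejected with an error.
#'
#' @param path file path.
#' @return data frame `snp_id, beta, se, maf, n`.
#' @export
read_summary <- function(path) {
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("snp_id", "beta", "se", "maf", "n")
  if (!all(need %in% names(tab)))
    stop("summary file needs columns: ", paste(need, collapse = ", "))
  bad <- which(!(tab$se > 0))
  if (length(bad)) stop("summary record with se <= 0 at line ", bad[1] + 1L)
  bad <- which(!(tab$maf > 0 & tab$maf <= 0.5))
  if (length(bad)) stop("summary record with maf outside (0,0.5] at line ",
                        bad[1] + 1L)
  tab[need]
}

#' @rdname read_summary
#' @param records summary data frame to write.
#' @export
write_summary_file <- function(records, path) {
  write.table(records, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

# ---- reference haplotype panel ------------------------------------------

#' Build the byte-offset index for a haplotype panel file
#'
#' The panel is one text row per SNP: `snp_id chrom pos` then `2H` alleles
#' coded 0/1.  The index maps each `snp_id` to the byte offset of its row so
#' single SNPs can be fetched without scanning the file.
#'
#' @param haps_path panel file.
#' @param index_path where to write the index (tab-separated
#'   `snp_id offset`); defaults to `<haps_path>.idx`.
#' @return `index_path`, invisibly.
#' @export
build_panel_index <- function(haps_path, index_path = paste0(haps_path, ".idx")) {
  lines <- readLines(haps_path)
  sizes <- nchar(lines, type = "bytes") + 1L  # newline
  offs <- c(0L, cumsum(sizes))[seq_along(lines)]
  ids <- sub("[ \t].*$", "", lines)
  if (anyDuplicated(ids)) stop("duplicate SNP id in panel: ",
                               ids[duplicated(ids)][1])
  write.table(data.frame(snp_id = ids, offset = offs), index_path,
              quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(index_path)
}

#' Open a reference haplotype panel
#'
#' @param haps_path panel file (see [build_panel_index()] for the format).
#' @param index_path its index; built on the fly when missing.
#' @return class `"reference_panel"`: the paths plus an id->offset lookup.
#' @export
read_panel <- function(haps_path, index_path = paste0(haps_path, ".idx")) {
  if (!file.exists(haps_path)) stop("panel file not found: ", haps_path)
  if (!file.exists(index_path)) build_panel_index(haps_path, index_path)
  idx <- read.table(index_path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("snp_id", "offset"))
  lookup <- new.env(parent = emptyenv(), size = nrow(idx))
  for (i in seq_len(nrow(idx))) assign(idx$snp_id[i], idx$offset[i], lookup)
  structure(list(haps_path = haps_path, index_path = index_path,
                 lookup = lookup, n_snps = nrow(idx)),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("reference panel: %d indexed SNPs (%s)\n", x$n_snps,
              x$haps_path))
  invisible(x)
}

#' Fetch one SNP's haplotype alleles from an indexed panel
#'
#' @param panel a [read_panel()] object.
#' @param snp_id SNP identifier.
#' @return integer 0/1 vector of length `2H`, or `NULL` when the id is not
#'   in the index (a lookup miss, distinct from file errors which throw).
#' @export
panel_fetch <- function(panel, snp_id) {
  off <- get0(snp_id, envir = panel$lookup, inherits = FALSE)
  if (is.null(off)) return(NULL)
  con <- file(panel$haps_path, "rb")
  on.exit(close(con))
  seek(con, where = off, origin = "start")
  line <- readLines(con, n = 1L)
  toks <- strsplit(line, "[ \t]+")[[1]]
  if (toks[1] != snp_id)
    stop("panel index out of date: expected ", snp_id, ", found ", toks[1])
  al <- as.integer(toks[-(1:3)])
  if (anyNA(al) || any(al < 0 | al > 1))
    stop("non-binary haplotype allele for ", snp_id)
  al
}

#' Write a genotype block as a haplotype panel
#'
#' Integer dosages are split into two pseudo-haplotypes (2 -> 1/1, 1 -> 1/0,
#' 0 -> 0/0), so the panel's genotype dosages reproduce the block exactly.
#' Intended for self-panel validation and simulated reference panels;
#' fractional dosages are rejected.
#'
#' @param block a [genotype_block()] with integer dosages.
#' @param haps_path output panel path.
#' @return `haps_path`, invisibly (index written alongside).
#' @export
write_panel_files <- function(block, haps_path) {
  X <- block$dosages
  if (any(X != round(X)))
    stop("panel export requires integer dosages (phased surrogate)")
  h1 <- ifelse(X >= 1, 1L, 0L)
  h2 <- ifelse(X >= 2, 1L, 0L)
  N <- nrow(X)
  lines <- character(ncol(X))
  for (j in seq_len(ncol(X))) {
    al <- as.vector(rbind(h1[, j], h2[, j]))  # interleave the two haplotypes
    lines[j] <- paste(c(block$snps$id[j], block$snps$chrom[j],
                        block$snps$pos[j], al), collapse = "\t")
  }
  writeLines(lines, haps_path)
  build_panel_index(haps_path)
  invisible(haps_path)
}

#' Combine per-method gene results into one report table
#'
#' One row per gene; per method a column group
#' `<method>_stat, <method>_p, <method>_k`.  A gene skipped by one method
#' keeps its row with empty cells for that method.
#'
#' @param results_by_method named list of per-method gene-result data frames
#'   (columns `gene_id`, `statistic`, `p_value`, `model_size`, ...), e.g. the
#'   `$genes` element of a [gene_scan()] split by method, or independently
#'   produced per-method tables.
#' @param path optional output file; when given the table is written
#'   tab-separated with `#`-prefixed provenance header lines.
#' @param header character vector of provenance lines (seed, n_perm, ...).
#' @return the combined data frame, invisibly when `path` is given.
#' @export
write_combined_report <- function(results_by_method, path = NULL,
                                  header = character()) {
  all_genes <- unique(unlist(lapply(results_by_method,
                                    function(d) d$gene_id)))
  out <- data.frame(gene_id = all_genes, stringsAsFactors = FALSE)
  for (m in names(results_by_method)) {
    d <- results_by_method[[m]]
    i <- match(all_genes, d$gene_id)
    out[[paste0(m, "_stat")]] <- d$statistic[i]
    out[[paste0(m, "_p")]] <- d$p_value[i]
    out[[paste0(m, "_k")]] <- d$model_size[i]
  }
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    for (h in header) writeLines(paste0("# ", h), con)
    suppressWarnings(write.table(out, con, quote = FALSE, row.names = FALSE,
                                 sep = "\t"))
    return(invisible(out))
  }
  out
}
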