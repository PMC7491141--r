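# Readers and writers for the pipeline's tabular formats. Dialect: tab
# separated, UTF-8, '.' for missing, no quoting; '#'-prefixed header lines
# carry the run configuration so every output is self-describing.

#' Run configuration
#'
#' Bundle of the pipeline's analysis thresholds. Defaults are the standard
#' operating points: EWA candidate threshold p < 0.001, cis-meQTL instrument
#' threshold p < 0.01 within a 1 Mb window, LD pruning at r-squared < 0.1,
#' exposure-GWAS instrument threshold p < 1e-5.
#'
#' @param ewa_p dual-EWA candidate selection p-value cutoff (strict `<`).
#' @param meqtl_p cis-meQTL instrument p-value cutoff.
#' @param ld_r2 LD pruning squared-correlation cutoff.
#' @param cis_window cis window half-width in bp (closed interval, 1-based).
#' @param instrument_p exposure-GWAS instrument p-value cutoff.
#' @param bootstrap_reps default bootstrap replicates for mediation inference.
#' @param rng_seed integer seed recorded in output headers.
#' @param output_dir directory for pipeline outputs.
#' @return object of class `run_config`.
#' @export
run_config <- function(ewa_p = 0.001, meqtl_p = 0.01, ld_r2 = 0.1,
                       cis_window = 1e6, instrument_p = 1e-5,
                       bootstrap_reps = 10000L, rng_seed = 1L,
                       output_dir = ".") {
  stopifnot(ewa_p > 0, ewa_p < 1, meqtl_p > 0, meqtl_p < 1,
            ld_r2 > 0, ld_r2 <= 1, cis_window > 0, instrument_p > 0,
            instrument_p < 1, bootstrap_reps >= 1)
  structure(list(ewa_p = ewa_p, meqtl_p = meqtl_p, ld_r2 = ld_r2,
                 cis_window = cis_window, instrument_p = instrument_p,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 rng_seed = as.integer(rng_seed), output_dir = output_dir),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-14s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

config_header <- function(config) {
  if (is.null(config)) return(character(0))
  vals <- vapply(unclass(config), function(v) paste(format(v), collapse = ","),
                 character(1))
  c("# methmediate run configuration",
    sprintf("# %s=%s", names(vals), vals))
}

# Format numeric columns at full double precision so write -> read round
# trips are bit exact.
format_full <- function(x) {
  if (is.double(x)) {
    out <- formatC(x, digits = 17, format = "g")
    out[is.na(x)] <- NA_character_
    trimws(out)
  } else x
}

write_tsv <- function(df, path, config = NULL) {
  df_out <- as.data.frame(lapply(df, format_full), stringsAsFactors = FALSE,
                          check.names = FALSE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(config_header(config), con)
  utils::write.table(df_out, con, sep = "\t", quote = FALSE, na = ".",
                     row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, colClasses = NA) {
  utils::read.delim(path, sep = "\t", na.strings = ".", quote = "",
                    comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = colClasses, check.names = FALSE)
}

sample_table_required <- function() {
  c("sample_id", "exposure_group", "exposure_freq", "sex", "age", "race",
    "smoking", "adherence", "alcohol_auditc", "cannabis_freq", "opioid_freq",
    "wbc", "cd4t", "cd8t", "nk", "bcell", "mono", "gran",
    "vacs_at_draw", "vacs_avg_after")
}

cell_prop_cols <- function() c("cd4t", "cd8t", "nk", "bcell", "mono", "gran")

#' Validate a sample/phenotype table
#'
#' Enforces the sample-table invariants: unique sample ids, exposure group in
#' \{persistent, none, inconsistent\}, ordinal exposure frequency 0-5, the six
#' cell-type proportions summing to one (tolerance 1e-6), and positive
#' survival times where present. Factors (`exposure_group`, `sex`, `race`)
#' are coerced to fixed level sets so design matrices are stable.
#'
#' @param samples data frame with the required phenotype columns.
#' @return the validated data frame, classed `sample_table`.
#' @export
validate_sample_table <- function(samples) {
  missing_cols <- setdiff(sample_table_required(), names(samples))
  if (length(missing_cols) > 0L) {
    stop("sample table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id values in sample table", call. = FALSE)
  }
  samples$exposure_group <- factor(as.character(samples$exposure_group),
                                   levels = c("none", "inconsistent",
                                              "persistent"))
  if (anyNA(samples$exposure_group)) {
    stop("exposure_group must be one of persistent/none/inconsistent",
         call. = FALSE)
  }
  if (!all(samples$exposure_freq %in% 0:5)) {
    stop("exposure_freq must be ordinal 0-5", call. = FALSE)
  }
  samples$sex <- factor(as.character(samples$sex),
                        levels = c("male", "female"))
  samples$race <- factor(as.character(samples$race),
                         levels = c("caucasian", "african_american", "other"))
  props <- as.matrix(samples[, cell_prop_cols()])
  bad <- which(abs(rowSums(props) - 1) > 1e-6)
  if (length(bad) > 0L) {
    stop("cell-type proportions do not sum to 1 for sample(s): ",
         paste(utils::head(samples$sample_id[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  if ("surv_years" %in% names(samples)) {
    sv <- samples$surv_years
    if (any(!is.na(sv) & sv <= 0)) {
      stop("surv_years must be > 0 where present", call. = FALSE)
    }
  }
  class(samples) <- c("sample_table", "data.frame")
  samples
}

#' Read a sample/phenotype table from TSV
#'
#' @param path TSV file with one row per sample; '#' lines are ignored.
#' @return validated `sample_table` data frame.
#' @seealso [validate_sample_table()] for the invariants enforced.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  validate_sample_table(read_tsv(path))
}

#' @rdname read_sample_table
#' @param samples validated sample table.
#' @param config optional [run_config()] recorded in the file header.
#' @export
write_sample_table <- function(samples, path, config = NULL) {
  df <- as.data.frame(samples)
  df$exposure_group <- as.character(df$exposure_group)
  df$sex <- as.character(df$sex)
  df$race <- as.character(df$race)
  write_tsv(df, path, config)
}

#' Read a CpG annotation table from TSV
#'
#' Columns: cpg, chr, pos (1-based), gene, and optionally gene_group and
#' island_relation.
#'
#' @param path TSV file.
#' @return data frame with unique `cpg` and `pos >= 1`.
#' @export
read_cpg_annotation <- function(path) {
  ann <- read_tsv(path, colClasses = c(chr = "character"))
  req <- c("cpg", "chr", "pos", "gene")
  missing_cols <- setdiff(req, names(ann))
  if (length(missing_cols) > 0L) {
    stop("annotation missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(ann$cpg)) stop("duplicate cpg ids in annotation",
                                   call. = FALSE)
  if (any(ann$pos < 1)) stop("annotation pos must be >= 1 (1-based)",
                             call. = FALSE)
  ann
}

#' @rdname read_cpg_annotation
#' @param annot annotation data frame.
#' @param config optional [run_config()].
#' @export
write_cpg_annotation <- function(annot, path, config = NULL) {
  write_tsv(annot, path, config)
}

#' Read a methylation beta matrix from TSV
#'
#' First column `cpg_id`, remaining columns one per sample. Rows are
#' restricted to CpGs present in the annotation, preserving file order.
#' Any value outside \[0,1\] is fatal, naming the offending cell.
#'
#' @param path TSV file.
#' @param annot CpG annotation data frame (see [read_cpg_annotation()]).
#' @return numeric matrix, CpGs x samples.
#' @export
read_beta_matrix <- function(path, annot) {
  df <- read_tsv(path)
  if (names(df)[1] != "cpg_id") {
    stop("beta matrix first column must be 'cpg_id'", call. = FALSE)
  }
  keep <- df$cpg_id %in% annot$cpg
  df <- df[keep, , drop = FALSE]
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$cpg_id
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("beta value out of [0,1] at cpg %s, sample %s (%.4g)",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]],
                 m[bad[1, , drop = FALSE]]), call. = FALSE)
  }
  m
}

#' @rdname read_beta_matrix
#' @param beta CpGs x samples numeric matrix with rownames/colnames.
#' @param config optional [run_config()].
#' @export
write_beta_matrix <- function(beta, path, config = NULL) {
  df <- data.frame(cpg_id = rownames(beta),
                   as.data.frame(beta, check.names = FALSE),
                   check.names = FALSE)
  write_tsv(df, path, config)
}

#' Impute missing beta values by per-CpG mean
#'
#' The analysis set must be complete before any scan; missing entries are
#' replaced by the CpG's mean over non-missing samples and the count of
#' imputed cells is attached as attribute `n_imputed`.
#'
#' @param beta CpGs x samples matrix, possibly with NAs.
#' @return complete matrix with attribute `n_imputed`.
#' @export
impute_beta_means <- function(beta) {
  n_missing <- sum(is.na(beta))
  if (n_missing > 0L) {
    means <- rowMeans(beta, na.rm = TRUE)
    idx <- which(is.na(beta), arr.ind = TRUE)
    beta[idx] <- means[idx[, 1]]
  }
  attr(beta, "n_imputed") <- n_missing
  beta
}

new_genotype_matrix <- function(dosages, info) {
  stopifnot(nrow(dosages) == nrow(info))
  if (any(dosages < 0 | dosages > 2, na.rm = TRUE)) {
    stop("dosages must lie in [0,2]", call. = FALSE)
  }
  rownames(dosages) <- info$snp_id
  structure(list(dosages = dosages, info = info), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d SNPs x %d samples (MAF %.3f-%.3f)\n",
              nrow(x$dosages), ncol(x$dosages),
              min(x$info$maf), max(x$info$maf)))
  invisible(x)
}

#' Read genotype dosages from VCF or TSV
#'
#' VCF files (detected by a `##fileformat=VCF` first line or `.vcf`
#' extension) are parsed with \pkg{vcfR}; per-sample dosage is taken from the
#' DS FORMAT field when present, otherwise from the GT alternate-allele
#' count. Multiallelic records are skipped with a warning giving the count.
#' TSV files carry columns snp_id, chr, pos, optionally ref/alt, then one
#' column per sample. SNPs with minor allele frequency below `maf_min` are
#' dropped; sporadic missing dosages are mean-imputed per SNP.
#'
#' @param path VCF or TSV file.
#' @param maf_min minor-allele-frequency filter (default 0.01).
#' @return `genotype_matrix`: list with `dosages` (SNPs x samples, values in
#'   \[0,2\]) and `info` (snp_id, chr, pos, ref, alt, maf).
#' @export
read_genotypes <- function(path, maf_min = 0.01) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  is_vcf <- grepl("^##fileformat=VCF", first) || grepl("\\.vcf$", path)
  if (is_vcf) {
    parsed <- read_genotypes_vcf(path)
  } else {
    parsed <- read_genotypes_tsv(path)
  }
  dos <- parsed$dosages
  # per-SNP mean imputation of sporadic missingness
  if (anyNA(dos)) {
    means <- rowMeans(dos, na.rm = TRUE)
    idx <- which(is.na(dos), arr.ind = TRUE)
    dos[idx] <- means[idx[, 1]]
  }
  m <- rowMeans(dos) / 2
  maf <- pmin(m, 1 - m)
  keep <- maf >= maf_min & maf > 0
  info <- parsed$info[keep, , drop = FALSE]
  info$maf <- maf[keep]
  new_genotype_matrix(dos[keep, , drop = FALSE], info)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("package 'vcfR' is required to read VCF genotypes", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    warning(sum(multi), " multiallelic record(s) skipped", call. = FALSE)
  }
  ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  if (!is.null(ds) && !all(is.na(ds))) {
    dos <- ds
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- apply(gt, 2, function(g) {
      vapply(strsplit(g, "[/|]"), function(a) {
        if (length(a) == 0L || any(a == ".")) NA_real_
        else sum(a != "0")
      }, numeric(1))
    })
    if (is.null(dim(dos))) dos <- matrix(dos, nrow = nrow(gt))
  }
  dos <- dos[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  info <- data.frame(snp_id = fix$ID, chr = fix$CHROM,
                     pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT,
                     stringsAsFactors = FALSE)
  colnames(dos) <- colnames(v@gt)[-1]
  list(dosages = dos, info = info)
}

read_genotypes_tsv <- function(path) {
  df <- read_tsv(path, colClasses = c(chr = "character"))
  req <- c("snp_id", "chr", "pos")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop("genotype TSV missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  meta_cols <- intersect(c("snp_id", "chr", "pos", "ref", "alt"), names(df))
  dos <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  storage.mode(dos) <- "double"
  info <- df[, meta_cols, drop = FALSE]
  if (is.null(info$ref)) info$ref <- "A"
  if (is.null(info$alt)) info$alt <- "B"
  list(dosages = dos, info = info)
}

#' Write genotypes as TSV or minimal VCF
#'
#' `write_genotypes_tsv` emits the dosage-matrix dialect read back by
#' [read_genotypes()]; `write_genotypes_vcf` emits a minimal VCFv4.2 with GT
#' calls and therefore requires integer dosages.
#'
#' @param geno `genotype_matrix`.
#' @param path output file.
#' @param config optional [run_config()] (TSV header only).
#' @export
write_genotypes_tsv <- function(geno, path, config = NULL) {
  df <- data.frame(geno$info[, c("snp_id", "chr", "pos", "ref", "alt")],
                   as.data.frame(geno$dosages, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path, config)
}

#' @rdname write_genotypes_tsv
#' @export
write_genotypes_vcf <- function(geno, path) {
  dos <- round(geno$dosages)
  if (max(abs(dos - geno$dosages)) > 1e-9) {
    stop("VCF GT output requires integer dosages", call. = FALSE)
  }
  gt_code <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(dos)), collapse = "\t"))
  body <- vapply(seq_len(nrow(dos)), function(i) {
    paste(c(geno$info$chr[i],
            format(geno$info$pos[i], scientific = FALSE, trim = TRUE),
            geno$info$snp_id[i],
            geno$info$ref[i], geno$info$alt[i], ".", "PASS", ".", "GT",
            gt_code[dos[i, ] + 1L]), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read/write an external GWAS instrument summary-statistics table
#'
#' Columns: snp, effect_allele, beta, se, p.
#'
#' @param path TSV file.
#' @return data frame of instrument summary statistics.
#' @export
read_external_stats <- function(path) {
  df <- read_tsv(path)
  req <- c("snp", "effect_allele", "beta", "se", "p")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop("summary-stats table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname read_external_stats
#' @param stats_df summary-statistics data frame.
#' @param config optional [run_config()].
#' @export
write_external_stats <- function(stats_df, path, config = NULL) {
  write_tsv(stats_df, path, config)
}
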