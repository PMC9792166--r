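#' Recognised mutation consequence classes
#'
#' Consequence vocabulary used throughout the package. Unknown strings read
#' from input tables are mapped to `"other"` with a warning.
#' @export
CONSEQUENCE_CLASSES <- c("missense", "nonsense", "frameshift", "splice",
                         "inframe_indel", "synonymous", "other")

#' Recognised gene roles
#' @export
GENE_ROLES <- c("oncogene", "tumor_suppressor", "other")

# Column schema for the somatic-variant table. Required columns must be
# present in every input; optional annotation columns default to the
# least-favorable value for ranking so missing evidence never inflates a
# score.
variant_required_cols <- function() {
  c("patient_id", "gene", "chrom", "pos", "ref", "alt", "consequence",
    "ffpe_vaf")
}

variant_optional_defaults <- function() {
  list(protein_change = NA_character_,
       cosmic_count = 0L,
       clinvar_pathogenic = FALSE,
       predicted_deleterious = FALSE,
       gene_role = "other",
       in_house_validated = FALSE,
       in_low_complexity = FALSE)
}

#' Build and validate a somatic-variant table
#'
#' Coerces a data frame to the package's somatic-variant schema: one row per
#' tumor-derived mutation, with 1-based VCF-style coordinates, an FFPE
#' variant allele fraction in `[0, 1]`, and annotation evidence used by the
#' tracking-panel scoring criteria. Missing optional annotation columns are
#' filled with `FALSE`/`0`/`"other"`.
#'
#' @param df A data frame with at least the columns `patient_id`, `gene`,
#'   `chrom`, `pos`, `ref`, `alt`, `consequence`, `ffpe_vaf`. Optional
#'   columns: `protein_change`, `cosmic_count`, `clinvar_pathogenic`,
#'   `predicted_deleterious`, `gene_role`, `in_house_validated`,
#'   `in_low_complexity`.
#' @return The validated data frame with all schema columns present.
#' @details Invariants enforced: `0 <= ffpe_vaf <= 1`, `pos >= 1`,
#'   `ref != alt`, `consequence` in [CONSEQUENCE_CLASSES] (unknown strings
#'   are mapped to `"other"` with a warning naming the rows), `gene_role`
#'   in [GENE_ROLES]. Violations raise an error naming the row and column.
#' @export
somatic_variants <- function(df) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(variant_required_cols(), names(df))
  if (length(missing_cols) > 0L) {
    stop("variant table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  defaults <- variant_optional_defaults()
  for (col in names(defaults)) {
    if (!col %in% names(df)) df[[col]] <- rep(defaults[[col]], nrow(df))
    df[[col]][is.na(df[[col]])] <- defaults[[col]]
  }

  df$patient_id <- as.character(df$patient_id)
  df$gene <- as.character(df$gene)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$ref <- as.character(df$ref)
  df$alt <- as.character(df$alt)
  df$consequence <- as.character(df$consequence)
  df$protein_change <- as.character(df$protein_change)
  df$ffpe_vaf <- as.numeric(df$ffpe_vaf)
  df$cosmic_count <- as.integer(df$cosmic_count)
  df$gene_role <- as.character(df$gene_role)
  for (col in c("clinvar_pathogenic", "predicted_deleterious",
                "in_house_validated", "in_low_complexity")) {
    df[[col]] <- as.logical(df[[col]])
  }

  .check_rows <- function(bad, column, what) {
    if (any(bad, na.rm = TRUE) || anyNA(bad)) {
      rows <- which(bad | is.na(bad))
      stop(sprintf("invalid %s in column '%s' at row(s) %s", what, column,
                   paste(utils::head(rows, 5L), collapse = ", ")),
           call. = FALSE)
    }
  }
  .check_rows(!(df$ffpe_vaf >= 0 & df$ffpe_vaf <= 1), "ffpe_vaf",
              "VAF (must be in [0, 1])")
  .check_rows(!(df$pos >= 1L), "pos", "position (must be >= 1)")
  .check_rows(df$ref == df$alt, "alt", "allele (ref must differ from alt)")
  .check_rows(!(df$cosmic_count >= 0L), "cosmic_count", "count")

  unknown <- !(df$consequence %in% CONSEQUENCE_CLASSES)
  if (any(unknown)) {
    warning(sprintf("unknown consequence class(es) %s mapped to 'other' at row(s) %s",
                    paste(unique(df$consequence[unknown]), collapse = ", "),
                    paste(utils::head(which(unknown), 5L), collapse = ", ")),
            call. = FALSE)
    df$consequence[unknown] <- "other"
  }
  unknown_role <- !(df$gene_role %in% GENE_ROLES)
  if (any(unknown_role)) {
    warning("unknown gene_role value(s) mapped to 'other'", call. = FALSE)
    df$gene_role[unknown_role] <- "other"
  }

  all_cols <- c(variant_required_cols(), names(defaults))
  df[, c(all_cols, setdiff(names(df), all_cols)), drop = FALSE]
}

#' Read a tumor somatic-variant table
#'
#' Reads either a MAF-style tab-separated table (the package's native
#' dialect, one mutation per row with the [somatic_variants] columns) or a
#' single-sample somatic VCF. Coordinates are kept 1-based as given.
#'
#' @param path Path to the input file.
#' @param format `"maf_tsv"` (default) or `"vcf"`.
#' @param patient_id Patient identifier to assign when the table does not
#'   carry one (required for VCF input, optional for TSV).
#' @return A validated somatic-variant data frame; zero rows for a
#'   header-only file.
#' @details For VCF input the allele fraction is taken from the `AF` FORMAT
#'   field when present, otherwise computed as `AD[2]/DP`. Annotation
#'   columns the VCF does not carry (COSMIC recurrence, ClinVar flag, gene
#'   role, ...) are read from the INFO keys `GENE`, `CLASS`, `PCHANGE`,
#'   `COSMIC_N`, `CLNPATH`, `DELET`, `ROLE`, `INHOUSE`, `LOWCX` when
#'   present and defaulted otherwise.
#' @export
read_variants <- function(path, format = c("maf_tsv", "vcf"),
                          patient_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "maf_tsv") {
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "#")
    if (nrow(df) == 0L) {
      df <- empty_variant_table()
      if (!is.null(patient_id)) df$patient_id <- character(0)
      return(df)
    }
    if (!is.null(patient_id) && !"patient_id" %in% names(df)) {
      df$patient_id <- patient_id
    }
    return(somatic_variants(df))
  }
  read_variants_vcf(path, patient_id = patient_id)
}

empty_variant_table <- function() {
  somatic_variants(data.frame(patient_id = character(0),
                              gene = character(0), chrom = character(0),
                              pos = integer(0), ref = character(0),
                              alt = character(0), consequence = character(0),
                              ffpe_vaf = numeric(0),
                              stringsAsFactors = FALSE))
}

read_variants_vcf <- function(path, patient_id = NULL) {
  if (is.null(patient_id)) {
    stop("patient_id is required for VCF input", call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    out <- empty_variant_table()
    return(out)
  }
  info_field <- function(key) {
    vcfR::extract.info(vcf, element = key)
  }
  vaf <- tryCatch({
    af <- vcfR::extract.gt(vcf, element = "AF", as.numeric = TRUE)
    as.numeric(af[, 1L])
  }, error = function(e) rep(NA_real_, nrow(fix)))
  if (anyNA(vaf)) {
    ad <- tryCatch(vcfR::extract.gt(vcf, element = "AD"),
                   error = function(e) NULL)
    dp <- tryCatch(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE),
                   error = function(e) NULL)
    if (!is.null(ad) && !is.null(dp)) {
      alt_reads <- as.numeric(vapply(strsplit(ad[, 1L], ","),
                                     function(x) x[2L], character(1)))
      vaf_ad <- alt_reads / as.numeric(dp[, 1L])
      vaf[is.na(vaf)] <- vaf_ad[is.na(vaf)]
    }
  }
  if (anyNA(vaf)) {
    stop("cannot derive VAF from VCF: need FORMAT/AF or FORMAT/AD + DP",
         call. = FALSE)
  }
  g <- function(key, default) {
    x <- tryCatch(info_field(key), error = function(e) NULL)
    if (is.null(x)) rep(default, nrow(fix)) else ifelse(is.na(x), default, x)
  }
  df <- data.frame(patient_id = patient_id,
                   gene = g("GENE", "."),
                   chrom = fix$CHROM,
                   pos = as.integer(fix$POS),
                   ref = fix$REF,
                   alt = fix$ALT,
                   consequence = g("CLASS", "other"),
                   protein_change = g("PCHANGE", NA_character_),
                   ffpe_vaf = vaf,
                   cosmic_count = as.integer(g("COSMIC_N", "0")),
                   clinvar_pathogenic = g("CLNPATH", "0") %in% c("1", "TRUE"),
                   predicted_deleterious = g("DELET", "0") %in% c("1", "TRUE"),
                   gene_role = g("ROLE", "other"),
                   in_house_validated = g("INHOUSE", "0") %in% c("1", "TRUE"),
                   in_low_complexity = g("LOWCX", "0") %in% c("1", "TRUE"),
                   stringsAsFactors = FALSE)
  somatic_variants(df)
}

#' Tumor sample sequencing QC
#'
#' A tumor sample passes QC when strictly more than 98% of target bases
#' reach 20X coverage and strictly less than 1% of target regions have a
#' zero-coverage base.
#'
#' @param frac_bases_ge_20x Fraction of target bases with depth >= 20X.
#' @param frac_targets_zero_coverage Fraction of target regions containing
#'   at least one uncovered base.
#' @return `TRUE` (pass) or `FALSE`.
#' @export
qc_tumor_sample <- function(frac_bases_ge_20x, frac_targets_zero_coverage) {
  stopifnot(frac_bases_ge_20x >= 0, frac_bases_ge_20x <= 1,
            frac_targets_zero_coverage >= 0, frac_targets_zero_coverage <= 1)
  frac_bases_ge_20x > 0.98 & frac_targets_zero_coverage < 0.01
}

#' Apply the mutational-spectrum VAF floor
#'
#' Retains variants with FFPE VAF at or above `min_vaf` (inclusive floor;
#' default 5%). Used for landscape summaries; panel ranking uses the raw
#' variant set.
#'
#' @param variants A somatic-variant data frame.
#' @param min_vaf Minimum FFPE VAF retained, default `0.05`.
#' @return The subset of rows with `ffpe_vaf >= min_vaf`, order preserved.
#' @export
filter_spectrum <- function(variants, min_vaf = 0.05) {
  stopifnot(is.data.frame(variants), min_vaf >= 0, min_vaf <= 1)
  variants[variants$ffpe_vaf >= min_vaf, , drop = FALSE]
}

#' Write a somatic-variant table in the package's TSV dialect
#' @param variants A somatic-variant data frame.
#' @param path Output path.
#' @export
write_variants <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
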