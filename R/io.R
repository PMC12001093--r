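#' Read a SNP weight file
#'
#' Tab-separated scoring layout with required columns `rsid`,
#' `effect_allele`, `other_allele`, `weight` and optional `chrom`, `pos`,
#' `pathway`, `se`. Malformed alleles or non-numeric weights are parse errors
#' naming the offending line; duplicated rsids are rejected by name.
#'
#' @param path Path to a TSV file.
#' @return A SNP weight tibble.
#' @export
read_weights <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  assert_cols(raw, c("rsid", "effect_allele", "other_allele", "weight"),
              "weights file")
  dup <- raw$rsid[duplicated(raw$rsid)]
  if (length(dup) > 0) {
    abort(sprintf("duplicated rsid(s) in weights file: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  bad_allele <- which(!(raw$effect_allele %in% c("A", "C", "G", "T")) |
                        !(raw$other_allele %in% c("A", "C", "G", "T")))
  if (length(bad_allele) > 0) {
    abort(sprintf("malformed allele at line %d of %s",
                  bad_allele[1] + 1, path))
  }
  w <- suppressWarnings(as.numeric(raw$weight))
  if (anyNA(w)) {
    abort(sprintf("non-numeric weight at line %d of %s",
                  which(is.na(w))[1] + 1, path))
  }
  out <- raw
  out$weight <- w
  for (col in c("chrom", "pos", "se")) {
    if (col %in% names(out)) out[[col]] <- suppressWarnings(as.numeric(out[[col]]))
  }
  out
}

#' Write a SNP weight file
#' @param weights Weight tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  readr::write_tsv(weights, path, progress = FALSE)
  invisible(path)
}

#' Read a dosage matrix
#'
#' TSV layout: an `id` column followed by one column per SNP, dosages in
#' `[0, 2]` with `NA` for missing. VCF import reads the `DS` (dosage) format
#' field; the counted allele is ALT, and the REF/ALT pairs are attached as
#' attribute `alleles` (`rsid`, `allele1`, `allele2`).
#'
#' @param path Input path.
#' @param format `"tsv"` or `"vcf"`.
#' @return Individuals x SNPs numeric matrix.
#' @export
read_dosages <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "vcf") {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      abort("VCF import requires the 'vcfR' package.")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    if (nrow(v@gt) == 0) abort("empty VCF input.")
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    rownames(ds) <- vcfR::getID(v)
    mat <- t(ds)
    bad <- which(!is.na(mat) & (mat < 0 | mat > 2), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      abort(sprintf("dosage out of [0,2] at individual %s, SNP %s",
                    rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]]))
    }
    attr(mat, "alleles") <- tibble(rsid = vcfR::getID(v),
                                   allele1 = vcfR::getALT(v),
                                   allele2 = vcfR::getREF(v))
    return(mat)
  }
  raw <- readr::read_tsv(path, col_types = readr::cols("id" = "c",
                                                       .default = "d"),
                         progress = FALSE)
  if (nrow(raw) == 0 || ncol(raw) < 2) abort("empty dosage input.")
  mat <- as.matrix(raw[-1])
  rownames(mat) <- raw$id
  bad <- which(!is.na(mat) & (mat < 0 | mat > 2), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("dosage out of [0,2] at individual %s, SNP %s",
                  rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]]))
  }
  mat
}

#' Write a dosage matrix as TSV
#' @param dosages Individuals x SNPs matrix (`NA` for missing).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dosages <- function(dosages, path) {
  df <- as_tibble(dosages)
  df <- dplyr::bind_cols(tibble(id = rownames(dosages)), df)
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read / write phenotype and follow-up tables
#'
#' Plain CSV round-trips for the participant and follow-up tables.
#' @param path File path.
#' @return A tibble.
#' @export
read_phenotypes <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (v in intersect(c("sex", "district", "education", "smoking", "alcohol"),
                      names(out))) {
    out[[v]] <- factor(out[[v]])
  }
  out
}

#' @rdname read_phenotypes
#' @param data Tibble to write.
#' @export
write_phenotypes <- function(data, path) {
  readr::write_csv(data, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' @rdname read_phenotypes
#' @export
read_followup <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(secondary_causes = "c",
                                          .default = readr::col_guess()))
}

#' @rdname read_phenotypes
#' @export
write_followup <- function(data, path) {
  readr::write_csv(data, path, na = "", progress = FALSE)
  invisible(path)
}

#' Write / read generator truths
#'
#' True SNP effects, true cause-specific log rate ratios and the seed, as
#' JSON, for parameter-recovery tests.
#'
#' @param truth Truth list from [simulate_cohort()].
#' @param path JSON path.
#' @return `path` (write) or the truth list (read).
#' @export
write_truth <- function(truth, path) {
  truth$beta_true <- as.list(truth$beta_true)
  truth$cause_log_rr <- as.list(truth$cause_log_rr)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$beta_true <- unlist(x$beta_true)
  x$cause_log_rr <- unlist(x$cause_log_rr)
  x
}
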