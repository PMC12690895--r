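#' Read a samples-by-features matrix from TSV/CSV
#'
#' Expects the first column to hold sample identifiers; remaining columns are
#' numeric features (probes, SNP dosages, exposures or covariates).
#'
#' @param path Path to a TSV or CSV file (delimiter auto-detected).
#' @return Numeric matrix with sample ids as rownames and feature ids as
#'   colnames.
#' @export
read_sample_matrix <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  ids <- as.character(dt[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in ", path)
  rownames(m) <- ids
  m
}

#' Read a probe or SNP manifest
#'
#' A BED-like TSV with columns id, chrom, pos (1-based). Extra columns are
#' ignored.
#'
#' @param path Path to the manifest file.
#' @param id_col Name for the identifier column in the returned data frame
#'   (`"probe_id"` or `"snp_id"`).
#' @return data.frame with columns `<id_col>`, `chrom`, `pos`, sorted by
#'   (chrom, pos).
#' @export
read_manifest <- function(path, id_col = "probe_id") {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(dt) < 3L) stop("manifest needs at least 3 columns (id, chrom, pos)")
  out <- data.frame(
    id = as.character(dt[[1L]]),
    chrom = as.character(dt[[2L]]),
    pos = as.integer(dt[[3L]]),
    stringsAsFactors = FALSE
  )
  names(out)[1L] <- id_col
  validate_manifest(out, id_col)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

validate_manifest <- function(manifest, id_col) {
  ids <- manifest[[id_col]]
  if (anyDuplicated(ids)) {
    stop("duplicate ids in manifest: ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5L), collapse = ", "))
  }
  if (any(is.na(manifest$pos)) || any(manifest$pos < 1L)) {
    stop("manifest positions must be integers >= 1 (1-based coordinates)")
  }
  invisible(manifest)
}

# Autosome filter used when aligning; chrom labels may or may not carry the
# "chr" prefix.
is_autosome <- function(chrom) {
  core <- sub("^chr", "", chrom)
  core %in% as.character(1:22)
}

#' Assemble an aligned gene-environment methylation dataset
#'
#' Restricts the methylation, genotype, exposome and covariate matrices to
#' their common samples, in a single canonical (sorted) order, and validates
#' the result: no missing values, genotype dosages in \[0, 2\], no constant
#' exposure columns, full-rank covariate design. Probes and SNPs absent from
#' their manifests are dropped with a message, as are non-autosomal features
#' when `autosomes_only = TRUE`.
#'
#' @param methylation Samples x probes numeric matrix of M values.
#' @param genotype Samples x SNPs numeric matrix of additive dosages in
#'   \[0, 2\].
#' @param exposome Samples x exposures numeric matrix (binary exposures coded
#'   0/1).
#' @param covariates Samples x covariates numeric matrix of concomitant
#'   variables (e.g. sex, gestational age, cell-type proportions, ancestry
#'   components), included unpenalized in every model downstream.
#' @param probe_manifest data.frame (`probe_id`, `chrom`, `pos`).
#' @param snp_manifest data.frame (`snp_id`, `chrom`, `pos`).
#' @param autosomes_only Drop probes/SNPs on non-autosomal chromosomes
#'   (default TRUE).
#' @return An object of class `aligned_dataset`: a list with elements
#'   `methylation`, `genotype`, `exposome`, `covariates`, `probe_manifest`,
#'   `snp_manifest`, `sample_ids`, `n_samples`.
#' @export
align_dataset <- function(methylation, genotype, exposome, covariates,
                          probe_manifest, snp_manifest,
                          autosomes_only = TRUE) {
  if (inherits(methylation, "aligned_dataset")) {
    d <- methylation
    return(align_dataset(d$methylation, d$genotype, d$exposome, d$covariates,
                         d$probe_manifest, d$snp_manifest,
                         autosomes_only = autosomes_only))
  }
  mats <- list(methylation = methylation, genotype = genotype,
               exposome = exposome, covariates = covariates)
  for (nm in names(mats)) {
    if (is.null(rownames(mats[[nm]]))) {
      stop("'", nm, "' must carry sample ids as rownames")
    }
    if (anyDuplicated(rownames(mats[[nm]]))) {
      stop("duplicate sample ids in '", nm, "'")
    }
  }
  common <- Reduce(intersect, lapply(mats, rownames))
  if (length(common) == 0L) stop("no samples shared across all input tables")
  common <- sort(common)
  dropped <- lapply(mats, function(m) setdiff(rownames(m), common))
  n_drop <- sum(lengths(dropped))
  if (n_drop > 0L) {
    message("align_dataset: dropped ", n_drop,
            " sample entries absent from the common set (n = ",
            length(common), " retained)")
  }
  mats <- lapply(mats, function(m) m[common, , drop = FALSE])

  validate_manifest(probe_manifest, "probe_id")
  validate_manifest(snp_manifest, "snp_id")
  if (autosomes_only) {
    probe_manifest <- probe_manifest[is_autosome(probe_manifest$chrom), ,
                                     drop = FALSE]
    snp_manifest <- snp_manifest[is_autosome(snp_manifest$chrom), ,
                                 drop = FALSE]
  }
  keep_p <- intersect(colnames(mats$methylation), probe_manifest$probe_id)
  keep_s <- intersect(colnames(mats$genotype), snp_manifest$snp_id)
  if (length(keep_p) == 0L) stop("no probes shared with the probe manifest")
  n_pdrop <- ncol(mats$methylation) - length(keep_p)
  if (n_pdrop > 0L) {
    message("align_dataset: dropped ", n_pdrop,
            " probes without (autosomal) manifest coordinates")
  }
  n_sdrop <- ncol(mats$genotype) - length(keep_s)
  if (n_sdrop > 0L) {
    message("align_dataset: dropped ", n_sdrop,
            " SNPs without (autosomal) manifest coordinates")
  }
  mats$methylation <- mats$methylation[, keep_p, drop = FALSE]
  mats$genotype <- mats$genotype[, keep_s, drop = FALSE]
  probe_manifest <- probe_manifest[probe_manifest$probe_id %in% keep_p, ,
                                   drop = FALSE]
  snp_manifest <- snp_manifest[snp_manifest$snp_id %in% keep_s, ,
                               drop = FALSE]
  probe_manifest <- probe_manifest[order(probe_manifest$chrom,
                                         probe_manifest$pos), , drop = FALSE]
  rownames(probe_manifest) <- NULL
  snp_manifest <- snp_manifest[order(snp_manifest$chrom, snp_manifest$pos), ,
                               drop = FALSE]
  rownames(snp_manifest) <- NULL

  # Complete cases are required: imputation is an upstream responsibility.
  for (nm in names(mats)) {
    bad <- which(!is.finite(mats[[nm]]), arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      stop("missing/non-finite value in '", nm, "' at sample ",
           rownames(mats[[nm]])[bad[1L, 1L]], ", column ",
           colnames(mats[[nm]])[bad[1L, 2L]])
    }
  }
  out_of_range <- which(mats$genotype < 0 | mats$genotype > 2,
                        arr.ind = TRUE)
  if (nrow(out_of_range) > 0L) {
    stop("genotype dosage outside [0, 2] at sample ",
         rownames(mats$genotype)[out_of_range[1L, 1L]], ", SNP ",
         colnames(mats$genotype)[out_of_range[1L, 2L]])
  }
  const_e <- vapply(seq_len(ncol(mats$exposome)), function(j) {
    length(unique(mats$exposome[, j])) < 2L
  }, logical(1L))
  if (any(const_e)) {
    stop("constant exposure column(s): ",
         paste(colnames(mats$exposome)[const_e], collapse = ", "))
  }
  design <- cbind(1, mats$covariates)
  if (qr(design)$rank < ncol(design)) {
    stop("covariate design (with intercept) is rank-deficient")
  }

  structure(list(
    methylation = mats$methylation,
    genotype = mats$genotype,
    exposome = mats$exposome,
    covariates = mats$covariates,
    probe_manifest = probe_manifest,
    snp_manifest = snp_manifest,
    sample_ids = common,
    n_samples = length(common)
  ), class = "aligned_dataset")
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat("aligned_dataset:", x$n_samples, "samples\n")
  cat("  probes:    ", ncol(x$methylation), "\n")
  cat("  SNPs:      ", ncol(x$genotype), "\n")
  cat("  exposures: ", ncol(x$exposome), "\n")
  cat("  covariates:", ncol(x$covariates), "\n")
  invisible(x)
}

#' Load and align a dataset from files
#'
#' Reads the five input tables from disk and calls [align_dataset()].
#'
#' @param methylation,genotype,exposome,covariates Paths to samples-first
#'   TSV/CSV matrices (see [read_sample_matrix()]).
#' @param probe_manifest,snp_manifest Paths to BED-like manifests (see
#'   [read_manifest()]).
#' @param autosomes_only Passed to [align_dataset()].
#' @return An `aligned_dataset`.
#' @export
load_dataset <- function(methylation, genotype, exposome, covariates,
                         probe_manifest, snp_manifest,
                         autosomes_only = TRUE) {
  align_dataset(
    methylation = read_sample_matrix(methylation),
    genotype = read_sample_matrix(genotype),
    exposome = read_sample_matrix(exposome),
    covariates = read_sample_matrix(covariates),
    probe_manifest = read_manifest(probe_manifest, "probe_id"),
    snp_manifest = read_manifest(snp_manifest, "snp_id"),
    autosomes_only = autosomes_only
  )
}
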