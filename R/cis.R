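#' Map VMLs to their cis SNPs
#'
#' A SNP is cis to a VML when it lies on the same chromosome within `window`
#' bp of the locus span, i.e. `start - window <= pos <= end + window`
#' (boundaries inclusive). A VML may have no cis SNPs; such loci can only
#' ever be explained by an exposure-only or baseline model.
#'
#' @param vml VML table from [find_vml()].
#' @param snp_manifest data.frame (`snp_id`, `chrom`, `pos`).
#' @param window Flanking window in bp on each side (default 1e6, the
#'   conventional cis-mQTL window).
#' @return Named list mapping `vml_id` to a position-ordered character vector
#'   of SNP ids (possibly empty).
#' @export
find_cis_snps <- function(vml, snp_manifest, window = 1e6) {
  if (nrow(vml) == 0L) return(stats::setNames(list(), character(0)))
  vr <- GenomicRanges::GRanges(
    seqnames = vml$chrom,
    ranges = IRanges::IRanges(start = pmax(1L, vml$start - as.integer(window)),
                              end = vml$end + as.integer(window))
  )
  sm <- snp_manifest[order(snp_manifest$chrom, snp_manifest$pos), ,
                     drop = FALSE]
  sr <- GenomicRanges::GRanges(
    seqnames = sm$chrom,
    ranges = IRanges::IRanges(start = sm$pos, width = 1L)
  )
  hits <- suppressWarnings(GenomicRanges::findOverlaps(vr, sr))
  by_vml <- split(S4Vectors::subjectHits(hits),
                  factor(S4Vectors::queryHits(hits),
                         levels = seq_len(nrow(vml))))
  out <- lapply(by_vml, function(idx) sm$snp_id[sort(idx)])
  names(out) <- vml$vml_id
  out
}
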