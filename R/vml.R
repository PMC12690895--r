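#' Group highly variable probes into variably methylated loci
#'
#' HVPs are first chained by proximity: maximal runs of consecutive HVPs on a
#' chromosome with inter-probe gaps below `max_gap`. Within a chain, adjacent
#' probe pairs must also share a methylation profile (Pearson r of their
#' unadjusted M values above `min_r`); chains are split at uncorrelated
#' pairs. Surviving runs of two or more probes become VMRs (variably
#' methylated regions). HVPs left without a partner become sparse VMPs
#' (sVMPs) only when the array design itself is sparse there, i.e. no
#' manifest probe at all lies within `max_gap`; HVPs with a near but
#' unlinked neighbour are discarded.
#'
#' @param hvp_ids Character vector of HVP probe ids.
#' @param probe_manifest data.frame (`probe_id`, `chrom`, `pos`) covering the
#'   full array, not only HVPs.
#' @param methylation Samples x probes matrix of unadjusted M values.
#' @param max_gap Maximum probe spacing in bp; gaps must be strictly smaller
#'   to chain (default 1000).
#' @param min_r Minimum Pearson correlation between adjacent chained probes
#'   (strictly greater to link; default 0.15). Set to -1 to disable the
#'   correlation rule.
#' @param svmp_mode `"array"` (default) tests sVMP eligibility against the
#'   full manifest; `"hvp"` tests only against other HVPs.
#' @param cor_mode `"adjacent"` (default) splits chains at adjacent pairs
#'   with r below the threshold; `"allpairs"` keeps a whole chain iff the
#'   mean of all pairwise correlations exceeds the threshold.
#' @return data.frame with columns `vml_id`, `kind` ("VMR"/"sVMP"), `chrom`,
#'   `start`, `end`, `n_probes` and list-column `probes` (position-ordered
#'   member probe ids). Attribute `discarded` holds HVP ids assigned to no
#'   locus.
#' @export
find_vml <- function(hvp_ids, probe_manifest, methylation,
                     max_gap = 1000L, min_r = 0.15,
                     svmp_mode = c("array", "hvp"),
                     cor_mode = c("adjacent", "allpairs")) {
  svmp_mode <- match.arg(svmp_mode)
  cor_mode <- match.arg(cor_mode)
  missing_ids <- setdiff(hvp_ids, probe_manifest$probe_id)
  if (length(missing_ids) > 0L) {
    stop("HVP probe(s) missing from manifest: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "))
  }
  missing_m <- setdiff(hvp_ids, colnames(methylation))
  if (length(missing_m) > 0L) {
    stop("HVP probe(s) missing from methylation matrix: ",
         paste(utils::head(missing_m, 5L), collapse = ", "))
  }
  hm <- probe_manifest[probe_manifest$probe_id %in% hvp_ids, , drop = FALSE]
  hm <- hm[order(hm$chrom, hm$pos), , drop = FALSE]

  groups <- list()
  singletons <- character(0)
  for (chrom in unique(hm$chrom)) {
    cm <- hm[hm$chrom == chrom, , drop = FALSE]
    # proximity chains: break where the gap reaches max_gap
    brk <- if (nrow(cm) > 1L) diff(cm$pos) >= max_gap else logical(0)
    chain_id <- cumsum(c(TRUE, brk))
    for (ch in split(seq_len(nrow(cm)), chain_id)) {
      ids <- cm$probe_id[ch]
      if (length(ids) == 1L) {
        singletons <- c(singletons, ids)
        next
      }
      runs <- split_chain_by_correlation(ids, methylation, min_r, cor_mode)
      for (run in runs) {
        if (length(run) >= 2L) {
          groups[[length(groups) + 1L]] <- list(chrom = chrom, probes = run)
        } else {
          singletons <- c(singletons, run)
        }
      }
    }
  }

  # sVMP eligibility: only array sparsity rescues a singleton
  neighbour_pool <- if (svmp_mode == "array") probe_manifest else hm
  svmps <- character(0)
  discarded <- character(0)
  for (id in singletons) {
    row <- hm[hm$probe_id == id, ]
    pool <- neighbour_pool[neighbour_pool$chrom == row$chrom &
                             neighbour_pool$probe_id != id, , drop = FALSE]
    near <- nrow(pool) > 0L && min(abs(pool$pos - row$pos)) < max_gap
    if (near) discarded <- c(discarded, id) else svmps <- c(svmps, id)
  }

  pos_of <- stats::setNames(probe_manifest$pos, probe_manifest$probe_id)
  chrom_of <- stats::setNames(probe_manifest$chrom, probe_manifest$probe_id)
  rows <- lapply(groups, function(g) {
    p <- g$probes
    list(kind = "VMR", chrom = g$chrom,
         start = min(pos_of[p]), end = max(pos_of[p]), probes = p)
  })
  rows <- c(rows, lapply(svmps, function(id) {
    list(kind = "sVMP", chrom = unname(chrom_of[id]),
         start = unname(pos_of[id]), end = unname(pos_of[id]),
         probes = id)
  }))
  if (length(discarded) > 0L) {
    message("find_vml: discarded ", length(discarded),
            " HVP(s) with near but unlinked neighbours")
  }
  if (length(rows) == 0L) {
    out <- data.frame(vml_id = character(0), kind = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), n_probes = integer(0),
                      stringsAsFactors = FALSE)
    out$probes <- list()
    attr(out, "discarded") <- discarded
    return(out)
  }
  out <- data.frame(
    vml_id = vapply(rows, function(r) {
      sprintf("%s:%d-%d(%s)", r$chrom, r$start, r$end, r$kind)
    }, character(1L)),
    kind = vapply(rows, `[[`, character(1L), "kind"),
    chrom = vapply(rows, `[[`, character(1L), "chrom"),
    start = vapply(rows, function(r) as.integer(r$start), integer(1L)),
    end = vapply(rows, function(r) as.integer(r$end), integer(1L)),
    n_probes = vapply(rows, function(r) length(r$probes), integer(1L)),
    stringsAsFactors = FALSE
  )
  out$probes <- lapply(rows, `[[`, "probes")
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "discarded") <- discarded
  out
}

split_chain_by_correlation <- function(ids, methylation, min_r, cor_mode) {
  if (min_r <= -1) return(list(ids))
  if (cor_mode == "allpairs") {
    cm <- stats::cor(methylation[, ids, drop = FALSE])
    mean_r <- mean(cm[upper.tri(cm)])
    if (mean_r > min_r) return(list(ids)) else return(as.list(ids))
  }
  r_adj <- vapply(seq_len(length(ids) - 1L), function(i) {
    stats::cor(methylation[, ids[i]], methylation[, ids[i + 1L]])
  }, numeric(1L))
  brk <- !(r_adj > min_r)
  split(ids, cumsum(c(TRUE, brk)))
}

#' Summarize a VMR as the per-sample median M value
#'
#' @param methylation Samples x probes matrix of unadjusted M values.
#' @param probe_ids Member probe ids (>= 2 for a region).
#' @return Named numeric vector, one median M value per sample.
#' @export
summarize_vmr <- function(methylation, probe_ids) {
  missing_m <- setdiff(probe_ids, colnames(methylation))
  if (length(missing_m) > 0L) {
    stop("probe(s) missing from methylation matrix: ",
         paste(missing_m, collapse = ", "))
  }
  apply(methylation[, probe_ids, drop = FALSE], 1L, stats::median)
}

#' Summarized methylation matrix for a VML set
#'
#' VMRs are summarized by the per-sample median of their member probes
#' ([summarize_vmr()]); a sVMP's summary is its own M-value column.
#'
#' @param methylation Samples x probes matrix of unadjusted M values.
#' @param vml VML table from [find_vml()].
#' @return Samples x VML numeric matrix, columns named by `vml_id`.
#' @export
summarize_vml <- function(methylation, vml) {
  out <- vapply(seq_len(nrow(vml)), function(i) {
    p <- vml$probes[[i]]
    if (length(p) == 1L) methylation[, p] else summarize_vmr(methylation, p)
  }, numeric(nrow(methylation)))
  out <- matrix(out, nrow = nrow(methylation),
                dimnames = list(rownames(methylation), vml$vml_id))
  out
}

#' Export a VML table to BED (0-based half-open) coordinates
#'
#' @param vml VML table from [find_vml()].
#' @return data.frame with columns `chrom`, `start` (0-based), `end`, `name`.
#' @export
vml_to_bed <- function(vml) {
  data.frame(chrom = vml$chrom, start = vml$start - 1L, end = vml$end,
             name = vml$vml_id, stringsAsFactors = FALSE)
}
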