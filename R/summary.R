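# Aggregation of per-protein feature calls into per-group conservation
# tables and AH/CC/TM set partitions.

feature_flags <- function(ids, calls, annotations) {
  best_ids <- unique(calls$protein_id[calls$is_best])
  unknown <- setdiff(best_ids, ids)
  if (length(unknown) > 0) {
    stop("calls reference protein(s) absent from the sequence set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  data.frame(
    protein_id = ids,
    ah = ids %in% best_ids,
    cc = ids %in% annotations$protein_id[annotations$feature == "CC"],
    tm = ids %in% annotations$protein_id[annotations$feature == "TM"],
    stringsAsFactors = FALSE
  )
}

#' Per-group feature-conservation summary
#'
#' For each phylogenetic group, counts and percentages of proteins with at
#' least one best amphipathic-helix call, at least one coiled-coil
#' annotation, and at least one transmembrane annotation. Proteins without
#' a group label are binned as `"unassigned"`; empty groups are omitted.
#' Percentages are reported to one decimal, with companion booleans
#' flagging values above 30 (a conventional notability cut used when such
#' tables are typeset).
#'
#' @param records protein data.frame (defines the protein universe).
#' @param calls scored window data.frame with an `is_best` column.
#' @param annotations CC/TM annotation data.frame.
#' @param group_map named character vector protein_id -> group (optional;
#'   the records' own `group` column is used as fallback).
#' @return data.frame with columns `group`, `n`, `n_ah`, `n_cc`, `n_tm`,
#'   `pct_ah`, `pct_cc`, `pct_tm`, `bold_ah`, `bold_cc`, `bold_tm`.
#' @export
summarize_feature_conservation <- function(records, calls, annotations,
                                           group_map = NULL) {
  flags <- feature_flags(records$id, calls, annotations)
  groups <- if (!is.null(group_map)) {
    unname(group_map[records$id])
  } else {
    records$group
  }
  groups[is.na(groups) | !nzchar(groups)] <- "unassigned"
  out <- lapply(split(seq_along(groups), groups), function(idx) {
    n <- length(idx)
    n_ah <- sum(flags$ah[idx]); n_cc <- sum(flags$cc[idx]); n_tm <- sum(flags$tm[idx])
    data.frame(group = groups[idx[1]], n = n,
               n_ah = n_ah, n_cc = n_cc, n_tm = n_tm,
               pct_ah = round(100 * n_ah / n, 1),
               pct_cc = round(100 * n_cc / n, 1),
               pct_tm = round(100 * n_tm / n, 1),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$bold_ah <- res$pct_ah > 30
  res$bold_cc <- res$pct_cc > 30
  res$bold_tm <- res$pct_tm > 30
  res
}

#' AH / CC / TM set partition
#'
#' Assigns each protein to exactly one of the eight regions of the
#' three-set Venn partition defined by its (AH, CC, TM) positivity triple,
#' so region counts always sum to the number of proteins.
#'
#' @inheritParams summarize_feature_conservation
#' @return named integer vector over the regions `AH`, `CC`, `TM`,
#'   `AH+CC`, `AH+TM`, `CC+TM`, `AH+CC+TM`, `none`.
#' @export
venn_partition <- function(records, calls, annotations) {
  flags <- feature_flags(records$id, calls, annotations)
  region <- function(ah, cc, tm) {
    parts <- c("AH", "CC", "TM")[c(ah, cc, tm)]
    if (length(parts) == 0) "none" else paste(parts, collapse = "+")
  }
  labels <- mapply(region, flags$ah, flags$cc, flags$tm)
  all_regions <- c("AH", "CC", "TM", "AH+CC", "AH+TM", "CC+TM",
                   "AH+CC+TM", "none")
  counts <- table(factor(labels, levels = all_regions))
  stats::setNames(as.integer(counts), all_regions)
}
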