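# End-to-end amphipathic-helix scan: windows -> scores -> domain projection
# -> overlap filter -> best-hit reduction.

#' Find candidate membrane-binding amphipathic helices
#'
#' Runs the full scan for a set of proteins with paired secondary-structure
#' tracks: extracts fully/partially helical 18-residue windows, scores each
#' for amphipathicity, projects the reference GTPase domain onto each query
#' by global alignment, excludes windows overlapping the projected domain,
#' and marks the single largest-D amphipathic hit per protein.
#'
#' @param records protein data.frame (see [read_protein_fasta()]).
#' @param tracks secondary-structure tracks (see [read_ss_track()]).
#' @param anchor a `reference_anchor`; set `gtpase_filter = FALSE` to skip
#'   domain projection and overlap exclusion entirely.
#' @param scale hydrophobicity scale.
#' @param gtpase_filter apply the GTPase-overlap exclusion (default TRUE).
#' @param allow_missing skip proteins without a track instead of erroring.
#' @param verbose emit per-stage counts to stderr.
#' @return object of class `ah_scan`: list with `calls` (per-window table
#'   with score, exclusion and best-hit columns), `domains` (per-protein
#'   projected spans; NULL when `gtpase_filter = FALSE`) and `pairing`
#'   (the validation report).
#' @export
find_amphipathic_helices <- function(records, tracks,
                                     anchor = default_anchor(),
                                     scale = hydrophobicity_scale(),
                                     gtpase_filter = TRUE,
                                     allow_missing = FALSE,
                                     verbose = FALSE) {
  pairing <- validate_pairing(records, tracks)
  problems <- pairing[pairing$issue %in% c("missing_track", "length_mismatch"), ]
  if (nrow(problems) > 0 && !allow_missing) {
    stop("unpaired or mismatched input (set allow_missing=TRUE to skip): ",
         paste(unique(problems$protein_id), collapse = ", "), call. = FALSE)
  }
  usable <- setdiff(records$id, problems$protein_id)

  calls_list <- list()
  domains_list <- list()
  for (id in usable) {
    rec <- records[records$id == id, , drop = FALSE]
    trk <- tracks[tracks$protein_id == id, , drop = FALSE]
    calls <- scan_windows(rec, trk, scale)
    if (gtpase_filter) {
      aln <- global_align(rec$sequence, anchor$reference$sequence,
                          gap_open = anchor$gap_open,
                          gap_extend = anchor$gap_extend)
      span <- project_reference_span(aln, anchor, protein_id = id)
      domains_list[[id]] <- span
      calls <- filter_gtpase_overlap(calls, span)
    } else {
      calls$excluded_gtpase_overlap <- rep(FALSE, nrow(calls))
    }
    calls <- select_best_hit(calls)
    calls_list[[id]] <- calls
  }
  calls <- if (length(calls_list) > 0) {
    do.call(rbind, c(calls_list, list(make.row.names = FALSE)))
  } else {
    cbind(scan_windows(protein_records("empty", strrep("A", 18)),
                       data.frame(protein_id = "empty",
                                  states = strrep("C", 18)))[0, ],
          excluded_gtpase_overlap = logical(0), is_best = logical(0))
  }
  domains <- if (length(domains_list) > 0) {
    do.call(rbind, c(domains_list, list(make.row.names = FALSE)))
  } else NULL
  if (verbose) {
    message(sprintf("proteins scanned: %d | windows: %d | excluded (GTPase overlap): %d | best hits: %d",
                    length(usable), nrow(calls),
                    sum(calls$excluded_gtpase_overlap), sum(calls$is_best)))
  }
  structure(list(calls = calls, domains = domains, pairing = pairing,
                 n_scanned = length(usable)),
            class = "ah_scan")
}

#' @export
print.ah_scan <- function(x, ...) {
  cat("Amphipathic-helix scan\n")
  cat(sprintf("  proteins scanned : %d\n", x$n_scanned))
  cat(sprintf("  candidate windows: %d (%d fully helical, %d partially)\n",
              nrow(x$calls), sum(x$calls$category == "full"),
              sum(x$calls$category == "partial")))
  cat(sprintf("  amphipathic      : %d\n", sum(x$calls$is_amphipathic)))
  cat(sprintf("  GTPase-overlap excluded: %d\n",
              sum(x$calls$excluded_gtpase_overlap)))
  cat(sprintf("  best hits        : %d protein(s)\n", sum(x$calls$is_best)))
  if (nrow(x$pairing) > 0) {
    cat(sprintf("  pairing issues   : %d (see $pairing)\n", nrow(x$pairing)))
  }
  invisible(x)
}
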