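# Extraction of 18-residue candidate helical windows from a per-residue
# secondary-structure track.

WINDOW_LEN <- 18L

#' Extract candidate helical 18-residue windows
#'
#' Slides an 18-residue window over the protein and emits every window that
#' is fully helical (all 18 states `H`) or partially helical (at least the
#' six residues at both ends of the window are `H`; the interior six are
#' unconstrained). The partial rule admits helices broken by a short
#' non-helical stretch — e.g. a `6xH-6xC-6xH` window qualifies while a
#' `5xH-6xC-7xH` window does not. `E` and `C` both count as non-helical.
#' Overlapping windows are all retained; reduction to a single best hit per
#' protein happens downstream in [select_best_hit()].
#'
#' @param record one-row protein data.frame (columns `id`, `sequence`).
#' @param track one-row track data.frame (columns `protein_id`, `states`),
#'   same length as the sequence.
#' @return data.frame with columns `protein_id`, `start`, `end`,
#'   `category` (`"full"` or `"partial"`), `aa`, `ss`; ascending `start`.
#'   Sequences shorter than 18 yield zero rows.
#' @export
extract_helix_windows <- function(record, track) {
  seq <- record$sequence[1]
  states <- track$states[1]
  if (nchar(states) != nchar(seq)) {
    stop(sprintf("track length %d != sequence length %d for '%s'",
                 nchar(states), nchar(seq), record$id[1]), call. = FALSE)
  }
  empty <- data.frame(protein_id = character(), start = integer(),
                      end = integer(), category = character(),
                      aa = character(), ss = character(),
                      stringsAsFactors = FALSE)
  L <- nchar(seq)
  if (L < WINDOW_LEN) return(empty)
  is_h <- seq_chars(states) == "H"
  starts <- seq_len(L - WINDOW_LEN + 1L)
  keep <- logical(length(starts))
  full <- logical(length(starts))
  for (i in starts) {
    w <- is_h[i:(i + WINDOW_LEN - 1L)]
    full_i <- all(w)
    partial_i <- all(w[1:6]) && all(w[13:18])
    keep[i] <- partial_i     # full windows satisfy the end-helical rule too
    full[i] <- full_i
  }
  if (!any(keep)) return(empty)
  st <- starts[keep]
  data.frame(
    protein_id = record$id[1],
    start = st,
    end = st + WINDOW_LEN - 1L,
    category = ifelse(full[keep], "full", "partial"),
    aa = substring(seq, st, st + WINDOW_LEN - 1L),
    ss = substring(states, st, st + WINDOW_LEN - 1L),
    stringsAsFactors = FALSE
  )
}

#' Report pairing problems between records and secondary-structure tracks
#'
#' @param records protein data.frame.
#' @param tracks track data.frame.
#' @return data.frame with columns `protein_id`, `issue` (one of
#'   `missing_track`, `missing_record`, `length_mismatch`), `detail`;
#'   zero rows when everything is paired and lengths agree.
#' @export
validate_pairing <- function(records, tracks) {
  issues <- list()
  missing_track <- setdiff(records$id, tracks$protein_id)
  for (id in missing_track) {
    issues[[length(issues) + 1L]] <- c(id, "missing_track", "no track for record")
  }
  missing_record <- setdiff(tracks$protein_id, records$id)
  for (id in missing_record) {
    issues[[length(issues) + 1L]] <- c(id, "missing_record", "no record for track")
  }
  common <- intersect(records$id, tracks$protein_id)
  for (id in common) {
    ls <- nchar(records$sequence[records$id == id])
    lt <- nchar(tracks$states[tracks$protein_id == id])
    if (ls != lt) {
      issues[[length(issues) + 1L]] <-
        c(id, "length_mismatch", sprintf("sequence %d vs track %d", ls, lt))
    }
  }
  if (length(issues) == 0) {
    return(data.frame(protein_id = character(), issue = character(),
                      detail = character(), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, issues)
  data.frame(protein_id = m[, 1], issue = m[, 2], detail = m[, 3],
             stringsAsFactors = FALSE)
}
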