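# Sliding-window isoelectric-point profiling of N-terminal extensions and
# reference-anchored single-residue classification (arginine finger,
# switch-I threonine/serine).

#' Sliding-window isoelectric-point profile
#'
#' For every window of `window_size` residues lying fully inside `span`,
#' reports the arithmetic mean of the per-residue pI values, plotted
#' against the window's first residue position. The span is typically the
#' NTE (residues before the projected GTPase-domain start); partial windows
#' at the span edge are not emitted, so a span shorter than the window
#' yields an empty profile.
#'
#' @param record one-row protein data.frame.
#' @param span integer c(start, end), 1-based inclusive.
#' @param window_size window length in residues (default 10).
#' @param pi_table per-residue pI lookup, see [aa_pi_table()].
#' @return data.frame with columns `protein_id`, `position` (window start),
#'   `value` (mean pI, pH units).
#' @export
isoelectric_profile <- function(record, span, window_size = 10,
                                pi_table = aa_pi_table()) {
  stopifnot(window_size >= 1)
  empty <- data.frame(protein_id = character(), position = integer(),
                      value = numeric(), stringsAsFactors = FALSE)
  if (any(is.na(span))) return(empty)
  L <- nchar(record$sequence[1])
  if (span[1] < 1 || span[2] > L || span[1] > span[2]) {
    stop("span outside sequence", call. = FALSE)
  }
  span_len <- span[2] - span[1] + 1L
  if (span_len < window_size) return(empty)
  chars <- seq_chars(substr(record$sequence[1], span[1], span[2]))
  vals <- unname(pi_table[chars])
  if (anyNA(vals)) {
    stop("residue missing from pI table: ",
         chars[which(is.na(vals))[1]], call. = FALSE)
  }
  cs <- cumsum(c(0, vals))
  starts <- seq_len(span_len - window_size + 1L)
  means <- (cs[starts + window_size] - cs[starts]) / window_size
  data.frame(protein_id = record$id[1],
             position = span[1] + starts - 1L,
             value = means, stringsAsFactors = FALSE)
}

#' Call polybasic regions from a pI profile
#'
#' Reports maximal runs of at least `min_run` consecutive window positions
#' whose mean pI is at or above `threshold_pi`, expanded to residue spans
#' (first window start through last window start + window size - 1). The
#' defaults (pI 8.0, run 3) are pragmatic automation thresholds, not values
#' taken from any reference analysis, which judged such profiles visually.
#'
#' @param profile data.frame from [isoelectric_profile()]; positions must
#'   be consecutive (they are, for a single-span profile).
#' @param threshold_pi minimum mean pI (pH units).
#' @param min_run minimum number of consecutive qualifying windows.
#' @param window_size window length used to build the profile.
#' @return data.frame with columns `protein_id`, `start`, `end`,
#'   `mean_value`; zero rows when no run qualifies.
#' @export
pb_region_call <- function(profile, threshold_pi = 8.0, min_run = 3L,
                           window_size = 10) {
  empty <- data.frame(protein_id = character(), start = integer(),
                      end = integer(), mean_value = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(profile) == 0) return(empty)
  qual <- profile$value >= threshold_pi
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_run)
  if (length(keep) == 0) return(empty)
  out <- lapply(keep, function(i) {
    idx <- starts[i]:ends[i]
    data.frame(protein_id = profile$protein_id[1],
               start = profile$position[starts[i]],
               end = profile$position[ends[i]] + window_size - 1L,
               mean_value = mean(profile$value[idx]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify the query residue aligned to a reference-anchored site
#'
#' Reads the query residue aligned to the anchor's arginine-finger or
#' switch-I column. For `site = "r_finger"` the call is `present` for R,
#' `histidine_variant` for H, and `absent` otherwise (including a gap).
#' For `site = "switch1"` the call is `active` for T or S and `inactive`
#' otherwise, following the convention that either hydroxyl residue
#' supports catalysis.
#'
#' @param aln alignment from [global_align()] (query vs anchor reference).
#' @param anchor a `reference_anchor`.
#' @param site `"r_finger"` or `"switch1"`.
#' @param protein_id id to report.
#' @return one-row data.frame: `protein_id`, `site`, `query_position`
#'   (NA for a gap), `residue` (`"-"` for a gap), `call`.
#' @export
classify_residue_at <- function(aln, anchor, site = c("r_finger", "switch1"),
                                protein_id = "query") {
  site <- match.arg(site)
  col <- switch(site, r_finger = anchor$r_finger_col,
                switch1 = anchor$switch1_col)
  if (col < 1 || col > aln$ref_len) {
    stop("config error: site column outside reference length", call. = FALSE)
  }
  hit <- aln$mapping[aln$mapping$r_pos == col, , drop = FALSE]
  if (nrow(hit) == 0) {
    q_pos <- NA_integer_
    residue <- "-"
  } else {
    q_pos <- hit$q_pos[1]
    residue <- substr_query(aln, q_pos)
  }
  call <- if (site == "r_finger") {
    if (residue == "R") "present"
    else if (residue == "H") "histidine_variant"
    else "absent"
  } else {
    if (residue %in% c("T", "S")) "active" else "inactive"
  }
  data.frame(protein_id = protein_id, site = site,
             query_position = q_pos, residue = residue, call = call,
             stringsAsFactors = FALSE)
}

# recover the query residue at an ungapped query position from the aligned string
substr_query <- function(aln, q_pos) {
  q <- gsub("-", "", aln$aligned_query, fixed = TRUE)
  substr(q, q_pos, q_pos)
}
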