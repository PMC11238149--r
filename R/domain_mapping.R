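# Reference-anchored GTPase-domain delimitation: global pairwise alignment
# of each query against the reference record, projection of the reference
# GTPase span onto query coordinates, overlap filtering of AH candidates,
# and reduction to the single largest-D hit per protein.

#' Construct a reference anchor
#'
#' Bundles the reference record with the coordinates that anchor all
#' downstream classification: the GTPase-domain span, the S3-region
#' arginine-finger column and the switch-I catalytic threonine/serine
#' column (all 1-based positions on the reference), plus alignment
#' parameters and the coverage floor below which a projection is flagged
#' unreliable.
#'
#' @param reference one-row protein data.frame.
#' @param gtpase_start,gtpase_end GTPase-domain span on the reference.
#' @param r_finger_col,switch1_col anchored residue columns, inside the span.
#' @param coverage_floor minimum fraction of reference GTPase columns that
#'   must align to query residues for the projection to be trusted.
#' @param gap_open,gap_extend affine gap penalties for the global alignment.
#' @return object of class `reference_anchor`.
#' @export
reference_anchor <- function(reference, gtpase_start, gtpase_end,
                             r_finger_col, switch1_col,
                             coverage_floor = 0.5,
                             gap_open = 10, gap_extend = 1) {
  L <- nchar(reference$sequence[1])
  if (is.na(gtpase_start) || is.na(gtpase_end) ||
      gtpase_start < 1 || gtpase_end > L || gtpase_start > gtpase_end) {
    stop("config error: invalid GTPase span", call. = FALSE)
  }
  for (col in c(r_finger_col, switch1_col)) {
    if (is.na(col) || col < gtpase_start || col > gtpase_end) {
      stop("config error: anchored residue column outside the GTPase span",
           call. = FALSE)
    }
  }
  structure(
    list(reference = reference,
         gtpase_start = as.integer(gtpase_start),
         gtpase_end = as.integer(gtpase_end),
         r_finger_col = as.integer(r_finger_col),
         switch1_col = as.integer(switch1_col),
         coverage_floor = coverage_floor,
         gap_open = gap_open, gap_extend = gap_extend),
    class = "reference_anchor"
  )
}

#' @export
print.reference_anchor <- function(x, ...) {
  cat("Reference anchor:", x$reference$id[1], "\n")
  cat(sprintf("  GTPase domain: %d..%d (length %d of %d)\n",
              x$gtpase_start, x$gtpase_end,
              x$gtpase_end - x$gtpase_start + 1L,
              nchar(x$reference$sequence[1])))
  cat(sprintf("  R-finger column: %d   switch-I column: %d\n",
              x$r_finger_col, x$switch1_col))
  cat(sprintf("  coverage floor: %.2f   gaps: open %.1f extend %.1f\n",
              x$coverage_floor, x$gap_open, x$gap_extend))
  invisible(x)
}

.ahscan_cache <- new.env(parent = emptyenv())

#' Synthetic reference septin record
#'
#' A deterministically generated septin-like record used as the packaged
#' default anchor: a 60-residue NTE, a 300-residue GTPase core carrying a
#' P-loop-like G1 motif, a switch-I threonine at position 110 and an
#' S3-region arginine finger at position 160, and a 40-residue CTE. This is
#' a synthetic stand-in, not a natural sequence; analyses of real data
#' should supply their own reference via [read_anchor_config()].
#'
#' @return one-row protein data.frame (id `synthetic_ref_septin`, 400 aa).
#' @export
synthetic_reference_septin <- function() {
  if (!is.null(.ahscan_cache$reference)) return(.ahscan_cache$reference)
  seqs <- with_fixture_seed(777001L, {
    nte <- paste(sample(NTE_BACKGROUND_POOL, 60, replace = TRUE), collapse = "")
    core <- paste(sample(AA_STANDARD, 300, replace = TRUE), collapse = "")
    cte <- paste(sample(NTE_BACKGROUND_POOL, 40, replace = TRUE), collapse = "")
    list(nte = nte, core = core, cte = cte)
  })
  core <- seqs$core
  # distinctive residues at the domain edges keep the projected boundary
  # alignment-unambiguous against low-complexity extensions, the way real
  # GTPase domains start and end at conserved motifs
  substr(core, 1, 6) <- "WKHFCM"
  substr(core, 8, 15) <- "GQSGLGKS"   # G1 / P-loop-like motif
  substr(core, 50, 50) <- "T"         # switch-I catalytic threonine
  substr(core, 100, 100) <- "R"       # S3-region arginine finger
  substr(core, 230, 233) <- "TKLD"    # G4-like motif
  substr(core, 295, 300) <- "YWFMHC"
  rec <- protein_records(
    id = "synthetic_ref_septin",
    sequence = paste0(seqs$nte, core, seqs$cte),
    description = "synthetic reference septin (generated, not a natural sequence)"
  )
  .ahscan_cache$reference <- rec
  rec
}

#' Default reference anchor built on the synthetic reference record
#'
#' GTPase span 61..360, R-finger column 160, switch-I column 110,
#' coverage floor 0.5, BLOSUM62 with gap open 10 / extend 1.
#' @return a `reference_anchor`.
#' @export
default_anchor <- function() {
  reference_anchor(
    reference = synthetic_reference_septin(),
    gtpase_start = 61L, gtpase_end = 360L,
    r_finger_col = 160L, switch1_col = 110L
  )
}

blosum62 <- function() {
  if (is.null(.ahscan_cache$BLOSUM62)) {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    .ahscan_cache$BLOSUM62 <- env$BLOSUM62
  }
  .ahscan_cache$BLOSUM62
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch global alignment (Biostrings backend) under BLOSUM62
#' with affine gap penalties (a gap of length L costs
#' `gap_open + gap_extend * L`). Returns the score and the strictly
#' increasing query/reference column mapping over aligned (non-gap)
#' columns.
#'
#' @param query_seq,ref_seq nonempty amino-acid strings.
#' @param gap_open,gap_extend gap penalties (positive costs).
#' @return list with `score`, `mapping` (data.frame `q_pos`, `r_pos`),
#'   `aligned_query`, `aligned_ref`, `query_len`, `ref_len`.
#' @export
global_align <- function(query_seq, ref_seq, gap_open = 10, gap_extend = 1) {
  if (!nzchar(query_seq) || !nzchar(ref_seq)) {
    stop("empty sequence in alignment", call. = FALSE)
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query_seq), Biostrings::AAString(ref_seq),
    substitutionMatrix = blosum62(),
    gapOpening = gap_open, gapExtension = gap_extend, type = "global"
  )
  aq <- as.character(Biostrings::alignedPattern(pa))
  ar <- as.character(Biostrings::alignedSubject(pa))
  qg <- seq_chars(aq) != "-"
  rg <- seq_chars(ar) != "-"
  both <- qg & rg
  mapping <- data.frame(q_pos = cumsum(qg)[both], r_pos = cumsum(rg)[both])
  list(score = Biostrings::score(pa), mapping = mapping,
       aligned_query = aq, aligned_ref = ar,
       query_len = nchar(query_seq), ref_len = nchar(ref_seq))
}

#' Project the reference GTPase span onto a query protein
#'
#' The query GTPase start is the query residue aligned to the first
#' reference column at or after the anchor start that aligns to a query
#' residue; the end comes from the last such column at or before the
#' anchor end. Coverage is the fraction of reference GTPase columns
#' aligned to query residues; projections below the anchor's coverage
#' floor are flagged. When no reference GTPase column aligns to any query
#' residue the protein is treated as all-extension (`NA` span, flagged).
#'
#' @param aln alignment from [global_align()] (query vs anchor reference).
#' @param anchor a `reference_anchor`.
#' @param protein_id id to report.
#' @return one-row data.frame: `protein_id`, `gtpase_start`, `gtpase_end`,
#'   `nte_len`, `cte_len`, `coverage`, `flagged`.
#' @export
project_reference_span <- function(aln, anchor, protein_id = "query") {
  span_cols <- anchor$gtpase_start:anchor$gtpase_end
  m <- aln$mapping[aln$mapping$r_pos %in% span_cols, , drop = FALSE]
  L <- aln$query_len
  if (nrow(m) == 0) {
    return(data.frame(protein_id = protein_id,
                      gtpase_start = NA_integer_, gtpase_end = NA_integer_,
                      nte_len = NA_integer_, cte_len = NA_integer_,
                      coverage = 0, flagged = TRUE,
                      stringsAsFactors = FALSE))
  }
  gs <- min(m$q_pos)
  ge <- max(m$q_pos)
  coverage <- nrow(m) / length(span_cols)
  data.frame(protein_id = protein_id,
             gtpase_start = as.integer(gs), gtpase_end = as.integer(ge),
             nte_len = gs - 1L, cte_len = L - ge,
             coverage = coverage,
             flagged = coverage < anchor$coverage_floor,
             stringsAsFactors = FALSE)
}

#' Flag AH candidates overlapping the projected GTPase domain
#'
#' A window is excluded iff it shares at least one residue with the
#' projected span. Proteins without a detected domain (`NA` span) keep all
#' windows.
#'
#' @param calls scored window data.frame (columns `start`, `end`, ...).
#' @param span one-row domain data.frame from [project_reference_span()].
#' @return `calls` with a logical `excluded_gtpase_overlap` column.
#' @export
filter_gtpase_overlap <- function(calls, span) {
  if (nrow(calls) == 0) {
    calls$excluded_gtpase_overlap <- logical(0)
    return(calls)
  }
  if (is.na(span$gtpase_start[1])) {
    calls$excluded_gtpase_overlap <- FALSE
    return(calls)
  }
  calls$excluded_gtpase_overlap <-
    calls$start <= span$gtpase_end[1] & calls$end >= span$gtpase_start[1]
  calls
}

#' Reduce one protein's calls to the single largest-D hit
#'
#' Among retained (not excluded) amphipathic windows, the window with the
#' largest discriminant D is marked `is_best`; ties are broken by smaller
#' start, then fully-helical before partially-helical category. A protein
#' with no qualifying window gets no best hit.
#'
#' @param calls scored, exclusion-flagged window data.frame for one protein.
#' @return `calls` with a logical `is_best` column (at most one TRUE).
#' @export
select_best_hit <- function(calls) {
  calls$is_best <- rep(FALSE, nrow(calls))
  if (nrow(calls) == 0) return(calls)
  eligible <- which(!calls$excluded_gtpase_overlap & calls$is_amphipathic)
  if (length(eligible) == 0) return(calls)
  ord <- order(-calls$D[eligible], calls$start[eligible],
               calls$category[eligible] != "full")
  calls$is_best[eligible[ord[1]]] <- TRUE
  calls
}
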