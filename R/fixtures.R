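# Deterministic synthetic-fixture generators: amphipathic peptides built on
# helical-wheel geometry, and toy septin-like records (NTE + reference
# GTPase core + CTE) with planted ground-truth spans. Everything here is
# synthetic and exists so the scanning pipeline is testable without any
# external sequence resource.

# Run code under a fixed RNG state, restoring the caller's state afterwards.
with_fixture_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

POLAR_POOL <- c("S", "T", "N", "Q", "A", "G")
NTE_BACKGROUND_POOL <- c("S", "T", "N", "Q", "A", "G", "P", "E", "D")

# Build one peptide with the current RNG stream (no seeding). Residues are
# placed by wheel angle (100 degrees per residue): under "strong"
# segregation, bulky hydrophobics occupy the 160-degree sector centred on
# angle 0 and charged/polar residues the rest, tuned to the requested net
# charge; "weak" widens the hydrophobic sector to 240 degrees; "none"
# permutes the same residue multiset without angular structure.
build_peptide <- function(length, segregation, net_charge_target) {
  k <- seq_len(length) - 1L
  angle <- (100 * k) %% 360
  offset <- pmin(angle, 360 - angle)
  half_width <- switch(segregation, strong = 80, weak = 120, none = 80)
  hydrophobic_slot <- offset <= half_width
  n_fill <- sum(!hydrophobic_slot)
  t <- as.integer(net_charge_target)
  if (abs(t) > n_fill) {
    stop(sprintf("net_charge_target %d unreachable: only %d non-hydrophobic slots",
                 t, n_fill), call. = FALSE)
  }
  n_pos <- max(t, 0L)
  n_neg <- max(-t, 0L)
  extra_pairs <- min((n_fill - n_pos - n_neg) %/% 2L, 2L)
  n_pos <- n_pos + extra_pairs
  n_neg <- n_neg + extra_pairs
  n_polar <- n_fill - n_pos - n_neg

  residues <- character(length)
  residues[hydrophobic_slot] <- sample(BULKY_HYDROPHOBIC,
                                       sum(hydrophobic_slot), replace = TRUE)
  # charged residues go to the slots farthest from the hydrophobic pole so
  # the 90-degree core stays charge-free
  fill_idx <- which(!hydrophobic_slot)
  fill_idx <- fill_idx[order(-offset[fill_idx])]
  charged <- c(sample(c("K", "R"), n_pos, replace = TRUE),
               sample(c("D", "E"), n_neg, replace = TRUE))
  if (length(charged) > 0) charged <- sample(charged)
  residues[fill_idx[seq_along(charged)]] <- charged
  if (n_polar > 0) {
    residues[fill_idx[length(charged) + seq_len(n_polar)]] <-
      sample(POLAR_POOL, n_polar, replace = TRUE)
  }
  if (segregation == "none") residues <- sample(residues)
  paste(residues, collapse = "")
}

#' Generate a synthetic peptide with controlled amphipathic character
#'
#' Builds a peptide on helical-wheel geometry (100 degrees of rotation per
#' residue). Under `"strong"` segregation, bulky hydrophobic residues
#' (L, V, F, I, W, M, Y) are placed at wheel positions within a 160-degree
#' sector and charged/polar residues elsewhere, with the charged-residue
#' count tuned to `net_charge_target`; `"weak"` uses a wider 240-degree
#' sector; `"none"` randomly permutes the same residue multiset, destroying
#' the angular structure. Generation is deterministic given the seed.
#'
#' @param length peptide length (>= 18).
#' @param segregation `"strong"`, `"weak"` or `"none"`.
#' @param net_charge_target requested net charge (K/R minus D/E count).
#' @param seed integer RNG seed.
#' @return list with elements `record` (one-row protein data.frame), `ss`
#'   (all-helical track), `planted_ah_span` (c(1, length) unless
#'   segregation is `"none"`), `planted_gtpase_span`, `planted_pb_span`
#'   (both NULL) and `seed`.
#' @export
generate_amphipathic_peptide <- function(length = 18,
                                         segregation = c("strong", "weak", "none"),
                                         net_charge_target = 0, seed = 1) {
  segregation <- match.arg(segregation)
  if (length < 18) stop("length must be >= 18", call. = FALSE)
  aa <- with_fixture_seed(seed, build_peptide(length, segregation, net_charge_target))
  id <- sprintf("pep_%s_z%d_s%d", segregation, net_charge_target, seed)
  rec <- protein_records(id = id, sequence = aa,
                         description = "synthetic peptide fixture")
  list(
    record = rec,
    ss = data.frame(protein_id = id, states = strrep("H", length),
                    stringsAsFactors = FALSE),
    planted_ah_span = if (segregation == "none") NULL else c(1L, as.integer(length)),
    planted_gtpase_span = NULL,
    planted_pb_span = NULL,
    seed = seed
  )
}

#' Generate a toy septin-like record with planted ground truth
#'
#' Assembles `NTE + reference GTPase core + CTE`, where the core is the
#' GTPase-domain subsequence of the packaged synthetic reference record
#' (see [synthetic_reference_septin()]), optionally with the residue at the
#' arginine-finger column substituted. A K/R-rich 12-residue stretch can be
#' planted in the NTE (`plant_pb`) and a strongly amphipathic 18-mer in the
#' CTE (`plant_ah`); planted spans are recorded as ground truth. A matching
#' secondary-structure track is emitted with `H` over the planted helix and
#' `C` elsewhere.
#'
#' @param nte_len,cte_len flank lengths (>= 0).
#' @param plant_ah plant an amphipathic 18-mer in the CTE (needs `cte_len >= 18`).
#' @param plant_pb plant a polybasic stretch in the NTE (needs `nte_len >= 12`).
#' @param r_finger residue at the reference arginine-finger column: `"R"`
#'   (kept), `"H"` (histidine variant) or `"other"` (serine).
#' @param seed integer RNG seed.
#' @param anchor reference anchor supplying the core sequence.
#' @return list with elements `record`, `ss`, `planted_ah_span`,
#'   `planted_gtpase_span`, `planted_pb_span`, `seed`.
#' @export
generate_toy_septin <- function(nte_len, cte_len, plant_ah = FALSE,
                                plant_pb = FALSE,
                                r_finger = c("R", "H", "other"),
                                seed = 1, anchor = default_anchor()) {
  r_finger <- match.arg(r_finger)
  if (nte_len < 0 || cte_len < 0) stop("flank lengths must be >= 0", call. = FALSE)
  if (plant_pb && nte_len < 12) {
    stop("plant_pb requires nte_len >= 12", call. = FALSE)
  }
  if (plant_ah && cte_len < 18) {
    stop("plant_ah requires cte_len >= 18", call. = FALSE)
  }
  core <- substr(anchor$reference$sequence,
                 anchor$gtpase_start, anchor$gtpase_end)
  rf_off <- anchor$r_finger_col - anchor$gtpase_start + 1L
  sub <- switch(r_finger, R = "R", H = "H", other = "S")
  substr(core, rf_off, rf_off) <- sub

  out <- with_fixture_seed(seed, {
    nte <- if (nte_len > 0) {
      paste(sample(NTE_BACKGROUND_POOL, nte_len, replace = TRUE), collapse = "")
    } else ""
    pb_span <- NULL
    if (plant_pb) {
      pb_len <- 12L
      pb_start <- sample.int(nte_len - pb_len + 1L, 1L)
      stretch <- paste(sample(c("K", "R"), pb_len, replace = TRUE), collapse = "")
      substr(nte, pb_start, pb_start + pb_len - 1L) <- stretch
      pb_span <- c(pb_start, pb_start + pb_len - 1L)
    }
    cte <- if (cte_len > 0) {
      paste(sample(NTE_BACKGROUND_POOL, cte_len, replace = TRUE), collapse = "")
    } else ""
    ah_span <- NULL
    if (plant_ah) {
      ah_start <- sample.int(cte_len - 18L + 1L, 1L)
      pep <- build_peptide(18L, "strong", 0L)
      substr(cte, ah_start, ah_start + 17L) <- pep
      ah_span <- c(nte_len + nchar(core) + ah_start,
                   nte_len + nchar(core) + ah_start + 17L)
    }
    list(nte = nte, cte = cte, pb_span = pb_span, ah_span = ah_span)
  })

  sequence <- paste0(out$nte, core, out$cte)
  id <- sprintf("toy_s%d", seed)
  rec <- protein_records(id = id, sequence = sequence,
                         description = "synthetic toy septin fixture")
  ss <- rep("C", nchar(sequence))
  if (!is.null(out$ah_span)) ss[out$ah_span[1]:out$ah_span[2]] <- "H"
  list(
    record = rec,
    ss = data.frame(protein_id = id, states = paste(ss, collapse = ""),
                    stringsAsFactors = FALSE),
    planted_ah_span = if (is.null(out$ah_span)) NULL else as.integer(out$ah_span),
    planted_gtpase_span = c(nte_len + 1L, nte_len + nchar(core)),
    planted_pb_span = if (is.null(out$pb_span)) NULL else as.integer(out$pb_span),
    seed = seed
  )
}
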