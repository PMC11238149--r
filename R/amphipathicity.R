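# Amphipathicity scoring of 18-residue helical windows: helical-wheel
# projection, mean hydrophobic moment <muH>, net charge z, discriminant
# D = 0.944 * <muH> + 0.33 * z, hydrophobic face/core geometry, and the
# three-part acceptance rule.

D_MUH_COEF <- 0.944
D_Z_COEF <- 0.33
D_THRESHOLD <- 0.68
MUH_THRESHOLD <- 0.4
FACE_HALF_DEG <- 90
CORE_HALF_DEG <- 45
# relative snap tolerance for declaring the moment vector zero (degenerate pole)
MOMENT_ZERO_TOL <- 1e-12

#' Project a window onto the helical wheel
#'
#' Residue `k` (0-indexed) sits at angle `100 * k mod 360` degrees,
#' the canonical alpha-helical rotation step. For an 18-residue window the
#' 18 angles are pairwise distinct multiples of 20 degrees covering the
#' whole wheel.
#'
#' @param aa amino-acid string.
#' @param scale hydrophobicity scale from [hydrophobicity_scale()].
#' @return data.frame with columns `k`, `angle_deg`, `residue`, `h`.
#' @export
wheel_projection <- function(aa, scale = hydrophobicity_scale()) {
  residues <- seq_chars(aa)
  validate_residues(aa)
  k <- seq_along(residues) - 1L
  data.frame(
    k = k,
    angle_deg = (100 * k) %% 360,
    residue = residues,
    h = unname(scale$values[residues]),
    stringsAsFactors = FALSE
  )
}

#' Mean hydrophobic moment of a wheel projection
#'
#' `muH = (1/n) * | sum_k h_k * (cos theta_k, sin theta_k) |`. The
#' hydrophobicities are mean-centred before summation: because the n unit
#' vectors of a full 18-residue wheel sum to zero analytically, centring
#' changes nothing mathematically but makes the uniform-hydrophobicity
#' window yield exactly zero in floating point. A vector magnitude below a
#' relative tolerance of 1e-12 is snapped to zero and the pole flagged
#' undefined (`pole_deg = NA`).
#'
#' @param proj projection from [wheel_projection()].
#' @return list with `muH` (>= 0) and `pole_deg` (degrees in \[0, 360), or
#'   NA when the moment vector vanishes).
#' @export
mean_hydrophobic_moment <- function(proj) {
  n <- nrow(proj)
  theta <- proj$angle_deg * pi / 180
  hc <- proj$h - mean(proj$h)
  vx <- sum(hc * cos(theta))
  vy <- sum(hc * sin(theta))
  norm <- sqrt(vx^2 + vy^2)
  if (norm <= MOMENT_ZERO_TOL * max(1, sum(abs(proj$h)))) {
    return(list(muH = 0, pole_deg = NA_real_))
  }
  pole <- atan2(vy, vx) * 180 / pi
  if (pole < 0) pole <- pole + 360
  list(muH = norm / n, pole_deg = pole)
}

#' Net charge of a peptide
#'
#' K and R count +1, D and E count -1; histidine and all other residues
#' (including X) contribute 0, and termini are ignored (the HeliQuest
#' convention).
#'
#' @param aa amino-acid string.
#' @return integer net charge.
#' @export
net_charge <- function(aa) {
  chars <- seq_chars(aa)
  sum(chars %in% c("K", "R")) - sum(chars %in% c("D", "E"))
}

#' Discriminant factor D
#'
#' `D = 0.944 * muH + 0.33 * z`, the linear discriminant HeliQuest uses to
#' separate membrane-binding amphipathic helices from other sequences.
#'
#' @param muH mean hydrophobic moment (>= 0).
#' @param z net charge.
#' @return numeric discriminant.
#' @examples
#' discriminant_d(1, 0)  # 0.944
#' discriminant_d(0, 1)  # 0.33
#' @export
discriminant_d <- function(muH, z) {
  D_MUH_COEF * muH + D_Z_COEF * z
}

#' Hydrophobic face and core of a projected window
#'
#' The face is the half-wheel within 90 degrees of the moment pole
#' (boundary-inclusive), ordered by signed angular offset from -90 to +90;
#' the core is the 90-degree sector centred on the pole (offset within
#' +/- 45 degrees, inclusive).
#'
#' @param proj projection from [wheel_projection()].
#' @param pole_deg pole direction in degrees; must be defined.
#' @return list of two data.frames (`face`, `core`) with columns `k`,
#'   `residue`, `offset_deg`; `core` rows are a subset of `face` rows.
#' @export
hydrophobic_face_and_core <- function(proj, pole_deg) {
  if (is.na(pole_deg)) {
    stop("pole undefined (zero hydrophobic moment): no face exists", call. = FALSE)
  }
  offset <- ((proj$angle_deg - pole_deg + 180) %% 360) - 180
  in_face <- abs(offset) <= FACE_HALF_DEG
  face <- data.frame(k = proj$k[in_face], residue = proj$residue[in_face],
                     offset_deg = offset[in_face], stringsAsFactors = FALSE)
  face <- face[order(face$offset_deg), , drop = FALSE]
  rownames(face) <- NULL
  core <- face[abs(face$offset_deg) <= CORE_HALF_DEG, , drop = FALSE]
  rownames(core) <- NULL
  list(face = face, core = core)
}

# criterion i: D > 0.68 OR (muH > 0.4 AND z == 0); strict comparisons
criterion_i <- function(muH, z) {
  (discriminant_d(muH, z) > D_THRESHOLD) || (muH > MUH_THRESHOLD && z == 0)
}

# criterion ii: >= `run` consecutive bulky hydrophobics in the angular
# ordering of the face
has_bulky_run <- function(face_residues, run = 3L) {
  if (length(face_residues) < run) return(FALSE)
  bulky <- face_residues %in% BULKY_HYDROPHOBIC
  r <- rle(bulky)
  any(r$values & r$lengths >= run)
}

# criterion iii: no charged residue (D, E, K, R) in the core
core_uncharged <- function(core_residues) {
  !any(core_residues %in% CHARGED_RESIDUES)
}

#' Assess the amphipathicity of an 18-residue window
#'
#' Computes the helical-wheel projection, mean hydrophobic moment, net
#' charge and discriminant, then applies the three acceptance criteria:
#' (i) `D > 0.68` or (`muH > 0.4` and `z = 0`); (ii) the hydrophobic face
#' contains at least three consecutive bulky hydrophobic residues
#' (L, V, F, I, W, M, Y) in its angular ordering; (iii) the core (the
#' 90-degree sector centred on the pole) contains no charged residue.
#' The window is called amphipathic only if all three hold. A window with
#' zero hydrophobic moment has no pole, hence no face: it is returned as
#' not amphipathic with the geometric fields NA.
#'
#' @param aa 18-residue amino-acid string (a data.frame row from
#'   [extract_helix_windows()] is also accepted; its `aa` column is used).
#' @param scale hydrophobicity scale.
#' @return one-row data.frame with columns `muH`, `z`, `D`, `pole_deg`,
#'   `face`, `core` (angular-order residue strings), `crit_i`, `crit_ii`,
#'   `crit_iii`, `is_amphipathic`.
#' @export
assess_amphipathicity <- function(aa, scale = hydrophobicity_scale()) {
  if (is.data.frame(aa)) aa <- aa$aa[1]
  if (nchar(aa) != WINDOW_LEN) {
    stop("assess_amphipathicity expects an 18-residue window", call. = FALSE)
  }
  proj <- wheel_projection(aa, scale)
  mom <- mean_hydrophobic_moment(proj)
  z <- net_charge(aa)
  D <- discriminant_d(mom$muH, z)
  if (is.na(mom$pole_deg)) {
    return(data.frame(muH = mom$muH, z = z, D = D, pole_deg = NA_real_,
                      face = NA_character_, core = NA_character_,
                      crit_i = FALSE, crit_ii = FALSE, crit_iii = FALSE,
                      is_amphipathic = FALSE, stringsAsFactors = FALSE))
  }
  fc <- hydrophobic_face_and_core(proj, mom$pole_deg)
  crit_i <- criterion_i(mom$muH, z)
  crit_ii <- has_bulky_run(fc$face$residue)
  crit_iii <- core_uncharged(fc$core$residue)
  data.frame(
    muH = mom$muH, z = z, D = D, pole_deg = mom$pole_deg,
    face = paste(fc$face$residue, collapse = ""),
    core = paste(fc$core$residue, collapse = ""),
    crit_i = crit_i, crit_ii = crit_ii, crit_iii = crit_iii,
    is_amphipathic = crit_i && crit_ii && crit_iii,
    stringsAsFactors = FALSE
  )
}

#' Extract and score every candidate window of one protein
#'
#' Convenience composition of [extract_helix_windows()] and
#' [assess_amphipathicity()].
#'
#' @param record one-row protein data.frame.
#' @param track matching secondary-structure track.
#' @param scale hydrophobicity scale.
#' @return data.frame: window columns plus the score columns.
#' @export
scan_windows <- function(record, track, scale = hydrophobicity_scale()) {
  win <- extract_helix_windows(record, track)
  if (nrow(win) == 0) {
    scores <- assess_amphipathicity(strrep("A", WINDOW_LEN), scale)[0, ]
    return(cbind(win, scores))
  }
  scores <- do.call(rbind, lapply(win$aa, assess_amphipathicity, scale = scale))
  cbind(win, scores)
}
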