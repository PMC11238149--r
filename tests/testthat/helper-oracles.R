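# Independent oracles used across the suite. These re-derive the quantities
# from first principles (per-residue loops, Gotoh dynamic programming) and
# never call the implementation paths they check.

# brute-force mean hydrophobic moment: naive per-residue loop
oracle_moment <- function(aa, scale = hydrophobicity_scale()) {
  chars <- strsplit(aa, "")[[1]]
  sx <- 0; sy <- 0
  for (k in seq_along(chars)) {
    theta <- (100 * (k - 1)) %% 360 * pi / 180
    h <- scale$values[[chars[k]]]
    sx <- sx + h * cos(theta)
    sy <- sy + h * sin(theta)
  }
  muH <- sqrt(sx^2 + sy^2) / length(chars)
  pole <- atan2(sy, sx) * 180 / pi
  if (pole < 0) pole <- pole + 360
  list(muH = muH, pole_deg = pole)
}

# brute-force face/core membership by explicit angular enumeration
oracle_face_core <- function(aa, pole_deg) {
  chars <- strsplit(aa, "")[[1]]
  rows <- lapply(seq_along(chars), function(k) {
    angle <- (100 * (k - 1)) %% 360
    d <- angle - pole_deg
    while (d > 180) d <- d - 360
    while (d <= -180) d <- d + 360
    data.frame(k = k - 1L, residue = chars[k], offset_deg = d)
  })
  df <- do.call(rbind, rows)
  face <- df[abs(df$offset_deg) <= 90, , drop = FALSE]
  face <- face[order(face$offset_deg), , drop = FALSE]
  core <- face[abs(face$offset_deg) <= 45, , drop = FALSE]
  list(face = face$residue, core = core$residue)
}

test_blosum62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
})

# Gotoh affine-gap global alignment score (gap of length L costs go + ge*L)
gotoh_score <- function(a, b, sub = test_blosum62, go = 10, ge = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(go + ge * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(go + ge * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- sub[av[i], bv[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - go - ge, X[i, j + 1] - ge,
                             Y[i, j + 1] - go - ge)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - go - ge, Y[i + 1, j] - ge,
                             X[i + 1, j] - go - ge)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# score an aligned string pair under the same affine convention
score_aligned_pair <- function(aq, ar, sub = test_blosum62, go = 10, ge = 1) {
  qa <- strsplit(aq, "")[[1]]; ra <- strsplit(ar, "")[[1]]
  stopifnot(length(qa) == length(ra))
  gap <- function(v) {
    r <- rle(v == "-")
    sum(r$lengths[r$values]) * ge + sum(r$values) * go
  }
  both <- qa != "-" & ra != "-"
  sum(vapply(which(both), function(i) sub[qa[i], ra[i]], numeric(1))) -
    gap(qa) - gap(ra)
}

random_aa <- function(n, pool = ahscan:::AA_STANDARD) {
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

random_ss <- function(n) paste(sample(c("H", "E", "C"), n, replace = TRUE,
                                      prob = c(0.5, 0.2, 0.3)), collapse = "")

# brute-force window predicate used by the window-extraction oracle test
oracle_windows <- function(states) {
  v <- strsplit(states, "")[[1]] == "H"
  L <- length(v)
  if (L < 18) return(integer(0))
  keep <- vapply(seq_len(L - 17), function(i) {
    w <- v[i:(i + 17)]
    all(w[1:6]) && all(w[13:18])
  }, logical(1))
  which(keep)
}
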