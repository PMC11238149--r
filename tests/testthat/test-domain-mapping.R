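test_that("global alignment handles identity, gaps and empty input", {
  aln <- global_align("ACDE", "ACDE")
  expect_equal(nrow(aln$mapping), 4L)
  expect_equal(aln$mapping$q_pos, aln$mapping$r_pos)

  aln2 <- global_align("MAKKK", "MKKK")
  expect_true(grepl("-", aln2$aligned_ref))
  expect_equal(aln2$score, gotoh_score("MAKKK", "MKKK"))

  expect_error(global_align("", "ACDE"), "empty sequence")
})

test_that("alignment score is symmetric and the mapping strictly increasing", {
  set.seed(202)
  for (i in 1:30) {
    q <- random_aa(sample(5:40, 1))
    r <- random_aa(sample(5:40, 1))
    a <- global_align(q, r)
    b <- global_align(r, q)
    expect_equal(a$score, b$score)
    if (nrow(a$mapping) > 1) {
      expect_true(all(diff(a$mapping$q_pos) > 0))
      expect_true(all(diff(a$mapping$r_pos) > 0))
    }
  }
})

test_that("alignment is optimal against an independent Gotoh oracle on short pairs", {
  set.seed(88)
  pool <- c("A", "C", "D", "E")
  for (i in 1:120) {
    q <- random_aa(sample(1:8, 1), pool)
    r <- random_aa(sample(1:8, 1), pool)
    aln <- global_align(q, r)
    best <- gotoh_score(q, r)
    expect_equal(aln$score, best)
    # the emitted aligned strings themselves realise the optimal score
    expect_equal(score_aligned_pair(aln$aligned_query, aln$aligned_ref), best)
  }
})

test_that("reference-span projection: identity, shift and truncation", {
  anchor <- default_anchor()
  ref <- anchor$reference$sequence

  aln <- global_align(ref, ref)
  span <- project_reference_span(aln, anchor, "self")
  expect_equal(c(span$gtpase_start, span$gtpase_end),
               c(anchor$gtpase_start, anchor$gtpase_end))
  expect_equal(span$coverage, 1)
  expect_false(span$flagged)

  shifted <- paste0(strrep("G", 10), ref)
  span2 <- project_reference_span(global_align(shifted, ref), anchor, "shift")
  expect_equal(span2$gtpase_start, anchor$gtpase_start + 10L)
  expect_equal(span2$gtpase_end, anchor$gtpase_end + 10L)

  truncated <- substr(ref, 1, 300)
  span3 <- project_reference_span(global_align(truncated, ref), anchor, "trunc")
  expect_equal(span3$gtpase_end, 300L)
  expect_lt(span3$coverage, 1)

  # nothing septin-like: no reference column aligns within the domain
  far <- global_align("WWWW", ref)
  span4 <- project_reference_span(far, anchor, "junk")
  if (is.na(span4$gtpase_start)) {
    expect_true(span4$flagged)
    expect_equal(span4$coverage, 0)
  } else {
    expect_true(span4$flagged)  # coverage far below the floor
    expect_lt(span4$coverage, anchor$coverage_floor)
  }
})

test_that("GTPase-overlap exclusion uses shared residues, boundary-exact", {
  span <- data.frame(protein_id = "p", gtpase_start = 20L, gtpase_end = 340L,
                     nte_len = 19L, cte_len = 20L, coverage = 1, flagged = FALSE)
  calls <- data.frame(start = c(5L, 341L, 1L), end = c(22L, 358L, 18L))
  out <- filter_gtpase_overlap(calls, span)
  expect_identical(out$excluded_gtpase_overlap, c(TRUE, FALSE, FALSE))

  span18 <- span; span18$gtpase_start <- 18L
  out2 <- filter_gtpase_overlap(calls, span18)
  expect_true(out2$excluded_gtpase_overlap[3])   # now shares residue 18
})

test_that("boundary-adjacent windows are retained", {
  span <- data.frame(protein_id = "p", gtpase_start = 19L, gtpase_end = 340L,
                     nte_len = 18L, cte_len = 0L, coverage = 1, flagged = FALSE)
  calls <- data.frame(start = 1L, end = 18L)
  expect_false(filter_gtpase_overlap(calls, span)$excluded_gtpase_overlap)
})

test_that("best-hit selection maximises D with deterministic tie-breaking", {
  base <- data.frame(
    protein_id = "p", start = c(5L, 40L, 12L), end = c(22L, 57L, 29L),
    category = c("full", "partial", "partial"),
    D = c(0.70, 0.91, 0.91), is_amphipathic = TRUE,
    excluded_gtpase_overlap = FALSE, stringsAsFactors = FALSE
  )
  out <- select_best_hit(base)
  expect_identical(out$is_best, c(FALSE, FALSE, TRUE))  # tie -> smaller start

  tie_cat <- base
  tie_cat$start <- c(12L, 12L, 40L)
  tie_cat$D <- c(0.91, 0.91, 0.5)
  tie_cat$category <- c("partial", "full", "full")
  expect_identical(select_best_hit(tie_cat)$is_best, c(FALSE, TRUE, FALSE))

  single <- base[1, ]
  expect_true(select_best_hit(single)$is_best)

  excluded <- base
  excluded$excluded_gtpase_overlap <- TRUE
  expect_false(any(select_best_hit(excluded)$is_best))
  expect_false(any(select_best_hit(base[0, ])$is_best))
})

test_that("no best hit ever overlaps the projected GTPase span", {
  for (seed in 1:10) {
    toy <- generate_toy_septin(nte_len = 40, cte_len = 40, plant_ah = TRUE,
                               seed = seed)
    scan <- find_amphipathic_helices(toy$record, toy$ss)
    best <- scan$calls[scan$calls$is_best, ]
    if (nrow(best) == 0) next
    dom <- scan$domains
    expect_true(best$end < dom$gtpase_start || best$start > dom$gtpase_end)
  }
})
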