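test_that("wheel projection places residues 100 degrees apart", {
  proj <- wheel_projection(strrep("A", 18))
  expect_equal(nrow(proj), 18L)
  expect_equal(proj$angle_deg, (100 * (0:17)) %% 360)
  expect_equal(length(unique(proj$angle_deg)), 18L)   # distinct multiples of 20
  expect_true(all(proj$angle_deg %% 20 == 0))
})

test_that("mean hydrophobic moment: analytic cases and degenerate pole", {
  # uniform hydrophobicity: 18 steps of 100 degrees complete 5 full turns
  for (res in c("A", "L", "K")) {
    mom <- mean_hydrophobic_moment(wheel_projection(strrep(res, 18)))
    expect_identical(mom$muH, 0)
    expect_true(is.na(mom$pole_deg))
  }
  # single contributing residue at k = 0: muH = h/18 after centring cancels
  # against the vanishing unit-vector sum; pole points at k = 0
  scale <- hydrophobicity_scale()
  proj <- wheel_projection(paste0("W", strrep("G", 17)), scale)
  mom <- mean_hydrophobic_moment(proj)
  expect_equal(mom$muH, scale$values[["W"]] / 18, tolerance = 1e-12)
  expect_lt(min(mom$pole_deg, 360 - mom$pole_deg), 1e-9)  # circular: 360 ~ 0
})

test_that("muH and pole match the brute-force per-residue loop on random windows", {
  set.seed(31)
  for (i in 1:1000) {
    aa <- random_aa(18, pool = c(ahscan:::AA_STANDARD, "X"))
    mom <- mean_hydrophobic_moment(wheel_projection(aa))
    orc <- oracle_moment(aa)
    expect_equal(mom$muH, orc$muH, tolerance = 1e-12)
    if (!is.na(mom$pole_deg)) {
      expect_equal(mom$pole_deg, orc$pole_deg, tolerance = 1e-9)
    }
  }
})

test_that("muH is mirror-symmetric and net charge is permutation-invariant", {
  set.seed(7)
  for (i in 1:25) {
    aa <- random_aa(18)
    proj <- wheel_projection(aa)
    mirrored <- proj
    mirrored$angle_deg <- (360 - proj$angle_deg) %% 360
    expect_equal(mean_hydrophobic_moment(proj)$muH,
                 mean_hydrophobic_moment(mirrored)$muH, tolerance = 1e-12)
    perm <- paste(sample(strsplit(aa, "")[[1]]), collapse = "")
    expect_identical(net_charge(aa), net_charge(perm))
  }
})

test_that("net charge counts K/R against D/E with H neutral", {
  expect_identical(net_charge(strrep("K", 18)), 18L)
  expect_identical(net_charge(strrep("D", 18)), -18L)
  expect_identical(net_charge("ACDEFGHIKLMNPQRSTV"), 0L)
  expect_identical(net_charge(strrep("H", 18)), 0L)
  expect_identical(net_charge("XXXX"), 0L)
})

test_that("the discriminant is exactly linear with the printed coefficients", {
  expect_identical(discriminant_d(1, 0), 0.944)
  expect_identical(discriminant_d(0, 1), 0.33)
  expect_identical(discriminant_d(0, 0), 0)
  expect_equal(discriminant_d(0.5, 2), 1.132, tolerance = 1e-15)
  set.seed(5)
  for (i in 1:20) {
    mu <- runif(1, 0, 2); z <- sample(-5:5, 1); a <- runif(1, 0.1, 3)
    expect_equal(discriminant_d(a * mu, z), a * 0.944 * mu + 0.33 * z,
                 tolerance = 1e-12)
  }
})

test_that("face and core geometry: exhaustive enumeration around a known pole", {
  # single contributing residue at k = 0 puts the pole at 0 degrees:
  # 9 wheel positions lie within 90 degrees, 5 within 45 degrees
  proj <- wheel_projection(paste0("W", strrep("G", 17)))
  fc <- hydrophobic_face_and_core(proj, 0)
  expect_equal(nrow(fc$face), 9L)
  expect_equal(nrow(fc$core), 5L)
  expect_setequal((100 * fc$face$k) %% 360,
                  c(0, 20, 40, 60, 80, 280, 300, 320, 340))
  expect_setequal((100 * fc$core$k) %% 360, c(0, 20, 40, 320, 340))
  # face ordered by signed offset, core a prefix-contiguous subset of it
  expect_true(!is.unsorted(fc$face$offset_deg))
  expect_true(all(paste(fc$core$k) %in% paste(fc$face$k)))
  expect_error(hydrophobic_face_and_core(proj, NA_real_), "pole undefined")
})

test_that("face and core membership match brute-force offsets on random windows", {
  set.seed(63)
  for (i in 1:500) {
    aa <- random_aa(18)
    proj <- wheel_projection(aa)
    mom <- mean_hydrophobic_moment(proj)
    if (is.na(mom$pole_deg)) next
    fc <- hydrophobic_face_and_core(proj, mom$pole_deg)
    orc <- oracle_face_core(aa, mom$pole_deg)
    expect_identical(fc$face$residue, orc$face)
    expect_identical(fc$core$residue, orc$core)
  }
})

test_that("rotating the wheel assignment rotates the pole and preserves face sizes", {
  set.seed(11)
  for (i in 1:20) {
    aa <- random_aa(18)
    s1 <- assess_amphipathicity(aa)
    if (is.na(s1$pole_deg)) next
    chars <- strsplit(aa, "")[[1]]
    rotated <- paste(c(chars[18], chars[1:17]), collapse = "")
    s2 <- assess_amphipathicity(rotated)
    expect_equal((s2$pole_deg - s1$pole_deg) %% 360, 100, tolerance = 1e-9)
    expect_equal(nchar(s2$face), nchar(s1$face))
    expect_equal(nchar(s2$core), nchar(s1$core))
    expect_equal(s2$muH, s1$muH, tolerance = 1e-12)
  }
})

test_that("criterion i uses strict thresholds", {
  crit_i <- ahscan:::criterion_i
  # engineered so that D is exactly 0.68 with nonzero charge: fails
  mu <- (0.68 - 0.33) / 0.944
  expect_identical(discriminant_d(mu, 1), 0.68)
  expect_false(crit_i(mu, 1))
  expect_true(crit_i(mu + 1e-9, 1))
  # muH exactly 0.4 with z = 0 (D = 0.3776 <= 0.68): fails
  expect_false(crit_i(0.4, 0))
  expect_true(crit_i(0.4 + 1e-12, 0))
  # charged branch: muH above 0.4 but z != 0 and D below threshold
  expect_false(crit_i(0.5, -1))
})

test_that("criterion ii accepts an angularly ordered face with a bulky run", {
  expect_true(ahscan:::has_bulky_run(c("S", "Y", "A", "L", "L", "V", "T")))
  expect_false(ahscan:::has_bulky_run(c("S", "L", "A", "L", "A", "V", "T")))
  expect_false(ahscan:::has_bulky_run(c("L", "V")))
})

test_that("assessment composes the three criteria", {
  uniform <- assess_amphipathicity(strrep("A", 18))
  expect_identical(uniform$muH, 0)
  expect_false(uniform$is_amphipathic)
  expect_true(is.na(uniform$pole_deg))

  p <- generate_amphipathic_peptide(18, "strong", 0, seed = 4)
  s <- assess_amphipathicity(p$record$sequence)
  expect_true(s$crit_i && s$crit_ii && s$crit_iii)
  expect_true(s$is_amphipathic)
  expect_identical(s$is_amphipathic, s$crit_i && s$crit_ii && s$crit_iii)

  # substituting a lysine at the residue nearest the pole charges the core
  proj <- wheel_projection(p$record$sequence)
  offs <- ((proj$angle_deg - s$pole_deg + 180) %% 360) - 180
  k_near <- proj$k[which.min(abs(offs))]
  mutated <- p$record$sequence
  substr(mutated, k_near + 1, k_near + 1) <- "K"
  s2 <- assess_amphipathicity(mutated)
  expect_false(s2$crit_iii)
  expect_false(s2$is_amphipathic)
  # consistency with the brute-force core: a charged residue sits inside it
  orc <- oracle_face_core(mutated, s2$pole_deg)
  expect_true(any(orc$core %in% c("D", "E", "K", "R")))
})
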