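mkpeak <- function(res_i, atom_i, res_j, atom_j, volume) {
  data.frame(res_i = res_i, atom_i = atom_i, res_j = res_j, atom_j = atom_j,
             volume = volume, stringsAsFactors = FALSE)
}

test_that("reference calibration averages qualifying H8-H1' volumes", {
  pk <- rbind(mkpeak(1, "H8", 1, "H1'", 10),
              mkpeak(2, "H8", 2, "H1'", 10),
              mkpeak(3, "H1'", 3, "H8", 10))
  expect_equal(calibrate_reference(pk, 1:3)$reference_volume, 10)
  pk2 <- rbind(mkpeak(1, "H8", 1, "H1'", 8), mkpeak(2, "H8", 2, "H1'", 12))
  cal <- calibrate_reference(pk2, 1:2)
  expect_equal(cal$reference_volume, 10)
  expect_equal(cal$ref_distance, 3.9)
  # residues not in the anti list are excluded
  expect_equal(calibrate_reference(pk2, 1)$reference_volume, 8)
  # inter-residue or non-H8/H1' peaks never qualify
  pk3 <- rbind(mkpeak(1, "H8", 2, "H1'", 5), mkpeak(1, "H2'", 1, "H8", 5))
  expect_error(calibrate_reference(pk3, 1:2), "calibration failed")
  expect_error(calibrate_reference(pk2[0, ], 1:2), "calibration failed")
})

test_that("NOE classification follows the inverse-sixth-power estimate", {
  ref <- list(reference_volume = 100, ref_distance = 3.9)
  # V = V_ref maps to exactly 3.9 A: medium, bounds 2.6-5.0
  r1 <- classify_noe(mkpeak(1, "H1", 2, "H8", 100), ref)
  expect_equal(r1$r_est, 3.9)
  expect_identical(r1$class, "medium")
  expect_equal(c(r1$lower, r1$upper), c(2.6, 5.0))
  # closed-form inversion: V = V_ref (3.9/2.5)^6 puts r at 2.5: strong
  r2 <- classify_noe(mkpeak(1, "H1", 2, "H8", 100 * (3.9 / 2.5)^6), ref)
  expect_equal(r2$r_est, 2.5, tolerance = 1e-12)
  expect_identical(r2$class, "strong")
  expect_equal(c(r2$lower, r2$upper), c(1.8, 3.6))
  # enormous volume: limit r -> 0: strong
  r3 <- classify_noe(mkpeak(1, "H1", 2, "H8", 1e12), ref)
  expect_identical(r3$class, "strong")
  # weak and very weak bins
  r4 <- classify_noe(mkpeak(1, "H1", 2, "H8", 100 * (3.9 / 5)^6), ref)
  expect_identical(r4$class, "weak")
  expect_equal(c(r4$lower, r4$upper), c(3.5, 6.5))
  r5 <- classify_noe(mkpeak(1, "H1", 2, "H8", 100 * (3.9 / 6)^6), ref)
  expect_identical(r5$class, "very_weak")
  expect_equal(c(r5$lower, r5$upper), c(4.5, 7.5))
  expect_equal(r1$force_constant, 20)
})

test_that("class index is monotone non-decreasing as volume decreases", {
  ref <- list(reference_volume = 50, ref_distance = 3.9)
  vols <- sort(exp(seq(log(1e-3), log(1e5), length.out = 200)),
               decreasing = TRUE)
  idx <- vapply(vols, function(v) {
    match(classify_noe(mkpeak(1, "H1", 2, "H8", v), ref)$class,
          c("strong", "medium", "weak", "very_weak"))
  }, numeric(1))
  expect_true(all(diff(idx) >= 0))
})

test_that("zero-noise NOE round trip brackets every true distance", {
  st <- build_quartet_stack(rep("GC_PAIR", 3), rise = 3.4, twist = 36,
                            backbone = TRUE)
  m <- get_model(st$ensemble, 1)
  noe <- simulate_noe_volumes(m, scale = 100, noise_cv = 0)
  # exact reference: estimates reproduce the true distances
  ref <- list(reference_volume = 100 * 3.9^-6, ref_distance = 3.9)
  rs <- noe_restraints(noe$peaks, ref)
  expect_equal(rs$r_est, noe$truth$distance, tolerance = 1e-10)
  expect_true(all(noe$truth$distance >= rs$lower &
                    noe$truth$distance <= rs$upper))
  # calibration route (anti H8-H1' referenced to 3.9 A): the small bias
  # from the true H8-H1' separation must stay within the class bounds
  cal <- calibrate_reference(noe$peaks, unique(noe$peaks$res_i))
  rs2 <- noe_restraints(noe$peaks, cal)
  expect_true(all(noe$truth$distance >= rs2$lower &
                    noe$truth$distance <= rs2$upper))
})

test_that("20 percent multiplicative noise keeps at least 95 percent containment", {
  st <- build_quartet_stack(rep("GC_PAIR", 3), rise = 3.4, twist = 36,
                            backbone = TRUE)
  m <- get_model(st$ensemble, 1)
  noe <- simulate_noe_volumes(m, scale = 100, noise_cv = 0.2, seed = 42)
  ref <- list(reference_volume = 100 * 3.9^-6, ref_distance = 3.9)
  rs <- noe_restraints(noe$peaks, ref)
  contained <- mean(noe$truth$distance >= rs$lower &
                      noe$truth$distance <= rs$upper)
  expect_gte(contained, 0.95)
})

test_that("chi restraints use the anti windows for purines and pyrimidines", {
  res <- data.frame(chain = "A", resno = 1:4,
                    restype = c("DG", "DC", "DG", "DA"),
                    chi_class = c("anti", "anti", "syn", "other"),
                    stringsAsFactors = FALSE)
  tr <- chi_restraints(res)
  expect_equal(nrow(tr), 2)   # syn / other emit nothing
  expect_equal(tr$lower, c(170, 170))
  expect_equal(tr$upper[tr$resno == 1], 280)   # purine
  expect_equal(tr$upper[tr$resno == 2], 310)   # pyrimidine
  expect_true(all(tr$force_constant == 200))
})

test_that("hydrogen-bond restraints count one per classified pattern bond", {
  for (cl in c("GG_PAIR", "GC_PAIR")) {
    m <- get_model(build_quartet_stack(cl)$ensemble, 1)
    hb <- find_hbonds(m)
    pr <- find_pairs(m, hb)
    hr <- hbond_restraints(pr, hb)
    expect_equal(nrow(hr), if (cl == "GC_PAIR") 3 else 2, info = cl)
    expect_true(all(hr$lower == 2.7 & hr$upper == 3.1))
    expect_true(all(hr$force_constant == 20))
  }
  empty <- find_pairs(get_model(build_quartet_stack("GC_PAIR")$ensemble, 1))[0, ]
  expect_equal(nrow(hbond_restraints(empty, find_hbonds(
    get_model(build_quartet_stack("GC_PAIR")$ensemble, 1)))), 0)
})

test_that("planarity groups cover GAGA-quartets and symmetric G-G pairs only", {
  m <- get_model(build_quartet_stack(c("GAGA", "GCGC_MAJOR", "GG_PAIR"),
                                     rise = 3.4, twist = 20)$ensemble, 1)
  hb <- find_hbonds(m)
  pr <- find_pairs(m, hb)
  q <- assemble_quartets(m, pr, hb)
  pl <- planarity_restraints(q, pr)
  expect_equal(sum(pl$group == "GAGA_quartet"), 1)
  expect_equal(sum(pl$group == "GG_N1_carbonyl_pair"), 1)
  expect_true(all(pl$force_constant == 50))
  expect_equal(nrow(planarity_restraints(q[0, ], pr[0, ])), 0)
})

test_that("restraint serialization round-trips and conserves counts", {
  m <- get_model(build_quartet_stack(c("GAGA", "GG_PAIR"), rise = 3.4,
                                     backbone = TRUE)$ensemble, 1)
  hb <- find_hbonds(m)
  pr <- find_pairs(m, hb)
  q <- assemble_quartets(m, pr, hb)
  noe <- simulate_noe_volumes(m, scale = 10)
  ref <- calibrate_reference(noe$peaks, unique(noe$peaks$res_i))
  tors <- torsion_table(m)
  set <- restraint_set(distance = noe_restraints(noe$peaks, ref),
                       torsion = chi_restraints(tors),
                       hbond = hbond_restraints(pr, hb),
                       planarity = planarity_restraints(q, pr),
                       provenance = list(reference_volume = ref$reference_volume,
                                         ref_distance = 3.9))
  counts <- restraint_counts(set)
  expect_true(all(counts[c("distance", "hbond")] > 0))
  for (dialect in c("tsv", "flat_list")) {
    tf <- tempfile()
    write_restraints(set, tf, dialect)
    back <- read_restraints(tf, dialect)
    expect_equal(nrow(back), sum(counts), info = dialect)
    expect_equal(sum(back$type == "distance"), unname(counts["distance"]))
    expect_equal(sort(unique(back$force_constant)),
                 sort(unique(c(20, if (counts["torsion"] > 0) 200, 50))),
                 info = dialect)
  }
  # empty set: header-only file
  tf2 <- tempfile()
  write_restraints(restraint_set(), tf2)
  expect_equal(nrow(read_restraints(tf2)), 0)
})
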