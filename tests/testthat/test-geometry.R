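rigid <- function(f, ax, ang, t) transform_frame(f, rot_axis(ax, ang), t)

test_that("base frame fitting recovers translations and rotations exactly", {
  tpl <- base_templates()
  g <- tpl[tpl$restype == "DG" & !grepl("'", tpl$atom) &
             !(tpl$atom %in% c("P", "OP1", "OP2")), ]
  res <- data.frame(chain = "A", resno = 1, restype = "DG", atom = g$atom,
                    element = g$element, x = g$x, y = g$y, z = g$z,
                    stringsAsFactors = FALSE)
  f0 <- fit_base_frame(res)
  expect_equal(f0$axes, diag(3), tolerance = 1e-8)
  expect_equal(f0$origin, c(0, 0, 0), tolerance = 1e-8)
  expect_lt(f0$rmsd, 1e-8)

  res_t <- res
  res_t[, c("x", "y", "z")] <- res[, c("x", "y", "z")] +
    rep(c(1, 2, 3), each = nrow(res))
  ft <- fit_base_frame(res_t)
  expect_equal(ft$origin, c(1, 2, 3), tolerance = 1e-8)

  R <- rot_axis(c(0, 0, 1), 25)
  res_r <- res
  res_r[, c("x", "y", "z")] <- t(R %*% t(as.matrix(res[, c("x", "y", "z")])))
  fr <- fit_base_frame(res_r)
  ang <- acos(min(1, (sum(diag(t(R) %*% fr$axes)) - 1) / 2)) * 180 / pi
  expect_lt(ang, 1e-6)
})

test_that("step and pair parameters invert their construction across the sweep", {
  set.seed(42)
  for (k in 1:60) {
    p <- c(runif(1, -2, 2), runif(1, -2, 2), runif(1, 2.5, 5.5),
           runif(1, -40, 40), runif(1, -40, 40), runif(1, -60, 60))
    fs <- frame_step_inverse(p[1], p[2], p[3], p[4], p[5], p[6])
    expect_equal(unname(step_params(fs$f1, fs$f2)), p, tolerance = 1e-9)
    # invariance under an arbitrary global rigid motion
    R <- rot_axis(runif(3, -1, 1), runif(1, 0, 360)); t <- runif(3, -50, 50)
    expect_equal(unname(step_params(transform_frame(fs$f1, R, t),
                                    transform_frame(fs$f2, R, t))),
                 p, tolerance = 1e-8)
  }
  # pure translation along the normal: rise only
  f1 <- list(origin = c(0, 0, 0), axes = diag(3))
  f2 <- list(origin = c(0, 0, 3.4), axes = diag(3))
  expect_equal(unname(step_params(f1, f2)), c(0, 0, 3.4, 0, 0, 0))
  # swapping the units negates the twist
  fs <- frame_step_inverse(rise = 3.4, twist = 30)
  expect_equal(unname(step_params(fs$f2, fs$f1)["twist"]), -30,
               tolerance = 1e-9)
})

test_that("injected helical parameters are recovered from generated stacks", {
  st <- build_quartet_stack(rep("GC_PAIR", 3), rise = 3.4, twist = 25)
  ss <- stack_steps(get_model(st$ensemble, 1), st$truth$residues)
  expect_equal(ss$steps$rise, c(3.4, 3.4), tolerance = 1e-6)
  expect_equal(ss$steps$twist, c(25, 25), tolerance = 1e-6)

  # property sweep over the generator's parameter ranges
  set.seed(9)
  for (k in 1:12) {
    ri <- runif(1, 2.5, 5.5); tw <- runif(1, -60, 60)
    bu <- runif(1, -40, 40); pr <- runif(1, -40, 40)
    st <- build_quartet_stack(c("GC_PAIR", "GC_PAIR"), rise = ri, twist = tw,
                              buckle = c(bu, 0), propeller = c(pr, 0))
    m <- get_model(st$ensemble, 1)
    ss <- stack_steps(m, st$truth$residues)
    expect_lt(abs(ss$steps$rise[1] - ri), 0.1)
    expect_lt(abs(ss$steps$twist[1] - tw), 0.1)
    fA <- fit_base_frame(m[m$chain == "A" & m$resno == 1, ])
    fB <- fit_base_frame(m[m$chain == "B" & m$resno == 1, ])
    pp <- pair_params(fA, fB)
    expect_lt(abs(pp["buckle"] - bu), 0.1)
    expect_lt(abs(pp["propeller"] - pr), 0.1)
  }
})

test_that("pair parameters recover a 28-degree buckle with zero propeller", {
  st <- build_quartet_stack("GC_PAIR", buckle = 28, propeller = 0)
  m <- get_model(st$ensemble, 1)
  fA <- fit_base_frame(m[m$chain == "A", ])
  fB <- fit_base_frame(m[m$chain == "B", ])
  pp <- pair_params(fA, fB)
  expect_equal(unname(pp["buckle"]), 28, tolerance = 0.1)
  expect_equal(unname(pp["propeller"]), 0, tolerance = 0.1)
})

test_that("quartet buckle equals the injected inter-pair plane angle", {
  res4 <- list(c("A", 1), c("B", 1), c("C", 1), c("D", 1))
  for (cl in c("GAGA", "GGGG", "GCGC_MINOR")) {
    st0 <- build_quartet_stack(cl)
    qp0 <- quartet_params(get_model(st0$ensemble, 1), res4)
    expect_lt(qp0$quartet_buckle, 0.1)
    expect_lt(qp0$plane_rmsd, 0.1)
    st <- build_quartet_stack(cl, buckle = 15)
    qp <- quartet_params(get_model(st$ensemble, 1), res4)
    expect_equal(qp$quartet_buckle, 15, tolerance = 0.1)
  }
})

test_that("pseudorotation closed form and classification behave canonically", {
  # generate endocyclic torsions from the defining relation
  # nu_j = tau_m cos(P + 144 (j - 2)) and invert them
  for (P in c(18, 162, 90, 340)) {
    nu <- vapply(0:4, function(j) 38 * cos(pi / 180 * (P + 144 * (j - 2))),
                 numeric(1))
    pk <- pseudorotation(nu)
    expect_equal(pk$phase, P, tolerance = 1e-9)
    expect_equal(pk$amplitude, 38, tolerance = 1e-9)
  }
  expect_identical(pucker_class(162), "South")    # C2'-endo
  expect_identical(pucker_class(9), "North")      # C3'-endo
  expect_identical(pucker_class(340), "North")
  expect_identical(pucker_class(90), "other")
})

test_that("glycosidic torsion classes follow the documented windows", {
  expect_identical(chi_class(60), "syn")
  expect_identical(chi_class(-150 %% 360), "anti")   # 210
  expect_identical(chi_class(170), "anti")
  expect_identical(chi_class(280), "anti")
  expect_identical(chi_class(300), "high_anti")
  expect_identical(chi_class(330), "other")
})

test_that("torsion profiles are computed for backbone-bearing models", {
  st <- build_quartet_stack(rep("GC_PAIR", 3), rise = 3.4, twist = 36,
                            backbone = TRUE)
  m <- get_model(st$ensemble, 1)
  tt <- torsion_table(m)
  expect_equal(nrow(tt), 6)
  expect_true(all(tt$chi_class == "anti"))
  expect_true(all(is.finite(tt$pucker_phase)))
  # terminal residues: no 5' neighbour means no alpha
  first_a <- tt[tt$chain == "A" & tt$resno == 1, ]
  expect_true(is.na(first_a$alpha))
  mid_a <- tt[tt$chain == "A" & tt$resno == 2, ]
  expect_false(is.na(mid_a$alpha))
  # bases-only models are skipped, not an error
  m2 <- get_model(build_quartet_stack("GC_PAIR")$ensemble, 1)
  expect_equal(nrow(torsion_table(m2)), 0)
  expect_error(torsion_profile(m2[m2$chain == "A", ]), "missing sugar")
})

test_that("groove widths follow the P-P minus 5.8 convention", {
  st <- build_quartet_stack(rep("GC_PAIR", 10), rise = 3.4, twist = 36,
                            backbone = TRUE)
  m <- get_model(st$ensemble, 1)
  gw <- groove_widths(m)
  expect_equal(gw$width, gw$p_p_distance - 5.8)
  expect_true(all(gw$label[gw$width < 4] == "narrow"))
  expect_true(all(gw$label[gw$width > 9] == "wide"))
  # canonical B-form-like duplex: the close-approach (minor groove) side
  # is narrower than the far (major groove) side
  off <- gw$res_a - gw$res_b
  minor <- min(gw$width[off >= 1 & off <= 4])
  major <- min(gw$width[off <= -2 & off >= -6])
  expect_lt(minor, major)
  # symmetric stack gives a symmetric width profile
  agg <- stats::aggregate(width ~ off, data.frame(width = gw$width, off = off),
                          min)
  prof <- agg$width[order(agg$off)]
  # offsets k and -k related by the duplex pseudo-symmetry need not be
  # identical here (hetero pair), but the profile must be smooth and finite
  expect_true(all(is.finite(prof)))
})

test_that("ensemble statistics aggregate mean and zero SD for identical models", {
  st <- build_quartet_stack(c("GC_PAIR", "GC_PAIR"), n_models = 4)
  tabs <- lapply(1:4, function(m) {
    mm <- get_model(st$ensemble, m)
    ss <- stack_steps(mm, st$truth$residues)
    ss$steps
  })
  es <- ensemble_stats(tabs)
  expect_equal(es$twist_mean, 25, tolerance = 1e-6)
  expect_equal(es$twist_sd, 0, tolerance = 1e-9)
  st2 <- build_quartet_stack(c("GC_PAIR", "GC_PAIR"), n_models = 4,
                             noise_sigma = 0.05, seed = 2)
  tabs2 <- lapply(1:4, function(m)
    stack_steps(get_model(st2$ensemble, m), st2$truth$residues)$steps)
  es2 <- ensemble_stats(tabs2)
  expect_gt(es2$twist_sd, 0)
  expect_equal(es2$twist_mean, 25, tolerance = 2)
})

test_that("all geometry parameters are invariant under global rigid motion", {
  st <- build_quartet_stack(c("GAGA", "GAGA"), rise = 3.4, twist = 25)
  ens <- st$ensemble
  R <- rot_axis(c(1, 2, 3), 77)
  tr <- c(11, -5, 40)
  ens2 <- ens
  ens2$coords[[1]] <- t(R %*% t(ens$coords[[1]])) +
    rep(tr, each = nrow(ens$coords[[1]]))
  s1 <- stack_steps(get_model(ens, 1), st$truth$residues)$steps
  s2 <- stack_steps(get_model(ens2, 1), st$truth$residues)$steps
  expect_equal(as.matrix(s1[, 3:8]), as.matrix(s2[, 3:8]), tolerance = 1e-6)
  res4 <- list(c("A", 1), c("B", 1), c("C", 1), c("D", 1))
  q1 <- quartet_params(get_model(ens, 1), res4)
  q2 <- quartet_params(get_model(ens2, 1), res4)
  expect_equal(q1$quartet_buckle, q2$quartet_buckle, tolerance = 1e-6)
})
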