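test_that("idealized Watson-Crick G-C pair yields its three hydrogen bonds", {
  m <- get_model(build_quartet_stack("GC_PAIR")$ensemble, 1)
  hb <- find_hbonds(m)
  sig <- sort(paste(hb$restype_d, hb$donor, hb$restype_a, hb$acceptor))
  expect_identical(sig, sort(c("DG N1 DC N3", "DG N2 DC O2", "DC N4 DG O6")))
  expect_true(all(hb$distance <= 3.5))
  expect_true(all(hb$theta >= 120))
})

test_that("G-A pair shows exactly the N1-N7 / carbonyl-amino bond pattern", {
  m <- get_model(build_quartet_stack("GA_PAIR")$ensemble, 1)
  hb <- find_hbonds(m)
  sig <- sort(paste(hb$restype_d, hb$donor, hb$restype_a, hb$acceptor))
  expect_identical(sig, sort(c("DG N1 DA N7", "DA N6 DG O6")))
})

test_that("distant bases produce no hydrogen bonds", {
  st <- build_quartet_stack(c("GC_PAIR", "GC_PAIR"), rise = 10)
  m <- get_model(st$ensemble, 1)
  hb <- find_hbonds(m)
  expect_true(all(paste(hb$res_d) == paste(hb$res_a)))  # only intra-layer
  m1 <- m[m$resno == 1 & m$chain == "A", ]
  m2 <- m[m$resno == 2 & m$chain == "B", ]
  expect_equal(nrow(find_hbonds(rbind(m1, m2))), 0)
})

test_that("pair classification matches the generated class for every type", {
  expected <- c(GC_PAIR = "WC_GC", GG_PAIR = "GG_N1_CARBONYL",
                GA_PAIR = "GA_N1N7_CARBONYLAMINO", GI_PAIR = "G_I_HOOGSTEEN")
  for (cl in names(expected)) {
    m <- get_model(build_quartet_stack(cl)$ensemble, 1)
    hb <- find_hbonds(m)
    p <- find_pairs(m, hb)
    expect_identical(p$class, unname(expected[cl]), info = cl)
    # symmetry in residue order
    a <- classify_pair(m, c("A", 1), c("B", 1), hb)
    b <- classify_pair(m, c("B", 1), c("A", 1), hb)
    expect_identical(a$class, b$class, info = cl)
    expect_equal(a$n_hbonds, b$n_hbonds, info = cl)
  }
})

test_that("quartet assembly recovers every generated quartet class", {
  for (cl in c("GAGA", "GGGG", "GCGC_MINOR", "GCGC_MAJOR")) {
    m <- get_model(build_quartet_stack(cl)$ensemble, 1)
    hb <- find_hbonds(m)
    q <- assemble_quartets(m, find_pairs(m, hb), hb)
    expect_equal(nrow(q), 1, info = cl)
    expect_identical(q$quartet_class, cl)
  }
})

test_that("classification survives 0.15 Angstrom coordinate noise", {
  for (cl in c("GAGA", "GGGG", "GCGC_MINOR", "GCGC_MAJOR")) {
    st <- build_quartet_stack(cl, noise_sigma = 0.15, seed = 11, n_models = 3)
    for (mm in 1:3) {
      m <- get_model(st$ensemble, mm)
      hb <- find_hbonds(m)
      q <- assemble_quartets(m, find_pairs(m, hb), hb)
      expect_true(cl %in% q$quartet_class, info = paste(cl, mm))
    }
  }
})

test_that("shuffled-coordinate decoys contain no quartets", {
  st <- build_quartet_stack("GAGA")
  ens <- st$ensemble
  set.seed(4)
  ens$coords[[1]] <- ens$coords[[1]][sample(nrow(ens$coords[[1]])), ]
  m <- get_model(ens, 1)
  hb <- find_hbonds(m)
  q <- assemble_quartets(m, find_pairs(m, hb), hb)
  expect_equal(sum(q$quartet_class %in%
                     c("GAGA", "GGGG", "GCGC_MINOR", "GCGC_MAJOR")), 0)
})

test_that("crisscross couples are detected above the twist threshold only", {
  st <- build_quartet_stack(c("GG_PAIR", "GG_PAIR"), rise = 3.4, twist = 55)
  m <- get_model(st$ensemble, 1)
  pr <- find_pairs(m)
  cc <- detect_crisscross(m, pr)
  expect_equal(nrow(cc), 1)
  expect_equal(abs(cc$twist), 55, tolerance = 0.5)
  st2 <- build_quartet_stack(c("GG_PAIR", "GG_PAIR"), rise = 3.4, twist = 20)
  m2 <- get_model(st2$ensemble, 1)
  expect_equal(nrow(detect_crisscross(m2, find_pairs(m2))), 0)
})

test_that("reports are deterministic for identical inputs", {
  st <- build_quartet_stack(c("GAGA", "GCGC_MINOR"), noise_sigma = 0.1,
                            seed = 21)
  m <- get_model(st$ensemble, 1)
  r1 <- find_pairs(m)
  r2 <- find_pairs(m)
  expect_identical(r1, r2)
  hb <- find_hbonds(m)
  expect_identical(assemble_quartets(m, r1, hb),
                   assemble_quartets(m, r2, hb))
})

test_that("consensus keeps entries present in at least half the models", {
  t1 <- data.frame(chain_i = "A", res_i = 1, chain_j = "B", res_j = 1,
                   class = "WC_GC", stringsAsFactors = FALSE)
  t2 <- rbind(t1, data.frame(chain_i = "A", res_i = 2, chain_j = "B",
                             res_j = 2, class = "OTHER",
                             stringsAsFactors = FALSE))
  cons <- consensus_table(list(t1, t2, t2, t1),
                          c("chain_i", "res_i", "chain_j", "res_j", "class"))
  expect_equal(nrow(cons), 2)
  cons2 <- consensus_table(list(t1, t1, t1, t2),
                           c("chain_i", "res_i", "chain_j", "res_j", "class"),
                           frac = 0.5)
  expect_equal(nrow(cons2), 1)
})
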