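test_that("dihedral matches a constructed right angle and the rotational oracle", {
  a <- c(1, 0, 0); b <- c(0, 0, 0); c_ <- c(0, 1, 0); d <- c(0, 1, 1)
  expect_equal(dihedral_angle(a, b, c_, d), -90, tolerance = 1e-10)
  expect_equal(dihedral_angle(a, b, c_, c(0, 1, -1)), 90, tolerance = 1e-10)
  set.seed(42)
  for (k in 1:50) {
    pts <- matrix(rnorm(12, sd = 3), 4, 3)
    # reject nearly degenerate configurations the oracle cannot resolve
    if (abs(dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])) > 178) next
    expect_lt(abs(dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ]) -
                    oracle_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])),
              1e-6)
  }
})

test_that("torsions are rigid-motion invariant and terminal torsions undefined", {
  m <- build_fiber_bdna("ACGTACGTT")
  t1 <- backbone_torsions(m)
  t2 <- backbone_torsions(random_rigid_motion(m, seed = 7))
  cols <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "chi")
  for (cc in cols)
    expect_equal(t1[[cc]], t2[[cc]], tolerance = 1e-6)
  # chain 5' ends have no phosphate: alpha/beta undefined, never zero
  first <- t1[!duplicated(t1$chain), ]
  expect_true(all(is.na(first$alpha)))
  expect_true(all(is.na(first$beta)))
  # chain 3' ends have no next phosphate: epsilon/zeta undefined
  last <- t1[rev(!duplicated(rev(t1$chain))), ]
  expect_true(all(is.na(last$epsilon)))
  expect_true(all(is.na(last$zeta)))
})

test_that("backbone substate classification follows eps - zeta bands", {
  # canonical B_I: eps trans, zeta gauche-
  expect_equal(as.character(classify_backbone_state(wrap_angle(-170 - (-90)))), "BI")
  # canonical B_II: wrapped difference +90
  expect_equal(as.character(classify_backbone_state(wrap_angle(-100 - 170))), "BII")
  expect_equal(as.character(classify_backbone_state(c(0, NA, 44.9, -44.9))),
               c("intermediate", "undefined", "intermediate", "intermediate"))
  # monotone: increasing eps - zeta never moves BII -> BI
  grid <- seq(-179.5, 180, by = 0.5)
  st <- as.integer(factor(classify_backbone_state(grid),
                          levels = c("BI", "intermediate", "BII")))
  expect_true(all(diff(st) >= 0))
  # band is configurable
  expect_equal(as.character(classify_backbone_state(50, band = 60)), "intermediate")
})

test_that("base pair detection finds the full duplex and nothing else", {
  m <- build_fiber_bdna(hmpa1_seq)
  pairs <- detect_base_pairs(m)
  expect_equal(nrow(pairs), 23)
  expect_true(all(pairs$type == "WC"))
  # separation kills pairing
  a <- as.data.frame(m)
  a$x[a$chain == "B"] <- a$x[a$chain == "B"] + 50
  pairs0 <- detect_base_pairs(structure_model(a))
  expect_equal(nrow(pairs0), 0)
  # construction-implied pairing: residue i pairs N+1-i on the other strand
  set.seed(11)
  s <- random_sequence(12)
  p <- detect_base_pairs(build_fiber_bdna(s))
  expect_equal(nrow(p), 12)
  expect_equal(p$resno_d, 12 + 1 - p$resno_c)
})

test_that("base frames are fixed points, equivariant and match the quaternion oracle", {
  m <- build_fiber_bdna("ACGT")
  a <- as.data.frame(m)
  # a base placed exactly at the standard geometry fits the identity frame
  std <- ideal_base_geometry("G", with_c1 = TRUE)
  res <- data.frame(chain = "A", resno = 1, icode = "", resid = "DG",
                    elety = rownames(std), elem = dnareadout:::infer_element(rownames(std)),
                    x = std[, 1], y = std[, 2], z = std[, 3],
                    occ = 1, b = 0, alt = "")
  fr <- base_frame(res)
  expect_equal(fr$R, diag(3), tolerance = 1e-8)
  expect_equal(fr$origin, c(0, 0, 0), tolerance = 1e-8)
  expect_lt(fr$rmsd, 1e-8)
  # equivariance under a known rotation
  R <- dnareadout:::rotation_about(c(1, 2, 2), 53)
  res2 <- res
  xyz <- as.matrix(res[, c("x", "y", "z")]) %*% t(R)
  res2$x <- xyz[, 1]; res2$y <- xyz[, 2]; res2$z <- xyz[, 3]
  fr2 <- base_frame(res2)
  expect_equal(fr2$R, R %*% fr$R, tolerance = 1e-6)
  # rmsd agrees with the independent quaternion superposition oracle
  r5 <- a[a$chain == "A" & a$resno == 2, ]
  b <- dnareadout:::.base_letter(r5$resid[1])
  ring <- dnareadout:::.base_ring[[b]]
  X <- dnareadout:::.base_geom[[b]][ring, ]
  Y <- as.matrix(r5[match(ring, r5$elety), c("x", "y", "z")])
  Yn <- Y + matrix(rnorm(length(Y), sd = 0.05), nrow(Y), 3)  # perturb
  fitted <- dnareadout:::kabsch_fit(X, Yn)
  expect_equal(fitted$rmsd, oracle_superpose_rmsd(X, Yn), tolerance = 1e-6)
})

test_that("pair/step parameters invert the generator and are rigid-motion invariant", {
  m <- build_fiber_bdna("GATTACAGCA", twist = 34.5, rise = 3.30,
                        roll = 3, propeller = -12)
  geo <- bp_and_step_parameters(m)
  expect_equal(geo$steps$twist, rep(34.5, 9), tolerance = 1e-6)
  expect_equal(geo$steps$rise, rep(3.30, 9), tolerance = 1e-6)
  expect_equal(geo$steps$roll, rep(3, 9), tolerance = 1e-6)
  expect_equal(geo$pairs$propeller, rep(-12, 10), tolerance = 1e-6)
  geo2 <- bp_and_step_parameters(random_rigid_motion(m, seed = 3))
  for (cc in c("tilt", "roll", "twist", "shift", "slide", "rise"))
    expect_equal(geo$steps[[cc]], geo2$steps[[cc]], tolerance = 1e-6)
  for (cc in c("buckle", "propeller", "opening"))
    expect_equal(geo$pairs[[cc]], geo2$pairs[[cc]], tolerance = 1e-6)
})

test_that("region average roll reproduces construction and rejects empty regions", {
  m <- build_fiber_bdna("ACGTACGTACGT")
  geo <- bp_and_step_parameters(m)
  num <- assign_operator_numbering(m, center = list("A", 6))
  expect_equal(region_average_roll(geo, c(-3, 3), num), 0, tolerance = 1e-8)
  m2 <- build_fiber_bdna("ACGTACGTACGT", roll = 4)
  geo2 <- bp_and_step_parameters(m2)
  expect_equal(region_average_roll(geo2, c(-3, 3), num), 4, tolerance = 1e-6)
  expect_error(region_average_roll(geo, c(40, 50), num), "no complete step")
})
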