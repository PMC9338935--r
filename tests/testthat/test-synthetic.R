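test_that("fiber builder produces the printed duplex and its reverse complement", {
  m <- build_fiber_bdna(hmpa1_seq)
  pairs <- detect_base_pairs(m)
  expect_equal(nrow(pairs), 23)
  expect_true(all(pairs$type == "WC"))
  a <- as.data.frame(m)
  resB <- a[a$chain == "B", ]
  seqB <- paste(sub("^D", "", resB$resid[!duplicated(resB$resno)]), collapse = "")
  expect_equal(seqB, revcomp(hmpa1_seq))
  expect_equal(seqB, "AATTGGTAGATGATATTCGTGTT")
})

test_that("builder is deterministic and rejects invalid sequences", {
  m1 <- build_fiber_bdna("ACGTACGT")
  m2 <- build_fiber_bdna("ACGTACGT")
  expect_identical(as.data.frame(m1), as.data.frame(m2))
  expect_error(build_fiber_bdna("ACGX"), "position 4")
  expect_error(build_fiber_bdna("ACG"), "at least 4")
})

test_that("reverse-complement duplexes have mirrored step parameters", {
  set.seed(21)
  s <- random_sequence(10)
  rolls <- round(runif(9, -4, 4), 2)
  g1 <- bp_and_step_parameters(build_fiber_bdna(s, roll = rolls))
  g2 <- bp_and_step_parameters(build_fiber_bdna(revcomp(s), roll = rev(rolls)))
  expect_equal(g2$steps$roll, rev(g1$steps$roll), tolerance = 1e-6)
  expect_equal(g2$steps$twist, rev(g1$steps$twist), tolerance = 1e-6)
})

test_that("step perturbations are recovered and identity is a no-op", {
  m <- build_fiber_bdna("ACGTACGTACGTA")
  expect_identical(apply_step_perturbations(m), m)
  p <- apply_step_perturbations(m, step_overrides = data.frame(
    step = c(4, 7), roll = c(5, -3), twist = c(33, 39)))
  geo <- bp_and_step_parameters(p)
  expect_equal(geo$steps$roll[c(4, 7)], c(5, -3), tolerance = 1e-6)
  expect_equal(geo$steps$twist[c(4, 7)], c(33, 39), tolerance = 1e-6)
  expect_equal(geo$steps$roll[-c(4, 7)], rep(0, 10), tolerance = 1e-6)
  expect_error(apply_step_perturbations(m, step_overrides = data.frame(
    step = 99, roll = 1)), "outside")
})

test_that("epsilon/zeta overrides flip exactly the requested substates", {
  m <- build_fiber_bdna(hmpa1_seq)
  ov <- data.frame(chain = c("A", "A", "B", "B"), resno = c(12, 14, 10, 12),
                   value = 90)
  p <- apply_step_perturbations(m, eps_zeta_overrides = ov)
  tor <- backbone_torsions(p)
  st <- classify_backbone_state(tor)
  expect_equal(sum(st == "BII"), 4)
  for (k in seq_len(nrow(ov))) {
    got <- tor$eps_minus_zeta[tor$chain == ov$chain[k] & tor$resno == ov$resno[k]]
    expect_equal(got, 90, tolerance = 1e-6)
  }
  # every other nucleotide keeps its B_I backbone
  untouched <- !(paste(tor$chain, tor$resno) %in% paste(ov$chain, ov$resno))
  expect_true(all(st[untouched & !is.na(tor$eps_minus_zeta)] == "BI"))
  # only the four phosphate groups moved
  a0 <- as.data.frame(m); a1 <- as.data.frame(p)
  moved <- which(abs(a0$x - a1$x) + abs(a0$y - a1$y) + abs(a0$z - a1$z) > 1e-9)
  expect_true(all(a0$elety[moved] %in% c("P", "OP1", "OP2")))
  expect_equal(length(unique(paste(a0$chain[moved], a0$resno[moved]))), 4)
})

test_that("probe groups are placed at the requested closest distance", {
  duplex <- build_fiber_bdna("ACGTACGTACGT")
  cplx <- make_probe_complex(duplex, data.frame(
    type = c("point", "ARG", "HIS"), index = c(2, 0, -2), strand = "c",
    groove = c("backbone", "minor", "backbone"), distance = c(3.2, 2.5, 3.1)))
  prot <- as.data.frame(select_component(cplx, "protein"))
  dna <- as.data.frame(select_component(cplx, "dna"))
  D <- sqrt(outer(rowSums(prot[, c("x", "y", "z")]^2),
                  rowSums(dna[, c("x", "y", "z")]^2), "+") -
              2 * as.matrix(prot[, c("x", "y", "z")]) %*%
                t(as.matrix(dna[, c("x", "y", "z")])))
  for (k in 1:3) {
    sub <- D[prot$resno == k, , drop = FALSE]
    expect_equal(min(sub), c(3.2, 2.5, 3.1)[k], tolerance = 0.05)
  }
  # infeasible placements are an error
  expect_error(make_probe_complex(duplex, data.frame(
    type = "point", index = 0, strand = "c", groove = "minor",
    distance = -1)), "positive")
})

test_that("probe fixtures drive the contact and clash rules as constructed", {
  duplex <- build_fiber_bdna("ACGTACGTACGTA")
  # point atom at 3.2 A from a phosphate oxygen: exactly one contact
  c1 <- make_probe_complex(duplex, data.frame(
    type = "point", index = 1, strand = "c", groove = "backbone",
    distance = 3.2, atom = "OP1"))
  ct <- enumerate_contacts(select_component(c1, "protein"),
                           select_component(c1, "dna"), cutoff = 3.8)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$distance, 3.2, tolerance = 0.05)
  # ARG-like probe deep in the minor groove: at least one clash
  c2 <- make_probe_complex(duplex, data.frame(
    type = "ARG", index = 0, strand = "c", groove = "minor", distance = 2.5))
  cs <- clash_scan(c2, select_component(c2, "protein"))
  expect_gte(attr(cs, "n_repulsive"), 1)
  # HIS-like probe N at 3.1 A from a phosphate O: salt bridge
  c3 <- make_probe_complex(duplex, data.frame(
    type = "HIS", index = 2, strand = "c", groove = "backbone",
    distance = 3.1, atom = "OP2"))
  ct3 <- classify_contacts(enumerate_contacts(select_component(c3, "protein"),
                                              select_component(c3, "dna")))
  expect_true("salt_bridge" %in% ct3$class)
})
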