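test_that("idealized base geometries carry the expected atom inventories", {
  expect_true("C7" %in% rownames(ideal_base_geometry("T")))
  expect_equal(nrow(ideal_base_geometry("A")), 10)  # purine ring + N6
  expect_error(ideal_base_geometry("X"), "unknown base")
  # bonded ring neighbors sit at covalent distances (self-consistency)
  for (b in c("A", "C", "G", "T")) {
    ring <- dnareadout:::.base_ring[[b]]
    g <- ideal_base_geometry(b)
    for (k in seq_along(ring)) {
      nxt <- ring[if (k == length(ring)) 1 else k + 1]
      d <- sqrt(sum((g[ring[k], ] - g[nxt, ])^2))
      expect_true(d > 1.28 && d < 1.50)
    }
  }
})

test_that("identity threading changes nothing, including contact classes", {
  duplex <- build_fiber_bdna("ACGTACGTACGT")
  cplx <- make_probe_complex(duplex, data.frame(
    type = "ARG", index = 0, strand = "c", groove = "minor", distance = 3.0))
  num <- assign_operator_numbering(select_component(cplx, "dna"),
                                   center = list("A", 6))
  own <- data.frame(index = -2:2,
                    base = strsplit("TACGT", "")[[1]])
  th <- thread_operator_sequence(cplx, own, numbering = num)
  expect_true(all(!th$changes$replaced))
  expect_identical(plain_atoms(th$model), plain_atoms(cplx))
  before <- classify_contacts(enumerate_contacts(
    select_component(cplx, "protein"), select_component(cplx, "dna")))
  after <- classify_contacts(enumerate_contacts(
    select_component(th$model, "protein"), select_component(th$model, "dna")))
  expect_equal(before$class, after$class)
})

test_that("threading rebuilds bases but never touches the backbone", {
  duplex <- build_fiber_bdna("ACGTACGTACGT")
  num <- assign_operator_numbering(duplex, center = list("A", 6))
  th <- thread_operator_sequence(duplex, data.frame(index = 0, base = "T"),
                                 numbering = num)
  ch <- th$changes
  expect_equal(ch$replaced, c(TRUE, TRUE))
  expect_equal(ch$new_base[ch$strand == "d"], "A")  # complementarity enforced
  a0 <- as.data.frame(duplex); a1 <- as.data.frame(th$model)
  bbnames <- c(rownames(dnareadout:::.backbone_geom), "C1'")
  b0 <- a0[a0$elety %in% bbnames, ]
  b1 <- a1[a1$elety %in% bbnames, ]
  expect_equal(nrow(b0), nrow(b1))
  k0 <- paste(b0$chain, b0$resno, b0$elety)
  expect_identical(unname(as.matrix(b0[, c("x", "y", "z")])),
                   unname(as.matrix(b1[match(k0, paste(b1$chain, b1$resno, b1$elety)),
                                       c("x", "y", "z")])))
  # a C -> T substitution gains the C7 methyl absent from the template
  a_new <- a1[a1$chain == "A" & a1$resno == 6, ]
  expect_true("C7" %in% a_new$elety)
  expect_equal(unique(a_new$resid), "DT")
  # replaced bases carry the complete standard heavy-atom set
  expect_setequal(setdiff(a_new$elety, bbnames), rownames(ideal_base_geometry("T")))
})

test_that("threaded bases keep near-ideal pair geometry in the pairing frame", {
  duplex <- build_fiber_bdna("ACGTACGTACGT")
  num <- assign_operator_numbering(duplex, center = list("A", 6))
  th <- thread_operator_sequence(duplex, data.frame(index = 1, base = "C"),
                                 numbering = num)
  pairs <- detect_base_pairs(th$model)
  expect_equal(nrow(pairs), 12)  # the swapped pair still pairs as WC
  expect_true(all(pairs$type == "WC"))
})

test_that("clash verdicts apply the steric cutoff and are monotone in it", {
  duplex <- build_fiber_bdna("ACGTACGTACGT")
  cplx <- make_probe_complex(duplex, data.frame(
    type = "point", index = 0, strand = "c", groove = "minor", distance = 2.5))
  cs <- clash_scan(cplx, select_component(cplx, "protein"))
  expect_equal(attr(cs, "n_repulsive"), 1)
  expect_equal(min(cs$distance[cs$verdict == "repulsive"]), 2.5,
               tolerance = 0.05)
  # raising the cutoff never removes a repulsive record
  cuts <- c(2.0, 2.85, 3.2, 4.0)
  reps <- lapply(cuts, function(cc)
    which(clash_scan(cplx, select_component(cplx, "protein"),
                     repulsive = cc)$verdict == "repulsive"))
  for (k in seq_len(length(cuts) - 1))
    expect_true(all(reps[[k]] %in% reps[[k + 1]]))
  # N/O pairs in the 2.6-2.85 window are flagged possible H-bonds
  c2 <- make_probe_complex(duplex, data.frame(
    type = "LYS", index = 2, strand = "c", groove = "minor", distance = 2.7))
  cs2 <- clash_scan(c2, select_component(c2, "protein"))
  rep2 <- cs2[cs2$verdict == "repulsive", ]
  polar <- rep2$p_elem == "N" & rep2$d_elem %in% c("N", "O") &
    rep2$distance >= 2.6
  expect_equal(rep2$possible_hbond[polar], rep(TRUE, sum(polar)))
})
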