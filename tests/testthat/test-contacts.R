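two_atom_models <- function(d, p_resid = "GLY", p_atom = "CA", p_elem = "C",
                            d_resid = "DA", d_atom = "N1", d_elem = "N") {
  p <- structure_model(data.frame(chain = "X", resno = 1, icode = "",
                                  resid = p_resid, elety = p_atom, elem = p_elem,
                                  x = 0, y = 0, z = 0, occ = 1, b = 0, alt = ""))
  q <- structure_model(data.frame(chain = "A", resno = 1, icode = "",
                                  resid = d_resid, elety = d_atom, elem = d_elem,
                                  x = d, y = 0, z = 0, occ = 1, b = 0, alt = ""))
  list(p = p, q = q)
}

test_that("contact enumeration finds exactly the pairs under the cutoff", {
  m <- two_atom_models(3.0)
  ct <- enumerate_contacts(m$p, m$q)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$distance, 3.0, tolerance = 1e-12)
  # threshold bracketing: 3.5 is vdw, 3.9 is out
  m2 <- two_atom_models(3.5, d_atom = "C2", d_elem = "C")
  ct2 <- classify_contacts(enumerate_contacts(m2$p, m2$q))
  expect_equal(ct2$class, "vdw")
  m3 <- two_atom_models(3.9, d_atom = "C2", d_elem = "C")
  expect_equal(nrow(enumerate_contacts(m3$p, m3$q)), 0)
  expect_error(enumerate_contacts(m$p, select_component(m$q, "protein")))
})

test_that("classification follows the polar and salt-bridge rules", {
  # main-chain N to OP1 at 2.9 A: H-bond with main-chain flag
  m <- two_atom_models(2.9, p_resid = "LYS", p_atom = "N", p_elem = "N",
                       d_atom = "OP1", d_elem = "O")
  ct <- classify_contacts(enumerate_contacts(m$p, m$q))
  expect_equal(ct$class, "hbond")
  expect_true(ct$p_mainchain)
  expect_equal(ct$moiety, "phosphate")
  # His side-chain NE2 to phosphate O at 3.1 A: possible salt bridge
  m2 <- two_atom_models(3.1, p_resid = "HIS", p_atom = "NE2", p_elem = "N",
                        d_atom = "OP2", d_elem = "O")
  ct2 <- classify_contacts(enumerate_contacts(m2$p, m2$q))
  expect_equal(ct2$class, "salt_bridge")
  expect_equal(ct2$qualifier, "possible")
  expect_false(ct2$p_mainchain)
  # Arg NH1 to phosphate O: salt bridge without the qualifier
  m3 <- two_atom_models(3.0, p_resid = "ARG", p_atom = "NH1", p_elem = "N",
                        d_atom = "OP1", d_elem = "O")
  expect_equal(classify_contacts(enumerate_contacts(m3$p, m3$q))$class,
               "salt_bridge")
  # polar pair beyond 3.3 A falls back to vdw
  m4 <- two_atom_models(3.5, p_atom = "N", p_elem = "N",
                        d_atom = "O2", d_elem = "O")
  expect_equal(classify_contacts(enumerate_contacts(m4$p, m4$q))$class, "vdw")
})

test_that("every polar class also satisfies the vdw distance criterion", {
  duplex <- build_fiber_bdna("ACGTACGTACGTAC")
  cplx <- make_probe_complex(duplex, data.frame(
    type = c("HIS", "ARG", "point"), index = c(-3, 0, 3),
    strand = "c", groove = c("backbone", "minor", "major"),
    distance = c(3.1, 3.0, 3.4)))
  ct <- classify_contacts(enumerate_contacts(select_component(cplx, "protein"),
                                             select_component(cplx, "dna")))
  expect_true(all(ct$distance < 3.8))
  expect_true(all(ct$distance[ct$class %in% c("hbond", "salt_bridge")] <= 3.3))
})

test_that("enumeration equals the brute-force all-pairs oracle and is symmetric", {
  duplex <- build_fiber_bdna("ACGTACGTAC")
  cplx <- make_probe_complex(duplex, data.frame(
    type = "ARG", index = c(-1, 2), strand = c("c", "d"),
    groove = "minor", distance = c(2.8, 3.5)))
  prot <- select_component(cplx, "protein")
  dna <- select_component(cplx, "dna")
  ct <- enumerate_contacts(prot, dna, cutoff = 3.8)
  bf <- oracle_contacts(prot, dna, cutoff = 3.8)
  expect_equal(nrow(ct), if (is.null(bf)) 0 else nrow(bf))
  expect_equal(sort(ct$distance), sort(bf$d), tolerance = 1e-12)
  ct_swapped <- enumerate_contacts(dna, prot, cutoff = 3.8)
  expect_equal(nrow(ct_swapped), nrow(ct))
  expect_equal(sort(ct_swapped$distance), sort(ct$distance), tolerance = 1e-12)
})

test_that("contact summary aggregates per residue and per nucleotide", {
  duplex <- build_fiber_bdna("ACGTACGTACGT")
  cplx <- make_probe_complex(duplex, data.frame(
    type = c("ARG", "HIS"), index = c(0, 2), strand = "c",
    groove = c("minor", "backbone"), distance = c(3.0, 3.1)))
  prot <- select_component(cplx, "protein")
  num <- assign_operator_numbering(select_component(cplx, "dna"),
                                  center = list("A", 6))
  ct <- classify_contacts(enumerate_contacts(prot, select_component(cplx, "dna"),
                                             numbering = num))
  s <- summarize_contacts(ct, protein = prot)
  expect_equal(sum(s$per_residue$n), nrow(ct))
  expect_equal(sum(s$per_nucleotide$n), nrow(ct))
  expect_true(all(c("hbond", "salt_bridge", "vdw") %in% names(s$per_residue)))
  # the probe fragments are incomplete side chains and flagged as such
  expect_true(all(s$per_residue$incomplete_side_chain))
})
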