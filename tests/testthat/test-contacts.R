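two_atom_pair <- function(d) {
  a <- toy_model(matrix(c(0, 0, 0), 1), chain = "A")
  b <- toy_model(matrix(c(d, 0, 0), 1), chain = "B")
  list(a = a, b = b)
}

test_that("the vdW criteria classify carbon pairs as in the defining formula", {
  # Bondi carbon radius 1.70: interface cut 1.1 * 3.40 = 3.74, collision cut 1.70
  p <- two_atom_pair(3.60)
  r <- find_contacts(p$a, p$b)
  expect_equal(r$counts$n_interface_pairs, 1L)
  expect_equal(r$counts$n_collision_pairs, 0L)

  p <- two_atom_pair(1.60)
  r <- find_contacts(p$a, p$b)
  expect_equal(r$counts$n_interface_pairs, 1L)
  expect_equal(r$counts$n_collision_pairs, 1L)

  # strict inequality at both boundaries (dyadic radii so the cuts are exact)
  cfg <- contact_config(radii = c(C = 1.0), interface_factor = 2,
                        collision_factor = 0.5)
  at_cut <- two_atom_pair(4.0)    # d == 2 * (1 + 1): not an interface
  expect_equal(find_contacts(at_cut$a, at_cut$b, cfg)$counts$n_interface_pairs, 0L)
  at_coll <- two_atom_pair(1.0)   # d == 0.5 * (1 + 1): interface, not a collision
  r <- find_contacts(at_coll$a, at_coll$b, cfg)
  expect_equal(r$counts$n_interface_pairs, 1L)
  expect_equal(r$counts$n_collision_pairs, 0L)
})

test_that("distant molecules give an empty report and an empty residue table", {
  p <- two_atom_pair(100)
  r <- find_contacts(p$a, p$b)
  expect_equal(r$counts$n_interface_pairs, 0L)
  expect_equal(nrow(interface_residue_table(r)), 0L)
})

test_that("hydrogens join the interface but are excluded from collisions by default", {
  a <- toy_model(matrix(c(0, 0, 0), 1), chain = "A", element = "H")
  b <- toy_model(matrix(c(0.5, 0, 0), 1), chain = "B", element = "C")
  r <- find_contacts(a, b)
  expect_equal(r$counts$n_interface_pairs, 1L)
  expect_equal(r$counts$n_collision_pairs, 0L)
  cfg <- contact_config(collision_excludes_hydrogen = FALSE)
  expect_equal(find_contacts(a, b, cfg)$counts$n_collision_pairs, 1L)
})

test_that("unknown elements error unless a default radius is supplied", {
  a <- toy_model(matrix(c(0, 0, 0), 1), chain = "A", element = "XX")
  b <- toy_model(matrix(c(3, 0, 0), 1), chain = "B")
  expect_error(find_contacts(a, b), "XX")
  cfg <- contact_config(default_radius = 1.7)
  expect_equal(find_contacts(a, b, cfg)$counts$n_interface_pairs, 1L)
})

test_that("config invariants are enforced", {
  expect_error(contact_config(interface_factor = 0.4, collision_factor = 0.5),
               "collision_factor < interface_factor")
  expect_error(contact_config(radii = c(1.7, 1.5)), "named")
})

test_that("the grid method equals the all-pairs oracle on random molecule pairs", {
  withr::local_seed(77)
  for (i in 1:100) {
    a <- toy_model(matrix(rnorm(150, 0, 6), ncol = 3), chain = "A",
                   element = sample(c("C", "N", "O", "S"), 50, replace = TRUE))
    b <- toy_model(matrix(rnorm(150, 2, 6), ncol = 3), chain = "B",
                   element = sample(c("C", "N", "O", "H"), 50, replace = TRUE))
    g <- find_contacts(a, b, method = "grid")
    o <- find_contacts(a, b, method = "all_pairs")
    expect_identical(g$pairs, o$pairs)
    expect_identical(g$counts, o$counts)
  }
})

test_that("collision pairs are a subset of interface pairs (heavy atoms)", {
  withr::local_seed(91)
  for (i in 1:20) {
    a <- toy_model(matrix(rnorm(90, 0, 4), ncol = 3), chain = "A")
    b <- toy_model(matrix(rnorm(90, 1, 4), ncol = 3), chain = "B")
    r <- find_contacts(a, b)
    expect_true(all(r$pairs$distance < 1.1 * r$pairs$vdw_sum))
    cp <- dplyr::filter(r$pairs, collision)
    expect_true(all(cp$distance < 0.5 * cp$vdw_sum))
  }
})

test_that("reports are symmetric and rigid-motion invariant", {
  withr::local_seed(13)
  a <- toy_model(matrix(rnorm(60, 0, 3), ncol = 3), chain = "A")
  b <- toy_model(matrix(rnorm(60, 1, 3), ncol = 3), chain = "B")
  ab <- find_contacts(a, b)
  ba <- find_contacts(b, a)
  expect_equal(ab$counts$n_interface_pairs, ba$counts$n_interface_pairs)
  expect_equal(ab$counts$n_colliding_atoms_a, ba$counts$n_colliding_atoms_b)
  key_ab <- with(ab$pairs, sort(paste(resno_a, atom_a, resno_b, atom_b)))
  key_ba <- with(ba$pairs, sort(paste(resno_b, atom_b, resno_a, atom_a)))
  expect_identical(key_ab, key_ba)
  tf <- random_transform()
  r2 <- find_contacts(apply_transform(a, tf), apply_transform(b, tf))
  expect_equal(r2$counts, ab$counts)
  expect_equal(r2$pairs$distance, ab$pairs$distance, tolerance = 1e-9)
})

test_that("widening the interface factor never removes pairs", {
  withr::local_seed(19)
  a <- toy_model(matrix(rnorm(60, 0, 3), ncol = 3), chain = "A")
  b <- toy_model(matrix(rnorm(60, 1, 3), ncol = 3), chain = "B")
  key <- function(r) with(r$pairs, paste(resno_a, atom_a, resno_b, atom_b))
  narrow <- find_contacts(a, b, contact_config(interface_factor = 1.0))
  wide <- find_contacts(a, b, contact_config(interface_factor = 1.3))
  expect_true(all(key(narrow) %in% key(wide)))
})

test_that("the residue rollup lists exactly the touching residues", {
  a <- toy_model(rbind(c(0, 0, 0), c(20, 0, 0)), chain = "A", resno = c(1L, 2L))
  b <- toy_model(rbind(c(3, 0, 0), c(50, 0, 0)), chain = "B", resno = c(7L, 8L))
  tab <- interface_residue_table(find_contacts(a, b))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$resno[tab$molecule == "a"], 1L)
  expect_equal(tab$resno[tab$molecule == "b"], 7L)
  expect_equal(tab$partners[tab$molecule == "a"], "B7")
  expect_equal(tab$n_pairs, c(1L, 1L))
})

test_that("clash fixtures reproduce their planted counts exactly", {
  for (spec in list(c(0, 0), c(10, 2), c(5, 5), c(7, 0))) {
    fx <- make_clash_fixture(spec[1], spec[2], seed = 3)
    r <- find_contacts(dplyr::filter(fx$model, chain == "A"),
                       dplyr::filter(fx$model, chain == "B"))
    expect_equal(r$counts$n_interface_pairs, spec[1])
    expect_equal(r$counts$n_collision_pairs, spec[2])
    expect_equal(r$counts$n_colliding_atoms_a, spec[2])
  }
  expect_error(make_clash_fixture(2, 5), "infeasible")
})

test_that("minimum CA-CA distance is exact and validates input", {
  m <- struct_tbl(tibble::tibble(
    atom = "CA", chain = c("A", "A", "B"), resno = c(1L, 2L, 1L), resid = "GLY",
    element = "C", x = c(0, 3, 0), y = c(0, 4, 12), z = 0))
  pairs <- tibble::tibble(chain_a = "A", resno_a = 1:2, chain_b = "B", resno_b = 1L)
  d <- min_ca_distance(m, pairs)
  expect_equal(as.numeric(d), sqrt(3^2 + 8^2))
  expect_equal(attr(d, "distances")$ca_distance, c(12, sqrt(73)))
  expect_error(min_ca_distance(m, pairs[0, ]), "empty")
  bad <- tibble::tibble(chain_a = "A", resno_a = 9L, chain_b = "B", resno_b = 1L)
  expect_error(min_ca_distance(m, bad), "missing CA")
})
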