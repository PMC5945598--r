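cofilactin_fixture <- function(n = 6, seed = 2) {
  make_decorated_filament(n_subunits = n, decorated = TRUE, seed = seed)
}

factin_fixture <- function(n = 6, seed = 2) {
  make_decorated_filament(n_subunits = n, decorated = FALSE, seed = seed)
}

ID_BODY <- residue_selection(1:10)
SD1_BODY <- residue_selection(11:20)

test_that("site extraction returns the planted barbed/pointed partner", {
  cf <- cofilactin_fixture()
  fx <- extract_site_complex(cf$filament, "F")
  info_f <- attr(fx, "site_complex")
  gx <- extract_site_complex(cf$filament, "G")
  info_g <- attr(gx, "site_complex")
  dec <- cf$truth$decoration
  expect_equal(info_f$subunit, dec$b_subunit[1])
  expect_equal(info_g$subunit, dec$p_subunit[1])
  expect_equal(info_g$subunit, info_f$subunit + 2L)   # same strand, two genetic steps
  expect_setequal(unique(fx$chain), c(info_f$actin_chain, info_f$cofilin_chain))
  # a specific cofilin can be requested
  x3 <- extract_site_complex(cf$filament, "F", cofilin_chain = dec$cofilin_chain[3])
  expect_equal(attr(x3, "site_complex")$subunit, dec$b_subunit[3])
})

test_that("pairing can be derived from interface contacts alone", {
  cf <- cofilactin_fixture()
  naked <- cf$filament
  attr(naked, "decoration") <- NULL
  fx <- extract_site_complex(naked, "F")
  expect_equal(attr(fx, "site_complex")$subunit, cf$truth$decoration$b_subunit[1])
})

test_that("monomeric input is rejected", {
  prot <- toy_model(toy_cloud(10))
  expect_error(extract_site_complex(prot, "F"), "monomeric")
})

test_that("grafting back onto the source filament is the identity", {
  cf <- cofilactin_fixture()$filament
  donor <- extract_site_complex(cf, "F")
  info <- attr(donor, "site_complex")
  g <- graft_by_rigid_body(cf, donor, align_body = SD1_BODY,
                           target_subunit = info$subunit)
  ginfo <- attr(g, "graft")
  expect_lt(ginfo$rmsd, 1e-9)
  orig <- dplyr::filter(cf, chain == info$cofilin_chain)
  added <- dplyr::filter(g, chain == ginfo$cofilin_chain)
  expect_equal(coords(added), coords(orig), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("F-site grafts add a cofilin without disturbing the filament", {
  cf <- cofilactin_fixture()$filament
  fa <- factin_fixture()$filament
  g <- graft_cofilin(fa, cf, site = "F", target_subunit = 3,
                     id_body = ID_BODY, sd1_body = SD1_BODY)
  info <- attr(g, "graft")
  expect_lt(info$rmsd, 1e-9)   # identical protomer geometry here
  kept <- dplyr::filter(g, chain != info$cofilin_chain)
  expect_equal(coords(kept), coords(fa), ignore_attr = TRUE)
  expect_equal(sum(g$chain == info$cofilin_chain),
               sum(cf$chain == attr(extract_site_complex(cf, "F"), "site_complex")$cofilin_chain))
})

test_that("grafting is equivariant under rigid motion of the target", {
  cf <- cofilactin_fixture()$filament
  fa <- factin_fixture()$filament
  tf <- withr::with_seed(5, random_transform())
  fa2 <- apply_transform(fa, tf)
  attr(fa2, "decoration") <- NULL
  g1 <- graft_cofilin(fa, cf, site = "Gi", target_subunit = 4,
                      id_body = ID_BODY, sd1_body = SD1_BODY)
  g2 <- graft_cofilin(fa2, cf, site = "Gi", target_subunit = 4,
                      id_body = ID_BODY, sd1_body = SD1_BODY)
  c1 <- dplyr::filter(g1, chain == attr(g1, "graft")$cofilin_chain)
  c2 <- dplyr::filter(g2, chain == attr(g2, "graft")$cofilin_chain)
  expect_equal(apply_transform(coords(c1), tf), coords(c2), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("the grafted cofilin's internal geometry is untouched", {
  cf <- cofilactin_fixture()$filament
  fa <- factin_fixture()$filament
  donor <- extract_site_complex(cf, "G")
  g <- graft_by_rigid_body(fa, donor, align_body = ID_BODY, target_subunit = 5)
  cof0 <- coords(dplyr::filter(donor, chain == attr(donor, "site_complex")$cofilin_chain))
  cof1 <- coords(dplyr::filter(g, chain == attr(g, "graft")$cofilin_chain))
  expect_equal(as.vector(dist(cof0)), as.vector(dist(cof1)), tolerance = 1e-9)
})

test_that("hybrid filaments replace one strand stretch and keep the other bitwise", {
  cf <- cofilactin_fixture(8)$filament
  fa <- factin_fixture(8)$filament
  h <- build_hybrid_filament(cf, fa, span = 3, center_subunit = 4,
                             id_body = ID_BODY)
  info <- attr(h, "hybrid")
  expect_equal(info$replaced_subunits, c(2, 4, 6))
  untouched <- dplyr::filter(fa, !(subunit %in% info$replaced_subunits))
  kept <- dplyr::filter(h, chain %in% unique(untouched$chain))
  expect_identical(coords(kept)[order(kept$chain, kept$eleno), ],
                   coords(untouched)[order(untouched$chain, untouched$eleno), ])
  # cofilins bound wholly within the donor stretch came along
  expect_equal(nrow(info$cofilins), 2L)
})

test_that("replaced and untouched strands carry their own twist", {
  cf <- cofilactin_fixture(9)$filament    # strand steps 35.8 deg
  fa <- factin_fixture(9)$filament        # strand steps 26.8 deg
  h <- build_hybrid_filament(cf, fa, span = 3, center_subunit = 5,
                             id_body = ID_BODY)
  info <- attr(h, "hybrid")
  repl <- dplyr::filter(h, subunit %in% info$replaced_subunits)
  fit_repl <- fit_helical_axis(repl)
  expect_equal(abs(fit_repl$twist_deg), 35.8, tolerance = 1e-6)
  other_subs <- setdiff(unique(fa$subunit), info$replaced_subunits)
  other_strand <- other_subs[other_subs %% 2 == (info$replaced_subunits[1] + 1) %% 2]
  oth <- dplyr::filter(h, subunit %in% other_strand)
  fit_oth <- fit_helical_axis(oth)
  expect_equal(abs(fit_oth$twist_deg), 26.8, tolerance = 1e-6)
})

test_that("hybrid of a filament with itself reproduces the input geometry", {
  cf <- cofilactin_fixture(7)$filament
  h <- build_hybrid_filament(cf, cf, span = 3, center_subunit = 3,
                             id_body = ID_BODY)
  for (k in sort(unique(cf$subunit))) {
    expect_equal(coords(dplyr::filter(h, subunit == k)),
                 coords(dplyr::filter(cf, subunit == k)),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # cofilin complement is preserved as a coordinate multiset
  cof_in <- coords(dplyr::filter(cf, is.na(subunit)))
  cof_out <- coords(dplyr::filter(h, is.na(subunit)))
  expect_equal(dim(cof_out), dim(cof_in))
  # order rows by rounded coordinates so ties are broken identically despite
  # 1e-15-level float differences from the (identity) alignment
  ord <- function(m) m[do.call(order, as.data.frame(round(m, 3))), ]
  expect_equal(ord(cof_out), ord(cof_in), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("span limits are enforced unless explicitly lifted", {
  cf <- cofilactin_fixture(8)$filament
  fa <- factin_fixture(8)$filament
  expect_error(build_hybrid_filament(cf, fa, span = 6, id_body = ID_BODY),
               "between 2 and 5")
  expect_error(build_hybrid_filament(cf, fa, span = 1, id_body = ID_BODY),
               "between 2 and 5")
  h1 <- build_hybrid_filament(cf, fa, span = 2, center_subunit = 4,
                              id_body = ID_BODY, allow_any_span = FALSE)
  expect_equal(length(attr(h1, "hybrid")$replaced_subunits), 2L)
  # even span: centre is the P-end-side middle subunit by default
  expect_equal(attr(h1, "hybrid")$replaced_subunits, c(2, 4))
  h2 <- build_hybrid_filament(cf, fa, span = 2, center_subunit = 4,
                              id_body = ID_BODY, center_rule = "b_end")
  expect_equal(attr(h2, "hybrid")$replaced_subunits, c(4, 6))
})

test_that("collision reduction matches the constructed fixtures", {
  fx_a <- make_clash_fixture(10, 2, seed = 1)$model
  fx_b <- make_clash_fixture(10, 10, seed = 1)$model
  spec <- list(a = "A", b = "B")
  red <- compare_collision_counts(fx_a, fx_b, spec)
  expect_equal(as.numeric(red), 80)
  expect_equal(unname(attr(red, "counts")), c(2 + 2, 10 + 10))
  # identical models: zero reduction
  expect_equal(as.numeric(compare_collision_counts(fx_b, fx_b, spec)), 0)
  # pair-count variant
  expect_equal(as.numeric(compare_collision_counts(fx_a, fx_b, spec, count = "pairs")), 80)
  # reference without collisions: undefined
  clean <- make_clash_fixture(4, 0, seed = 1)$model
  expect_error(compare_collision_counts(fx_a, clean, spec), "undefined")
})
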