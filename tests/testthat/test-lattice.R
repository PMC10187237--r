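test_that("blunt initialization builds the stated geometry for both ends", {
  for (end in c("plus", "minus")) {
    lat <- init_lattice(lattice_params(), end, seed_layers = 10)
    expect_identical(lat$end, end)
    expect_identical(lattice_heights(lat), rep(10L, 13))
    df <- as.data.frame(lat)
    expect_identical(nrow(df), 130L)
    expect_true(all(df$nucleotide == "CPP"))
    expect_identical(max(df$layer), 9L)
    # seed subunits are not dissociable: no tip entries at seed height
    expect_identical(nrow(tip_sites(lat)), 0L)
  }
  small <- init_lattice(lattice_params(n_protofilaments = 2), "plus",
                        seed_layers = 2)
  expect_identical(nrow(as.data.frame(small)), 4L)
  expect_identical(nrow(tip_sites(small)), 0L)
  expect_error(init_lattice(lattice_params(), "plus", seed_layers = 1),
               "seed_layers")
})

test_that("landing-site classes follow the lateral bond count", {
  lat <- grown_lattice("plus", layers = 1)
  # on a blunt face the next addition layer has no flush lateral partner;
  # only the down-shifted seam side offers half a bond (binned as corner)
  expect_identical(classify_landing_site(lat, 5), "long_only")
  expect_identical(classify_landing_site(lat, 1), "corner")
  expect_identical(classify_landing_site(lat, 13), "long_only")
  # a protofilament one layer ahead of both neighbours still has no
  # lateral partner at its next addition layer
  ahead <- mtkmc:::lattice_associate(lat, 5, "CPP")
  expect_identical(classify_landing_site(ahead, 5), "long_only")
  # its neighbours gain exactly one partner: corner
  expect_identical(classify_landing_site(ahead, 4), "corner")
  expect_identical(classify_landing_site(ahead, 6), "corner")
  # and with both neighbours ahead the site becomes a bucket
  both <- mtkmc:::lattice_associate(ahead, 7, "CPP")
  expect_identical(classify_landing_site(both, 6), "bucket")
  expect_error(classify_landing_site(lat, 14), "protofilament")
})

test_that("tip sites report polarity-correct interfacial nucleotides", {
  # plus-end: GDP tip over a CPP subunit buries the CPP at the interface
  lat <- grown_lattice("plus", layers = 1)
  lat <- mtkmc:::lattice_associate(lat, 3, "GDP")
  tp <- tip_sites(lat)
  row <- tp[tp$pf == 3, ]
  expect_identical(row$self_nt, "GDP")
  expect_identical(row$interfacial_nt, "CPP")
  # minus-end: the tip's own nucleotide is the interfacial one
  latm <- grown_lattice("minus", layers = 1)
  latm <- mtkmc:::lattice_associate(latm, 3, "GDP")
  tm <- tip_sites(latm)
  expect_identical(tm[tm$pf == 3, "self_nt"], "GDP")
  expect_identical(tm[tm$pf == 3, "interfacial_nt"], "GDP")
  # an all-CPP grown layer reports (CPP, CPP) everywhere
  all_cpp <- tip_sites(grown_lattice("plus", layers = 1))
  expect_identical(nrow(all_cpp), 13L)
  expect_true(all(all_cpp$self_nt == "CPP" & all_cpp$interfacial_nt == "CPP"))
})

test_that("tip count equals the number of protofilaments above the seed", {
  set.seed(42)
  for (i in 1:20) {
    lat <- random_lattice(sample(c("plus", "minus"), 1), extra = 5)
    expect_identical(nrow(tip_sites(lat)),
                     sum(lattice_heights(lat) > lat$seed_layers))
  }
})

test_that("seam bond weights are fractional and mirrored between ends", {
  # blunt tips: the down-shifted seam side holds both partner half-layers
  # (full bond); the up-shifted side only the lower one (half bond)
  lat <- grown_lattice("plus", layers = 1)
  tp <- tip_sites(lat)
  expect_equal(tp$lateral_weight[tp$pf == 1], 2.0)
  expect_equal(tp$lateral_weight[tp$pf == 13], 1.5)
  expect_true(all(tp$lateral_weight[!tp$pf %in% c(1, 13)] == 2))
  expect_true(all(tp$site_class == "bucket"))
  # the minus-end mirrors the seam shift: weights swap sides
  latm <- grown_lattice("minus", layers = 1)
  tm <- tip_sites(latm)
  expect_equal(tm$lateral_weight[tm$pf == 1], 1.5)
  expect_equal(tm$lateral_weight[tm$pf == 13], 2.0)
  # a flush seam restores full symmetry
  lat0 <- grown_lattice("plus", layers = 1,
                        params = lattice_params(seam_offset = 0))
  expect_true(all(tip_sites(lat0)$lateral_weight == 2))
})

test_that("lattice snapshots round-trip through CSV", {
  set.seed(7)
  lat <- random_lattice("minus", extra = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_lattice_csv(lat, path)
  back <- read_lattice_csv(path)
  expect_identical(back$end, lat$end)
  expect_identical(back$seed_layers, lat$seed_layers)
  expect_identical(back$stacks, lat$stacks)
  expect_equal(back$params$seam_offset, lat$params$seam_offset)
})

test_that("seed subunits can neither dissociate nor exchange", {
  lat <- init_lattice(lattice_params(), "plus")
  expect_error(mtkmc:::lattice_dissociate(lat, 1), "seed")
  expect_error(mtkmc:::lattice_exchange(lat, 1, "GDP"), "seed")
  grown <- mtkmc:::lattice_associate(lat, 1, "GDP")
  expect_silent(mtkmc:::lattice_dissociate(grown, 1))
})
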