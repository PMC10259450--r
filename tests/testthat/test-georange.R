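mk_occ <- function(...) load_occurrences(data.frame(...))

test_that("occurrence loading validates and deduplicates", {
  occ <- mk_occ(species = c("a", "a", "b"),
                lon = c(1, 1, 2), lat = c(1, 1, 2))
  expect_equal(nrow(occ), 2)  # exact duplicate dropped
  expect_error(mk_occ(species = "a", lon = 0, lat = 95), "latitude")
  expect_error(mk_occ(species = "a", lon = 200, lat = 0), "longitude")
  expect_error(mk_occ(species = "", lon = 0, lat = 0), "empty species")
  expect_error(load_occurrences(data.frame(species = "a", lon = 1)),
               "missing columns")
  expect_error(mk_occ(species = "a", lon = "x", lat = 0), "coordinates")
})

test_that("rasterisation follows the half-open integer-anchored grid rule", {
  occ <- mk_occ(species = c("a", "a"), lon = c(0.01, 0.04),
                lat = c(0.01, 0.04))
  expect_equal(range_size(rasterize(occ, "a", grid_spec(0.05))), 1)
  expect_equal(range_size(rasterize(occ, "a", grid_spec(0.01))), 2)
  expect_error(rasterize(occ, "zz", grid_spec(0.05)), "unknown species")

  # boundary point falls in the higher-index cell
  b <- mk_occ(species = "a", lon = 0.05, lat = 0.0)
  gr <- rasterize(b, "a", grid_spec(0.05))
  expect_equal(gr$cells$cell_x, 1)
  expect_equal(gr$cells$cell_y, 0)

  # one point, one cell
  expect_equal(range_size(rasterize(mk_occ(species = "a", lon = -71.3,
                                           lat = 4.2), "a",
                                    grid_spec(0.1))), 1)
})

test_that("overlap and asymmetry match their definitions and invariants", {
  g <- grid_spec(0.1)
  occ <- mk_occ(
    species = c(rep("a", 6), rep("b", 2), rep("c", 2), rep("d", 3)),
    lon = c(0.05, 0.15, 0.25, 0.35, 0.45, 0.55,   # a: 6 cells
            0.05, 0.15,                            # b: 2 cells nested in a
            5.05, 5.15,                            # c: 2 cells, disjoint
            0.05, 0.15, 0.25),                     # d: 3 cells nested in a
    lat = rep(0.05, 13))
  ga <- rasterize(occ, "a", g); gb <- rasterize(occ, "b", g)
  gc_ <- rasterize(occ, "c", g); gd <- rasterize(occ, "d", g)

  expect_equal(range_overlap(ga, gc_), 0)          # disjoint -> full allopatry
  expect_equal(range_overlap(ga, gb), 1)           # nested -> 1
  expect_equal(range_asymmetry(ga, gb), 3)         # 6 vs 2 cells
  expect_equal(range_asymmetry(ga, ga), 1)         # equal counts
  expect_equal(range_overlap(ga, gb), range_overlap(gb, ga))
  expect_equal(range_asymmetry(ga, gd), range_asymmetry(gd, ga))
  expect_error(range_overlap(ga, rasterize(occ, "b", grid_spec(0.05))),
               "different grid")

  # randomised invariants: O in [0,1], A >= 1, A = 1 iff equal cell counts
  set.seed(5)
  for (i in 1:10) {
    o2 <- load_occurrences(data.frame(
      species = rep(c("x", "y"), each = 15),
      lon = round(stats::runif(30, 0, 1), 3),
      lat = round(stats::runif(30, 0, 1), 3)))
    gx <- rasterize(o2, "x", g); gy <- rasterize(o2, "y", g)
    O <- range_overlap(gx, gy); A <- range_asymmetry(gx, gy)
    expect_gte(O, 0); expect_lte(O, 1); expect_gte(A, 1)
    expect_equal(A == 1, range_size(gx) == range_size(gy))
  }
})

test_that("coarsening an aligned grid keeps nested ranges fully overlapped", {
  set.seed(9)
  for (i in 1:5) {
    # points of x are a subset of points of y: nested ranges at any grid
    ypts <- data.frame(lon = stats::runif(40, 0, 2),
                       lat = stats::runif(40, 0, 2))
    xpts <- ypts[sample(40, 12), ]
    occ <- load_occurrences(data.frame(
      species = c(rep("y", 40), rep("x", 12)), rbind(ypts, xpts)))
    o_fine <- range_overlap(rasterize(occ, "x", grid_spec(0.05)),
                            rasterize(occ, "y", grid_spec(0.05)))
    o_coarse <- range_overlap(rasterize(occ, "x", grid_spec(0.1)),
                              rasterize(occ, "y", grid_spec(0.1)))
    expect_equal(o_fine, 1)
    expect_gte(o_coarse, o_fine)
  }
})

test_that("island assignment is point-in-polygon with explicit-id override", {
  im <- island_map(list(
    I1 = cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
    I2 = cbind(c(2, 3, 3, 2), c(0, 0, 1, 1))))
  occ <- mk_occ(species = c("a", "a", "b", "c"),
                lon = c(0.5, 2.5, 0.5, 10),
                lat = c(0.5, 0.5, 0.99, 10))
  asg <- assign_islands(occ, im)
  expect_setequal(asg$sets$a, c("I1", "I2"))
  expect_equal(asg$sets$b, "I1")
  expect_equal(length(asg$sets$c), 0)   # outside all polygons
  expect_equal(asg$outside, 4L)

  # boundary point counts as inside
  bocc <- mk_occ(species = "e", lon = 1, lat = 0.5)
  expect_equal(assign_islands(bocc, im)$sets$e, "I1")

  # explicit island_id bypasses geometry
  o2 <- load_occurrences(data.frame(species = "f", lon = 50, lat = 50,
                                    island_id = "I9"))
  expect_equal(assign_islands(o2, im)$sets$f, "I9")

  expect_error(island_map(list(I1 = cbind(c(0, 1), c(0, 1)))), "polygon")
  expect_error(island_map(stats::setNames(
    list(cbind(c(0, 1, 1), c(0, 0, 1)), cbind(c(0, 1, 1), c(0, 0, 1))),
    c("I1", "I1"))), "unique")
})

test_that("island map round-trips through GeoJSON", {
  im <- gen_islands(4, n_bioregions = 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_islands(im, path)
  back <- read_islands(path)
  expect_equal(names(back$polygons), names(im$polygons))
  expect_equal(back$bioregion, im$bioregion)
  expect_equal(back$polygons$I1, im$polygons$I1, ignore_attr = TRUE)
})

test_that("the island call distinguishes shared islands, disjoint islands and slopes", {
  sets <- list(a = c("1", "2"), b = "3", c = c("2", "5"), d = character())
  occ <- mk_occ(species = c("a", "b", "c", "d"), lon = 1:4, lat = 1:4)
  expect_equal(island_call("a", "b", sets, occ), "allopatric")
  expect_equal(island_call("a", "c", sets, occ), "sympatric")
  expect_equal(island_call("a", "d", sets, occ), "undetermined")

  # forest species co-occurring on one mountain but on disjoint flanks
  occ2 <- load_occurrences(data.frame(
    species = c("f1", "f2"), lon = c(1, 1.01), lat = c(1, 1.01),
    island_id = c("M1", "M1"), flank = c("east", "west"),
    habitat = c("forest", "forest")))
  sets2 <- list(f1 = "M1", f2 = "M1")
  expect_equal(island_call("f1", "f2", sets2, occ2), "allopatric")

  # same flanks -> sympatric; paramo habitat -> no slope exception
  occ3 <- occ2; occ3$flank <- c("east", "east")
  expect_equal(island_call("f1", "f2", sets2, occ3), "sympatric")
  occ4 <- occ2; occ4$habitat <- c("paramo", "paramo")
  expect_equal(island_call("f1", "f2", sets2, occ4), "sympatric")
})
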