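test_that("protection requires a positive-area intersection", {
  g <- build_grid(c(0, 0, 100, 100), 50)
  # corner overlap protects; edge contact does not
  res <- reserve_layer(list(rect_poly(40, 40, 60, 60),   # corners of all 4 cells
                            rect_poly(100, 0, 120, 50)), # touches cell 2's edge
                       tier = c("NNR", "PNR"))
  st <- protection_status(g, res)
  expect_true(all(st$by_nnr))
  expect_false(any(st$by_pnr))
  expect_equal(st$by_either, st$by_nnr | st$by_pnr)
  empty <- reserve_layer(list(), character(0))
  st0 <- protection_status(g, empty)
  expect_false(any(st0$by_either))
})

test_that("gap cells complement the protected set and are tier-monotone", {
  g <- build_grid(c(0, 0, 200, 50), 50)   # 4 x 1 cells
  res <- reserve_layer(list(rect_poly(0, 0, 60, 50),     # NNR over cells 1-2
                            rect_poly(110, 0, 160, 50)), # PNR over cells 3-4
                       tier = c("NNR", "PNR"))
  st <- protection_status(g, res)
  hs <- 1:4
  expect_equal(gap_cells(hs, st, "NNR"), c(3L, 4L))
  expect_equal(gap_cells(hs, st, "either"), integer(0))
  expect_true(all(gap_cells(hs, st, "either") %in% gap_cells(hs, st, "NNR")))
  st0 <- protection_status(g, reserve_layer(list(), character(0)))
  expect_equal(gap_cells(hs, st0), hs)
})

test_that("effectiveness summary partitions cells and bounds species coverage", {
  cfg <- small_cfg(seed = 19)
  ds <- generate_dataset(cfg)
  hs <- identify_hotspots(ds$pm, ds$checklist, fractions = 0.10)[[1]]
  st <- protection_status(ds$grid, ds$reserves)
  eff <- effectiveness_summary(hs$cell, st, ds$pm, ds$checklist)
  cells <- function(block) eff$count[eff$block == block & eff$measure == "cells"]
  for (tier in c("NNR", "PNR", "either"))
    expect_equal(cells(paste0("protected_", tier)) +
                   cells(paste0("unprotected_", tier)), length(hs$cell))
  sp <- function(block) eff$count[eff$block == block & eff$measure == "species_all"]
  expect_gte(sp("protected_either"), max(sp("protected_NNR"), sp("protected_PNR")))
  # species in protected cells + species found only in unprotected cells
  # partition the species present in hotspot cells
  prot <- hs$cell[st$by_either[hs$cell]]
  unprot <- setdiff(hs$cell, prot)
  in_cells <- function(cc) if (length(cc) == 0) character(0) else
    colnames(ds$pm)[Matrix::colSums(ds$pm[cc, , drop = FALSE]) > 0]
  only_unprot <- setdiff(in_cells(unprot), in_cells(prot))
  expect_equal(sp("protected_either") + length(only_unprot), sp("final_hotspots"))
  expect_warning(effectiveness_summary(integer(0), st, ds$pm, ds$checklist),
                 "empty hotspot")
})

test_that("all cells protected yields zero unprotected rows and full coverage", {
  fix <- effectiveness_fixture()
  full <- reserve_layer(list(rect_poly(-10, -10, 1600, 20)), tier = "NNR")
  st <- protection_status(fix$grid, full)
  eff <- effectiveness_summary(fix$hotspot_cells, st, fix$pm, fix$checklist)
  un <- eff[eff$block == "unprotected_NNR" & eff$measure == "cells", ]
  expect_equal(un$count, 0)
  pr <- eff[eff$block == "protected_NNR", ]
  expect_equal(pr$pct[pr$measure == "cells"], 100.00)
  # all species present in hotspots are covered
  expect_equal(pr$count[pr$measure == "species_all"],
               eff$count[eff$block == "final_hotspots" &
                           eff$measure == "species_all"])
})

test_that("record protection uses strict thresholds and boundary-inclusive points", {
  res <- reserve_layer(list(rect_poly(0, 0, 100, 100)), tier = "NNR")
  occ <- data.frame(species_id = rep(c("a", "b", "c"), each = 10),
                    x = c(rep(50, 3), rep(500, 7),    # a: 3/10 protected
                          rep(50, 10),                # b: 10/10
                          rep(500, 10)),              # c: 0/10
                    y = 50)
  rp <- species_record_protection(occ, res)
  expect_equal(rp$fraction[rp$species_id == "a"], 0.30)
  expect_false(rp$under_30[rp$species_id == "a"])    # strict <
  expect_true(rp$over_90[rp$species_id == "b"])
  expect_true(rp$under_30[rp$species_id == "c"])
  # a record on the polygon boundary counts as protected
  occ_edge <- data.frame(species_id = "e", x = 100, y = 50)
  expect_equal(species_record_protection(occ_edge, res)$fraction, 1)
  # no reserves: all fractions zero
  rp0 <- species_record_protection(occ, reserve_layer(list(), character(0)))
  expect_true(all(rp0$fraction == 0) && all(rp0$under_30))
})

test_that("point-in-polygon agrees with an independent implementation", {
  skip_if_not_installed("mgcv")
  withr::with_seed(23, {
    for (i in 1:10) {
      # random star-shaped polygon around a centre
      k <- sample(5:9, 1)
      th <- sort(runif(k, 0, 2 * pi))
      r <- runif(k, 2, 10)
      poly <- cbind(10 + r * cos(th), 10 + r * sin(th))
      poly <- rbind(poly, poly[1, ])
      x <- runif(100, -2, 22)
      y <- runif(100, -2, 22)
      mine <- point_in_polygon(x, y, poly, tol = 0)
      ref <- mgcv::in.out(poly, cbind(x, y))
      expect_equal(mine, as.logical(ref))
    }
  })
})

test_that("polygon-rectangle clipping computes the exact overlap area", {
  # rectangle-rectangle overlap has a closed form to compare against
  withr::with_seed(29, {
    for (i in 1:50) {
      a <- sort(runif(2, 0, 10)); b <- sort(runif(2, 0, 10))
      c_ <- sort(runif(2, 0, 10)); d <- sort(runif(2, 0, 10))
      p <- rect_poly(a[1], b[1], a[2], b[2])
      rect <- c(c_[1], d[1], c_[2], d[2])
      expected <- max(0, min(a[2], c_[2]) - max(a[1], c_[1])) *
        max(0, min(b[2], d[2]) - max(b[1], d[1]))
      expect_equal(hotspotr:::poly_rect_area(p, rect), expected,
                   tolerance = 1e-12)
    }
  })
  # a triangle half-covering a unit cell
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1), c(0, 0))
  expect_equal(hotspotr:::poly_rect_area(tri, c(0, 0, 1, 1)), 0.5)
})

test_that("degenerate reserve polygons are rejected with a warning", {
  expect_warning(res <- reserve_layer(list(rect_poly(0, 0, 0, 10),
                                           rect_poly(0, 0, 5, 5)),
                                      tier = c("NNR", "PNR")),
                 "degenerate")
  expect_length(res$polygons, 1)
  expect_equal(res$tier, "PNR")
})
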