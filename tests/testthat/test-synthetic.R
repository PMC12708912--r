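test_that("checklist category counts follow largest-remainder apportionment", {
  cfg <- small_cfg(n_species = 10,
                   category_fractions = c(CR = .1, EN = .2, VU = .3, NT = .2, CC = .2))
  chk <- generate_checklist(cfg)
  expect_equal(as.vector(table(chk$category)[c("CR", "EN", "VU", "NT", "CC")]),
               c(1L, 2L, 3L, 2L, 2L))
  expect_equal(nrow(chk), 10L)
})

test_that("checklist generation is deterministic and validates fractions", {
  cfg <- small_cfg(seed = 11)
  expect_identical(generate_checklist(cfg), generate_checklist(cfg))
  expect_error(small_cfg(category_fractions = c(CR = .5, EN = .5, VU = 0,
                                                NT = 0, CC = .5)),
               "sum to 1")
  expect_error(small_cfg(frac_endemic = 1.5), "frac_endemic")
})

test_that("occurrence generation respects range targets and cluster disks", {
  cfg <- small_cfg(seed = 3)
  chk <- generate_checklist(cfg)
  occ <- generate_occurrences(cfg, chk)
  grid <- attr(occ, "grid")
  expect_true(all(occ$x >= cfg$extent[1] & occ$x < cfg$extent[3]))
  expect_true(all(occ$y >= cfg$extent[2] & occ$y < cfg$extent[4]))
  # every species has at least one record
  expect_setequal(unique(occ$species_id), as.character(chk$species_id))
  # a species with target 1 occupies exactly one cell
  targets <- attr(occ, "targets")
  pm <- build_presence(occ, grid, as.character(chk$species_id))
  rs <- range_sizes(pm)
  one <- names(targets)[targets == 1]
  expect_true(length(one) > 0 && all(rs[one] == 1))
  # occupied cells never exceed the target
  expect_true(all(rs <= targets[names(rs)]))
  # narrow species records all fall in their cluster's cells
  cl <- attr(occ, "cluster_cells")[[1]]
  narrow <- attr(occ, "narrow_species")
  ncells <- locate(occ$x[occ$species_id %in% narrow],
                   occ$y[occ$species_id %in% narrow], grid)
  expect_true(all(ncells %in% cl))
})

test_that("occurrence generation is deterministic and guards tiny extents", {
  cfg <- small_cfg(seed = 5)
  chk <- generate_checklist(cfg)
  expect_identical(generate_occurrences(cfg, chk),
                   generate_occurrences(cfg, chk))
  tiny <- small_cfg(extent = c(0, 0, 100, 100), cluster_radius = 200)
  expect_error(generate_occurrences(tiny, generate_checklist(tiny)),
               "too small")
})

test_that("reserve generation hits the coverage target and validates inputs", {
  cfg <- small_cfg(seed = 9, n_nnr = 5, n_pnr = 8, reserve_coverage = 0.2)
  res <- generate_reserves(cfg)
  expect_length(res$polygons, 13)
  expect_equal(sum(res$tier == "NNR"), 5)
  area <- sum(vapply(res$polygons, function(p) abs(hotspotr:::poly_area(p)),
                     numeric(1)))
  target <- 0.2 * 500 * 500
  expect_lt(abs(area - target) / target, 0.2)
  expect_error(small_cfg(reserve_coverage = 1.5), "reserve_coverage")
  empty <- generate_reserves(small_cfg(n_nnr = 0, n_pnr = 0))
  expect_length(empty$polygons, 0)
})

test_that("reserve tiers survive a GeoJSON round trip", {
  cfg <- small_cfg(seed = 13)
  res <- generate_reserves(cfg)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_reserves_geojson(res, path)
  back <- read_reserves_geojson(path)
  expect_equal(back$tier, res$tier)
  expect_equal(back$id, res$id)
  for (k in seq_along(res$polygons))
    expect_equal(back$polygons[[k]], res$polygons[[k]], tolerance = 1e-12)
})

test_that("suitability stacks honour threshold margins and planted change", {
  cfg <- small_cfg(seed = 21, loss_fractions = 0.65, gain_fractions = 0.1)
  chk <- generate_checklist(cfg)
  occ <- generate_occurrences(cfg, chk)
  pm <- build_presence(occ, attr(occ, "grid"), as.character(chk$species_id))
  sui <- generate_suitability(cfg, pm)
  cur_bin <- binary_range(sui$current)
  # current stack binarizes exactly to the occupied cells
  expect_equal(unname(as.matrix(cur_bin)), unname(as.matrix(pm == 1)))
  # planted loss: exactly round(0.65 * A) range cells fall below threshold
  fut_bin <- binary_range(sui$future)
  lost <- colSums(as.matrix(pm == 1) & !fut_bin)
  expect_equal(unname(lost), unname(round_half_up(0.65 * sui$planted$a_cur)))
  gained <- colSums(!as.matrix(pm == 1) & fut_bin)
  expect_equal(unname(gained), unname(round_half_up(0.1 * sui$planted$a_cur)))
})

test_that("total loss and identity scenarios behave as planted", {
  cfg <- small_cfg(seed = 22, n_species = 12, loss_fractions = 1, gain_fractions = 0)
  chk <- generate_checklist(cfg)
  occ <- generate_occurrences(cfg, chk)
  pm <- build_presence(occ, attr(occ, "grid"), as.character(chk$species_id))
  sui <- generate_suitability(cfg, pm)
  expect_true(all(sui$future <= 0.6))    # loss 1, gain 0: nothing survives
  cfg0 <- small_cfg(seed = 22, n_species = 12, loss_fractions = 0, gain_fractions = 0)
  sui0 <- generate_suitability(cfg0, pm)
  expect_identical(binary_range(sui0$future), binary_range(sui0$current))
  expect_error(small_cfg(loss_fractions = 1.2), "loss_fractions")
})

test_that("suitability generation is deterministic and AUCs are plantable", {
  cfg <- small_cfg(seed = 31, n_low_auc = 3)
  chk <- generate_checklist(cfg)
  occ <- generate_occurrences(cfg, chk)
  pm <- build_presence(occ, attr(occ, "grid"), as.character(chk$species_id))
  s1 <- generate_suitability(cfg, pm)
  s2 <- generate_suitability(cfg, pm)
  expect_identical(s1, s2)
  expect_equal(sum(s1$auc$auc < 0.7), 3)
  expect_true(all(s1$auc$auc > 0.5 & s1$auc$auc <= 1))
})

test_that("environmental layers match the requested correlation", {
  g <- build_grid(c(0, 0, 5000, 5000), 50)  # 10000 cells
  cfg1 <- small_cfg(seed = 41, n_env_layers = 2, env_corr = 1)
  e1 <- generate_env_layers(cfg1, g)
  expect_equal(cor(e1[, 1], e1[, 2]), 1)
  cfg0 <- small_cfg(seed = 41, n_env_layers = 2, env_corr = 0)
  e0 <- generate_env_layers(cfg0, g)
  expect_lt(abs(cor(e0[, 1], e0[, 2])), 0.05)
  expect_error(small_cfg(env_corr = 1.2), "env_corr")
  expect_identical(generate_env_layers(cfg0, g), generate_env_layers(cfg0, g))
})

test_that("occurrence CSV writes are byte-identical across regenerations", {
  cfg <- small_cfg(seed = 51, n_species = 20)
  chk <- generate_checklist(cfg)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_occurrences_csv(generate_occurrences(cfg, chk), p1)
  write_occurrences_csv(generate_occurrences(cfg, chk), p2)
  expect_identical(readLines(p1), readLines(p2))
})
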