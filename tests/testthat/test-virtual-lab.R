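test_that("population generation respects its distribution spec", {
  # sd = 0: every diameter equals the mean
  p0 <- generate_population(population_spec("polystyrene", n = 50,
                                            diameter_mean = 15,
                                            diameter_sd = 0), seed = 1)
  d0 <- vapply(p0$particles, `[[`, numeric(1), "diameter")
  expect_true(all(d0 == 15))
  # CLT check at n = 1e4
  p1 <- generate_population(population_spec("WBC", n = 1e4), seed = 2)
  d1 <- vapply(p1$particles, `[[`, numeric(1), "diameter")
  expect_lt(abs(mean(d1) - 9), 3 * 1.5 / sqrt(1e4))
  expect_true(all(d1 > 0))
  # trajectories are assigned
  expect_setequal(unique(p1$trajectories), c("T1", "T2"))
  # reproducibility
  p2 <- generate_population(population_spec("WBC", n = 100), seed = 7)
  p3 <- generate_population(population_spec("WBC", n = 100), seed = 7)
  expect_identical(vapply(p2$particles, `[[`, numeric(1), "diameter"),
                   vapply(p3$particles, `[[`, numeric(1), "diameter"))
})

test_that("concentration x volume arithmetic and subsampling are recorded", {
  spec <- population_spec("WBC", concentration = 5e5, volume = 20)
  expect_equal(spec$n, 1e7)
  pop <- generate_population(spec, seed = 1, max_cells = 1000)
  expect_length(pop$particles, 1000)
  expect_equal(pop$subsample_factor, 1e4)
  expect_equal(pop$requested_n, 1e7)
})

test_that("sorting conserves cells and reports realized efficiencies", {
  wbc <- generate_population(population_spec("WBC", n = 3000), seed = 3)
  tum <- generate_population(population_spec("MCF-7", n = 3000), seed = 4)
  cells <- combine_collections(wbc, tum)
  # certain capture keeps everything
  all_keep <- apply_sorting(cells, sorting_stage(floor = 1, ceiling = 1))
  expect_equal(all_keep$report$recovery_efficiency$WBC, 1)
  expect_equal(all_keep$report$recovery_efficiency$TUMOR, 1)
  expect_length(all_keep$waste, 0)
  # conservation under a random stage
  st <- sorting_stage(midpoint = 12, steepness = 1, ceiling = 0.9, seed = 5)
  out <- apply_sorting(cells, st)
  expect_equal(length(out$product) + length(out$waste), length(cells))
  # bigger cells are kept more often
  expect_gt(out$report$recovery_efficiency$TUMOR,
            out$report$recovery_efficiency$WBC)
  # purity of the product favors the big class
  expect_gt(out$report$purity$TUMOR, 0.5)
  # RE + DE = 1 per class
  expect_equal(out$report$recovery_efficiency$WBC +
                 out$report$depletion_efficiency$WBC, 1)
  # seeded reproducibility
  out2 <- apply_sorting(cells, st)
  expect_identical(length(out2$product), length(out$product))
})

test_that("default separation stage hits the calibrated efficiencies", {
  n <- 1e5
  wbc <- generate_population(population_spec("WBC", n = n,
                                             dielectric_cv = 0), seed = 6)
  tum <- generate_population(population_spec("MCF-7", n = n,
                                             dielectric_cv = 0), seed = 7)
  st <- sorting_stage(seed = 8)
  de_wbc <- apply_sorting(wbc, st)$report$depletion_efficiency$WBC
  re_tum <- apply_sorting(tum, st)$report$recovery_efficiency$TUMOR
  # binomial 3-sigma at n = 1e5 is ~0.13% (WBC) / 0.28% (tumor); allow for
  # the truncation of the diameter distribution as well
  expect_lt(abs(de_wbc - 0.98), 0.005)
  expect_lt(abs(re_tum - 0.90), 0.01)
})

test_that("capture probability is monotone in diameter", {
  st <- sorting_stage()
  p_of <- function(d) st$floor + (st$ceiling - st$floor) /
    (1 + exp(-st$steepness * (d - st$midpoint)))
  d <- seq(2, 40, 0.5)
  expect_true(all(diff(p_of(d)) >= 0))          # saturates in the tails
  expect_true(all(diff(p_of(seq(8, 18, 0.5))) > 0))
  # realized recovery by diameter bin is non-decreasing (up to noise)
  pop <- generate_population(population_spec("MCF-7", n = 2e4,
                                             diameter_sd = 5), seed = 9)
  out <- apply_sorting(pop, st)
  d_all <- vapply(pop$particles, `[[`, numeric(1), "diameter")
  kept <- seq_along(d_all) %in% which(
    d_all %in% vapply(out$product$particles, `[[`, numeric(1), "diameter"))
  bins <- cut(d_all, breaks = quantile(d_all, 0:4 / 4), include.lowest = TRUE)
  re_bin <- tapply(kept, bins, mean)
  expect_true(all(diff(re_bin) > -0.05))
})

test_that("spike-in scenarios carry exact ground truth", {
  bg <- population_spec("WBC", concentration = 5e5, volume = 20)
  sc <- build_spikein_scenario(bg, c(0, 100), seed = 1, max_background = 500)
  labels0 <- vapply(sc[[1]]$cells$particles, `[[`, character(1), "label")
  expect_false(any(labels0 == "TUMOR"))
  labels1 <- vapply(sc[[2]]$cells$particles, `[[`, character(1), "label")
  expect_equal(sum(labels1 == "TUMOR"), 100)
  expect_equal(sc[[2]]$spike_count, 100)
  expect_equal(sc[[2]]$background_factor, 1e7 / 500)
  expect_error(build_spikein_scenario(bg, -5), "spike")
})
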