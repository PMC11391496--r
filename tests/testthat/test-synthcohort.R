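test_that("default region table matches the parcellation layout", {
  r <- make_region_table()
  expect_equal(nrow(r), 132)
  expect_equal(sum(!r$cortex %in% c("subcortical", "cerebellar")), 91)
  expect_equal(sum(r$cortex == "subcortical"), 15)
  expect_equal(sum(r$cortex == "cerebellar"), 26)
  expect_equal(sum(r$is_roi), 6)
  expect_setequal(r$name[r$is_roi],
                  paste0("L.", c("triIFG", "operIFG", "aMTG", "aITG",
                                 "toMTG", "toITG")))
  expect_false(any(duplicated(r$name)))
})

test_that("simulation is deterministic given (config, seed)", {
  cc <- mini_config()
  regions <- mini_regions(4)
  d <- make_design(1, 10, 10, 1)
  a <- simulate_subject("HC", d, regions, cc, seed = 11)
  b <- simulate_subject("HC", d, regions, cc, seed = 11)
  expect_identical(a, b)
  c2 <- simulate_subject("HC", d, regions, cc, seed = 12)
  expect_false(identical(a$series, c2$series))

  co1 <- simulate_cohort(mini_config(group_sizes = c("HC" = 2, "TLE-HS" = 2,
                                                     "TLE-NHS" = 2)),
                         d, regions)
  co2 <- simulate_cohort(mini_config(group_sizes = c("HC" = 2, "TLE-HS" = 2,
                                                     "TLE-NHS" = 2)),
                         d, regions)
  expect_identical(co1$subjects, co2$subjects)
  expect_identical(co1$series, co2$series)
})

test_that("cohort sizes follow the configured group sizes", {
  d <- make_design(1, 5, 5, 1)
  regions <- mini_regions(3)
  co <- simulate_cohort(mini_config(group_sizes = c("HC" = 2, "TLE-HS" = 2,
                                                    "TLE-NHS" = 2)),
                        d, regions)
  expect_equal(nrow(co$subjects), 6)
  expect_equal(as.vector(table(co$subjects$group)[c("HC", "TLE-HS", "TLE-NHS")]),
               c(2L, 2L, 2L))
  # default sizes reproduce the three-group design
  expect_equal(sum(cohort_config()$group_sizes), 87)
})

test_that("empirical correlations recover the target structure (quiet limit)", {
  regions <- mini_regions(6, c("left-frontal", "left-temporal"))
  cc <- mini_config(noise = quiet_noise(), task_amp = no_task(),
                    subject_sd = 0, seed = 3)
  d <- make_design(1, 5000, 5000, 1) # T = 10,000
  sub <- simulate_subject("HC", d, regions, cc, seed = 5)
  emp <- cor(t(unclass(sub$series)))
  target <- target_correlation("HC", regions, cc)
  rms <- sqrt(mean((emp - target)^2))
  expect_lt(rms, 0.05)
})

test_that("injected seed-edge offsets are recovered with sign and magnitude", {
  regions <- mini_regions(5, c("left-frontal", "left-temporal"))
  cc <- mini_config(noise = quiet_noise(), task_amp = no_task(),
                    subject_sd = 0,
                    offsets = c("HC" = 0, "TLE-HS" = -0.3, "TLE-NHS" = 0.15))
  d <- make_design(1, 1000, 1000, 1)
  seed_edges <- function(group, n = 20) {
    vapply(seq_len(n), function(i) {
      s <- simulate_subject(group, d, regions, cc, seed = 100 * i + 7)
      M <- cor(t(unclass(s$series)))
      mean(M["leftfrontal1", paste0("leftfrontal", 2:5)])
    }, numeric(1))
  }
  hc <- mean(seed_edges("HC"))
  hs <- mean(seed_edges("TLE-HS"))
  expect_lt(hs, hc)
  expect_equal(hc - hs, 0.3, tolerance = 0.06)
})

test_that("behavioural scores track seed connectivity under a positive slope", {
  regions <- mini_regions(5, c("left-frontal", "left-temporal"))
  cc <- mini_config(group_sizes = c("HC" = 70, "TLE-HS" = 65, "TLE-NHS" = 65),
                    subject_sd = 0.1, seed = 9)
  d <- make_design(1, 5, 5, 1)
  co <- suppressWarnings(simulate_cohort(cc, d, regions)) # PSD repair expected
  expect_equal(nrow(co$subjects), 200)
  expect_gt(cor(co$subjects$vfp, co$subjects$seed_conn), 0.3)
})

test_that("non-PSD targets are repaired with a warning; unknown group errors", {
  regions <- mini_regions(4, c("left-frontal", "left-temporal"))
  cc <- mini_config(offsets = c("HC" = 0, "TLE-HS" = -1.2, "TLE-NHS" = 0))
  expect_warning(C <- target_correlation("TLE-HS", regions, cc),
                 "positive semi-definite")
  expect_gte(min(eigen(C, symmetric = TRUE)$values), 0)
  expect_error(target_correlation("nope", regions, cc), "unknown group")
  expect_error(simulate_subject("nope", make_design(1, 5, 5, 1), regions, cc, 1),
               "unknown group")
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(group_sizes = c("HC" = 1, "TLE-HS" = 5,
                                             "TLE-NHS" = 5)))
  expect_error(cohort_config(noise = modifyList(quiet_noise(), list(ar = 1))),
               "AR")
  expect_error(cohort_config(noise = modifyList(quiet_noise(),
                                                list(obs_sd = -1))), "SD")
})
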