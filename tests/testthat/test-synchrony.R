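test_that("FDP equals positives over visits, including never-detected species", {
  counts <- tibble::tibble(
    site_id = rep(c("A", "B"), each = 2),
    year = rep(c(2000L, 2001L), 2),
    species_id = "sp1",
    k = c(5L, 0L, 10L, 2L)
  )
  obs <- obs_from_counts(counts, n_visits = 20)
  fdp <- compute_fdp(obs, species = c("sp1", "sp2"))
  expect_equal(nrow(fdp), 8) # 2 sites x 2 years x 2 species
  expect_equal(
    fdp$fdp[fdp$site_id == "A" & fdp$year == 2000 &
              fdp$species_id == "sp1"], 0.25)
  # sp2 never recorded: zero-positive records at every visited site-year
  sp2 <- fdp[fdp$species_id == "sp2", ]
  expect_equal(sp2$positives, rep(0L, 4))
  expect_equal(sp2$visits, rep(20L, 4))
})

test_that("FDP matches a brute-force tally on a toy table", {
  set.seed(31)
  obs <- tidyr::expand_grid(
    site_id = c("A", "B"), year = 2000:2001, visit_index = 1:6,
    species_id = c("x", "y")
  ) |>
    dplyr::mutate(detected = rbinom(dplyr::n(), 1, 0.4))
  fdp <- compute_fdp(obs)
  brute <- aggregate(detected ~ site_id + year + species_id, obs, sum)
  for (i in seq_len(nrow(brute))) {
    got <- fdp$fdp[fdp$site_id == brute$site_id[i] &
                     fdp$year == brute$year[i] &
                     fdp$species_id == brute$species_id[i]]
    expect_equal(got, brute$detected[i] / 6)
  }
})

test_that("delta-FDP is defined only for consecutive visited years", {
  fdp <- tibble::tibble(
    site_id = "A", species_id = "s",
    year = c(2000L, 2001L, 2002L), visits = 10L,
    positives = c(2L, 5L, 4L), fdp = c(0.2, 0.5, 0.4)
  )
  d <- compute_delta(fdp)
  expect_equal(d$delta_fdp, c(0.3, -0.1))
  # a gap yields no delta
  gap <- fdp[c(1, 3), ]
  expect_equal(nrow(compute_delta(gap)), 0)
  # constant series: all deltas zero; single year: empty, not an error
  const <- dplyr::mutate(fdp, fdp = 0.3)
  expect_true(all(compute_delta(const)$delta_fdp == 0))
  expect_equal(nrow(compute_delta(fdp[1, ])), 0)
})

test_that("inclusion rules drop absent sites and sparse species with a log", {
  base <- tidyr::expand_grid(
    site_id = c("A", "B", "C", "D"), species_id = c("s1", "s2"),
    year = 2000:2009
  ) |>
    dplyr::mutate(visits = 10L, positives = 3L, fdp = 0.3)
  # s1 absent 8 of 10 years at site A; s2 present only at A and B
  base$positives[base$site_id == "A" & base$species_id == "s1" &
                   base$year <= 2007] <- 0L
  base$positives[base$species_id == "s2" &
                   base$site_id %in% c("C", "D")] <- 0L
  res <- apply_inclusion_rules(base, min_sites = 3, absence_years = 8)
  expect_false(any(res$fdp$site_id == "A" & res$fdp$species_id == "s1"))
  expect_true(all(c("B", "C", "D") %in%
                    res$fdp$site_id[res$fdp$species_id == "s1"]))
  expect_false("s2" %in% res$fdp$species_id)
  expect_setequal(res$exclusions$rule[res$exclusions$species_id == "s2"],
                  c("site_absence", "min_sites"))
  # a species positive every year at enough sites is untouched
  ok <- tidyr::expand_grid(site_id = c("A", "B", "C", "D"),
                           species_id = "s3", year = 2000:2009) |>
    dplyr::mutate(visits = 10L, positives = 2L, fdp = 0.2)
  res2 <- apply_inclusion_rules(ok)
  expect_equal(nrow(res2$fdp), nrow(ok))
  expect_equal(nrow(res2$exclusions), 0)
})

test_that("consecutive-absence variant counts runs, not totals", {
  base <- tidyr::expand_grid(site_id = c("A", "B", "C"), species_id = "s",
                             year = 2000:2011) |>
    dplyr::mutate(visits = 10L, positives = 1L, fdp = 0.1)
  # site A: 8 absent years but longest run is 4
  absent_years <- c(2000:2003, 2006:2009)
  base$positives[base$site_id == "A" & base$year %in% absent_years] <- 0L
  total <- apply_inclusion_rules(base, min_sites = 2, absence_years = 8)
  expect_false("A" %in% total$fdp$site_id)
  runs <- apply_inclusion_rules(base, min_sites = 2, absence_years = 8,
                                consecutive = TRUE)
  expect_true("A" %in% runs$fdp$site_id)
})

test_that("synchrony index is the mean pairwise Pearson r", {
  # identical delta series at 3 sites: every pairwise r is 1
  d <- tidyr::expand_grid(site_id = c("A", "B", "C"), species_id = "s") |>
    tidyr::expand_grid(year = 2001:2006) |>
    dplyr::mutate(delta_fdp = rep(c(0.1, -0.2, 0.3, 0, -0.1, 0.2), 3))
  idx <- synchrony_index(d, min_overlap_years = 3)
  expect_equal(idx$index, 1.0)
  expect_equal(idx$n_pairs, 3L)

  # hand-computed mean of three pairwise correlations
  set.seed(7)
  d2 <- tidyr::expand_grid(site_id = c("A", "B", "C"), year = 2001:2006) |>
    dplyr::mutate(species_id = "s", delta_fdp = round(runif(18, -0.5, 0.5), 3))
  wide <- tidyr::pivot_wider(d2, id_cols = year, names_from = site_id,
                             values_from = delta_fdp)
  hand <- mean(c(cor(wide$A, wide$B), cor(wide$A, wide$C),
                 cor(wide$B, wide$C)))
  idx2 <- synchrony_index(d2, min_overlap_years = 3)
  expect_equal(idx2$index, hand, tolerance = 1e-12)
})

test_that("pairs with zero variance or short overlap are dropped and logged", {
  d <- tidyr::expand_grid(site_id = c("A", "B", "C"), year = 2001:2006) |>
    dplyr::mutate(species_id = "s",
                  delta_fdp = ifelse(site_id == "C", 0,
                                     round(sin(seq_len(18)), 3)))
  idx <- synchrony_index(d, min_overlap_years = 3)
  log <- attr(idx, "pair_log")
  expect_equal(sum(is.finite(log$r)), 1) # only A-B survives
  expect_true(any(grepl("zero-variance", log$dropped)))
  # overlap shorter than the threshold
  short <- d[d$site_id != "C" & d$year <= 2003, ]
  idx2 <- synchrony_index(short, min_overlap_years = 5)
  expect_true(is.na(idx2$index))
  expect_equal(idx2$n_pairs, 0L)
})

test_that("index is invariant to site relabeling/order", {
  set.seed(11)
  d <- tidyr::expand_grid(site_id = c("A", "B", "C", "D"),
                          year = 2001:2010) |>
    dplyr::mutate(species_id = "s", delta_fdp = rnorm(40, 0, 0.2))
  idx1 <- synchrony_index(d, min_overlap_years = 3)$index
  relab <- d |>
    dplyr::mutate(site_id = c(A = "Z", B = "Q", C = "M",
                              D = "B")[site_id]) |>
    dplyr::arrange(dplyr::desc(site_id), year)
  idx2 <- synchrony_index(relab, min_overlap_years = 3)$index
  expect_equal(idx1, idx2, tolerance = 1e-12)
})

test_that("species covariates have exact z-scores and sensible raw values", {
  st <- shared_study()
  fdp <- compute_fdp(st$observations)
  incl <- apply_inclusion_rules(fdp)
  delta <- compute_delta(incl$fdp)
  covs <- species_covariates(incl$fdp, delta)
  for (v in c("abundance_z", "avg_sites_occupied_z", "trend_z")) {
    expect_lt(abs(mean(covs[[v]])), 1e-12)
    expect_lt(abs(sd(covs[[v]]) - 1), 1e-12)
  }
  # a species detected on every visit everywhere has abundance 1
  # (v occupies only site A so the occupancy covariate has spread)
  always <- tidyr::expand_grid(site_id = c("A", "B"), year = 2000:2005,
                               species_id = c("u", "v")) |>
    dplyr::mutate(visits = 5L,
                  positives = dplyr::case_when(
                    species_id == "u" ~ 5L,
                    site_id == "A" ~ 1L + (year %% 2L),
                    TRUE ~ 0L
                  ),
                  fdp = positives / visits)
  cv <- species_covariates(always, compute_delta(always))
  expect_equal(cv$abundance[cv$species_id == "u"], 1.0)
  # monotone decline gives negative trend
  dec <- tidyr::expand_grid(site_id = c("A", "B"), year = 2000:2005,
                            species_id = c("w", "x")) |>
    dplyr::group_by(site_id, species_id) |>
    dplyr::mutate(visits = 10L,
                  fdp = dplyr::case_when(
                    species_id == "w" ~ 0.9 - 0.1 * (year - 2000),
                    site_id == "A" ~ 0.5,
                    TRUE ~ 0
                  ),
                  positives = as.integer(fdp * 10)) |>
    dplyr::ungroup()
  cv2 <- species_covariates(dec, compute_delta(dec))
  expect_lt(cv2$trend[cv2$species_id == "w"], 0)
  # single species: z-scoring undefined
  expect_error(species_covariates(always[always$species_id == "u", ],
                                  compute_delta(always)),
               class = "popsync_error_degenerate")
})

test_that("distribution summary counts thresholds exactly", {
  idx <- tibble::tibble(index = c(0.82, 0.56, 0.41, 0.30, 0.25, 0.21,
                                  0.15, 0.12, 0.07, 0.02, -0.04, -0.11))
  s <- synchrony_distribution_summary(idx)
  expect_equal(s$n_species, 12)
  expect_equal(s$n_over_0.1, 8)
  expect_equal(s$n_over_0.2, 6)
  expect_equal(s$n_over_0.4, 3)
  expect_equal(s$n_negative, 2)
  expect_equal(s$min_index, -0.11)
})
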