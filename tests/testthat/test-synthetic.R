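test_that("the generator is bitwise reproducible from its seed", {
  a <- generate_system(synthetic_spec(n_frames = 40L, seed = 33L))
  b <- generate_system(synthetic_spec(n_frames = 40L, seed = 33L))
  expect_identical(a$trajectory$positions, b$trajectory$positions)
  expect_identical(a$truth$intervals, b$truth$intervals)
  c <- generate_system(synthetic_spec(n_frames = 40L, seed = 34L))
  expect_false(identical(a$trajectory$positions, c$trajectory$positions))
})

test_that("spec validation rejects impossible configurations", {
  expect_error(synthetic_spec(seed = 1L, lipids_per_leaflet = 5000L),
               "overfilled")
  expect_error(synthetic_spec(
    seed = 1L,
    sites = list(list(residues = 1:2, leaflet = "inner",
                      affinity = list(PS = c(k_on = 1.5, k_off = 0.1))))
  ), "rates")
  expect_error(synthetic_spec(
    seed = 1L,
    sites = list(list(residues = 40:42, leaflet = "inner",
                      affinity = list(PS = c(k_on = 0.5, k_off = 0.1))))
  ), "exceed")
  expect_error(synthetic_spec(n_frames = 50L), "seed")
})

test_that("realised dwells are geometric with the planted mean", {
  k_off <- 0.05
  spec <- synthetic_spec(
    n_frames = 2000L,
    sites = list(
      list(residues = 1:3, leaflet = "inner",
           affinity = list(PIP2 = c(k_on = 0.6, k_off = k_off),
                           PS = c(k_on = 0.6, k_off = k_off))),
      list(residues = 7:9, leaflet = "inner",
           affinity = list(PS = c(k_on = 0.6, k_off = k_off)))
    ),
    seed = 101L
  )
  sys <- generate_system(spec)
  iv <- sys$truth$intervals
  # drop censored intervals at either end of the observation window
  iv <- iv[iv$start_frame > 0L & iv$end_frame < 1999L, ]
  dwell <- iv$end_frame - iv$start_frame + 1L
  expect_gte(length(dwell), 500L)
  se <- sd(dwell) / sqrt(length(dwell))
  expect_lt(abs(mean(dwell) - 1 / k_off), 2 * se + 1e-9)
  # goodness of fit against the geometric pmf (chi-squared, alpha = 0.01)
  brk <- c(seq(0, 60, by = 10), Inf)
  obs <- table(cut(dwell, brk))
  p <- diff(stats::pgeom(c(seq(0, 60, by = 10), Inf) - 1, k_off))
  keep <- p > 0
  gof <- suppressWarnings(stats::chisq.test(as.integer(obs)[keep],
                                            p = p[keep] / sum(p[keep])))
  expect_gt(gof$p.value, 0.01)
})

test_that("zero on-rates leave every site untouched", {
  spec <- synthetic_spec(
    n_frames = 80L,
    sites = list(list(residues = 1:3, leaflet = "inner",
                      affinity = list(PIP2 = c(k_on = 0, k_off = 0.05)))),
    seed = 55L
  )
  sys <- generate_system(spec)
  expect_equal(nrow(sys$truth$intervals), 0L)
  rec <- contact_events(sys$trajectory, sys$topology, "PIP2")
  occ <- site_occupancy(rec, sys$truth$sites$residues[[1L]])
  expect_equal(nrow(occ), 0L)
})

test_that("GRO output conforms to the fixed-width standard (read.fwf oracle)", {
  sys <- generate_system(synthetic_spec(n_frames = 2L,
                                        lipids_per_leaflet = 25L, seed = 3L))
  path <- withr::local_tempfile(fileext = ".gro")
  write_system(sys$topology, sys$trajectory, path)
  lines <- readLines(path)
  natoms <- as.integer(lines[2L])
  fwf <- utils::read.fwf(
    textConnection(lines[3:(2L + natoms)]),
    widths = c(5L, 5L, 5L, 5L, 8L, 8L, 8L), stringsAsFactors = FALSE
  )
  expect_false(anyNA(fwf$V1))
  expect_false(anyNA(fwf$V5 + fwf$V6 + fwf$V7))
  expect_equal(as.integer(fwf$V4), 1:natoms)
  got <- as.matrix(fwf[, 5:7])
  dimnames(got) <- NULL
  expect_lt(max(abs(got - frame_positions(sys$trajectory, 1L))), 5.001e-4)
})

test_that("occupancy-tier dwell means follow frame_interval / k_off", {
  occ <- simulate_site_occupancy(200L, 600L, k_on = 0.05, k_off = 0.05,
                                 seed = 77L)
  runs <- unlist(apply(unclass(occ), 1L, function(r) {
    e <- rle(r)
    e$lengths[e$values]
  }))
  expect_gt(length(runs), 500L)
  se <- sd(runs) / sqrt(length(runs))
  expect_lt(abs(mean(runs) - 20), 3 * se)
  # same seed reproduces exactly
  occ2 <- simulate_site_occupancy(200L, 600L, k_on = 0.05, k_off = 0.05,
                                  seed = 77L)
  expect_identical(unclass(occ), unclass(occ2))
})

test_that("two-species competition ranks site occupancy by affinity", {
  spec <- synthetic_spec(
    n_frames = 300L,
    sites = list(list(residues = 1:3, leaflet = "inner",
                      affinity = list(PIP2 = c(k_on = 0.5, k_off = 0.02),
                                      PS = c(k_on = 0.2, k_off = 0.10)))),
    seed = 202L
  )
  sys <- generate_system(spec)
  site <- sys$truth$sites$residues[[1L]]
  frac <- vapply(c("PIP2", "PS"), function(sp) {
    rec <- contact_events(sys$trajectory, sys$topology, sp)
    occ <- site_occupancy(rec, site)
    if (nrow(occ) == 0L) return(0)
    mean(colSums(unclass(occ)) > 0L)
  }, numeric(1L))
  expect_gt(frac[["PIP2"]], frac[["PS"]])
  expect_gt(frac[["PIP2"]], 0.5)
})
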