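# CLPP metrics from EcoPlate series: parsing, blank correction, Eqs for
# AWCD / McIntosh U / Shannon H' / Rsi, guild profiles, PCA.

test_that("well labels convert row-major and invalid labels error", {
  expect_identical(well_index(c("A1", "A2", "B1", "H12")),
                   c(0L, 1L, 12L, 95L))
  expect_identical(well_index(c(0, 95)), c(0L, 95L))
  expect_error(well_index("I1"), "Invalid well label")
  expect_error(well_index(96), "0..95")
})

test_that("the built-in EcoPlate layout satisfies its invariants", {
  layout <- eco_layout()
  expect_equal(sum(!layout$is_control), 31)
  expect_equal(sum(layout$is_control), 1)
  wells <- unlist(layout$wells)
  expect_equal(sort(wells), 0:95)
  expect_true(all(lengths(layout$wells) == 3))
  expect_setequal(unique(na.omit(layout$guild)), eco_guilds)
})

test_that("plate CSV round-trips and format violations are caught", {
  series <- plate_from_diffs(
    setNames(rep(0.5, 31), eco_layout()$substrate_id[!eco_layout()$is_control]),
    control = 0.1, times = c(0, 12))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::as_tibble(series), path)
  back <- read_plate_series(path)
  expect_equal(sort(unique(back$time_h)), c(0, 12))
  expect_equal(nrow(back), 2 * 2 * 96)

  # drop the 750 nm readings at t = 12 -> format error
  broken <- tibble::as_tibble(series)
  broken <- broken[!(broken$time_h == 12 & broken$wavelength == 750), ]
  readr::write_csv(broken, path)
  expect_error(read_plate_series(path), "Missing wavelength")

  # negative absorbance -> validation error naming the cell
  neg <- tibble::as_tibble(series)
  neg$od[1] <- -0.01
  readr::write_csv(neg, path)
  expect_error(read_plate_series(path), "Negative absorbance")
})

test_that("blank correction averages replicates, subtracts control, clamps", {
  subs <- eco_layout()$substrate_id[!eco_layout()$is_control]
  diffs <- setNames(rep(0.3, 31), subs)   # equal to control -> all zero
  diffs["Tween 40"] <- 0.9                # 0.9 - 0.3 = 0.6
  diffs["D-xylose"] <- 0.2                # 0.2 - 0.3 -> clamped to 0
  resp <- blank_corrected_response(plate_from_diffs(diffs, control = 0.3), 72)
  v <- setNames(resp$value, resp$substrate_id)
  expect_equal(unname(v["Tween 40"]), 0.6, tolerance = 1e-12)
  expect_equal(unname(v["D-xylose"]), 0)
  expect_equal(unname(v["L-arginine"]), 0)
  expect_equal(resp$raw_ci[resp$substrate_id == "D-xylose"] -
                 resp$control_value[resp$substrate_id == "D-xylose"],
               -0.1, tolerance = 1e-12)
})

test_that("snapshot selection snaps within tolerance and can interpolate", {
  subs <- eco_layout()$substrate_id[!eco_layout()$is_control]
  series <- plate_from_diffs(setNames(rep(0.8, 31), subs), control = 0.2,
                             times = c(0, 70, 140))
  snapped <- blank_corrected_response(series, 72)
  expect_equal(snapped$time_h[1], 70)
  expect_error(blank_corrected_response(series, 100), "No timepoint within")
  interp <- blank_corrected_response(series, 105, interpolate = TRUE)
  expect_equal(interp$time_h[1], 105)
  expect_equal(interp$value[1], 0.6, tolerance = 1e-12)  # constant diffs
})

test_that("AWCD, McIntosh U and Shannon H' match their closed forms", {
  expect_equal(awcd(c(0.2, 0.4, 0.6)), 0.4)
  expect_equal(awcd(rep(0, 5)), 0)
  # clamp then mean: raw Ci - R = (-0.1, 0.3, 0.6)
  resp <- response_from_values(c(-0.1, 0.3, 0.6))
  expect_equal(awcd(resp), 0.3)

  expect_equal(mcintosh_u(0.7), 0.7)
  expect_equal(mcintosh_u(c(3, 4)), 5)
  expect_equal(mcintosh_u(rep(0.42, 31)), 0.42 * sqrt(31))

  expect_equal(shannon_h(c(1, 1)), log(2))
  expect_equal(shannon_h(c(0, 5, 0)), 0)
  for (k in c(3, 7, 31)) expect_equal(shannon_h(rep(2.5, k)), log(k))
  expect_error(shannon_h(rep(0, 31)), "Degenerate")
})

test_that("Rsi normalisation sums to n and CLPP identities hold on random plates", {
  expect_equal(unname(normalize_rsi(c(0.2, 0.4, 0.6))), c(0.5, 1, 1.5))
  expect_true(all(normalize_rsi(rep(0.7, 31)) == 1))
  expect_error(normalize_rsi(rep(0, 4)), "AWCD is zero")

  set.seed(42)
  for (i in 1:200) {
    v <- pmax(rnorm(31, 0.6, 0.5), 0)
    if (sum(v) == 0) next
    expect_equal(sum(normalize_rsi(v)), 31, tolerance = 1e-9)
    expect_lte(shannon_h(v), log(31) + 1e-12)
    expect_equal(mcintosh_u(v), sqrt(sum(v^2)))
    expect_equal(awcd(sample(v)), awcd(v))  # label permutation invariance
  }
})

test_that("U is monotone in any single well value", {
  v <- c(0.1, 0.5, 0.9, 0.3)
  for (i in seq_along(v)) {
    w <- v; w[i] <- w[i] + 0.2
    expect_gt(mcintosh_u(w), mcintosh_u(v))
  }
})

test_that("awcd_curve is flat zero on blank plates and tracks kinetics", {
  subs <- eco_layout()$substrate_id[!eco_layout()$is_control]
  blank <- plate_from_diffs(setNames(rep(0.3, 31), subs), control = 0.3,
                            times = c(0, 24, 48))
  curve <- awcd_curve(blank)
  expect_equal(curve$awcd, rep(0, 3))

  single <- plate_from_diffs(setNames(rep(0.5, 31), subs), control = 0.1,
                             times = 72)
  expect_equal(nrow(awcd_curve(single)), 1)

  # noiseless logistic kinetics -> nondecreasing curve
  cfg <- scenario_config(samples_per_group = 1)
  cfg$plate$noise_sd <- 0
  meta <- gen_metadata(cfg, seed = 5)[1, ]
  curve <- awcd_curve(gen_plate_series(cfg, meta, seed = 5))
  expect_true(all(diff(curve$awcd) >= -1e-9))
})

test_that("guild profile equals direct per-guild averaging", {
  layout <- eco_layout()
  subs <- layout$substrate_id[!layout$is_control]
  set.seed(7)
  diffs <- setNames(runif(31, 0.2, 1.2), subs)
  resp <- blank_corrected_response(plate_from_diffs(diffs, control = 0.2), 72)
  prof <- guild_profile(resp)
  # independent oracle: direct tapply over the layout's guild map
  v <- setNames(resp$value, resp$substrate_id)
  guild_map <- setNames(layout$guild, layout$substrate_id)[names(v)]
  expected <- tapply(v, guild_map, mean)
  expect_equal(prof$mean_response, as.vector(expected[prof$guild]),
               tolerance = 1e-12)

  # only esters nonzero
  d2 <- setNames(rep(0.2, 31), subs)
  ester <- layout$substrate_id[!is.na(layout$guild) & layout$guild == "ester"]
  d2[ester] <- 0.9
  prof2 <- guild_profile(blank_corrected_response(
    plate_from_diffs(d2, control = 0.2), 72))
  vals <- setNames(prof2$mean_response, prof2$guild)
  expect_gt(vals["ester"], 0)
  expect_true(all(vals[setdiff(names(vals), "ester")] == 0))
})

test_that("CLPP PCA matches a direct eigendecomposition oracle", {
  # rank-1 matrix: first axis explains everything
  r1 <- outer(c(1, 2, 3, 4), c(0.5, 1, 1.5))
  p1 <- clpp_pca(otu_tbl(r1))
  expect_equal(p1$explained[1], 1, tolerance = 1e-12)

  # duplicated samples get identical scores
  m <- rbind(c(1, 0, 2), c(1, 0, 2), c(0, 2, 1), c(2, 1, 0))
  p2 <- clpp_pca(otu_tbl(m))
  expect_equal(unlist(p2$scores[1, -1]), unlist(p2$scores[2, -1]))

  # 4 x 3 hand matrix: eigendecomposition of the covariance as oracle
  set.seed(1)
  h <- matrix(rnorm(12), 4, 3)
  ph <- clpp_pca(otu_tbl(h))
  ev <- eigen(stats::cov(h))
  expect_equal(ph$sdev^2, ev$values[seq_along(ph$sdev)], tolerance = 1e-9)
  centered <- scale(h, scale = FALSE)
  oracle_scores <- centered %*% ev$vectors
  got <- as.matrix(ph$scores[-1])
  for (j in 1:ncol(got)) {
    expect_equal(abs(got[, j]), abs(oracle_scores[, j]), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }

  # scores preserve pairwise distances of the centred input
  expect_equal(as.matrix(dist(got)), as.matrix(dist(centered)),
               tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(clpp_pca(otu_tbl(matrix(1, 3, 3))), "zero variance")
})

test_that("clpp_metrics summarises many samples at once", {
  subs <- eco_layout()$substrate_id[!eco_layout()$is_control]
  s1 <- plate_from_diffs(setNames(rep(0.6, 31), subs), control = 0.2,
                         sample_id = "A")
  s2 <- plate_from_diffs(setNames(rep(0.9, 31), subs), control = 0.2,
                         sample_id = "B")
  series <- plate_series(dplyr::bind_rows(s1, s2))
  met <- clpp_metrics(series, time_h = 72)
  expect_equal(met$awcd, c(0.4, 0.7), tolerance = 1e-12)
  expect_equal(met$mcintosh_u, c(0.4, 0.7) * sqrt(31), tolerance = 1e-12)
  expect_equal(met$shannon_h, rep(log(31), 2), tolerance = 1e-12)
})
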