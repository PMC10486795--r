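constant_voi <- function(value = 80, n = 5) {
  list(vol = image_volume(array(value, c(n, n, n)), c(1, 1, 1)),
       mask = array(TRUE, c(n, n, n)))
}

test_that("grey-level descriptors are order statistics over the mask only", {
  cv <- constant_voi(80)
  g <- grey_level_descriptors(cv$vol, cv$mask)
  expect_equal(unname(g[c("HUmin", "HUmean", "HUmax", "HUQ2")]), rep(80, 4))
  expect_equal(unname(g["HUstd"]), 0)

  vals <- array(0, c(3, 3, 3)); vals[1:9] <- 1:9
  m <- array(FALSE, c(3, 3, 3)); m[1:9] <- TRUE
  q <- grey_level_descriptors(vals, m)
  expect_equal(unname(q[c("HUQ1", "HUQ2", "HUQ3")]), c(3, 5, 7))
  expect_true(q["HUQ1"] <= q["HUQ2"] && q["HUQ2"] <= q["HUQ3"])

  m1 <- array(FALSE, c(3, 3, 3)); m1[2, 2, 2] <- TRUE
  vals[2, 2, 2] <- 42.5
  s <- grey_level_descriptors(vals, m1)
  expect_equal(unname(s[c("HUmin", "HUmean", "HUmax", "HUQ1", "HUQ2", "HUQ3")]),
               rep(42.5, 6))
  expect_equal(unname(s["HUstd"]), 0)

  expect_error(grey_level_descriptors(vals, array(FALSE, c(3, 3, 3))), "empty")
})

test_that("histogram features match their analytic values", {
  vals <- array(0, c(3, 1, 1)); vals[] <- c(-1, 0, 1)
  m <- array(TRUE, c(3, 1, 1))
  h <- histogram_features(vals, m, discretization_scheme(n_bins = 2))
  expect_equal(unname(h["Skewness"]), 0)

  cv <- constant_voi(80)  # all mass in one bin
  h2 <- suppressWarnings(histogram_features(cv$vol, cv$mask))
  expect_equal(unname(h2["Histogram_Energy"]), 1)
  expect_equal(unname(h2["Histogram_Entropy"]), 0)
  expect_true(is.na(h2["Skewness"]) && is.na(h2["Kurtosis"]))
  expect_warning(histogram_features(cv$vol, cv$mask), "zero-variance")

  # uniform over B bins: entropy log2(B), energy 1/B
  B <- 8L
  vals3 <- array(rep(seq_len(B), each = 4), c(B * 4, 1, 1))
  m3 <- array(TRUE, c(B * 4, 1, 1))
  h3 <- histogram_features(vals3, m3, discretization_scheme(n_bins = B))
  expect_equal(unname(h3["Histogram_Entropy"]), log2(B))
  expect_equal(unname(h3["Histogram_Energy"]), 1 / B)
})

test_that("shape features reproduce closed forms and refine toward a sphere", {
  cm <- array(FALSE, c(12, 12, 12)); cm[3:8, 3:8, 3:8] <- TRUE
  sf <- shape_features(cm, c(1, 1, 1), method = "faces")
  expect_equal(unname(sf["Shape_Sphericity"]), (pi / 6)^(1 / 3), tolerance = 1e-10)
  expect_equal(unname(sf["Shape_Compacity"]),
               (6 * 36)^1.5 / 216, tolerance = 1e-10)

  v10 <- shape_features(array(TRUE, c(10, 10, 10)), c(1, 1, 1))
  expect_equal(unname(v10["Shape_Volume_mL"]), 1.0)

  digital_sphere <- function(r, sp = 1) {
    n <- 2 * ceiling(r / sp) + 9
    ax <- ((1:n) - (n + 1) / 2) * sp
    outer(outer(ax^2, ax^2, `+`), ax^2, `+`) <= r^2
  }
  sph <- vapply(c(8, 12, 20), function(r)
    shape_features(digital_sphere(r), c(1, 1, 1))[["Shape_Sphericity"]],
    numeric(1))
  expect_true(all(abs(sph[-1] - 1) < abs(sph[1] - 1)))  # refinement approaches 1
  expect_gt(sph[3], 0.95)
  expect_lt(sph[3], 1.02)
  # mesh area of a digital ball is close to the analytic sphere area
  r <- 12
  expect_equal(surface_area(digital_sphere(r), c(1, 1, 1)), 4 * pi * r^2,
               tolerance = 0.03)
})

test_that("GLCM features on degenerate and structured VOIs", {
  cv <- constant_voi(80)
  g <- suppressWarnings(glcm_features(cv$vol, cv$mask))
  expect_equal(unname(g["GLCM_Energy"]), 1)
  expect_equal(unname(g["GLCM_Contrast"]), 0)
  expect_equal(unname(g["GLCM_Dissimilarity"]), 0)
  expect_true(is.na(g["GLCM_Correlation"]))

  # two levels alternating along x: x-direction matrix has contrast = gap^2
  vals <- array(rep(c(0, 100), length.out = 6 * 5 * 5), c(6, 5, 5))
  m <- array(TRUE, c(6, 5, 5))
  sch <- discretization_scheme(n_bins = 2)
  o <- oracle_glcm(vals, m, 2)
  p <- glcm_features(vals, m, sch)
  expect_equal(unname(p), unname(o), tolerance = 1e-12)
  # hand enumeration for the x direction alone: all pairs (1,2) -> contrast 1
  glev <- oracle_discretize(vals, m, 2)
  xpairs <- 0; same <- 0
  for (x in 1:5) for (y in 1:5) for (z in 1:5) {
    same <- same + (glev[x, y, z] == glev[x + 1, y, z])
    xpairs <- xpairs + 1
  }
  expect_equal(same, 0)  # strict alternation: every x-pair crosses the gap
})

test_that("matrix-based texture features equal exhaustive oracles on random VOIs", {
  sch <- discretization_scheme(n_bins = 6)
  for (seed in 1:12) {
    f <- random_voi(seed)
    vol <- image_volume(f$vals, c(1, 1, 1))
    expect_equal(unname(glcm_features(vol, f$mask, sch)),
                 unname(oracle_glcm(f$vals, f$mask, 6)),
                 tolerance = 1e-10, info = paste("glcm seed", seed))
    expect_equal(unname(glrlm_features(vol, f$mask, sch)),
                 unname(oracle_glrlm(f$vals, f$mask, 6)),
                 tolerance = 1e-10, info = paste("glrlm seed", seed))
    expect_equal(unname(ngldm_features(vol, f$mask, sch)),
                 unname(oracle_ngldm(f$vals, f$mask, 6)),
                 tolerance = 1e-10, info = paste("ngldm seed", seed))
    expect_equal(unname(glzlm_features(vol, f$mask, sch)),
                 unname(oracle_glzlm(f$vals, f$mask, 6)),
                 tolerance = 1e-10, info = paste("glzlm seed", seed))
  }
})

test_that("GLRLM single-run and alternating closed forms hold per direction", {
  # 1x1x5 constant line: z direction has one run of length 5
  vals <- array(50, c(7, 7, 9))
  m <- array(FALSE, c(7, 7, 9)); m[4, 4, 3:7] <- TRUE
  g <- oracle_discretize(vals, m, 4)
  runs_z <- oracle_runs(g, m, c(0, 0, 1))
  expect_equal(nrow(runs_z), 1)
  expect_equal(runs_z[1, 2], 5)
  iz <- oracle_rlm_indices(runs_z, sum(m))
  expect_equal(unname(iz["SRE"]), 1 / 25)
  expect_equal(unname(iz["RP"]), 1 / 5)
  # package path agrees with the oracle on the same VOI (direction average)
  expect_equal(unname(glrlm_features(vals, m, discretization_scheme(n_bins = 4))),
               unname(oracle_glrlm(vals, m, 4)), tolerance = 1e-12)

  # strict alternation along z: all z-runs length 1 -> SRE = 1 for that direction
  va <- array(0, c(3, 3, 8))
  va[] <- rep(c(0, 90), length.out = length(va)) # alternates along x; use x dir
  ma <- array(TRUE, c(3, 3, 8))
  ga <- oracle_discretize(va, ma, 2)
  runs_x <- oracle_runs(ga, ma, c(1, 0, 0))
  expect_true(all(runs_x[, 2] == 1))
  expect_equal(unname(oracle_rlm_indices(runs_x, sum(ma))["SRE"]), 1)
})

test_that("GLZLM zone closed forms hold", {
  cv <- constant_voi(70, 4)                      # one zone of 64 voxels
  z <- glzlm_features(cv$vol, cv$mask)
  expect_equal(unname(z["GLZLM_ZP"]), 1 / 64)
  expect_equal(unname(z["GLZLM_ZLNU"]), 1)
  # two disjoint constant zones of equal size and level -> ZLNU = 2
  vals <- array(0, c(9, 3, 3))
  m <- array(FALSE, c(9, 3, 3))
  m[1:2, 1, 1] <- TRUE; m[8:9, 1, 1] <- TRUE     # separated by > 1 voxel
  z2 <- glzlm_features(vals, m)
  expect_equal(unname(z2["GLZLM_ZLNU"]), 2)
  expect_equal(unname(z2["GLZLM_ZP"]), 2 / 4)
})

test_that("index identities hold on random fixtures", {
  sch <- discretization_scheme(n_bins = 5)
  for (seed in 21:26) {
    f <- random_voi(seed)
    vol <- image_volume(f$vals, c(1, 1, 1))
    r <- glrlm_features(vol, f$mask, sch)
    expect_lte(r[["GLRLM_SRE"]], 1 + 1e-12)
    expect_gt(r[["GLRLM_RP"]], 0)
    expect_lte(r[["GLRLM_RP"]], 1 + 1e-12)
    z <- glzlm_features(vol, f$mask, sch)
    expect_lte(z[["GLZLM_SZE"]], 1 + 1e-12)
    expect_gt(z[["GLZLM_ZP"]], 0)
    expect_lte(z[["GLZLM_ZP"]], 1 + 1e-12)
  }
})

test_that("texture features are invariant to global HU shifts under VOI-relative binning", {
  f <- random_voi(99)
  vol <- image_volume(f$vals, c(1, 1, 1))
  vol2 <- image_volume(f$vals + 250, c(1, 1, 1))
  sch <- discretization_scheme(n_bins = 8)
  expect_equal(glcm_features(vol, f$mask, sch), glcm_features(vol2, f$mask, sch))
  expect_equal(glrlm_features(vol, f$mask, sch), glrlm_features(vol2, f$mask, sch))
  expect_equal(glzlm_features(vol, f$mask, sch), glzlm_features(vol2, f$mask, sch))
  expect_equal(ngldm_features(vol, f$mask, sch), ngldm_features(vol2, f$mask, sch))
})

test_that("extract_all returns the stable 45-key contract per VOI", {
  cfg <- phantom_config(grid_shape = c(26, 26, 26), lesion_radii_mm = c(5, 5, 5),
                        seed = 5)
  ph <- make_phantom(cfg)
  pair <- make_margin(ph$tumor_mask, ph$volume, 5)
  fv <- extract_all(ph$volume, pair)
  expect_length(fv, 90)
  expect_equal(sum(startsWith(names(fv), "Portal_Tumor_")), 45)
  expect_equal(sum(startsWith(names(fv), "Portal_Margin_")), 45)
  expect_identical(sub("^Portal_Tumor_", "", names(fv)[1:45]),
                   radiomic_feature_names())
  # deterministic
  expect_identical(fv, extract_all(ph$volume, pair))
  # tumor and margin vectors differ on a heterogeneity-contrasted phantom
  expect_gt(sum(fv[1:45] != fv[46:90]), 40)

  # constant tumor: texture contrasts are 0, volume matches the voxel count
  c0 <- phantom_config(grid_shape = c(26, 26, 26), lesion_radii_mm = c(5, 5, 5),
                       heterogeneity = 0, noise_sd_hu = 0, seed = 1)
  p0 <- make_phantom(c0)
  pr0 <- make_margin(p0$tumor_mask, p0$volume, 5)
  f0 <- suppressWarnings(extract_all(p0$volume, pr0))
  expect_equal(unname(f0["Portal_Tumor_GLCM_Contrast"]), 0)
  expect_equal(unname(f0["Portal_Tumor_NGLDM_Contrast"]), 0)
  expect_equal(unname(f0["Portal_Tumor_Shape_Volume_mL"]),
               sum(p0$tumor_mask) / 1000)
})
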