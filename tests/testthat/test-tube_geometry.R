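test_that("regions tile [0, L] and canonical lesion layout is exact", {
  for (age in c("20s", "30s", "40s")) {
    tube <- build_tube(age, with_endometriosis = TRUE)
    lens <- vapply(tube$regions, function(r) r$end_s - r$start_s, numeric(1))
    expect_equal(sum(lens), tube$total_length)
    b <- vapply(tube$regions, function(r) r$start_s, numeric(1))
    e <- vapply(tube$regions, function(r) r$end_s, numeric(1))
    expect_equal(unname(e[1:3]), unname(b[2:4]))

    expect_length(tube$lesions, 5L)
    centers <- vapply(tube$lesions, function(l) l$center_s, numeric(1))
    # lesion 1 centred in the isthmus
    isth <- tube$regions$isthmus
    expect_equal(centers[1], (isth$start_s + isth$end_s) / 2)
    # lesions 2-5 inside the ampulla, consecutive spacing exactly 17 mm
    amp <- tube$regions$ampulla
    expect_true(all(centers[2:5] >= amp$start_s & centers[2:5] <= amp$end_s))
    expect_equal(diff(centers[2:5]), rep(17, 3))
    # printed footprint 10 x 5 mm
    expect_equal(vapply(tube$lesions, function(l) l$length, numeric(1)),
                 rep(10, 5))
    expect_equal(vapply(tube$lesions, function(l) l$width, numeric(1)),
                 rep(5, 5))
  }
})

test_that("age-dependent defaults are monotone and in the printed ranges", {
  t20 <- build_tube("20s"); t30 <- build_tube("30s"); t40 <- build_tube("40s")
  expect_equal(t30$cilia_density, 1600)
  expect_true(t20$cilia_density > t30$cilia_density)
  expect_true(t30$cilia_density > t40$cilia_density)
  for (tb in list(t20, t30, t40)) {
    expect_gte(tb$total_length, 85)
    expect_lte(tb$total_length, 105)
    expect_length(tb$lesions, 0L)
  }
  expect_error(build_tube("50s"), "unknown age group")
  expect_error(build_tube("20s", TRUE, lesion_count = 4), "lesion_count")
})

test_that("appendix lesion-count variants build valid models", {
  for (nl in c(3L, 7L, 10L)) {
    tube <- build_tube("20s", TRUE, lesion_count = nl)
    expect_length(tube$lesions, nl)
    centers <- vapply(tube$lesions, function(l) l$center_s, numeric(1))
    expect_true(all(centers >= 0 & centers <= tube$total_length))
  }
})

test_that("local radius is continuous across region boundaries", {
  tube <- build_tube("30s")
  for (r in tube$regions[1:3]) {
    s0 <- r$end_s
    expect_lt(abs(local_radius(tube, s0 - 1e-10, 0.3) -
                  local_radius(tube, s0 + 1e-10, 0.3)), 1e-9)
  }
  expect_error(local_radius(tube, tube$total_length + 1, 0), "outside")
})

test_that("lesions carve the lumen at their footprint only", {
  tube <- build_tube("20s", TRUE)
  les <- tube$lesions[[2]]
  r_les <- local_radius(tube, les$center_s, les$azimuth, folds = FALSE)
  r_free <- local_radius(build_tube("20s"), les$center_s, les$azimuth,
                         folds = FALSE)
  expect_equal(r_free - r_les, les$protrusion_frac * r_free)
  # opposite azimuth untouched
  expect_equal(local_radius(tube, les$center_s, les$azimuth + pi,
                            folds = FALSE),
               local_radius(build_tube("20s"), les$center_s,
                            les$azimuth + pi, folds = FALSE))
  expect_gt(min(local_radius(tube, seq(0, 105, by = 0.5), les$azimuth)), 0)
})

test_that("luminal area matches pi r^2 on circular sections and stays in range", {
  tube <- build_tube("20s", overrides = list(fold_depth = 0))
  s_mid <- mean(region_bounds(tube, "isthmus"))
  r <- local_radius(tube, s_mid, 0)
  expect_equal(luminal_area(tube, s_mid), pi * r^2,
               tolerance = 1e-6)
  # default 20s model: all areas within the anatomical 5-40 mm^2 range
  tube20 <- build_tube("20s")
  areas <- luminal_area(tube20, seq(0, tube20$total_length, length.out = 60))
  expect_true(all(areas >= 5 & areas <= 40))
  # lesioned section strictly smaller than lesion-free at the same s
  tend <- build_tube("20s", TRUE)
  les <- tend$lesions[[3]]
  expect_lt(luminal_area(tend, les$center_s), luminal_area(tube20, les$center_s))
})

test_that("zero-protrusion lesions leave the lumen identical to lesion-free", {
  tube0 <- build_tube("20s", TRUE,
                      overrides = list(lesion_protrusion_frac = 0))
  free <- build_tube("20s")
  s <- seq(1, 104, length.out = 40)
  expect_equal(luminal_area(tube0, s), luminal_area(free, s))
  expect_equal(local_radius(tube0, s, 0.7), local_radius(free, s, 0.7))
})

test_that("exported meshes are watertight and lesions reduce volume", {
  tube <- build_tube("20s")
  mesh <- export_mesh(tube, resolution = 16L)
  chk <- mesh_is_watertight(mesh)
  expect_true(chk$watertight)
  expect_equal(chk$euler, 2)  # closed capped tube is sphere-like
  # vertex count grows with resolution
  expect_gt(nrow(export_mesh(tube, 24L)$vertices), nrow(mesh$vertices))
  # lesions encroach: enclosed volume shrinks
  mesh_endo <- export_mesh(build_tube("20s", TRUE), resolution = 16L)
  expect_lt(mesh_volume(mesh_endo), mesh_volume(mesh))
  expect_error(export_mesh(tube, 4L), "resolution")
})

test_that("OBJ round-trip preserves the mesh", {
  mesh <- export_mesh(build_tube("40s"), resolution = 8L)
  f <- tempfile(fileext = ".obj")
  write_mesh(mesh, f)
  back <- read_obj(f)
  expect_equal(nrow(back$vertices), nrow(mesh$vertices))
  expect_equal(back$faces, mesh$faces)
  expect_equal(back$vertices, mesh$vertices, tolerance = 1e-6)
  fply <- tempfile(fileext = ".ply")
  write_mesh(mesh, fply)
  expect_true(file.exists(fply))
  unlink(c(f, fply))
})
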