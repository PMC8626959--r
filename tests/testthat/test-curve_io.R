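test_that("centerline construction recomputes arc lengths and validates input", {
  cl <- centerline(data.frame(x = c(0, 1, 2), y = 0, z = 0))
  expect_equal(cl$arclength, c(0, 1, 2))
  expect_equal(total_length(cl), 2)
  expect_error(centerline(data.frame(x = 1, y = 1, z = 1)), class = "bendmark_config_error")
  expect_error(centerline(data.frame(x = c(0, NA), y = 0, z = 0)), class = "bendmark_config_error")
  expect_warning(
    cl2 <- centerline(data.frame(x = c(0, 1, 1, 2), y = 0, z = 0)),
    "duplicate"
  )
  expect_equal(nrow(cl2), 3)
})

test_that("csv and vtp round trips preserve coordinates and agree across formats", {
  sip <- canonical_siphon()$centerline
  csv <- withr::local_tempfile(fileext = ".csv")
  vtp <- withr::local_tempfile(fileext = ".vtp")
  write_centerline(sip, csv)
  write_centerline(sip, vtp)
  c_csv <- read_centerline(csv)
  c_vtp <- read_centerline(vtp)
  expect_lt(max(abs(as_points(c_csv) - as_points(sip))), 1e-9)
  expect_lt(max(abs(as_points(c_vtp) - as_points(sip))), 1e-9)
  expect_equal(as_points(c_csv), as_points(c_vtp))
  expect_equal(c_csv$arclength, c_vtp$arclength)
})

test_that("reading rejects missing, malformed, and non-polyline inputs", {
  expect_error(read_centerline("no/such/file.csv"), class = "bendmark_io_error")
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,z", "1,2,three"), bad)
  expect_error(read_centerline(bad), class = "bendmark_io_error")
  short <- withr::local_tempfile(fileext = ".csv")
  writeLines("0,0,0", short)
  expect_error(read_centerline(short), class = "bendmark_io_error")
  novtp <- withr::local_tempfile(fileext = ".vtp")
  writeLines("<VTKFile type='PolyData'><PolyData><Piece>
    <Points><DataArray format='ascii'>0 0 0 1 0 0</DataArray></Points>
    </Piece></PolyData></VTKFile>", novtp)
  expect_error(read_centerline(novtp), class = "bendmark_io_error")
})

test_that("headerless csv input is accepted", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,0,0", "1,0,0", "2,0,0"), f)
  cl <- read_centerline(f)
  expect_equal(cl$arclength, c(0, 1, 2))
})

test_that("orient_centerline reverses only when the inlet is nearer the far end", {
  sip <- canonical_siphon()$centerline
  p <- as_points(sip)
  same <- orient_centerline(sip, p[1, ])
  expect_equal(as_points(same), p)
  flipped <- orient_centerline(sip, p[nrow(p), ])
  expect_equal(as_points(flipped), p[nrow(p):1, ])
  expect_equal(total_length(flipped), total_length(sip), tolerance = 1e-12)
  # Idempotence: orienting an already-oriented curve is a no-op.
  again <- orient_centerline(flipped, p[nrow(p), ])
  expect_equal(as_points(again), as_points(flipped))
  # Equidistant inlet is ambiguous.
  line <- centerline(cbind(c(0, 1, 2), 0, 0))
  expect_error(orient_centerline(line, c(1, 5, 0)), class = "bendmark_config_error")
})

test_that("write_result produces a faithful JSON + annotated polyline round trip", {
  res <- canonical_bogunovic()
  json <- withr::local_tempfile(fileext = ".json")
  vtp <- withr::local_tempfile(fileext = ".vtp")
  write_result(res, json_path = json, annotated_path = vtp)
  back <- read_result(json)
  expect_equal(back$algorithm, "bogunovic")
  expect_equal(
    as.data.frame(back$bends[, names(res$bends)]),
    as.data.frame(res$bends)
  )
  expect_equal(back$interfaces, res$interfaces)
  # Annotated polyline carries one BendId per point, -1 outside bends.
  doc <- xml2::read_xml(vtp)
  arr <- xml2::xml_find_first(doc, ".//PointData/DataArray[@Name='BendId']")
  ids <- as.integer(strsplit(trimws(xml2::xml_text(arr)), "\\s+")[[1]])
  expect_length(ids, nrow(res$centerline))
  expect_setequal(unique(ids), c(-1L, 0L, 1L, 2L, 3L))
  # Ids are ordered proximal -> distal where assigned.
  assigned <- ids[ids >= 0]
  expect_true(!is.unsorted(assigned))
})

test_that("empty and whole-curve results annotate every point consistently", {
  line <- resample_centerline(centerline(cbind(seq(0, 30, 5), 0, 0)), 0.5)
  empty <- suppressWarnings(landmark_piccinelli(
    line, piccinelli_config(preprocess_config(r = 0.5, lam = 0, n_iter = 0))
  ))
  expect_equal(nrow(empty$bends), 0)
  json <- withr::local_tempfile(fileext = ".json")
  vtp <- withr::local_tempfile(fileext = ".vtp")
  write_result(empty, json_path = json, annotated_path = vtp)
  back <- read_result(json)
  expect_equal(nrow(back$bends), 0)
  ids <- as.integer(strsplit(trimws(xml2::xml_text(xml2::xml_find_first(
    xml2::read_xml(vtp), ".//PointData/DataArray[@Name='BendId']"
  ))), "\\s+")[[1]])
  expect_true(all(ids == -1L))
  # One bend covering the whole curve annotates every point with 0.
  ids2 <- bendmark:::bend_id_per_point(
    tibble::tibble(start_arclength = 0, end_arclength = total_length(line)),
    line$arclength
  )
  expect_true(all(ids2 == 0L))
})
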