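test_that("read_mdf assembles base/tip clusters and computes extents", {
  path <- write_mdf(list(list(id = 1, tracks = list(
    `1` = pts(1:3, 0, 0),
    `2` = cbind(frame = 1:3, x = c(3, 6, 3), y = c(4, 8, 4))))))
  tracks <- read_mdf(path, acquisition_meta())
  expect_length(tracks, 1)
  expect_s3_class(tracks[[1]], "filopodium_track")
  pairs <- pair_frames(tracks[[1]])
  expect_equal(nrow(pairs), 3)
  s <- compute_extent_series(pairs, tracks[[1]])
  expect_equal(s$extents, c(5, 10, 5))
  expect_equal(nrow(attr(tracks, "rejected")), 0)
})

test_that("read_mdf handles empty files, missing tracks and exclusions", {
  p0 <- tempfile(); writeLines("MTrackJ 1.5.1 Data File", p0)
  expect_length(read_mdf(p0), 0)

  p1 <- write_mdf(list(list(id = 3, tracks = list(`1` = pts(1:3, 0, 0)))))
  tracks <- read_mdf(p1)
  expect_length(tracks, 0)
  rej <- attr(tracks, "rejected")
  expect_equal(rej$filopodium_id, 3L)
  expect_equal(rej$reason, "missing tip track")

  # non-filopodium reference tracks excluded via sidecar config
  p2 <- write_mdf(list(
    list(id = 1, tracks = list(`1` = pts(1:2, 0, 0),
                               `2` = pts(1:2, 3, 4))),
    list(id = 165, tracks = list(`1` = pts(1:2, 1, 1),
                                 `2` = pts(1:2, 2, 2)))))
  tracks <- read_mdf(p2, exclude_clusters = 165)
  expect_length(tracks, 1)
  expect_equal(attr(tracks, "rejected")$reason, "excluded by config")
})

test_that("read_mdf applies pixel calibration and linearity holds", {
  cl <- list(list(id = 1, tracks = list(
    `1` = pts(1:2, 0, 0), `2` = cbind(frame = 1:2, x = c(3, 6), y = c(4, 8)))))
  path <- write_mdf(cl)
  t_um <- read_mdf(path, acquisition_meta(pixel_size_um = 0.25))[[1]]
  expect_equal(series_of(t_um)$extents, c(5, 10))  # default: already um
  for (c_px in c(0.25, 0.5, 2)) {
    t_px <- read_mdf(path, acquisition_meta(pixel_size_um = c_px,
                                            coords = "pixel"))[[1]]
    expect_equal(series_of(t_px)$extents, c_px * c(5, 10))
  }
})

test_that("read_mdf rejects malformed input with line numbers", {
  bad <- tempfile()
  writeLines(c("MTrackJ 1.5.1", "Cluster 1 FF0000", "Track 1 FF0000",
               "Point 1 abc 2.0 1.0 1 1"), bad)
  expect_error(read_mdf(bad), "line 4")
  bad2 <- tempfile()
  writeLines(c("MTrackJ 1.5.1", "Cluster 1 FF0000", "Track 1 FF0000",
               "Point 1 1.0 2.0 1.0 1 1", "Point 2 1.5 2.0 1.0 1 1",
               "Track 2 FF0000", "Point 1 1.0 2.0 1.0 1 1"), bad2)
  expect_error(read_mdf(bad2), "duplicate frame")
  bad3 <- tempfile()
  writeLines(c("MTrackJ 1.5.1", "Garbage 1 2 3"), bad3)
  expect_error(read_mdf(bad3), "unknown record")
  notmdf <- tempfile(); writeLines("frame,x,y", notmdf)
  expect_error(read_mdf(notmdf), "MTrackJ")
})

test_that("parser accounts for every Point record", {
  path <- write_mdf(list(
    list(id = 1, tracks = list(`1` = pts(1:3, 0, 0), `2` = pts(1:3, 3, 4))),
    list(id = 2, tracks = list(`1` = pts(1:3, 1, 1)))))
  tracks <- read_mdf(path)
  n_accepted <- sum(vapply(tracks, function(tr)
    nrow(tr$base) + nrow(tr$tip), 1L))
  expect_equal(attr(tracks, "n_points"), 9L)
  expect_equal(n_accepted, 6L)  # remaining 3 belong to the rejected cluster
  expect_equal(nrow(attr(tracks, "rejected")), 1L)
})

test_that("CSV dialect round-trips bit-exactly and sorts deterministically", {
  fixture <- c("filopodium_id,role,frame,x_um,y_um,group_label",
               "1,base,1,0,0,wt", "1,base,2,0.25,0.5,wt", "1,base,3,0,0,wt",
               "1,tip,1,3,4,wt", "1,tip,2,6.125,8.5,wt", "1,tip,3,3,4,wt")
  f <- tempfile(fileext = ".csv")
  writeLines(fixture, f)
  tracks <- read_csv_tracks(f)
  expect_length(tracks, 1)
  expect_equal(tracks[[1]]$group_label, "wt")
  f2 <- tempfile(fileext = ".csv")
  write_csv_tracks(tracks, f2)
  expect_identical(readLines(f2), fixture)

  # output independent of input row order
  f3 <- tempfile(fileext = ".csv")
  writeLines(c(fixture[1], fixture[sample(2:7)]), f3)
  f4 <- tempfile(fileext = ".csv")
  write_csv_tracks(read_csv_tracks(f3), f4)
  expect_identical(readLines(f4), fixture)
})

test_that("CSV edge cases: header-only, empty list, bad role/number", {
  f <- tempfile(); writeLines(.track_csv_header <- paste0(
    "filopodium_id,role,frame,x_um,y_um,group_label"), f)
  expect_length(read_csv_tracks(f), 0)
  fo <- tempfile()
  write_csv_tracks(list(), fo)
  expect_identical(readLines(fo),
                   "filopodium_id,role,frame,x_um,y_um,group_label")
  fb <- tempfile()
  writeLines(c("filopodium_id,role,frame,x_um,y_um,group_label",
               "1,shaft,1,0,0,wt"), fb)
  expect_error(read_csv_tracks(fb), "unknown role")
  fn <- tempfile()
  writeLines(c("filopodium_id,role,frame,x_um,y_um,group_label",
               "1,base,1,zero,0,wt"), fn)
  expect_error(read_csv_tracks(fn), "non-numeric")
})

test_that("write_csv_tracks produces header + 2 rows per frame", {
  tr <- make_track(c(2, 4, 2))
  f <- tempfile()
  write_csv_tracks(list(tr), f)
  expect_length(readLines(f), 7L)
})

test_that("pair_frames keeps only common frames and rejects short tracks", {
  tr <- filopodium_track(1,
    base = data.frame(frame = 1:3, x = 0, y = 0),
    tip = data.frame(frame = 1:3, x = 3, y = 4))
  expect_equal(nrow(pair_frames(tr)), 3)

  tr2 <- filopodium_track(1,
    base = data.frame(frame = 1:3, x = 0, y = 0),
    tip = data.frame(frame = 2:4, x = 3, y = 4))
  expect_message(p2 <- pair_frames(tr2), "dropped 2")
  expect_equal(p2$frame, 2:3)
  expect_equal(attr(p2, "n_dropped"), 2L)

  tr3 <- filopodium_track(1,
    base = data.frame(frame = c(1, 5), x = 0, y = 0),
    tip = data.frame(frame = c(1, 7), x = 3, y = 4))
  expect_error(suppressMessages(pair_frames(tr3)), "track too short")
})
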