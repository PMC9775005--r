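test_that("a constant trace draws exactly one horizontal line", {
  sp <- raster_spec(64, 64)
  img <- render_trace_bitmap(rep(0.5, 250), sp)
  line_rows <- which(apply(img, 1, function(r) any(r == 0)))
  expect_length(line_rows, 1)
  expect_equal(line_rows, floor(0.5 * 63 + 0.5) + 1)  # y-map, 1-based row
  expect_equal(sum(img == 0), 64)                     # full-width line
})

test_that("rasterization is two-valued, connected and deterministic", {
  sp <- raster_spec(64, 64)
  set.seed(7)
  for (rep in 1:5) {
    tr <- runif(250)
    img <- render_trace_bitmap(tr, sp)
    expect_true(all(img %in% c(0L, 255L)))
    # every column is visited (the polyline spans the full width)
    expect_true(all(apply(img, 2, function(cc) any(cc == 0))))
    expect_identical(img, render_trace_bitmap(tr, sp))
  }
  # steep two-point segment hits both endpoint corners
  img2 <- render_trace_bitmap(c(0, 1), raster_spec(32, 32))
  expect_equal(img2[32, 1], 0)   # first sample: value 0 -> bottom-left
  expect_equal(img2[1, 32], 0)   # last sample: value 1 -> top-right
})

test_that("rasterizer rejects bad traces and unsupported modes", {
  sp <- raster_spec(64, 64)
  expect_error(render_trace_bitmap(c(0.5, NA, 0.2), sp),
               class = "eegdan_invalid_argument")
  expect_error(render_trace_bitmap(c(0.5, 1.5), sp),
               class = "eegdan_invalid_argument")
  expect_error(render_trace_bitmap(0.5, sp), class = "eegdan_invalid_argument")
  expect_error(render_trace_bitmap(runif(10), raster_spec(64, 64, antialias = TRUE)),
               class = "eegdan_invalid_argument")
  expect_error(raster_spec(16, 64), class = "eegdan_invalid_argument")
  expect_error(raster_spec(64, 64, line_value = 255, background_value = 255),
               class = "eegdan_invalid_argument")
})

test_that("merged chart overlays traces; overdraw is idempotent", {
  sp <- raster_spec(64, 64)
  w <- rbind(rep(0.25, 100), rep(0.5, 100), rep(0.75, 100))
  mc <- encode_merged_chart(w, sp)
  expect_equal(dim(mc$pixels), c(64, 64))
  rows <- which(apply(mc$pixels, 1, function(r) any(r == 0)))
  expect_equal(rows, floor((1 - c(0.75, 0.5, 0.25)) * 63 + 0.5) + 1)
  expect_true(all(mc$pixels %in% c(0L, 255L)))

  set.seed(2)
  tr <- runif(250)
  same <- rbind(tr, tr, tr)
  m3 <- encode_merged_chart(same, sp)
  expect_identical(m3$pixels, render_trace_bitmap(tr, sp))
})

test_that("RGB planes carry one channel each with white background", {
  sp <- raster_spec(64, 64)
  w <- rbind(rep(0.2, 250), rep(0.5, 250), rep(0.8, 250))
  im <- encode_rgb(w, sp)
  expect_equal(dim(im$pixels), c(64, 64, 3))
  # background pixel is white in all planes
  expect_equal(as.numeric(im$pixels[2, 2, ]), c(255, 255, 255))
  # a pixel covered only by the R-assigned channel is (0, 255, 255)
  r_row <- which(apply(im$pixels[, , 1], 1, function(r) any(r == 0)))[1]
  expect_equal(as.numeric(im$pixels[r_row, 1, ]), c(0, 255, 255))
  # identical traces in all channels give the merged silhouette in black
  set.seed(5)
  tr <- runif(250)
  im2 <- encode_rgb(rbind(tr, tr, tr), sp)
  mask <- im2$pixels[, , 1] == 0
  expect_true(all(im2$pixels[, , 2][mask] == 0) && all(im2$pixels[, , 3][mask] == 0))
  expect_identical(matrix(im2$pixels[, , 1], 64), render_trace_bitmap(tr, sp))
})

test_that("encode_rgb refuses axes and non-permutation maps", {
  w <- random_window()
  expect_error(encode_rgb(w, raster_spec(64, 64, draw_axes = TRUE)),
               class = "eegdan_invalid_argument")
  expect_error(encode_rgb(w, raster_spec(64, 64), channel_map = c(1L, 1L, 2L)),
               class = "eegdan_invalid_argument")
})

test_that("decode_rgb inverts encode_rgb on random windows", {
  sp <- raster_spec(64, 64)
  set.seed(11)
  for (rep in 1:100) {
    w <- random_window(100)
    im <- encode_rgb(w, sp)
    dec <- decode_rgb(im)
    for (ch in 1:3) {
      expect_identical(dec[[ch]], render_trace_bitmap(w[ch, ], sp))
    }
  }
  # all-white image decodes to empty masks
  blank <- im
  blank$pixels[] <- 255L
  dec0 <- decode_rgb(blank)
  expect_true(all(vapply(dec0, function(p) all(p == 255), TRUE)))
  # a gray plane violates the binary contract
  gray <- im
  gray$pixels[1, 1, 1] <- 128L
  expect_error(decode_rgb(gray), class = "eegdan_invalid_argument")
})

test_that("permuting the channel map permutes planes and nothing else", {
  sp <- raster_spec(64, 64)
  set.seed(13)
  w <- random_window()
  base <- encode_rgb(w, sp, channel_map = c(1L, 2L, 3L))
  perm <- c(3L, 1L, 2L)
  im <- encode_rgb(w, sp, channel_map = perm)
  for (p in 1:3) {
    expect_identical(im$pixels[, , p], base$pixels[, , perm[p]])
  }
  expect_identical(decode_rgb(im), decode_rgb(base))
})

test_that("PNG round-trip preserves pixels for both encodings", {
  sp <- raster_spec(64, 64)
  set.seed(17)
  w <- random_window()
  dir <- withr::local_tempdir()
  mc <- encode_merged_chart(w, sp)
  p1 <- file.path(dir, "merged.png")
  write_image_png(mc, p1)
  expect_equal(read_image_png(p1), mc$pixels, ignore_attr = TRUE)
  im <- encode_rgb(w, sp)
  p2 <- file.path(dir, "rgb.png")
  write_image_png(im, p2)
  expect_equal(read_image_png(p2), im$pixels, ignore_attr = TRUE)
})

test_that("encode_window_set rescales filtered windows and tags provenance", {
  co <- generate_cohort(1, 0, seed = 9, duration_s = 12)
  ws <- preprocess_recording(co[[1]])
  imgs <- encode_window_set(ws, "rgb", raster_spec(64, 64))
  expect_length(imgs, length(ws$windows))
  expect_equal(imgs[[2]]$window_index, 2)
  expect_equal(imgs[[1]]$subject_id, co[[1]]$subject_id)
  expect_equal(imgs[[1]]$label, "healthy")
})
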