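test_that("tile grids follow floor arithmetic and row-major order", {
  g <- tile_grid(4000, 3000, 1000)
  expect_equal(nrow(g), 12)
  expect_equal(max(g$row) + 1, 3)
  expect_equal(max(g$col) + 1, 4)
  expect_equal(g$origin_x[1:4], c(0, 1000, 2000, 3000)) # first row, row-major
  g1 <- tile_grid(1000, 1000, 1000)
  expect_equal(nrow(g1), 1)
  expect_equal(c(g1$origin_x, g1$origin_y), c(0, 0))
  # 1050 x 2100 (h x w): remainders dropped
  g2 <- tile_grid(2100, 1050, 1000)
  expect_equal(nrow(g2), 2)
  expect_error(tile_grid(500, 2000, 1000), "smaller than tile_size")
})

test_that("tiling then reassembling reproduces the cropped source exactly", {
  withr::local_seed(8)
  img <- array(runif(130 * 210 * 3, 0, 255), dim = c(130, 210, 3))
  tl <- tile_image(img, tile_size = 100)
  expect_equal(nrow(tl$grid), 2)
  rebuilt <- array(NA_real_, dim = c(100, 200, 3))
  for (i in seq_len(nrow(tl$grid))) {
    oy <- tl$grid$origin_y[i]; ox <- tl$grid$origin_x[i]
    rebuilt[(oy + 1):(oy + 100), (ox + 1):(ox + 100), ] <- tl$tiles[[i]]
  }
  expect_identical(rebuilt, img[1:100, 1:200, ])
})

test_that("flush patch grids end at the border and cover every pixel", {
  g <- patch_grid(1000, 1000, 128, edge_mode = "flush")
  expect_equal(nrow(g), 64)
  expect_equal(sort(unique(g$origin_x)), c(0, 128, 256, 384, 512, 640, 768, 872))
  covered <- logical(1000)
  for (o in unique(g$origin_x)) covered[(o + 1):(o + 128)] <- TRUE
  expect_true(all(covered))

  gd <- patch_grid(1000, 1000, 128, edge_mode = "drop")
  expect_equal(nrow(gd), 49)
  expect_equal(max(gd$origin_x) + 128, 896) # 104-px remainder unclassified

  expect_equal(nrow(patch_grid(128, 128, 128)), 1)
  g2 <- patch_grid(256, 256, 128)
  expect_equal(sort(unique(g2$origin_x)), c(0, 128))
  expect_error(patch_grid(100, 100, 128), "smaller than patch_size")
})

test_that("map_to_source is the exact inverse of cropping coordinates", {
  g <- tile_grid(4000, 3000, 1000)
  idx <- which(g$origin_x == 1000 & g$origin_y == 2000)
  out <- map_to_source(g, boxes(10, 20, 30, 40), idx)
  expect_equal(unlist(out), c(xmin = 1010, ymin = 2020, xmax = 1030, ymax = 2040))
  expect_equal(map_to_source(g, boxes(10, 20, 30, 40), 1),
               boxes(10, 20, 30, 40)) # origin (0,0): identity
  expect_error(map_to_source(g, boxes(990, 0, 1010, 10), 1), "bounds")

  withr::local_seed(21)
  for (rep in 1:20) {
    i <- sample(nrow(g), 1)
    b <- random_int_boxes(1)
    src <- map_to_source(g, b, i)
    back <- shift_boxes(src, -g$origin_x[i], -g$origin_y[i])
    expect_equal(back, b)
  }
})

test_that("positive patches are centred, clipped in-bounds, fixed size, and hit their box", {
  withr::local_seed(31)
  img <- array(runif(600 * 600 * 3, 0, 255), dim = c(600, 600, 3))
  ann <- boxes(c(480, 2), c(480, 2), c(520, 8), c(520, 8))
  p <- extract_positive_patches(img, ann, patch_size = 128)
  expect_equal(p$origin_x, c(436, 0))
  expect_equal(p$origin_y, c(436, 0))
  for (i in seq_len(nrow(p))) {
    expect_equal(dim(p$patch[[i]]), c(128, 128, 3))
    expect_gt(box_intersection(p[i, c("xmin", "ymin", "xmax", "ymax")],
                               ann[i, ]), 0)
  }
  # crop content equals source crop
  expect_identical(p$patch[[1]], img[437:564, 437:564, ])
  expect_equal(nrow(extract_positive_patches(img, ann[0, ])), 0)
})

test_that("negative sampling is seeded-deterministic, in-bounds, and guarded", {
  withr::local_seed(41)
  img <- array(runif(300 * 400 * 3, 0, 255), dim = c(300, 400, 3))
  p1 <- extract_negative_patches(img, n = 25, seed = 9)
  p2 <- extract_negative_patches(img, n = 25, seed = 9)
  expect_equal(p1$origin_x, p2$origin_x)
  expect_equal(p1$origin_y, p2$origin_y)
  expect_true(all(p1$origin_x >= 0 & p1$origin_x + 128 <= 400))
  expect_true(all(p1$origin_y >= 0 & p1$origin_y + 128 <= 300))
  expect_equal(nrow(extract_negative_patches(img, n = 0, seed = 1)), 0)
  expect_error(extract_negative_patches(img, annotations = boxes(0, 0, 5, 5),
                                        n = 5, seed = 1),
               "zero annotations")
})
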