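test_that("avatar sprite composition is local and exact", {
  base <- compose_avatar_sprite(c(150, 0, 0), ready = FALSE)
  expect_equal(dim(base), c(8L, 8L, 3L))
  # body block carries the body color
  expect_true(all(base[2:8, 2:7, 1] == 150 & base[2:8, 2:7, 2] == 0 &
                    base[2:8, 2:7, 3] == 0))
  # toggling ready changes only the headband row
  ready <- compose_avatar_sprite(c(150, 0, 0), ready = TRUE)
  diff <- which(ready != base, arr.ind = TRUE)
  expect_true(all(diff[, 1] == 1L))
  expect_gt(nrow(diff), 0L)
  # an individuation pixel changes exactly one pixel
  marked <- compose_avatar_sprite(c(150, 0, 0), ready = FALSE,
                                  individuation_pixel = c(255, 255, 0))
  diffpix <- which(marked != base, arr.ind = TRUE)
  expect_equal(unique(diffpix[, 1:2, drop = FALSE]),
               matrix(c(4L, 4L), 1, 2), ignore_attr = TRUE)
  # bright vs dark variants differ in exactly that one pixel
  dark <- compose_avatar_sprite(c(150, 0, 0), ready = FALSE,
                                individuation_pixel = c(80, 80, 0))
  dd <- which(dark != marked, arr.ind = TRUE)
  expect_true(all(dd[, 1] == 4L & dd[, 2] == 4L))
})

test_that("configured group colors set the avatar RGB distance", {
  for (pair in list(list(c(150, 0, 0), c(0, 0, 150)),
                    list(c(150, 0, 50), c(50, 0, 150)),
                    list(c(150, 0, 100), c(100, 0, 150)))) {
    t1 <- compose_avatar_sprite(pair[[1]])
    t2 <- compose_avatar_sprite(pair[[2]])
    # body pixels differ by exactly the configured color distance
    expect_equal(sqrt(sum((t1[4, 4, ] - t2[4, 4, ])^2)),
                 sqrt(sum((pair[[1]] - pair[[2]])^2)))
  }
})

test_that("observation geometry: 11x11 sprites, self position, window extents", {
  cfg <- env_config(make_layout("default"), restock_prob = 0)
  st <- face_off_state(cfg = cfg, pos = list(c(8L, 8L), c(8L, 11L)),
                       orient = c(1L, 1L))
  obs <- render_observation(st, "a")
  expect_equal(dim(obs), c(88L, 88L, 3L))
  # self tile at window row 10, col 6
  self_tile <- obs[73:80, 41:48, ]
  expect_equal(self_tile, compose_avatar_sprite(c(150, 0, 0), ready = TRUE))
  # facing north: agent b is 3 cells east -> 3 sprites right of self
  b_tile <- obs[73:80, 65:72, ]
  expect_equal(b_tile, compose_avatar_sprite(c(0, 0, 150), ready = TRUE))
})

test_that("rendering is egocentric: turning relocates scene content consistently", {
  cfg <- env_config(make_layout("default"), restock_prob = 0)
  b_tile <- compose_avatar_sprite(c(0, 0, 150), ready = TRUE)
  tile_at <- function(obs, wr, wc) {
    obs[((wr - 1) * 8 + 1):(wr * 8), ((wc - 1) * 8 + 1):(wc * 8), ]
  }
  # facing east, b 3 cells east -> 3 sprites ahead (window row 7, col 6)
  st_e <- face_off_state(cfg = cfg, pos = list(c(8L, 8L), c(8L, 11L)),
                         orient = c(2L, 1L))
  expect_equal(tile_at(render_observation(st_e, "a"), 7L, 6L), b_tile)
  # facing south, same b -> 3 sprites to the left (window row 10, col 3)
  st_s <- face_off_state(cfg = cfg, pos = list(c(8L, 8L), c(8L, 11L)),
                         orient = c(3L, 1L))
  expect_equal(tile_at(render_observation(st_s, "a"), 10L, 3L), b_tile)
  # brute-force cross-check of the full window under a turn: every tile of the
  # east-facing render must appear at the coordinates predicted by rotating
  # the window mapping by 90 degrees
  obs_n <- render_observation(face_off_state(cfg = cfg,
                                             pos = list(c(8L, 8L), c(8L, 11L)),
                                             orient = c(1L, 1L)), "a")
  obs_e <- render_observation(st_e, "a")
  for (f in -1:5) for (r in -4:4) {
    # world cell at (forward f, right r) under east heading sits at
    # (forward ?, right ?) under north heading: east fwd=(0,1), right=(1,0)
    dr <- f * 0L + r * 1L; dc <- f * 1L + r * 0L
    fn <- -dr; rn <- dc     # north: fwd=(-1,0), right=(0,1)
    if (fn < -1 || fn > 9 || abs(rn) > 5) next
    expect_equal(tile_at(obs_e, 10L - f, 6L + r),
                 tile_at(obs_n, 10L - fn, 6L + rn))
  }
})

test_that("rendering is a pure function and translation-equivariant", {
  # large arena so the whole window stays interior before and after the shift
  cfg <- env_config(make_layout("default", width = 25, height = 25),
                    restock_prob = 0)
  st <- face_off_state(cfg = cfg, pos = list(c(13L, 10L), c(13L, 13L)))
  o1 <- render_observation(st, "a")
  o2 <- render_observation(st, "a")
  expect_identical(o1, o2)
  # translate the whole scene by (+2, +1): observation unchanged
  st2 <- face_off_state(cfg = cfg, pos = list(c(15L, 11L), c(15L, 14L)))
  expect_identical(render_observation(st2, "a"), o1)
})

test_that("removed agents yield a no-observation signal", {
  st <- face_off_state()
  st$agents$row[1] <- NA_integer_
  st$agents$removal[1] <- 10L
  expect_null(render_observation(st, "a"))
  expect_null(feature_observation(st, "a"))
})

test_that("feature observation reports egocentric offsets by population slot", {
  cfg <- env_config(make_layout("default"), restock_prob = 0)
  st <- face_off_state(cfg = cfg, pos = list(c(8L, 8L), c(8L, 11L)),
                       orient = c(2L, 1L))  # facing east, blue 3 ahead
  f <- feature_observation(st, "a")
  expect_length(f, FEATURE_DIM)
  expect_equal(f[1], 1)                    # ready
  expect_equal(f[11:13], c(1, 3 / 9, 0))   # slot-2 ready agent 3 forward
  expect_equal(f[8:10], c(0, 0, 0))        # no other slot-1 agent visible
})

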