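unit_sq <- function(x, y) list(x = x, y = y, width = 1, height = 1)

test_that("pair overlap area is the frame intersection", {
  expect_equal(pair_overlap_area(unit_sq(0, 0), unit_sq(5, 0)), 0)
  expect_equal(pair_overlap_area(unit_sq(0, 0), unit_sq(0, 0)), 1)
  expect_equal(pair_overlap_area(unit_sq(0, 0), unit_sq(0.5, 0.5)), 0.25)
  # mixed rectangle sizes against the independent R formula
  withr::with_seed(4, {
    for (k in 1:50) {
      a <- list(x = runif(1, 0, 10), y = runif(1, 0, 10),
                width = runif(1, 0.5, 4), height = runif(1, 0.5, 4))
      b <- list(x = runif(1, 0, 10), y = runif(1, 0, 10),
                width = runif(1, 0.5, 4), height = runif(1, 0.5, 4))
      expect_equal(pair_overlap_area(a, b),
                   oracle_overlap(a$x, a$y, a$width, a$height,
                                  b$x, b$y, b$width, b$height))
    }
  })
})

test_that("placement score sums weighted overlap and center distance", {
  cfg <- layout_config(canvas_width = 20, canvas_height = 20,
                       w_overlap = 1, w_distance = 1)
  placed <- data.frame(x = 0, y = 0, width = 1, height = 1)
  expect_equal(placement_score(unit_sq(10, 0), data.frame()[0, ], cfg), 0)
  expect_equal(placement_score(unit_sq(10, 0), placed, cfg), 10)
  expect_equal(placement_score(unit_sq(0, 0), placed, cfg), 1)
})

test_that("a single item is centered on the canvas", {
  cfg <- layout_config(canvas_width = 30, canvas_height = 20,
                       grid_nx = 7, grid_ny = 5)
  g <- greedy_place(cloud_items("a", 4, 3), cfg)
  expect_equal(g$x, 15)
  expect_equal(g$y, 10)
})

test_that("greedy placement equals exhaustive per-step minimization", {
  for (seed in 1:12) {
    withr::with_seed(seed, {
      n <- sample(2:5, 1)
      w <- runif(n, 1, 4); h <- runif(n, 1, 4)
      nx <- sample(4:10, 1); ny <- sample(4:10, 1)
      cw <- runif(1, 12, 20); ch <- runif(1, 10, 16)
      wd <- sample(c(0, 0.05, 1), 1)
    })
    cfg <- layout_config(canvas_width = cw, canvas_height = ch,
                         grid_nx = nx, grid_ny = ny, w_overlap = 1,
                         w_distance = wd, corner_strength = 0)
    got <- greedy_place(cloud_items(sprintf("i%d", 1:n), w, h), cfg)
    exp <- oracle_greedy(w, h, cw, ch,
                         seq(0, cw, length.out = nx),
                         seq(0, ch, length.out = ny), 1, wd)
    expect_equal(got$x, exp$x, label = paste("x, seed", seed))
    expect_equal(got$y, exp$y, label = paste("y, seed", seed))
  }
})

test_that("two items that fit disjointly end with zero overlap", {
  cfg <- layout_config(canvas_width = 10, canvas_height = 10,
                       grid_nx = 11, grid_ny = 11, w_overlap = 1,
                       w_distance = 1e-4, corner_strength = 0)
  g <- greedy_place(cloud_items(c("a", "b"), c(3, 3), c(3, 3)), cfg)
  expect_equal(pair_overlap_area(g[1, ], g[2, ]), 0)
})

test_that("an item larger than the canvas is an identified error", {
  cfg <- layout_config(canvas_width = 10, canvas_height = 10,
                       grid_nx = 5, grid_ny = 5)
  expect_error(greedy_place(cloud_items(c("a", "b"), c(3, 12), c(3, 2)), cfg),
               "larger than the canvas")
})

test_that("refinement is monotone and only ever improves the total score", {
  items <- random_items(40, seed = 7)
  cv <- canvas_for(items, 2.5)
  cfg <- layout_config(canvas_width = cv["width"], canvas_height = cv["height"])
  g <- greedy_place(items, cfg)
  r <- refine(g, cfg)
  st <- attr(r, "sweep_totals")
  expect_true(all(diff(st) <= 1e-9))
  expect_lte(total_score(r, cfg), total_score(g, cfg) + 1e-9)
})

test_that("refinement separates fully overlapping squares", {
  items <- cloud_items(c("a", "b"), c(2, 2), c(2, 2))
  items$x <- c(10, 10); items$y <- c(10, 10)
  cfg <- layout_config(canvas_width = 20, canvas_height = 20,
                       w_distance = 0, corner_strength = 0, step_size = 0.5)
  r <- refine(items, cfg)
  expect_lt(pair_overlap_area(r[1, ], r[2, ]), 4)
  st <- attr(r, "sweep_totals")
  expect_lt(st[length(st)], st[1])
})

test_that("refinement with zero sweeps returns the input unchanged", {
  items <- cloud_items(c("a", "b"), c(2, 2), c(2, 2))
  items$x <- c(5, 9); items$y <- c(5, 9)
  cfg <- layout_config(canvas_width = 20, canvas_height = 20,
                       max_iterations = 0)
  r <- refine(items, cfg)
  expect_equal(r$x, items$x)
  expect_equal(r$y, items$y)
})

test_that("a single centered item is a refinement fixpoint", {
  cfg <- layout_config(canvas_width = 20, canvas_height = 20,
                       grid_nx = 5, grid_ny = 5)
  g <- greedy_place(cloud_items("a", 2, 2), cfg)
  r <- refine(g, cfg)
  # center is the minimum of the symmetric corner penalty; nothing to gain
  expect_equal(r$x, 10)
  expect_equal(r$y, 10)
})

test_that("corner penalty is finite, symmetric, and off when disabled", {
  cfg0 <- layout_config(canvas_width = 10, canvas_height = 10,
                        corner_strength = 0)
  expect_equal(corner_penalty(unit_sq(1, 1), cfg0), 0)
  cfg <- layout_config(canvas_width = 10, canvas_height = 10,
                       corner_strength = 2, corner_eps = 0.1)
  pc <- corner_penalty(unit_sq(5, 5), cfg)
  pcorner <- corner_penalty(unit_sq(0, 0), cfg)
  expect_lt(pc, pcorner)
  expect_true(is.finite(pcorner))
  # independent formula
  d <- function(x, y, cx, cy) sqrt((x - cx)^2 + (y - cy)^2)
  expected <- 2 * sum(1 / (0.1 + c(d(3, 4, 0, 0), d(3, 4, 10, 0),
                                   d(3, 4, 0, 10), d(3, 4, 10, 10))))
  expect_equal(corner_penalty(unit_sq(3, 4), cfg), expected)
})

test_that("all frames stay inside the canvas through both passes", {
  items <- random_items(35, seed = 13)
  cv <- canvas_for(items, 2)
  cfg <- layout_config(canvas_width = cv["width"], canvas_height = cv["height"])
  r <- refine(greedy_place(items, cfg), cfg)
  expect_true(all(r$x - r$width / 2 >= -1e-9))
  expect_true(all(r$x + r$width / 2 <= cv["width"] + 1e-9))
  expect_true(all(r$y - r$height / 2 >= -1e-9))
  expect_true(all(r$y + r$height / 2 <= cv["height"] + 1e-9))
})

test_that("the layout is deterministic, bit for bit", {
  items <- random_items(30, seed = 3)
  cv <- canvas_for(items, 2.5)
  cfg <- layout_config(canvas_width = cv["width"], canvas_height = cv["height"])
  r1 <- refine(greedy_place(items, cfg), cfg)
  r2 <- refine(greedy_place(items, cfg), cfg)
  expect_identical(r1$x, r2$x)
  expect_identical(r1$y, r2$y)
})

test_that("the layout is scale-equivariant when lengths are scaled uniformly", {
  items <- random_items(12, seed = 5)
  cv <- canvas_for(items, 2.5)
  lam <- 3.7
  mk_cfg <- function(s) layout_config(
    canvas_width = s * cv["width"], canvas_height = s * cv["height"],
    grid_nx = 15, grid_ny = 11, w_overlap = 1, w_distance = 0,
    corner_strength = NULL,   # default scales as diagonal^3
    step_size = s * 4, max_iterations = 50,
    tolerance = 1e-9 * s^2)  # score units scale like area
  items2 <- items
  items2$width <- lam * items$width
  items2$height <- lam * items$height
  r1 <- refine(greedy_place(items, mk_cfg(1)), mk_cfg(1))
  r2 <- refine(greedy_place(items2, mk_cfg(lam)), mk_cfg(lam))
  expect_equal(r2$x, lam * r1$x, tolerance = 1e-8)
  expect_equal(r2$y, lam * r1$y, tolerance = 1e-8)
})

test_that("greedy debug traces record a non-increasing running best score", {
  items <- random_items(15, seed = 17)
  cv <- canvas_for(items, 2)
  cfg <- layout_config(canvas_width = cv["width"], canvas_height = cv["height"],
                       grid_nx = 20, grid_ny = 14)
  g <- greedy_place(items, cfg, debug = TRUE)
  traces <- attr(g, "score_traces")
  steps <- attr(g, "step_scores")
  expect_length(traces, nrow(g))
  for (k in seq_along(traces)) {
    expect_true(all(diff(traces[[k]]) < 0), label = paste("trace", k))
    expect_equal(steps[k], traces[[k]][length(traces[[k]])])
  }
  # the chosen position scores no worse than any grid point (spot check)
  grid <- moleculecloud:::mc_grid(g, cfg)
  k <- nrow(g)
  placed <- g[seq_len(k - 1), ]
  cand <- g[k, ]
  for (cx in grid$gx[c(1, 7, 14)]) for (cy in grid$gy[c(2, 8)]) {
    if (cx - cand$width / 2 < 0 || cx + cand$width / 2 > cfg$canvas_width ||
        cy - cand$height / 2 < 0 || cy + cand$height / 2 > cfg$canvas_height)
      next
    probe <- cand; probe$x <- cx; probe$y <- cy
    expect_gte(placement_score(probe, placed, cfg) + 1e-12,
               placement_score(cand, placed, cfg))
  }
})
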