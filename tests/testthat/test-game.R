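test_that("blink detector scores well against generator ground truth", {
  mont <- montage_spec(fs = 250)
  sch <- build_schedule(1, 2, 10, seed = 5)
  rec <- render_recording(default_source_model(mont), sch, mont, seed = 7,
                          blink_rate_per_min = 6)
  det <- detect_blinks(rec)
  truth <- rec$blink_truth
  expect_gt(nrow(truth), 10)
  hit <- vapply(seq_len(nrow(truth)), function(k) {
    i <- which(abs(det$time_s - truth$time_s[k] - 0.1) < 0.5)
    length(i) > 0 && det$kind[i[1]] == truth$kind[k]
  }, logical(1))
  expect_gte(mean(hit), 0.95)
  fp <- sum(vapply(det$time_s, function(t0)
    !any(abs(truth$time_s + 0.1 - t0) < 0.6), logical(1)))
  minutes <- ncol(rec$data) / mont$fs / 60
  expect_lte(fp / minutes, 1)
})

test_that("pulse pairs merge into doubles and flat signals yield nothing", {
  fs <- 250
  x <- numeric(10 * fs)
  x <- x + mibci:::blink_template(3, fs, length(x)) +
    mibci:::blink_template(3.4, fs, length(x))
  x <- x + rnorm(length(x), 0, 1)
  det <- detect_blinks(x, fs = fs)
  expect_equal(nrow(det), 1)
  expect_equal(det$kind, "double")
  expect_equal(nrow(detect_blinks(rep(0, 1000), fs = fs)), 0)
})

test_that("double blinks cycle the rotation axis and singles rotate the block", {
  g <- game_new(width = 5, depth = 5, layers = 10, seed = 1,
                shapes = "tromino_i")
  expect_equal(g$rotation_axis, "X")
  g <- apply_rotation(g, "double")
  expect_equal(g$rotation_axis, "Y")
  g <- apply_rotation(g, "double"); g <- apply_rotation(g, "double")
  expect_equal(g$rotation_axis, "X")
  ## four quarter-turns about one axis restore the orientation
  g <- apply_rotation(g, "double")  # -> Y: rotates in the x-z plane
  cells0 <- g$block$cells
  for (i in 1:4) g <- apply_rotation(g, "single")
  expect_equal(g$block$cells, cells0)
})

test_that("blocked rotations leave the state unchanged and are logged", {
  g <- game_new(width = 3, depth = 1, layers = 10, seed = 1,
                shapes = "tromino_i")   # 3-long bar in a 1-deep corridor
  ## rotating about Z would need depth 3
  g$rotation_axis <- "Z"
  g2 <- apply_rotation(g, "single")
  expect_equal(g2$block$cells, g$block$cells)
  expect_true("rotation_blocked" %in% g2$events)
})

test_that("completing a layer scores and drops the stack", {
  g <- game_new(width = 2, depth = 2, layers = 6, fall_rate = 1, seed = 1,
                shapes = "single", spawn = TRUE)
  ## pre-fill layer 1 except under the falling cube; add a marker above
  g$grid[1, 2, 1] <- TRUE; g$grid[2, 1, 1] <- TRUE; g$grid[2, 2, 1] <- TRUE
  g$grid[1, 2, 2] <- TRUE
  g$block$x <- 1; g$block$y <- 1
  steps <- 0
  while (!is.null(g$block) && g$n_spawned == 1 && steps < 100) {
    g <- game_tick(g, 0.5); steps <- steps + 1
  }
  expect_equal(g$score, 1L)
  ## the marker dropped from layer 2 to layer 1
  expect_true(g$grid[1, 2, 1])
  expect_false(g$grid[1, 2, 2])
  expect_equal(sum(g$grid), 1)
})

test_that("wall contact emits Touch and zeroes the speed through the automaton", {
  g <- game_new(width = 3, depth = 3, layers = 10, fall_rate = 0.1, seed = 1,
                shapes = "single")
  g <- game_tick(g, 0.25, commands = "Null")  # N_B -> V_zero
  g <- game_tick(g, 0.25, commands = "right") # -x speed
  expect_equal(g$fsa, "VX_minus")
  expect_equal(g$vx, -1)
  for (i in 1:30) g <- game_tick(g, 0.25)
  expect_equal(g$fsa, "V_zero")
  expect_equal(g$vx, 0)
  expect_equal(g$block$x, 1)   # resting against the wall
})

test_that("an uncommanded block lands at its shadow after height/fall_rate", {
  g <- game_new(width = 4, depth = 4, layers = 12, fall_rate = 0.5, seed = 2,
                shapes = "single")
  sh <- block_shadow(g)
  z0 <- floor(g$block$zf)
  expect_equal(sh, 1)
  landing <- mibci:::block_cells(g$block, sh)
  t_expect <- (z0 - 1) / 0.5
  t <- 0
  while (g$n_spawned == 1 && t < 100) { g <- game_tick(g, 0.25); t <- t + 0.25 }
  expect_equal(t, t_expect + 0.25, tolerance = 0.5)
  expect_true(all(g$grid[landing]))
})

test_that("settled cell count is conserved outside landings and clears", {
  g <- game_new(width = 3, depth = 3, layers = 8, fall_rate = 1, seed = 3)
  prev <- sum(g$grid)
  for (i in 1:400) {
    if (g$over) break
    nblk <- if (is.null(g$block)) 0 else nrow(g$block$cells)
    g <- game_tick(g, 0.25)
    now <- sum(g$grid)
    cleared <- sum(g$events == "layer_cleared")
    if ("Fallen" %in% g$events) {
      expect_equal(now, prev + nblk - cleared * 9)
    } else {
      expect_equal(now, prev)
    }
    prev <- now
  }
})

test_that("shadow predicts the landing site under no further commands", {
  for (seed in 1:5) {
    g <- game_new(width = 4, depth = 4, layers = 10, fall_rate = 1, seed = seed)
    sh <- block_shadow(g)
    cells_pred <- mibci:::block_cells(g$block, sh)
    while (g$n_spawned == 1 && !g$over) g <- game_tick(g, 0.25)
    expect_true(all(g$grid[cells_pred]))
  }
})

test_that("goal-directed control outscores random control on average", {
  run_score <- function(dec, seed) {
    g <- game_new(width = 2, depth = 2, layers = 10, fall_rate = 0.5,
                  seed = seed, shapes = c("single", "domino"))
    run_session(dec, duration_s = 900, game = g)$state$score
  }
  oracle <- vapply(1:8, function(s) run_score(decoder_oracle(), s), numeric(1))
  random <- vapply(1:8, function(s) run_score(decoder_random(s), s), numeric(1))
  expect_gt(mean(oracle), mean(random))
})

test_that("an always-idle decoder drops blocks straight onto their shadows", {
  g <- game_new(width = 4, depth = 4, layers = 8, fall_rate = 1, seed = 4,
                shapes = "single")
  sh <- mibci:::block_cells(g$block, block_shadow(g))
  s <- run_session(function(t, state) "idle", duration_s = 30, game = g)
  expect_equal(s$state$score, 0L)
  expect_true(all(s$state$grid[sh]))
})

test_that("sessions are deterministic given seed and decoder", {
  mk <- function() {
    g <- game_new(width = 3, depth = 3, layers = 8, seed = 6)
    run_session(decoder_random(11), duration_s = 60, game = g)
  }
  s1 <- mk(); s2 <- mk()
  expect_identical(s1$log, s2$log)
})

test_that("screen game score is the population SD of class percentages", {
  expect_equal(screen_game_score(rep(mi_classes(), 25)), 0)
  ## direct-formula oracles
  sd_pop <- function(p) sqrt(mean((p - mean(p))^2))
  expect_equal(screen_game_score(rep("right_hand", 10)),
               sd_pop(c(100, 0, 0, 0)), tolerance = 1e-10)
  expect_equal(round(screen_game_score(rep("right_hand", 10)), 2), 43.30)
  labs <- c(rep("right_hand", 40), rep("left_hand", 30), rep("foot", 20),
            rep("tongue", 10), rep("idle", 55))
  expect_equal(round(screen_game_score(labs), 2), 11.18)
  expect_warning(v <- screen_game_score(rep("idle", 5)), "idle")
  expect_true(is.na(v))
})
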