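## Headless 3-D falling-blocks engine. The play space is a W x D footprint
## with L vertical layers; block groups (polycubes) descend at a constant
## fall rate while the shared-control automaton adjusts their lateral speed.
## Filling a layer clears it and scores one unit; landing a block that
## leaves gaps in the topmost occupied layer forfeits one layer; the run
## ends (Cross -> Reset) when the settled stack reaches the shrinking
## ceiling.

block_shapes <- function() {
  list(
    single = rbind(c(0, 0, 0)),
    domino = rbind(c(0, 0, 0), c(1, 0, 0)),
    tromino_i = rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
    tromino_l = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
    tetro_i = rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)),
    square = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
    tetro_l = rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 1, 0)),
    corner3d = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
}

#' Create a new game
#'
#' @param width,depth Footprint of the play space in cells (default 6 x 6).
#' @param layers Number of vertical layers (default 20).
#' @param fall_rate Constant descent speed, layers per second (default 0.5).
#' @param dv Speed increment per control command, cells per second
#'   (default 1).
#' @param seed Seed governing the shape sequence.
#' @param spawn Spawn the first block immediately (default `TRUE`).
#' @param shapes Optional character vector naming a subset of the built-in
#'   polycube shapes (see names of the internal shape list: "single",
#'   "domino", "tromino_i", "tromino_l", "tetro_i", "square", "tetro_l",
#'   "corner3d"), or a list of integer offset matrices. Default: all 8.
#' @param layer_rule How an incompletely filled layer forfeits play height:
#'   `"overhang"` (default) deducts one layer when a landing covers empty
#'   cells below it (gaps sealed under blocks); `"topgap"` deducts one
#'   whenever the topmost occupied layer has gaps after a landing -- a
#'   stricter reading under which runs are very short.
#' @return An object of class `"game_state"`.
#' @export
game_new <- function(width = 6, depth = 6, layers = 20, fall_rate = 0.5,
                     dv = 1, seed = 1, spawn = TRUE, shapes = NULL,
                     layer_rule = c("overhang", "topgap")) {
  layer_rule <- match.arg(layer_rule)
  shape_set <- if (is.null(shapes)) block_shapes()
               else if (is.character(shapes)) block_shapes()[shapes]
               else shapes
  state <- structure(list(
    W = check_count(width, "width"), D = check_count(depth, "depth"),
    L = check_count(layers, "layers"),
    grid = array(FALSE, dim = c(width, depth, layers)),
    block = NULL, rotation_axis = "X",
    vx = 0, vy = 0, acc_dx = 0, acc_dy = 0,
    fall_rate = fall_rate, dv = dv,
    fsa = "Start", score = 0L, layers_remaining = as.integer(layers),
    layer_rule = layer_rule, shapes = shape_set,
    over = FALSE, seed = seed, n_spawned = 0L, events = character(0)),
    class = "game_state")
  if (spawn) state <- spawn_block(state) else state
}

## absolute cell coordinates of the active block at integer height z
block_cells <- function(block, z = NULL) {
  z <- z %||% floor(block$zf)
  sweep(block$cells, 2, c(block$x, block$y, z), "+")
}

## "" = free; otherwise the obstruction kind
cell_conflict <- function(state, cells) {
  if (any(cells[, 1] < 1 | cells[, 1] > state$W |
          cells[, 2] < 1 | cells[, 2] > state$D)) return("wall")
  if (any(cells[, 3] < 1)) return("floor")
  inb <- cells[cells[, 3] <= state$L, , drop = FALSE]
  if (nrow(inb) && any(state$grid[inb])) return("block")
  ""
}

spawn_block <- function(state) {
  state$n_spawned <- state$n_spawned + 1L
  shape <- with_seed(state$seed * 1000L + state$n_spawned, {
    shapes <- Filter(function(s)
      max(s[, 1]) < state$W && max(s[, 2]) < state$D &&
        max(s[, 3]) < state$L, state$shapes)
    if (!length(shapes)) shapes <- block_shapes()["single"]
    shapes[[sample.int(length(shapes), 1)]]
  })
  block <- list(cells = shape,
                x = max(1L, floor((state$W - max(shape[, 1])) / 2) + 1L),
                y = max(1L, floor((state$D - max(shape[, 2])) / 2) + 1L),
                zf = state$layers_remaining - max(shape[, 3]))
  state$block <- block
  state$vx <- 0; state$vy <- 0; state$acc_dx <- 0; state$acc_dy <- 0
  if (cell_conflict(state, block_cells(block)) != "") {
    state$events <- c(state$events, "Cross")
    state$fsa <- fsa_step(state$fsa, "Cross")
    state$over <- TRUE
  } else {
    state$fsa <- "N_B"
  }
  state
}

#' Shadow (landing) position of the active block
#'
#' The layer at which the block would settle if it fell straight down with
#' no further commands; recomputed from the current stack.
#'
#' @param state A `"game_state"` with an active block.
#' @return Integer landing height of the block origin.
#' @export
block_shadow <- function(state) {
  if (is.null(state$block)) mibci_stop("no active block")
  z <- floor(state$block$zf)
  while (cell_conflict(state, block_cells(state$block, z - 1)) == "") z <- z - 1
  z
}

#' Rotate the active block with a blink command
#'
#' A double blink advances the rotation axis in the X -> Y -> Z -> X loop;
#' a single blink rotates the block group 90 degrees about the current axis
#' (integer lattice rotation about the block's bounding-box pivot). A
#' rotation that would collide or leave the space is ignored and logged.
#'
#' @param state A `"game_state"`.
#' @param kind `"single"` or `"double"` (a `BlinkEvent` kind).
#' @return Updated state.
#' @export
apply_rotation <- function(state, kind) {
  if (is.null(state$block)) mibci_stop("no active block")
  if (kind == "double") {
    state$rotation_axis <- c(X = "Y", Y = "Z", Z = "X")[[state$rotation_axis]]
    state$events <- c(state$events, "axis_switch")
    return(state)
  }
  cells <- state$block$cells
  rot <- switch(state$rotation_axis,
                X = cbind(cells[, 1], -cells[, 3], cells[, 2]),
                Y = cbind(cells[, 3], cells[, 2], -cells[, 1]),
                Z = cbind(-cells[, 2], cells[, 1], cells[, 3]))
  rot <- sweep(rot, 2, apply(rot, 2, min))   # re-anchor at origin
  cand <- state$block
  cand$cells <- rot
  if (cell_conflict(state, block_cells(cand)) == "") {
    state$block <- cand
    state$events <- c(state$events, "rotated")
  } else {
    state$events <- c(state$events, "rotation_blocked")
  }
  state
}

## feed one FSA input. Speed side effects: a direction command adds one
## increment along its axis; P_plus adds another increment along the active
## state's direction, P_minus_moving removes one, P_eq holds; V_zero stops.
apply_fsa_input <- function(state, sym) {
  nxt <- fsa_step(state$fsa, sym)
  dir_of <- c(VX_plus = 1, VX_minus = -1, VY_plus = 1, VY_minus = -1)
  if (sym %in% c("left", "right", "ton", "foot") &&
      nxt %in% names(dir_of)) {
    if (nxt %in% c("VX_plus", "VX_minus"))
      state$vx <- state$vx + dir_of[[nxt]] * state$dv
    else state$vy <- state$vy + dir_of[[nxt]] * state$dv
  } else if (sym %in% c("P_plus", "P_minus_moving") &&
             state$fsa %in% names(dir_of)) {
    sgn <- dir_of[[state$fsa]] * if (sym == "P_plus") 1 else -1
    if (state$fsa %in% c("VX_plus", "VX_minus"))
      state$vx <- state$vx + sgn * state$dv
    else state$vy <- state$vy + sgn * state$dv
  } else if (nxt == "V_zero") {
    state$vx <- 0; state$vy <- 0
  } else if (nxt == "Reset") state$over <- TRUE
  state$fsa <- nxt
  state
}

## one-cell lateral move with wall/stack contact -> Touch
try_move <- function(state, dx, dy) {
  cand <- state$block
  cand$x <- cand$x + dx; cand$y <- cand$y + dy
  if (cell_conflict(state, block_cells(cand)) == "") {
    state$block <- cand
  } else {
    state$events <- c(state$events, "Touch")
    state <- apply_fsa_input(state, "Touch")
    state$acc_dx <- 0; state$acc_dy <- 0
  }
  state
}

settle_block <- function(state) {
  cells <- block_cells(state$block)
  if (any(cells[, 3] > state$L)) {   # block protrudes above the space
    state$events <- c(state$events, "Cross")
    state <- apply_fsa_input(state, "Cross")
    state$over <- TRUE
    return(state)
  }
  state$grid[cells] <- TRUE
  ## overhang rule: did this landing seal empty cells underneath?
  sealed_gap <- any(apply(cells, 1, function(cc) {
    below <- seq_len(cc[3] - 1)
    length(below) > 0 && !all(state$grid[cc[1], cc[2], below])
  }))
  state$block <- NULL
  state$events <- c(state$events, "Fallen")
  state <- apply_fsa_input(state, "Fallen")
  ## clear complete layers bottom-up
  z <- 1
  while (z <= state$L) {
    if (all(state$grid[, , z])) {
      state$score <- state$score + 1L
      state$events <- c(state$events, "layer_cleared")
      if (z < state$L)
        state$grid[, , z:(state$L - 1)] <- state$grid[, , (z + 1):state$L]
      state$grid[, , state$L] <- FALSE
    } else z <- z + 1
  }
  ## layer-loss rule
  occ <- apply(state$grid, 3, any)
  top <- if (any(occ)) max(which(occ)) else 0L
  lost <- if (state$layer_rule == "topgap")
    top > 0 && !all(state$grid[, , top])
  else sealed_gap
  if (lost) {
    state$layers_remaining <- state$layers_remaining - 1L
    state$events <- c(state$events, "layer_lost")
  }
  if (state$layers_remaining <= 0L || top >= state$layers_remaining) {
    state$events <- c(state$events, "Cross")
    state <- apply_fsa_input(state, "Cross")
    state$over <- TRUE
    return(state)
  }
  spawn_block(state)
}

#' Advance the game by `dt` seconds
#'
#' Applies any control inputs (FSA symbols), integrates the lateral speed
#' into accumulated displacement (quantised to one-cell moves with wall
#' collision emitting `Touch`), and integrates the constant fall. Landing
#' emits `Fallen`, settles the block, clears full layers (one score unit
#' each), applies the layer-loss rule, and spawns the next block; overflow
#' emits `Cross` and ends the run. All emitted events are fed to the
#' automaton.
#'
#' @param state A `"game_state"`.
#' @param dt Time step in seconds (> 0).
#' @param commands Character vector of FSA input symbols to apply first.
#' @return Updated state; events of this tick in `$events`.
#' @export
game_tick <- function(state, dt, commands = character(0)) {
  if (dt <= 0) mibci_stop("dt must be positive")
  state$events <- character(0)
  if (state$over) return(state)
  for (cmd in commands) state <- apply_fsa_input(state, cmd)
  if (state$over || is.null(state$block)) return(state)
  ## lateral motion
  state$acc_dx <- state$acc_dx + state$vx * dt
  state$acc_dy <- state$acc_dy + state$vy * dt
  while (!state$over && abs(state$acc_dx) >= 1) {
    s <- sign(state$acc_dx)
    state$acc_dx <- state$acc_dx - s
    state <- try_move(state, s, 0)
  }
  while (!state$over && abs(state$acc_dy) >= 1) {
    s <- sign(state$acc_dy)
    state$acc_dy <- state$acc_dy - s
    state <- try_move(state, 0, s)
  }
  if (state$over || is.null(state$block)) return(state)
  ## descent
  zf_new <- state$block$zf - state$fall_rate * dt
  while (floor(state$block$zf) > floor(zf_new)) {
    z <- floor(state$block$zf)
    if (cell_conflict(state, block_cells(state$block, z - 1)) == "") {
      state$block$zf <- state$block$zf - 1
    } else {
      return(settle_block(state))
    }
  }
  state$block$zf <- zf_new
  state
}

#' @export
print.game_state <- function(x, ...) {
  cat(sprintf("<game_state> %dx%dx%d, score %d, layers left %d, FSA %s%s\n",
              x$W, x$D, x$L, x$score, x$layers_remaining, x$fsa,
              if (x$over) " (over)" else ""))
  invisible(x)
}
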