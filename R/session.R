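#' Run a closed-loop game session from a decoder
#'
#' Decodes one label per sliding window (`hop_s` apart), converts it to a
#' shared-control symbol -- the class symbol when the command direction
#' changes, otherwise a count comparison (`P_plus` / `P_eq` /
#' `P_minus_moving`) over the rolling one-second command counts, `Null`
#' when idle -- feeds the symbol and the game's own events to the
#' automaton, and routes blink events to rotation commands. The run ends on
#' `Cross` (the automaton's `Reset`) or at `duration_s`.
#'
#' @param decoder Function `(t_s, state) -> label` returning one of
#'   [mi_classes()] or `"idle"`. See [decoder_random()],
#'   [decoder_oracle()], [pipeline_decoder()].
#' @param duration_s Maximum session length in seconds.
#' @param game A `"game_state"` to play on (default [game_new()] with the
#'   given seed).
#' @param blinks Optional data frame `time_s`, `kind` (e.g. from
#'   [detect_blinks()] or a recording's `blink_truth`) applied as rotation
#'   commands.
#' @param hop_s Decoding hop (default 0.25 s; the command-count window is
#'   1 s).
#' @param seed Seed for the default game.
#' @return An object of class `"session_log"`: data frame `log` (time,
#'   label, symbol, FSA state, speeds, score, events) and the final
#'   `state`.
#' @export
run_session <- function(decoder, duration_s, game = NULL, blinks = NULL,
                        hop_s = 0.25, seed = 1) {
  state <- game %||% game_new(seed = seed)
  window <- max(1L, round(1 / hop_s))          # hops per second
  recent <- character(0)                       # labels of the last 2 s
  last_cmd <- ""
  rows <- list()
  t <- 0
  bi <- 1
  if (!is.null(blinks) && nrow(blinks))
    blinks <- blinks[order(blinks$time_s), , drop = FALSE]
  else blinks <- NULL
  while (!state$over && t < duration_s) {
    label <- decoder(t, state)
    recent <- c(recent, label)
    if (length(recent) > 2 * window) recent <- tail(recent, 2 * window)
    sym <- if (label == "idle") "Null" else {
      if (label != last_cmd) {
        last_cmd <- label
        class_to_symbol(label)
      } else {
        now <- sum(tail(recent, window) == label)
        prev <- sum(head(tail(recent, 2 * window), window) == label)
        if (now > prev) "P_plus"
        else if (now == prev) "P_eq"
        else if (abs(state$vx) + abs(state$vy) > 0) "P_minus_moving"
        else class_to_symbol(label)
      }
    }
    ## blink rotations due in this hop
    while (!is.null(blinks) && bi <= nrow(blinks) &&
           blinks$time_s[bi] <= t + hop_s) {
      if (!is.null(state$block) && !state$over)
        state <- apply_rotation(state, blinks$kind[bi])
      bi <- bi + 1
    }
    state <- game_tick(state, hop_s, commands = sym)
    rows[[length(rows) + 1L]] <- data.frame(
      t = t, label = label, symbol = sym, fsa = state$fsa,
      vx = state$vx, vy = state$vy, score = state$score,
      layers_remaining = state$layers_remaining,
      events = paste(state$events, collapse = ";"),
      stringsAsFactors = FALSE)
    t <- t + hop_s
  }
  structure(list(log = do.call(rbind, rows), state = state),
            class = "session_log")
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log> %d windows, %.1f s, final score %d%s\n",
              nrow(x$log), max(x$log$t), x$state$score,
              if (x$state$over) " (run ended)" else ""))
  invisible(x)
}

#' Scripted decoders
#'
#' `decoder_random` emits uniformly random classes (with an idle
#' probability); `decoder_oracle` always outputs the class that moves the
#' active block towards the column with the lowest stack under a greedy
#' fill strategy -- an upper reference for controllability, not a model of
#' a player.
#'
#' @param seed Seed for the random decoder.
#' @param p_idle Idle probability of the random decoder (default 0.2).
#' @return A decoder function `(t_s, state) -> label`.
#' @export
decoder_random <- function(seed = 1, p_idle = 0.2) {
  env <- new.env()
  env$k <- 0L
  function(t, state) {
    env$k <- env$k + 1L
    with_seed(seed * 100003L + env$k, {
      if (runif(1) < p_idle) "idle" else sample(mi_classes(), 1)
    })
  }
}

#' @rdname decoder_random
#' @export
decoder_oracle <- function() {
  function(t, state) {
    if (is.null(state$block) || state$over) return("idle")
    if (state$fsa == "N_B") return("idle")   # release the new-block state
    tgt <- best_placement(state)
    dx <- sign(tgt[1] - state$block$x)
    dy <- sign(tgt[2] - state$block$y)
    ## cancel residual drift before switching axes
    if (dx == 0 && dy == 0) {
      if (state$vx > 0) return("right_hand")
      if (state$vx < 0) return("left_hand")
      if (state$vy > 0) return("tongue")
      if (state$vy < 0) return("foot")
      return("idle")
    }
    if (dx > 0) return("left_hand")
    if (dx < 0) return("right_hand")
    if (dy > 0) return("foot")
    "tongue"
  }
}

## greedy placement: the (x, y) whose straight drop seals the fewest empty
## cells, then lands lowest
best_placement <- function(state) {
  blk <- state$block
  best <- c(blk$x, blk$y); best_cost <- Inf
  for (x in seq_len(state$W)) {
    for (y in seq_len(state$D)) {
      cand <- blk; cand$x <- x; cand$y <- y
      cells0 <- block_cells(cand, floor(cand$zf))
      if (any(cells0[, 1] > state$W | cells0[, 2] > state$D)) next
      st2 <- state; st2$block <- cand
      if (cell_conflict(st2, cells0) != "") next
      z <- block_shadow(st2)
      cells <- block_cells(cand, z)
      cols <- unique(cells[, 1:2, drop = FALSE])
      seals <- sum(apply(cols, 1, function(cc) {
        zmin <- min(cells[cells[, 1] == cc[1] & cells[, 2] == cc[2], 3])
        below <- seq_len(zmin - 1)
        if (!length(below)) 0 else sum(!state$grid[cc[1], cc[2], below])
      }))
      cost <- seals * 1000 + z + 0.01 * (abs(x - blk$x) + abs(y - blk$y))
      if (cost < best_cost) { best_cost <- cost; best <- c(x, y) }
    }
  }
  best
}

#' Balance score of the 2-D screen game
#'
#' Feedback game without a control strategy: each class's share of the
#' decoded commands (idle excluded from the denominator) is shown as a
#' percentage, and the *population* standard deviation of the four
#' percentages is the score -- 0 for perfectly balanced imagery production,
#' decreasing scores across sessions indicate improvement.
#'
#' @param labels Character vector of decoded labels within the scoring
#'   window.
#' @param window_s Unused size annotation kept for API symmetry.
#' @return Scalar score; `NA` (with a warning and attribute
#'   `"all_idle" = TRUE`) when the window holds no imagery commands.
#' @export
screen_game_score <- function(labels, window_s = NULL) {
  if (length(labels) < 1) mibci_stop("need at least one label")
  n <- vapply(mi_classes(), function(cl) sum(labels == cl), numeric(1))
  if (sum(n) == 0) {
    warning("window contains only idle labels; score undefined")
    return(structure(NA_real_, all_idle = TRUE))
  }
  pct <- 100 * n / sum(n)
  sqrt(mean((pct - mean(pct))^2))
}
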