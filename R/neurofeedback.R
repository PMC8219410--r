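# Closed-loop neurofeedback: the five-level attention quantizer and the
# three headless game controllers (sustained = tug of war, selective =
# bird flight, focus = skill release). One tick = one classifier
# prediction; there is no real-time clock here.

#' Quantize an attention level into a control value
#'
#' low -> 0, medium-low -> 0.25, medium -> 0.5, medium-high -> 0.75,
#' high -> 1.
#'
#' @param level Attention level(s): codes 0..4 or names.
#' @return Numeric control value(s) in \{0, 0.25, 0.5, 0.75, 1\}.
#' @export
#' @examples
#' quantize("medium-high")  # 0.75
quantize <- function(level) {
  c(0, 0.25, 0.5, 0.75, 1)[as_attention_level(level) + 1L]
}

#' One tick of the sustained-attention game (tug of war)
#'
#' The player's character advances only when the control value is strictly
#' higher than the threshold; otherwise the enemy pulls back.
#'
#' @param c Control value.
#' @param threshold Strength threshold in (0, 1), default 0.5.
#' @return `"advance"` or `"retreat"`.
#' @export
sustained_step <- function(c, threshold = 0.5) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    abort_fmt("threshold must be in (0, 1)")
  }
  ifelse(c > threshold, "advance", "retreat")
}

#' One tick of the selective-attention game (bird flight)
#'
#' High control (>= 0.75) steers the bird upward, medium (0.5) keeps it
#' level, low (<= 0.25) lets it sink.
#'
#' @param c Control value.
#' @return `"upward"`, `"horizontal"`, or `"downward"`.
#' @export
selective_step <- function(c) {
  ifelse(c >= 0.75, "upward", ifelse(c <= 0.25, "downward", "horizontal"))
}

#' One tick of the focus-attention game (skill release)
#'
#' The skill fires only when attention is at the maximum level
#' (control value exactly 1).
#'
#' @param c Control value.
#' @return `"release"` or `"idle"`.
#' @export
focus_step <- function(c) {
  ifelse(c == 1, "release", "idle")
}

#' Game configuration
#'
#' @param game `"sustained"`, `"selective"`, or `"focus"`.
#' @param threshold Sustained-game strength threshold (default 0.5).
#' @param margin Sustained-game win margin: cumulative advances minus
#'   retreats needed to win (default 10 ticks).
#' @param floor Selective-game obstacle course: per-tick minimum bird
#'   altitude. Default is a ramp rising one unit every `ramp_every` ticks
#'   from `floor_start`, so the bird must climb to survive (the course has
#'   no ceiling, so flying higher is never worse).
#' @param floor_start,ramp_every Parameters of the default ramp.
#' @return Named list of game parameters.
#' @export
game_config <- function(game = c("sustained", "selective", "focus"),
                        threshold = 0.5, margin = 10,
                        floor = NULL, floor_start = -4, ramp_every = 8) {
  game <- match.arg(game)
  list(game = game, threshold = threshold, margin = margin, floor = floor,
       floor_start = floor_start, ramp_every = ramp_every)
}

course_floor <- function(cfg, n_ticks) {
  if (!is.null(cfg$floor)) {
    if (length(cfg$floor) < n_ticks) {
      abort_fmt("obstacle course (%d ticks) shorter than the session (%d ticks)",
                length(cfg$floor), n_ticks)
    }
    return(cfg$floor[seq_len(n_ticks)])
  }
  cfg$floor_start + (seq_len(n_ticks) - 1) %/% cfg$ramp_every
}

#' Run one neurofeedback session
#'
#' Quantizes an attention-level stream and feeds it tick by tick through
#' the selected game controller, recording the per-tick events and the
#' game's training indicator: `win_time` (ticks until the sustained game
#' is won; `NA` if never), `game_score` (ticks survived in the selective
#' game), or `skill_times` (0-based ticks at which the focus skill fired).
#' The run is a pure function of `(level_stream, game, config)`.
#'
#' @param level_stream Nonempty vector of attention levels (codes 0..4 or
#'   names).
#' @param game `"sustained"`, `"selective"`, or `"focus"`.
#' @param config A [game_config()] for that game.
#' @return A `session_log`: list with `game`, `levels`, `control`,
#'   `events`, and `indicators`.
#' @export
run_session <- function(level_stream,
                        game = c("sustained", "selective", "focus"),
                        config = game_config(game)) {
  game <- match.arg(game)
  levels <- as_attention_level(level_stream)
  if (length(levels) == 0) abort_fmt("level stream must be nonempty")
  control <- quantize(levels)
  n <- length(control)
  indicators <- list()

  if (game == "sustained") {
    events <- sustained_step(control, config$threshold)
    pos <- cumsum(ifelse(events == "advance", 1L, -1L))
    won <- which(pos >= config$margin)
    indicators$win_time <- if (length(won)) won[1] else NA_integer_
  } else if (game == "selective") {
    events <- selective_step(control)
    delta <- ifelse(events == "upward", 1L,
                    ifelse(events == "downward", -1L, 0L))
    altitude <- cumsum(delta)
    floor <- course_floor(config, n)
    crash <- which(altitude < floor)
    score <- if (length(crash)) crash[1] - 1L else n
    if (length(crash)) events[crash[1]] <- paste0(events[crash[1]], "+collision")
    indicators$game_score <- score
  } else {
    events <- focus_step(control)
    indicators$skill_times <- which(events == "release") - 1L
  }

  structure(list(game = game, levels = levels, control = control,
                 events = events, indicators = indicators),
            class = "session_log")
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log> game=%s, %d ticks\n", x$game, length(x$levels)))
  ind <- x$indicators
  for (nm in names(ind)) {
    cat(sprintf("  %s: %s\n", nm, paste(ind[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' Write a session log as JSON
#' @param log A `session_log`.
#' @param path Output path.
#' @export
write_session_log <- function(log, path) {
  stopifnot(inherits(log, "session_log"))
  jsonlite::write_json(unclass(log), path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}
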