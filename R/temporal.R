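#' Time spent in each ear position
#'
#' Each frame with a defined posture contributes `1 / frame_rate`
#' seconds to that posture's total; frames with a missing posture
#' contribute to neither, so `time_front + time_back` equals the count
#' of defined frames divided by the frame rate.
#'
#' @param positions Character vector of `"frontward"` / `"backward"`,
#'   with `NA` for frames where the posture is undefined.
#' @param frame_rate Frames per second, > 0. Default 1.
#' @return A list: `time_front`, `time_back` (seconds), `n_frames`
#'   (defined frames), `frame_rate`.
#' @export
time_in_position <- function(positions, frame_rate = 1) {
  if (!length(positions)) stop("empty position sequence", call. = FALSE)
  if (frame_rate <= 0) stop("frame_rate must be > 0", call. = FALSE)
  ok <- !is.na(positions)
  bad <- positions[ok][!positions[ok] %in% c("frontward", "backward")]
  if (length(bad)) {
    stop("unknown position labels: ", paste(unique(bad), collapse = ", "),
      call. = FALSE
    )
  }
  list(
    time_front = sum(positions[ok] == "frontward") / frame_rate,
    time_back = sum(positions[ok] == "backward") / frame_rate,
    n_frames = sum(ok),
    frame_rate = frame_rate
  )
}

# maximal runs of consecutive non-missing positions as (start, length)
position_runs <- function(positions) {
  ok <- !is.na(positions)
  if (!any(ok)) {
    return(data.frame(start = integer(0), len = integer(0)))
  }
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], len = r$lengths[r$values])
}

#' Count ear movements within qualifying windows
#'
#' An ear movement is a transition between frontward and backward
#' posture in consecutive frames. Movements are quantified only where at
#' least `min_window` consecutive defined frames are available (20
#' frames = 20 s at 1 fps): the position sequence is cut at missing
#' frames into maximal runs; runs shorter than `min_window` yield
#' nothing; within a qualifying run, transitions are counted per window
#' — non-overlapping `min_window`-frame segments from the run start
#' ("tumbling", the default, so no transition is counted twice) or every
#' `min_window`-frame offset ("sliding"). Trailing partial segments are
#' dropped. Gaps never contribute a transition: positions on the two
#' sides of a missing frame are never compared.
#'
#' @param positions Character vector of `"frontward"` / `"backward"` /
#'   `NA` for one ear of one trajectory.
#' @param min_window Minimum consecutive defined frames, default 20.
#' @param mode `"tumbling"` (default) or `"sliding"` windows.
#' @return A data.frame with one row per window: `window_start` (1-based
#'   frame position in the input), `window_len`, `n_transitions`.
#'   Zero rows when no run qualifies.
#' @export
count_transitions <- function(positions, min_window = 20L,
                              mode = c("tumbling", "sliding")) {
  mode <- match.arg(mode)
  min_window <- as.integer(min_window)
  if (min_window < 2L) stop("min_window must be at least 2 frames", call. = FALSE)
  runs <- position_runs(positions)
  out <- list()
  for (i in seq_len(nrow(runs))) {
    s <- runs$start[i]
    len <- runs$len[i]
    if (len < min_window) next
    starts <- if (mode == "tumbling") {
      seq(s, s + len - min_window, by = min_window)
    } else {
      seq(s, s + len - min_window, by = 1L)
    }
    for (ws in starts) {
      seg <- positions[ws:(ws + min_window - 1L)]
      out[[length(out) + 1L]] <- data.frame(
        window_start = ws,
        window_len = min_window,
        n_transitions = sum(seg[-1] != seg[-min_window])
      )
    }
  }
  if (!length(out)) {
    return(data.frame(
      window_start = integer(0), window_len = integer(0),
      n_transitions = integer(0)
    ))
  }
  do.call(rbind, out)
}

#' Per-window ear statistics: time budgets and movement counts
#'
#' Combines [time_in_position()] and the transition count over the same
#' qualifying windows, so the per-window time in front plus time in back
#' always equals the window length over the frame rate.
#'
#' @inheritParams count_transitions
#' @param frame_rate Frames per second.
#' @return A data.frame with one row per qualifying window:
#'   `window_start`, `time_front_s`, `time_back_s`, `n_transitions`.
#' @export
ear_window_stats <- function(positions, frame_rate = 1, min_window = 20L,
                             mode = c("tumbling", "sliding")) {
  wins <- count_transitions(positions, min_window = min_window, mode = mode)
  if (!nrow(wins)) {
    return(data.frame(
      window_start = integer(0), time_front_s = numeric(0),
      time_back_s = numeric(0), n_transitions = integer(0)
    ))
  }
  budgets <- lapply(seq_len(nrow(wins)), function(i) {
    seg <- positions[wins$window_start[i]:(wins$window_start[i] + wins$window_len[i] - 1L)]
    time_in_position(seg, frame_rate)
  })
  data.frame(
    window_start = wins$window_start,
    time_front_s = vapply(budgets, `[[`, numeric(1), "time_front"),
    time_back_s = vapply(budgets, `[[`, numeric(1), "time_back"),
    n_transitions = wins$n_transitions
  )
}
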