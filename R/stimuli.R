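#' Color-name association stimuli
#'
#' Tools for generating the five-alternative color discrimination stimuli used
#' in errorless (EL) and trial-and-error (T&E) color-name association learning,
#' planning a learning/test session, and scoring test responses.
#'
#' Colors live in HSL coordinates with every channel rescaled to the integer
#' range 0-255. A target color (lightness restricted to 100-200) is embedded
#' among four distractors that share its hue and lightness but differ in
#' saturation by multiples of a fixed step (default 35), so that the
#' discrimination is moderately difficult and the target's position within the
#' candidate set is uniformly distributed when target saturations are uniform.
#'
#' @name stimuli
NULL

#' Construct an HSL color
#'
#' @param hue,saturation,lightness Integers in \[0, 255\].
#' @return An object of class `hsl_color` (a named integer vector).
#' @examples
#' hsl_color(120, 46, 150)
#' @export
hsl_color <- function(hue, saturation, lightness) {
  v <- c(hue = as.integer(hue), saturation = as.integer(saturation),
         lightness = as.integer(lightness))
  if (anyNA(v) || any(v < 0L) || any(v > 255L))
    stop("HSL channels must be integers in [0, 255]")
  structure(v, class = "hsl_color")
}

#' @export
print.hsl_color <- function(x, ...) {
  cat(sprintf("HSL(%d, %d, %d)\n", x[["hue"]], x[["saturation"]], x[["lightness"]]))
  invisible(x)
}

#' Saturation grid around a target value
#'
#' Generates all saturation values `target_saturation + k * step` (k any
#' integer, positive or negative) that fall inside `[lo, hi]`, sorted
#' ascending. For the default step of 35 on the 0-255 scale the grid always
#' has 7 or 8 elements.
#'
#' @param target_saturation Integer target saturation, within `[lo, hi]`.
#' @param step Positive integer grid step (default 35).
#' @param lo,hi Channel bounds (defaults 0 and 255).
#' @return An object of class `saturation_grid`: list with `values`,
#'   `target_saturation`, `step`.
#' @examples
#' build_saturation_grid(46)$values  # 11 46 81 116 151 186 221
#' @export
build_saturation_grid <- function(target_saturation, step = 35L, lo = 0L, hi = 255L) {
  if (step <= 0) stop("step must be positive")
  if (target_saturation < lo || target_saturation > hi)
    stop(sprintf("target saturation %d outside [%d, %d]", target_saturation, lo, hi))
  k_lo <- -floor((target_saturation - lo) / step)
  k_hi <- floor((hi - target_saturation) / step)
  values <- as.integer(target_saturation + step * seq.int(k_lo, k_hi))
  structure(list(values = values,
                 target_saturation = as.integer(target_saturation),
                 step = as.integer(step)),
            class = "saturation_grid")
}

#' Enumerate candidate windows containing the target
#'
#' All runs of five consecutive grid values that contain the target
#' saturation, in ascending order of their starting value.
#'
#' @param grid A [build_saturation_grid()] result.
#' @return A list of integer vectors of length 5.
#' @examples
#' length(enumerate_candidate_windows(build_saturation_grid(46)))  # 2
#' @export
enumerate_candidate_windows <- function(grid) {
  stopifnot(inherits(grid, "saturation_grid"))
  v <- grid$values
  if (length(v) < 5) stop("saturation grid has fewer than 5 values")
  t_pos <- match(grid$target_saturation, v)
  starts <- seq_len(length(v) - 4L)
  starts <- starts[starts <= t_pos & t_pos <= starts + 4L]
  lapply(starts, function(s) v[s:(s + 4L)])
}

#' Sample a candidate set for a target color
#'
#' Picks one of the admissible five-value saturation windows uniformly at
#' random and materializes the five candidate colors (shared hue and
#' lightness, distinct saturations).
#'
#' @param target An [hsl_color()] with lightness in \[100, 200\].
#' @param step Grid step, default 35.
#' @return An object of class `candidate_set`: list with `colors` (list of 5
#'   `hsl_color`), `saturations`, `target_index` (1-based position of the
#'   target within the window).
#' @export
sample_candidate_set <- function(target, step = 35L) {
  stopifnot(inherits(target, "hsl_color"))
  L <- target[["lightness"]]
  if (L < 100L || L > 200L)
    stop("target lightness must lie in [100, 200]")
  grid <- build_saturation_grid(target[["saturation"]], step = step)
  windows <- enumerate_candidate_windows(grid)
  w <- windows[[sample.int(length(windows), 1L)]]
  colors <- lapply(w, function(s) hsl_color(target[["hue"]], s, L))
  structure(list(colors = colors, saturations = w,
                 target_index = match(target[["saturation"]], w)),
            class = "candidate_set")
}

#' Sample target colors with evenly represented hues
#'
#' Draws `n` target colors: hues by stratified sampling (one uniform draw per
#' equal-width hue bin spanning \[0, 255\], then shuffled, so the whole color
#' palette is represented evenly), lightness uniform on \[100, 200\],
#' saturation uniform on \[0, 255\].
#'
#' @param n Number of colors (1-256; beyond 256 the hue bins would be
#'   narrower than one hue unit).
#' @return A list of `hsl_color`, with names `color01`, `color02`, ...
#' @export
sample_target_colors <- function(n) {
  if (n < 1) stop("n must be at least 1")
  if (n > 256) stop("n must not exceed 256 (hue bins narrower than 1 unit)")
  edges <- floor(seq(0, 256, length.out = n + 1))
  hues <- vapply(seq_len(n), function(i) {
    lo <- edges[i]; hi <- edges[i + 1] - 1
    if (hi < lo) hi <- lo
    sample(seq.int(lo, hi), 1L)
  }, integer(1))
  hues <- sample(hues)
  cols <- lapply(seq_len(n), function(i) {
    hsl_color(hues[i],
              sample.int(256L, 1L) - 1L,
              sample(100:200, 1L))
  })
  names(cols) <- sprintf("color%02d", seq_len(n))
  cols
}

#' Build a learning/test session plan
#'
#' A session presents 10 color-name associations, repeated in 4 blocks; each
#' block is a fresh random permutation of the 10 associations and each trial
#' randomizes the on-screen positions of the five candidate colors so the
#' target appears in each location with equal probability.
#'
#' Exposure timings (candidate display 9 s, feedback display 6 s) are carried
#' as metadata only; no presentation engine is provided. For T&E sessions the
#' plan schema admits multiple attempts per trial (the repeat-until-correct
#' loop); attempt simulation belongs to the cohort simulator.
#'
#' @param colors Named list of exactly 10 [hsl_color()] targets with unique
#'   names.
#' @param condition `"EL"` or `"TE"`.
#' @return An object of class `session_plan`: data frame of 40 trials with
#'   block, association id/name, the 5 candidate HSL triples in display order,
#'   and the target's display position (1-5), plus attributes `condition` and
#'   `timing` (seconds).
#' @export
build_session_plan <- function(colors, condition = c("EL", "TE")) {
  condition <- match.arg(condition)
  if (length(colors) != 10L) stop("exactly 10 color-name associations required")
  if (anyDuplicated(names(colors)) || is.null(names(colors)) || any(!nzchar(names(colors))))
    stop("association color names must be unique and non-empty")
  sets <- lapply(colors, sample_candidate_set)
  rows <- vector("list", 40L)
  r <- 0L
  for (block in 1:4) {
    order_ids <- sample.int(10L)
    for (assoc in order_ids) {
      cs <- sets[[assoc]]
      pos <- sample.int(5L)          # pos[j]: display slot of window member j
      slots <- order(pos)            # slots[s]: window member shown at slot s
      r <- r + 1L
      row <- data.frame(block = block, assoc_id = assoc,
                        name = names(colors)[assoc],
                        target_position = pos[cs$target_index],
                        target_saturation = cs$saturations[cs$target_index],
                        stringsAsFactors = FALSE)
      for (s in 1:5) {
        cc <- cs$colors[[slots[s]]]
        row[[sprintf("h%d", s)]] <- cc[["hue"]]
        row[[sprintf("s%d", s)]] <- cc[["saturation"]]
        row[[sprintf("l%d", s)]] <- cc[["lightness"]]
      }
      rows[[r]] <- row
    }
  }
  plan <- do.call(rbind, rows)
  rownames(plan) <- NULL
  structure(plan, condition = condition,
            timing = c(candidates_s = 9, feedback_s = 6),
            class = c("session_plan", "data.frame"))
}

#' Score a test session
#'
#' The test score is 10 times the number of correct responses over the 40
#' test trials, giving a 0-400 scale in steps of 10.
#'
#' @param responses Data frame with integer columns `chosen` and `correct`
#'   (positions 1-5), 40 rows.
#' @return Integer score in \[0, 400\].
#' @examples
#' score_test(data.frame(chosen = rep(1, 40), correct = rep(1, 40)))  # 400
#' @export
score_test <- function(responses) {
  if (!all(c("chosen", "correct") %in% names(responses)))
    stop("responses needs 'chosen' and 'correct' columns")
  if (nrow(responses) != 40L) stop("a test session has exactly 40 trials")
  if (any(responses$chosen < 1 | responses$chosen > 5) ||
      any(responses$correct < 1 | responses$correct > 5))
    stop("positions must be in 1-5")
  10L * sum(responses$chosen == responses$correct)
}

#' Write a session plan as TSV
#'
#' One row per trial; the condition and timing metadata are written as
#' comment header lines (`# key: value`).
#'
#' @param plan A [build_session_plan()] result.
#' @param path Output path.
#' @export
write_session_plan <- function(plan, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# condition: %s", attr(plan, "condition")), con)
  tm <- attr(plan, "timing")
  writeLines(sprintf("# %s: %g", names(tm), tm), con)
  utils::write.table(as.data.frame(plan), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
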