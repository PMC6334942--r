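#' Hexagonal target layout
#'
#' Vertex coordinates of the regular hexagon the target travels along,
#' clockwise starting from the bottom (central-lower) vertex. For a regular
#' hexagon the side length equals the circumradius, so placing vertices at
#' radius `inter_target_distance` makes every clockwise neighbour exactly
#' `inter_target_distance` dva away.
#'
#' @param inter_target_distance distance between neighbouring vertices (dva).
#' @return data.frame with columns `vertex`, `x`, `y` (dva, screen-centred).
#' @export
hexagon_vertices <- function(inter_target_distance = 10) {
  stopifnot(inter_target_distance > 0)
  ang <- -pi / 2 - (0:5) * pi / 3  # decreasing angle = clockwise (y up)
  data.frame(
    vertex = 1:6,
    x = inter_target_distance * cos(ang),
    y = inter_target_distance * sin(ang)
  )
}

#' Default trial timing parameters
#'
#' Fixation intervals are drawn from a shifted exponential (minimum 250 ms,
#' mean 550 ms); the fixated target then flashes for 150 ms, after which the
#' experiment software polls for a saccade (online displacement threshold
#' 1.5 dva, at most 2750 ms). The awareness probe appears 500 ms after the
#' intrasaccadic displacement with a 2000 ms response window.
#'
#' @return named list of timing parameters (ms and dva).
#' @export
protocol_timing <- function() {
  list(
    fixation_min_ms = 250,
    fixation_mean_ms = 550,
    flash_duration_ms = 150,
    saccade_poll_threshold_dva = 1.5,
    poll_timeout_ms = 2750,
    probe_delay_ms = 500,
    response_window_ms = 2000
  )
}

#' Build a session protocol
#'
#' Describes one experimental session: four blocks (baseline, two adaptation
#' blocks, baseline) of saccades around a clockwise hexagonal path. During
#' adaptation blocks the target is displaced intrasaccadically, either
#' forward along the saccade trajectory (gain-up) or backward (gain-down).
#' Perturbations are expressed as relative post-displacement gain minus 1:
#' with the default geometry (10 dva between targets, +3.3 forward, -2.5
#' backward) the perturbation is +0.33 for gain-up and -0.25 for gain-down,
#' matching the equal relative gains 13.3/10 and 7.5/10.
#'
#' @param saccade_type `"reactive"` (single stepping target) or `"scanning"`
#'   (all six targets always visible).
#' @param direction_order `"down-up"` (block 2 gain-down, block 3 gain-up) or
#'   `"up-down"`.
#' @param n_baseline,n_adaptation trials in the baseline (blocks 1 and 4) and
#'   adaptation (blocks 2 and 3) blocks.
#' @param inter_target_distance hexagon side length (dva).
#' @param displacement_forward,displacement_backward intrasaccadic target
#'   displacement magnitudes (dva) for gain-up and gain-down.
#' @param timing list as produced by [protocol_timing()].
#' @return object of class `protocol_spec`.
#' @export
build_protocol <- function(saccade_type = c("reactive", "scanning"),
                           direction_order = c("down-up", "up-down"),
                           n_baseline = 48, n_adaptation = 96,
                           inter_target_distance = 10,
                           displacement_forward = 3.3,
                           displacement_backward = 2.5,
                           timing = protocol_timing()) {
  saccade_type <- match.arg(saccade_type)
  direction_order <- match.arg(direction_order)
  if (n_baseline <= 0 || n_adaptation <= 0)
    stop("block trial counts must be positive")
  if (inter_target_distance <= 0) stop("inter_target_distance must be > 0")

  p_up <- displacement_forward / inter_target_distance
  p_down <- -displacement_backward / inter_target_distance
  adapt_p <- if (direction_order == "down-up") c(p_down, p_up) else c(p_up, p_down)

  blocks <- data.frame(
    block = 1:4,
    n_trials = c(n_baseline, n_adaptation, n_adaptation, n_baseline),
    perturbation = c(0, adapt_p[1], adapt_p[2], 0)
  )
  structure(
    list(
      saccade_type = saccade_type,
      direction_order = direction_order,
      blocks = blocks,
      hexagon = hexagon_vertices(inter_target_distance),
      inter_target_distance = inter_target_distance,
      displacement_forward = displacement_forward,
      displacement_backward = displacement_backward,
      timing = timing
    ),
    class = "protocol_spec"
  )
}

#' Expand a protocol into its per-trial design table
#'
#' Each trial is a saccade from the current hexagon vertex to the next one
#' clockwise; the direction label (1-6) is the hexagon edge and cycles with
#' period six. `post_target` is the pre-saccadic target shifted along the
#' saccade direction by the block's displacement.
#'
#' @param protocol a `protocol_spec`.
#' @return data.frame with one row per trial: `trial`, `block`,
#'   `trial_in_block`, `direction`, `perturbation`, `pre_target_x/y`,
#'   `post_target_x/y`.
#' @export
protocol_trials <- function(protocol) {
  stopifnot(inherits(protocol, "protocol_spec"))
  hx <- protocol$hexagon
  blocks <- protocol$blocks
  n_total <- sum(blocks$n_trials)
  trial <- seq_len(n_total)
  block <- rep(blocks$block, blocks$n_trials)
  trial_in_block <- unlist(lapply(blocks$n_trials, seq_len), use.names = FALSE)
  perturbation <- rep(blocks$perturbation, blocks$n_trials)

  from <- ((trial - 1) %% 6) + 1          # start vertex of the trial
  to <- (trial %% 6) + 1                  # next clockwise vertex
  direction <- from                       # edge index = start vertex
  dx <- hx$x[to] - hx$x[from]
  dy <- hx$y[to] - hx$y[from]
  len <- sqrt(dx^2 + dy^2)
  ux <- dx / len
  uy <- dy / len
  disp <- perturbation * protocol$inter_target_distance

  data.frame(
    trial = trial, block = block, trial_in_block = trial_in_block,
    direction = direction, perturbation = perturbation,
    start_vertex = from,
    pre_target_x = hx$x[to], pre_target_y = hx$y[to],
    post_target_x = hx$x[to] + disp * ux,
    post_target_y = hx$y[to] + disp * uy,
    fix_target_x = hx$x[from], fix_target_y = hx$y[from]
  )
}

#' Validate protocol invariants
#'
#' Checks the structural invariants of a session protocol: four blocks with
#' zero perturbation in the baseline blocks, and hexagon vertices equidistant
#' from their clockwise neighbours.
#'
#' @param protocol a `protocol_spec`.
#' @return `TRUE` invisibly; stops with a message otherwise.
#' @export
validate_protocol <- function(protocol) {
  stopifnot(inherits(protocol, "protocol_spec"))
  b <- protocol$blocks
  if (nrow(b) != 4) stop("protocol must have exactly 4 blocks")
  if (any(b$perturbation[c(1, 4)] != 0))
    stop("baseline blocks must have zero perturbation")
  if (any(b$n_trials <= 0)) stop("non-positive block length")
  hx <- protocol$hexagon
  nb <- c(2:6, 1)
  d <- sqrt((hx$x[nb] - hx$x)^2 + (hx$y[nb] - hx$y)^2)
  if (any(abs(d - protocol$inter_target_distance) > 1e-9))
    stop("hexagon vertices are not equidistant from clockwise neighbours")
  invisible(TRUE)
}
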