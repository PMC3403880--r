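#' Layout configuration
#'
#' Controls the two-pass rectangle layout: canvas size, density of the grid
#' of candidate layout points, the weights of the two terms of the overlap
#' score, the corner-repulsion strength, and the refinement schedule.
#'
#' The overlap score of a placement is
#' `w_overlap * sum(pairwise frame intersection areas) +
#'  w_distance * sum(pairwise center distances)`; lower is better. The two
#' terms are incommensurate (area vs length), so by default `w_distance` is
#' set to `1 / canvas_diagonal`: pulling an item across the whole canvas
#' then costs about as much as one unit square of overlap, keeping the
#' compaction term gentle relative to overlap avoidance.
#'
#' Corner repulsion adds
#' `corner_strength * sum(1 / (corner_eps + distance to corner))` over the
#' four canvas corners, nudging the refined cloud into an oval rather than
#' a filled rectangle. Its default strength scales with `diagonal^3` so the
#' whole score scales uniformly (like area) when all lengths are scaled.
#'
#' @param canvas_width,canvas_height canvas size in canvas units (pixels).
#' @param grid_nx,grid_ny number of layout grid points per axis; `NULL`
#'   auto-selects a pitch of 1/4 of the median item dimension, capped at
#'   200 points per axis.
#' @param w_overlap,w_distance score weights (non-negative); `w_distance =
#'   NULL` uses `1/canvas_diagonal`.
#' @param corner_strength corner repulsion strength; `NULL` uses
#'   `1e-5 * canvas_diagonal^3`; `0` disables.
#' @param corner_eps regularizer keeping the corner penalty finite at the
#'   corner itself; `NULL` uses 1% of the canvas diagonal.
#' @param step_size refinement move length; `NULL` uses 2% of the canvas
#'   diagonal. Halved (down to `step_size/8`) whenever a sweep stalls.
#' @param max_iterations maximum refinement sweeps.
#' @param tolerance absolute per-sweep improvement below which the step is
#'   halved / refinement stops; `NULL` uses `1e-6 *` the initial total
#'   score.
#' @param seed integer seed (reserved for optional jitter; the layout
#'   itself is deterministic and does not consume randomness).
#' @return an object of class `layout_config`.
#' @export
layout_config <- function(canvas_width = 2000, canvas_height = 1400,
                          grid_nx = NULL, grid_ny = NULL,
                          w_overlap = 1, w_distance = NULL,
                          corner_strength = NULL, corner_eps = NULL,
                          step_size = NULL, max_iterations = 500L,
                          tolerance = NULL, seed = 1L) {
  stopifnot(canvas_width > 0, canvas_height > 0, w_overlap >= 0,
            max_iterations >= 0L)
  diag <- sqrt(canvas_width^2 + canvas_height^2)
  if (is.null(w_distance)) w_distance <- 1 / diag
  if (is.null(corner_strength)) corner_strength <- 1e-5 * diag^3
  if (is.null(corner_eps)) corner_eps <- 0.01 * diag
  if (is.null(step_size)) step_size <- 0.02 * diag
  stopifnot(w_distance >= 0, corner_strength >= 0, corner_eps > 0,
            step_size > 0)
  if (!is.null(grid_nx)) stopifnot(grid_nx >= 2L)
  if (!is.null(grid_ny)) stopifnot(grid_ny >= 2L)
  structure(list(canvas_width = canvas_width, canvas_height = canvas_height,
                 grid_nx = grid_nx, grid_ny = grid_ny,
                 w_overlap = w_overlap, w_distance = w_distance,
                 corner_strength = corner_strength, corner_eps = corner_eps,
                 step_size = step_size,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, seed = as.integer(seed)),
            class = "layout_config")
}

#' Build a cloud item table
#'
#' @param id item keys (unique).
#' @param width,height frame dimensions (> 0, canvas units).
#' @param pinned logical; pinned items are never moved by [refine()].
#' @return `data.frame` of class `cloud_items` with `x`/`y` position
#'   columns initialized to `NA`.
#' @export
cloud_items <- function(id, width, height, pinned = FALSE) {
  stopifnot(length(width) == length(id), length(height) == length(id),
            all(width > 0), all(height > 0), !anyDuplicated(id))
  df <- data.frame(id = as.character(id), width = width, height = height,
                   x = NA_real_, y = NA_real_,
                   pinned = rep_len(pinned, length(id)),
                   stringsAsFactors = FALSE)
  class(df) <- c("cloud_items", "data.frame")
  df
}

#' Intersection area of two item frames
#'
#' @param a,b items: lists or one-row data frames with `x`, `y`, `width`,
#'   `height`.
#' @return non-negative intersection area (0 when disjoint).
#' @export
pair_overlap_area <- function(a, b) {
  pair_overlap_cpp(a$x, a$y, a$width, a$height, b$x, b$y, b$width, b$height)
}

#' Placement score of a candidate item against placed items
#'
#' The greedy objective: weighted sum of the candidate's overlap area with
#' every placed item plus the weighted sum of center distances.
#'
#' @param candidate item with `x`, `y`, `width`, `height`.
#' @param placed positioned items (`data.frame`).
#' @param cfg a [layout_config()].
#' @return the score (lower is better); 0 against an empty set.
#' @export
placement_score <- function(candidate, placed, cfg = layout_config()) {
  if (NROW(placed) == 0L) return(0)
  placement_score_cpp(candidate$x, candidate$y, candidate$width,
                      candidate$height, placed$x, placed$y, placed$width,
                      placed$height, cfg$w_overlap, cfg$w_distance)
}

#' Corner repulsion penalty of a positioned item
#'
#' `corner_strength * sum over the 4 canvas corners of
#' 1 / (corner_eps + distance(center, corner))`; finite everywhere, 0 when
#' `corner_strength = 0`.
#'
#' @param item positioned item.
#' @param cfg a [layout_config()].
#' @return non-negative penalty.
#' @export
corner_penalty <- function(item, cfg = layout_config()) {
  corner_penalty_cpp(item$x, item$y, cfg$canvas_width, cfg$canvas_height,
                     cfg$corner_strength, cfg$corner_eps)
}

#' Total layout score
#'
#' Sum over all item pairs of weighted overlap area and weighted center
#' distance, plus each item's corner penalty. The quantity [refine()]
#' monotonically decreases.
#'
#' @param items positioned items.
#' @param cfg a [layout_config()].
#' @return the total score.
#' @export
total_score <- function(items, cfg = layout_config()) {
  total_score_cpp(items$x, items$y, items$width, items$height,
                  cfg$canvas_width, cfg$canvas_height, cfg$w_overlap,
                  cfg$w_distance, cfg$corner_strength, cfg$corner_eps)
}

mc_grid <- function(items, cfg) {
  nx <- cfg$grid_nx; ny <- cfg$grid_ny
  if (is.null(nx) || is.null(ny)) {
    pitch <- stats::median(c(items$width, items$height)) / 4
    if (is.null(nx)) nx <- max(2L, min(200L, floor(cfg$canvas_width / pitch) + 1L))
    if (is.null(ny)) ny <- max(2L, min(200L, floor(cfg$canvas_height / pitch) + 1L))
  }
  list(gx = seq(0, cfg$canvas_width, length.out = nx),
       gy = seq(0, cfg$canvas_height, length.out = ny))
}

#' First layout pass: greedy placement on a dense grid
#'
#' Items are sorted by frame area (largest first); the largest is centered
#' on the canvas, and each further item is evaluated at every grid point
#' whose frame lies fully inside the canvas and fixed at the point with the
#' minimal [placement_score()] (ties keep the first point in row-major scan
#' order). Already-placed items never move, so the state after k placements
#' is exactly the first k rows of the result — which is how progression
#' snapshots are obtained.
#'
#' @param items a [cloud_items()] table (positions ignored).
#' @param cfg a [layout_config()].
#' @param debug also record, per placement step, the running-best score
#'   trace over the grid scan (attribute `"score_traces"`).
#' @return items ordered by decreasing area with `x`/`y` filled in;
#'   attribute `"step_scores"` holds the chosen score of each placement
#'   step.
#' @export
greedy_place <- function(items, cfg = layout_config(), debug = FALSE) {
  stopifnot(NROW(items) >= 1L)
  ord <- order(-(items$width * items$height), seq_len(NROW(items)))
  items <- items[ord, , drop = FALSE]
  grid <- mc_grid(items, cfg)
  res <- greedy_place_cpp(items$width, items$height, cfg$canvas_width,
                          cfg$canvas_height, grid$gx, grid$gy,
                          cfg$w_overlap, cfg$w_distance, isTRUE(debug))
  items$x <- res$x
  items$y <- res$y
  rownames(items) <- NULL
  attr(items, "step_scores") <- res$step_score
  if (isTRUE(debug)) attr(items, "score_traces") <- res$traces
  items
}

#' Second layout pass: iterative hill-climbing refinement
#'
#' Sweeps over the items; each item in turn tries moves of `step_size` in
#' the 8 compass directions and accepts the best one only if it lowers the
#' total score (its pairwise terms plus its corner penalty), so the total
#' is non-increasing across sweeps by construction. When a sweep improves
#' the total by less than `tolerance` the step is halved, down to a floor
#' of 1/8 of the initial step, after which refinement stops.
#'
#' @param items positioned items ([greedy_place()] output).
#' @param cfg a [layout_config()].
#' @return items with refined positions; attribute `"sweep_totals"` holds
#'   the total score before refinement and after each sweep.
#' @export
refine <- function(items, cfg = layout_config()) {
  stopifnot(all(is.finite(items$x)), all(is.finite(items$y)))
  if (cfg$max_iterations == 0L || NROW(items) == 0L) {
    attr(items, "sweep_totals") <- total_score(items, cfg)
    return(items)
  }
  tol <- cfg$tolerance
  if (is.null(tol)) tol <- 1e-6 * max(total_score(items, cfg), 1e-12)
  res <- refine_cpp(items$x, items$y, items$width, items$height,
                    items$pinned, cfg$canvas_width, cfg$canvas_height,
                    cfg$w_overlap, cfg$w_distance, cfg$corner_strength,
                    cfg$corner_eps, cfg$step_size, cfg$step_size / 8,
                    cfg$max_iterations, tol)
  items$x <- res$x
  items$y <- res$y
  attr(items, "sweep_totals") <- res$sweep_totals
  items
}

#' Total pairwise overlap area of a layout
#'
#' @param items positioned items.
#' @return sum of all pairwise frame intersection areas.
#' @export
total_overlap_area <- function(items) {
  total_score_cpp(items$x, items$y, items$width, items$height,
                  1, 1, 1, 0, 0, 1)
}

#' Write a layout as a debug SVG of bare rectangles
#'
#' Renders item frames (no chemistry) for visual inspection of layout
#' progression snapshots.
#'
#' @param items positioned items.
#' @param cfg a [layout_config()] (canvas size).
#' @param path output file.
#' @export
write_layout_svg <- function(items, cfg, path) {
  num <- function(v) formatC(v, format = "fg", digits = 8)
  rects <- sprintf(
    '<rect id="%s" x="%s" y="%s" width="%s" height="%s" fill="none" stroke="black" stroke-width="1"/>',
    xml_escape(items$id), num(items$x - items$width / 2),
    num(items$y - items$height / 2), num(items$width), num(items$height))
  writeLines(c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
            num(cfg$canvas_width), num(cfg$canvas_height),
            num(cfg$canvas_width), num(cfg$canvas_height)),
    rects, "</svg>"), path)
  invisible(path)
}
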