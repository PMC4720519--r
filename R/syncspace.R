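#' Classify synchrony of calcium rises between two cells
#'
#' A rise in one cell is synchronous when some rise of the partner cell
#' falls within `window_s` seconds of it (absolute lag, boundary inclusive).
#' The 10-s default mirrors the criterion used to decide whether tip- and
#' stalk-cell oscillations reflect intercellular calcium waves: a rise
#' occurring within 10 s of a rise in the other cell is called synchronous.
#' The window is applied symmetrically in both directions, and a rise may
#' match any partner rise.
#'
#' @param rises_A,rises_B Sorted rise (onset or apex) times of the two
#'   cells, seconds.
#' @param window_s Synchrony window, seconds.
#' @param cell_A,cell_B Labels stored in the result.
#' @return A list of class `ca_synchrony`: per-rise logical vectors
#'   `synchronous_A`, `synchronous_B` and the percentages
#'   `pct_synchronous_A`, `pct_synchronous_B` (`NA` when the cell has no
#'   rises, not 0).
#' @examples
#' classify_synchrony(c(100, 200, 300, 400), c(105, 290))$pct_synchronous_A
#' @export
classify_synchrony <- function(rises_A, rises_B, window_s = 10,
                               cell_A = "A", cell_B = "B") {
  check_number(window_s, "window_s", 0)
  near_any <- function(a, b) {
    if (length(a) == 0) return(logical(0))
    if (length(b) == 0) return(rep(FALSE, length(a)))
    vapply(a, function(t) any(abs(b - t) <= window_s), logical(1))
  }
  syn_a <- near_any(rises_A, rises_B)
  syn_b <- near_any(rises_B, rises_A)
  pct <- function(x) if (length(x) == 0) NA_real_ else 100 * mean(x)
  structure(
    list(
      cell_A = cell_A, cell_B = cell_B, window_s = window_s,
      synchronous_A = syn_a, synchronous_B = syn_b,
      pct_synchronous_A = pct(syn_a), pct_synchronous_B = pct(syn_b)
    ),
    class = "ca_synchrony"
  )
}

#' @export
print.ca_synchrony <- function(x, ...) {
  cat(sprintf(
    "<ca_synchrony> %s vs %s (window %g s): %s%% / %s%% synchronous\n",
    x$cell_A, x$cell_B, x$window_s,
    format(x$pct_synchronous_A), format(x$pct_synchronous_B)
  ))
  invisible(x)
}

#' Tidy a synchrony result
#' @param x A `ca_synchrony`.
#' @param ... Unused.
#' @return One-row tibble with the pair labels, rise counts and synchronous
#'   percentages.
#' @method tidy ca_synchrony
#' @export
tidy.ca_synchrony <- function(x, ...) {
  tibble::tibble(
    cell_A = x$cell_A, cell_B = x$cell_B,
    n_rises_A = length(x$synchronous_A),
    n_rises_B = length(x$synchronous_B),
    pct_synchronous_A = x$pct_synchronous_A,
    pct_synchronous_B = x$pct_synchronous_B,
    window_s = x$window_s
  )
}

#' Pairwise synchrony across a cohort of peak tables
#'
#' @param peaks Peak tibble from [detect_peaks()] (uses `apex_time_s`).
#' @param pairs Two-column data frame (`cell_A`, `cell_B`) of pairs to test.
#' @param window_s Synchrony window, seconds.
#' @return A tibble with one row per pair (see [tidy.ca_synchrony()]).
#' @export
synchrony_table <- function(peaks, pairs, window_s = 10) {
  check_columns(pairs, c("cell_A", "cell_B"), "pairs")
  purrr::map_dfr(seq_len(nrow(pairs)), function(k) {
    a <- sort(peaks$apex_time_s[peaks$cell_id == pairs$cell_A[k]])
    b <- sort(peaks$apex_time_s[peaks$cell_id == pairs$cell_B[k]])
    tidy(classify_synchrony(a, b, window_s,
                            cell_A = pairs$cell_A[k],
                            cell_B = pairs$cell_B[k]))
  })
}

#' Assign cells to regions between somite boundaries
#'
#' Each inter-boundary interval along the vessel axis is split into three
#' equal half-open thirds `[left, left + L/3)`, `[left + L/3, left + 2L/3)`,
#' `[left + 2L/3, right)`; a cell belongs to the third containing its
#' nucleus x-position at the first frame. Cells outside every interval are
#' left unassigned (`NA`) with a warning.
#'
#' @param cells Tibble with `cell_id` and `nucleus_x_at_t0_um` (or a
#'   trajectory tibble with `frame` and `x_um`, from which the first-frame
#'   position is taken).
#' @param boundaries_x_um Sorted somite-boundary positions, micrometres.
#' @return A tibble `cell_id`, `region` (1-3 or `NA`), `left_x_um`,
#'   `right_x_um`, `nucleus_x_at_t0_um`.
#' @examples
#' cells <- tibble::tibble(cell_id = c("a", "b"),
#'                         nucleus_x_at_t0_um = c(5, 10))
#' assign_region(cells, c(0, 30))$region # 1 then 2 (half-open thirds)
#' @export
assign_region <- function(cells, boundaries_x_um) {
  boundaries_x_um <- sort(boundaries_x_um)
  if (length(boundaries_x_um) < 2) {
    abort("at least two somite boundaries are required")
  }
  if (!"nucleus_x_at_t0_um" %in% names(cells)) {
    check_columns(cells, c("cell_id", "frame", "x_um"), "cells")
    cells <- dplyr::summarise(
      dplyr::group_by(cells, .data$cell_id),
      nucleus_x_at_t0_um = .data$x_um[which.min(.data$frame)],
      .groups = "drop"
    )
  }
  out <- purrr::map_dfr(seq_len(nrow(cells)), function(k) {
    x <- cells$nucleus_x_at_t0_um[k]
    i <- findInterval(x, boundaries_x_um)
    last_b <- length(boundaries_x_um)
    # the global last boundary belongs to region 3 of the final interval
    if (i == last_b && x == boundaries_x_um[last_b]) i <- last_b - 1L
    if (i < 1 || i >= last_b) {
      return(tibble::tibble(
        cell_id = cells$cell_id[k], region = NA_integer_,
        left_x_um = NA_real_, right_x_um = NA_real_,
        nucleus_x_at_t0_um = x
      ))
    }
    left <- boundaries_x_um[i]
    right <- boundaries_x_um[i + 1]
    third <- (right - left) / 3
    region <- min(floor((x - left) / third) + 1, 3)
    tibble::tibble(
      cell_id = cells$cell_id[k], region = as.integer(region),
      left_x_um = left, right_x_um = right, nucleus_x_at_t0_um = x
    )
  })
  if (anyNA(out$region)) {
    warn(sprintf(
      "%d cell(s) lie outside all boundary intervals and were left unassigned",
      sum(is.na(out$region))
    ))
  }
  out
}

#' Count oscillating budding cells per somite boundary or per ISV
#'
#' Mirrors the sprout-selection counts: every oscillating budding cell is
#' attributed to its nearest somite boundary (absolute x distance) and
#' boundaries are categorised by how many oscillating cells they carry
#' (1, 2, 3+). Percentages are over boundaries carrying at least one
#' oscillating cell. With `mode = "per_isv"` the count is restricted to
#' cells following a tip cell (requires a logical `following_tip` column).
#'
#' @param cells_with_metrics Tibble with `cell_id`, `oscillating`,
#'   `budding`, an x-position column `boundary_ref_x_um` (e.g. nucleus x at
#'   first frame), and `following_tip` for `mode = "per_isv"`.
#' @param boundaries_x_um Somite-boundary positions, micrometres.
#' @param mode `"per_boundary"` or `"per_isv"`.
#' @return A list with `counts` (tibble `boundary_x_um`, `n_oscillating`,
#'   `category`) and `percentages` (tibble `category`, `n_boundaries`,
#'   `pct`).
#' @export
count_oscillating_cells <- function(cells_with_metrics,
                                    boundaries_x_um,
                                    mode = c("per_boundary", "per_isv")) {
  mode <- match.arg(mode)
  if (length(boundaries_x_um) == 0) {
    abort("no somite boundaries supplied")
  }
  check_columns(cells_with_metrics,
                c("cell_id", "oscillating", "budding", "boundary_ref_x_um"),
                "cells_with_metrics")
  d <- cells_with_metrics
  keep <- !is.na(d$oscillating) & !is.na(d$budding) &
    d$oscillating & d$budding
  d <- d[keep, , drop = FALSE]
  if (mode == "per_isv") {
    check_columns(d, "following_tip", "cells_with_metrics")
    d <- d[d$following_tip, , drop = FALSE]
  }
  if (nrow(d) == 0) {
    return(list(
      counts = tibble::tibble(boundary_x_um = numeric(),
                              n_oscillating = integer(),
                              category = character()),
      percentages = tibble::tibble(category = character(),
                                   n_boundaries = integer(), pct = numeric())
    ))
  }
  nearest <- vapply(d$boundary_ref_x_um, function(x) {
    boundaries_x_um[which.min(abs(boundaries_x_um - x))]
  }, numeric(1))
  counts <- dplyr::count(
    tibble::tibble(boundary_x_um = nearest), .data$boundary_x_um,
    name = "n_oscillating"
  )
  counts$category <- ifelse(counts$n_oscillating >= 3, "3+",
                            as.character(counts$n_oscillating))
  pct <- dplyr::count(counts, .data$category, name = "n_boundaries")
  pct$pct <- 100 * pct$n_boundaries / sum(pct$n_boundaries)
  list(counts = counts, percentages = pct)
}
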