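#' Build a site-selection problem from benefit, cost, and constraints
#'
#' Flattens co-registered surfaces into the vectors of a constrained
#' 0/1 selection problem over the analyzable pixel set `N` (cells that
#' are available for restoration and carry a valid cost and benefit):
#' objective coefficients `B_xi / C_xi` (cost per pixel = USD/ha x pixel
#' area in ha), a total-area cap `T_A`, and per-habitat minimum areas
#' `H_A(a)`. Because every pixel has the same area, both constraints are
#' pixel counts: the cap is `floor(per_iteration_fraction * N)` and each
#' habitat minimum is `ceiling(min_habitat_fraction_total / n_iterations
#' * |G_a|)` - the ceiling guarantees the cumulative minimum after all
#' iterations.
#'
#' When iterating, `n_total` and `habitat_totals` should be the *initial*
#' analyzable counts so that caps stay fixed while the candidate set
#' shrinks; they default to the current candidates.
#'
#' @param total_benefit A `total_benefit` surface (`B_xi`).
#' @param cost Continuous cost surface in USD/ha.
#' @param available An `available_area` surface (habitat membership).
#' @param config A [scenario_config()].
#' @param candidate Optional logical matrix marking still-selectable
#'   cells (used by the iteration loop to drop already-restored pixels).
#' @param n_total Pixel count `N` used for the area cap.
#' @param habitat_totals Named vector of `|G_a|` pixel counts used for
#'   the habitat minima.
#' @return An object of class `restoration_problem`: a pixel tibble
#'   (`idx`, `row`, `col`, `habitat`, `benefit`, `cost_usd`, `ratio`)
#'   plus the cap and minima in pixel counts.
#' @export
build_problem <- function(total_benefit, cost, available, config,
                          candidate = NULL, n_total = NULL, habitat_totals = NULL) {
  stopifnot(inherits(total_benefit, "rp_continuous"),
            inherits(cost, "rp_continuous"),
            inherits(available, "available_area"))
  stop_if_grid_mismatch(total_benefit$grid, cost$grid, "benefit and cost")
  stop_if_grid_mismatch(total_benefit$grid, available$grid, "benefit and available area")
  if (!identical(cost$units, "USD/ha")) {
    stop("cost surface must be in USD/ha (apply exp_transform_cost first)")
  }
  grid <- available$grid
  analyzable <- !is.na(available$values) & !is.na(cost$values) & !is.na(total_benefit$values)
  if (any(cost$values[analyzable] <= 0)) stop("cost must be > 0 on all analyzable cells")
  if (is.null(candidate)) candidate <- matrix(TRUE, grid$n_rows, grid$n_cols)
  sel <- analyzable & candidate
  if (!any(sel)) stop("analyzable candidate set is empty")

  idx <- which(sel)
  area_ha <- pixel_area_ha(grid)
  pixels <- tibble::tibble(
    idx = idx,
    row = ((idx - 1L) %% grid$n_rows) + 1L,
    col = ((idx - 1L) %/% grid$n_rows) + 1L,
    habitat = as.integer(available$values[idx]),
    benefit = as.numeric(total_benefit$values[idx]),
    cost_usd = as.numeric(cost$values[idx]) * area_ha
  )
  pixels$ratio <- pixels$benefit / pixels$cost_usd

  if (is.null(n_total)) n_total <- nrow(pixels)
  if (is.null(habitat_totals)) {
    habitat_totals <- table(pixels$habitat)
    habitat_totals <- stats::setNames(as.integer(habitat_totals), names(habitat_totals))
  }
  cap_n <- floor(config$per_iteration_fraction * n_total)
  min_frac <- config$min_habitat_fraction_total / config$n_iterations
  min_n <- if (config$min_habitat_fraction_total > 0) {
    stats::setNames(ceiling(min_frac * as.numeric(habitat_totals)), names(habitat_totals))
  } else {
    stats::setNames(numeric(0), character(0))
  }
  if (sum(min_n) > cap_n) {
    stop("infeasible: total area cap (", cap_n, " pixels) is below the summed habitat minima (",
         sum(min_n), " pixels)")
  }
  for (a in names(min_n)) {
    have <- sum(pixels$habitat == as.integer(a))
    if (have < min_n[[a]]) {
      stop("infeasible: habitat ", a, " has ", have,
           " candidate pixel(s) but requires at least ", min_n[[a]])
    }
  }
  structure(
    list(pixels = pixels, cap_n = as.integer(cap_n),
         min_n = stats::setNames(as.integer(min_n), names(min_n)),
         pixel_area_ha = area_ha, grid = grid,
         budget_usd = config$budget_usd %||% NULL),
    class = "restoration_problem"
  )
}

#' @export
print.restoration_problem <- function(x, ...) {
  cat(sprintf("<restoration_problem> %d candidate pixels, cap %d pixels",
              nrow(x$pixels), x$cap_n))
  if (length(x$min_n)) {
    cat(", minima {", paste(names(x$min_n), x$min_n, sep = ":", collapse = ", "), "}")
  }
  if (!is.null(x$budget_usd)) cat(sprintf(", budget $%.0f", x$budget_usd))
  cat("\n")
  invisible(x)
}

#' Solve the site-selection problem exactly
#'
#' Maximizes `sum(B_i / C_i * x_i)` over binary `x` subject to the pixel
#' cap (`sum(x) <= cap`) and the per-habitat minima
#' (`sum(x_i : i in G_a) >= k_a`).
#'
#' Because pixel areas are uniform, both constraints are cardinality
#' constraints over a partition of the pixels, and the problem has an
#' exact combinatorial solution: within each habitat class, any optimum
#' can be rearranged (by exchange) to take that class's highest-ratio
#' members, so a solution that takes the top `k_a` pixels of each class
#' and then fills the remaining slots with the globally best remaining
#' positive-ratio pixels attains the proven optimum - the same optimum
#' an integer-programming solver would return. Zero-benefit pixels are
#' selected only when a habitat minimum requires them (cheapest first),
#' so the selection is also cost-minimal among trivially tied optima.
#' Ties are broken deterministically by (ratio, then cost, then pixel
#' index).
#'
#' When the problem carries a `budget_usd` (cost moved from the
#' objective to a constraint, maximizing `sum(B_i x_i)` subject to
#' `sum(C_i x_i) <= budget` plus the cap and minima), the problem is a
#' genuine knapsack and is solved by exact depth-first branch-and-bound
#' with a fractional relaxation bound; this mode is intended for small
#' instances (hundreds of pixels, not tens of thousands).
#'
#' @param problem A [build_problem()] result.
#' @return An object of class `site_selection`: the chosen-pixel tibble,
#'   the achieved objective, and bookkeeping.
#' @export
solve_site_selection <- function(problem) {
  stopifnot(inherits(problem, "restoration_problem"))
  if (!is.null(problem$budget_usd)) return(solve_budget_bnb(problem))
  px <- problem$pixels
  n <- nrow(px)
  ord <- order(-px$ratio, px$cost_usd, px$idx)
  chosen <- logical(n)
  # habitat minima first: the top k_a of each class in tie-broken order
  for (a in names(problem$min_n)) {
    k <- problem$min_n[[a]]
    if (k == 0) next
    members <- ord[px$habitat[ord] == as.integer(a)]
    chosen[members[seq_len(k)]] <- TRUE
  }
  # then the globally best remaining positive-ratio pixels up to the cap
  slots <- problem$cap_n - sum(chosen)
  if (slots > 0) {
    rest <- ord[!chosen[ord] & px$ratio[ord] > 0]
    if (length(rest) > 0) chosen[rest[seq_len(min(slots, length(rest)))]] <- TRUE
  }
  new_selection(problem, chosen)
}

new_selection <- function(problem, chosen) {
  px <- problem$pixels[chosen, , drop = FALSE]
  structure(
    list(pixels = px,
         objective = sum(px$ratio),
         total_benefit = sum(px$benefit),
         total_cost_usd = sum(px$cost_usd),
         n_selected = nrow(px),
         cap_n = problem$cap_n, min_n = problem$min_n,
         pixel_area_ha = problem$pixel_area_ha, grid = problem$grid),
    class = "site_selection"
  )
}

#' @export
print.site_selection <- function(x, ...) {
  cat(sprintf("<site_selection> %d pixels (cap %d), objective %.6g, cost $%s\n",
              x$n_selected, x$cap_n, x$objective,
              format(round(x$total_cost_usd), big.mark = ",")))
  invisible(x)
}

# Exact 0/1 branch-and-bound for the budget-constrained variant.
solve_budget_bnb <- function(problem) {
  px <- problem$pixels
  n <- nrow(px)
  if (n > 400) {
    stop("budget mode is exact branch-and-bound and is limited to small problems (n <= 400)")
  }
  ord <- order(-(px$benefit / px$cost_usd), px$cost_usd, px$idx)
  b <- px$benefit[ord]; cst <- px$cost_usd[ord]; hab <- px$habitat[ord]
  budget <- problem$budget_usd; cap <- problem$cap_n
  min_n <- problem$min_n
  classes <- as.integer(names(min_n))
  need0 <- as.integer(min_n)
  # suffix counts per class for feasibility pruning
  suffix_count <- sapply(classes, function(a) rev(cumsum(rev(hab == a))))
  if (length(classes) == 1) suffix_count <- matrix(suffix_count, ncol = 1)

  best <- list(obj = -Inf, cost = Inf, take = logical(n))
  frac_bound <- function(i, cost_left, slots) {
    # fractional knapsack relaxation of the remaining items
    gain <- 0
    k <- i
    while (k <= n && slots > 0 && cost_left > 0) {
      if (cst[k] <= cost_left) {
        gain <- gain + b[k]; cost_left <- cost_left - cst[k]; slots <- slots - 1
      } else {
        gain <- gain + b[k] * cost_left / cst[k]
        cost_left <- 0
      }
      k <- k + 1
    }
    gain
  }
  take <- logical(n)
  recurse <- function(i, obj, cost, slots, need) {
    if (any(need > 0)) {
      if (i > n) return()
      # can the remaining items still cover the deficits?
      for (ci in seq_along(classes)) {
        if (need[ci] > (if (i <= n) suffix_count[i, ci] else 0)) return()
      }
    }
    if (sum(pmax(need, 0)) > slots) return()
    if (all(need <= 0) && (obj > best$obj + 1e-12 ||
                           (abs(obj - best$obj) <= 1e-12 && cost < best$cost))) {
      best <<- list(obj = obj, cost = cost, take = take)
    }
    if (i > n || slots == 0) return()
    if (obj + frac_bound(i, budget - cost, slots) <= best$obj + 1e-12 && all(need <= 0)) return()
    # branch: take item i (if affordable), then skip it
    if (cost + cst[i] <= budget + 1e-9) {
      take[i] <<- TRUE
      ci <- match(hab[i], classes)
      need2 <- need; if (!is.na(ci)) need2[ci] <- need2[ci] - 1L
      recurse(i + 1, obj + b[i], cost + cst[i], slots - 1L, need2)
      take[i] <<- FALSE
    }
    recurse(i + 1, obj, cost, slots, need)
  }
  recurse(1L, 0, 0, cap, need0)
  if (!is.finite(best$obj)) stop("infeasible: no selection satisfies the habitat minima within the budget")
  chosen_ord <- which(best$take)
  chosen <- logical(n); chosen[ord[chosen_ord]] <- TRUE
  out <- new_selection(problem, chosen)
  out$objective <- best$obj # budget mode maximizes total benefit, not ratio
  out
}

#' Greedy reference selection (test oracle)
#'
#' Selects pixels in descending benefit/cost order until the pixel cap,
#' with the same deterministic tie-break as [solve_site_selection()]
#' (cost, then index). Defined only for problems with uniform pixel
#' areas and no habitat minima, where greedy top-k is provably optimal;
#' calling it with habitat minima is a contract error.
#'
#' @param problem A [build_problem()] result without habitat minima.
#' @return A `site_selection`.
#' @export
greedy_reference <- function(problem) {
  stopifnot(inherits(problem, "restoration_problem"))
  if (length(problem$min_n) > 0 && any(problem$min_n > 0)) {
    stop("greedy_reference is only valid without habitat minima")
  }
  if (!is.null(problem$budget_usd)) stop("greedy_reference is only valid in ratio mode")
  px <- problem$pixels
  ord <- order(-px$ratio, px$cost_usd, px$idx)
  ord <- ord[px$ratio[ord] > 0]
  chosen <- logical(nrow(px))
  if (length(ord) > 0) chosen[ord[seq_len(min(problem$cap_n, length(ord)))]] <- TRUE
  new_selection(problem, chosen)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
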