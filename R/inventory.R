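#' Quadratic mean diameter
#'
#' The quadratic mean diameter (QMD) is the square root of the mean squared
#' DBH, i.e. the diameter of the tree of mean basal area. It is the standard
#' mean-size metric of stand-level self-thinning analysis and is always at
#' least as large as the arithmetic mean diameter.
#'
#' @param dbh numeric vector of diameters at breast height (cm), all > 0.
#' @return QMD in cm.
#' @examples
#' quadratic_mean_diameter(c(30, 40)) # 35.3553
#' @export
quadratic_mean_diameter <- function(dbh) {
  if (length(dbh) == 0L) stop("quadratic_mean_diameter: empty diameter vector")
  if (anyNA(dbh) || any(dbh <= 0)) {
    stop("quadratic_mean_diameter: diameters must be positive and non-missing")
  }
  sqrt(mean(dbh^2))
}

#' Summarize one plot census
#'
#' Computes the stand-level state from a tree list: QMD of live trees,
#' per-hectare density, raw live count, and the basal-area share of the
#' target species (used by the purity filter).
#'
#' @param trees data.frame with columns `tree_id`, `dbh`, `status`
#'   (one of `"alive"`, `"dead"`, `"removed"`) and `species`.
#' @param area plot area in m2, > 0.
#' @param target_species species label whose basal-area share is reported.
#' @return list with `D` (cm; `NA` when no live trees, see `qmd_defined`),
#'   `N` (trees/ha), `N_raw` (live count), `basal_area_share_target`,
#'   and `qmd_defined` (logical flag; never silently propagates NaN).
#' @export
summarize_census <- function(trees, area, target_species = NULL) {
  stopifnot(is.data.frame(trees), all(c("dbh", "status") %in% names(trees)))
  if (!is.numeric(area) || length(area) != 1L || area <= 0) {
    stop("summarize_census: area must be a positive scalar (m2)")
  }
  alive <- trees[trees$status == "alive", , drop = FALSE]
  n_raw <- nrow(alive)
  if (n_raw == 0L) {
    return(list(D = NA_real_, N = 0, N_raw = 0L,
                basal_area_share_target = NA_real_, qmd_defined = FALSE))
  }
  ba <- (pi / 4) * alive$dbh^2
  share <- if (is.null(target_species) || !("species" %in% names(trees))) {
    1
  } else {
    sum(ba[alive$species == target_species]) / sum(ba)
  }
  list(D = quadratic_mean_diameter(alive$dbh),
       N = n_raw * 1e4 / area,
       N_raw = n_raw,
       basal_area_share_target = share,
       qmd_defined = TRUE)
}

#' Build intercensus periods from a long-format tree inventory
#'
#' For each pair of successive censuses on the same plot, counts the trees
#' that died (`delta_N`) and were removed by thinning (`removed_N`,
#' never counted as mortality), and computes the net QMD increase
#' (`delta_D`). The QMD of the trees that died is recorded per period
#' (`D_dead`) for the k-factor analysis.
#'
#' @param inventory data.frame with columns `plot_id`, `census_date`
#'   (decimal year), `tree_id`, `dbh` (cm), `status`, `species`.
#' @param plot_meta data.frame with `plot_id`, `area_m2` and optionally
#'   `disturbed` (logical).
#' @param target_species species whose basal-area share is tracked.
#' @return data.frame of periods with state at start, changes, and the
#'   start census' basal-area share. Trees present at the end of a period
#'   but absent at its start (ingrowth / id mismatch) are excluded with a
#'   warning and listed in `attr(, "unmatched")`.
#' @export
build_periods <- function(inventory, plot_meta, target_species = NULL) {
  stopifnot(all(c("plot_id", "census_date", "tree_id", "dbh", "status") %in%
                  names(inventory)))
  stopifnot(all(c("plot_id", "area_m2") %in% names(plot_meta)))
  out <- list()
  unmatched <- character(0)
  for (pid in unique(inventory$plot_id)) {
    inv <- inventory[inventory$plot_id == pid, , drop = FALSE]
    area <- plot_meta$area_m2[match(pid, plot_meta$plot_id)]
    if (is.na(area)) stop("build_periods: no metadata for plot ", pid)
    if (anyDuplicated(inv[, c("census_date", "tree_id")])) {
      stop("build_periods: duplicate census dates in plot ", pid,
           " (a tree appears twice on the same date)")
    }
    dates <- sort(unique(inv$census_date))
    if (length(dates) < 2L) next
    for (k in seq_len(length(dates) - 1L)) {
      s0 <- inv[inv$census_date == dates[k], , drop = FALSE]
      s1 <- inv[inv$census_date == dates[k + 1L], , drop = FALSE]
      new_ids <- setdiff(s1$tree_id, s0$tree_id)
      if (length(new_ids) > 0L) {
        unmatched <- c(unmatched, paste0(pid, ":", new_ids))
        s1 <- s1[!(s1$tree_id %in% new_ids), , drop = FALSE]
      }
      alive0 <- s0[s0$status == "alive", , drop = FALSE]
      end_status <- s1$status[match(alive0$tree_id, s1$tree_id)]
      died <- !is.na(end_status) & end_status == "dead"
      removed <- !is.na(end_status) & end_status == "removed"
      sum0 <- summarize_census(s0, area, target_species)
      sum1 <- summarize_census(s1, area, target_species)
      dead_dbh <- s1$dbh[match(alive0$tree_id[died], s1$tree_id)]
      out[[length(out) + 1L]] <- data.frame(
        plot_id = pid,
        start = dates[k], end = dates[k + 1L],
        interval = dates[k + 1L] - dates[k],
        area_m2 = area,
        D_start = sum0$D, N_start = sum0$N, N_raw_start = sum0$N_raw,
        delta_N = sum(died), removed_N = sum(removed),
        delta_D = if (sum1$qmd_defined && sum0$qmd_defined)
          sum1$D - sum0$D else NA_real_,
        D_dead = if (sum(died) > 0L)
          quadratic_mean_diameter(dead_dbh) else NA_real_,
        ba_share_start = sum0$basal_area_share_target,
        stringsAsFactors = FALSE)
    }
  }
  periods <- if (length(out)) do.call(rbind, out) else empty_periods()
  if (length(unmatched) > 0L) {
    warning("build_periods: ", length(unmatched),
            " tree id(s) at a period end had no match at its start; excluded")
  }
  attr(periods, "unmatched") <- unmatched
  periods
}

empty_periods <- function() {
  data.frame(plot_id = character(0), start = numeric(0), end = numeric(0),
             interval = numeric(0), area_m2 = numeric(0),
             D_start = numeric(0), N_start = numeric(0),
             N_raw_start = integer(0), delta_N = integer(0),
             removed_N = integer(0), delta_D = numeric(0),
             D_dead = numeric(0), ba_share_start = numeric(0),
             stringsAsFactors = FALSE)
}

#' Filter criteria for plot/period selection
#'
#' Defaults reproduce the selection rules used for pure, undisturbed,
#' adequately measured even-aged plots: >=80% target-species basal area,
#' plot area >= 400 m2, intercensus interval >= 0.5 yr, annualized QMD
#' growth >= 0.1 cm/yr, and exclusion of disturbed plots.
#'
#' @param min_ba_share minimum basal-area share of the target species.
#' @param min_area minimum plot area (m2).
#' @param min_interval minimum intercensus interval (years).
#' @param min_annual_delta_D minimum annualized net QMD increase (cm/yr).
#' @param exclude_disturbed drop plots flagged as disturbed
#'   (fire, psyllid, storm); disturbance is an input flag, never inferred.
#' @export
filter_criteria <- function(min_ba_share = 0.80, min_area = 400,
                            min_interval = 0.5, min_annual_delta_D = 0.1,
                            exclude_disturbed = TRUE) {
  stopifnot(min_ba_share >= 0, min_area >= 0, min_interval >= 0,
            min_annual_delta_D >= 0)
  structure(list(min_ba_share = min_ba_share, min_area = min_area,
                 min_interval = min_interval,
                 min_annual_delta_D = min_annual_delta_D,
                 exclude_disturbed = exclude_disturbed),
            class = "filter_criteria")
}

#' Apply selection filters to intercensus periods
#'
#' A period is retained iff it satisfies every rule; the result is
#' therefore independent of the order in which rules are checked. Every
#' exclusion is logged with its reason(s), sorted and comma-joined.
#'
#' @param periods data.frame from [build_periods()] or the synthetic
#'   generator (columns `area_m2`, `interval`, `delta_D`, `ba_share_start`).
#' @param plot_meta data.frame with `plot_id` and optional `disturbed` flag.
#' @param criteria a [filter_criteria()] object.
#' @return `periods` with logical `retained` and character
#'   `exclusion_reason` (`NA` when retained) columns added.
#' @export
apply_filters <- function(periods, plot_meta = NULL,
                          criteria = filter_criteria()) {
  stopifnot(inherits(criteria, "filter_criteria"))
  n <- nrow(periods)
  disturbed <- rep(FALSE, n)
  if (!is.null(plot_meta) && "disturbed" %in% names(plot_meta)) {
    disturbed <- plot_meta$disturbed[match(periods$plot_id,
                                           plot_meta$plot_id)]
    disturbed[is.na(disturbed)] <- FALSE
  }
  annual_dD <- periods$delta_D / periods$interval
  fails <- list(
    area = periods$area_m2 < criteria$min_area,
    interval = periods$interval < criteria$min_interval,
    growth = is.na(annual_dD) | annual_dD < criteria$min_annual_delta_D,
    purity = !is.na(periods$ba_share_start) &
      periods$ba_share_start < criteria$min_ba_share,
    disturbance = criteria$exclude_disturbed & disturbed)
  reason <- vapply(seq_len(max(n, 0L)), function(i) {
    r <- sort(names(fails)[vapply(fails, `[`, logical(1), i)])
    if (length(r) == 0L) NA_character_ else paste(r, collapse = ",")
  }, character(1))
  periods$retained <- is.na(reason)
  periods$exclusion_reason <- reason
  periods
}

#' Identify control plots
#'
#' A plot is a control iff no period ever records a removal (and it is not
#' flagged thinned in the metadata). The static allometry is fitted on
#' control plots only.
#'
#' @param periods periods table.
#' @param plot_meta optional metadata with a `thinned` flag.
#' @return character vector of control plot ids.
#' @export
control_plots <- function(periods, plot_meta = NULL) {
  rem <- tapply(periods$removed_N, periods$plot_id, function(x) any(x > 0))
  ids <- names(rem)[!rem]
  if (!is.null(plot_meta) && "thinned" %in% names(plot_meta)) {
    thinned <- plot_meta$plot_id[isTRUE_vec(plot_meta$thinned)]
    ids <- setdiff(ids, thinned)
  }
  ids
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Read a long-format inventory CSV
#'
#' Expected columns: `plot_id, census_date, tree_id, dbh_cm, status, species`.
#' @param path file path.
#' @return data.frame with the column names used by [build_periods()].
#' @export
read_inventory_csv <- function(path) {
  inv <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "census_date", "tree_id", "dbh_cm", "status", "species")
  if (!all(need %in% names(inv))) {
    stop("read_inventory_csv: missing columns: ",
         paste(setdiff(need, names(inv)), collapse = ", "))
  }
  names(inv)[names(inv) == "dbh_cm"] <- "dbh"
  inv
}

#' Write the periods table to CSV
#' @param periods periods table (after [apply_filters()]).
#' @param path output file path.
#' @export
write_periods_csv <- function(periods, path) {
  utils::write.csv(periods, path, row.names = FALSE)
  invisible(path)
}
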