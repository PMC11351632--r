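# Aggregation of transport results into the outcome statistics: percentage
# of agents reaching their goal, SEM across replicates, per-lesion stuck
# counts, and the endometriosis reduction rate.

.condition_of <- function(result) {
  d <- result$design
  list(age_group = d$age_group, with_endometriosis = d$with_endometriosis,
       kind = d$kind)
}

#' Summarise transport results for one condition
#'
#' Pools the agents of one or more [run_transport()] results obtained under
#' the same condition (age group, endometriosis flag, agent kind), and
#' reports the percentage that reached the goal, the standard error of the
#' mean across replicates, and the number of agents stuck at each lesion.
#'
#' @param results A `transport_result` or list of them (same condition).
#' @return Object of class `transport_summary` with fields `condition`,
#'   `pct_reached`, `sem`, `n_agents`, `n_replicates`,
#'   `replicate_pct`, `per_lesion_stuck`.
#' @export
summarize_runs <- function(results) {
  if (inherits(results, "transport_result")) results <- list(results)
  stopifnot(length(results) >= 1)
  cond <- .condition_of(results[[1]])
  for (r in results)
    if (!identical(.condition_of(r), cond))
      stop("all results must share one condition (age, endometriosis, kind)")

  rep_pct <- unlist(lapply(seq_along(results), function(i) {
    a <- results[[i]]$agents
    tapply(a$status == "reached_goal", a$replicate, function(z) 100 * mean(z))
  }), use.names = FALSE)
  all_agents <- do.call(rbind, lapply(results, function(r)
    r$agents[c("status", "stuck_at")]))
  n <- nrow(all_agents)
  pct <- 100 * mean(all_agents$status == "reached_goal")
  sem <- if (length(rep_pct) > 1)
    stats::sd(rep_pct) / sqrt(length(rep_pct)) else 0

  stuck <- all_agents$stuck_at[all_agents$status == "stuck"]
  lesion_ids <- grep("^lesion_", unique(stuck), value = TRUE)
  per_lesion <- vapply(sort(lesion_ids), function(l) sum(stuck == l),
                       integer(1))

  structure(list(condition = cond, pct_reached = pct, sem = sem,
                 n_agents = n, n_replicates = length(rep_pct),
                 replicate_pct = rep_pct, per_lesion_stuck = per_lesion),
            class = "transport_summary")
}

#' Endometriosis reduction rate
#'
#' Relative reduction of the reached-percentage caused by endometriosis:
#' `(pct_normal - pct_endo) / pct_normal * 100`.
#'
#' @param normal,endo `transport_summary` objects for the same age group
#'   and agent kind, without and with endometriosis.
#' @return Object of class `reduction_rate` with fields `age_group`,
#'   `kind`, `rate` (%).
#' @export
reduction_rate <- function(normal, endo) {
  stopifnot(inherits(normal, "transport_summary"),
            inherits(endo, "transport_summary"))
  if (!identical(normal$condition$age_group, endo$condition$age_group) ||
      !identical(normal$condition$kind, endo$condition$kind))
    stop("summaries must share age group and agent kind")
  if (normal$pct_reached <= 0)
    stop("reduction rate undefined when the normal-tube percentage is 0")
  structure(list(age_group = normal$condition$age_group,
                 kind = normal$condition$kind,
                 pct_normal = normal$pct_reached,
                 pct_endo = endo$pct_reached,
                 rate = (normal$pct_reached - endo$pct_reached) /
                        normal$pct_reached * 100),
            class = "reduction_rate")
}

#' @export
print.transport_summary <- function(x, ...) {
  cat(sprintf("%s | %s | %s: %.1f%% reached (SEM %.2f, n = %d, %d replicates)\n",
              x$condition$kind, x$condition$age_group,
              if (x$condition$with_endometriosis) "endometriosis" else "normal",
              x$pct_reached, x$sem, x$n_agents, x$n_replicates))
  if (length(x$per_lesion_stuck)) {
    cat("  stuck per lesion:",
        paste(names(x$per_lesion_stuck), x$per_lesion_stuck,
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.reduction_rate <- function(x, ...) {
  cat(sprintf("%s %s: reduction rate %.1f%% (normal %.1f%% -> endometriosis %.1f%%)\n",
              x$kind, x$age_group, x$rate, x$pct_normal, x$pct_endo))
  invisible(x)
}

.grid_conditions <- function() {
  g <- expand.grid(kind = c("sperm", "oocyte"),
                   age_group = c("20s", "30s", "40s"),
                   with_endometriosis = c(FALSE, TRUE),
                   stringsAsFactors = FALSE)
  g[order(g$kind, g$age_group, g$with_endometriosis), ]
}

.cond_key <- function(kind, age, endo)
  paste(kind, age, if (endo) "endo" else "normal", sep = "_")

#' Write outcome tables and figures for a full condition grid
#'
#' Expects one `transport_summary` per condition of the 2 (kind) x 3 (age)
#' x 2 (endometriosis) grid, keyed as `"sperm_20s_normal"`,
#' `"oocyte_40s_endo"`, etc. Writes, per agent kind, a CSV outcome table
#' and a reduction-rate CSV, plus a mean +/- SEM bar chart and a tube map
#' figure with lesion markers and final agent positions (anterior view,
#' axes in mm). Available conditions are written even when the grid is
#' incomplete; missing ones are then reported as an error.
#'
#' @param summaries Named list of `transport_summary` objects.
#' @param out_dir Output directory (created if needed).
#' @param results Optional named list of `transport_result` objects (same
#'   keys) used for the tube map figures.
#' @param format Character vector, subset of `c("csv", "png")`.
#' @return Invisibly, the paths written.
#' @export
report <- function(summaries, out_dir, results = NULL,
                   format = c("csv", "png")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- .grid_conditions()
  keys <- mapply(.cond_key, grid$kind, grid$age_group,
                 grid$with_endometriosis)
  missing <- setdiff(keys, names(summaries))
  paths <- character(0)

  for (kd in c("sperm", "oocyte")) {
    have <- grid[grid$kind == kd, ]
    kk <- mapply(.cond_key, have$kind, have$age_group,
                 have$with_endometriosis)
    kk <- kk[kk %in% names(summaries)]
    if (!length(kk)) next
    if ("csv" %in% format) {
      tab <- do.call(rbind, lapply(kk, function(k) {
        s <- summaries[[k]]
        data.frame(kind = s$condition$kind, age_group = s$condition$age_group,
                   endometriosis = s$condition$with_endometriosis,
                   pct_reached = s$pct_reached, sem = s$sem,
                   n_agents = s$n_agents, n_replicates = s$n_replicates)
      }))
      f <- file.path(out_dir, paste0(kd, "_outcomes.csv"))
      utils::write.csv(tab, f, row.names = FALSE)
      paths <- c(paths, f)

      red <- do.call(rbind, lapply(c("20s", "30s", "40s"), function(a) {
        kn <- .cond_key(kd, a, FALSE); ke <- .cond_key(kd, a, TRUE)
        if (!(kn %in% names(summaries)) || !(ke %in% names(summaries)))
          return(NULL)
        rr <- reduction_rate(summaries[[kn]], summaries[[ke]])
        data.frame(kind = kd, age_group = a, pct_normal = rr$pct_normal,
                   pct_endo = rr$pct_endo, reduction_rate = rr$rate)
      }))
      if (!is.null(red)) {
        f <- file.path(out_dir, paste0(kd, "_reduction_rates.csv"))
        utils::write.csv(red, f, row.names = FALSE)
        paths <- c(paths, f)
      }
    }
    if ("png" %in% format) {
      f <- file.path(out_dir, paste0(kd, "_outcomes.png"))
      grDevices::png(f, width = 800, height = 500)
      .plot_outcome_bars(summaries[kk], kd)
      grDevices::dev.off()
      paths <- c(paths, f)
      f <- file.path(out_dir, paste0(kd, "_tube_map.png"))
      grDevices::png(f, width = 900, height = 420)
      .plot_tube_map(summaries[kk], results, kd)
      grDevices::dev.off()
      paths <- c(paths, f)
    }
  }
  if (length(missing))
    stop("missing conditions (partial output written): ",
         paste(missing, collapse = ", "))
  invisible(paths)
}

# Mean +/- SEM bar chart across the age x endometriosis grid for one kind.
.plot_outcome_bars <- function(summ, kind) {
  pct <- vapply(summ, function(s) s$pct_reached, numeric(1))
  sem <- vapply(summ, function(s) s$sem, numeric(1))
  lab <- vapply(summ, function(s)
    paste0(s$condition$age_group,
           if (s$condition$with_endometriosis) "\nendo" else "\nnormal"),
    character(1))
  bp <- graphics::barplot(pct, names.arg = lab, ylim = c(0, 105),
                          ylab = "% reached goal",
                          main = paste(kind, "reaching the goal"),
                          col = ifelse(vapply(summ, function(s)
                            s$condition$with_endometriosis, logical(1)),
                            "indianred", "steelblue"))
  nz <- sem > 0
  if (any(nz))
    graphics::arrows(bp[nz], pct[nz] - sem[nz], bp[nz], pct[nz] + sem[nz],
                     angle = 90, code = 3, length = 0.05)
}

# Anterior-view (x-y) tube map with lesion markers; overlays final agent
# positions (or trajectory samples when available) projected through the
# centerline frame. Axes in mm.
.plot_tube_map <- function(summ, results, kind) {
  res <- NULL
  if (!is.null(results)) {
    for (k in names(results))
      if (startsWith(k, kind) && !is.null(results[[k]])) { res <- results[[k]]; break }
  }
  tube <- if (!is.null(res)) res$tube else
    build_tube("20s", TRUE)
  sg <- seq(0, tube$total_length, length.out = 200)
  cl <- centerline_points(tube, sg)
  r <- .base_radius(tube, sg)
  nx <- -sin(cl[, "psi"]); ny <- cos(cl[, "psi"])
  graphics::plot(cl[, "x"], cl[, "y"], type = "l", lty = 2, asp = 1,
                 xlab = "x (mm)", ylab = "y (mm)",
                 main = paste(kind, "tube map (anterior view)"))
  graphics::lines(cl[, "x"] + r * nx, cl[, "y"] + r * ny)
  graphics::lines(cl[, "x"] - r * nx, cl[, "y"] - r * ny)
  for (l in tube$lesions) {
    p <- centerline_points(tube, l$center_s)
    graphics::points(p[1], p[2], pch = 4, cex = 2, col = "red", lwd = 2)
  }
  if (!is.null(res)) {
    a <- res$agents
    p <- centerline_points(tube, pmin(pmax(a$final_s, 0), tube$total_length))
    graphics::points(p[, "x"], p[, "y"],
                     pch = 16, cex = 0.3,
                     col = ifelse(a$status == "stuck", "red", "grey40"))
  }
}
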