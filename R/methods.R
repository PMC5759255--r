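#' @export
print.burden_sim <- function(x, ...) {
  gt <- x$tables$grand_total
  cat("<burden_sim> scenario '", x$scenario$name, "': ",
      format(x$n_iterations, big.mark = ","), " iterations, seed ", x$seed,
      "\n", sep = "")
  cat("  total recreation events (mean): ",
      format(signif(x$tables$exposure$mean[
        x$tables$exposure$activity == "total"], 4), big.mark = ","),
      " person-days/yr\n", sep = "")
  cat("  grand total cost: ", format(signif(gt$mean / 1e9, 3)),
      " billion (C90 ", format(signif(gt$p5 / 1e9, 3)), "-",
      format(signif(gt$p95 / 1e9, 3)), ")\n", sep = "")
  invisible(x)
}

#' Tidy a burden simulation into one long summary table
#'
#' @param x A `burden_sim`.
#' @param ... Unused.
#' @return A tibble with columns `table`, `term`, `mean`, `p5`, `p95`,
#'   `n_draws`; one row per reported cell (exposure, caseload, severe
#'   outcome, cost component, per-case cost, grand total).
#' @export
tidy.burden_sim <- function(x, ...) {
  tb <- x$tables
  bind_rows(
    tb$exposure |>
      mutate(table = "exposure",
             term = paste(.data$activity, .data$quantity, sep = ".")),
    tb$cases |>
      mutate(table = "cases",
             term = paste(.data$activity, .data$illness, sep = ".")),
    tb$severe |>
      mutate(table = "severe",
             term = paste(.data$pathogen, .data$outcome, sep = ".")),
    tb$costs |>
      mutate(table = "costs",
             term = paste(.data$tier, .data$component, sep = ".")),
    tb$per_case |>
      mutate(table = "per_case", term = paste0(.data$tier, ".per_case")),
    tb$grand_total |>
      mutate(table = "costs", term = "grand_total")
  ) |>
    select("table", "term", "mean", "p5", "p95", "n_draws")
}

#' One-row summary of a burden simulation
#'
#' @param x A `burden_sim`.
#' @param ... Unused.
#' @return A one-row tibble: iteration count, seed, mean annual recreation
#'   events, mean sporadic cases and the moderate-severity share,
#'   hospitalization and death means, and the grand-total cost with its C90.
#' @export
glance.burden_sim <- function(x, ...) {
  per_draw_cases <- x$draws$cases_by_illness |>
    group_by(.data$draw) |>
    summarise(total = sum(.data$total_cases),
              moderate = sum(.data$moderate_cases), .groups = "drop")
  gt <- x$tables$grand_total
  sev <- x$draws$severe_totals
  tibble(
    n_iterations = x$n_iterations,
    seed = x$seed,
    total_events = mean(x$draws$total_events),
    total_cases = mean(per_draw_cases$total),
    moderate_share = mean(per_draw_cases$moderate / per_draw_cases$total),
    hospitalizations = mean(sev$hospitalizations),
    deaths = mean(sev$deaths),
    grand_total = gt$mean,
    grand_total_p5 = gt$p5,
    grand_total_p95 = gt$p95
  )
}

#' Plot a burden simulation summary table
#'
#' Column chart of means with central-90% error bars for one of the summary
#' tables.
#'
#' @param object A `burden_sim`.
#' @param table Which summary to plot: `"costs"` (default), `"cases"`,
#'   `"exposure"` (person-days), or `"severe"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.burden_sim <- function(object, table = c("costs", "cases",
                                                  "exposure", "severe"), ...) {
  table <- match.arg(table)
  df <- switch(table,
    costs = object$tables$costs |>
      filter(.data$component != "total") |>
      mutate(x = .data$component, fill = .data$tier,
             lab = "cost (USD/yr)"),
    cases = object$tables$cases |>
      filter(.data$activity != "total") |>
      mutate(x = .data$illness, fill = .data$activity,
             lab = "cases/yr"),
    exposure = object$tables$exposure |>
      filter(.data$quantity == "person_days", .data$activity != "total") |>
      mutate(x = .data$activity, fill = .data$activity,
             lab = "person-days/yr"),
    severe = object$tables$severe |>
      filter(.data$outcome != "community_cases", .data$pathogen != "total") |>
      mutate(x = .data$pathogen, fill = .data$outcome, lab = "count/yr")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$mean,
                                   fill = .data$fill)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$p5, ymax = .data$p95),
                           position = ggplot2::position_dodge(width = 0.9),
                           width = 0.25) +
    ggplot2::labs(x = NULL, y = df$lab[1], fill = NULL,
                  title = paste0("Simulated ", table,
                                 " (mean and central 90%)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}
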