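#' Round half away from zero
#'
#' Monetary display rounding: exact halves round away from zero
#' (2.5 -> 3, -2.5 -> -3), unlike [round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @examples
#' round_half_up(c(0.125, -0.125), 2)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # tiny eps guards against decimal values held just under .5 in binary
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# "x.xx (lo-hi)" with a display floor: magnitudes below half the last
# printed digit show as "<0.01" (or "<0.1" at 1 decimal).
format_amount <- function(x, digits = 2, floor_display = TRUE) {
  vapply(x, function(v) {
    if (floor_display && v != 0 && round_half_up(abs(v), digits) == 0) {
      sprintf("<%s", formatC(10^(-digits), format = "f", digits = digits))
    } else {
      formatC(round_half_up(v, digits), format = "f", digits = digits)
    }
  }, character(1))
}

format_cell <- function(cell, digits = 2, floor_display = TRUE) {
  sprintf("%s (%s-%s)",
          format_amount(cell$central, digits, floor_display),
          format_amount(cell$lower, digits, floor_display),
          format_amount(cell$upper, digits, floor_display))
}

#' Render annual savings reports as a scenario-column table
#'
#' Lays out one condition's savings reports (one per scenario) in the
#' conventional form: categories as rows, scenarios as columns, each cell
#' `central (lower-upper)` rounded half-away-from-zero, with sub-threshold
#' values displayed as e.g. `<0.01`. CSV output is lossless: it carries
#' the unrounded values alongside the display strings.
#'
#' @param reports List of [compute_savings()] reports for one condition,
#'   one per scenario.
#' @param format `"text"`, `"markdown"` or `"csv"`.
#' @param digits Display decimal places (2 for condition-level tables in
#'   the tens of millions, 1 for larger aggregates).
#' @return A character vector of lines (`text`/`markdown`) or a
#'   data.frame (`csv`).
#' @export
render_savings <- function(reports, format = c("text", "markdown", "csv"),
                           digits = 2) {
  format <- match.arg(format)
  stopifnot(length(reports) > 0L,
            all(vapply(reports, inherits, logical(1), "savings_report")))
  cats <- reports[[1]]$per_category$category
  scen_names <- vapply(reports, `[[`, character(1), "scenario_name")

  if (format == "csv") {
    rows <- do.call(rbind, lapply(reports, function(r) {
      per <- rbind(r$per_category,
                   data.frame(category = "Total", central = r$total$central,
                              lower = r$total$lower, upper = r$total$upper))
      data.frame(condition = r$condition, scenario = r$scenario_name,
                 uptake = r$uptake, per,
                 display = vapply(seq_len(nrow(per)), function(i) {
                   format_cell(list(central = per$central[i],
                                    lower = per$lower[i],
                                    upper = per$upper[i]), digits)
                 }, character(1)),
                 stringsAsFactors = FALSE)
    }))
    rownames(rows) <- NULL
    return(rows)
  }

  cells <- vapply(reports, function(r) {
    per <- r$per_category
    c(vapply(seq_len(nrow(per)), function(i) {
      format_cell(list(central = per$central[i], lower = per$lower[i],
                       upper = per$upper[i]), digits)
    }, character(1)),
    format_cell(r$total, digits))
  }, character(length(cats) + 1L))
  cells <- matrix(cells, ncol = length(reports))
  rownames(cells) <- c(cats, "All direct health savings")

  if (format == "markdown") {
    header <- paste0("| Direct health expenditure savings | ",
                     paste(scen_names, collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", length(scen_names) + 1L),
                             collapse = "|"), "|")
    body <- vapply(seq_len(nrow(cells)), function(i) {
      paste0("| ", rownames(cells)[i], " | ",
             paste(cells[i, ], collapse = " | "), " |")
    }, character(1))
    return(c(header, sep, body))
  }

  widths <- pmax(nchar(scen_names),
                 apply(nchar(cells), 2, max))
  rw <- max(nchar(rownames(cells)))
  pad <- function(s, w) formatC(s, width = w, flag = "-")
  header <- paste(c(pad("", rw),
                    mapply(pad, scen_names, widths)), collapse = "  ")
  body <- vapply(seq_len(nrow(cells)), function(i) {
    paste(c(pad(rownames(cells)[i], rw),
            mapply(pad, cells[i, ], widths)), collapse = "  ")
  }, character(1))
  c(header, body)
}

#' Render a discounted-savings table (blocks by condition, scenarios as columns)
#'
#' Produces the staged-horizon layout: for each 5-year block and each
#' condition, the present value of each scenario's annual savings over
#' that block; then per-scenario horizon totals and the staged
#' incremental-adoption total.
#'
#' @param model A [coi_model()] object.
#' @param format `"text"`, `"markdown"` or `"csv"`.
#' @param digits Display decimal places (default 1).
#' @return Character lines, or a data.frame for `"csv"`.
#' @export
render_discounted <- function(model, format = c("text", "markdown", "csv"),
                              digits = 1) {
  format <- match.arg(format)
  stopifnot(inherits(model, "coi_model"))
  sched <- model$schedule
  scen_names <- vapply(sched$scenarios, `[[`, character(1), "name")
  conditions <- names(model$outcomes)

  long <- model$discounted_blocks
  if (format == "csv") return(long)

  lines <- character(0)
  add <- function(...) lines <<- c(lines, ...)
  sepmd <- paste0("|", paste(rep("---", length(scen_names) + 1L),
                             collapse = "|"), "|")
  md <- format == "markdown"
  row_of <- function(label, cells) {
    if (md) {
      paste0("| ", label, " | ", paste(cells, collapse = " | "), " |")
    } else {
      paste(c(formatC(label, width = 24, flag = "-"),
              formatC(cells, width = 22, flag = "-")), collapse = "  ")
    }
  }
  if (md) add(row_of("", scen_names), sepmd) else add(row_of("", scen_names))

  fetch <- function(cond, scen, block) {
    r <- long[long$condition == cond & long$scenario == scen &
                long$block == block, ]
    format_cell(list(central = r$central, lower = r$lower, upper = r$upper),
                digits)
  }
  for (s in sched$scenarios) {
    yr <- block_years(sched, s$block_index)
    add(row_of(sprintf("Total savings of years %d to %d", yr[1], yr[2]),
               rep("", length(scen_names))))
    for (cond in conditions) {
      add(row_of(cond, vapply(scen_names, fetch, character(1), cond = cond,
                              block = s$block_index)))
    }
  }
  add(row_of("Total discounted savings for each scenario",
             rep("", length(scen_names))))
  for (cond in conditions) {
    add(row_of(cond, vapply(scen_names, function(sn) {
      format_cell(model$horizon_totals[[cond]][[sn]], digits)
    }, character(1))))
  }
  add(row_of("Total incremental discounted savings (staged adoption)",
             rep("", length(scen_names))))
  for (cond in conditions) {
    cells <- c(rep("-", length(scen_names) - 1L),
               format_cell(model$incremental[[cond]], digits))
    add(row_of(cond, cells))
  }
  lines
}

#' Write a model's report bundle to a directory
#'
#' Writes, per condition, the annual savings table and, overall, the
#' discounted table in the requested format. CSV output additionally
#' carries unrounded values.
#'
#' @param model A [coi_model()] object.
#' @param dir Output directory (created if needed).
#' @param format `"csv"`, `"markdown"` or `"text"`.
#' @return Invisibly, the paths written.
#' @export
write_reports <- function(model, dir, format = c("csv", "markdown", "text")) {
  format <- match.arg(format)
  stopifnot(inherits(model, "coi_model"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- c(csv = "csv", markdown = "md", text = "txt")[[format]]
  paths <- character(0)
  for (cond in names(model$outcomes)) {
    p <- file.path(dir, sprintf("annual_%s.%s", gsub("\\W+", "_", cond), ext))
    out <- render_savings(model$annual[[cond]], format,
                          digits = model$outcomes[[cond]]$report_digits)
    if (format == "csv") utils::write.csv(out, p, row.names = FALSE)
    else writeLines(out, p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, paste0("discounted.", ext))
  out <- render_discounted(model, format)
  if (format == "csv") utils::write.csv(out, p, row.names = FALSE)
  else writeLines(out, p)
  invisible(c(paths, p))
}
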