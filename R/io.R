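## Validated delimited-table IO and the end-to-end pipeline driver:
## desirability -> quadratic fit -> ANOVA -> bounded optimization, with
## JSON/CSV report output.

#' Read a delimited table against a declared schema
#'
#' Reads a UTF-8, comma-delimited file with a header row and validates it
#' against a named schema: required columns must be present, and cells in
#' `"numeric"` columns must parse as numbers. Rows with unparseable numeric
#' cells are rejected (not silently coerced); the rejected row numbers and
#' reasons are attached as attribute `"rejected"` and reported in a
#' warning.
#'
#' @param path File path.
#' @param schema Named character vector mapping required column names to
#'   `"numeric"` or `"character"`.
#' @param sep Field separator (default comma).
#' @return A validated `data.frame` (rejected rows removed), with
#'   attributes `"rejected"` (data frame of `row`, `reason`) and
#'   `"n_read"`.
#' @export
read_table <- function(path, schema, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           encoding = "UTF-8", stringsAsFactors = FALSE)
  missing <- setdiff(names(schema), names(raw))
  if (length(missing))
    stop("'", basename(path), "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  rejected <- data.frame(row = integer(), reason = character())
  keep <- rep(TRUE, nrow(raw))
  for (col in names(schema)) {
    if (schema[[col]] != "numeric") next
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(num) & keep)
    if (length(bad)) {
      rejected <- rbind(rejected, data.frame(
        row = bad,
        reason = sprintf("non-numeric '%s' in column '%s'",
                         raw[[col]][bad], col)))
      keep[bad] <- FALSE
    }
    raw[[col]] <- num
  }
  if (nrow(rejected)) {
    rejected <- rejected[order(rejected$row), , drop = FALSE]
    warning("rejected ", nrow(rejected), " row(s) of '", basename(path),
            "': ", paste(sprintf("row %d (%s)", rejected$row,
                                 rejected$reason), collapse = "; "))
  }
  out <- raw[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  attr(out, "n_read") <- nrow(raw)
  out
}

#' Write a table as CSV with repr-stable numeric formatting
#'
#' Numbers are serialized with 15 significant digits so a
#' write/read round trip preserves values to within representation
#' accuracy and reports diff cleanly.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  y <- as.data.frame(x)
  for (col in names(y))
    if (is.numeric(y[[col]]))
      y[[col]] <- formatC(y[[col]], digits = 15, format = "g")
  utils::write.csv(y, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML configs require the 'yaml' package")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a JSON/YAML path")
  config
}

#' Run the extraction-optimization pipeline end to end
#'
#' Orchestrates the full analysis: read the factor levels and response
#' table, aggregate the per-index responses into overall desirability
#' (skipped if the table already carries an `od` column), fit the
#' second-order surface, compute the lack-of-fit ANOVA, maximize the
#' surface over the coded design cube, optionally snap the optimum to
#' operable settings, and write JSON and CSV reports.
#'
#' @param config A list, or path to a JSON/YAML file, with elements:
#'   `factors` (path to a factor-level CSV with columns
#'   name/unit/low/center/high), `responses` (path to a CSV with `run_id`,
#'   one column per factor in actual units, and either an `od` column or
#'   one column per quality index), optional `directions` (named
#'   larger_better/smaller_better vector for the index columns), optional
#'   `rounding` (named quanta for [round_to_practice()]), optional
#'   `bounds` (coded `c(lower, upper)`, default `c(-1, 1)`), and `out_dir`
#'   (directory for reports; created if absent).
#' @return Invisibly, a list with `design`, `od`, `model`, `anova`,
#'   `optimum`, `rounded` (or `NULL`) and the written file paths.
#' @export
run_pipeline <- function(config) {
  cfg <- read_config(config)
  for (field in c("factors", "responses", "out_dir"))
    if (is.null(cfg[[field]])) stop("config is missing '", field, "'")
  for (field in c("factors", "responses"))
    if (!file.exists(cfg[[field]]))
      stop("config: ", field, " file not found: ", cfg[[field]])

  ftab <- read_table(cfg$factors,
                     c(name = "character", unit = "character",
                       low = "numeric", center = "numeric",
                       high = "numeric"))
  factors <- lapply(seq_len(nrow(ftab)), function(i)
    factor_spec(ftab$name[i], ftab$low[i], ftab$high[i],
                center = ftab$center[i], unit = ftab$unit[i]))
  names(factors) <- ftab$name

  rtab <- utils::read.csv(cfg$responses, check.names = FALSE)
  need <- c("run_id", ftab$name)
  missing <- setdiff(need, names(rtab))
  if (length(missing))
    stop("response table is missing column(s): ",
         paste(missing, collapse = ", "))
  design <- code_design(rtab[need], factors)

  if ("od" %in% names(rtab)) {
    od <- as.numeric(rtab$od)
    des <- NULL
  } else {
    if (is.null(cfg$directions))
      stop("config needs 'directions' when the response table has no ",
           "'od' column")
    spec <- desirability_spec(unlist(cfg$directions))
    des <- compute_desirability(rtab[names(cfg$directions)], spec)
    od <- des$od
  }

  model <- fit_quadratic(design, od)
  anova_tab <- rsm_anova(model)
  bounds <- cfg$bounds %||% c(-1, 1)
  opt <- maximize_surface(model, bounds[1], bounds[2])
  rounded <- NULL
  if (!is.null(cfg$rounding))
    rounded <- round_to_practice(opt, unlist(cfg$rounding))

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    anova_csv = file.path(cfg$out_dir, "anova.csv"),
    report_json = file.path(cfg$out_dir, "report.json")
  )
  write_table(as.data.frame(anova_tab), paths$anova_csv)
  report <- list(
    coefficients = as.list(round(model$coef, 10)),
    r_squared = round(attr(anova_tab, "R2"), 10),
    r_squared_adj = round(attr(anova_tab, "R2_adj"), 10),
    model_F = round(anova_tab$F[anova_tab$source == "model"], 10),
    optimum = list(
      coded = as.list(round(opt$x, 10)),
      actual = as.list(round(opt$X, 10)),
      predicted = round(opt$predicted, 10),
      at_boundary = as.list(opt$at_boundary),
      classification = opt$classification
    )
  )
  if (!is.null(rounded))
    report$rounded_optimum <- list(
      actual = as.list(round(rounded$X, 10)),
      predicted = round(rounded$predicted, 10))
  jsonlite::write_json(report, paths$report_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(design = design, od = od, desirability = des,
                 model = model, anova = anova_tab, optimum = opt,
                 rounded = rounded, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
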