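#' Read and write per-pair disector count tables (CSV)
#'
#' The interchange format is a CSV with header `animal_id, region, side,
#' pair_index, q_forward, q_reverse, p_points`, one row per disector pair in
#' cutting order. `read_count_table()` validates the file and reports
#' malformed rows with their line numbers; counts must be non-negative
#' integers and pair indices unique within each `animal_id`/`region`/`side`
#' group.
#'
#' @param path CSV file path.
#' @return `read_count_table()`: a validated `count_table` tibble in cutting
#'   order. `write_count_table()`: the path, invisibly.
#' @export
read_count_table <- function(path) {
  need <- c("animal_id", "region", "side", "pair_index",
            "q_forward", "q_reverse", "p_points")
  raw <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("count table %s is missing column(s): %s",
                  path, paste(missing_cols, collapse = ", ")))
  }
  problems <- character(0)
  for (col in c("pair_index", "q_forward", "q_reverse", "p_points")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad)) {
      problems <- c(problems, sprintf(
        "line %s: `%s` must be a non-negative integer (got %s)",
        bad + 1L, col, raw[[col]][bad]))
    }
  }
  if (length(problems)) {
    abort(paste(c(sprintf("malformed rows in %s:", path), problems),
                collapse = "\n  "))
  }
  dup <- duplicated(raw[, c("animal_id", "region", "side", "pair_index")])
  if (any(dup)) {
    abort(sprintf("duplicate pair indices in %s at line(s) %s.",
                  path, paste(which(dup) + 1L, collapse = ", ")))
  }
  out <- tibble::as_tibble(raw)
  out <- dplyr::arrange(out, .data$animal_id, .data$region, .data$side,
                        .data$pair_index)
  out$q <- out$q_forward + out$q_reverse
  new_count_table(out)
}

#' @rdname read_count_table
#' @param count_table A `count_table` tibble.
#' @export
write_count_table <- function(count_table, path) {
  df <- as.data.frame(count_table)
  for (col in c("animal_id", "region", "side")) {
    if (!col %in% names(df)) df[[col]] <- NA
  }
  if (!"p_points" %in% names(df)) df$p_points <- 0L
  df <- df[, c("animal_id", "region", "side", "pair_index",
               "q_forward", "q_reverse", "p_points")]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write a sampling design as JSON
#'
#' @param path JSON file path.
#' @return `read_design()`: a [sampling_design()]. `write_design()`: the
#'   path, invisibly.
#' @export
read_design <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("ssf_period", "frame_area", "step_x", "step_y", "section_thickness")
  missing_f <- setdiff(need, names(cfg))
  if (length(missing_f)) {
    abort(sprintf("design %s is missing field(s): %s",
                  path, paste(missing_f, collapse = ", ")))
  }
  sampling_design(
    ssf_period = cfg$ssf_period, frame_area = cfg$frame_area,
    step_x = cfg$step_x, step_y = cfg$step_y,
    section_thickness = cfg$section_thickness,
    disector_separation = cfg$disector_separation %||% cfg$section_thickness,
    smoothness_constant = cfg$smoothness_constant %||% 240,
    seed = cfg$seed
  )
}

#' @rdname read_design
#' @param design A [sampling_design()].
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "sampling_design"))
  jsonlite::write_json(unclass(design)[!vapply(unclass(design), is.null, logical(1))],
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full estimation pipeline from a configuration
#'
#' Binds the modules into one reproducible run: ingest counts (CSV) or
#' simulate them from a phantom, estimate N and V per group, predict CEs,
#' and summarise groups. The returned report contains everything needed to
#' reproduce its own numbers (inputs, per-pair count lists, design, seeds,
#' package version) and is written as JSON plus a human-readable Markdown
#' summary by [write_report()].
#'
#' @param config A named list or path to a JSON file with fields:
#'   * `design`: a [sampling_design()], a design file path, or a list of
#'     design fields;
#'   * `counts_csv`: path to a count table CSV (counts mode), or
#'   * `simulate`: list with `n_particles` and optionally `roi_lengths_um`,
#'     `radius_range`, `axis` (simulation mode);
#'   * `inv_asf`, `inv_ssf`: optional printed-value overrides;
#'   * `thickness_um`: optional calculated mean section thickness;
#'   * `seed`: integer seed for simulation mode.
#' @return A list of class `disector_report`: `estimates` (tidy per-group
#'   tibble including per-pair `q_list`), `glance`, `design`, `config
#'   echo`, `seed`, `version`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  design <- config$design
  if (is.character(design)) design <- read_design(design)
  if (is.list(design) && !inherits(design, "sampling_design")) {
    design <- do.call(sampling_design, design)
  }
  if (!inherits(design, "sampling_design")) {
    abort("pipeline config: no usable `design`.")
  }
  seed <- config$seed
  if (!is.null(config$counts_csv)) {
    ct <- read_count_table(config$counts_csv)
    source_desc <- config$counts_csv
  } else if (!is.null(config$simulate)) {
    sim <- config$simulate
    roi <- roi_box(sim$roi_lengths_um %||% c(3000, 2000, 1200))
    ph <- generate_phantom(
      n = sim$n_particles,
      roi = roi,
      radius_range = sim$radius_range %||% c(5, 10),
      min_separation = sim$min_separation %||% 2,
      seed = seed
    )
    ct <- simulate_study(ph, design, seed = seed, axis = sim$axis %||% "x")
    source_desc <- sprintf("simulated phantom (n = %d)", ph$true_n)
  } else {
    abort("pipeline config: provide `counts_csv` or `simulate`.")
  }
  est <- fractionator_estimate(
    ct, design,
    inv_asf = config$inv_asf, inv_ssf = config$inv_ssf,
    thickness = config$thickness_um
  )
  structure(
    list(
      estimates = est$estimates,
      glance = glance(est),
      design = design,
      inv_asf_used = est$inv_asf,
      inv_ssf_used = est$inv_ssf,
      thickness_used = est$thickness,
      source = source_desc,
      seed = seed,
      truth = attr(ct, "truth"),
      version = as.character(packageVersion("disectr"))
    ),
    class = "disector_report"
  )
}

#' @export
print.disector_report <- function(x, ...) {
  cat(sprintf("<disector_report> source: %s (disectr %s)\n", x$source, x$version))
  print(dplyr::select(x$estimates, -dplyr::any_of(c("q_list", "n_raw",
                                                    "v_raw_mm3", "var_surs_raw"))))
  invisible(x)
}

#' Write a pipeline report as JSON and Markdown
#'
#' @param report A [run_pipeline()] report.
#' @param json_path Destination for the machine-readable JSON report.
#' @param md_path Optional destination for a human-readable Markdown
#'   summary.
#' @return `json_path`, invisibly. Reruns of the same seeded pipeline write
#'   byte-identical files.
#' @export
write_report <- function(report, json_path, md_path = NULL) {
  stopifnot(inherits(report, "disector_report"))
  payload <- list(
    source = report$source,
    seed = report$seed,
    version = report$version,
    design = unclass(report$design)[!vapply(unclass(report$design), is.null, logical(1))],
    inv_asf_used = report$inv_asf_used,
    inv_ssf_used = report$inv_ssf_used,
    thickness_used = report$thickness_used,
    truth = report$truth,
    estimates = report$estimates
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  if (!is.null(md_path)) {
    est <- report$estimates
    lines <- c(
      "# Disector fractionator report",
      "",
      sprintf("- source: %s", report$source),
      sprintf("- seed: %s", report$seed %||% "none"),
      sprintf("- 1/ssf = %s, 1/asf = %s", format(report$inv_ssf_used),
              format(report$inv_asf_used)),
      "",
      "| group | sum Q- | sum P | N | V (mm^3) | CE |",
      "|---|---|---|---|---|---|"
    )
    keys <- intersect(c("animal_id", "region", "side"), names(est))
    for (i in seq_len(nrow(est))) {
      label <- if (length(keys)) {
        paste(unlist(est[i, keys]), collapse = "/")
      } else "all"
      lines <- c(lines, sprintf(
        "| %s | %d | %d | %s | %.2f | %s |",
        label, est$sum_q[i], est$sum_p[i],
        format(est$n[i], big.mark = ","), est$v_mm3[i],
        ifelse(is.na(est$ce[i]), "-", sprintf("%.2f", est$ce[i]))))
    }
    writeLines(lines, md_path)
  }
  invisible(json_path)
}
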