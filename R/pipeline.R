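# End-to-end orchestration: simulate (or ingest), quality-filter, select the
# model on smoothed layers, fit annual surfaces, bootstrap, and emit the
# delimited report bundle (trend, closure, typology and stagnation tables)
# with full provenance headers.

#' Configure a pipeline run
#'
#' @param out_dir output directory for the report bundle.
#' @param seed master seed; every random stage derives its stream from it.
#' @param simulate a [scenario_config()] to generate inputs, or `NULL` to
#'   read census tables from `input_path`.
#' @param input_path census table path (ignored when `simulate` is given).
#' @param crop crop archetype (selects the starting formula); required.
#' @param tau quantile level.
#' @param B bootstrap replicates for the coefficient ensembles.
#' @param level confidence level.
#' @param select run temporal model selection (otherwise the starting spec,
#'   stripped of time terms, is fitted directly).
#' @param spec_terms optional character vector of starting model terms;
#'   defaults to the crop archetype's [base_spec()].
#' @param trend_years analysis window for gap trends.
#' @param periods list of `c(start, end)` periods for the area tables.
#' @param base_years named vector mapping period labels to reference years.
#' @return object of class `yg_run_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, simulate = NULL,
                            input_path = NULL, crop = NULL, tau = 0.95,
                            B = 100, level = 0.95, select = FALSE,
                            spec_terms = NULL,
                            trend_years = 1998:2012,
                            periods = list(c(1975, 2010), c(1975, 1985),
                                           c(2000, 2010)),
                            base_years = c("1975-2010" = 2000,
                                           "1975-1985" = 1975,
                                           "2000-2010" = 2000)) {
  crop <- crop %||% (if (!is.null(simulate)) simulate$crop else NULL)
  if (is.null(crop)) stop_yg("config lacks a crop archetype")
  if (is.null(simulate) && is.null(input_path))
    stop_yg("either simulate or input_path is required")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, input_path = input_path, crop = crop,
                 tau = tau, B = as.integer(B), level = level,
                 select = select, spec_terms = spec_terms,
                 trend_years = trend_years,
                 periods = periods, base_years = base_years),
            class = "yg_run_config")
}

write_report_table <- function(df, path, config, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# yieldgaps report table",
               sprintf("# config_hash: %s", hash),
               sprintf("# seed: %d", config$seed),
               sprintf("# config: %s", {
                 cfg <- unclass(config)
                 cfg$out_dir <- NULL
                 paste(deparse(cfg, control = "all"), collapse = " ")
               })), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Sequences simulation/ingest, quality filtering, layer smoothing and model
#' selection, annual regularized fits, bootstrap ensembles, gap trends,
#' time-to-closure, typology and stagnation stages, writing one delimited
#' table per product into `out_dir`.  Each output carries the config hash
#' and seed, so a bundle can be reproduced from its header.  Stage failures
#' are caught and recorded in a machine-readable `manifest.json`; the
#' returned object reports completeness.
#'
#' @param config a [pipeline_config()].
#' @return list with `status` (`"complete"` or `"partial"`), `paths` of the
#'   written files, the selected `spec`, and the `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "yg_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_id <- unclass(config)
  cfg_id$out_dir <- NULL   # provenance describes the run, not its location
  hash <- config_hash(cfg_id)
  paths <- character()
  manifest <- list(config_hash = hash, seed = config$seed,
                   stages = list(), errors = list())
  failed <- FALSE
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) e)
    dt <- as.numeric(Sys.time() - t0, units = "secs")
    if (inherits(res, "error")) {
      manifest$errors[[name]] <<- conditionMessage(res)
      manifest$stages[[name]] <<- list(ok = FALSE, seconds = round(dt, 2))
      failed <<- TRUE
      NULL
    } else {
      manifest$stages[[name]] <<- list(ok = TRUE, seconds = round(dt, 2))
      res
    }
  }
  emit <- function(df, file) {
    p <- file.path(config$out_dir, file)
    write_report_table(df, p, config, hash)
    paths <<- c(paths, p)
  }

  panel <- NULL
  records <- stage("ingest", {
    if (!is.null(config$simulate)) {
      panel <- generate_panel(config$simulate)
      panel$records
    } else {
      read_census_table(config$input_path)
    }
  })
  qc <- if (!is.null(records)) stage("qc", qc_filter(records)) else NULL
  if (!is.null(qc)) {
    emit(qc$rejected[c(CENSUS_COLS, "qc_flag", "qc_reason")], "qc_rejects.csv")
    records <- qc$kept
  }

  spec <- stage("spec", {
    start <- if (is.null(config$spec_terms)) {
      base_spec(config$crop, time_terms = config$select)
    } else {
      tm <- config$spec_terms
      pr <- intersect(c("IRR", "IRR:MAP"), tm)
      if (config$select) {
        tm <- union(tm, c("t", "t^2"))
        pr <- c(pr, "t", "t^2")
      }
      model_spec(tm, protected = pr)
    }
    if (config$select) {
      layers <- build_layers(records)
      sel <- select_model(start, layers, tau = config$tau,
                          seed = derive_seed(config$seed, "select"))
      emit(sel$trace, "selection_trace.csv")
      strip_time_terms(sel$spec)
    } else strip_time_terms(start)
  })

  series <- if (!is.null(spec) && !is.null(records))
    stage("annual_fits", fit_annual_series(records, spec, tau = config$tau))
  else NULL
  if (!is.null(series)) {
    coefs <- do.call(rbind, lapply(series$fits, function(f)
      data.frame(year = f$year, term = spec$terms,
                 estimate = f$coefficients,
                 fraction_below = f$fraction_below,
                 stringsAsFactors = FALSE)))
    emit(coefs, "annual_coefficients.csv")
    emit(series$factors, "normalization_factors.csv")
  }

  ensembles <- if (!is.null(series)) stage("bootstrap", {
    yrs <- as.integer(names(series$fits))
    out <- lapply(yrs, function(yr)
      bootstrap_fit(records, spec, yr, B = config$B,
                    seed = derive_seed(config$seed, "boot"),
                    tau = config$tau, factors = series$factors))
    names(out) <- yrs
    out
  }) else NULL

  gaps <- if (!is.null(ensembles))
    stage("gap_table", gap_table(records, series, ensembles))
  else NULL

  if (!is.null(gaps)) {
    stage("trend_tables", {
      rows <- list()
      for (k in seq_along(config$periods)) {
        per <- config$periods[[k]]
        lab <- sprintf("%d-%d", per[1], per[2])
        ref <- unname(config$base_years[lab])
        if (is.null(ref) || is.na(ref)) ref <- per[1]
        for (val in c("attainable", "gap")) {
          for (dir in c("positive", "negative")) {
            sh <- area_fraction_significant(gaps, val, dir, per, ref,
                                            config$level)
            rows[[length(rows) + 1L]] <- data.frame(
              crop = config$crop, period = lab, quantity = val,
              direction = dir, area_share_pct = as.numeric(sh),
              stringsAsFactors = FALSE)
          }
          gc <- global_average_change(gaps, val, per,
                                      base_year = ref, level = config$level)
          rows[[length(rows) + 1L]] <- data.frame(
            crop = config$crop, period = lab, quantity = val,
            direction = "global_rate",
            area_share_pct = NA_real_, stringsAsFactors = FALSE)
          rows[[length(rows)]]$rate_pct_yr <- gc$rate
          rows[[length(rows)]]$rate_lo <- gc$lo
          rows[[length(rows)]]$rate_hi <- gc$hi
        }
      }
      tab <- do.call(rbind, lapply(rows, function(r) {
        for (cn in c("rate_pct_yr", "rate_lo", "rate_hi"))
          if (!cn %in% names(r)) r[[cn]] <- NA_real_
        r
      }))
      emit(tab, "trend_summary.csv")
      tr <- unit_trends(gaps, "gap", years = config$trend_years,
                        level = config$level)
      tc <- time_to_closure(tr)
      emit(merge(as.data.frame(tr)[c("unit_id", "x0", "x1", "lo", "hi", "sig")],
                 tc, by = "unit_id"), "time_to_closure.csv")
      lab <- typology_labels(gaps, years = config$trend_years,
                             level = config$level)
      ref_area <- gaps[gaps$rep == gaps$rep[1L] & gaps$year == 2000,
                       c("unit_id", "area")]
      lab$area <- ref_area$area[match(lab$unit_id, ref_area$unit_id)]
      emit(lab, "typology_units.csv")
      emit(typology_area_table(lab[!is.na(lab$area), ]), "typology_shares.csv")
      TRUE
    })
    stage("stagnation", {
      units <- sort(unique(records$unit_id))
      st <- vapply(units, function(u) {
        s <- records[records$unit_id == u, ]
        isTRUE(piecewise_stagnation(s$year, s$yield_t_ha)$stagnant)
      }, logical(1))
      tr86 <- unit_trends(gaps, "gap", years = 1986:2000, origin = 1986,
                          level = config$level)
      tc86 <- -tr86$x0 / tr86$x1 - 14   # years past 2000 at gap zero-crossing
      closing <- tr86$sig == "negative" & is.finite(tc86) & tc86 <= 30
      growth <- unit_trends(gaps, "actual", years = 1986:2000,
                            origin = 1986, level = config$level)$x1
      u <- data.frame(unit_id = tr86$unit_id,
                      closing = closing,
                      stagnant = st[match(tr86$unit_id, units)],
                      growth = growth, stringsAsFactors = FALSE)
      rr <- stagnation_risk_ratio(u)
      emit(u, "stagnation_units.csv")
      emit(data.frame(statistic = c("risk_ratio", "p_stagnant_closing",
                                    "p_stagnant_other", "risk_ratio_q3",
                                    "risk_ratio_top_quartile"),
                      value = c(rr$ratio, rr$p_closing, rr$p_other,
                                rr$ratio_q3, rr$ratio_top),
                      stringsAsFactors = FALSE), "stagnation_summary.csv")
      TRUE
    })
  }

  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  list(status = if (failed) "partial" else "complete",
       paths = c(paths, manifest_path), spec = spec, manifest = manifest)
}
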