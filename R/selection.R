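# Temporal model selection: half-decadal smoothing layers, bootstrap
# significance pruning, and child-model generation with leave-one-layer-out
# cross-validation.

#' Smooth a census panel into half-decadal layers
#'
#' Builds one pseudo-record per unit per layer by averaging yield and
#' covariates (area-weighted) over each central year +/- `half_width` years;
#' the layer's area weight is the mean annual harvested area over the window.
#' Units absent from a window are omitted from that layer.  The default eight
#' central years 1975, 1980, ..., 2010 tile the 1973-2012 panel into
#' non-overlapping windows.
#'
#' @param records census records.
#' @param central_years layer centres.
#' @param half_width window half-width in years.
#' @return `data.frame` of pseudo-records with columns `layer`, `t` (central
#'   year) and the averaged value columns.
#' @export
build_layers <- function(records, central_years = seq(1975, 2010, by = 5),
                         half_width = 2) {
  num_cols <- names(records)[vapply(records, is.numeric, logical(1))]
  avg_cols <- setdiff(num_cols, c("year", "area_ha", "area_fraction"))
  out <- vector("list", length(central_years))
  for (k in seq_along(central_years)) {
    cy <- central_years[k]
    win <- records[abs(records$year - cy) <= half_width, , drop = FALSE]
    if (!nrow(win)) next
    f <- factor(win$unit_id)
    sa <- rowsum(win$area_ha, f)
    keep <- drop(sa) > 0
    lay <- data.frame(unit_id = rownames(sa), stringsAsFactors = FALSE)
    for (v in avg_cols)
      lay[[v]] <- drop(rowsum(win[[v]] * win$area_ha, f)) / drop(sa)
    lay$area_ha <- drop(rowsum(win$area_ha, f)) / drop(rowsum(rep(1, nrow(win)), f))
    if ("crop" %in% names(win))
      lay$crop <- win$crop[match(lay$unit_id, win$unit_id)]
    lay$layer <- k
    lay$t <- cy
    lay$year <- cy
    out[[k]] <- lay[keep, , drop = FALSE]
  }
  do.call(rbind, out)
}

# pooled unregularized fit on layer pseudo-records; returns z-space
# coefficients.  Layers carry a `t` column so time terms are available.
fit_layers <- function(layers, spec, tau, factors) {
  X <- build_design(layers, spec, factors)
  yf <- factors[factors$var == "yield_t_ha", ]
  yz <- (layers$yield_t_ha - yf$mean) / yf$sd
  fit_quantile(X, yz, layers$area_ha, tau = tau, regularized = FALSE)
}

layer_factors <- function(layers, spec) {
  normalization_factors(layers, c(tolower(term_vars(spec$terms)), "yield_t_ha"))
}

#' Prune non-significant model terms
#'
#' Iteratively removes terms whose bootstrap confidence interval overlaps
#' zero, starting each round with the term whose interval most centrally
#' overlaps zero (smallest `|lo + hi| / (hi - lo)`), until every remaining
#' term is significant.  The intercept and the protected terms are never
#' removed.  Intervals come from a case-resampling bootstrap of the pooled
#' layer fit; resampling is by unit (cluster bootstrap), because each unit
#' contributes one pseudo-record per layer and treating those as independent
#' would understate coefficient uncertainty.
#'
#' @param spec a [model_spec()].
#' @param layers output of [build_layers()].
#' @param level confidence level of the pruning intervals.
#' @param seed integer seed for the bootstrap.
#' @param B bootstrap replicates per round.
#' @param tau quantile level.
#' @param protect extra protected terms (defaults to the spec's own).
#' @return the pruned [model_spec()], with a `trace` attribute listing each
#'   removal.
#' @export
prune_nonsignificant <- function(spec, layers, level = 0.95, seed = 1,
                                 B = 200, tau = 0.95,
                                 protect = spec$protected) {
  stopifnot(inherits(spec, "yg_spec"))
  trace <- character()
  round <- 0L
  repeat {
    round <- round + 1L
    factors <- layer_factors(layers, spec)
    unit_rows <- split(seq_len(nrow(layers)), layers$unit_id)
    nu <- length(unit_rows)
    coefs <- matrix(NA_real_, B, length(spec$terms),
                    dimnames = list(NULL, spec$terms))
    for (b in seq_len(B)) {
      set.seed(derive_seed(seed, "prune", round, "rep", b))
      idx <- unlist(unit_rows[sample.int(nu, nu, replace = TRUE)],
                    use.names = FALSE)
      fit <- tryCatch(fit_layers(layers[idx, , drop = FALSE], spec, tau, factors),
                      error = function(e) NULL)
      if (!is.null(fit)) coefs[b, ] <- fit$coefficients
    }
    coefs <- coefs[stats::complete.cases(coefs), , drop = FALSE]
    if (nrow(coefs) < 2) stop_yg("pruning bootstrap failed")
    removable <- setdiff(spec$terms, c("1", protect))
    if (!length(removable)) break
    cent <- vapply(removable, function(tm) {
      ci <- percentile_ci(coefs[, tm], level)
      if (ci[1] > 0 || ci[2] < 0) return(Inf)      # significant
      wid <- ci[2] - ci[1]
      if (wid <= 0) return(Inf)                     # degenerate, keep
      abs(ci[1] + ci[2]) / wid
    }, numeric(1))
    if (all(!is.finite(cent))) break                # all significant
    drop_term <- removable[which.min(cent)]
    trace <- c(trace, drop_term)
    spec <- model_spec(setdiff(spec$terms, drop_term),
                       protected = spec$protected)
  }
  attr(spec, "trace") <- trace
  spec
}

#' Leave-one-layer-out cross-validation loss
#'
#' For each smoothing layer, fits the model on the remaining layers and
#' evaluates the area-weighted check loss on the held-out layer; returns the
#' sum over layers.  A failed fold disqualifies the spec (`Inf`).
#'
#' @param spec a [model_spec()].
#' @param layers output of [build_layers()].
#' @param tau quantile level.
#' @param factors optional pooled [normalization_factors()] (computed from
#'   all layers when `NULL`); the same factors are used on every fold so
#'   losses are comparable across specs.
#' @return summed loss (z-score response units) with per-fold attribute.
#' @export
cv_loss <- function(spec, layers, tau = 0.95, factors = NULL) {
  stopifnot(inherits(spec, "yg_spec"))
  ids <- sort(unique(layers$layer))
  if (length(ids) < 2) stop_yg("need at least 2 layers")
  if (is.null(factors)) factors <- layer_factors(layers, spec)
  yf <- factors[factors$var == "yield_t_ha", ]
  fold <- numeric(length(ids))
  for (k in seq_along(ids)) {
    test <- layers$layer == ids[k]
    train <- layers[!test, , drop = FALSE]
    held <- layers[test, , drop = FALSE]
    fit <- tryCatch(fit_layers(train, spec, tau, factors),
                    error = function(e) NULL)
    if (is.null(fit)) {
      fold[k] <- Inf
      next
    }
    Xh <- build_design(held, spec, factors)
    qh <- drop(Xh %*% fit$coefficients)
    yh <- (held$yield_t_ha - yf$mean) / yf$sd
    fold[k] <- quantile_loss(yh, qh, held$area_ha, tau)
  }
  structure(sum(fold), folds = fold)
}

#' Stepwise model selection by temporal cross-validation
#'
#' Starting from `start_spec` (optionally pre-pruned by bootstrap
#' significance), each generation forms child models by deleting one
#' deletable term each (the intercept, irrigation, irrigation-precipitation
#' and time terms are never deleted), adopts the child with the lowest summed
#' leave-one-layer-out loss while it improves on the parent, and on the first
#' non-improving generation explores one generation further before
#' finalizing.  Ties between children delete the term appearing later in
#' spec order.
#'
#' @param start_spec a [model_spec()], typically [base_spec()] with time
#'   terms.
#' @param layers output of [build_layers()].
#' @param tau quantile level.
#' @param seed seed for the pruning bootstrap.
#' @param level confidence level for pruning.
#' @param B_prune bootstrap replicates for pruning.
#' @param protect terms never deleted (in both phases); defaults to the
#'   spec's protected set plus `t` and `t^2`.
#' @param prune run the significance-pruning phase first.
#' @return object of class `yg_selection`: final `spec` and a `trace`
#'   `data.frame` (generation, terms, cv_loss, action).
#' @export
select_model <- function(start_spec, layers, tau = 0.95, seed = 1,
                         level = 0.95, B_prune = 200,
                         protect = union(start_spec$protected,
                                         c("IRR", "IRR:MAP", "t", "t^2")),
                         prune = TRUE) {
  stopifnot(inherits(start_spec, "yg_spec"))
  protect <- intersect(protect, start_spec$terms)
  spec <- start_spec
  trace <- data.frame(generation = integer(), terms = character(),
                      cv_loss = numeric(), action = character(),
                      stringsAsFactors = FALSE)
  add <- function(gen, sp, loss, action) {
    rbind(trace, data.frame(generation = gen,
                            terms = paste(sp$terms, collapse = "+"),
                            cv_loss = loss, action = action,
                            stringsAsFactors = FALSE))
  }
  if (prune) {
    spec <- prune_nonsignificant(spec, layers, level = level, seed = seed,
                                 B = B_prune, tau = tau, protect = protect)
    spec$protected <- union(start_spec$protected, intersect(protect, spec$terms))
  }
  parent_loss <- cv_loss(spec, layers, tau)
  trace <- add(0L, spec, parent_loss, if (prune) "pruned start" else "start")

  gen <- 0L
  repeat {
    gen <- gen + 1L
    deletable <- setdiff(spec$terms, c("1", protect))
    if (!length(deletable)) break
    children <- lapply(deletable, function(tm)
      model_spec(setdiff(spec$terms, tm), protected = spec$protected))
    losses <- vapply(children, function(ch) as.numeric(cv_loss(ch, layers, tau)),
                     numeric(1))
    # tie-break: later term in spec order wins, so use <= when scanning
    best <- 1L
    for (j in seq_along(losses)) if (losses[j] <= losses[best]) best <- j
    if (is.finite(losses[best]) && losses[best] < parent_loss) {
      spec <- children[[best]]
      parent_loss <- losses[best]
      trace <- add(gen, spec, parent_loss, sprintf("deleted %s", deletable[best]))
      next
    }
    # explore one generation past the minimum before stopping
    trace <- add(gen, children[[best]], losses[best], "no improvement")
    probe <- children[[best]]
    pdel <- setdiff(probe$terms, c("1", protect))
    if (length(pdel)) {
      gchildren <- lapply(pdel, function(tm)
        model_spec(setdiff(probe$terms, tm), protected = probe$protected))
      glosses <- vapply(gchildren, function(ch)
        as.numeric(cv_loss(ch, layers, tau)), numeric(1))
      gbest <- 1L
      for (j in seq_along(glosses)) if (glosses[j] <= glosses[gbest]) gbest <- j
      if (is.finite(glosses[gbest]) && glosses[gbest] < parent_loss) {
        spec <- gchildren[[gbest]]
        parent_loss <- glosses[gbest]
        trace <- add(gen + 1L, spec, parent_loss,
                     sprintf("deleted %s and %s (second look)",
                             deletable[best], pdel[gbest]))
        next
      }
      trace <- add(gen + 1L, gchildren[[gbest]], glosses[gbest],
                   "second look, no improvement")
    }
    break
  }
  trace <- add(gen, spec, parent_loss, "selected")
  structure(list(spec = spec, trace = trace), class = "yg_selection")
}

#' @export
print.yg_selection <- function(x, ...) {
  cat("Temporal cross-validation model selection\n")
  print(x$spec)
  cat(sprintf("  %d trace steps, final cv loss %.5g\n",
              nrow(x$trace), x$trace$cv_loss[nrow(x$trace)]))
  invisible(x)
}
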