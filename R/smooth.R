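## Penalized-spline mixed models (via mgcv) for (a) afternoon heat
## responses of behaviour proportions / mean ODBA and (b) hot-vs-cool-day
## diel activity curves, with term significance, intercept contrasts and
## concurvity diagnostics.
##
## Families: proportions are modelled on the logit scale with a
## quasibinomial variance and cell sizes as weights; mean ODBA with an
## identity link and constant variance. Random effects are random
## intercepts per individual. Month (3 levels in the hot season) enters
## as a factor: a 3-point smooth would be degenerate.

smooth_fit <- function(gam, response, behaviour, alpha, extras = list()) {
  s <- summary(gam)
  stat_col <- if ("F" %in% colnames(s$s.table)) "F" else "Chi.sq"
  terms <- tibble::tibble(
    term = c(rownames(s$p.table), rownames(s$s.table)),
    type = rep(c("parametric", "smooth"),
               c(nrow(s$p.table), nrow(s$s.table))),
    edf = c(rep(NA_real_, nrow(s$p.table)), s$s.table[, "edf"]),
    ref_df = c(rep(NA_real_, nrow(s$p.table)), s$s.table[, "Ref.df"]),
    statistic = c(s$p.table[, "t value"], s$s.table[, stat_col]),
    p_value = c(s$p.table[, "Pr(>|t|)"], s$s.table[, "p-value"])
  )
  structure(
    c(list(gam = gam, response = response, behaviour = behaviour,
           terms = terms, alpha = alpha,
           concurvity = concurvity_worst(gam)),
      extras),
    class = "smooth_fit"
  )
}

concurvity_worst <- function(gam) {
  if (length(gam$smooth) == 0L) return(numeric())
  cc <- mgcv::concurvity(gam, full = TRUE)
  out <- pmin(pmax(cc["worst", , drop = TRUE], 0), 1)
  out <- out[names(out) != "para"]
  # random-intercept smooths overlap the parametric intercept by
  # construction and sit at 1 trivially; only covariate smooths are
  # screened against the 0.8 rule
  is_re <- vapply(gam$smooth,
                  function(s) inherits(s, "random.effect"), logical(1))
  screened <- out[!is_re[seq_along(out)]]
  if (any(screened >= 0.8)) {
    warn(paste0("concurvity >= 0.8 for: ",
                paste(names(screened)[screened >= 0.8], collapse = ", ")))
  }
  out
}

#' Worst-case concurvity of each smooth term
#'
#' Concurvity is the nonlinear analogue of collinearity among smooth
#' terms, on \[0, 1\]; values at or above 0.8 trigger a warning when the
#' model is fitted.
#'
#' @param fit A `"smooth_fit"`.
#' @return Named numeric vector, one value per smooth term.
#' @export
concurvity_values <- function(fit) {
  stopifnot(inherits(fit, "smooth_fit"))
  fit$concurvity
}

#' @export
print.smooth_fit <- function(x, ...) {
  cat(sprintf("Penalized-spline mixed model: %s of %s (alpha = %g)\n",
              x$response, x$behaviour, x$alpha))
  print(as.data.frame(x$terms), digits = 4)
  if (length(x$concurvity) > 0) {
    cat("worst-case concurvity:",
        paste(sprintf("%s=%.2f", names(x$concurvity), x$concurvity),
              collapse = ", "), "\n")
  }
  if (!is.null(x$pct_diff_24h)) {
    cat(sprintf("24-h mean, hot vs cool: %+.1f%% (interaction p = %.3g, intercept p = %.3g)\n",
                x$pct_diff_24h, x$interaction_p, x$intercept_p))
  }
  invisible(x)
}

## Cap a basis dimension at the number of distinct covariate values.
cap_k <- function(k, values) max(3L, min(k, length(unique(values)) - 1L))

#' Afternoon heat-response model for one behaviour
#'
#' Fits `response ~ species + s(blackglobe, by = species) +
#' s(hour, by = species) + month + random intercept(individual)` with
#' penalized regression splines (REML smoothing selection). With a single
#' species the by-terms collapse to plain smooths and the species factor
#' is dropped. The response is either the time-budget `proportion` of
#' `behaviour` (quasibinomial, weighted by cell size) or the cell
#' `mean_odba` (gaussian).
#'
#' @param cells Tidy cells from [time_budget()] or [mean_odba_cells()],
#'   optionally with a `species` column.
#' @param behaviour One of [analysis_categories()].
#' @param response `"proportion"` or `"mean_odba"`.
#' @param k_blackglobe,k_hour Basis dimensions for the temperature and
#'   hour smooths (defaults 10 and 8; reference df 9 for temperature).
#' @param alpha Significance level recorded with the fit, default 0.05.
#' @param ... Passed on to [mgcv::gam()] (e.g. `sp` to fix smoothing
#'   parameters).
#' @return A `"smooth_fit"` with a term table (edf, reference df,
#'   statistic, p-value) and worst-case concurvity per smooth.
#' @export
fit_heat_model <- function(cells, behaviour,
                           response = c("proportion", "mean_odba"),
                           k_blackglobe = 10L, k_hour = 8L, alpha = 0.05,
                           ...) {
  response <- match.arg(response)
  dat <- as.data.frame(cells[cells$category == behaviour, ])
  if (nrow(dat) < 20L) abort("need at least 20 cells to fit the heat model")
  dat$blackglobe <- as.numeric(dat$blackglobe_bin)
  dat$hour <- as.numeric(dat$hour)
  dat$individual_id <- factor(dat$individual_id)
  dat$month <- factor(dat$month)
  kb <- cap_k(k_blackglobe, dat$blackglobe)
  kh <- cap_k(k_hour, dat$hour)

  multi_species <- "species" %in% names(dat) &&
    length(unique(dat$species)) > 1L
  if (multi_species) dat$species <- factor(dat$species)
  rhs <- c(
    if (multi_species) "species",
    if (multi_species) sprintf("s(blackglobe, by = species, k = %d)", kb)
    else sprintf("s(blackglobe, k = %d)", kb),
    if (multi_species) sprintf("s(hour, by = species, k = %d)", kh)
    else sprintf("s(hour, k = %d)", kh),
    if (nlevels(dat$month) > 1L) "month",
    if (nlevels(dat$individual_id) > 1L) 's(individual_id, bs = "re")'
  )
  if (response == "proportion") {
    fml <- stats::as.formula(paste("proportion ~", paste(rhs, collapse = " + ")))
    gam <- mgcv::gam(fml, data = dat, family = stats::quasibinomial(),
                     weights = dat$n_records, method = "REML", ...)
  } else {
    fml <- stats::as.formula(paste("mean_odba ~", paste(rhs, collapse = " + ")))
    gam <- mgcv::gam(fml, data = dat, family = stats::gaussian(),
                     method = "REML", ...)
  }
  smooth_fit(gam, response, behaviour, alpha)
}

#' Diel hot-versus-cool-day model for one behaviour
#'
#' Fits the time-budget proportion over the 24-hour cycle as
#' `proportion ~ dayclass + s(hour) + s(hour, by = dayclass contrast) +
#' random intercept(individual)` with a cyclic cubic basis for hour (the
#' day wraps at midnight). The day-class contrast smooth captures a
#' difference in diel *shape* between hot and cool days; the parametric
#' day-class term captures a difference in the 24-h *mean*. The fit also
#' reports the percentage difference of the model's 24-h mean proportion
#' on hot relative to cool days (ratio of 24-h means over an hourly
#' grid, random effects excluded).
#'
#' @param cells Diel cells from [diel_budget()].
#' @param behaviour One of [analysis_categories()].
#' @param k_hour Basis dimension of the cyclic hour smooth, default 8.
#' @param alpha Significance level recorded with the fit.
#' @param ... Passed on to [mgcv::gam()].
#' @return A `"smooth_fit"` with extras `interaction_p` (shape
#'   difference), `intercept_p` (24-h mean difference) and
#'   `pct_diff_24h`.
#' @export
fit_diel_model <- function(cells, behaviour, k_hour = 8L, alpha = 0.05, ...) {
  dat <- as.data.frame(cells[cells$category == behaviour, ])
  if (length(unique(dat$dayclass)) < 2L) {
    abort("both day classes (hot, cool) must be present")
  }
  if (length(unique(dat$hour)) < 12L) {
    abort("need coverage of at least 12 distinct hours")
  }
  dat$hour <- as.numeric(dat$hour)
  dat$individual_id <- factor(dat$individual_id)
  dat$dayclass <- factor(dat$dayclass, levels = c("cool", "hot"))
  dat$dayclass_o <- ordered(dat$dayclass, levels = c("cool", "hot"))
  kh <- cap_k(k_hour, dat$hour)
  knots <- list(hour = seq(0, 24, length.out = kh))

  rhs <- c("dayclass",
           sprintf('s(hour, bs = "cc", k = %d)', kh),
           sprintf('s(hour, by = dayclass_o, bs = "cc", k = %d)', kh),
           if (nlevels(dat$individual_id) > 1L) 's(individual_id, bs = "re")')
  fml <- stats::as.formula(paste("proportion ~", paste(rhs, collapse = " + ")))
  gam <- mgcv::gam(fml, data = dat, family = stats::quasibinomial(),
                   weights = dat$n_records, method = "REML", knots = knots,
                   ...)

  s <- summary(gam)
  inter_row <- grep("dayclass", rownames(s$s.table))
  interaction_p <- unname(s$s.table[inter_row[1], "p-value"])
  par_row <- grep("dayclasshot", rownames(s$p.table))
  intercept_p <- unname(s$p.table[par_row[1], "Pr(>|t|)"])

  grid <- expand.grid(hour = 0:23, dayclass = factor(c("cool", "hot"),
                                                     levels = c("cool", "hot")),
                      individual_id = levels(dat$individual_id)[1])
  grid$dayclass_o <- ordered(grid$dayclass, levels = c("cool", "hot"))
  excl <- if (nlevels(dat$individual_id) > 1L) "s(individual_id)" else NULL
  pred <- predict(gam, newdata = grid, type = "response", exclude = excl,
                  newdata.guaranteed = TRUE)
  m_cool <- mean(pred[grid$dayclass == "cool"])
  m_hot <- mean(pred[grid$dayclass == "hot"])
  pct <- 100 * (m_hot - m_cool) / m_cool

  smooth_fit(gam, "proportion", behaviour, alpha,
             extras = list(interaction_p = interaction_p,
                           intercept_p = intercept_p,
                           pct_diff_24h = pct,
                           mean_24h = c(cool = m_cool, hot = m_hot)))
}

#' Partial effect of one smooth term on a grid
#'
#' Evaluates the centred partial effect (link scale) and its standard
#' error for one smooth over a grid of its covariate, holding all other
#' covariates at reference values.
#'
#' @param fit A `"smooth_fit"`.
#' @param term Smooth label as in the fitted model, e.g.
#'   `"s(blackglobe)"`.
#' @param n Grid size, default 100.
#' @return Tibble with the covariate grid, `effect` and `se`.
#' @export
partial_effect <- function(fit, term, n = 100L) {
  stopifnot(inherits(fit, "smooth_fit"))
  gam <- fit$gam
  labels <- vapply(gam$smooth, function(s) s$label, character(1))
  idx <- match(term, labels)
  if (is.na(idx)) abort(paste0("no smooth term '", term, "'; have: ",
                               paste(labels, collapse = ", ")))
  var <- gam$smooth[[idx]]$term[1]
  mf <- gam$model
  grid_var <- seq(min(mf[[var]]), max(mf[[var]]), length.out = n)
  newdata <- mf[rep(1L, n), , drop = FALSE]
  newdata[[var]] <- grid_var
  pt <- predict(gam, newdata = newdata, type = "terms", se.fit = TRUE,
                newdata.guaranteed = TRUE)
  col <- match(term, colnames(pt$fit))
  out <- tibble::tibble(value = grid_var,
                        effect = pt$fit[, col], se = pt$se.fit[, col])
  names(out)[1] <- var
  out
}

#' Write a model term table as structured text
#'
#' @param fit A `"smooth_fit"`.
#' @param path Output path; columns mirror the standard GAMM report
#'   (term, type, edf, reference df, statistic, p-value).
#' @return `path`, invisibly.
#' @export
write_smooth_fit <- function(fit, path) {
  hdr <- sprintf("# response: %s; behaviour: %s; family: %s; alpha: %g",
                 fit$response, fit$behaviour, fit$gam$family$family, fit$alpha)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(as.data.frame(fit$terms), con, row.names = FALSE)
  invisible(path)
}
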