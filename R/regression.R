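# Multivariable models for hotspot outcomes: logistic regression for presence
# (0/1), proportional-odds ordinal regression for hotspot counts. Model 1
# adjusts for age, log10 normalized WMH volume, number of lacunes and
# microbleeds; model 2 adds SVD type. Complete-case handling per model;
# collinearity screened by variance inflation factors with VIF < 5 acceptable.

model_adjustment_sets <- function(model_version) {
  base <- c("age", "log10_wmh_norm", "n_lacunes", "n_cmb")
  switch(as.character(model_version),
         "1" = base,
         "2" = c(base, "svd_type"),
         stop("`model_version` must be 1 or 2", call. = FALSE))
}

#' Variance inflation factors of a design matrix
#'
#' For each column j, VIF_j = 1 / (1 - R^2_j) where R^2_j comes from the
#' least-squares regression of column j on all other columns (with
#' intercept). Exact linear dependence yields an infinite-VIF marker. VIF
#' below 5 is flagged acceptable.
#'
#' @param design Numeric matrix or data frame of covariates (>= 2 columns,
#'   more rows than columns).
#' @param threshold Acceptability cut-off (default 5).
#' @return Tibble: `term`, `vif`, `acceptable`.
#' @export
#' @examples
#' X <- cbind(a = rnorm(50), b = rnorm(50))
#' vif_screen(X)  # orthogonal-ish: VIFs near 1
vif_screen <- function(design, threshold = 5) {
  X <- as.matrix(design)
  storage.mode(X) <- "double"
  if (ncol(X) < 2L) stop("VIF needs at least 2 covariates", call. = FALSE)
  if (nrow(X) <= ncol(X)) stop("VIF needs more observations than covariates",
                               call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  vifs <- vapply(seq_len(ncol(X)), function(j) {
    y <- X[, j]
    Z <- cbind(1, X[, -j, drop = FALSE])
    fit <- stats::lm.fit(Z, y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    if (tss == 0) return(Inf)  # constant column
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble::tibble(term = colnames(X), vif = vifs,
                 acceptable = is.finite(vifs) & vifs < threshold)
}

# collapse a count outcome to ordinal levels, merging everything above the
# cohort's 90th percentile into one top category for a stable
# proportional-odds fit
collapse_count_outcome <- function(y, top_quantile = 0.9) {
  cap <- stats::quantile(y, top_quantile, type = 2)
  ordered(pmin(y, cap))
}

#' Fit the multivariable hotspot models
#'
#' Fits the presence (logistic) or number (proportional-odds ordinal) model
#' for a hotspot outcome, using the screened candidate covariates plus the
#' pre-established adjustment set: model 1 is age, log10 normalized WMH
#' volume, lacune count and microbleed count; model 2 adds SVD type. Rows
#' with missing values in any used column are dropped (complete-case) and
#' the n actually used is recorded. Separation and non-convergence are
#' flagged, never silently returned as estimates.
#'
#' @param records Per-patient data frame.
#' @param outcome Outcome column: binary 0/1 for presence (logistic), a
#'   non-negative count for number (ordinal).
#' @param candidates Character vector of screened candidate covariates
#'   (already including the vascular function measures).
#' @param model_version 1 or 2.
#' @param family `"auto"` (default: logistic for 2-valued outcomes, ordinal
#'   otherwise), `"logistic"` or `"ordinal"`.
#' @return Object of class `bbb_model`: list with `coefficients` (tibble:
#'   `term`, `estimate`, `std_error`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_value`), `vif` (tibble), `n_used`, `label`, `outcome`, `converged`,
#'   `separation`, and the underlying `fit`.
#' @export
fit_models <- function(records, outcome, candidates = character(),
                       model_version = 1, family = c("auto", "logistic",
                                                     "ordinal")) {
  family <- match.arg(family)
  records <- tibble::as_tibble(records)
  adjust <- model_adjustment_sets(model_version)
  covars <- union(setdiff(candidates, outcome), adjust)
  covars <- setdiff(covars, outcome)
  missing_cols <- setdiff(c(outcome, covars), names(records))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dat <- records[, c(outcome, covars)]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n_used <- nrow(dat)
  y <- dat[[outcome]]
  if (family == "auto") {
    family <- if (length(unique(y)) <= 2L) "logistic" else "ordinal"
  }

  # drop covariates constant in the complete-case sample (unestimable)
  keep <- vapply(covars, function(v) length(unique(dat[[v]])) > 1L, logical(1))
  dropped <- covars[!keep]
  covars <- covars[keep]
  fml <- stats::reformulate(covars, response = outcome)

  separation <- FALSE
  converged <- TRUE
  if (family == "logistic") {
    dat[[outcome]] <- as.integer(y != min(y))  # presence indicator
    fit <- withCallingHandlers(
      stats::glm(fml, data = dat, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          separation <<- TRUE
        }
        invokeRestart("muffleWarning")
      }
    )
    converged <- fit$converged
    sm <- summary(fit)$coefficients
    sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
    est <- sm[, 1L]; se <- sm[, 2L]; p <- sm[, 4L]
    if (any(abs(est) > 15)) separation <- TRUE
  } else {
    dat[[outcome]] <- collapse_count_outcome(as.numeric(y))
    if (nlevels(droplevels(dat[[outcome]])) < 2L) {
      stop("ordinal outcome is constant after collapsing", call. = FALSE)
    }
    fit <- suppressWarnings(MASS::polr(fml, data = dat, Hess = TRUE))
    converged <- fit$convergence == 0
    sm <- summary(fit)$coefficients
    # slope rows come first, before the threshold intercepts
    sm <- sm[seq_along(fit$coefficients), , drop = FALSE]
    est <- sm[, 1L]; se <- sm[, 2L]
    p <- 2 * stats::pnorm(-abs(est / se))
    if (any(abs(est) > 15)) separation <- TRUE
  }

  coef_tbl <- tibble::tibble(
    term = names(est) %||% rownames(sm),
    estimate = unname(est),
    std_error = unname(se),
    odds_ratio = exp(unname(est)),
    ci_low = exp(unname(est) - 1.96 * unname(se)),
    ci_high = exp(unname(est) + 1.96 * unname(se)),
    p_value = unname(p)
  )

  vif_tbl <- if (length(covars) >= 2L) {
    X <- stats::model.matrix(stats::reformulate(covars), data = dat)[, -1L, drop = FALSE]
    vif_screen(X)
  } else {
    tibble::tibble(term = character(), vif = numeric(), acceptable = logical())
  }

  structure(
    list(coefficients = coef_tbl, vif = vif_tbl, n_used = n_used,
         label = sprintf("%s model %s", family, model_version),
         family = family, model_version = model_version,
         outcome = outcome, covariates = covars, dropped = dropped,
         converged = converged, separation = separation, fit = fit),
    class = "bbb_model"
  )
}

#' @export
print.bbb_model <- function(x, ...) {
  cat(sprintf("<bbb_model> %s for '%s' (n = %d%s%s)\n", x$label, x$outcome,
              x$n_used,
              if (!x$converged) ", NOT converged" else "",
              if (x$separation) ", SEPARATION flagged" else ""))
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.bbb_model <- function(x, ...) {
  x$coefficients
}

#' @export
glance.bbb_model <- function(x, ...) {
  tibble::tibble(label = x$label, outcome = x$outcome, n_used = x$n_used,
                 converged = x$converged, separation = x$separation,
                 max_vif = if (nrow(x$vif)) max(x$vif$vif) else NA_real_,
                 aic = tryCatch(stats::AIC(x$fit), error = function(e) NA_real_))
}

#' Forest plot of a fitted hotspot model
#'
#' Odds ratios with 95% confidence intervals on a log scale.
#'
#' @param object A `bbb_model` object.
#' @param ... Unused.
#' @export
autoplot.bbb_model <- function(object, ...) {
  df <- object$coefficients
  ggplot2::ggplot(df, ggplot2::aes(x = .data$odds_ratio, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% CI)", y = NULL,
                  title = sprintf("%s: %s (n = %d)", object$label,
                                  object$outcome, object$n_used))
}
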