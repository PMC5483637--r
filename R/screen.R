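#' Full single-predictor classification screen
#'
#' Runs the complete per-predictor analysis over a participant table: for
#' each predictor, robust (MAD) outlier filtering per group, logistic fit,
#' within-sample accuracy with a stratified BCa bootstrap interval, LOOCV
#' accuracy with a permutation p-value, and a Welch group comparison with
#' Cohen's d on the SD-filtered values; permutation p-values are
#' Benjamini-Hochberg adjusted across predictors. Results are ranked by
#' within-sample accuracy (descending, ties broken by predictor name).
#' Predictors left with fewer than 2 observations per class after filtering
#' are skipped with a recorded reason. Given the same configuration
#' (including its seed) the screen is exactly reproducible: every
#' predictor's resampling seed is derived deterministically from the root
#' seed and the predictor name.
#'
#' @param table A data frame with a two-level `group` column (positive
#'   class `"MS"`) and numeric predictor columns.
#' @param config A [classification_config()] object.
#' @return A data frame of class `predictor_screen`, one row per analysed
#'   predictor, with attributes `skipped` (named reasons) and `config`.
#' @export
run_full_screen <- function(table, config = classification_config()) {
  stopifnot(is.data.frame(table), "group" %in% names(table),
            inherits(config, "classification_config"))
  y_all <- as_binary_labels(table$group)
  predictors <- setdiff(names(table), c("group", "participant_id"))
  predictors <- predictors[vapply(table[predictors], is.numeric, logical(1))]
  if (!length(predictors)) stop("no numeric predictor columns found")

  rows <- list()
  skipped <- character(0)
  for (name in predictors) {
    x <- table[[name]]
    ok <- is.finite(x)
    x0 <- x[ok]
    y0 <- y_all[ok]
    # robust filter, per group, single pass on unfiltered statistics
    keep <- logical(length(x0))
    for (g in unique(y0)) {
      gi <- which(y0 == g)
      if (length(gi) < 3L) {
        keep[gi] <- TRUE
        next
      }
      keep[gi] <- filter_outliers_mad(x0[gi], k = config$mad_k)$keep
    }
    xf <- x0[keep]
    yf <- y0[keep]
    if (length(unique(yf)) < 2L || min(table(yf)) < 2L) {
      skipped[name] <- "fewer than 2 observations per class after filtering"
      next
    }

    fit <- fit_logistic(xf, yf)
    boot <- bca_bootstrap_accuracy(
      xf, yf, n_boot = config$n_boot, chance = config$chance,
      seed = derive_seed(config$seed, paste0("boot:", name)))
    perm <- permutation_pvalue(
      xf, yf, n_perm = config$n_perm,
      seed = derive_seed(config$seed, paste0("perm:", name)))

    # group comparison on the SD-filtered (unfiltered-statistics) values
    a <- filter_outliers_sd(x0[y0 == 1], k = config$sd_k)$values
    b <- filter_outliers_sd(x0[y0 == 0], k = config$sd_k)$values
    cmp <- tryCatch(welch_t(a, b), error = function(e) NULL)
    d <- tryCatch(cohens_d(a, b), error = function(e) NA_real_)

    rows[[name]] <- data.frame(
      predictor = name,
      n_used = length(xf),
      n_removed = sum(!keep) + sum(!ok),
      separated = fit$separated,
      within_accuracy = boot$observed,
      bca_lcl = boot$lcl,
      bca_ucl = boot$ucl,
      significant_within = boot$significant,
      loocv_accuracy = perm$observed,
      perm_p = perm$p,
      t = if (is.null(cmp)) NA_real_ else cmp$t,
      df = if (is.null(cmp)) NA_real_ else cmp$df,
      p_welch = if (is.null(cmp)) NA_real_ else cmp$p,
      cohens_d = d,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) stop("no predictor could be analysed")
  out <- do.call(rbind, rows)
  out$bh_p <- benjamini_hochberg(out$perm_p)
  out <- out[order(-out$within_accuracy, out$predictor), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "config") <- config
  class(out) <- c("predictor_screen", "data.frame")
  out
}
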