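#' Filter entities and measures by completeness
#'
#' Entities reporting fewer than `row_completeness_min` of the measures are
#' dropped first; then measures reported by fewer than `col_completeness_min`
#' of the surviving entities are dropped. The row pass runs before the column
#' pass, so column completeness is always assessed on the filtered entities.
#'
#' @param m A [quality_matrix()].
#' @param cfg A [pipeline_config()].
#' @return A filtered [quality_matrix()].
#' @export
filter_completeness <- function(m, cfg = pipeline_config()) {
  row_frac <- rowMeans(m$observed)
  keep_rows <- row_frac >= cfg$row_completeness_min
  if (!any(keep_rows)) stop("no entities survive filters", call. = FALSE)
  obs <- m$observed[keep_rows, , drop = FALSE]
  col_frac <- colMeans(obs)
  keep_cols <- col_frac >= cfg$col_completeness_min
  if (!any(keep_cols)) stop("no measures survive filters", call. = FALSE)
  quality_matrix(
    m$values[keep_rows, keep_cols, drop = FALSE],
    m$meta[m$meta$measure_id %in% m$measure_ids[keep_cols], , drop = FALSE],
    observed = obs[, keep_cols, drop = FALSE],
    standardized = m$standardized, clipped = m$clipped, imputed = m$imputed
  )
}

#' Orient all measures so higher means better
#'
#' Measures tagged `lower_better` (mortality, readmission, complication and
#' infection rates, spending) are negated and re-tagged `higher_better`, so a
#' positive standardized score reads as good performance in every domain.
#' Idempotent: a second application is a no-op.
#'
#' @param m A [quality_matrix()].
#' @return An oriented [quality_matrix()].
#' @export
orient_measures <- function(m) {
  dir <- m$meta$direction
  bad <- setdiff(unique(dir), c("higher_better", "lower_better"))
  if (length(bad) > 0) {
    stop("unknown direction tag(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  flip <- dir == "lower_better"
  vals <- m$values
  vals[, flip] <- -vals[, flip]
  meta <- m$meta
  meta$direction <- "higher_better"
  quality_matrix(vals, meta, observed = m$observed,
                 standardized = m$standardized, clipped = m$clipped,
                 imputed = m$imputed)
}

#' Standardize each measure to mean 0, SD 1
#'
#' Per column over observed cells: subtract the mean and divide by the sample
#' standard deviation (n - 1 denominator). With
#' `cfg$standardize_method = "normal_scores"` a rank-based inverse-normal
#' (Blom) transform is applied instead.
#'
#' @param m A [quality_matrix()].
#' @param cfg A [pipeline_config()].
#' @return A standardized [quality_matrix()].
#' @export
standardize_measures <- function(m, cfg = pipeline_config()) {
  vals <- m$values
  for (j in seq_len(ncol(vals))) {
    obs <- m$observed[, j]
    x <- vals[obs, j]
    if (length(x) < 2) {
      stop("measure ", m$measure_ids[j], " has fewer than 2 observed values",
           call. = FALSE)
    }
    if (cfg$standardize_method == "normal_scores") {
      r <- rank(x, ties.method = "average")
      z <- stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
      z <- (z - mean(z)) / stats::sd(z)
      vals[obs, j] <- z
    } else {
      s <- stats::sd(x)
      if (s == 0) {
        stop("measure ", m$measure_ids[j], " is constant (zero spread)",
             call. = FALSE)
      }
      vals[obs, j] <- (x - mean(x)) / s
    }
  }
  quality_matrix(vals, m$meta, observed = m$observed,
                 standardized = TRUE, clipped = m$clipped,
                 imputed = m$imputed)
}

#' Winsorize extreme standardized values
#'
#' Observed values beyond `clip_sd` standard deviations from the mean are set
#' to the bound itself; no re-standardization follows.
#'
#' @param m A standardized [quality_matrix()].
#' @param cfg A [pipeline_config()].
#' @return A clipped [quality_matrix()].
#' @export
clip_extremes <- function(m, cfg = pipeline_config()) {
  if (!m$standardized) stop("clip_extremes expects a standardized matrix",
                            call. = FALSE)
  vals <- m$values
  vals[m$observed] <- pmin(pmax(vals[m$observed], -cfg$clip_sd), cfg$clip_sd)
  quality_matrix(vals, m$meta, observed = m$observed,
                 standardized = TRUE, clipped = TRUE, imputed = m$imputed)
}

#' Impute residual missing cells with the column mean
#'
#' After the completeness filters at most 10% of any row or column is missing.
#' Unobserved cells are set to 0 — the column mean on the standardized scale —
#' which preserves column moments. The observed mask is retained for audit.
#'
#' @param m A standardized, clipped [quality_matrix()].
#' @return An imputed [quality_matrix()].
#' @export
impute_missing <- function(m) {
  if (!m$standardized) stop("impute_missing expects a standardized matrix",
                            call. = FALSE)
  vals <- m$values
  vals[!m$observed] <- 0
  quality_matrix(vals, m$meta, observed = m$observed,
                 standardized = TRUE, clipped = m$clipped, imputed = TRUE)
}

#' Run the full preprocessing chain
#'
#' Completeness filtering, orientation, standardization, winsorization, and
#' imputation, in that order.
#'
#' @param m A raw [quality_matrix()].
#' @param cfg A [pipeline_config()].
#' @return A preprocessed [quality_matrix()].
#' @export
preprocess <- function(m, cfg = pipeline_config()) {
  m |>
    filter_completeness(cfg) |>
    orient_measures() |>
    standardize_measures(cfg) |>
    clip_extremes(cfg) |>
    impute_missing()
}
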