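#' Entity-by-measure quality matrix
#'
#' The central data container: a numeric matrix of entities (rows) by quality
#' measures (columns), a logical `observed` mask of the same shape, and a
#' per-measure metadata tibble with the measurement `domain` (process,
#' experience, value, safety, surgery, readmission, mortality) and `direction`
#' (`higher_better` / `lower_better`). Rows are an entity's performance
#' profile; columns are a measure's profile across entities.
#'
#' @param values Numeric matrix with entity ids as rownames and measure ids as
#'   colnames. `NA` cells are treated as unobserved.
#' @param meta Tibble/data frame with columns `measure_id`, `domain`,
#'   `direction`, one row per measure.
#' @param observed Optional logical matrix; defaults to `!is.na(values)`.
#' @param standardized,clipped,imputed Internal stage flags.
#'
#' @return A `quality_matrix` object.
#' @export
quality_matrix <- function(values, meta, observed = NULL,
                           standardized = FALSE, clipped = FALSE,
                           imputed = FALSE) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  entity_ids <- rownames(values)
  measure_ids <- colnames(values)
  dup_e <- entity_ids[duplicated(entity_ids)]
  if (length(dup_e) > 0) {
    stop("duplicate entity id(s): ", paste(unique(dup_e), collapse = ", "),
         call. = FALSE)
  }
  dup_m <- measure_ids[duplicated(measure_ids)]
  if (length(dup_m) > 0) {
    stop("duplicate measure id(s): ", paste(unique(dup_m), collapse = ", "),
         call. = FALSE)
  }
  meta <- tibble::as_tibble(meta)
  req <- c("measure_id", "domain", "direction")
  if (!all(req %in% names(meta))) {
    stop("meta must have columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  missing_meta <- setdiff(measure_ids, meta$measure_id)
  if (length(missing_meta) > 0) {
    stop("measure(s) missing from meta: ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  meta <- meta[match(measure_ids, meta$measure_id), , drop = FALSE]
  if (is.null(observed)) observed <- !is.na(values)
  stopifnot(is.logical(observed), all(dim(observed) == dim(values)))
  dimnames(observed) <- dimnames(values)
  if (any(!is.finite(values[observed]))) {
    stop("non-finite value in an observed cell", call. = FALSE)
  }
  structure(
    list(values = values, observed = observed, meta = meta,
         entity_ids = entity_ids, measure_ids = measure_ids,
         standardized = standardized, clipped = clipped, imputed = imputed),
    class = "quality_matrix"
  )
}

#' Load a quality matrix from CSV files
#'
#' The matrix CSV has a header row, first column `entity_id`, remaining columns
#' one per measure; empty cells (or the `na` sentinel) are missing. The
#' metadata CSV has columns `measure_id`, `domain`, `direction`.
#'
#' @param path Path to the entity-by-measure CSV.
#' @param meta_path Path to the measure-metadata CSV.
#' @param na Missing-value sentinel strings (default empty string and `"NA"`).
#' @return A [quality_matrix()].
#' @export
load_matrix <- function(path, meta_path, na = c("", "NA")) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("matrix CSV needs an entity id column plus measures",
                         call. = FALSE)
  entity_ids <- df[[1]]
  measure_ids <- names(df)[-1]
  vals <- matrix(NA_real_, nrow(df), length(measure_ids),
                 dimnames = list(entity_ids, measure_ids))
  for (j in seq_along(measure_ids)) {
    cell <- df[[j + 1]]
    is_na <- is.na(cell) | cell %in% na
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is_na & is.na(num))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric cell '%s' at row %s (entity %s), column %s",
                   cell[bad[1]], bad[1], entity_ids[bad[1]], measure_ids[j]),
           call. = FALSE)
    }
    num[is_na] <- NA_real_
    vals[, j] <- num
  }
  meta <- readr::read_csv(meta_path, show_col_types = FALSE)
  quality_matrix(vals, meta)
}

#' @export
print.quality_matrix <- function(x, ...) {
  cat(sprintf("<quality_matrix> %d entities x %d measures (%.1f%% observed)\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$observed)))
  stages <- c("standardized", "clipped", "imputed")[c(x$standardized,
                                                      x$clipped, x$imputed)]
  if (length(stages)) cat("  stages:", paste(stages, collapse = ", "), "\n")
  cat("  domains:", paste(sort(unique(x$meta$domain)), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy an entity-by-measure matrix into long form
#'
#' @param x A [quality_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `entity_id`, `measure_id`, `value`,
#'   `observed`, `domain`, `direction`.
#' @export
tidy.quality_matrix <- function(x, ...) {
  long <- tibble::tibble(
    entity_id = rep(x$entity_ids, times = length(x$measure_ids)),
    measure_id = rep(x$measure_ids, each = length(x$entity_ids)),
    value = as.vector(x$values),
    observed = as.vector(x$observed)
  )
  dplyr::left_join(long, x$meta, by = "measure_id")
}

#' @export
glance.quality_matrix <- function(x, ...) {
  tibble::tibble(
    n_entities = nrow(x$values),
    n_measures = ncol(x$values),
    frac_observed = mean(x$observed),
    n_domains = dplyr::n_distinct(x$meta$domain),
    standardized = x$standardized,
    clipped = x$clipped,
    imputed = x$imputed
  )
}

#' @export
as.matrix.quality_matrix <- function(x, ...) x$values

#' @export
dim.quality_matrix <- function(x) dim(x$values)
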