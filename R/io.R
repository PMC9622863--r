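#' Write / read a perturbation dataset as tidy CSV plus metadata JSON
#'
#' The CSV holds columns `time`, `condition` (`vehicle` or `pert_<j>`),
#' `node`, `value`; the sidecar JSON records node count, perturbation
#' strength, noise level, seed, grid and kind.
#'
#' @param ds a [perturbation_dataset].
#' @param path CSV path; the sidecar defaults to the same path with a
#'   `.json` extension.
#' @param meta_path optional explicit sidecar path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, meta_path = NULL) {
  stopifnot(inherits(ds, "perturbation_dataset"))
  if (is.null(meta_path)) meta_path <- sub("\\.csv$", ".json", path)
  write.csv(as.data.frame(ds), path, row.names = FALSE)
  meta <- list(n = ds$n, p = ds$p, d = ds$noise_d, seed = ds$seed,
               grid = ds$times, kind = ds$kind, warnings = ds$warnings)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, null = "null"),
             meta_path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- sub("\\.csv$", ".json", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::fromJSON(meta_path)
  times <- sort(unique(df$time))
  n <- meta$n
  grab <- function(cond) {
    sub <- df[df$condition == cond, ]
    m <- matrix(NA_real_, length(times), n)
    m[cbind(match(sub$time, times), sub$node)] <- sub$value
    m
  }
  perturbation_dataset(times, grab("vehicle"),
                       lapply(seq_len(n), function(j) grab(sprintf("pert_%d", j))),
                       p = meta$p, kind = meta$kind, noise_d = meta$d,
                       seed = meta$seed,
                       warnings = as.character(unlist(meta$warnings)))
}

#' Validate an on-disk dataset
#'
#' Checks grid consistency, condition completeness (vehicle plus one
#' perturbation per node), strictly increasing times and finite values,
#' returning machine-readable diagnostics rather than failing at first error.
#'
#' @param path CSV path (sidecar JSON resolved as in [read_dataset()]).
#' @param meta_path optional explicit sidecar path.
#' @return data.frame with columns `code` and `message`; zero rows when the
#'   dataset is well formed.
#' @export
validate_dataset <- function(path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- sub("\\.csv$", ".json", path)
  diag <- function(code, message) data.frame(code = code, message = message,
                                             stringsAsFactors = FALSE)
  out <- diag(character(), character())
  if (!file.exists(path)) return(diag("missing_file", path))
  if (!file.exists(meta_path)) return(diag("missing_metadata", meta_path))
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) e)
  if (inherits(df, "error")) return(diag("parse_error", conditionMessage(df)))
  need <- c("time", "condition", "node", "value")
  if (!all(need %in% names(df)))
    return(diag("missing_columns",
                paste(setdiff(need, names(df)), collapse = ", ")))
  meta <- tryCatch(jsonlite::fromJSON(meta_path), error = function(e) e)
  if (inherits(meta, "error")) return(diag("parse_error", conditionMessage(meta)))
  n <- meta$n
  expected <- c("vehicle", sprintf("pert_%d", seq_len(n)))
  missing_cond <- setdiff(expected, unique(df$condition))
  if (length(missing_cond))
    out <- rbind(out, diag("missing_condition",
                           paste(missing_cond, collapse = ", ")))
  if (!all(is.finite(df$value)))
    out <- rbind(out, diag("non_finite_value",
                           sprintf("%d non-finite values", sum(!is.finite(df$value)))))
  for (cond in intersect(expected, unique(df$condition))) {
    for (nd in seq_len(n)) {
      tt <- df$time[df$condition == cond & df$node == nd]
      if (length(tt) == 0) {
        out <- rbind(out, diag("missing_node",
                               sprintf("condition %s node %d absent", cond, nd)))
      } else if (any(diff(tt) <= 0)) {
        out <- rbind(out, diag("time_ordering",
                               sprintf("non-increasing times in %s node %d", cond, nd)))
      }
    }
  }
  grids <- tapply(df$time, df$condition, function(t) paste(sort(unique(t)), collapse = ","))
  if (length(unique(grids)) > 1)
    out <- rbind(out, diag("grid_mismatch",
                           "conditions do not share one time grid"))
  out
}

#' Write / read a single trajectory as tidy CSV
#'
#' @param tr a [trajectory].
#' @param path CSV path (columns `time`, `node`, `value`).
#' @export
write_trajectory_csv <- function(tr, path) {
  stopifnot(inherits(tr, "trajectory"))
  write.csv(as.data.frame(tr), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- read.csv(path)
  times <- sort(unique(df$time))
  n <- max(df$node)
  m <- matrix(NA_real_, length(times), n)
  m[cbind(match(df$time, times), df$node)] <- df$value
  trajectory(times, m)
}
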