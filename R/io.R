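#' Writers for trajectories, summaries, histograms and comparisons
#'
#' Plain tab-separated files with headered columns: trajectories as
#' `time` plus one column per recorded variable; ensemble summaries as
#' `time`, `mean_X`, `std_X` per variable; histograms as `value`,
#' `probability`; comparison reports as `time`, `var`, `z_mean`, `z_sd`.
#'
#' @param x The object to write (one realization slice, an
#'   `ensemble_summary`, or an `ensemble_comparison`).
#' @param path Output file path.
#' @param realization Realization index for `write_trajectory`.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(x, path, realization = 1) {
  stopifnot(inherits(x, "ensemble_states"))
  df <- data.frame(time = attr(x, "times"), x[, , realization])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
write_ensemble_summary <- function(x, path) {
  stopifnot(inherits(x, "ensemble_summary"))
  df <- data.frame(time = x$times)
  for (v in x$vars) {
    df[[paste0("mean_", v)]] <- x$mean[, v]
    df[[paste0("std_", v)]] <- x$sd[, v]
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
write_histograms <- function(x, path) {
  stopifnot(inherits(x, "ensemble_summary"))
  rows <- NULL
  for (tn in names(x$histograms)) {
    for (v in names(x$histograms[[tn]])) {
      cnt <- x$histograms[[tn]][[v]]
      rows <- rbind(rows, data.frame(
        time = as.numeric(tn), var = v,
        value = as.numeric(names(cnt)),
        probability = as.numeric(cnt) / sum(cnt)))
    }
  }
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
write_comparison <- function(x, path) {
  stopifnot(inherits(x, "ensemble_comparison"))
  df <- data.frame(time = rep(x$times, length(x$vars)),
                   var = rep(x$vars, each = length(x$times)),
                   z_mean = as.vector(x$z_mean),
                   z_sd = as.vector(x$z_sd))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(x$chisq)) {
    write.table(x$chisq, sub("(\\.[^.]+)?$", "_chisq.tsv", path, perl = TRUE),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
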