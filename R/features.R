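## Per-particle feature table assembly and interquartile-range outlier
## filtering.

#' Assemble the per-particle feature table
#'
#' Builds one row per particle from a list of [trap_fit()] results: per
#' peak the fitted amplitude `A`, centre frequency (Hz) and width (Hz);
#' per particle the conversion factor, the radius estimated from each
#' peak's width, and the mass. Particles with any non-converged peak fit
#' are excluded (with a message reporting how many).
#'
#' @param fits list of `trap_fit` objects (or a list of lists with the
#'   same structure, e.g. read back from JSON reports).
#' @param labels optional character vector of class labels; defaults to
#'   each fit's trace metadata.
#' @return a `data.frame` of class `"feature_table"`; numeric feature
#'   columns plus a `class` factor. The number of excluded particles is
#'   attached as attribute `"n_excluded"`.
#' @export
assemble_features <- function(fits, labels = NULL) {
  stopifnot(length(fits) > 0)
  ok <- vapply(fits, function(ft)
    length(ft$fits) == 3 && all(vapply(ft$fits, function(f) f$converged, TRUE)),
    TRUE)
  if (any(!ok))
    message(sum(!ok), " particle(s) excluded: non-converged peak fits")
  if (!is.null(labels)) labels <- labels[ok]
  fits <- fits[ok]
  if (length(fits) == 0) stop("no particle with three converged fits")
  rows <- lapply(seq_along(fits), function(i) {
    ft <- fits[[i]]
    lab <- if (!is.null(labels)) labels[i]
    else ft$metadata$class_label %||% NA_character_
    row <- list()
    for (p in c("f1", "f2", "f3")) {
      f <- ft$fits[[p]]
      row[[paste0(p, "_A")]] <- f$A
      row[[paste0(p, "_freq_hz")]] <- f$B / (2 * pi)
      row[[paste0(p, "_width_hz")]] <- f$C / (2 * pi)
    }
    row$gamma_v_per_m <- ft$gamma
    row$radius_f1_m <- ft$radius[["f1"]]
    row$radius_f2_m <- ft$radius[["f2"]]
    row$radius_f3_m <- ft$radius[["f3"]]
    row$mass_kg <- ft$mass
    row$class <- lab
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$class <- factor(out$class)
  num <- vapply(out, is.numeric, TRUE)
  if (anyNA(out[num])) stop("missing values in numeric feature columns")
  class(out) <- c("feature_table", "data.frame")
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Remove outliers by the interquartile-range rule
#'
#' A row is an outlier if, in any numeric column, its value lies more than
#' `k` interquartile ranges from the column median:
#' `|x - median(col)| > k * IQR(col)`. Medians and IQRs are computed once
#' on the input table (single pass; the statistics are not re-computed
#' after removals), with quartiles by linear interpolation of order
#' statistics (`stats::quantile` type 7). The class/label column is not
#' screened.
#'
#' @param table a `feature_table` (or plain data.frame with numeric
#'   feature columns).
#' @param k fence width in IQRs (default 1.5).
#' @param per_class if `TRUE`, medians/IQRs are computed within each class
#'   and the rule applied class-wise; default is global.
#' @return list with `table` (survivors, same class as input), `removed`
#'   (the removed rows plus a `reason` column naming the first offending
#'   feature), and `stats` (per-column median and IQR used).
#' @examples
#' d <- data.frame(a = c(1, 2, 3, 4, 100), b = 1)
#' remove_outliers(d)$table          # 4 survivors; 100 is fenced out
#' @export
remove_outliers <- function(table, k = 1.5, per_class = FALSE) {
  df <- as.data.frame(table)
  num_cols <- names(df)[vapply(df, is.numeric, TRUE)]
  if (nrow(df) < 4) {
    warning("fewer than 4 rows: quartiles ill-defined, nothing removed")
    return(list(table = table, removed = df[0, , drop = FALSE],
                stats = NULL))
  }
  fence <- function(d) {
    med <- vapply(d[num_cols], stats::median, 0)
    iqr <- vapply(d[num_cols], stats::IQR, 0, type = 7)
    list(median = med, iqr = iqr)
  }
  flag_rows <- function(d, st) {
    bad <- matrix(FALSE, nrow(d), length(num_cols),
                  dimnames = list(NULL, num_cols))
    for (j in num_cols)
      bad[, j] <- abs(d[[j]] - st$median[[j]]) > k * st$iqr[[j]]
    bad
  }
  bad <- matrix(FALSE, nrow(df), length(num_cols),
                dimnames = list(NULL, num_cols))
  if (!per_class) {
    stats_out <- fence(df)
    bad <- flag_rows(df, stats_out)
  } else {
    stats_out <- list()
    for (cl in unique(as.character(df$class))) {
      idx <- which(as.character(df$class) == cl)
      if (length(idx) < 4) next
      stats_out[[cl]] <- fence(df[idx, , drop = FALSE])
      bad[idx, ] <- flag_rows(df[idx, , drop = FALSE], stats_out[[cl]])
    }
  }
  out_rows <- rowSums(bad) > 0
  removed <- df[out_rows, , drop = FALSE]
  if (nrow(removed))
    removed$reason <- apply(bad[out_rows, , drop = FALSE], 1,
                            function(b) paste(num_cols[b], collapse = ","))
  kept <- table[!out_rows, , drop = FALSE]
  list(table = kept, removed = removed, stats = stats_out)
}

#' Write a feature table with a JSON metadata sidecar
#'
#' @param table a `feature_table`.
#' @param path CSV path; the sidecar is written at `paste0(path, ".json")`.
#' @param meta list of settings to record (e.g. the outlier-filter stats).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, meta = list()) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
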