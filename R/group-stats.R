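#' Paired Student t-test on per-subject feature values
#'
#' Two-sided paired t-test on the within-subject differences `a - b`.
#' Identically equal vectors (all differences exactly zero) return the
#' degenerate but well-defined result `t = 0, p = 1`; zero-variance
#' differences with a nonzero mean are an error.
#'
#' @param values_a,values_b Numeric vectors of equal length (>= 2), paired
#'   by subject.
#' @param feature,band Optional labels stored on the result.
#' @return A `paired_test_result` list: `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `mean_difference`, `direction`
#'   (sign of the mean difference), `n_pairs`, `feature`, `band`.
#' @export
paired_ttest <- function(values_a, values_b, feature = NA_character_,
                         band = NA_character_) {
  if (length(values_a) != length(values_b)) stop("paired vectors differ in length")
  n <- length(values_a)
  if (n < 2) stop("need at least 2 pairs")
  d <- values_a - values_b
  if (sd(d) == 0) {
    if (all(d == 0)) {
      res <- list(t = 0, df = n - 1, p = 1, md = 0)
    } else {
      stop("zero-variance differences with nonzero mean: t-test degenerate")
    }
  } else {
    tt <- t.test(values_a, values_b, paired = TRUE)
    res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value, md = unname(tt$estimate))
  }
  structure(list(feature = feature, band = band,
                 t_statistic = res$t, degrees_of_freedom = res$df,
                 p_value = res$p, mean_difference = res$md,
                 direction = sign(res$md), n_pairs = n),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("<paired_test_result> %s/%s: t(%d) = %.4g, p = %.4g, mean diff = %.4g\n",
              x$feature, x$band, x$degrees_of_freedom, x$t_statistic,
              x$p_value, x$mean_difference))
  invisible(x)
}

#' Build a long-format study result table
#'
#' @param subject_id,condition,band,feature,value Vectors (recycled to a
#'   common length); optional `distortion_type`.
#' @param distortion_type Optional distortion label (defaults to "all").
#' @return A `study_result_table` data frame.
#' @export
study_result_table <- function(subject_id, condition, band, feature, value,
                               distortion_type = "all") {
  out <- data.frame(subject_id = subject_id, condition = condition,
                    distortion_type = distortion_type, band = band,
                    feature = feature, value = value)
  structure(out, class = c("study_result_table", "data.frame"))
}

#' Paired comparisons of every feature x band (x distortion type)
#'
#' Aggregates the table to one value per (subject, condition, band,
#' feature, distortion) by the mean over rows (e.g. trials), then runs a
#' two-sided paired t-test between the two conditions for every
#' feature x band x distortion cell. Subjects missing either condition are
#' dropped with a warning. Raw p-values are reported as the primary
#' result; a Holm-adjusted column (`p_holm`, across all cells tested) is
#' added as a conservative extension.
#'
#' @param table A [study_result_table()] (long format).
#' @param conditions Optional length-2 character vector selecting and
#'   ordering the conditions compared (`a` vs `b`); default the two
#'   condition labels present.
#' @return Data frame with one row per feature x band x distortion:
#'   t statistic, df, p_value, p_holm, mean_difference, direction, n_pairs.
#' @export
study_summary <- function(table, conditions = NULL) {
  stopifnot(is.data.frame(table))
  if (is.null(conditions)) {
    conditions <- sort(unique(table$condition))
  }
  if (length(conditions) != 2) {
    stop("paired comparison needs exactly 2 conditions, got ",
         length(conditions))
  }
  if (!"distortion_type" %in% names(table)) table$distortion_type <- "all"
  agg <- stats::aggregate(
    value ~ subject_id + condition + distortion_type + band + feature,
    data = table, FUN = mean
  )
  cells <- unique(agg[, c("feature", "band", "distortion_type")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- agg[agg$feature == cells$feature[i] & agg$band == cells$band[i] &
                 agg$distortion_type == cells$distortion_type[i], ]
    a <- sub[sub$condition == conditions[1], c("subject_id", "value")]
    b <- sub[sub$condition == conditions[2], c("subject_id", "value")]
    common <- intersect(a$subject_id, b$subject_id)
    dropped <- setdiff(union(a$subject_id, b$subject_id), common)
    if (length(dropped)) {
      warning("dropping subject(s) missing a condition: ",
              paste(dropped, collapse = ", "))
    }
    va <- a$value[match(common, a$subject_id)]
    vb <- b$value[match(common, b$subject_id)]
    tt <- paired_ttest(va, vb, feature = cells$feature[i],
                       band = cells$band[i])
    data.frame(feature = cells$feature[i], band = cells$band[i],
               distortion_type = cells$distortion_type[i],
               condition_a = conditions[1], condition_b = conditions[2],
               t_statistic = tt$t_statistic,
               degrees_of_freedom = tt$degrees_of_freedom,
               p_value = tt$p_value,
               mean_difference = tt$mean_difference,
               direction = tt$direction, n_pairs = tt$n_pairs)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- p.adjust(out$p_value, method = "holm")
  rownames(out) <- NULL
  out
}
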