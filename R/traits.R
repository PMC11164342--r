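#' OLS slope of log CA-125 against time
#'
#' The elementary estimator behind both data-based traits: ordinary least
#' squares of natural-log CA-125 on day. The slope is in log(U/mL) per day;
#' slopes under other log bases are a constant multiple.
#'
#' @param points data.frame with columns \code{day} and \code{ca125}
#'   (positive).
#' @return The slope, or \code{NA_real_} when fewer than 2 points are given
#'   (insufficient data is a signal, not an error).
#' @export
line_slope <- function(points) {
  if (nrow(points) < 2L) return(NA_real_)
  if (any(points$ca125 <= 0)) stop("CA-125 values must be positive")
  if (length(unique(points$day)) < 2L)
    stop("degenerate window: all measurement days identical")
  x <- points$day - mean(points$day)
  y <- log(points$ca125)
  sum(x * (y - mean(y))) / sum(x^2)
}

#' Data-based resistance and aggressiveness for one patient
#'
#' For each treatment line k, the data-based resistance is the OLS slope of
#' log CA-125 over measurements falling in line k's closed on-treatment
#' interval (decline during treatment gives a negative slope); the data-based
#' aggressiveness after line k is the slope over measurements strictly
#' between the end of line k and the start of line k+1 (after the final line,
#' up to the last measurement). Slopes are absent (\code{NA}) where fewer
#' than 2 measurements fall in the window.
#'
#' @param patient a \code{\link{ca125_patient}}.
#' @return An object of class \code{trait_estimates}: list with
#'   \code{patient_id} and data.frame \code{traits} (columns
#'   \code{line_number}, \code{resistance}, \code{aggressiveness},
#'   \code{n_on}, \code{n_gap}).
#' @export
estimate_traits <- function(patient) {
  lines <- patient$schedule$lines
  m <- patient$measurements
  rows <- lapply(seq_len(nrow(lines)), function(i) {
    on <- m[m$day >= lines$start_day[i] & m$day <= lines$end_day[i], ,
            drop = FALSE]
    gap_end <- if (i < nrow(lines)) lines$start_day[i + 1L] else
      max(m$day) + 1
    gap <- m[m$day > lines$end_day[i] & m$day < gap_end, , drop = FALSE]
    res <- if (nrow(on) >= 2L && length(unique(on$day)) >= 2L)
      line_slope(on) else NA_real_
    agg <- if (nrow(gap) >= 2L && length(unique(gap$day)) >= 2L)
      line_slope(gap) else NA_real_
    data.frame(line_number = lines$line_number[i], resistance = res,
               aggressiveness = agg, n_on = nrow(on), n_gap = nrow(gap))
  })
  traits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(line_number = integer(), resistance = numeric(),
               aggressiveness = numeric(), n_on = integer(),
               n_gap = integer())
  structure(list(patient_id = patient$patient_id, traits = traits),
            class = "trait_estimates")
}

#' @export
print.trait_estimates <- function(x, ...) {
  cat("Data-based traits for patient", x$patient_id, "\n")
  print(x$traits, row.names = FALSE)
  invisible(x)
}

#' Cohort-level trait table
#'
#' Long-format table of per-line data-based resistance and aggressiveness
#' across a cohort (lines 1 to \code{max_lines}), plus a per-line summary.
#'
#' @param cohort a \code{\link{ca125_cohort}}.
#' @param max_lines largest line number tabulated (default 6).
#' @return List with \code{table} (columns \code{patient_id},
#'   \code{line_number}, \code{trait}, \code{slope}, \code{n_points}) and
#'   \code{summary} (per line and trait: \code{mean}, \code{sd}, \code{n}).
#' @export
cohort_trait_table <- function(cohort, max_lines = 6L) {
  rows <- lapply(cohort, function(p) {
    tr <- estimate_traits(p)$traits
    tr <- tr[tr$line_number <= max_lines, , drop = FALSE]
    if (nrow(tr) == 0L) return(NULL)
    rbind(
      data.frame(patient_id = p$patient_id, line_number = tr$line_number,
                 trait = "resistance", slope = tr$resistance,
                 n_points = tr$n_on),
      data.frame(patient_id = p$patient_id, line_number = tr$line_number,
                 trait = "aggressiveness", slope = tr$aggressiveness,
                 n_points = tr$n_gap)
    )
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(patient_id = character(), line_number = integer(),
                      trait = character(), slope = numeric(),
                      n_points = integer())
  rownames(tab) <- NULL
  tab <- tab[!is.na(tab$slope), , drop = FALSE]
  summ <- if (nrow(tab)) {
    agg <- stats::aggregate(slope ~ line_number + trait, data = tab,
                            FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                                n = length(v)))
    data.frame(line_number = agg$line_number, trait = agg$trait,
               mean = agg$slope[, "mean"], sd = agg$slope[, "sd"],
               n = agg$slope[, "n"])
  } else {
    data.frame(line_number = integer(), trait = character(),
               mean = numeric(), sd = numeric(), n = numeric())
  }
  list(table = tab, summary = summ)
}
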