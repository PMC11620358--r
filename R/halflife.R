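# BRIC-Seq half-life estimation. Per-gene log2 fold changes vs the 0 h
# sample are renormalized to the mean change of spike-in RNAs, then fitted
# by ordinary least squares over nested time prefixes (0-4, 0-6, 0-10,
# 0-24 h); the prefix with maximal R-squared is selected (ties -> longest
# prefix) and -1/slope is the half-life in hours. A fit is reliable when
# R-squared > 0.9 and 0 < half-life < 24 h (both strict).

#' Renormalize decay courses to the mean spike-in change
#'
#' Subtracts, at each timepoint, the mean log2 fold change of the spike-in
#' rows from every row (spike-ins included), removing global recovery
#' drift. Idempotent; preserves between-gene differences at each timepoint.
#'
#' @param courses data.frame: `gene`, `is_spikein`, then one `lfc_<t>h`
#'   column per timepoint (log2 fold change vs 0 h).
#' @return The renormalized table (spike-in column means become 0).
#' @export
spikein_renormalize <- function(courses) {
  lfc_cols <- grep("^lfc_", names(courses), value = TRUE)
  spike <- courses$is_spikein
  if (!any(spike)) stop("no spike-in rows")
  for (cl in lfc_cols)
    courses[[cl]] <- courses[[cl]] - mean(courses[[cl]][spike])
  courses
}

#' Fit an mRNA half-life from one log2 decay course
#'
#' Ordinary least squares of log2 fold change on time (intercept
#' estimated), fitted separately over every prefix of the timepoint grid
#' with at least `min_points` observations; on the log2 scale the halving
#' time is `-1/slope` hours. The selected prefix maximizes R-squared
#' (squared Pearson correlation of fitted and observed values); ties go to
#' the longest prefix. The fit is `reliable` when the selected R-squared
#' exceeds 0.9 and the half-life lies strictly between 0 and 24 h.
#'
#' @param timepoints hours, strictly increasing, first element 0.
#' @param log2fc log2 fold changes vs 0 h (so `log2fc[1]` is 0 up to
#'   normalization shifts).
#' @param gene gene label carried into the fit.
#' @param min_points minimum observations per prefix (default 3).
#' @param r2_min,halflife_max reliability bounds (strict).
#' @return Object of class `decay_fit` with components `gene`, `prefixes`
#'   (per-prefix end time, slope, intercept, r2, half_life), `selected`
#'   (row index), `slope`, `intercept`, `r2`, `half_life`, `reliable`,
#'   `timepoints`, `log2fc`.
#' @examples
#' fit_halflife(c(0, 2, 4), c(0, -0.5, -1))  # t1/2 = 4 h exactly
#' @export
fit_halflife <- function(timepoints, log2fc, gene = "gene",
                         min_points = 3L, r2_min = 0.9,
                         halflife_max = 24) {
  if (length(timepoints) != length(log2fc))
    stop("timepoints and log2fc lengths differ")
  if (is.unsorted(timepoints, strictly = TRUE) || timepoints[1L] != 0)
    stop("timepoints must be strictly increasing and start at 0")
  n <- length(timepoints)
  if (n < min_points) stop("need at least ", min_points, " timepoints")
  ends <- seq.int(min_points, n)
  rows <- lapply(ends, function(k) {
    t <- timepoints[seq_len(k)]; y <- log2fc[seq_len(k)]
    fit <- stats::lm(y ~ t)
    slope <- unname(stats::coef(fit)[2L])
    fv <- stats::fitted(fit)
    r2 <- if (stats::var(y) == 0 || stats::var(fv) == 0) 0
          else stats::cor(fv, y)^2
    data.frame(prefix_end = timepoints[k], n_points = k,
               slope = slope, intercept = unname(stats::coef(fit)[1L]),
               r2 = r2,
               half_life = if (slope < 0) -1 / slope else NA_real_)
  })
  prefixes <- do.call(rbind, rows)
  # max R2; ties broken toward the longest prefix
  sel <- which(prefixes$r2 >= max(prefixes$r2) - 1e-12)
  sel <- sel[length(sel)]
  hl <- prefixes$half_life[sel]
  structure(list(gene = gene, prefixes = prefixes, selected = sel,
                 slope = prefixes$slope[sel],
                 intercept = prefixes$intercept[sel],
                 r2 = prefixes$r2[sel], half_life = hl,
                 reliable = isTRUE(prefixes$r2[sel] > r2_min &&
                                     !is.na(hl) && hl > 0 &&
                                     hl < halflife_max),
                 timepoints = timepoints, log2fc = log2fc),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("decay_fit:", x$gene, "\n")
  cat(sprintf("  half-life %.3g h (prefix 0-%g h, R2 = %.4f, %s)\n",
              x$half_life, x$prefixes$prefix_end[x$selected], x$r2,
              if (x$reliable) "reliable" else "not reliable"))
  invisible(x)
}

#' @export
summary.decay_fit <- function(object, ...) {
  cat("BRIC-Seq decay fit for", object$gene, "\n\n")
  print(object$prefixes, row.names = FALSE)
  cat(sprintf("\nselected prefix: 0-%g h (max R2, longest on ties)\n",
              object$prefixes$prefix_end[object$selected]))
  cat(sprintf("half-life: %.4g h; reliable: %s\n",
              object$half_life, object$reliable))
  invisible(object)
}

#' @export
coef.decay_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.decay_fit <- function(object, newtimes = object$timepoints, ...) {
  object$intercept + object$slope * newtimes
}

#' @export
residuals.decay_fit <- function(object, ...) {
  object$log2fc - predict(object)
}

#' @export
plot.decay_fit <- function(x, ...) {
  plot(x$timepoints, x$log2fc, xlab = "time (h)",
       ylab = "log2 fold change vs 0 h",
       main = sprintf("%s: t1/2 = %.3g h", x$gene, x$half_life), ...)
  graphics::abline(x$intercept, x$slope, lty = 2)
  invisible(x)
}

#' Fit half-lives for a whole course table
#'
#' @param courses table as in [spikein_renormalize()] (typically its
#'   output); spike-in rows are skipped.
#' @param timepoints hours matching the `lfc_` columns in order.
#' @param ... passed to [fit_halflife()].
#' @return data.frame with one row per gene: `gene`, `slope`, `r2`,
#'   `half_life`, `prefix_end`, `reliable`.
#' @export
fit_halflives <- function(courses, timepoints = c(0, 2, 4, 6, 10, 24),
                          ...) {
  lfc_cols <- grep("^lfc_", names(courses), value = TRUE)
  if (length(lfc_cols) != length(timepoints))
    stop("timepoints do not match lfc_ columns")
  genes <- which(!courses$is_spikein)
  rows <- lapply(genes, function(i) {
    f <- fit_halflife(timepoints,
                      as.numeric(courses[i, lfc_cols]),
                      gene = courses$gene[i], ...)
    data.frame(gene = f$gene, slope = f$slope, r2 = f$r2,
               half_life = f$half_life,
               prefix_end = f$prefixes$prefix_end[f$selected],
               reliable = f$reliable, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Keep only reliable half-life fits
#'
#' Strict bounds: R-squared must exceed `r2_min` and the half-life must lie
#' strictly inside (0, `halflife_max`) hours.
#'
#' @param fits table from [fit_halflives()].
#' @param r2_min,halflife_max bounds.
#' @return Subset of `fits`.
#' @export
filter_reliable <- function(fits, r2_min = 0.9, halflife_max = 24) {
  fits[!is.na(fits$half_life) & fits$r2 > r2_min &
         fits$half_life > 0 & fits$half_life < halflife_max, ,
       drop = FALSE]
}

#' Per-gene log2 change in half-life between two conditions
#'
#' @param fitsA,fitsB fit tables (e.g. control and knockdown); only genes
#'   reliable in both conditions are compared.
#' @return data.frame `gene`, `lfc_halflife` = log2(t1/2 B / t1/2 A);
#'   attribute `n_excluded` counts genes dropped for missing/unreliable
#'   fits.
#' @export
halflife_fold_change <- function(fitsA, fitsB) {
  a <- filter_reliable(fitsA); b <- filter_reliable(fitsB)
  shared <- intersect(a$gene, b$gene)
  out <- data.frame(
    gene = shared,
    lfc_halflife = log2(b$half_life[match(shared, b$gene)] /
                          a$half_life[match(shared, a$gene)]),
    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <-
    length(union(fitsA$gene, fitsB$gene)) - length(shared)
  out
}

#' Read BRIC-Seq decay courses from TSV
#'
#' Expects columns `gene is_spikein lfc_0h lfc_2h ...`.
#' @param path TSV file.
#' @return Course data.frame.
#' @export
read_decay_courses <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  x$is_spikein <- as.logical(x$is_spikein)
  x
}

#' Write BRIC-Seq decay courses as TSV
#' @param courses course table.
#' @param path output file.
#' @export
write_decay_courses <- function(courses, path) {
  utils::write.table(courses, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
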