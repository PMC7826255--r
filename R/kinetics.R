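# Repair kinetics: per-pattern frequency trajectories across the 4-48 h
# time course and estimation of T50, the time at which a pattern reaches
# half of its maximal frequency. The parametric model is the saturation
# curve f(t) = F_max * (1 - 2^(-t / T50)), which makes T50 a direct model
# parameter (f(T50) = F_max / 2); when it fits poorly the estimator falls
# back to monotone linear interpolation of the normalized curve.

#' Construct a time course
#'
#' @param times sampling times in hours (strictly increasing).
#' @param frequencies absolute pattern frequencies (fractions of all reads).
#' @param pattern_id identifier (allele signature or category label).
#' @return a `time_course` object.
#' @export
time_course <- function(times, frequencies, pattern_id = "pattern") {
  stopifnot(length(times) == length(frequencies))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(frequencies < 0 | frequencies > 1))
    stop("frequencies must be fractions in [0, 1]")
  structure(list(pattern_id = pattern_id, times = as.numeric(times),
                 frequencies = as.numeric(frequencies)),
            class = "time_course")
}

#' Normalize a time course to its final value
#'
#' Divides every frequency by the final-timepoint frequency, so the last
#' point equals 1 (the convention used when summarising dynamic changes
#' relative to 48 h).
#'
#' @param tc a [time_course()].
#' @return the normalized `time_course`.
#' @export
normalize_to_final <- function(tc) {
  stopifnot(inherits(tc, "time_course"))
  fin <- tc$frequencies[length(tc$frequencies)]
  if (fin <= 0) stop("final-timepoint frequency is zero: pattern absent")
  tc$frequencies <- tc$frequencies / fin
  tc$normalized <- TRUE
  tc
}

#' Kinetic eligibility of a pattern
#'
#' A pattern's T50 is calculated and summarised only when (a) its maximum
#' absolute frequency exceeds 1\% and (b) its share of total indel events at
#' the final timepoint exceeds 2\%.
#'
#' @param tc a [time_course()] (absolute frequencies).
#' @param total_indels_final total edited (indel) frequency at the final
#'   timepoint, used for the share criterion.
#' @param min_abs,min_share the two thresholds (defaults 0.01 and 0.02).
#' @return logical.
#' @export
check_eligibility <- function(tc, total_indels_final, min_abs = 0.01,
                              min_share = 0.02) {
  stopifnot(inherits(tc, "time_course"))
  if (max(tc$frequencies) <= min_abs) return(FALSE)
  if (total_indels_final <= 0) return(FALSE)
  fin <- tc$frequencies[length(tc$frequencies)]
  fin / total_indels_final > min_share
}

# profile least squares: for fixed T50 the optimal F_max is closed-form
.t50_rss <- function(T50, t, y, fmax_hi = 1) {
  g <- 1 - 2^(-t / T50)
  F <- sum(y * g) / sum(g * g)
  F <- min(max(F, 1e-12), fmax_hi)
  sum((y - F * g)^2)
}

.t50_fmax <- function(T50, t, y, fmax_hi = 1) {
  g <- 1 - 2^(-t / T50)
  min(max(sum(y * g) / sum(g * g), 1e-12), fmax_hi)
}

# linear interpolation of the 0.5 crossing on the normalized curve
.interp_t50 <- function(t, y) {
  fin <- y[length(y)]
  if (fin <= 0) return(NA_real_)
  yn <- y / fin
  i <- which(yn >= 0.5)[1L]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) {
    if (yn[1L] <= 0) return(NA_real_)
    return(t[1L] * 0.5 / yn[1L])  # linear from the origin
  }
  if (yn[i] == yn[i - 1L]) return(t[i - 1L])
  t[i - 1L] + (0.5 - yn[i - 1L]) / (yn[i] - yn[i - 1L]) * (t[i] - t[i - 1L])
}

#' Fit T50 to a pattern time course
#'
#' Least-squares fit of `f(t) = F_max * (1 - 2^(-t/T50))` with bounds
#' `T50 in (0, 96]`, `F_max in (0, 1]`, profiled over `F_max` (closed form
#' for fixed T50) and optimised on T50 to high precision. If the fit
#' converges poorly (relative residual above `rss_tol`, or T50 at the upper
#' bound) the estimator falls back to monotone linear interpolation of the
#' normalized curve crossing 0.5; the method used is recorded.
#'
#' @param tc a [time_course()] (absolute frequencies).
#' @param rss_tol relative residual threshold (rss / total sum of squares)
#'   above which the parametric fit is rejected (default 0.02).
#' @param t50_max upper T50 bound in hours (default 96).
#' @param eligible eligibility flag, normally from [check_eligibility()];
#'   ineligible patterns are returned unfitted.
#' @return a `kinetic_fit`: list with `pattern_id`, `T50`, `F_max`, `rss`,
#'   `method` ("least_squares" or "interpolation"), `eligible`, `ok`.
#' @export
fit_t50 <- function(tc, rss_tol = 0.02, t50_max = 96, eligible = TRUE) {
  stopifnot(inherits(tc, "time_course"))
  out <- list(pattern_id = tc$pattern_id, T50 = NA_real_, F_max = NA_real_,
              rss = NA_real_, method = NA_character_, eligible = eligible,
              ok = FALSE)
  class(out) <- "kinetic_fit"
  if (!eligible) return(out)
  t <- tc$times; y <- tc$frequencies
  if (length(t) < 4L) stop("need at least 4 timepoints to fit T50")
  opt <- optimize(.t50_rss, c(1e-3, t50_max), t = t, y = y, tol = 1e-10)
  T50 <- opt$minimum
  # polish: local quadratic refinement around the optimum
  for (h in c(1e-4, 1e-6)) {
    r0 <- .t50_rss(T50, t, y); rp <- .t50_rss(T50 + h, t, y)
    rm <- .t50_rss(T50 - h, t, y)
    denom <- rp - 2 * r0 + rm
    if (is.finite(denom) && denom > 0) {
      step <- 0.5 * h * (rm - rp) / denom
      if (abs(step) < 10 * h) T50 <- T50 + step
    }
  }
  rss <- .t50_rss(T50, t, y)
  tss <- sum((y - mean(y))^2)
  good <- is.finite(rss) && (tss == 0 || rss <= rss_tol * tss) &&
    T50 < 0.98 * t50_max
  if (good) {
    out$T50 <- T50
    out$F_max <- .t50_fmax(T50, t, y)
    out$rss <- rss
    out$method <- "least_squares"
    out$ok <- TRUE
    return(out)
  }
  ti <- .interp_t50(t, y)
  if (is.na(ti)) {
    out$method <- "failed"
    return(out)
  }
  out$T50 <- ti
  out$F_max <- max(y)
  out$rss <- rss
  out$method <- "interpolation"
  out$ok <- TRUE
  out
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("<kinetic_fit> ", x$pattern_id, ": T50 = ",
      if (is.na(x$T50)) "NA" else sprintf("%.3f h", x$T50),
      " (", x$method, if (!x$eligible) ", ineligible", ")\n", sep = "")
  invisible(x)
}

#' Build per-pattern time courses from a series of sample tables
#'
#' Samples must share amplicon and condition and differ in `timepoint_h`.
#' Every allele signature seen at any timepoint gets a trajectory (absent =
#' frequency 0).
#'
#' @param samples list of `sample_table`s across timepoints.
#' @return list with `time_courses` (named list of [time_course()]),
#'   `total_indels_final` (edited frequency at the last timepoint).
#' @export
build_time_courses <- function(samples) {
  stopifnot(length(samples) >= 2L)
  tp <- vapply(samples, function(s) s$timepoint_h, numeric(1L))
  samples <- samples[order(tp)]
  tp <- sort(tp)
  if (anyDuplicated(tp)) stop("duplicate timepoints")
  sigs <- unique(unlist(lapply(samples, function(s) s$alleles$signature)))
  tcs <- lapply(sigs, function(sg) {
    fr <- vapply(samples, function(s) {
      i <- match(sg, s$alleles$signature)
      if (is.na(i)) 0 else s$alleles$frequency[i]
    }, numeric(1L))
    time_course(tp, fr, pattern_id = sg)
  })
  names(tcs) <- sigs
  fin <- samples[[length(samples)]]
  list(time_courses = tcs,
       total_indels_final = editing_efficiency(fin))
}

#' Fit T50 for every pattern of a time-course set and summarise by category
#'
#' @param samples list of classified `sample_table`s across timepoints (the
#'   final sample's classification columns provide the category labels).
#' @param scheme category scheme for the summary (default `"t50_bins"`).
#' @param ... passed to [fit_t50()].
#' @return list with `fits` (data.frame: pattern, category, repair class,
#'   T50, F_max, method, eligible) and `summary` (per-category mean, sd, n
#'   over eligible fits).
#' @export
kinetics_by_category <- function(samples, scheme = "t50_bins", ...) {
  btc <- build_time_courses(samples)
  fin <- samples[[which.max(vapply(samples, function(s) s$timepoint_h,
                                   numeric(1L)))]]
  al <- fin$alleles
  catcol <- paste0("cat_", scheme)
  if (!catcol %in% names(al))
    stop("samples must be classified (run classify_sample) before kinetics")
  rows <- lapply(names(btc$time_courses), function(sg) {
    tc <- btc$time_courses[[sg]]
    elig <- check_eligibility(tc, btc$total_indels_final)
    ft <- fit_t50(tc, eligible = elig, ...)
    i <- match(sg, al$signature)
    data.frame(pattern = sg,
               category = if (is.na(i)) NA_character_ else al[[catcol]][i],
               repair_class = if (is.na(i)) NA_character_
                              else al$repair_class[i],
               T50 = ft$T50, F_max = ft$F_max, method = ft$method,
               eligible = elig, stringsAsFactors = FALSE)
  })
  fits <- do.call(rbind, rows)
  summary <- summarize_t50(fits)
  list(fits = fits, summary = summary)
}

#' Summarise T50 fits per category
#'
#' @param fits data.frame with columns `category`, `T50`, `eligible` (as
#'   produced by [kinetics_by_category()]).
#' @return data.frame with per-category mean, sample sd (0 when n = 1) and n
#'   over eligible, successfully fitted patterns; empty categories are
#'   omitted with a warning.
#' @export
summarize_t50 <- function(fits) {
  use <- fits[fits$eligible & !is.na(fits$T50) & !is.na(fits$category), ,
              drop = FALSE]
  cats <- unique(fits$category[!is.na(fits$category)])
  empty <- setdiff(cats, use$category)
  if (length(empty) > 0L)
    warning("categories without eligible fits omitted: ",
            paste(empty, collapse = ", "))
  if (nrow(use) == 0L)
    return(data.frame(category = character(), mean_T50 = numeric(),
                      sd_T50 = numeric(), n = integer()))
  agg <- split(use$T50, use$category)
  data.frame(category = names(agg),
             mean_T50 = vapply(agg, mean, numeric(1L)),
             sd_T50 = vapply(agg, function(v)
               if (length(v) > 1L) sd(v) else 0, numeric(1L)),
             n = vapply(agg, length, integer(1L)),
             row.names = NULL, stringsAsFactors = FALSE)
}
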