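#' Correlation with a Fisher-z confidence interval
#'
#' Pearson (default) or Spearman correlation with a 95% CI from the Fisher
#' z-transform, `atanh(r) +/- z * 1/sqrt(n - 3)`. For Spearman the interval
#' is the usual large-sample approximation on the rank scale.
#'
#' @param x,y paired numeric vectors.
#' @param method `"pearson"` or `"spearman"`.
#' @param conf confidence level (default 0.95).
#' @return a one-row tibble: `r`, `ci_lo`, `ci_hi`, `n`, `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman"), conf = 0.95) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: one margin is constant", call. = FALSE)
  }
  r <- stats::cor(x, y, method = method)
  if (n > 3L && abs(r) < 1) {
    z <- stats::qnorm(1 - (1 - conf) / 2)
    se <- 1 / sqrt(n - 3)
    ci <- tanh(atanh(r) + c(-1, 1) * z * se)
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  tibble::tibble(r = r, ci_lo = ci[1], ci_hi = ci[2], n = n, method = method)
}

#' Technical correlation between replicate wells
#'
#' Pools, across populations, all unordered pairs of distinct technical
#' replicate indices of the same population (and timepoint), and correlates
#' the first member of each pair against the second. This is the ceiling any
#' biological correlation can reach: it reflects measurement noise only. With
#' 18 populations and 4 technical replicates it yields n = 18 * C(4,2) = 108
#' pairs.
#'
#' @param well_table per-well tibble with `infection_index` and the grouping
#'   column(s) in `by`; QC-flagged and non-infected wells are dropped.
#' @param by columns identifying a culture (default
#'   `c("population_id", "branch")`).
#' @inheritParams correlate
#' @return a one-row tibble as [correlate()].
#' @export
technical_correlation <- function(well_table, by = c("population_id", "branch"),
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  by <- intersect(by, names(well_table))
  stopifnot(length(by) > 0, "infection_index" %in% names(well_table))
  x <- well_table
  if ("qc_flag" %in% names(x)) x <- x[!x$qc_flag, ]
  if ("condition" %in% names(x)) x <- x[x$condition == "infected", ]
  groups <- split(x$infection_index, x[by], drop = TRUE)
  pairs <- lapply(groups, function(v) {
    if (length(v) < 2L) return(NULL)
    cmb <- utils::combn(length(v), 2L)
    cbind(v[cmb[1, ]], v[cmb[2, ]])
  })
  m <- do.call(rbind, pairs)
  if (is.null(m) || nrow(m) < 3L) {
    stop("need at least 3 replicate pairs across populations", call. = FALSE)
  }
  correlate(m[, 1], m[, 2], method = method)
}

#' Biological correlation between A and B replicate splits
#'
#' Correlates the per-population mean infection index of biological branch A
#' against branch B at one timepoint, paired by population id. Under no
#' heritable memory the split cultures drift apart and the correlation decays
#' to 0; under strong memory it approaches the technical ceiling.
#'
#' @param summaries either a tibble with `population_id`, `branch` (values
#'   `"A"`/`"B"`) and `mean_index` (one timepoint), or a numeric vector of A
#'   means (then `b` must give the matching B means).
#' @param b optional numeric vector of B means paired with `summaries`.
#' @inheritParams correlate
#' @return a one-row tibble as [correlate()].
#' @export
biological_correlation <- function(summaries, b = NULL,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.numeric(summaries)) {
    stopifnot(is.numeric(b), length(b) == length(summaries))
    a <- summaries
  } else {
    stopifnot(is.data.frame(summaries),
              all(c("population_id", "branch", "mean_index") %in% names(summaries)))
    wide <- split(summaries, summaries$branch)
    if (!all(c("A", "B") %in% names(wide))) {
      stop("summaries must contain both branches A and B", call. = FALSE)
    }
    ids_a <- wide$A$population_id; ids_b <- wide$B$population_id
    unpaired <- c(setdiff(ids_a, ids_b), setdiff(ids_b, ids_a))
    if (length(unpaired) > 0) {
      stop("unpaired population id(s): ", paste(unique(unpaired), collapse = ", "),
           call. = FALSE)
    }
    a <- wide$A$mean_index[order(ids_a)]
    b <- wide$B$mean_index[order(ids_b)]
  }
  if (length(a) < 3L) stop("need >= 3 populations", call. = FALSE)
  correlate(a, b, method = method)
}

#' Permutation baseline for a correlation
#'
#' The correlation expected when sample labels carry no information: one
#' margin's labels are permuted uniformly at random and the correlation is
#' recomputed per permutation. For `n <= exhaustive_max` all `n!` label
#' permutations are enumerated instead, in which case the mean permuted
#' correlation is exactly 0: each pairing `(i, j)` occurs `(n-1)!` times, so
#' the centered cross-sums cancel. (The *within*-permutation correlation of
#' two labels drawn without replacement is `-1/(n - 1)`; the mean of the
#' permutation distribution of `r` is not that quantity.)
#'
#' @param x,y paired numeric vectors (>= 4 observations).
#' @param n_perm number of random permutations (default 1000).
#' @param seed optional integer seed for the random mode.
#' @param exhaustive_max enumerate all permutations when `n` is at most this
#'   (default 7).
#' @inheritParams correlate
#' @return list with `mean_r`, `q025`, `q975`, `r` (the permutation
#'   distribution), `n_perm`, `exhaustive`.
#' @export
permutation_baseline <- function(x, y, n_perm = 1000, seed = NULL,
                                 method = c("pearson", "spearman"),
                                 exhaustive_max = 7) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4L) stop("need >= 4 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("permutation baseline undefined: constant margin", call. = FALSE)
  }
  exhaustive <- n <= exhaustive_max
  if (exhaustive) {
    perms <- .all_perms(n)
  } else {
    if (!is.null(seed)) set.seed(seed)
    perms <- t(vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)))
  }
  r <- apply(perms, 1, function(p) stats::cor(x, y[p], method = method))
  list(mean_r = mean(r),
       q025 = unname(stats::quantile(r, 0.025, type = 7)),
       q975 = unname(stats::quantile(r, 0.975, type = 7)),
       r = r, n_perm = nrow(perms), exhaustive = exhaustive)
}

# All permutations of 1..n as a matrix (n! rows); n is small by construction.
.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)), deparse.level = 0)
  }))
}

#' Early-vs-late susceptibility correlation
#'
#' Spearman rank correlation (average ranks on ties) between an early
#' infection readout (infection index at 1 dpi) and a late readout (plaque
#' counts at 4 dpi), paired by population.
#'
#' @param early numeric vector of early infection indices per population.
#' @param late numeric vector of matching late readouts (e.g. plaque counts).
#' @return a one-row tibble as [correlate()] with `method = "spearman"`.
#' @export
early_late_correlation <- function(early, late) {
  stopifnot(length(early) == length(late))
  if (length(early) < 5L) stop("need >= 5 populations", call. = FALSE)
  correlate(early, late, method = "spearman")
}

#' Temporal trend of normalized susceptibility
#'
#' Per-week mean and SD across cultures of the reference-normalized infection
#' index. A flat series at 1 with small SD indicates that relative
#' susceptibility is stable over passaging.
#'
#' @param df tibble with columns `week` and `normalized_index` (one row per
#'   culture and week).
#' @return tibble with `week`, `mean_norm`, `sd_norm`, `n`; weeks with fewer
#'   than 2 cultures are omitted with a warning.
#' @export
temporal_trend <- function(df) {
  stopifnot(is.data.frame(df), all(c("week", "normalized_index") %in% names(df)))
  out <- df |>
    dplyr::filter(is.finite(.data$normalized_index)) |>
    dplyr::group_by(.data$week) |>
    dplyr::summarise(mean_norm = mean(.data$normalized_index),
                     sd_norm = stats::sd(.data$normalized_index),
                     n = dplyr::n(), .groups = "drop")
  if (any(out$n < 2)) {
    warning(sprintf("%d week(s) omitted (fewer than 2 cultures)", sum(out$n < 2)))
    out <- out[out$n >= 2, ]
  }
  out
}

#' Recover the AR(1) persistence parameter from weekly correlations
#'
#' Under the stationary AR(1) latent model the A/B biological correlation at
#' week `t` is `rho^(2t)` times an attenuation ceiling set by measurement
#' noise (estimated by the technical correlation). Fitting
#' `log(biological_r / ceiling) = 2 t log(rho)` by least squares through the
#' origin recovers `rho`. The fit is inverse-variance weighted on the log
#' scale (`Var log r ~ (1 - r^2)^2 / (n r^2)` by the delta method), so late
#' weeks where the correlation has decayed into the noise floor do not
#' dominate the estimate.
#'
#' @param biological_r biological correlations by week (> 0 to enter the fit).
#' @param weeks matching week numbers (>= 1; week 0 is the split itself).
#' @param ceiling attenuation ceiling, e.g. the technical correlation
#'   (default 1).
#' @return the `rho` estimate in (0, 1]; the number of weeks used is attached
#'   as attribute `"n_weeks_used"`.
#' @export
recover_persistence <- function(biological_r, weeks, ceiling = 1) {
  stopifnot(length(biological_r) == length(weeks))
  .assert_scalar_number(ceiling, "ceiling")
  if (ceiling <= 0) stop("`ceiling` must be positive", call. = FALSE)
  ok <- is.finite(biological_r) & biological_r > 0 & weeks >= 1
  if (sum(ok) < length(biological_r)) {
    warning(sprintf("%d week(s) dropped from persistence fit (nonpositive or missing r)",
                    sum(!ok)))
  }
  if (sum(ok) < 2L) {
    stop("persistence fit needs >= 2 weeks with positive biological correlation",
         call. = FALSE)
  }
  r_ok <- biological_r[ok]
  y <- log(r_ok / ceiling)
  x <- 2 * weeks[ok]
  w <- r_ok^2 / (1 - pmin(r_ok, 0.99)^2)^2
  log_rho <- sum(w * x * y) / sum(w * x^2)
  rho <- min(exp(log_rho), 1)
  attr(rho, "n_weeks_used") <- sum(ok)
  rho
}
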