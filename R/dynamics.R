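# Temporal-variation statistics: coefficient of variation of metabolite
# time courses, the quadrant permutation test linking shadow prices to
# temporal variation, the Matthews correlation coefficient for sign-based
# classification, and rank/linear correlation reports.

#' Temporal variation of a metabolite time course
#'
#' The coefficient of variation CV = sd/mean of the measurements within
#' the post-perturbation window, using the sample (n-1) standard
#' deviation. CV is dimensionless and invariant to rescaling the
#' abundances.
#'
#' @param times measurement times in minutes since the perturbation
#'   (ascending).
#' @param values abundance measurements (same length as \code{times}).
#' @param window_minutes only points with \code{times <= window_minutes}
#'   enter the calculation (default 30).
#' @param include_t0 keep a baseline point labeled time 0
#'   (default \code{TRUE}).
#' @return the CV; \code{NA} with a warning if the windowed mean is
#'   (numerically) zero, in which case the metabolite should be excluded
#'   downstream.
#' @export
temporal_variation <- function(times, values, window_minutes = 30,
                               include_t0 = TRUE) {
  stopifnot(length(times) == length(values))
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  keep <- times <= window_minutes
  if (!include_t0) keep <- keep & times > 0
  x <- values[keep]
  if (length(x) < 2)
    stop("need at least 2 measurements within the window (got ",
         length(x), ")")
  mu <- mean(x)
  if (abs(mu) < 1e-12 * max(1, max(abs(x)))) {
    warning("windowed mean is zero; CV undefined")
    return(NA_real_)
  }
  stats::sd(x) / mu
}

#' Per-metabolite variation table
#'
#' Joins time-course CVs with shadow prices on metabolite id.
#'
#' @param timecourses long data.frame with \code{metabolite_id},
#'   \code{time_min}, \code{value} (as from
#'   \code{\link{read_timecourses}}).
#' @param shadow_prices named numeric vector of shadow prices.
#' @param window_minutes,include_t0 forwarded to
#'   \code{\link{temporal_variation}}.
#' @return data.frame with \code{metabolite_id}, \code{cv},
#'   \code{lambda}; metabolites lacking either input, or with undefined
#'   CV, are dropped.
#' @export
variation_table <- function(timecourses, shadow_prices,
                            window_minutes = 30, include_t0 = TRUE) {
  ids <- intersect(unique(timecourses$metabolite_id), names(shadow_prices))
  cv <- vapply(ids, function(id) {
    tc <- timecourses[timecourses$metabolite_id == id, ]
    tc <- tc[order(tc$time_min), ]
    suppressWarnings(temporal_variation(tc$time_min, tc$value,
                                        window_minutes, include_t0))
  }, numeric(1))
  out <- data.frame(metabolite_id = ids, cv = as.numeric(cv),
                    lambda = as.numeric(shadow_prices[ids]),
                    stringsAsFactors = FALSE)
  out[is.finite(out$cv), , drop = FALSE]
}

#' Quadrant permutation test of shadow price vs temporal variation
#'
#' Tests whether metabolites avoid the "forbidden" quadrant of strongly
#' negative shadow price (more negative than the center \eqn{m_S} of the
#' \eqn{\lambda} values) combined with large temporal variation (above
#' the center \eqn{m_T} of the CV values). The observed count
#' \eqn{p_{original}} of such metabolites is compared with its null
#' distribution under random re-pairings of \eqn{\lambda} and CV.
#'
#' With \code{strict = TRUE} (the default) the p-value is the fraction
#' of permutations with \eqn{p_i < p_{original}}; the \code{strict =
#' FALSE} variant uses \eqn{p_i \le p_{original}}, which on discrete
#' counts is the conservative (validity-preserving) choice and is the
#' one to use when calibrating type-I error.
#'
#' @param lambda numeric shadow prices.
#' @param cv numeric temporal variations, same length.
#' @param n_perm number of random permutations (default \code{1e5}).
#' @param center \code{"mean"} or \code{"median"}.
#' @param seed optional integer seed for the permutation stream.
#' @param strict inequality convention, see above.
#' @return object of class \code{permutation_result}: \code{m_S},
#'   \code{m_T}, \code{p_original}, \code{n_permutations},
#'   \code{p_value}, \code{center}, \code{strict}, \code{seed},
#'   \code{degenerate} (\code{TRUE}, with \code{p_value = NA}, when all
#'   \eqn{\lambda} or all CV are tied so no quadrant exists).
#' @export
permutation_test <- function(lambda, cv, n_perm = 1e5,
                             center = c("mean", "median"), seed = NULL,
                             strict = TRUE) {
  center <- match.arg(center)
  stopifnot(length(lambda) == length(cv))
  keep <- is.finite(lambda) & is.finite(cv)
  lambda <- lambda[keep]; cv <- cv[keep]
  n <- length(lambda)
  if (n < 3) stop("need at least 3 metabolites with finite lambda and CV")
  cfun <- if (center == "mean") mean else stats::median
  m_S <- cfun(lambda); m_T <- cfun(cv)
  res <- list(m_S = m_S, m_T = m_T, center = center, strict = strict,
              seed = seed, n_permutations = as.integer(n_perm))
  if (length(unique(lambda)) == 1 && length(unique(cv)) == 1) {
    res$p_original <- NA_integer_; res$p_value <- NA_real_
    res$degenerate <- TRUE
    return(structure(res, class = "permutation_result"))
  }
  a <- lambda < m_S
  b <- cv > m_T
  p_orig <- sum(a & b)
  if (!is.null(seed)) set.seed(seed)
  p_i <- vapply(seq_len(n_perm),
                function(k) sum(a[sample.int(n)] & b), integer(1))
  res$p_original <- p_orig
  res$p_value <- if (strict) mean(p_i < p_orig) else mean(p_i <= p_orig)
  res$degenerate <- FALSE
  structure(res, class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "quadrant permutation test (%s centers, %s): p_original = %s, p = %s (%d permutations)\n",
    x$center, if (x$strict) "p_i < p_orig" else "p_i <= p_orig",
    format(x$p_original), format(x$p_value), x$n_permutations))
  invisible(x)
}

#' Matthews correlation coefficient of a binary classifier
#'
#' Standard MCC from the 2x2 confusion matrix, with a label-permutation
#' p-value (two-sided on \eqn{|MCC|}, with the add-one correction).
#'
#' @param predicted logical (or 2-level) predicted labels.
#' @param observed logical (or 2-level) observed labels; both classes
#'   must be present.
#' @param n_perm permutations for the p-value (default \code{1e5});
#'   \code{0} skips it.
#' @param seed optional integer seed.
#' @return list with \code{mcc}, \code{p_value}, \code{table} (the
#'   confusion matrix), and \code{degenerate} (\code{TRUE} with
#'   \code{mcc = NA} when the predictions are single-class so the
#'   coefficient is undefined).
#' @export
mcc <- function(predicted, observed, n_perm = 1e5, seed = NULL) {
  predicted <- as.logical(predicted); observed <- as.logical(observed)
  stopifnot(length(predicted) == length(observed))
  if (length(unique(observed)) < 2)
    stop("observed labels contain a single class")
  mcc_of <- function(pred) {
    tp <- sum(pred & observed); tn <- sum(!pred & !observed)
    fp <- sum(pred & !observed); fn <- sum(!pred & observed)
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (den == 0) return(NA_real_)
    (tp * tn - fp * fn) / den
  }
  m <- mcc_of(predicted)
  tab <- table(predicted = factor(predicted, c(TRUE, FALSE)),
               observed = factor(observed, c(TRUE, FALSE)))
  if (is.na(m))
    return(list(mcc = NA_real_, p_value = NA_real_, table = tab,
                degenerate = TRUE))
  p_value <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    mi <- vapply(seq_len(n_perm), function(k) {
      v <- mcc_of(predicted[sample.int(length(predicted))])
      if (is.na(v)) 0 else v
    }, numeric(1))
    p_value <- (1 + sum(abs(mi) >= abs(m) - 1e-12)) / (1 + n_perm)
  }
  list(mcc = m, p_value = p_value, table = tab, degenerate = FALSE)
}

#' Rank and linear association between two variables
#'
#' Reports both the Spearman (rank-based, midranks for ties) and Pearson
#' (linear) correlation with their two-sided p-values, as is customary
#' when there is no a-priori reason to expect linearity.
#'
#' @param x,y numeric vectors of equal length (>= 3), finite.
#' @return list with \code{spearman_rho}, \code{spearman_p},
#'   \code{pearson_r}, \code{pearson_p}; all \code{NA} with
#'   \code{degenerate = TRUE} when either vector is constant.
#' @export
associate <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(list(spearman_rho = NA_real_, spearman_p = NA_real_,
                pearson_r = NA_real_, pearson_p = NA_real_,
                degenerate = TRUE))
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  pe <- stats::cor.test(x, y, method = "pearson")
  list(spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       degenerate = FALSE)
}
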