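# Statistics and imaging metrology.

#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum statistic with midrank ties. For small samples
#' (`m + n <= exact_max`) the null distribution is enumerated exactly over
#' all group assignments of the observed (tied) ranks; otherwise the normal
#' approximation with tie correction (and 0.5 continuity correction) is used.
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (of `x`).
#' @param exact_max largest `m + n` for exact enumeration.
#' @return list with `statistic` (rank sum of `x`), `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = c("two.sided", "less",
                                                    "greater"),
                              exact_max = 20) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(m)])
  if (m + n <= exact_max) {
    combs <- utils::combn(m + n, m)
    sums <- colSums(matrix(r[combs], nrow = m))
    tol <- 1e-9
    p <- switch(alternative,
      less      = mean(sums <= W + tol),
      greater   = mean(sums >= W - tol),
      two.sided = {
        mu <- m * (m + n + 1) / 2
        min(1, 2 * min(mean(sums <= W + tol), mean(sums >= W - tol)))
      })
    list(statistic = W, p_value = p, method = "exact enumeration")
  } else {
    N <- m + n
    mu <- m * (N + 1) / 2
    ties <- table(r)
    sig2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sig2 <= 0) return(list(statistic = W, p_value = 1,
                               method = "normal approximation"))
    z <- (W - mu)
    cc <- 0.5
    p <- switch(alternative,
      less      = stats::pnorm((z + cc) / sqrt(sig2)),
      greater   = 1 - stats::pnorm((z - cc) / sqrt(sig2)),
      two.sided = {
        zz <- (abs(z) - cc) / sqrt(sig2)
        min(1, 2 * (1 - stats::pnorm(max(zz, 0))))
      })
    list(statistic = W, p_value = p, method = "normal approximation")
  }
}

#' Empirical ROC curve and trapezoidal AUC
#'
#' Threshold sweep over the unique score values; discrete (FPR, TPR) pairs
#' are connected, tied scores moving both rates simultaneously (diagonal
#' segments), and the AUC is the summed trapezoid area.
#'
#' @param scores numeric marker values.
#' @param labels logical or two-level vector; `TRUE`/second level = positive.
#' @param direction `">"` when larger scores indicate the positive class,
#'   `"<"` for the reverse.
#' @return object of class `roc_curve`: `fpr`, `tpr` (including (0,0) and
#'   (1,1)), `auc`, `thresholds`.
#' @export
empirical_roc_auc <- function(scores, labels, direction = c(">", "<")) {
  direction <- match.arg(direction)
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  if (!is.logical(labels)) {
    u <- sort(unique(labels))
    if (length(u) != 2) stop("labels must have exactly two classes", call. = FALSE)
    labels <- labels == u[2]
  }
  if (all(labels) || !any(labels))
    stop("both classes must be present", call. = FALSE)
  s <- if (direction == ">") scores else -scores
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; lab <- labels[ord]
  uniq <- !duplicated(s, fromLast = TRUE)   # last index of each tie group
  tp <- cumsum(lab)[uniq]; fp <- cumsum(!lab)[uniq]
  tpr <- c(0, tp / sum(labels), 1)
  fpr <- c(0, fp / sum(!labels), 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr, auc = auc,
                 thresholds = c(Inf, s[uniq], -Inf)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f\n", length(x$fpr), x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlab = "False-positive rate",
                 ylab = "True-positive rate", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Krippendorff's alpha for inter-rater agreement
#'
#' Coincidence-matrix estimator with the nominal distance metric; missing
#' ratings are allowed (items need at least two ratings to be pairable).
#' The confidence interval is a seeded percentile bootstrap over items.
#'
#' @param ratings graders x items matrix (character, factor or numeric
#'   labels; `NA` = missing).
#' @param metric only `"nominal"` is implemented.
#' @param bootstrap_n bootstrap resamples for the CI (0 = no CI).
#' @param conf_level CI level.
#' @param seed RNG seed for the bootstrap.
#' @return list with `alpha`, `ci` (or `NULL`), `n_items`, `n_graders`.
#' @export
krippendorff_alpha <- function(ratings, metric = "nominal",
                               bootstrap_n = 0, conf_level = 0.95,
                               seed = 1L) {
  metric <- match.arg(metric, "nominal")
  ratings <- as.matrix(ratings)
  if (nrow(ratings) < 2) stop("need at least 2 graders", call. = FALSE)
  alpha_of <- function(cols) {
    r <- ratings[, cols, drop = FALSE]
    labs <- sort(unique(stats::na.omit(as.vector(r))))
    L <- length(labs)
    co <- matrix(0, L, L, dimnames = list(labs, labs))
    for (u in seq_len(ncol(r))) {
      vals <- r[!is.na(r[, u]), u]
      mu <- length(vals)
      if (mu < 2) next
      idx <- match(vals, labs)
      tab <- tabulate(idx, nbins = L)
      pair <- (tab %o% tab - diag(tab, L)) / (mu - 1)
      co <- co + pair
    }
    n_tot <- sum(co)
    if (n_tot <= 0) return(NA_real_)
    nc <- rowSums(co)
    Do <- n_tot - sum(diag(co))
    De <- (n_tot^2 - sum(nc^2)) / (n_tot - 1)
    if (De == 0) return(1)
    1 - Do / De
  }
  a <- alpha_of(seq_len(ncol(ratings)))
  if (is.na(a)) stop("no pairable values", call. = FALSE)
  ci <- NULL
  if (bootstrap_n > 0) {
    set.seed(as.integer(seed))
    bs <- vapply(seq_len(bootstrap_n), function(i)
      alpha_of(sample.int(ncol(ratings), replace = TRUE)), numeric(1))
    bs <- bs[!is.na(bs)]
    qs <- stats::quantile(bs, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                          names = FALSE)
    ci <- qs
  }
  list(alpha = a, ci = ci, n_items = ncol(ratings), n_graders = nrow(ratings))
}

#' Confusion-matrix classification metrics
#'
#' Accuracy, sensitivity and specificity of calls against truth, with an
#' optional positive set defining the binary grouping (e.g. neoplasia =
#' dysplasia + intramucosal cancer).
#'
#' @param calls,truth aligned label vectors.
#' @param positive_set labels counted as positive; when `NULL` the metrics
#'   are multi-class (accuracy only; sensitivity/specificity `NA`).
#' @return list with `accuracy`, `sensitivity`, `specificity` (percent) and
#'   the confusion `table`.
#' @export
classification_metrics <- function(calls, truth, positive_set = NULL) {
  if (length(calls) != length(truth))
    stop("length mismatch between calls and truth", call. = FALSE)
  tab <- table(truth = truth, call = calls)
  acc <- mean(calls == truth) * 100
  sens <- spec <- NA_real_
  if (!is.null(positive_set)) {
    pos_t <- truth %in% positive_set
    pos_c <- calls %in% positive_set
    if (!any(pos_t)) stop("empty positive class: sensitivity undefined",
                          call. = FALSE)
    if (all(pos_t)) stop("empty negative class: specificity undefined",
                         call. = FALSE)
    sens <- mean(pos_c[pos_t]) * 100
    spec <- mean(!pos_c[!pos_t]) * 100
    acc <- mean(pos_c == pos_t) * 100
  }
  list(accuracy = acc, sensitivity = sens, specificity = spec, table = tab)
}

#' Full width at half maximum of a peaked profile
#'
#' `gaussian_fit`: nonlinear least-squares Gaussian (plus constant offset),
#' `FWHM = 2 sqrt(2 ln 2) sigma` - the convention for line-spread functions
#' obtained as negative derivatives of edge-spread functions.
#' `linear_crossing`: linear interpolation of the half-maximum crossings.
#'
#' @param profile numeric profile with a single dominant peak.
#' @param spacing sample spacing (um, samples, ...); the FWHM is returned in
#'   the same unit.
#' @param method `"gaussian_fit"` or `"linear_crossing"`.
#' @return scalar FWHM.
#' @export
fwhm_of_profile <- function(profile, spacing = 1,
                            method = c("gaussian_fit", "linear_crossing")) {
  method <- match.arg(method)
  if (max(profile) == min(profile)) stop("flat profile", call. = FALSE)
  x <- (seq_along(profile) - 1) * spacing
  if (method == "gaussian_fit") {
    i0 <- which.max(profile)
    a0 <- max(profile) - min(profile)
    w <- profile - min(profile)
    s0 <- sqrt(sum(w * (x - x[i0])^2) / sum(w))
    # warnOnly + suppressWarnings: exact Gaussian inputs are zero-residual,
    # which the Gauss-Newton iteration reports as non-convergence
    fit <- suppressWarnings(
      stats::nls(profile ~ c0 + a * exp(-(x - m)^2 / (2 * s^2)),
                 start = list(c0 = min(profile), a = a0, m = x[i0],
                              s = max(s0, spacing / 2)),
                 control = stats::nls.control(warnOnly = TRUE)))
    2 * sqrt(2 * log(2)) * abs(stats::coef(fit)[["s"]])
  } else {
    half <- (max(profile) + min(profile)) / 2
    i0 <- which.max(profile)
    above <- profile >= half
    left <- right <- NA_real_
    for (i in seq(i0, 2)) if (!above[i - 1]) {
      left <- x[i - 1] + (half - profile[i - 1]) /
        (profile[i] - profile[i - 1]) * spacing
      break
    }
    for (i in seq(i0, length(profile) - 1)) if (!above[i + 1]) {
      right <- x[i] + (profile[i] - half) /
        (profile[i] - profile[i + 1]) * spacing
      break
    }
    if (is.na(left) || is.na(right)) stop("half-maximum crossing not found",
                                          call. = FALSE)
    right - left
  }
}

#' Spectral band limits of a signal
#'
#' Magnitude spectrum with linearly interpolated crossings at `level_db`
#' below the spectral peak; the centre frequency is the crossing midpoint.
#'
#' @param x time-domain signal.
#' @param fs sampling rate, Hz.
#' @param level_db level below the peak, dB (negative).
#' @return list with `f_lo`, `f_hi`, `f_centre`, `bandwidth` (Hz).
#' @export
spectral_band_limits <- function(x, fs, level_db = -6) {
  n <- length(x)
  sp <- Mod(stats::fft(x))[1:(n %/% 2 + 1)]
  f <- (seq_along(sp) - 1) * fs / n
  pk <- which.max(sp)
  thr <- sp[pk] * 10^(level_db / 20)
  cross_down <- function(idx_seq) {
    prev <- pk
    for (i in idx_seq) {
      if (sp[i] < thr) {
        f1 <- f[prev]; f2 <- f[i]
        return(f1 + (sp[prev] - thr) / (sp[prev] - sp[i]) * (f2 - f1))
      }
      prev <- i
    }
    NA_real_
  }
  f_hi <- cross_down(seq(pk + 1, length(sp)))
  f_lo <- if (pk == 1) 0 else cross_down(seq(pk - 1, 1))
  if (is.na(f_hi) || is.na(f_lo))
    stop("no -6 dB crossing found", call. = FALSE)
  list(f_lo = min(f_lo, f_hi), f_hi = max(f_lo, f_hi),
       f_centre = (f_lo + f_hi) / 2, bandwidth = abs(f_hi - f_lo))
}

#' Box-and-whisker summary
#'
#' Quartiles by linear interpolation (type 7); outliers lie beyond
#' 1.5 x IQR from the quartiles; whiskers extend to the most extreme points
#' not considered outliers.
#'
#' @param x numeric sample.
#' @return list with `median`, `q1`, `q3`, `whiskers` (length 2),
#'   `outliers`.
#' @export
box_stats <- function(x) {
  if (!length(x)) stop("empty sample", call. = FALSE)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr; hi <- q[3] + 1.5 * iqr
  out <- x[x < lo | x > hi]
  inl <- x[x >= lo & x <= hi]
  list(median = q[2], q1 = q[1], q3 = q[3],
       whiskers = c(min(inl), max(inl)), outliers = sort(out))
}

#' Read / write a graders-by-items ratings table
#'
#' CSV layout: items as rows, graders as columns (first column = item id).
#'
#' @param path CSV path.
#' @param ratings graders x items matrix for the writer.
#' @return `read_ratings` returns a graders x items matrix.
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- df[[1]]
  m
}

#' @rdname read_ratings
#' @export
write_ratings <- function(ratings, path) {
  df <- data.frame(item = colnames(ratings) %||% seq_len(ncol(ratings)),
                   t(ratings), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
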