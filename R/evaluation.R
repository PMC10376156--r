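#' Relative root-mean-square error
#'
#' `100 * RMSE / (0.5 * (range(y_true) + range(y_pred)))`: the RMSE relative
#' to the mean of the ground-truth and predicted signal ranges, in percent.
#' Scale-invariant: rescaling both series leaves it unchanged.
#'
#' @param y_true,y_pred numeric vectors of equal length (>= 2), at least one
#'   non-constant.
#' @return rRMSE in percent (>= 0).
#' @examples
#' rrmse(c(0, 1), c(1, 0))  # 100
#' @export
rrmse <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  denom <- (diff(range(y_true)) + diff(range(y_pred))) / 2
  if (denom == 0) stop("undefined metric: both series are constant")
  100 * sqrt(mean((y_true - y_pred)^2)) / denom
}

#' Coefficient of determination
#'
#' Default definition `1 - SS_res / SS_tot` (may be negative and is reported
#' as computed). `method = "cor"` returns the squared Pearson correlation
#' instead; the two agree for a perfectly calibrated linear predictor but
#' differ under bias, and curve-prediction studies use both under the same
#' name.
#'
#' @param y_true,y_pred numeric vectors of equal length (>= 2);
#'   `var(y_true) > 0` required.
#' @param method `"ss"` (residual-based, default) or `"cor"`.
#' @return R-squared, unitless.
#' @export
r_squared <- function(y_true, y_pred, method = c("ss", "cor")) {
  method <- match.arg(method)
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  if (stats::var(y_true) == 0) stop("undefined metric: var(y_true) = 0")
  if (method == "ss")
    1 - sum((y_true - y_pred)^2) / sum((y_true - mean(y_true))^2)
  else
    suppressWarnings(stats::cor(y_true, y_pred))^2
}

.output_names <- c("sag_angle", "front_angle", "sag_moment", "front_moment")

#' Subject-wise leave-one-out cross-validation of the wearable network
#'
#' For each training round and each held-out subject, the network is trained
#' on all other subjects' feature rows and evaluated on the held-out
#' subject: predictions are gait-normalized (101 points per cycle, using the
#' subject's insole events), concatenated across cycles and compared with
#' the identically normalized ground truth by [rrmse()] and [r_squared()]
#' per output. With 17 subjects and 10 rounds this yields 170 trained and
#' tested network iterates.
#'
#' Features are pre-processed once per subject via [build_features()];
#' training rows are thinned to every `train_stride`-th sample (the curves
#' are smooth and heavily oversampled at 128 Hz, and full-rate prediction
#' is still used for evaluation). Initialization seeds are derived
#' deterministically from `seed` per (round, subject); a training failure is
#' recorded in the iterate table, not fatal.
#'
#' @param cohort a [generate_cohort()] result.
#' @param config a [train_config()] (its `seed` is overridden per iterate).
#' @param n_rounds number of training rounds (default 10).
#' @param seed master seed for the round/iterate seed table.
#' @param train_stride training-row thinning factor.
#' @param n_points samples per normalized gait cycle.
#' @return An `eval_result` list: `iterates` (data frame with one row per
#'   subject x round x output), `summary` (mean/SD per output plus overall),
#'   `curves` (per-subject mean benchmark and predicted 101-point curves per
#'   output, averaged over cycles and rounds) and `n_iterates`.
#' @export
loocv <- function(cohort, config = train_config(), n_rounds = 10, seed = 1,
                  train_stride = 8, n_points = 101) {
  n_sub <- length(cohort)
  stopifnot(n_sub >= 2)
  feats <- lapply(cohort, build_features)
  set.seed(seed)
  # one initialization seed per round, shared by all held-out subjects, so
  # per-subject results do not depend on the order subjects are listed in
  round_seeds <- sample.int(.Machine$integer.max - 1, n_rounds)

  norm_mat <- function(f) {
    # n_outputs x (cycles * n_points) matrix of gait-normalized curves
    lapply(seq_len(ncol(f$Y)), function(j) {
      normalize_to_gait_percent(f$Y[, j], f$fs, f$events,
                                n_points = n_points, t0 = f$t[1])
    })
  }
  bench_cycles <- lapply(feats, norm_mat)

  rows <- list()
  pred_sum <- lapply(seq_len(n_sub), function(i)
    matrix(0, length(.output_names), n_points))
  pred_cnt <- integer(n_sub)
  for (r in seq_len(n_rounds)) {
    for (s in seq_len(n_sub)) {
      train_idx <- setdiff(seq_len(n_sub), s)
      Xtr <- do.call(rbind, lapply(feats[train_idx], function(f)
        f$X[seq(1, nrow(f$X), by = train_stride), , drop = FALSE]))
      Ytr <- do.call(rbind, lapply(feats[train_idx], function(f)
        f$Y[seq(1, nrow(f$Y), by = train_stride), , drop = FALSE]))
      cfg <- config
      cfg$seed <- round_seeds[r]
      model <- ann_model(n_in = ncol(Xtr), n_out = ncol(Ytr),
                         seed = cfg$seed)
      fit <- tryCatch(train_lm(model, Xtr, Ytr, cfg), error = identity)
      if (inherits(fit, "error")) {
        rows[[length(rows) + 1L]] <-
          data.frame(subject = s, round = r, output = .output_names,
                     r2 = NA_real_, rrmse = NA_real_,
                     stop_reason = "training_failure", epochs = NA_integer_)
        next
      }
      f <- feats[[s]]
      P <- ann_predict(fit, f$X)
      for (j in seq_along(.output_names)) {
        pm <- normalize_to_gait_percent(P[, j], f$fs, f$events,
                                        n_points = n_points, t0 = f$t[1])
        bm <- bench_cycles[[s]][[j]]
        rows[[length(rows) + 1L]] <-
          data.frame(subject = s, round = r, output = .output_names[j],
                     r2 = r_squared(as.numeric(t(bm)), as.numeric(t(pm))),
                     rrmse = rrmse(as.numeric(t(bm)), as.numeric(t(pm))),
                     stop_reason = fit$log$stop_reason,
                     epochs = nrow(fit$log$trace))
        pred_sum[[s]][j, ] <- pred_sum[[s]][j, ] + colMeans(pm)
      }
      pred_cnt[s] <- pred_cnt[s] + 1L
    }
  }
  iterates <- do.call(rbind, rows)
  ok <- !is.na(iterates$r2)
  agg <- stats::aggregate(cbind(r2, rrmse) ~ output, data = iterates[ok, ],
                          function(v) c(mean = mean(v), sd = stats::sd(v)))
  summary_df <- data.frame(output = agg$output,
                           r2_mean = agg$r2[, "mean"], r2_sd = agg$r2[, "sd"],
                           rrmse_mean = agg$rrmse[, "mean"],
                           rrmse_sd = agg$rrmse[, "sd"])
  overall <- data.frame(output = "overall",
                        r2_mean = mean(iterates$r2[ok]),
                        r2_sd = stats::sd(iterates$r2[ok]),
                        rrmse_mean = mean(iterates$rrmse[ok]),
                        rrmse_sd = stats::sd(iterates$rrmse[ok]))
  curves <- list(
    benchmark = lapply(bench_cycles, function(bc)
      do.call(rbind, lapply(bc, colMeans))),
    predicted = lapply(seq_len(n_sub), function(i)
      if (pred_cnt[i] > 0) pred_sum[[i]] / pred_cnt[i] else pred_sum[[i]]))
  structure(list(iterates = iterates,
                 summary = rbind(summary_df, overall),
                 curves = curves,
                 n_iterates = n_sub * n_rounds,
                 n_subjects = n_sub, n_rounds = n_rounds),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %d subjects x %d rounds = %d iterates\n",
              x$n_subjects, x$n_rounds, x$n_iterates))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Paired t-tests at discrete gait percents
#'
#' Two-sided paired t-tests between benchmark and predicted subject-level
#' mean curves at critical gait percents: heel strike (0%), mid-stance
#' (30%), toe off (~60%) and mid-swing (80%). Pairs with zero variance of
#' the differences are degenerate and reported as `undefined` rather than
#' an infinite t statistic.
#'
#' @param benchmark,predicted lists (one element per subject) of
#'   `n_outputs x 101` matrices of subject-mean curves, as produced in
#'   `loocv()$curves`.
#' @param points gait percents to test (must be multiples of the grid step).
#' @param alpha significance level for the `sig` flag.
#' @return Data frame: `output`, `percent`, `t`, `df`, `p`, `sig`, `note`.
#' @export
discrete_point_tests <- function(benchmark, predicted,
                                 points = c(0, 30, 60, 80), alpha = 0.05) {
  n_sub <- length(benchmark)
  if (n_sub < 3) stop("insufficient data: need at least 3 paired subjects")
  n_points <- ncol(benchmark[[1]])
  grid <- seq(0, 100, length.out = n_points)
  out <- list()
  for (j in seq_len(nrow(benchmark[[1]]))) {
    for (p in points) {
      k <- which.min(abs(grid - p))
      b <- vapply(benchmark, function(m) m[j, k], 0)
      w <- vapply(predicted, function(m) m[j, k], 0)
      d <- b - w
      if (stats::sd(d) < .Machine$double.eps^0.5) {
        identical_curves <- all(abs(d) < 1e-12)
        out[[length(out) + 1L]] <- data.frame(
          output = .output_names[j], percent = p,
          t = if (identical_curves) 0 else NA_real_,
          df = n_sub - 1L, p = if (identical_curves) 1 else NA_real_,
          sig = FALSE,
          note = if (identical_curves) "identical curves"
                 else "undefined: zero variance of non-zero differences")
      } else {
        tt <- stats::t.test(b, w, paired = TRUE)
        out[[length(out) + 1L]] <- data.frame(
          output = .output_names[j], percent = p,
          t = unname(tt$statistic), df = unname(tt$parameter),
          p = tt$p.value, sig = tt$p.value < alpha, note = "")
      }
    }
  }
  do.call(rbind, out)
}

#' Violin summary of per-subject performance values
#'
#' Statistical outliers beyond 1.5 interquartile ranges from the median are
#' removed, then a Gaussian kernel density (Silverman's bandwidth) is fitted
#' to the retained values — the violin shape — alongside their median and
#' IQR.
#'
#' @param values numeric vector (>= 3 values) of per-subject metrics.
#' @param n_grid density grid size.
#' @return List: `x`, `density` (KDE on the grid), `median`, `iqr`,
#'   `retained` (values kept), `degenerate` (TRUE when all values are
#'   identical, giving a zero-width violin).
#' @export
violin_summary <- function(values, n_grid = 512) {
  stopifnot(length(values) >= 3)
  med <- stats::median(values)
  iqr <- stats::IQR(values)
  keep <- values >= med - 1.5 * iqr & values <= med + 1.5 * iqr
  retained <- values[keep]
  if (stats::sd(retained) < .Machine$double.eps^0.5) {
    return(list(x = rep(retained[1], 2), density = c(Inf, Inf),
                median = med, iqr = iqr, retained = retained,
                degenerate = TRUE))
  }
  kde <- stats::density(retained, bw = "nrd0", kernel = "gaussian",
                        n = n_grid)
  list(x = kde$x, density = kde$y, median = stats::median(retained),
       iqr = stats::IQR(retained), retained = retained, degenerate = FALSE)
}

#' Write the evaluation report as delimited text
#'
#' One row per subject x round x output plus a summary block mirroring the
#' descriptive-statistics layout (per-output mean +/- SD of R^2 and rRMSE).
#'
#' @param result an [loocv()] result.
#' @param path output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# stairgait evaluation report", con)
  utils::write.table(result$iterates, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  writeLines("", con)
  writeLines("# summary (mean +/- sd across iterates)", con)
  utils::write.table(format(result$summary, digits = 4), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
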