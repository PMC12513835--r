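#' Fit a bounded logistic dose-response model
#'
#' Least-squares fit of `change = a + K / (1 + exp(-s (d - d50)))` with
#' box constraints (`a` in [-0.2, 0.2], `K` in [0, 3], `s` in [0.1, 20],
#' `d50` in [0, max_dose + 1]) and a multi-start over a fixed grid of
#' (d50, s) initial values; the best-RMSE converged solution is returned.
#' The plateau `a + K` is the TF's reprogramming capacity and `d50`/`s`
#' capture its dose sensitivity.
#'
#' @param doses,changes per-cell dose (ln(1+UMI)) and overall transcriptomic
#'   change. At least 20 cells spanning at least 2 ln-UMI units of dose are
#'   required.
#' @param n_d50_starts number of d50 starting values (dose quantiles).
#' @param s_starts slope starting values.
#' @return a one-row data.frame of class `dose_response_fit` with columns
#'   `a`, `K`, `d50`, `s`, `rmse`, `n_cells`, `max_dose`, `converged`.
#' @export
fit_logistic <- function(doses, changes, n_d50_starts = 5,
                         s_starts = c(0.5, 2, 8)) {
  stopifnot(length(doses) == length(changes))
  ok <- is.finite(doses) & is.finite(changes)
  doses <- doses[ok]; changes <- changes[ok]
  if (length(doses) < 20) stop("need at least 20 cells to fit")
  if (diff(range(doses)) < 2) stop("doses must span at least 2 ln-UMI units")
  max_dose <- max(doses)
  lower <- c(a = -0.2, K = 0, s = 0.1, d50 = 0)
  upper <- c(a = 0.2, K = 3, s = 20, d50 = max_dose + 1)
  resid_fn <- function(p) {
    p["a"] + p["K"] * logistic_response(doses, p["d50"], p["s"]) - changes
  }
  d50_starts <- unique(quantile(doses, seq(0.1, 0.9,
                                           length.out = n_d50_starts),
                                names = FALSE))
  K0 <- min(max(quantile(changes, 0.95, names = FALSE) - median(changes[
    doses <= quantile(doses, 0.2)]), 0.01), 3)
  best <- NULL
  for (d0 in d50_starts) {
    for (s0 in s_starts) {
      start <- c(a = 0, K = K0, s = s0, d50 = unname(min(max(d0, 0),
                                                         max_dose + 1)))
      fit <- tryCatch(
        minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                           fn = resid_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit) || !fit$info %in% 1:4) next
      rmse <- sqrt(mean(fit$fvec^2))
      if (is.null(best) || rmse < best$rmse) {
        best <- list(par = fit$par, rmse = rmse)
      }
    }
  }
  if (is.null(best)) {
    out <- data.frame(a = NA_real_, K = NA_real_, d50 = NA_real_,
                      s = NA_real_, rmse = NA_real_,
                      n_cells = length(doses), max_dose = max_dose,
                      converged = FALSE)
  } else {
    p <- best$par
    out <- data.frame(a = unname(p["a"]), K = unname(p["K"]),
                      d50 = unname(p["d50"]), s = unname(p["s"]),
                      rmse = best$rmse, n_cells = length(doses),
                      max_dose = max_dose, converged = TRUE)
  }
  class(out) <- c("dose_response_fit", class(out))
  out
}

#' Fit logistic dose-response models for every TF
#'
#' @param obs data.frame with columns `tf`, `dose`, `change` (e.g. from
#'   [simulate_dose_response_obs()] or an annotated cell table).
#' @param ... passed to [fit_logistic()].
#' @return data.frame with one fit row per TF (unfittable TFs are flagged
#'   `converged = FALSE`).
#' @export
fit_logistic_all <- function(obs, ...) {
  stopifnot(all(c("tf", "dose", "change") %in% names(obs)))
  fits <- lapply(split(obs, obs$tf), function(d) {
    f <- tryCatch(fit_logistic(d$dose, d$change, ...), error = function(e) {
      data.frame(a = NA_real_, K = NA_real_, d50 = NA_real_, s = NA_real_,
                 rmse = NA_real_, n_cells = nrow(d),
                 max_dose = suppressWarnings(max(d$dose)), converged = FALSE)
    })
    cbind(tf = d$tf[1], f)
  })
  out <- do.call(rbind, fits)
  rownames(out) <- NULL
  out
}

#' Classify TFs by reprogramming capacity and dose sensitivity
#'
#' A TF is high capacity when its fitted asymptote `a + K` exceeds the
#' capacity threshold and the asymptote is supported by the observed dose
#' range (`d50 < max_dose`); high-capacity TFs are further split into high
#' and low dose sensitivity by their midpoint `d50`. Low-capacity TFs get
#' `NA` sensitivity; unconverged fits stay unclassified.
#'
#' @param fits data.frame of fits (from [fit_logistic_all()] or a single
#'   [fit_logistic()] row).
#' @param capacity_threshold change threshold on the asymptote (default
#'   0.23, the functional-change cutoff).
#' @param sensitivity_threshold_d50 midpoint threshold; default is the
#'   median `d50` of the high-capacity TFs in `fits` (data-driven split).
#' @return `fits` with `capacity_class` (`"high"`/`"low"`/`NA`) and
#'   `sensitivity_class` (`"high"`/`"low"`/`NA`) columns.
#' @export
classify_tf <- function(fits, capacity_threshold = 0.23,
                        sensitivity_threshold_d50 = NULL) {
  stopifnot(is.data.frame(fits))
  cap <- ifelse(!fits$converged, NA_character_,
                ifelse(fits$a + fits$K > capacity_threshold &
                         fits$d50 < fits$max_dose, "high", "low"))
  if (is.null(sensitivity_threshold_d50)) {
    hi <- which(!is.na(cap) & cap == "high")
    sensitivity_threshold_d50 <- if (length(hi)) median(fits$d50[hi]) else NA
  }
  sens <- ifelse(is.na(cap) | cap != "high", NA_character_,
                 ifelse(fits$d50 <= sensitivity_threshold_d50, "high", "low"))
  fits$capacity_class <- cap
  fits$sensitivity_class <- sens
  attr(fits, "sensitivity_threshold_d50") <- sensitivity_threshold_d50
  fits
}

#' Truncation power analysis for low-capacity calls
#'
#' For every high-capacity TF, cells above a descending grid of dose
#' thresholds (from the TF's max dose down to 2, step `step`) are removed,
#' the logistic model refitted and the TF re-classified; refit failures
#' count as misclassification. The pooled (max dose, still-correct) pairs
#' feed a binomial-logit regression of correct classification on max dose,
#' whose prediction at each low-capacity TF's observed max dose gives that
#' TF's probability of being falsely called low capacity.
#'
#' @param fits classified fits (from [classify_tf()]).
#' @param obs per-cell data.frame `tf`, `dose`, `change`.
#' @param step truncation grid step in ln-UMI units (default 0.25).
#' @param min_threshold lowest truncation threshold (default 2).
#' @param capacity_threshold passed to [classify_tf()].
#' @return list with `truncation` (per TF x threshold outcomes), `model`
#'   (the fitted glm), `curve` (predicted correctness over a max-dose grid)
#'   and `p_false_low` (per low-capacity TF).
#' @export
power_analysis <- function(fits, obs, step = 0.25, min_threshold = 2,
                           capacity_threshold = 0.23) {
  stopifnot("capacity_class" %in% names(fits))
  high <- fits[!is.na(fits$capacity_class) & fits$capacity_class == "high", ]
  if (nrow(high) < 5) stop("need at least 5 high-capacity TFs")
  rows <- list()
  for (i in seq_len(nrow(high))) {
    tf <- high$tf[i]
    d <- obs[obs$tf == tf, ]
    thresholds <- seq(high$max_dose[i], min_threshold, by = -step)
    for (t in thresholds) {
      keep <- d$dose <= t
      refit <- tryCatch(fit_logistic(d$dose[keep], d$change[keep]),
                        error = function(e) NULL)
      correct <- FALSE
      if (!is.null(refit) && refit$converged) {
        cls <- classify_tf(refit, capacity_threshold = capacity_threshold,
                           sensitivity_threshold_d50 = Inf)
        correct <- identical(cls$capacity_class, "high")
      }
      rows[[length(rows) + 1]] <- data.frame(
        tf = tf, threshold = t,
        max_dose = if (any(keep)) max(d$dose[keep]) else NA_real_,
        correct = correct)
    }
  }
  trunc <- do.call(rbind, rows)
  trunc <- trunc[is.finite(trunc$max_dose), ]
  model <- glm(correct ~ max_dose, family = binomial(), data = trunc)
  grid <- data.frame(max_dose = seq(min(trunc$max_dose),
                                    max(trunc$max_dose), length.out = 100))
  grid$p_correct <- predict(model, grid, type = "response")
  low <- fits[!is.na(fits$capacity_class) & fits$capacity_class == "low", ]
  p_false_low <- data.frame(
    tf = low$tf, max_dose = low$max_dose,
    p_false_low = 1 - predict(model,
                              data.frame(max_dose = low$max_dose),
                              type = "response"))
  rownames(p_false_low) <- NULL
  list(truncation = trunc, model = model, curve = grid,
       p_false_low = p_false_low)
}
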