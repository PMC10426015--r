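#' Highest posterior density interval
#'
#' The shortest contiguous interval over the sorted draws containing
#' `ceil(mass * n)` of them. Ties between equally short windows are broken in
#' favour of the left-most window, for reproducibility.
#'
#' @param samples numeric vector of posterior draws (>= 50).
#' @param mass interval mass in (0, 1). Default 0.9.
#' @return named numeric vector `c(lower, upper)`.
#' @export
hpdi <- function(samples, mass = 0.9) {
  stopifnot(mass > 0, mass < 1)
  n <- length(samples)
  if (n < 50) stop("need at least 50 samples for an HPDI", call. = FALSE)
  w <- ceiling(mass * n)
  if (w > n) stop("window larger than sample", call. = FALSE)
  s <- sort(samples)
  if (w == n) return(c(lower = s[1], upper = s[n]))
  widths <- s[w:n] - s[1:(n - w + 1)]
  i <- which.min(widths)  # which.min takes the first minimum
  c(lower = s[i], upper = s[i + w - 1])
}

#' Probability of direction
#'
#' The share of draws strictly on the posterior median's side of zero; an
#' index in `[0.5, 1]` of how certain the sign of an effect is. Draws exactly
#' at zero count toward neither side, and a median of exactly zero returns
#' 0.5. Defined for any sample size (50+ draws recommended for a stable
#' estimate).
#'
#' @param samples non-empty numeric vector of posterior draws.
#' @return scalar in `[0.5, 1]`.
#' @export
probability_of_direction <- function(samples) {
  if (length(samples) < 1) stop("need at least 1 sample", call. = FALSE)
  med <- stats::median(samples)
  if (med == 0) return(0.5)
  if (med > 0) mean(samples > 0) else mean(samples < 0)
}

#' Classify the evidence for an effect
#'
#' `"strong"` if the 90% HPDI excludes zero, else `"moderate"` if the 80%
#' HPDI excludes zero, else `"weak"`.
#'
#' @param hpdi90,hpdi80 length-2 intervals from [hpdi()] on the same draws.
#' @return one of `"strong"`, `"moderate"`, `"weak"`.
#' @export
classify_evidence <- function(hpdi90, hpdi80) {
  excludes0 <- function(iv) iv[1] > 0 || iv[2] < 0
  if (excludes0(hpdi90)) "strong" else if (excludes0(hpdi80)) "moderate" else "weak"
}

#' Summarise slope posteriors
#'
#' One row per outcome x predictor (in model-spec order): posterior median
#' log-odds, 90% HPDI, probability of direction, and evidence class. A row is
#' flagged when the median falls outside its 90% HPDI (possible only for
#' pathological multimodal posteriors).
#'
#' @param fit a `punish_fit`.
#' @return data.frame with columns outcome, predictor, median, hpdi90_lo,
#'   hpdi90_hi, pd, class, median_in_hpdi.
#' @export
summarize_effects <- function(fit) {
  stopifnot(inherits(fit, "punish_fit"))
  if (is.null(fit$draws$beta)) stop("fit contains no slope draws (beta)", call. = FALSE)
  outs <- fit$outcome_names
  preds <- fit$predictor_names
  rows <- vector("list", length(outs) * length(preds))
  r <- 0L
  for (k in seq_along(outs)) {
    for (p in seq_along(preds)) {
      b <- fit$draws$beta[, k, p]
      h90 <- hpdi(b, 0.9)
      h80 <- hpdi(b, 0.8)
      med <- stats::median(b)
      r <- r + 1L
      rows[[r]] <- data.frame(
        outcome = outs[k], predictor = preds[p],
        median = med, hpdi90_lo = h90[[1]], hpdi90_hi = h90[[2]],
        pd = probability_of_direction(b),
        class = classify_evidence(h90, h80),
        median_in_hpdi = med >= h90[[1]] && med <= h90[[2]],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(!out$median_in_hpdi)) {
    warning("posterior median outside its 90% HPDI for some effects (flagged rows)",
            call. = FALSE)
  }
  out
}

#' Write an effect-summary table to CSV and JSON
#'
#' @param summary data.frame from [summarize_effects()].
#' @param path_csv CSV output path; a `.json` mirror is written alongside.
#' @export
write_effect_summary <- function(summary, path_csv) {
  utils::write.csv(summary, path_csv, row.names = FALSE)
  jsonlite::write_json(summary, sub("\\.csv$", ".json", path_csv),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path_csv)
}
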