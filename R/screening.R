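#' Median/MAD outlier mask
#'
#' Robust screening rule: a value `x` is excluded when
#' `|x - median| > k * b * MAD` with `MAD = median(|x - median|)` and the
#' consistency constant `b = 1.4826` that makes the scaled MAD estimate the
#' SD under normality. With `k = 2.5` a Gaussian sample therefore loses
#' about `2 * (1 - pnorm(2.5))`, i.e. 1.24 percent, of its values.
#'
#' A zero MAD (for instance more than half the values identical) would
#' exclude everything not exactly at the median; the rule then degenerates
#' and nothing is excluded (with a warning). Non-finite values are always
#' excluded.
#'
#' @param values Numeric vector (at least 3 finite values).
#' @param k Threshold in scaled MAD units.
#' @param b Consistency constant.
#' @return Logical vector, `TRUE` = keep.
#' @examples
#' mad_mask(c(1, 2, 3, 4, 100))  # only 100 excluded
#' @export
mad_mask <- function(values, k = 2.5, b = 1.4826) {
  fin <- is.finite(values)
  if (sum(fin) < 3L) stop("need at least 3 finite values to screen")
  med <- stats::median(values[fin])
  mad_raw <- stats::median(abs(values[fin] - med))
  if (mad_raw == 0) {
    warning("MAD is zero; degenerate screening excludes nothing")
    return(fin)
  }
  fin & (abs(values - med) <= k * b * mad_raw)
}

#' Screen a study's estimate records
#'
#' Applies the median/MAD rule to the estimate table in the two pools the
#' analysis uses: all JND values together, and the per-cell pre-to-post
#' differences of the cued-PSS distance (`post - pre` within participant x
#' session x condition) together. An excluded difference removes both its
#' pre and post distance rows. Flagged estimates (non-converged fits,
#' negative slopes) enter the pools like any other value; non-finite values
#' are excluded outright. Cells missing one phase cannot form a difference
#' and are left unscreened.
#'
#' `scope = "per_group"` instead pools JND values within each condition x
#' phase cell and PSS differences within each condition, for sensitivity
#' checks against alternative readings of the pooling rule.
#'
#' @param estimates Estimate records, as from [estimate_study()].
#' @param k,b Passed to [mad_mask()].
#' @param scope `"pooled"` (default) or `"per_group"`.
#' @return An object of class `toj_screen`: list with `estimates` (the
#'   surviving records), `report` (exclusion counts and fractions) and
#'   `excluded` (the removed records with reasons).
#' @export
screen_estimates <- function(estimates, k = 2.5, b = 1.4826,
                             scope = c("pooled", "per_group")) {
  scope <- match.arg(scope)
  stopifnot(all(c("participant", "session", "phase", "condition",
                  "kind", "value") %in% names(estimates)))
  drop <- rep(FALSE, nrow(estimates))
  reason <- rep(NA_character_, nrow(estimates))

  jnd_i <- which(estimates$kind == "JND")
  if (length(jnd_i) >= 3L) {
    grp <- if (scope == "pooled") rep(1L, length(jnd_i)) else
      paste(estimates$condition[jnd_i], estimates$phase[jnd_i])
    for (g in unique(grp)) {
      ii <- jnd_i[grp == g]
      keep <- mad_mask(estimates$value[ii], k, b)
      drop[ii[!keep]] <- TRUE
      reason[ii[!keep]] <- ifelse(is.finite(estimates$value[ii[!keep]]),
                                  "JND beyond MAD bound", "non-finite JND")
    }
  }

  d_i <- which(estimates$kind == "PSS_distance")
  if (length(d_i)) {
    dd <- estimates[d_i, ]
    key <- paste(dd$participant, dd$session, dd$condition, sep = "\r")
    pre <- dd$phase == "pre"
    pre_val <- stats::setNames(dd$value[pre], key[pre])
    post_val <- stats::setNames(dd$value[!pre], key[!pre])
    common <- intersect(names(pre_val), names(post_val))
    if (length(common) >= 3L) {
      diffs <- post_val[common] - pre_val[common]
      grp <- if (scope == "pooled") rep(1L, length(common)) else
        vapply(strsplit(common, "\r"), `[`, "", 3L)
      for (g in unique(grp)) {
        ii <- which(grp == g)
        keep <- mad_mask(diffs[ii], k, b)
        for (bk in common[ii[!keep]]) {
          sel <- d_i[key == bk]
          drop[sel] <- TRUE
          reason[sel] <- if (is.finite(diffs[[bk]]))
            "PSS pre-post difference beyond MAD bound" else
              "non-finite PSS difference"
        }
      }
    }
  }

  n_jnd <- length(jnd_i); n_pss <- length(d_i)
  report <- list(
    jnd_total = n_jnd, jnd_excluded = sum(drop[jnd_i]),
    jnd_fraction = if (n_jnd) sum(drop[jnd_i]) / n_jnd else NA_real_,
    pss_total = n_pss, pss_excluded = sum(drop[d_i]),
    pss_fraction = if (n_pss) sum(drop[d_i]) / n_pss else NA_real_,
    k = k, b = b, scope = scope)
  excluded <- estimates[drop, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- reason[drop]
  structure(list(estimates = estimates[!drop, , drop = FALSE],
                 report = report, excluded = excluded),
            class = "toj_screen")
}

#' @export
print.toj_screen <- function(x, ...) {
  r <- x$report
  cat("MAD screening (k =", r$k, ", b =", r$b, ", scope =", r$scope, ")\n")
  cat(sprintf("  JND: %d of %d excluded (%.1f%%)\n",
              r$jnd_excluded, r$jnd_total, 100 * r$jnd_fraction))
  cat(sprintf("  PSS distance: %d of %d rows excluded (%.1f%%)\n",
              r$pss_excluded, r$pss_total, 100 * r$pss_fraction))
  invisible(x)
}
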