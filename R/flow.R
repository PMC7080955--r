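#' Default AFSS item-to-subscale mapping
#'
#' The 26-item Activity Flow State Scale covers the nine flow dimensions
#' with subscale sizes 3, 3, 4, 2, 3, 3, 2, 3, 3 (merging of action and
#' awareness; clear goals; concentration; unambiguous feedback;
#' challenge-skill balance; transformation of time; sense of control; loss
#' of self-consciousness; autotelic experience). The published instrument's
#' exact item ordering is not reproduced here; by default items 1..26 are
#' assigned to subscales consecutively, and any alternative assignment with
#' the same subscale sizes can be supplied wherever a mapping is accepted.
#'
#' @return Named list mapping subscale code to item indices.
#' @export
afss_mapping <- function() {
  sizes <- c(MAA = 3, CG = 3, CO = 4, UF = 2, CS = 3, TT = 3,
             CN = 2, SC = 3, AE = 3)
  idx <- split(seq_len(sum(sizes)), rep(names(sizes), sizes))
  idx[names(sizes)]
}

#' Score one AFSS response set
#'
#' Computes the nine subscale means and the global flow score (the mean of
#' all items) from 26 Likert responses.
#'
#' @param items Integer vector of 26 responses in 1..5.
#' @param mapping Item-to-subscale mapping, as from [afss_mapping()].
#' @return List with `subscale_means` (named, in scale order) and
#'   `global_flow`.
#' @examples
#' score_afss(rep(3L, 26))$global_flow  # 3
#' @export
score_afss <- function(items, mapping = afss_mapping()) {
  n <- sum(lengths(mapping))
  if (length(items) != n)
    stop(sprintf("expected %d item responses, got %d", n, length(items)))
  if (anyNA(items) || !all(items == round(items)) ||
      any(items < 1) || any(items > 5))
    stop("item responses must be integers in 1..5 with no missing values")
  list(subscale_means = vapply(mapping, function(ix) mean(items[ix]), 0),
       global_flow = mean(items))
}

#' Score a questionnaire table into per-session flow records
#'
#' Applies [score_afss()] row-wise to a questionnaire table. Rows failing
#' validation (out-of-range or missing items) are rejected and listed with
#' reasons rather than stopping the run.
#'
#' @param questionnaire Data frame with columns `participant`, `session`,
#'   `item_1` .. `item_26` and `control_q`.
#' @param mapping Item-to-subscale mapping.
#' @return Data frame with `participant`, `session`, one column per
#'   subscale mean, `global_flow` and `control_q`; rejected rows are
#'   attached as the `"rejected"` attribute.
#' @export
score_flow_table <- function(questionnaire, mapping = afss_mapping()) {
  item_cols <- paste0("item_", seq_len(sum(lengths(mapping))))
  miss <- setdiff(c("participant", "session", item_cols, "control_q"),
                  names(questionnaire))
  if (length(miss)) stop("questionnaire lacks columns: ", paste(miss, collapse = ", "))
  out <- list(); rejected <- list()
  for (r in seq_len(nrow(questionnaire))) {
    row <- questionnaire[r, ]
    sc <- tryCatch(score_afss(as.numeric(row[item_cols]), mapping),
                   error = function(e) conditionMessage(e))
    if (is.character(sc)) {
      rejected[[length(rejected) + 1L]] <-
        data.frame(participant = row$participant, session = row$session,
                   reason = sc, stringsAsFactors = FALSE)
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      participant = row$participant, session = row$session,
      t(sc$subscale_means), global_flow = sc$global_flow,
      control_q = row$control_q, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(participant = numeric(), session = numeric())
  attr(res, "rejected") <- if (length(rejected)) do.call(rbind, rejected) else NULL
  res
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' \deqn{\alpha = \frac{k}{k-1}\Big(1 - \frac{\sum_i s_i^2}{s_T^2}\Big)}
#' where \eqn{s_i^2} are the item variances and \eqn{s_T^2} the variance of
#' the respondent total scores, all with the sample (n-1) denominator.
#'
#' @param item_matrix Numeric matrix or data frame, respondents in rows,
#'   items in columns (at least 2 of each).
#' @return Alpha (scalar).
#' @examples
#' cronbach_alpha(cbind(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))  # 1
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need at least 2 respondents and 2 items")
  if (anyNA(m)) stop("missing responses are not supported")
  k <- ncol(m)
  total_var <- stats::var(rowSums(m))
  if (total_var == 0)
    stop("total-score variance is zero; alpha is undefined")
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}
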