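#' Per-participant mean \eqn{\Delta}PD summaries
#'
#' The scalar dependent variable for the supporting ANOVAs: the mean of
#' non-missing \eqn{\Delta}PD samples per participant and block.
#'
#' @param clean tidy clean data frame from [preprocess()].
#' @return Data frame: `participant_id`, `group`, `block_id`, `mean_dpd_mm`
#'   (one row per participant x block; all-missing series are omitted with a
#'   message).
#' @export
summarize_timecourses <- function(clean) {
  if (nrow(clean) == 0)
    return(data.frame(participant_id = character(0), group = character(0),
                      block_id = integer(0), mean_dpd_mm = numeric(0),
                      stringsAsFactors = FALSE))
  key <- interaction(clean$participant_id, clean$block_id, drop = TRUE)
  rows <- lapply(split(clean, key), function(df) {
    m <- mean(df$dpd_mm, na.rm = TRUE)
    if (is.nan(m)) {
      message(sprintf("participant %s block %s: no observed samples; omitted",
                      df$participant_id[1], df$block_id[1]))
      return(NULL)
    }
    data.frame(participant_id = df$participant_id[1], group = df$group[1],
               block_id = df$block_id[1], mean_dpd_mm = m,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$group, out$participant_id, out$block_id), , drop = FALSE]
}

anova_result <- function(effect, F, df_num, df_den, p) {
  data.frame(effect = effect, F = F, df_num = df_num, df_den = df_den, p = p,
             stringsAsFactors = FALSE)
}

#' One-way fixed-effects ANOVA
#'
#' Classical between-groups F from sums of squares.
#'
#' @param values numeric response.
#' @param factor_ grouping variable (coerced to factor).
#' @return One-row data frame: `effect`, `F`, `df_num`, `df_den`, `p`.
#' @export
oneway_anova <- function(values, factor_) {
  f <- factor(factor_)
  ok <- !is.na(values) & !is.na(f)
  values <- values[ok]
  f <- droplevels(f[ok])
  k <- nlevels(f)
  if (k < 2) stop_pw("one-way ANOVA needs >= 2 levels", "pw_input_error")
  if (any(table(f) < 2))
    stop_pw("one-way ANOVA needs >= 2 observations per level",
            "pw_input_error")
  n <- length(values)
  grand <- mean(values)
  means <- tapply(values, f, mean)
  ns <- tapply(values, f, length)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(tapply(values, f, function(v) sum((v - mean(v))^2)))
  Fstat <- (ssb / (k - 1)) / (ssw / (n - k))
  anova_result(deparse(substitute(factor_)), Fstat, k - 1L, n - k,
               pf(Fstat, k - 1, n - k, lower.tail = FALSE))
}

rss_of <- function(y, mm) {
  q <- qr(mm)
  list(rss = sum(qr.resid(q, y)^2), rank = q$rank)
}

#' Two-way fixed-effects ANOVA with Type II sums of squares
#'
#' Main effects are each adjusted for the other main effect (ignoring the
#' interaction) and the interaction for both mains, so unbalanced cell sizes
#' are handled; in balanced designs Type II reduces to the classical
#' decomposition.
#'
#' @param values numeric response.
#' @param factorA,factorB crossed grouping variables.
#' @return Data frame with rows for `A`, `B` and `A:B`.
#' @export
twoway_anova <- function(values, factorA, factorB) {
  fA <- factor(factorA)
  fB <- factor(factorB)
  ok <- !is.na(values) & !is.na(fA) & !is.na(fB)
  y <- values[ok]
  fA <- droplevels(fA[ok])
  fB <- droplevels(fB[ok])
  if (nlevels(fA) < 2 || nlevels(fB) < 2)
    stop_pw("two-way ANOVA needs >= 2 levels per factor", "pw_input_error")
  cells <- table(fA, fB)
  if (any(cells == 0)) {
    empties <- which(cells == 0, arr.ind = TRUE)
    stop_pw(paste0("empty design cells: ",
                   paste(sprintf("%s:%s", rownames(cells)[empties[, 1]],
                                 colnames(cells)[empties[, 2]]),
                         collapse = ", ")), "pw_input_error")
  }
  d <- data.frame(y = y, A = fA, B = fB)
  m_full <- rss_of(y, model.matrix(~ A * B, d))
  m_ab <- rss_of(y, model.matrix(~ A + B, d))
  m_a <- rss_of(y, model.matrix(~ A, d))
  m_b <- rss_of(y, model.matrix(~ B, d))
  df_e <- length(y) - m_full$rank
  if (df_e <= 0)
    stop_pw("interaction untestable: no residual degrees of freedom (single observation per cell?)",
            "pw_input_error")
  mse <- m_full$rss / df_e
  row <- function(name, ss, df_num) {
    Fstat <- (ss / df_num) / mse
    anova_result(name, Fstat, df_num, df_e,
                 pf(Fstat, df_num, df_e, lower.tail = FALSE))
  }
  rbind(row("A", m_b$rss - m_ab$rss, m_ab$rank - m_b$rank),
        row("B", m_a$rss - m_ab$rss, m_ab$rank - m_a$rank),
        row("A:B", m_ab$rss - m_full$rss, m_full$rank - m_ab$rank))
}

#' Post hoc pairwise Welch comparisons
#'
#' All pairwise unequal-variance t-tests between factor levels, two-sided,
#' with multiplicity adjustment (Holm by default).
#'
#' @param values numeric response.
#' @param factor_ grouping variable.
#' @param method adjustment passed to [stats::p.adjust()].
#' @return Data frame: `group1`, `group2`, `diff`, `t`, `df`, `p`, `p_adj`.
#' @export
posthoc_pairwise <- function(values, factor_, method = "holm") {
  f <- factor(factor_)
  ok <- !is.na(values) & !is.na(f)
  values <- values[ok]
  f <- droplevels(f[ok])
  levs <- levels(f)
  if (length(levs) < 2)
    stop_pw("post hoc comparison needs >= 2 groups", "pw_input_error")
  pairs <- utils::combn(levs, 2)
  rows <- apply(pairs, 2, function(pr) {
    a <- values[f == pr[1]]
    b <- values[f == pr[2]]
    w <- welch_from_moments(mean(a), var(a), length(a),
                            mean(b), var(b), length(b))
    data.frame(group1 = pr[1], group2 = pr[2], diff = mean(a) - mean(b),
               t = w$t, df = w$df, p = 2 * pt(-abs(w$t), w$df),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = method)
  rownames(out) <- NULL
  out
}
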