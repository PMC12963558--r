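#' Two-by-two mixed repeated-measures ANOVA
#'
#' Fits the classic mixed design with one two-level within-subject factor
#' (e.g. interface condition) and one two-level between-subject factor
#' (e.g. expertise group), possibly unbalanced between groups. The
#' between-subject sum of squares is split into the group effect and
#' subjects-within-groups (the between error term); the within-subject sum
#' of squares into the condition effect, the condition x group interaction,
#' and condition x subjects-within-groups (the within error term). Effects
#' are computed on unweighted cell means, so under group imbalance the sums
#' of squares coincide with the Type III convention. F ratios use the error
#' term of their stratum, p-values come from the F distribution, and both
#' eta-squared conventions are reported (classical: SS over the total of all
#' five SS rows; partial: SS over SS plus its stratum's residual SS). With
#' two within levels no sphericity correction is applicable.
#'
#' @param data data.frame in long format.
#' @param value,subject,group,condition column names.
#' @return an object of class `mixed_anova` with components `table` (the
#'   five-row ANOVA table), `cell_means` (unweighted 2x2 cell means),
#'   `cell_ns`, `factors`, and the error terms; methods: [print.mixed_anova],
#'   [summary.mixed_anova], [coef.mixed_anova], [duncan_mrt()] via
#'   [duncan.mixed_anova].
#' @examples
#' d <- expand.grid(subject = paste0("s", 1:8), condition = c("A", "B"))
#' d$group <- rep(rep(c("g1", "g2"), each = 4), 2)
#' set.seed(1)
#' d$value <- rnorm(nrow(d)) + (d$condition == "B") * 0.5
#' fit <- mixed_anova(d, value = "value")
#' fit
#' @export
mixed_anova <- function(data, value = "value", subject = "subject_id",
                        group = "group", condition = "condition") {
  need <- c(value, subject, group, condition)
  if (!all(need %in% names(data))) {
    stop("data must have columns: ", paste(need, collapse = ", "))
  }
  d <- data.frame(y = data[[value]],
                  s = as.character(data[[subject]]),
                  g = as.character(data[[group]]),
                  c = as.character(data[[condition]]),
                  stringsAsFactors = FALSE)
  if (!all(is.finite(d$y))) stop("non-finite response values")
  glev <- sort(unique(d$g))
  clev <- sort(unique(d$c))
  if (length(glev) != 2L || length(clev) != 2L) {
    stop("design must have exactly 2 groups and 2 conditions")
  }
  gmap <- tapply(d$g, d$s, function(v) unique(v))
  if (any(lengths(gmap) != 1L)) {
    stop("each subject must belong to exactly one group")
  }
  subj <- names(gmap)
  y1 <- y2 <- stats::setNames(rep(NA_real_, length(subj)), subj)
  for (k in seq_len(nrow(d))) {
    if (d$c[k] == clev[1]) y1[d$s[k]] <- d$y[k] else y2[d$s[k]] <- d$y[k]
  }
  if (anyNA(y1) || anyNA(y2)) {
    stop("incomplete design: every subject needs one value per condition")
  }
  gs <- unlist(gmap)[subj]
  n1 <- sum(gs == glev[1]); n2 <- sum(gs == glev[2])
  if (n1 < 2L || n2 < 2L) stop("need at least 2 subjects per group")
  N <- n1 + n2
  h <- 1 / n1 + 1 / n2

  diff_ <- y1 - y2                       # within-subject contrast
  msub <- (y1 + y2) / 2                  # subject means
  d1 <- mean(diff_[gs == glev[1]]); d2 <- mean(diff_[gs == glev[2]])
  theta <- (d1 + d2) / 2                 # unweighted condition effect
  gamma <- (d1 - d2) / 2                 # interaction contrast
  ss_c <- 2 * theta^2 / h
  ss_gc <- 2 * gamma^2 / h
  dbar_g <- ifelse(gs == glev[1], d1, d2)
  ss_wr <- sum((diff_ - dbar_g)^2) / 2

  m1 <- mean(msub[gs == glev[1]]); m2 <- mean(msub[gs == glev[2]])
  ss_g <- 2 * (m1 - m2)^2 / h
  mbar_g <- ifelse(gs == glev[1], m1, m2)
  ss_br <- 2 * sum((msub - mbar_g)^2)

  df <- c(1, 1, N - 2, 1, N - 2)
  ss <- c(ss_c, ss_gc, ss_wr, ss_g, ss_br)
  ms <- ss / df
  f_of <- function(ss_num, ms_num, ms_err) {
    if (ms_err > 0) ms_num / ms_err
    else if (ss_num == 0) 0
    else {
      warning("zero residual sum of squares; F is infinite")
      Inf
    }
  }
  Fv <- c(f_of(ss_c, ms[1], ms[3]), f_of(ss_gc, ms[2], ms[3]), NA,
          f_of(ss_g, ms[4], ms[5]), NA)
  pv <- rep(NA_real_, 5L)
  pv[c(1, 2, 4)] <- p_from_f(Fv[c(1, 2, 4)], 1, N - 2)
  tab <- data.frame(
    source = c(condition, paste(condition, group, sep = " x "),
               "Residuals (within)", group, "Residuals (between)"),
    stratum = c("within", "within", "within", "between", "between"),
    ss = ss, df = df, ms = ms, F = Fv, p = pv,
    stringsAsFactors = FALSE
  )
  tab <- add_eta_squared(tab)

  cells <- matrix(c(mean(y1[gs == glev[1]]), mean(y2[gs == glev[1]]),
                    mean(y1[gs == glev[2]]), mean(y2[gs == glev[2]])),
                  2, 2, byrow = TRUE,
                  dimnames = list(glev, clev))
  structure(
    list(table = tab, cell_means = cells,
         cell_ns = stats::setNames(c(n1, n2), glev),
         factors = list(group = group, condition = condition,
                        group_levels = glev, condition_levels = clev),
         error_within = list(ms = ms[3], df = N - 2),
         error_between = list(ms = ms[5], df = N - 2),
         n_subjects = N),
    class = "mixed_anova")
}

add_eta_squared <- function(tab) {
  total <- sum(tab$ss)
  resid_of <- ifelse(tab$stratum == "within", tab$ss[3], tab$ss[5])
  testable <- !grepl("^Residuals", tab$source)
  cls <- if (total > 0) tab$ss / total else rep(0, nrow(tab))
  tab$eta_classical <- ifelse(testable, cls, NA)
  tab$eta_partial <- ifelse(testable,
                            ifelse(tab$ss + resid_of > 0,
                                   tab$ss / (tab$ss + resid_of), 0), NA)
  tab
}

#' Upper-tail p-value of the F distribution
#'
#' @param f observed F statistic(s), >= 0.
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @return `P(F >= f)`.
#' @export
p_from_f <- function(f, df1, df2) {
  if (any(f < 0, na.rm = TRUE)) stop("F must be non-negative")
  stats::pf(f, df1, df2, lower.tail = FALSE)
}

format_p <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "< .001", sprintf("%.3f", p)))
}

#' @export
print.mixed_anova <- function(x, digits = 3, ...) {
  cat(sprintf("2 x 2 mixed repeated-measures ANOVA (N = %d; %s: %s between, %s: %s within)\n",
              x$n_subjects,
              x$factors$group, paste(x$cell_ns, collapse = "+"),
              x$factors$condition,
              paste(x$factors$condition_levels, collapse = "/")))
  tab <- x$table
  out <- data.frame(
    Source = tab$source,
    `Sum of squares` = signif(tab$ss, 4),
    df = tab$df,
    `Mean square` = signif(tab$ms, 4),
    F = ifelse(is.na(tab$F), "", sprintf("%.3f", tab$F)),
    p = format_p(tab$p),
    eta2 = ifelse(is.na(tab$eta_classical), "",
                  sprintf("%.3f", tab$eta_classical)),
    eta2p = ifelse(is.na(tab$eta_partial), "",
                   sprintf("%.3f", tab$eta_partial)),
    check.names = FALSE
  )
  print(out, row.names = FALSE)
  cat("Type III (unweighted cell means); eta2 = classical, eta2p = partial.\n")
  invisible(x)
}

#' @export
summary.mixed_anova <- function(object, ...) {
  cat("Cell means (unweighted):\n")
  print(round(object$cell_means, 4))
  cat("\n")
  print(object)
  invisible(object$table)
}

#' @export
coef.mixed_anova <- function(object, ...) {
  cm <- object$cell_means
  c(grand = mean(cm),
    stats::setNames(mean(cm[1, ]) - mean(cm),
                    rownames(cm)[1]),
    stats::setNames(mean(cm[, 1]) - mean(cm),
                    colnames(cm)[1]),
    interaction = (cm[1, 1] - cm[1, 2] - cm[2, 1] + cm[2, 2]) / 4)
}

#' Per-source eta squared in a chosen convention
#'
#' @param fit a [mixed_anova()] fit (or its `table`).
#' @param convention `"classical"` (SS over total SS) or `"partial"`
#'   (SS over SS + its stratum's residual SS).
#' @return named numeric vector over the testable sources.
#' @export
eta_squared <- function(fit, convention = c("classical", "partial")) {
  convention <- match.arg(convention)
  tab <- if (inherits(fit, "mixed_anova")) fit$table else fit
  col <- paste0("eta_", convention)
  keep <- !is.na(tab[[col]])
  stats::setNames(tab[[col]][keep], tab$source[keep])
}

# ---- Duncan's multiple range test ------------------------------------------

#' Duncan significant-range quantile
#'
#' The critical studentized range for a span of `p` ordered means at
#' Duncan's protection level `(1 - alpha)^(p - 1)`, i.e. the studentized
#' range quantile `q` with `P(Q <= q) = (1 - alpha)^(p - 1)` for `p` means
#' and `df` error degrees of freedom.
#'
#' @param p span (number of ordered means covered), >= 2.
#' @param df error degrees of freedom.
#' @param alpha per-comparison level.
#' @export
q_duncan <- function(p, df, alpha = 0.05) {
  stats::qtukey((1 - alpha)^(p - 1), nmeans = p, df = df)
}

#' Duncan's multiple range post-hoc test
#'
#' Means are sorted in descending order; a comparison spanning `p` ordered
#' means is significant when the difference exceeds
#' `q_duncan(p, df_error, alpha) * sqrt(ms_error / n_h)`, with `n_h` the
#' harmonic mean of the spanned cell sizes. Testing is stepwise with the
#' standard non-crossing protection rule: a pair inside a wider
#' non-significant span is declared non-significant regardless of its own
#' range. With exactly two means the procedure reduces to the two-sided
#' t-test on the same error term.
#'
#' @param means named numeric vector of cell means.
#' @param ns cell sizes (recycled if scalar).
#' @param ms_error,df_error pooled error mean square and its df.
#' @param alpha level (default 0.05).
#' @return object of class `duncan_mrt`: sorted `means`, `comparisons`
#'   data.frame (`a`, `b`, `diff`, `span`, `q_crit`, `critical_range`,
#'   `significant`), `alpha`, `ms_error`, `df_error`.
#' @export
duncan_mrt <- function(means, ns, ms_error, df_error, alpha = 0.05) {
  if (length(means) < 2L) stop("need at least 2 means")
  if (ms_error <= 0) stop("ms_error must be positive")
  if (length(ns) == 1L) ns <- rep(ns, length(means))
  if (is.null(names(means))) {
    names(means) <- paste0("cell", seq_along(means))
  }
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]; nn <- ns[ord]
  k <- length(m)
  sig <- matrix(NA, k, k)
  rows <- list()
  for (span in k:2) {
    for (i in 1:(k - span + 1L)) {
      j <- i + span - 1L
      n_h <- span / sum(1 / nn[i:j])
      crit_q <- q_duncan(span, df_error, alpha)
      crit <- crit_q * sqrt(ms_error / n_h)
      delta <- m[i] - m[j]
      this_sig <- delta > crit
      # non-crossing rule: inside a non-significant wider span, never reject
      blocked <- FALSE
      if (span < k) {
        for (ii in 1:(k - 1L)) {
          for (jj in (ii + 1L):k) {
            if (ii <= i && jj >= j && (jj - ii + 1L) > span &&
                identical(sig[ii, jj], FALSE)) {
              blocked <- TRUE
            }
          }
        }
      }
      if (blocked) this_sig <- FALSE
      sig[i, j] <- this_sig
      rows[[length(rows) + 1L]] <- data.frame(
        a = names(m)[i], b = names(m)[j], diff = delta, span = span,
        q_crit = crit_q, critical_range = crit, significant = this_sig,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(means = m, ns = nn,
                 comparisons = do.call(rbind, rows), alpha = alpha,
                 ms_error = ms_error, df_error = df_error),
            class = "duncan_mrt")
}

#' @export
print.duncan_mrt <- function(x, digits = 4, ...) {
  cat(sprintf("Duncan multiple range test (alpha = %g, MSe = %.4g, df = %d)\n",
              x$alpha, x$ms_error, x$df_error))
  cat("Ordered means:\n")
  print(round(x$means, digits))
  cmp <- x$comparisons
  cmp$diff <- round(cmp$diff, digits)
  cmp$critical_range <- round(cmp$critical_range, digits)
  cmp$q_crit <- round(cmp$q_crit, 3)
  print(cmp, row.names = FALSE)
  invisible(x)
}

#' Duncan post-hoc on a fitted mixed ANOVA
#'
#' Applies [duncan_mrt()] to the four group x condition cell means. The
#' default error term pools the two strata's residual sums of squares
#' (`(SS_between_resid + SS_within_resid) / (df_b + df_w)`), which is the
#' appropriate denominator for comparisons that cross both factors; either
#' single stratum can be requested instead. Cell n is the group size (the
#' within factor is complete), compared via harmonic means.
#'
#' @param fit a [mixed_anova()] object.
#' @param alpha level.
#' @param error `"pooled"`, `"within"`, or `"between"`.
#' @export
duncan <- function(fit, alpha = 0.05, error = c("pooled", "within",
                                                "between")) {
  UseMethod("duncan")
}

#' @rdname duncan
#' @export
duncan.mixed_anova <- function(fit, alpha = 0.05,
                               error = c("pooled", "within", "between")) {
  error <- match.arg(error)
  tab <- fit$table
  ew <- fit$error_within; eb <- fit$error_between
  term <- switch(error,
                 pooled = list(ms = (tab$ss[3] + tab$ss[5]) /
                                 (tab$df[3] + tab$df[5]),
                               df = tab$df[3] + tab$df[5]),
                 within = ew, between = eb)
  cm <- fit$cell_means
  means <- stats::setNames(
    as.vector(t(cm)),
    paste(rep(rownames(cm), each = ncol(cm)),
          rep(colnames(cm), times = nrow(cm)), sep = ":"))
  ns <- rep(fit$cell_ns, each = ncol(cm))
  duncan_mrt(means, ns, term$ms, term$df, alpha)
}
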