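#' Likert response table
#'
#' Long-format 5-point Likert responses: one row per subject x condition x
#' item, responses in 1..5.
#'
#' @param df data.frame with columns `subject_id`, `group`, `condition`,
#'   `item`, `response`.
#' @return the validated table, class `likert_table`.
#' @export
likert_table <- function(df) {
  need <- c("subject_id", "group", "condition", "item", "response")
  if (!all(need %in% names(df))) {
    stop("likert table needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(df$response %in% 1:5)) stop("responses must lie in {1,...,5}")
  key <- paste(df$subject_id, df$condition, df$item)
  if (anyDuplicated(key)) {
    stop("duplicate response for a subject x condition x item cell")
  }
  structure(as.data.frame(df), class = c("likert_table", "data.frame"))
}

#' Composite (construct) specification
#'
#' Names a construct and the ordered Likert items that are candidates for
#' merging into its composite index.
#'
#' @param name construct name; `items` character vector of item ids;
#'   `wording` optional item texts.
#' @export
composite_spec <- function(name, items, wording = NULL) {
  structure(list(name = name, items = items, wording = wording),
            class = "composite_spec")
}

#' The default two-construct item battery
#'
#' A "willingness to use" construct with two acceptability items and a
#' "work performance" construct with four perceived-impact items, mirroring
#' the usual technology-acceptance phrasing. Editable metadata, not a fixed
#' instrument.
#' @export
default_composites <- function() {
  list(
    composite_spec("willingness_to_use",
                   c("will_use_future", "like_interface"),
                   c("I would like to use this tool in the future",
                     "I like the new decision support interface")),
    composite_spec("work_performance",
                   c("solve_faster", "accuracy", "performance", "easier"),
                   c("Working with this tool would allow me to solve conflicts faster",
                     "Working with this tool would increase my accuracy in solving conflicts",
                     "Working with this tool would improve my performance",
                     "Using this tool would make my work easier"))
  )
}

#' Pearson correlation with a p-value from the t-transform
#'
#' `t = r * sqrt((n - 2) / (1 - r^2))` referred to a t distribution with
#' `n - 2` degrees of freedom (two-sided). `|r| = 1` gives `p = 0`.
#'
#' @param x,y numeric vectors, length >= 3, finite.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_r_with_p <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Item-by-item correlation matrix
#'
#' Pearson r and two-sided p for every item pair, pooling observations
#' across subjects and conditions (one observation = one subject x
#' condition). Zero-variance items yield NA entries and a warning.
#'
#' @param table a [likert_table()].
#' @param items item ids to include (default: all items present).
#' @param by_condition if a condition name, restrict to that condition.
#' @return object of class `likert_cor`: matrices `r`, `p`, `n`.
#' @export
correlation_matrix <- function(table, items = NULL, by_condition = NULL) {
  if (!is.null(by_condition)) {
    table <- table[table$condition == by_condition, , drop = FALSE]
  }
  if (is.null(items)) items <- unique(table$item)
  wide <- stats::reshape(
    as.data.frame(table)[table$item %in% items,
                         c("subject_id", "condition", "item", "response")],
    idvar = c("subject_id", "condition"), timevar = "item",
    direction = "wide")
  mat <- as.matrix(wide[, paste0("response.", items), drop = FALSE])
  colnames(mat) <- items
  k <- length(items)
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(items, items))
  for (i in seq_len(k)) {
    for (j in i:k) {
      ok <- stats::complete.cases(mat[, c(i, j)])
      if (sum(ok) < 3) next
      if (i == j) {
        if (stats::sd(mat[ok, i]) == 0) {
          warning("item '", items[i], "' has zero variance")
          next
        }
        r[i, j] <- 1; p[i, j] <- 0; nmat[i, j] <- sum(ok)
        next
      }
      res <- withCallingHandlers(
        pearson_r_with_p(mat[ok, i], mat[ok, j]),
        warning = function(w) {
          warning("item pair ", items[i], "/", items[j], ": ",
                  conditionMessage(w), call. = FALSE)
          invokeRestart("muffleWarning")
        })
      r[i, j] <- r[j, i] <- res$r
      p[i, j] <- p[j, i] <- res$p
      nmat[i, j] <- nmat[j, i] <- res$n
    }
  }
  structure(list(r = r, p = p, n = nmat, items = items),
            class = "likert_cor")
}

#' @export
print.likert_cor <- function(x, digits = 3, ...) {
  cat("Item correlation matrix (Pearson r):\n")
  print(round(x$r, digits))
  invisible(x)
}

#' Validate an item merge by positive-correlation screening
#'
#' Approves merging the spec's items into one composite iff every pairwise
#' correlation among them is positive with `p < alpha`. Rejection is a valid
#' outcome; the report lists every pair.
#'
#' @param matrix a [correlation_matrix()] result.
#' @param spec a [composite_spec()].
#' @param alpha significance threshold (default 0.001).
#' @return list with `approved`, `construct`, `alpha` and a per-pair
#'   data.frame `report` (`item_a`, `item_b`, `r`, `p`, `ok`).
#' @export
validate_merge <- function(matrix, spec, alpha = 0.001) {
  items <- spec$items
  missing <- setdiff(items, matrix$items)
  if (length(missing)) {
    stop("items not in correlation matrix: ", paste(missing, collapse = ", "))
  }
  pairs <- utils::combn(items, 2)
  report <- data.frame(
    item_a = pairs[1, ], item_b = pairs[2, ],
    r = matrix$r[cbind(pairs[1, ], pairs[2, ])],
    p = matrix$p[cbind(pairs[1, ], pairs[2, ])]
  )
  report$ok <- !is.na(report$r) & report$r > 0 & report$p < alpha
  list(approved = all(report$ok), construct = spec$name, alpha = alpha,
       report = report)
}

#' Build a composite index
#'
#' The composite is the unweighted arithmetic mean of the constituent item
#' responses per subject x condition (so it stays on the 1-5 scale); `"sum"`
#' and `"zmean"` (mean of per-item z-scores) are available alternatives.
#' Rows with a missing item response are excluded with a warning.
#'
#' @param table a [likert_table()].
#' @param spec a [composite_spec()].
#' @param method aggregation method.
#' @param validation optional [validate_merge()] result; if it rejected the
#'   merge, building requires `force = TRUE` (logged override).
#' @param force build despite a rejected validation.
#' @return data.frame: `subject_id`, `group`, `condition`, `composite`.
#' @export
build_composite <- function(table, spec, method = c("mean", "sum", "zmean"),
                            validation = NULL, force = FALSE) {
  method <- match.arg(method)
  if (!is.null(validation) && !validation$approved) {
    if (!force) {
      stop("merge for '", spec$name,
           "' was not validated; pass force = TRUE to override")
    }
    warning("building composite '", spec$name,
            "' despite failed correlation screening (forced override)")
  }
  sub <- as.data.frame(table)[table$item %in% spec$items, , drop = FALSE]
  if (method == "zmean") {
    for (it in spec$items) {
      sel <- sub$item == it
      sub$response[sel] <- as.numeric(scale(sub$response[sel]))
    }
  }
  agg <- stats::aggregate(
    response ~ subject_id + group + condition, data = sub,
    FUN = if (method == "sum") sum else mean)
  counts <- stats::aggregate(response ~ subject_id + group + condition,
                             data = sub, FUN = length)
  incomplete <- counts$response < length(spec$items)
  if (any(incomplete)) {
    warning(sum(incomplete), " row(s) excluded from composite '",
            spec$name, "' due to missing item responses")
    agg <- agg[!incomplete, , drop = FALSE]
  }
  names(agg)[names(agg) == "response"] <- "composite"
  agg$construct <- spec$name
  agg
}

#' Cronbach's alpha (informational diagnostic)
#'
#' @param table a [likert_table()]; `items` the item set.
#' @return alpha coefficient.
#' @export
cronbach_alpha <- function(table, items) {
  wide <- stats::reshape(
    as.data.frame(table)[table$item %in% items,
                         c("subject_id", "condition", "item", "response")],
    idvar = c("subject_id", "condition"), timevar = "item",
    direction = "wide")
  mat <- as.matrix(wide[, paste0("response.", items), drop = FALSE])
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  k <- ncol(mat)
  k / (k - 1) * (1 - sum(apply(mat, 2, stats::var)) /
                   stats::var(rowSums(mat)))
}
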