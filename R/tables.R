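#' Published ANOVA tables shipped for verification
#'
#' Loads the packaged fixture of the four published 2x2 mixed ANOVA tables
#' (questionnaire composites: work-performance impact and willingness to
#' use; neurometrics: workload and acceptance), as printed: per-source sums
#' of squares, df, F, p and eta squared, together with the printed precision
#' (ulp) of each number and the eta-squared convention each table's printed
#' values follow arithmetically.
#'
#' @return named list of tables; each has `outcome`, `eta_convention`, and a
#'   data.frame `rows`.
#' @export
reference_tables <- function() {
  path <- system.file("extdata", "printed_anova_tables.json",
                      package = "eegmetrics")
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  lapply(raw, function(tb) {
    tb$rows <- as.data.frame(tb$rows)
    tb
  })
}

#' Reconstruct an ANOVA table from printed sums of squares
#'
#' Recomputes mean squares, F ratios, p-values and both eta-squared
#' conventions purely from the printed per-source SS and df (within-stratum
#' sources tested against the within residual, between against the between
#' residual), and compares them against the printed F, p and eta-squared.
#'
#' Because the printed SS are themselves rounded, exact agreement to the
#' printed precision cannot be expected for every derived value; alongside
#' the point recomputation the comparison therefore propagates the half-ulp
#' rounding interval of every printed SS through each derived quantity
#' (monotone interval arithmetic) and flags a value `consistent` when the
#' derived interval overlaps the printed value's own rounding band. A
#' genuinely wrong printed value fails this check; a value that differs only
#' through input rounding passes.
#'
#' @param printed one table from [reference_tables()], or a compatible list
#'   with `rows` (columns `source`, `stratum`, `ss`, `ss_ulp`, `df`, and the
#'   printed `F`, `p` (string), `eta2`, `eta2_ulp`) and `eta_convention`.
#' @return object of class `table_verification`: the reconstructed table and
#'   a comparison data.frame with columns `source`, `quantity`, `printed`,
#'   `recomputed`, `diff`, `consistent`.
#' @export
verify_printed_table <- function(printed) {
  rows <- printed$rows
  conv <- printed$eta_convention
  if (is.null(rows$ss_ulp)) rows$ss_ulp <- 0.001
  within <- rows$stratum == "within"
  resid_row <- function(str) which(rows$stratum == str &
                                     grepl("Residuals", rows$source))
  rw <- resid_row("within"); rb <- resid_row("between")
  res_of <- ifelse(within, rw, rb)
  ms <- rows$ss / rows$df
  testable <- !grepl("Residuals", rows$source)

  lo <- rows$ss - rows$ss_ulp / 2
  hi <- rows$ss + rows$ss_ulp / 2
  lo <- pmax(lo, 0)
  total <- sum(rows$ss)

  recon <- data.frame(source = rows$source, stratum = rows$stratum,
                      ss = rows$ss, df = rows$df, ms = ms,
                      F = NA_real_, p = NA_real_,
                      eta_classical = NA_real_, eta_partial = NA_real_)
  cmp <- list()
  push <- function(source, quantity, printed_chr, printed_band, value,
                   interval) {
    cmp[[length(cmp) + 1L]] <<- data.frame(
      source = source, quantity = quantity, printed = printed_chr,
      recomputed = value, diff = value - mean(printed_band),
      consistent = interval[1] <= printed_band[2] &&
        interval[2] >= printed_band[1],
      stringsAsFactors = FALSE)
  }
  for (i in which(testable)) {
    j <- res_of[i]
    ms_err <- rows$ss[j] / rows$df[j]
    if (ms_err == 0) {
      warning("zero residual SS in stratum; F infinite for ",
              rows$source[i])
      recon$F[i] <- Inf
      next
    }
    recon$F[i] <- ms[i] / ms_err
    recon$p[i] <- p_from_f(recon$F[i], rows$df[i], rows$df[j])
    f_int <- c(lo[i] / rows$df[i] / (hi[j] / rows$df[j]),
               hi[i] / rows$df[i] / (lo[j] / rows$df[j]))
    if (!is.na(rows$F[i])) {
      f_band <- band_of(rows$F[i], ulp_of(rows, "F_ulp", i, 0.001))
      push(rows$source[i], "F", sprintf("%g", rows$F[i]), f_band,
           recon$F[i], f_int)
    }
    if (!is.na(rows$p[i]) && nzchar(rows$p[i])) {
      p_band <- parse_p_band(rows$p[i])
      p_int <- c(p_from_f(f_int[2], rows$df[i], rows$df[j]),
                 p_from_f(f_int[1], rows$df[i], rows$df[j]))
      push(rows$source[i], "p", rows$p[i], p_band, recon$p[i], p_int)
    }
    others <- setdiff(seq_len(nrow(rows)), i)
    recon$eta_classical[i] <- if (total > 0) rows$ss[i] / total else 0
    recon$eta_partial[i] <- rows$ss[i] / (rows$ss[i] + rows$ss[j])
    eta_val <- if (conv == "classical") recon$eta_classical[i] else
      recon$eta_partial[i]
    eta_int <- if (conv == "classical") {
      c(lo[i] / (lo[i] + sum(hi[others])),
        hi[i] / (hi[i] + sum(lo[others])))
    } else {
      c(lo[i] / (lo[i] + hi[j]), hi[i] / (hi[i] + lo[j]))
    }
    if (!is.na(rows$eta2[i])) {
      e_band <- band_of(rows$eta2[i], ulp_of(rows, "eta2_ulp", i, 0.001))
      push(rows$source[i], paste0("eta2_", conv),
           sprintf("%g", rows$eta2[i]), e_band, eta_val, eta_int)
    }
  }
  structure(list(reconstructed = recon,
                 comparison = do.call(rbind, cmp),
                 eta_convention = conv,
                 outcome = printed$outcome),
            class = "table_verification")
}

ulp_of <- function(rows, col, i, default) {
  if (!is.null(rows[[col]]) && !is.na(rows[[col]][i])) rows[[col]][i]
  else default
}

band_of <- function(x, ulp) c(x - ulp / 2, x + ulp / 2)

parse_p_band <- function(p_chr) {
  p_chr <- trimws(p_chr)
  if (grepl("^<", p_chr)) {
    c(0, as.numeric(sub("^<\\s*", "", p_chr)))
  } else {
    x <- as.numeric(p_chr)
    dec <- nchar(sub("^[^.]*\\.?", "", p_chr))
    band_of(x, 10^(-dec))
  }
}

#' @export
print.table_verification <- function(x, ...) {
  cat("Reconstruction of printed ANOVA table")
  if (!is.null(x$outcome)) cat(" (", x$outcome, ")", sep = "")
  cat("; printed eta2 convention: ", x$eta_convention, "\n", sep = "")
  cmp <- x$comparison
  cmp$recomputed <- signif(cmp$recomputed, 5)
  cmp$diff <- signif(cmp$diff, 3)
  print(cmp, row.names = FALSE)
  if (all(x$comparison$consistent)) {
    cat("All printed values are consistent with the printed sums of squares.\n")
  } else {
    cat("INCONSISTENT rows present.\n")
  }
  invisible(x)
}

#' Verify all packaged published tables
#'
#' Runs [verify_printed_table()] on every packaged table and additionally
#' checks the exactly-reproducible anchor values (the within-factor F of the
#' willingness and workload tables reproduce the print to three decimals).
#'
#' @param tables as from [reference_tables()].
#' @return list with per-table `verifications`, logical `all_consistent`,
#'   and `anchors` (data.frame of exact 3-decimal checks).
#' @export
run_verify_tables <- function(tables = reference_tables()) {
  ver <- lapply(tables, verify_printed_table)
  anchors <- do.call(rbind, lapply(names(ver), function(nm) {
    v <- ver[[nm]]$reconstructed
    p <- tables[[nm]]$rows
    i <- which(!grepl("Residuals", v$source))
    data.frame(table = nm, source = v$source[i],
               F_recomputed = v$F[i], F_printed = p$F[i],
               exact_3dp = !is.na(p$F[i]) &
                 round(v$F[i], 3) == round(p$F[i], 3))
  }))
  list(verifications = ver,
       all_consistent = all(vapply(ver, function(v)
         all(v$comparison$consistent), logical(1))),
       anchors = anchors)
}
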