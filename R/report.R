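# Deliverables: VIP-ranked bins, chemical-shift annotation, Table-style
# direction-of-change reports, and the generic Levene-gated univariate test.

#' Rank bins by VIP score
#'
#' @param vip_scores named numeric vector (see [vip()]).
#' @param threshold strict lower bound; only bins with `VIP > threshold` are
#'   kept (so a vector of exact 1.0 scores yields an empty list at the
#'   default threshold).
#' @return data.frame `bin`, `vip`, sorted by VIP descending.
#' @export
rank_bins <- function(vip_scores, threshold = 1.0) {
  stopifnot(is.numeric(vip_scores))
  assert_number(threshold, "threshold")
  keep <- vip_scores > threshold
  out <- data.frame(bin = names(vip_scores)[keep],
                    vip = unname(vip_scores[keep]),
                    stringsAsFactors = FALSE)
  out[order(-out$vip), , drop = FALSE]
}

#' Chemical-shift lookup table
#'
#' @param metabolite,ppm_lo,ppm_hi,note equal-length vectors; intervals in
#'   [-0.5, 10] ppm. A bin may intersect several metabolites' intervals —
#'   that ambiguity is preserved by [annotate_bins()].
#' @return data.frame of class `shift_table`.
#' @export
shift_table <- function(metabolite, ppm_lo, ppm_hi, note = "") {
  stopifnot(length(metabolite) == length(ppm_lo),
            length(ppm_lo) == length(ppm_hi))
  if (any(ppm_lo >= ppm_hi)) stop_f("shift table intervals need lo < hi")
  if (any(ppm_lo < -0.5 | ppm_hi > 10.0))
    stop_f("shift table intervals must lie within [-0.5, 10] ppm")
  structure(data.frame(metabolite = metabolite, ppm_lo = ppm_lo,
                       ppm_hi = ppm_hi, note = note,
                       stringsAsFactors = FALSE),
            class = c("shift_table", "data.frame"))
}

#' Default shift table for a sample matrix
#'
#' Derived from the simulator's metabolite library: each template peak
#' contributes the interval center +/- max(2 x HWHM, 0.01 ppm). Broad
#' lipoprotein envelopes therefore produce wide, mutually overlapping
#' intervals (HDL/VLDL CH3), which is how joint annotations arise. Users may
#' supply their own table via [shift_table()] or a CSV with the same columns.
#'
#' @param matrix `"plasma"` or `"brain"`.
#' @export
default_shift_table <- function(matrix) {
  lib <- default_metabolite_library(matrix)
  rows <- lapply(lib, function(t) {
    half <- pmax(2 * t$peaks$half_width, 0.01)
    data.frame(metabolite = t$name,
               ppm_lo = pmax(t$peaks$center - half, -0.5),
               ppm_hi = pmin(t$peaks$center + half, 10.0),
               note = "library constant", stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  shift_table(df$metabolite, df$ppm_lo, df$ppm_hi, df$note)
}

#' Annotate bins against a shift table
#'
#' Each bin is mapped to every metabolite whose interval intersects it;
#' multiple hits are joined with "/" (ambiguity preserved), no hit yields
#' `"unassigned"`.
#'
#' @param bins character bin labels (`"b2.00_2.02"`) or a 2-column lo/hi
#'   matrix.
#' @param table a [shift_table()].
#' @return data.frame `bin`, `annotation`.
#' @export
annotate_bins <- function(bins, table) {
  stopifnot(inherits(table, "shift_table"))
  if (is.character(bins)) {
    edges <- parse_bin_label(bins)
    labels <- bins
  } else {
    edges <- cbind(lo = bins[, 1], hi = bins[, 2])
    labels <- bin_label(edges[, "lo"], edges[, "hi"])
  }
  ann <- vapply(seq_len(nrow(edges)), function(i) {
    hit <- table$ppm_lo < edges[i, "hi"] & table$ppm_hi > edges[i, "lo"]
    if (!any(hit)) "unassigned"
    else paste(unique(table$metabolite[hit]), collapse = "/")
  }, character(1))
  data.frame(bin = labels, annotation = ann, stringsAsFactors = FALSE)
}

p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", ""))))
}

#' Independent two-group comparison with Levene gate
#'
#' Levene's test (center = mean) at alpha 0.05 decides between the pooled
#' and the Welch t-test; Cohen's d uses the pooled standard deviation on the
#' analysed (possibly square-root transformed) scale. The mean difference
#' and its 95% CI refer to `mean(a) - mean(b)`.
#'
#' @param values_a,values_b numeric vectors, >= 2 values each.
#' @param sqrt_transform apply sqrt first (requires non-negative data; used
#'   for right-skewed measures).
#' @return list of class `univariate_result`: `t`, `df` (fractional on the
#'   Welch path), `p`, `mean_diff`, `ci`, `cohens_d`, `levene_p`,
#'   `var_equal`, `transform`.
#' @export
univariate_test <- function(values_a, values_b, sqrt_transform = FALSE) {
  assert_flag(sqrt_transform, "sqrt_transform")
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) < 2L || length(b) < 2L)
    stop_f("each group needs >= 2 values")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop_f("non-finite values in input")
  if (sqrt_transform) {
    if (any(a < 0) || any(b < 0))
      stop_f("sqrt_transform requires non-negative values")
    a <- sqrt(a); b <- sqrt(b)
  }
  # Levene with centre = mean: two-group ANOVA on absolute deviations,
  # equivalent to a pooled t-test on them.
  za <- abs(a - mean(a)); zb <- abs(b - mean(b))
  lev_p <- tryCatch(stats::t.test(za, zb, var.equal = TRUE)$p.value,
                    error = function(e) 1)
  var_equal <- lev_p >= 0.05
  # t.test refuses essentially-constant data; degenerate bins fall back to
  # the limiting values (t = 0, p = 1 for equal means; |t| = Inf otherwise).
  htest <- tryCatch(
    stats::t.test(a, b, var.equal = var_equal, conf.level = 0.95),
    error = function(e) NULL)
  n1 <- length(a); n2 <- length(b)
  sp <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
               (n1 + n2 - 2))
  md <- mean(a) - mean(b)
  d <- if (sp == 0) { if (md == 0) 0 else sign(md) * Inf }
       else md / sp
  structure(list(
    t = if (is.null(htest)) { if (md == 0) 0 else sign(md) * Inf }
        else unname(htest$statistic),
    df = if (is.null(htest)) n1 + n2 - 2 else unname(htest$parameter),
    p = if (is.null(htest)) { if (md == 0) 1 else 0 } else htest$p.value,
    mean_diff = md,
    ci = if (is.null(htest)) c(md, md) else unname(htest$conf.int),
    cohens_d = d,
    levene_p = lev_p, var_equal = var_equal,
    transform = if (sqrt_transform) "sqrt" else "none"),
    class = "univariate_result")
}

#' Direction of change per bin
#'
#' For each requested bin, compares treated vs control values with
#' [univariate_test()]; direction is an up-arrow when the treated-group mean
#' exceeds the control mean, a down-arrow otherwise. Zero-variance bins with
#' equal means have no defined direction and are flagged.
#'
#' @param m a `binned_matrix` (or plain matrix with bin-label columns).
#' @param y group labels per row.
#' @param bins bin labels to test; defaults to all retained bins.
#' @param positive_class treated-like label; defaults to the second distinct
#'   value of `y`.
#' @return data.frame `bin`, `direction`, `p`, `stars`, `mean_treated`,
#'   `mean_control`, `flagged`.
#' @export
direction_of_change <- function(m, y, bins = NULL, positive_class = NULL) {
  X <- if (inherits(m, "binned_matrix")) model_matrix(m) else as.matrix(m)
  code <- code_response(y, positive_class)
  if (is.null(bins)) bins <- colnames(X)
  missing_ <- setdiff(bins, colnames(X))
  if (length(missing_))
    stop_f("bins absent from the matrix: %s", paste(missing_, collapse = ", "))
  pos <- code$y_num > 0
  rows <- lapply(bins, function(bn) {
    va <- X[pos, bn]; vb <- X[!pos, bn]
    flagged <- stats::sd(va) == 0 && stats::sd(vb) == 0 &&
      mean(va) == mean(vb)
    ut <- univariate_test(va, vb)
    data.frame(bin = bn,
               direction = if (flagged) NA_character_
                           else if (mean(va) > mean(vb)) "↑"
                           else "↓",
               p = ut$p, stars = p_stars(ut$p),
               mean_treated = mean(va), mean_control = mean(vb),
               flagged = flagged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full discriminant table (VIP, annotation, direction, significance)
#'
#' Combines [vip()], [rank_bins()], [annotate_bins()] and
#' [direction_of_change()] into the Table-style deliverable: one row per
#' VIP-selected bin, sorted by VIP descending. A supplementary
#' Benjamini-Hochberg column (`p_bh`) is included as a labelled extension;
#' the `p` column itself is unadjusted.
#'
#' @param m a `binned_matrix`.
#' @param y group labels per row.
#' @param model fitted [fit_opls_da()] model on the retained bins of `m`.
#' @param table a [shift_table()]; default from the matrix type.
#' @param vip_threshold strict VIP cut-off (default 1).
#' @param positive_class treated-like label.
#' @return data.frame of class `discriminant_table`.
#' @export
discriminant_report <- function(m, y, model, table = NULL,
                                vip_threshold = 1.0, positive_class = NULL) {
  stopifnot(inherits(m, "binned_matrix"), inherits(model, "opls_model"))
  if (is.null(table)) table <- default_shift_table(m$matrix_type)
  v <- vip(model)
  ranked <- rank_bins(v, vip_threshold)
  if (nrow(ranked) == 0L) {
    out <- data.frame(bin = character(0), vip = numeric(0),
                      annotation = character(0), direction = character(0),
                      p = numeric(0), p_bh = numeric(0), stars = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("discriminant_table", "data.frame")
    return(out)
  }
  ann <- annotate_bins(ranked$bin, table)
  doc <- direction_of_change(m, y, bins = ranked$bin,
                             positive_class = positive_class)
  out <- data.frame(bin = ranked$bin, vip = ranked$vip,
                    annotation = ann$annotation[match(ranked$bin, ann$bin)],
                    direction = doc$direction[match(ranked$bin, doc$bin)],
                    p = doc$p[match(ranked$bin, doc$bin)],
                    stringsAsFactors = FALSE)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out$stars <- p_stars(out$p)
  attr(out, "footer") <-
    "p-values are unadjusted; p_bh (Benjamini-Hochberg) is a supplementary extension."
  class(out) <- c("discriminant_table", "data.frame")
  out
}

#' Write a discriminant table as CSV + Markdown twins
#'
#' @param report a `discriminant_table`.
#' @param path_csv,path_md output paths (either may be NULL to skip).
#' @return invisibly, the written paths.
#' @export
write_report <- function(report, path_csv = NULL, path_md = NULL) {
  stopifnot(inherits(report, "discriminant_table"))
  footer <- attr(report, "footer")
  if (!is.null(path_csv))
    utils::write.csv(report, path_csv, row.names = FALSE)
  if (!is.null(path_md)) {
    con <- file(path_md, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines("| bin | VIP | annotation | direction | p | stars |", con)
    writeLines("|---|---|---|---|---|---|", con)
    for (i in seq_len(nrow(report)))
      writeLines(sprintf("| %s | %.2f | %s | %s | %.3g | %s |",
                         report$bin[i], report$vip[i], report$annotation[i],
                         ifelse(is.na(report$direction[i]), "-",
                                report$direction[i]),
                         report$p[i], report$stars[i]), con)
    writeLines(c("", footer), con)
  }
  invisible(c(csv = path_csv, md = path_md))
}
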