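#' Per-ROI means of scalar maps
#'
#' Arithmetic mean of FA, MD, axial and radial diffusivity over the unflagged
#' voxels of each label in an integer ROI mask. Empty ROIs yield `NA` with a
#' warning.
#'
#' @param maps a [scalar_maps()] result.
#' @param labels integer 3D label array (0 = outside all ROIs).
#' @param roi_names optional named integer vector mapping names to label
#'   codes (default: the phantom label table for codes present).
#' @return data.frame with columns `roi`, `label`, `n_voxels`, `FA`, `MD`,
#'   `D_ax`, `D_rad`.
#' @export
roi_means <- function(maps, labels, roi_names = NULL) {
  if (is.null(roi_names)) {
    lt <- phantom_labels()
    codes <- sort(unique(labels[labels > 0L]))
    roi_names <- codes
    names(roi_names) <- names(lt)[match(codes, lt)]
    names(roi_names)[is.na(names(roi_names))] <-
      paste0("roi", codes[is.na(names(roi_names))])
  }
  ok <- !maps$flags & maps$mask
  rows <- lapply(seq_along(roi_names), function(i) {
    sel <- labels == roi_names[i] & ok
    nv <- sum(sel)
    if (nv == 0L) {
      warning(sprintf("ROI '%s' is empty after flag exclusion",
                      names(roi_names)[i]))
      data.frame(roi = names(roi_names)[i], label = roi_names[i],
                 n_voxels = 0L, FA = NA_real_, MD = NA_real_,
                 D_ax = NA_real_, D_rad = NA_real_)
    } else {
      data.frame(roi = names(roi_names)[i], label = roi_names[i],
                 n_voxels = nv,
                 FA = mean(maps$fa[sel]), MD = mean(maps$md[sel]),
                 D_ax = mean(maps$d_ax[sel]), D_rad = mean(maps$d_rad[sel]))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ordinary least squares with inference
#'
#' Closed-form normal-equation solve of `y ~ intercept + X`, with standard
#' errors, t statistics and two-sided p-values. Rejects near-collinear
#' designs (condition number of the augmented design > 1e8).
#'
#' @param y response vector.
#' @param x predictor matrix or data.frame (no intercept column; one is
#'   added).
#' @return object of class `ols_fit`: `coefficients` data.frame (term,
#'   estimate, se, t, p), `df_residual`, `sigma`, `r_squared`.
#' @export
ols <- function(y, x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- length(y)
  if (nrow(x) != n) stop("length(y) must equal nrow(x)")
  p <- ncol(x) + 1L
  if (n <= p) stop(sprintf("need n > %d observations for %d predictors",
                           p, ncol(x)))
  X <- cbind(`(Intercept)` = 1, x)
  if (kappa(X, exact = TRUE) > 1e8)
    stop("collinear design (condition number > 1e8)")
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  resid <- y - X %*% beta
  df <- n - p
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- as.numeric(beta) / se
  pval <- 2 * pt(-abs(tval), df)
  tss <- sum((y - mean(y))^2)
  structure(list(
    coefficients = data.frame(term = colnames(X), estimate = as.numeric(beta),
                              se = se, t = tval, p = pval, row.names = NULL),
    df_residual = df, sigma = sqrt(sigma2),
    r_squared = if (tss > 0) 1 - sum(resid^2) / tss else NA_real_),
    class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  print(x$coefficients, digits = 4)
  cat(sprintf("residual df %d, sigma %.4g, R^2 %.4f\n",
              x$df_residual, x$sigma, x$r_squared))
  invisible(x)
}

#' Regress ROI diffusion indices on post-mortem and scan intervals
#'
#' For each white matter ROI column (CC, SLF, Opt, Cing, PLIC, plus an
#' `Average` column formed from each specimen's mean over the five white
#' matter ROIs) and each index (FA, MD, D_ax, D_rad): a single regression on
#' PMI and on SI (the slopes shown in scatter plots) and a multiple
#' regression on PMI + SI (used for inference). P-values from the multiple
#' regression are corrected across the family of tests (4 indices x 6
#' columns per predictor; Bonferroni by default) and slopes with corrected
#' p above `report_p` are suppressed from the `reported` column, following
#' the table reporting rule.
#'
#' @param roi_table data.frame as from [cohort_roi_table()] (columns
#'   `specimen`, `roi`, `FA`, `MD`, `D_ax`, `D_rad`, `pmi_hours`,
#'   `si_months`).
#' @param wm_rois ROI columns analysed (default the five WM regions).
#' @param correction multiple-comparison method (any [stats::p.adjust()]
#'   method; default `"bonferroni"`).
#' @param report_p corrected-p threshold above which slopes are not reported.
#' @param alpha significance level on corrected p-values.
#' @return data.frame of class `cohort_report`: one row per predictor x index
#'   x column with single-regression slope, multiple-regression slope, se, t,
#'   raw and corrected p, significance flag and `reported` slope (NA when
#'   suppressed).
#' @export
analyze_cohort <- function(roi_table,
                           wm_rois = c("CC", "SLF", "Opt", "Cing", "PLIC"),
                           correction = "bonferroni",
                           report_p = 0.25, alpha = 0.05) {
  need <- c("specimen", "roi", "FA", "MD", "D_ax", "D_rad",
            "pmi_hours", "si_months")
  miss <- setdiff(need, names(roi_table))
  if (length(miss) > 0L)
    stop("roi_table lacks columns: ", paste(miss, collapse = ", "))
  if (anyNA(roi_table[, c("pmi_hours", "si_months")])) {
    bad <- roi_table$specimen[
      !stats::complete.cases(roi_table[, c("pmi_hours", "si_months")])]
    stop("missing covariates for specimen(s): ",
         paste(unique(bad), collapse = ", "))
  }
  specs <- unique(roi_table$specimen)
  if (length(specs) < 5L) stop("need at least 5 specimens")
  cov <- roi_table[!duplicated(roi_table$specimen),
                   c("specimen", "pmi_hours", "si_months")]
  indices <- c("FA", "MD", "D_ax", "D_rad")

  # per-specimen value of one index in one column (ROI or WM average)
  col_value <- function(column, index) {
    if (column == "Average") {
      sub <- roi_table[roi_table$roi %in% wm_rois, ]
      v <- tapply(sub[[index]], sub$specimen, mean)
    } else {
      sub <- roi_table[roi_table$roi == column, ]
      v <- stats::setNames(sub[[index]], sub$specimen)
    }
    as.numeric(v[cov$specimen])
  }

  columns <- c(wm_rois, "Average")
  rows <- list()
  for (column in columns) {
    for (index in indices) {
      y <- col_value(column, index)
      f_pmi <- ols(y, cbind(PMI = cov$pmi_hours))
      f_si <- ols(y, cbind(SI = cov$si_months))
      f_multi <- ols(y, cbind(PMI = cov$pmi_hours, SI = cov$si_months))
      for (pred in c("PMI", "SI")) {
        single <- if (pred == "PMI") f_pmi else f_si
        crow <- single$coefficients[single$coefficients$term == pred, ]
        mrow <- f_multi$coefficients[f_multi$coefficients$term == pred, ]
        rows[[length(rows) + 1L]] <- data.frame(
          predictor = pred, index = index, column = column,
          slope_single = crow$estimate,
          slope_multi = mrow$estimate, se_multi = mrow$se, t_multi = mrow$t,
          p_raw = mrow$p, df_residual = f_multi$df_residual)
      }
    }
  }
  rep_tab <- do.call(rbind, rows)
  # correction within each predictor's family (4 indices x 6 columns)
  rep_tab$p_corrected <- NA_real_
  for (pred in c("PMI", "SI")) {
    sel <- rep_tab$predictor == pred
    rep_tab$p_corrected[sel] <- stats::p.adjust(rep_tab$p_raw[sel],
                                                method = correction)
  }
  rep_tab$significant <- rep_tab$p_corrected <= alpha
  rep_tab$reported <- ifelse(rep_tab$p_corrected <= report_p,
                             rep_tab$slope_single, NA_real_)
  class(rep_tab) <- c("cohort_report", "data.frame")
  attr(rep_tab, "correction") <- correction
  rep_tab
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("cohort regression report (%s-corrected)\n",
              attr(x, "correction")))
  for (pred in unique(x$predictor)) {
    cat(pred, "slopes (single regression; '*' corrected p <= 0.05, blank p > 0.25):\n")
    sub <- x[x$predictor == pred, ]
    wide <- stats::reshape(
      sub[, c("index", "column", "reported", "significant")],
      idvar = "index", timevar = "column", direction = "wide")
    print(wide, digits = 3)
  }
  invisible(x)
}
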