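#' Soluble-biomarker panel analytics
#'
#' Detectability filtering of multiplex (Luminex-style) panels, one-way
#' ANOVA with Sidak-corrected pairwise comparisons against a reference
#' group, and Oil-Red-O absorbance normalisation to total protein.
#'
#' @name panels
NULL

#' Analyte-by-sample panel container
#'
#' @param conc Numeric matrix, analytes x samples (non-negative where
#'   detected).
#' @param detected Logical matrix of the same shape, `TRUE` where the
#'   measurement is above the detection limit.
#' @param sample_info Data frame with columns `sample`, `condition` and
#'   optionally `day`; one row per column of `conc`.  When `day` is
#'   present it is folded into the grouping key (`condition.day`), since
#'   sampling day is part of the experimental condition.
#' @return A `panel_matrix`.
#' @export
panel_matrix <- function(conc, detected = NULL, sample_info = NULL) {
  conc <- as.matrix(conc)
  detected <- detected %||% (is.finite(conc))
  if (!all(dim(detected) == dim(conc)))
    abort_input("detected mask and concentration matrix differ in shape")
  if (any(conc[detected] < 0)) abort_input("detected concentrations must be >= 0")
  if (is.null(sample_info))
    sample_info <- data.frame(sample = colnames(conc) %||%
                                paste0("S", seq_len(ncol(conc))),
                              condition = "all", day = NA_real_)
  if (nrow(sample_info) != ncol(conc))
    abort_input("sample_info must have one row per sample column")
  if (is.null(sample_info$day)) sample_info$day <- NA_real_
  grp <- ifelse(is.na(sample_info$day), as.character(sample_info$condition),
                paste(sample_info$condition, sample_info$day, sep = "."))
  structure(list(conc = conc, detected = detected,
                 sample_info = sample_info, group = grp),
            class = "panel_matrix")
}

#' Filter a panel to consistently detected, responsive analytes
#'
#' An analyte is retained when its detected fraction reaches
#' `min_detected_frac` in at least one condition group; optionally
#' (`require_group_signal`) it must additionally show a significant
#' group difference by one-way ANOVA at `alpha`.  Every dropped analyte
#' appears exactly once in the exclusion report with its primary reason
#' (`"undetected"` screens first).
#'
#' @param panel A [panel_matrix()].
#' @param min_detected_frac Detection-fraction threshold (default 0.5).
#' @param require_group_signal Also require an ANOVA group signal.
#' @param alpha Significance level for the optional signal screen.
#' @return List: `panel` (the retained subset), `report` (analyte,
#'   excluded, reason).
#' @export
filter_detected <- function(panel, min_detected_frac = 0.5,
                            require_group_signal = FALSE, alpha = 0.05) {
  stopifnot(inherits(panel, "panel_matrix"))
  groups <- unique(panel$group)
  n_a <- nrow(panel$conc)
  analytes <- rownames(panel$conc) %||% paste0("A", seq_len(n_a))
  reason <- rep(NA_character_, n_a)
  for (i in seq_len(n_a)) {
    frac <- vapply(groups, function(g)
      mean(panel$detected[i, panel$group == g]), numeric(1))
    if (max(frac) < min_detected_frac) {
      reason[i] <- "undetected"
    } else if (require_group_signal && length(groups) >= 2) {
      vals <- panel$conc[i, ]
      ok <- panel$detected[i, ]
      enough <- all(vapply(groups, function(g)
        sum(ok & panel$group == g) >= 2, logical(1)))
      p <- if (enough && sd(vals[ok]) > 0)
        anova_sidak(vals[ok], panel$group[ok],
                    reference = groups[1])$p else 1
      if (!enough || p >= alpha) reason[i] <- "no_group_difference"
    }
  }
  keep <- is.na(reason)
  sub <- panel_matrix(panel$conc[keep, , drop = FALSE],
                      panel$detected[keep, , drop = FALSE],
                      panel$sample_info)
  list(panel = sub,
       report = data.frame(analyte = analytes, excluded = !keep,
                           reason = reason))
}

#' One-way ANOVA with Sidak-corrected pairwise comparisons
#'
#' Classic fixed-effects one-way ANOVA (F and p), followed by two-tailed
#' pairwise t-tests of every non-reference group against the reference
#' using the pooled ANOVA mean-square error, Sidak-adjusted over the `m`
#' comparisons made: `p_adj = 1 - (1 - p)^m`.
#'
#' @param values Numeric vector of measurements.
#' @param groups Group label per value (>= 2 groups, >= 2 values each).
#' @param reference Reference group label.
#' @return A `group_stats` list: `F`, `p`, `df`, and `comparisons` (data
#'   frame group, estimate, p, p_adj).
#' @export
anova_sidak <- function(values, groups, reference) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) < 2L) abort_input("need >= 2 groups")
  if (!reference %in% lv) abort_input("reference group '%s' absent", reference)
  n_g <- vapply(lv, function(g) sum(groups == g), integer(1))
  if (any(n_g < 2L))
    abort_input("group '%s' has fewer than 2 values", lv[which(n_g < 2L)[1]])
  fit <- lm(values ~ factor(groups))
  av <- anova(fit)
  Fv <- av$`F value`[1]
  p <- av$`Pr(>F)`[1]
  mse <- av$`Mean Sq`[2]
  df_err <- av$Df[2]
  others <- setdiff(lv, reference)
  m <- length(others)
  mean_ref <- mean(values[groups == reference])
  comp <- do.call(rbind, lapply(others, function(g) {
    est <- mean(values[groups == g]) - mean_ref
    se <- sqrt(mse * (1 / sum(groups == g) + 1 / sum(groups == reference)))
    praw <- 2 * pt(-abs(est / se), df_err)
    data.frame(group = g, estimate = est, p = praw,
               p_adj = 1 - (1 - praw)^m)
  }))
  structure(list(F = Fv, p = p, df = av$Df, mse = mse,
                 comparisons = comp), class = "group_stats")
}

#' Normalise Oil-Red-O absorbance to total protein
#'
#' Relative fat content: eluted-stain absorbance divided by total protein.
#'
#' @param absorbance Absorbance (arbitrary units) at the configured
#'   wavelength.
#' @param protein_mg Total protein, milligrams (> 0).
#' @param wavelength_nm Recorded wavelength (metadata only).
#' @return An `oro_measurement`: `absorbance`, `protein_mg`, `normalized`
#'   (A.U. per mg), `wavelength_nm`.
#' @export
oro_normalize <- function(absorbance, protein_mg, wavelength_nm = 515) {
  if (any(protein_mg <= 0)) abort_input("protein_mg must be > 0")
  if (any(absorbance < 0)) abort_input("absorbance must be >= 0")
  structure(list(absorbance = absorbance, protein_mg = protein_mg,
                 normalized = absorbance / protein_mg,
                 wavelength_nm = wavelength_nm), class = "oro_measurement")
}
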