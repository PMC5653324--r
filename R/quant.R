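## qPCR absolute quantification by genome-copy conversion, crystal-violet
## biofilm dye quantification, and competition fold-change statistics.

.AVOGADRO <- 6.022e23

#' qPCR genome-copy quantification model
#'
#' Holds the genome-size-based mass-to-copies conversion constants and,
#' after [fit_standard_curve()], the linear standard curve of Cq against
#' log10(copies).
#'
#' @param genome_size_mbp Genome size in Mbp (default 2.21, the mean draft
#'   genome size of the 21 isolates).
#' @param bp_molar_mass Mean molar mass of a base pair in g/mol/bp
#'   (default 655, the conventional constant that converts 1 pg of a
#'   2.21 Mbp genome to 4.16e2 copies).
#' @return An object of class `quant_model`.
#' @export
quant_model <- function(genome_size_mbp = 2.21, bp_molar_mass = 655) {
  if (genome_size_mbp <= 0 || bp_molar_mass <= 0)
    stop("genome size and bp molar mass must be positive", call. = FALSE)
  structure(list(genome_size_mbp = genome_size_mbp,
                 bp_molar_mass = bp_molar_mass,
                 avogadro = .AVOGADRO,
                 slope = NULL, intercept = NULL, r_squared = NULL,
                 efficiency = NULL, cq_range = NULL, copies_range = NULL),
            class = "quant_model")
}

#' @export
print.quant_model <- function(x, ...) {
  cat(sprintf("quant_model: genome %.2f Mbp, %.0f g/mol/bp\n",
              x$genome_size_mbp, x$bp_molar_mass))
  if (!is.null(x$slope))
    cat(sprintf("  curve: Cq = %.4f * log10(copies) + %.4f (r2 %.4f, efficiency %.2f)\n",
                x$slope, x$intercept, x$r_squared, x$efficiency))
  invisible(x)
}

#' Convert DNA mass to genome copies
#'
#' `copies = mass * N_A / (genome_size_bp * bp_molar_mass)`; strictly
#' linear in mass. With the defaults (2.21 Mbp, 655 g/mol/bp), 1 pg is
#' 4.16e2 genome copies and 100 ng is 4.16e7.
#'
#' @param mass_g DNA mass in grams (vectorised, >= 0).
#' @param model A [quant_model()].
#' @return Genome copies.
#' @export
mass_to_copies <- function(mass_g, model = quant_model()) {
  if (any(mass_g < 0)) stop("mass must be >= 0", call. = FALSE)
  mass_g * model$avogadro / (model$genome_size_mbp * 1e6 * model$bp_molar_mass)
}

#' Fit a qPCR standard curve (Cq on log10 copies)
#'
#' Ordinary least squares of Cq against log10(copies) over the standard
#' dilution series; reports slope, intercept, r-squared and amplification
#' efficiency `10^(-1/slope) - 1` (1.0 for perfect doubling chemistry,
#' slope -log2(10) ~ -3.32).
#'
#' @param points data.frame with columns `copies` (> 0) and `cq`, with at
#'   least 3 distinct copy levels.
#' @param model A [quant_model()] to update.
#' @return The updated `quant_model` with curve fields populated.
#' @export
fit_standard_curve <- function(points, model = quant_model()) {
  if (!all(c("copies", "cq") %in% names(points)))
    stop_stage("fit_standard_curve", "points need columns copies, cq")
  if (any(points$copies <= 0))
    stop_stage("fit_standard_curve", "standard copies must be positive")
  if (length(unique(points$copies)) < 3L)
    stop_stage("fit_standard_curve",
               ">= 3 distinct copy levels required for a standard curve")
  lx <- log10(points$copies)
  fit <- lm(points$cq ~ lx)
  model$slope <- unname(coef(fit)[2])
  model$intercept <- unname(coef(fit)[1])
  tss <- sum((points$cq - mean(points$cq))^2)
  model$r_squared <- if (tss == 0) 1 else 1 - sum(fit$residuals^2) / tss
  model$efficiency <- 10^(-1 / model$slope) - 1
  model$cq_range <- range(predict(fit))
  model$copies_range <- range(points$copies)
  model
}

#' Quantify unknown samples from their Cq values
#'
#' Inverts the fitted standard curve: `copies = 10^((cq - intercept) /
#' slope)`. Cq values outside the fitted standard range are reported but
#' flagged as extrapolated rather than silently trusted.
#'
#' @param cq_values Numeric Cq values.
#' @param model A fitted [quant_model()] (after [fit_standard_curve()]).
#' @return data.frame with `cq`, `copies`, `extrapolated`.
#' @export
quantify_unknowns <- function(cq_values, model) {
  if (is.null(model$slope))
    stop_stage("quantify_unknowns",
               "model has no fitted standard curve; run fit_standard_curve")
  copies <- 10^((cq_values - model$intercept) / model$slope)
  lo <- min(model$cq_range); hi <- max(model$cq_range)
  data.frame(cq = cq_values, copies = copies,
             extrapolated = cq_values < lo - 1e-9 | cq_values > hi + 1e-9)
}

#' Convert crystal-violet absorbance readings to dye mass
#'
#' OLS of standard dye mass (μg) on absorbance, applied to the readings;
#' predictions below zero (readings under the blank) are clamped to 0 and
#' flagged.
#'
#' @param absorbance Numeric absorbance readings.
#' @param cv_curve data.frame with columns `mass_ug` and `absorbance`
#'   (>= 2 standard points).
#' @return data.frame with `absorbance`, `mass_ug`, `clamped`.
#' @export
crystal_violet_mass <- function(absorbance, cv_curve) {
  if (!all(c("mass_ug", "absorbance") %in% names(cv_curve)) ||
      nrow(cv_curve) < 2L)
    stop_stage("crystal_violet_mass",
               "cv_curve needs >= 2 rows of mass_ug, absorbance")
  fit <- lm(mass_ug ~ absorbance, data = cv_curve)
  pred <- unname(predict(fit, data.frame(absorbance = absorbance)))
  data.frame(absorbance = absorbance, mass_ug = pmax(pred, 0),
             clamped = pred < -1e-9)
}

#' Group mean ± SD summary of a measurement table
#'
#' @param table data.frame with columns `group`, `timepoint_h`, `value`.
#' @return data.frame with `group`, `timepoint_h`, `n`, `mean`, `sd`.
#' @export
summarize_measurements <- function(table) {
  agg <- split(table$value, list(table$group, table$timepoint_h),
               drop = TRUE)
  out <- do.call(rbind, lapply(names(agg), function(k) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    data.frame(group = parts[1], timepoint_h = as.numeric(parts[2]),
               n = length(agg[[k]]), mean = mean(agg[[k]]),
               sd = if (length(agg[[k]]) > 1) sd(agg[[k]]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out[order(out$timepoint_h, out$group), , drop = FALSE]
}

#' Per-strain competition fold change and group comparison
#'
#' Fold change is value(48 h) / value(24 h) per strain; strains missing a
#' time point or with a zero 24-h value are excluded with a warning. The
#' group comparison is a Welch t-test on log fold changes (counts act
#' multiplicatively).
#'
#' @param table data.frame with columns `strain_id`, `group`,
#'   `timepoint_h` (24 and 48), `value`.
#' @param t_from,t_to Time points compared (defaults 24 and 48 h).
#' @return List with `fold_changes` (data.frame `strain_id`, `group`,
#'   `fold_change`) and `test` (`t`, `df`, `p_value` on log fold changes).
#' @export
competition_fold_change <- function(table, t_from = 24, t_to = 48) {
  need <- c("strain_id", "group", "timepoint_h", "value")
  if (!all(need %in% names(table)))
    stop_stage("competition_fold_change", "table needs columns: ",
               paste(need, collapse = ", "))
  rows <- lapply(unique(table$strain_id), function(s) {
    sub <- table[table$strain_id == s, ]
    v0 <- sub$value[sub$timepoint_h == t_from]
    v1 <- sub$value[sub$timepoint_h == t_to]
    if (length(v0) != 1L || length(v1) != 1L) {
      warning("strain ", s, " missing a time point; excluded",
              call. = FALSE)
      return(NULL)
    }
    if (v0 <= 0) {
      warning("strain ", s, " has zero baseline count; excluded",
              call. = FALSE)
      return(NULL)
    }
    data.frame(strain_id = s, group = sub$group[1], fold_change = v1 / v0,
               stringsAsFactors = FALSE)
  })
  fc <- do.call(rbind, rows)
  if (is.null(fc) || nrow(fc) == 0L)
    stop_stage("competition_fold_change", "no strain with both time points")
  gl <- unique(fc$group)
  test <- if (length(gl) == 2L &&
              all(table(fc$group) >= 2L))
    welch_t_test(log(fc$fold_change[fc$group == gl[1]]),
                 log(fc$fold_change[fc$group == gl[2]]))
  else NULL
  list(fold_changes = fc, test = test)
}
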