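# Zooid morphometrics: elliptical areas, log-area ANCOVA between
# phylogroups, and zooid-length versus SST regression.

#' Zooid and orifice areas from linear dimensions
#'
#' Ellipse approximation `(pi / 4) L W`; a `"rectangle"` mode (`L W`) is
#' available since on the log scale a constant factor only shifts
#' intercepts and leaves the ANCOVA F statistics unchanged.
#'
#' @param records Data frame of zooid records with columns `L_z_mm`,
#'   `W_z_mm`, `L_or_mm`, `W_or_mm` (all positive, millimetres).
#' @param shape `"ellipse"` (default) or `"rectangle"`.
#' @return `records` with added columns `zooid_area`, `orifice_area`
#'   (mm^2).
#' @export
zooid_areas <- function(records, shape = c("ellipse", "rectangle")) {
  shape <- match.arg(shape)
  dims <- c("L_z_mm", "W_z_mm", "L_or_mm", "W_or_mm")
  missing_cols <- setdiff(dims, names(records))
  if (length(missing_cols) > 0L) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (d in dims) {
    if (any(!is.finite(records[[d]]) | records[[d]] <= 0)) {
      stop("non-positive or missing dimension in ", d, call. = FALSE)
    }
  }
  k <- if (shape == "ellipse") pi / 4 else 1
  records$zooid_area <- k * records$L_z_mm * records$W_z_mm
  records$orifice_area <- k * records$L_or_mm * records$W_or_mm
  records
}

#' ANCOVA of log10 orifice area on log10 zooid area between groups
#'
#' Fits `log10(orifice_area) ~ log10(zooid_area) + group` and tests the
#' group term by nested-model sum-of-squares comparison against the
#' covariate-only model; a second test adds the `covariate x group`
#' interaction to test slope heterogeneity. A Bartlett test of the
#' full-model residuals across groups is reported as a
#' homogeneity-of-variance diagnostic.
#'
#' @param records Zooid records (see [zooid_areas()]) with a grouping
#'   column.
#' @param grouping Name of the grouping column (default `"phylogroup"`),
#'   or a vector of group labels aligned with `records`.
#' @param shape Area mode passed to [zooid_areas()].
#' @return List of two `ancova_result` rows (`term`, `F`, `df_num`,
#'   `df_den`, `p`) named `group` and `slope_heterogeneity`, plus
#'   `variance_homogeneity_p`.
#' @export
ancova_log_areas <- function(records, grouping = "phylogroup",
                             shape = "ellipse") {
  grp <- if (length(grouping) == 1L && is.character(grouping)) {
    records[[grouping]]
  } else {
    grouping
  }
  grp <- factor(grp)
  if (nlevels(grp) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(table(grp) < 3L)) stop("need >= 3 records per group",
                                 call. = FALSE)
  records <- zooid_areas(records, shape = shape)
  dat <- data.frame(y = log10(records$orifice_area),
                    x = log10(records$zooid_area), g = grp)
  m0 <- stats::lm(y ~ x, data = dat)
  m1 <- stats::lm(y ~ x + g, data = dat)
  m2 <- stats::lm(y ~ x * g, data = dat)
  if (any(!is.finite(stats::coef(m2)))) {
    stop("collinearity: singular design", call. = FALSE)
  }
  f_test <- function(small, big) {
    a <- stats::anova(small, big)
    list(F = a$F[2L], df_num = a$Df[2L], df_den = a$Res.Df[2L],
         p = a$`Pr(>F)`[2L])
  }
  grp_t <- f_test(m0, m1)
  slope_t <- f_test(m1, m2)
  homo <- stats::bartlett.test(stats::residuals(m2), dat$g)
  as_row <- function(term, t) {
    data.frame(term = term, F = t$F, df_num = t$df_num, df_den = t$df_den,
               p = t$p, stringsAsFactors = FALSE)
  }
  list(
    group = as_row("group", grp_t),
    slope_heterogeneity = as_row("slope-heterogeneity", slope_t),
    variance_homogeneity_p = unname(homo$p.value)
  )
}

#' Least-squares regression of zooid length on SST
#'
#' Ordinary least squares of `L_z_mm` on `sst_c`, returning the slope
#' (mm per deg C), intercept, R-squared and the slope t-test p-value.
#'
#' @param records Zooid records with columns `L_z_mm` and `sst_c`.
#' @return List with `slope`, `intercept`, `r_squared`, `p`, `n`.
#' @export
length_sst_regression <- function(records) {
  if (nrow(records) < 3L) stop("need at least 3 records", call. = FALSE)
  if (length(unique(records$sst_c)) < 2L) {
    stop("degenerate regressor: SST is constant", call. = FALSE)
  }
  fit <- stats::lm(L_z_mm ~ sst_c, data = records)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared,
       p = sm$coefficients[2L, 4L],
       n = nrow(records),
       fit = fit)
}

#' Read zooid-morphometric records from CSV
#'
#' @param path CSV with columns `colony_id`, `phylogroup`, `site`, `sst_c`,
#'   `L_z_mm`, `W_z_mm`, `L_or_mm`, `W_or_mm`.
#' @return Validated data frame.
#' @export
read_zooid_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("colony_id", "phylogroup", "site", "sst_c", "L_z_mm",
                "W_z_mm", "L_or_mm", "W_or_mm")
  missing_cols <- setdiff(required, names(rec))
  if (length(missing_cols) > 0L) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  zooid_areas(rec)[required]   # validates positivity, returns schema cols
}
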