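## Per-portal infiltrated boundary ratios and slide-level statistics.

#' Infiltrated boundary ratio of one portal
#'
#' The infiltrated length sums the arc lengths of regions predicted
#' infiltrated: protruding regions contribute their boundary arc (not the
#' chord), non-protruding segments their run length (the contribution of
#' each kind can be switched off). The ratio is clipped to \[0, 1\], since
#' protruding arcs absorb half of each flanking quiet stretch and the two
#' accountings can overlap slightly.
#'
#' @param predictions Prediction table from [predict_regions()] for one
#'   portal.
#' @param portal The `portal_region` (provides the perimeter).
#' @param include_protruding,include_nonprotruding Which infiltrated kinds
#'   count towards the length, both `TRUE` by default.
#' @return `list(portal_id, infiltrated_length_um, perimeter_um, ratio)`.
#' @export
portal_ratio <- function(predictions, portal, include_protruding = TRUE,
                         include_nonprotruding = TRUE) {
  per <- portal$perimeter_um
  if (!is.finite(per) || per <= 0) stop("portal perimeter must be positive")
  len <- 0
  inf <- predictions$label == "infiltrated"
  if (include_protruding) {
    sel <- inf & predictions$kind == "protruding"
    len <- len + sum(predictions$contour_length_um[sel], na.rm = TRUE)
  }
  if (include_nonprotruding) {
    sel <- inf & predictions$kind == "non_protruding"
    len <- len + sum(predictions$length_um[sel], na.rm = TRUE)
  }
  len <- min(len, per)
  list(portal_id = portal$id, infiltrated_length_um = len,
       perimeter_um = per, ratio = len / per)
}

#' Slide-level statistics of the per-portal infiltrated ratios
#'
#' Five summaries of the per-portal infiltrated boundary ratios:
#' \describe{
#'   \item{mode}{most frequent ratio after quantising to bins of width
#'     `quantization` (ties broken towards the smaller bin; the bin's lower
#'     edge is reported). In weakly infiltrated slides most portals have
#'     ratio zero, so the mode is typically 0.}
#'   \item{median}{ordinary sample median.}
#'   \item{S_avg}{mean of the per-portal ratios.}
#'   \item{S_mdt}{the mediant: summed infiltrated lengths over summed
#'     perimeters.}
#'   \item{S_avg25}{mean ratio of the ceiling(n/4) most infiltrated
#'     portals.}
#' }
#'
#' @param ratios Data frame (or list of [portal_ratio()] results) with
#'   columns `ratio`, `infiltrated_length_um`, `perimeter_um`.
#' @param quantization Mode bin width, default 0.05.
#' @return `list(mode, median, S_avg, S_mdt, S_avg25, n_portals)`.
#' @export
scene_statistics <- function(ratios, quantization = 0.05) {
  if (is.list(ratios) && !is.data.frame(ratios)) {
    ratios <- do.call(rbind, lapply(ratios, as.data.frame))
  }
  n <- nrow(ratios)
  if (is.null(n) || n == 0L) stop("at least one portal ratio is required")
  r <- ratios$ratio
  bins <- floor(r / quantization + 1e-9) * quantization
  tab <- table(bins)
  best <- max(tab)
  mode_val <- min(as.numeric(names(tab)[tab == best]))
  k <- ceiling(n / 4)
  top <- sort(r, decreasing = TRUE)[seq_len(k)]
  list(mode = mode_val,
       median = median(r),
       S_avg = mean(r),
       S_mdt = sum(ratios$infiltrated_length_um) / sum(ratios$perimeter_um),
       S_avg25 = mean(top),
       n_portals = n)
}

#' Correlate a ratio statistic with a clinical covariate
#'
#' Numerical covariates (grades, AST, ALT, age, ...) are tested with
#' Spearman rank correlation (tie-corrected, asymptotic p); binary
#' covariates (sex, virus status, ...) with a two-sided Mann-Whitney U
#' test.
#'
#' @param stat_values Numeric vector of per-slide statistic values.
#' @param covariate Numeric vector (numerical kind) or 2-level
#'   factor/vector (binary kind), same length.
#' @param covariate_kind `"numerical"` or `"binary"`.
#' @return `list(estimate, p_value, method, flag)`; `estimate` is the
#'   Spearman rho or the U statistic. Constant input sets `flag` and
#'   returns `NA` estimates.
#' @export
correlate_statistic <- function(stat_values, covariate,
                                covariate_kind = c("numerical", "binary")) {
  covariate_kind <- match.arg(covariate_kind)
  ok <- is.finite(stat_values) & !is.na(covariate)
  x <- stat_values[ok]
  if (length(x) < 4L) stop("need at least 4 paired finite values")
  if (length(unique(x)) < 2L) {
    return(list(estimate = NA_real_, p_value = NA_real_,
                method = covariate_kind, flag = "constant statistic"))
  }
  if (covariate_kind == "numerical") {
    g <- as.numeric(covariate)[ok]
    if (length(unique(g)) < 2L) {
      return(list(estimate = NA_real_, p_value = NA_real_,
                  method = "spearman", flag = "constant covariate"))
    }
    ct <- suppressWarnings(cor.test(x, g, method = "spearman", exact = FALSE))
    list(estimate = unname(ct$estimate), p_value = ct$p.value,
         method = "spearman", flag = NA_character_)
  } else {
    g <- factor(covariate[ok])
    if (nlevels(g) != 2L) stop("binary covariate must have exactly 2 levels")
    wt <- suppressWarnings(wilcox.test(x ~ g, exact = length(x) <= 20))
    list(estimate = unname(wt$statistic), p_value = wt$p.value,
         method = "mann-whitney", flag = NA_character_)
  }
}
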