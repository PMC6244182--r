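# vacuum permittivity, F/m
EPS0 <- 8.8541878128e-12

#' Evaluate the single-pole Debye complex relative permittivity
#'
#' \deqn{\varepsilon^*(\omega) = \varepsilon_\infty +
#'   \frac{\Delta\varepsilon}{1 + j\omega\tau} +
#'   \frac{\sigma_s}{j\omega\varepsilon_0}, \quad \omega = 2\pi f}
#'
#' The loss convention is \eqn{\varepsilon^* = \varepsilon' -
#' j\varepsilon''}: the imaginary part returned is negative (or zero)
#' for physical parameters.
#'
#' @param params a [DebyeParameters-class].
#' @param frequency_Hz one or more positive frequencies in Hz.
#' @return Complex relative permittivity, one value per frequency.
#' @examples
#' debyePermittivity(debyeParameters(7, 10, 13e-12, 0.2), 3e9)
#' @export
debyePermittivity <- function(params, frequency_Hz) {
  stopifnot(is(params, "DebyeParameters"))
  if (any(!is.finite(frequency_Hz)) || any(frequency_Hz <= 0))
    stop("invalid frequency: frequencies must be positive")
  w <- 2 * pi * frequency_Hz
  params@eps_inf + params@delta_eps / (1 + 1i * w * params@tau_s) +
    params@sigma_s / (1i * w * EPS0)
}

#' Dielectric spectrum of a Debye parameter set
#'
#' Tabulates \eqn{\varepsilon'}, \eqn{\varepsilon''} and the effective
#' conductivity \eqn{\sigma(\omega) = \omega\varepsilon_0\varepsilon''}
#' over a frequency grid.
#'
#' @param params a [DebyeParameters-class].
#' @param frequencies_Hz ascending positive frequencies in Hz.
#' @return A data.frame with columns \code{frequency_Hz},
#'   \code{eps_real}, \code{eps_imag} (signed, negative = loss),
#'   \code{sigma_S_m}.
#' @examples
#' debyeSpectrum(debyeParameters(7, 10, 13e-12, 0.2), c(1e9, 3e9, 6e9))
#' @export
debyeSpectrum <- function(params, frequencies_Hz = seq(5e8, 1e10,
                                                       length.out = 20)) {
  if (is.unsorted(frequencies_Hz))
    stop("frequencies must be ascending")
  eps <- debyePermittivity(params, frequencies_Hz)
  data.frame(frequency_Hz = frequencies_Hz,
             eps_real = Re(eps), eps_imag = Im(eps),
             sigma_S_m = -Im(eps) * 2 * pi * frequencies_Hz * EPS0)
}

#' Linear intensity-to-weight mapping
#'
#' Maps a cluster mean intensity onto \eqn{[0, 1]} linearly across the
#' tissue intensity range, clamping outside it:
#' \eqn{w = (\bar I - l) / (u - l)}.
#'
#' @param mean_intensity cluster mean intensity.
#' @param range numeric(2), (lower, upper) with lower < upper.
#' @return Weight in [0, 1].
#' @examples
#' mapIntensityToWeight(190, c(120, 260))
#' @export
mapIntensityToWeight <- function(mean_intensity, range) {
  stopifnot(length(range) == 2L, range[1] < range[2])
  min(max((mean_intensity - range[1]) / (range[2] - range[1]), 0), 1)
}

#' Convex combination of two Debye property curves
#'
#' Combines the lower and upper bounding curves componentwise:
#' each of \eqn{\varepsilon_\infty}, \eqn{\Delta\varepsilon},
#' \eqn{\tau}, \eqn{\sigma_s} becomes \eqn{(1-w)\,l + w\,u}. Parameter-
#' space combination keeps the result a valid single-pole Debye model
#' (a pointwise-in-frequency mixture generally is not).
#'
#' @param w weight in [0, 1].
#' @param lower,upper [DebyeParameters-class] endpoint curves.
#' @return A [DebyeParameters-class].
#' @examples
#' tab <- defaultPropertyTable()
#' combinePropertyCurves(0.5, tab@entries$fgt_lower, tab@entries$fgt_upper)
#' @export
combinePropertyCurves <- function(w, lower, upper) {
  stopifnot(w >= 0, w <= 1, is(lower, "DebyeParameters"),
            is(upper, "DebyeParameters"))
  mix <- function(a, b) (1 - w) * a + w * b
  debyeParameters(mix(lower@eps_inf, upper@eps_inf),
                  mix(lower@delta_eps, upper@delta_eps),
                  mix(lower@tau_s, upper@tau_s),
                  mix(lower@sigma_s, upper@sigma_s))
}

#' Apply a fibroglandular property level
#'
#' Scales \eqn{\varepsilon_\infty}, \eqn{\Delta\varepsilon} and
#' \eqn{\sigma_s} by the level's factor (1.0 / 0.85 / 0.75 for
#' high / med / low) and leaves \eqn{\tau} unchanged, so that the whole
#' complex permittivity curve is scaled by the factor at every
#' frequency. A warning is emitted if the scaled \eqn{\varepsilon_\infty}
#' drops below 1 (unphysical but permitted by the literal scaling).
#'
#' @param params a [DebyeParameters-class].
#' @param level a [PropertyLevel-class].
#' @return A scaled [DebyeParameters-class].
#' @examples
#' applyPropertyLevel(debyeParameters(16, 25, 13e-12, 0.7),
#'                    propertyLevel("med"))
#' @export
applyPropertyLevel <- function(params, level) {
  stopifnot(is(params, "DebyeParameters"), is(level, "PropertyLevel"))
  s <- level@scale
  out <- params
  # literal curve scaling may push eps_inf below the physical bound; it
  # is permitted with a warning, so bypass the class validity here
  slot(out, "eps_inf", check = FALSE) <- s * params@eps_inf
  slot(out, "delta_eps", check = FALSE) <- s * params@delta_eps
  slot(out, "sigma_s", check = FALSE) <- s * params@sigma_s
  if (out@eps_inf < 1)
    warning(sprintf("scaled eps_inf = %.3g < 1 (unphysical)", out@eps_inf))
  out
}

#' Default reference property table
#'
#' Loads the representative tissue property table shipped with the
#' package (see \code{inst/extdata/default_properties.yaml}): one
#' single-pole Debye parameter set per tissue role plus the intensity
#' ranges of the linear mapping. The values are representative synthetic
#' defaults; replace them with your own table via [readPropertyTable()]
#' for quantitative work.
#'
#' @return A [ReferencePropertyTable-class].
#' @examples
#' defaultPropertyTable()
#' @export
defaultPropertyTable <- function() {
  readPropertyTable(system.file("extdata", "default_properties.yaml",
                                package = "BreastPhantom", mustWork = TRUE))
}

#' Read / write a reference property table (YAML config)
#'
#' Human-editable key-value config with one block per tissue role (four
#' Debye entries each) and one intensity range per role.
#'
#' @param path YAML file path.
#' @param table a [ReferencePropertyTable-class] (writer).
#' @return The reader returns a [ReferencePropertyTable-class]; the
#'   writer returns \code{path} invisibly.
#' @examples
#' tab <- defaultPropertyTable()
#' f <- tempfile(fileext = ".yaml")
#' writePropertyTable(tab, f)
#' readPropertyTable(f)
#' @export
readPropertyTable <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$entries)) stop("property table config lacks 'entries'")
  entries <- lapply(cfg$entries, function(e)
    debyeParameters(e$eps_inf, e$delta_eps, e$tau_s, e$sigma_s))
  ranges <- lapply(cfg$ranges, as.numeric)
  new("ReferencePropertyTable", entries = entries, ranges = ranges)
}

#' @rdname readPropertyTable
#' @export
writePropertyTable <- function(table, path) {
  stopifnot(is(table, "ReferencePropertyTable"))
  cfg <- list(
    entries = lapply(table@entries, function(e)
      list(eps_inf = e@eps_inf, delta_eps = e@delta_eps,
           tau_s = e@tau_s, sigma_s = e@sigma_s)),
    ranges = lapply(table@ranges, as.numeric))
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

#' Assign dielectric properties to all model elements
#'
#' Skin, fat and tumour clusters receive their reference parameters
#' directly. Each fibroglandular cluster is mapped linearly: its mean
#' intensity is converted to a weight over the fibroglandular intensity
#' range ([mapIntensityToWeight()]), the lower and upper bounding curves
#' are combined with that weight ([combinePropertyCurves()]), and the
#' requested property level is applied ([applyPropertyLevel()]).
#'
#' @param labelmap a [TissueLabelMap-class].
#' @param stats the matching [clusterStatistics()] data.frame.
#' @param table a [ReferencePropertyTable-class] covering every tissue
#'   role present.
#' @param level a [PropertyLevel-class]; scales fibroglandular curves
#'   only.
#' @param model_name stored in the model attributes.
#' @return A [BreastModel-class] with one [DebyeParameters-class] per
#'   non-background label and recomputable attributes (density, class).
#' @examples
#' p <- syntheticParams(grid = c(32, 32, 16), spacing = c(2, 2, 2),
#'                      breast_semi_axes_mm = c(30, 24, 14),
#'                      skin_thickness_mm = 3)
#' gen <- generateBreastVolume(p)
#' bm <- buildBreastMask(gen$volume)
#' lm <- segmentTissues(gen$volume, bm, skin_thickness_mm = 3)
#' st <- clusterStatistics(gen$volume, lm)
#' assignProperties(lm, st, defaultPropertyTable(), propertyLevel("high"))
#' @export
assignProperties <- function(labelmap, stats, table,
                             level = propertyLevel("high"),
                             model_name = "BM_Model_001") {
  stopifnot(is(labelmap, "TissueLabelMap"),
            is.data.frame(stats),
            is(table, "ReferencePropertyTable"),
            is(level, "PropertyLevel"))
  lg <- labelLegend(labelmap)
  roles <- setdiff(names(lg), "background")
  if (!all(roles %in% stats$tissue))
    stop("stats does not cover all labels")

  need <- unique(ifelse(grepl("^fgt_", roles), "fgt", roles))
  have <- names(table@entries)
  if (any(grepl("^fgt_", roles)) &&
      !all(c("fgt_lower", "fgt_upper") %in% have))
    stop("incomplete property table: missing fgt_lower/fgt_upper")
  plain <- setdiff(need, "fgt")
  if (!all(plain %in% have))
    stop("incomplete property table: missing ",
         paste(setdiff(plain, have), collapse = ", "))
  if (any(grepl("^fgt_", roles)) && is.null(table@ranges$fgt))
    stop("incomplete property table: missing fgt intensity range")

  props <- list()
  for (role in roles) {
    if (grepl("^fgt_", role)) {
      mi <- stats$mean_intensity[stats$tissue == role]
      w <- mapIntensityToWeight(mi, table@ranges$fgt)
      par <- combinePropertyCurves(w, table@entries$fgt_lower,
                                   table@entries$fgt_upper)
      props[[role]] <- applyPropertyLevel(par, level)
    } else {
      props[[role]] <- table@entries[[role]]
    }
  }

  density <- computeDensity(labelmap)
  new("BreastModel", labelmap = labelmap, properties = props,
      attributes = list(
        breast_health = if ("tumour" %in% roles) "diseased" else "healthy",
        breast_class = classifyBreast(density),
        density_percent = density,
        model_name = model_name,
        n_fgt_clusters = sum(grepl("^fgt_", roles)),
        property_level = level@name,
        voxel_size_mm = voxelSpacing(labelmap)))
}
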