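#' Define the fuel complex for the simulated stand
#'
#' A static surface + canopy fuel description of the single hypothetical stand
#' being burned. Defaults follow Anderson Fuel Model 10 (timber litter with
#' understory), the anchor for the inter-class load ratios: 1-h 6.75, 10-h
#' 4.48, 100-h 11.23, live woody 4.48 Mg/ha, with a 30.5-cm fuel bed. Use
#' [scale_fuel_complex()] to move along the fuel-loading gradient while
#' preserving these ratios.
#'
#' @param load_1h,load_10h,load_100h Dead fuel loads, Mg/ha.
#' @param load_live_herb,load_live_woody Live fuel loads, Mg/ha.
#' @param sav_1h Surface-area-to-volume ratio of 1-h fuels, 1/cm.
#' @param fuelbed_depth Fuel bed depth, cm.
#' @param heat_content Heat content, kJ/kg.
#' @param moisture_of_extinction Dead fuel moisture of extinction (fraction).
#' @param slope Terrain slope, percent.
#' @param wind_adj Wind adjustment factor from open (6.1-m) windspeed to
#'   midflame windspeed (unitless).
#' @param canopy_base_height Canopy base height, m.
#' @param canopy_bulk_density Canopy bulk density, kg/m^3.
#' @param canopy_fuel_load Available canopy fuel load, Mg/ha.
#'
#' @return A list of class `fuel_complex`.
#' @export
fuel_complex <- function(load_1h = 6.75,
                         load_10h = 4.48,
                         load_100h = 11.23,
                         load_live_herb = 0,
                         load_live_woody = 4.48,
                         sav_1h = 65.6,
                         fuelbed_depth = 30.5,
                         heat_content = 18608,
                         moisture_of_extinction = 0.25,
                         slope = 40,
                         wind_adj = 0.4,
                         canopy_base_height = 1.2,
                         canopy_bulk_density = 0.18,
                         canopy_fuel_load = 12) {
  loads <- c(load_1h, load_10h, load_100h, load_live_herb, load_live_woody)
  if (any(loads < 0)) stop("fuel loads must be >= 0", call. = FALSE)
  if (moisture_of_extinction <= 0 || moisture_of_extinction >= 1)
    stop("`moisture_of_extinction` must be in (0, 1)", call. = FALSE)
  if (slope < 0) stop("`slope` must be >= 0", call. = FALSE)
  if (fuelbed_depth <= 0) stop("`fuelbed_depth` must be > 0", call. = FALSE)
  structure(as.list(environment())[names(formals(fuel_complex))],
            class = "fuel_complex")
}

#' Scale a fuel complex to a target 100-h load
#'
#' Rescales every surface fuel load (and the fuel bed depth, so the packing
#' ratio is preserved) so that the 100-h dead load equals `load_100h`, keeping
#' the Fuel Model 10 inter-class ratios. This is how the fuel-loading gradient
#' is traversed.
#'
#' @param fuels A [fuel_complex()].
#' @param load_100h Target 100-h dead fuel load, Mg/ha.
#' @return A rescaled `fuel_complex`.
#' @export
scale_fuel_complex <- function(fuels, load_100h) {
  stopifnot(inherits(fuels, "fuel_complex"), load_100h > 0)
  s <- load_100h / fuels$load_100h
  for (f in c("load_1h", "load_10h", "load_100h",
              "load_live_herb", "load_live_woody", "fuelbed_depth"))
    fuels[[f]] <- fuels[[f]] * s
  fuels
}

#' @export
print.fuel_complex <- function(x, ...) {
  cat(sprintf(
    paste0("<fuel_complex> loads (Mg/ha): 1h %.2f, 10h %.2f, 100h %.2f, ",
           "herb %.2f, woody %.2f\n  depth %.1f cm, slope %.0f%%, Mx %.0f%%, ",
           "CBH %.1f m, CBD %.2f kg/m3\n"),
    x$load_1h, x$load_10h, x$load_100h, x$load_live_herb, x$load_live_woody,
    x$fuelbed_depth, x$slope, 100 * x$moisture_of_extinction,
    x$canopy_base_height, x$canopy_bulk_density))
  invisible(x)
}
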