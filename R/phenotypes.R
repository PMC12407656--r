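#' Smoking initiation from questionnaire response
#'
#' A person counts as a smoker only after having smoked for a full year or
#' longer; shorter smoking histories code as 0. Missing answers propagate.
#'
#' @param everSmokedFullYear logical/0-1 vector (NA = not answered).
#' @return integer 0/1 vector with NA preserved.
#' @export
smokingInitiation <- function(everSmokedFullYear) {
  out <- as.integer(as.logical(everSmokedFullYear))
  out
}

#' Pack-years of smoking
#'
#' Cumulative smoking exposure: the sum over tobacco product types of daily
#' units times a cigarette-equivalence weight, divided by 20 (one pack-year
#' is 20 cigarettes per day for one year) and multiplied by years smoked.
#' Equivalence weights default to 1 for every product type (cigarettes,
#' cigarillos, cigars, pipe tobacco grams) and are configurable.
#'
#' @param unitsPerDay named numeric vector (or single number) of average
#'   daily units by product type; all non-negative.
#' @param years years smoked, non-negative.
#' @param equivalence cigarette-equivalence weight per product type; recycled
#'   against \code{unitsPerDay}.
#' @return pack-years (non-negative scalar).
#' @examples
#' packYears(20, 1)        # 1 pack-year
#' packYears(10, 30)       # 15 pack-years
#' @export
packYears <- function(unitsPerDay, years, equivalence = 1) {
  if (any(unitsPerDay < 0, na.rm = TRUE) || any(years < 0, na.rm = TRUE))
    stop("units per day and years must be non-negative")
  cigEq <- sum(unitsPerDay * equivalence)
  cigEq / 20 * years
}

#' Default alcohol frequency-category midpoints (days per week)
#'
#' Labels follow the food-frequency questionnaire: 'not this month' maps to
#' 0 days/week, single-day categories to their value, and ranged categories
#' to their midpoint ('6-7 days per week' to 6.5).
#'
#' @return named numeric vector.
#' @export
alcoholFrequencyMidpoints <- function() {
  c("not this month" = 0, "1 day per month" = 0.25,
    "2-3 days per month" = 0.625, "1 day per week" = 1,
    "2-3 days per week" = 2.5, "4-5 days per week" = 4.5,
    "6-7 days per week" = 6.5)
}

#' Default glasses-per-drinking-day midpoints
#'
#' Categories '1' through '11' map to their value; '12 or more' to 12.
#'
#' @return named numeric vector.
#' @export
alcoholGlassMidpoints <- function() {
  g <- as.character(1:11)
  setNames(c(1:11, 12), c(g, "12 or more"))
}

#' Default ethanol grams per glass by beverage
#'
#' 10 g (the Dutch standard glass) for every alcoholic beverage, 0 for
#' alcohol-free beer.
#'
#' @return named numeric vector.
#' @export
ethanolPerGlassDefaults <- function() {
  c(beer = 10, alcohol_free_beer = 0, red_wine_rose = 10, white_wine = 10,
    sherry = 10, distilled = 10, other = 10)
}

#' Average daily alcohol intake in grams per day
#'
#' For each beverage, (midpoint days/week / 7) x midpoint glasses x grams
#' ethanol per glass, summed over beverages. A frequency of 'not this month'
#' contributes nothing regardless of the glasses category.
#'
#' @param frequency named character vector: frequency category per beverage.
#' @param glasses named character vector: glasses category per beverage
#'   (same names).
#' @param freqMidpoints,glassMidpoints,ethanolPerGlass conversion tables;
#'   see the corresponding default constructors.
#' @return grams of ethanol per day (scalar).
#' @examples
#' dailyAlcoholGrams(c(beer = "6-7 days per week"), c(beer = "2"))
#' @export
dailyAlcoholGrams <- function(frequency, glasses,
                              freqMidpoints = alcoholFrequencyMidpoints(),
                              glassMidpoints = alcoholGlassMidpoints(),
                              ethanolPerGlass = ethanolPerGlassDefaults()) {
  if (!identical(names(frequency), names(glasses)))
    stop("frequency and glasses must cover the same beverages")
  bad <- setdiff(frequency, names(freqMidpoints))
  if (length(bad)) stop("unknown frequency category: ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(glasses, names(glassMidpoints))
  if (length(bad)) stop("unknown glasses category: ",
                        paste(bad, collapse = ", "))
  bev <- names(frequency)
  if (any(!bev %in% names(ethanolPerGlass)))
    stop("no ethanol-per-glass entry for: ",
         paste(setdiff(bev, names(ethanolPerGlass)), collapse = ", "))
  daysWk <- freqMidpoints[frequency]
  gl <- glassMidpoints[glasses]
  sum(daysWk / 7 * gl * ethanolPerGlass[bev])
}

#' Lifetime cannabis use from the two-gate drug questions
#'
#' Cannabis use is asked only of respondents who ever used drugs: the coding
#' is 1 iff both gates are yes, 0 if either gate is no, and missing when the
#' first gate is unanswered.
#'
#' @param everDrugs 0/1/NA vector: ever used drugs.
#' @param everCannabis 0/1/NA vector: ever used cannabis (asked when
#'   \code{everDrugs == 1}).
#' @return integer 0/1 vector with NA where the first gate is missing.
#' @export
lifetimeCannabis <- function(everDrugs, everCannabis) {
  out <- ifelse(is.na(everDrugs), NA_integer_,
                ifelse(everDrugs == 0, 0L,
                       ifelse(is.na(everCannabis), NA_integer_,
                              as.integer(everCannabis == 1))))
  out
}
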