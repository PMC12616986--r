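#' Seasonal feed calendars for the two nutritional scenarios
#'
#' Generates the daily dry-matter (DM) offer and metabolizable-energy (ME)
#' content of the diet for the non-limiting ("HS", high & stable: ad libitum
#' feed) and limiting ("MS", moderate & stable: seasonally restricted offer)
#' nutritional environments. The calendar is deterministic and periodic with
#' a 365-day season cycle; day 1 is defined as the first day of the calving
#' season.
#'
#' The MS offer follows a raised-cosine-power seasonal curve
#' \deqn{o(d) = o_{min} + (o_{max}-o_{min})\,\left[\tfrac{1}{2}(1+\cos\theta_d)\right]^p}
#' with \eqn{\theta_d = 2\pi(d - \code{peak_day})/365}. The exponent `p` is
#' solved once (by root finding) so that the mean of the 365 daily values
#' equals the annual mean exactly. Defaults reproduce an annual mean offer of
#' 12.2 kg DM/d within the range 10--16.8 kg DM/d. The ME content uses the
#' same functional form (range 10.85--12.45 MJ/kg DM, annual mean 11.70) and
#' is identical across scenarios. Under HS the offer is the unconstrained
#' sentinel `Inf`.
#'
#' @param scenario `"HS"` (ad libitum) or `"MS"` (seasonally limiting offer).
#' @param n_years Number of 365-day cycles to generate (>= 1).
#' @param peak_day Calendar day (integer, 1--365) at which offer and ME peak;
#'   the phase of the season relative to the calving season is a calibration
#'   knob. Default 61 (about two months after the start of calving).
#' @param offer_range,offer_mean Range (min, max) and annual mean of the MS
#'   daily DM offer, kg DM/d.
#' @param me_range,me_mean Range and annual mean of diet ME content, MJ/kg DM.
#'
#' @return A tibble of class `feed_calendar` with columns `day` (1..365 *
#'   n_years), `dm_offer_kg` and `me_mj_per_kg`, and a `scenario` attribute.
#' @examples
#' cal <- make_feed_calendar("MS", 1)
#' mean(cal$dm_offer_kg) # 12.2
#' range(cal$me_mj_per_kg)
#' @export
make_feed_calendar <- function(scenario = c("HS", "MS"), n_years = 1,
                               peak_day = 61,
                               offer_range = c(10, 16.8), offer_mean = 12.2,
                               me_range = c(10.85, 12.45), me_mean = 11.70) {
  if (!is.character(scenario) || !all(scenario %in% c("HS", "MS"))) {
    cfg_error(sprintf("unknown scenario label '%s' (use \"HS\" or \"MS\")",
                      paste(scenario[1], collapse = "")))
  }
  scenario <- match.arg(scenario)
  if (!is.numeric(n_years) || length(n_years) != 1 || n_years < 1 ||
      n_years != round(n_years)) {
    cfg_error("n_years must be a whole number >= 1")
  }
  peak_day <- as.integer(peak_day)

  day1 <- seq_len(365L)
  shape <- function(p, rng, mu) rng[1] + diff(rng) * seasonal_shape(day1, peak_day, p)
  solve_p <- function(rng, mu) {
    target <- (mu - rng[1]) / diff(rng)
    uniroot(function(p) mean(seasonal_shape(day1, peak_day, p)) - target,
            interval = c(1e-3, 50), tol = 1e-12)$root
  }
  me1 <- shape(solve_p(me_range, me_mean), me_range, me_mean)
  offer1 <- if (scenario == "HS") rep(Inf, 365L)
            else shape(solve_p(offer_range, offer_mean), offer_range, offer_mean)

  out <- tibble(
    day = seq_len(365L * n_years),
    dm_offer_kg = rep(offer1, n_years),
    me_mj_per_kg = rep(me1, n_years)
  )
  attr(out, "scenario") <- scenario
  class(out) <- c("feed_calendar", class(out))
  out
}

# normalized raised-cosine-power seasonal shape in [0, 1], peak at peak_day
seasonal_shape <- function(day, peak_day, p) {
  ((1 + cos(2 * pi * (day - peak_day) / 365)) / 2)^p
}

#' @export
print.feed_calendar <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat(sprintf("<feed_calendar> scenario %s, %d days (%d season cycles)\n",
              sc, nrow(x), nrow(x) %/% 365L))
  NextMethod()
}

#' Write a feed calendar to CSV
#'
#' Columns `day`, `dm_offer_kg`, `me_mj_per_kg`; the HS unconstrained offer is
#' written as `Inf`.
#'
#' @param calendar A [make_feed_calendar()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feed_calendar <- function(calendar, path) {
  utils::write.csv(as.data.frame(calendar[c("day", "dm_offer_kg", "me_mj_per_kg")]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname make_feed_calendar
#' @param object A `feed_calendar`.
#' @param ... Unused.
#' @method autoplot feed_calendar
#' @export
autoplot.feed_calendar <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::mutate(as_tibble(object),
                  dm_offer_kg = ifelse(is.finite(.data$dm_offer_kg),
                                       .data$dm_offer_kg, NA_real_)),
    c("dm_offer_kg", "me_mj_per_kg"),
    names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1,
                        labeller = ggplot2::as_labeller(c(
                          dm_offer_kg = "DM offer (kg/d)",
                          me_mj_per_kg = "ME content (MJ/kg DM)"))) +
    ggplot2::labs(x = "day of simulation", y = NULL)
}
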