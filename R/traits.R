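#' Cumulative 280-day milk yield with spline fill-in
#'
#' Standardizes lactation milk yield to a common 280-day horizon. Lactations
#' of 280 days or more are summed over days 1--280. For shorter lactations
#' of at least 220 days, a cubic smoothing spline with 8 knots is fitted to
#' the observed daily yields, the missing days up to 280 are predicted, and
#' observed plus predicted yields are summed. Lactations shorter than 220
#' days yield a missing value.
#'
#' @param daily_milk Numeric vector of daily yields (kg ECM/d), day 1
#'   onwards; trailing `NA`s are dropped.
#' @param min_days Minimal lactation length for a phenotype (default 220).
#' @param horizon Standardized lactation length (default 280).
#' @return Cumulative yield in kg, or `NA_real_`.
#' @examples
#' cumulative_milk_280(rep(20, 300)) # 5600
#' @export
cumulative_milk_280 <- function(daily_milk, min_days = 220, horizon = 280) {
  y <- daily_milk[seq_len(max(which(!is.na(daily_milk)), 0))]
  if (anyNA(y)) y <- y[!is.na(y)]
  if (any(y < 0)) contract_error("daily milk yields must be non-negative")
  len <- length(y)
  if (len < min_days) return(NA_real_)
  if (len >= horizon) return(sum(y[seq_len(horizon)]))
  days <- seq_len(len)
  fit <- smooth.spline(days, y, nknots = 8)
  miss <- seq(len + 1, horizon)
  sum(y) + sum(predict(fit, miss)$y)
}

#' Derive complex-trait phenotypes from simulated life histories
#'
#' Computes, per cow: body weight at first calving (`bw_calv1`, kg);
#' third-lactation cumulative 280-d milk (`milk_280`, kg ECM), mean daily
#' intake (`dmi_mean`, kg DM/d), lactation efficiency (`lact_eff`, %, energy
#' allocated to milk over ME intake within the lactation) and interval from
#' first insemination to conception (`ifc`, days); lifetime efficiency
#' (`life_eff`, %, over the whole life from birth to culling) and the number
#' of completed lactations. Third-lactation traits are missing for cows that
#' never reach a third lactation; `milk_280` additionally requires a
#' third lactation of at least 220 days; `ifc` is missing without a
#' conception.
#'
#' Because third-lactation traits exist only for survivors of the first two
#' lactations, their means are subject to selection bias; see
#' [lifetime_summary()] for all-cow summaries.
#'
#' @param sim A [simulate_herd()] result.
#' @return A tibble, one row per cow, with the traits above and
#'   `cull_reason`.
#' @export
derive_phenotypes <- function(sim) {
  s <- sim$summary
  n <- nrow(s)
  p3_days <- rowSums(!is.na(sim$p3$milk))
  milk_280 <- rep(NA_real_, n)
  has3 <- which(s$final_parity >= 3)
  for (i in has3) {
    milk_280[i] <- cumulative_milk_280(sim$p3$milk[i, ])
  }
  tibble(
    animal_id = s$animal_id,
    bw_calv1 = s$bw_calv1,
    milk_280 = milk_280,
    dmi_mean = ifelse(p3_days > 0, s$p3_dmi_kg / p3_days, NA_real_),
    lact_eff = 100 * s$p3_alloc_lactation_mj / s$p3_me_intake_mj,
    ifc = as.numeric(s$p3_conception - s$p3_first_insem),
    life_eff = 100 * s$life_alloc_lactation_mj / s$life_me_intake_mj,
    lactations_completed = s$lactations_completed,
    cull_reason = s$cull_reason
  )
}

#' Mean phenotypic trajectories of cows reaching a parity
#'
#' Day-in-milk-aligned means over all cows that reach the given parity (only
#' parity 3 records are retained by the simulator), for intake, milk yield,
#' body weight and body reserves. Note these means describe survivors of the
#' preceding lactations, not the whole population.
#'
#' @param sim A [simulate_herd()] result.
#' @param parity Parity of interest (3, the stored window).
#' @return Tibble with `day_in_milk`, `dmi`, `milk_ecm`, `body_weight`,
#'   `body_reserves`, `n_cows`.
#' @export
mean_trajectories <- function(sim, parity = 3) {
  if (parity != 3) cfg_error("only third-lactation trajectories are stored")
  keep <- rowSums(!is.na(sim$p3$milk)) > 0
  if (!any(keep)) {
    return(tibble(day_in_milk = integer(), dmi = numeric(),
                  milk_ecm = numeric(), body_weight = numeric(),
                  body_reserves = numeric(), n_cows = integer()))
  }
  cm <- function(M) colMeans(M[keep, , drop = FALSE], na.rm = TRUE)
  n_cows <- colSums(!is.na(sim$p3$milk[keep, , drop = FALSE]))
  out <- tibble(day_in_milk = seq_len(ncol(sim$p3$milk)),
                dmi = cm(sim$p3$dmi), milk_ecm = cm(sim$p3$milk),
                body_weight = cm(sim$p3$bw), body_reserves = cm(sim$p3$br),
                n_cows = n_cows)
  dplyr::filter(out, .data$n_cows > 0)
}

#' Population summary of longevity and lifetime efficiency
#'
#' Means over all simulated cows (including those culled early): number of
#' completed lactations and lifetime efficiency (total energy allocated to
#' milk over total ME intake, %).
#'
#' @param x A [simulate_herd()] result or a [derive_phenotypes()] tibble.
#' @return One-row tibble: `n_cows`, `mean_lactations`, `life_eff`.
#' @export
lifetime_summary <- function(x) {
  ph <- if (inherits(x, "herd_sim")) derive_phenotypes(x) else x
  tibble(n_cows = nrow(ph),
         mean_lactations = mean(ph$lactations_completed),
         life_eff = mean(ph$life_eff, na.rm = TRUE))
}

#' @method glance herd_sim
#' @export
glance.herd_sim <- function(x, ...) {
  cbind(lifetime_summary(x),
        tibble(scenario = x$scenario,
               frac_reaching_parity3 = mean(x$summary$final_parity >= 3)))
}

#' @method tidy herd_sim
#' @export
tidy.herd_sim <- function(x, ...) derive_phenotypes(x)

#' @rdname mean_trajectories
#' @param object A `herd_sim`.
#' @param ... Unused.
#' @method autoplot herd_sim
#' @export
autoplot.herd_sim <- function(object, ...) {
  tr <- mean_trajectories(object)
  df <- tidyr::pivot_longer(tr, c("dmi", "milk_ecm", "body_weight",
                                  "body_reserves"),
                            names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day_in_milk, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "day in milk (third lactation)", y = NULL,
                  title = sprintf("Mean third-lactation trajectories (%s)",
                                  object$scenario))
}

#' Write derived phenotypes to CSV
#' @param phenotypes A [derive_phenotypes()] tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(as.data.frame(phenotypes), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
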