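# Dollar flows: vehicle purchase, recurring ownership / parking /
# productivity / taxi salary, per-crash costs (with the AV scaling that adds
# damage to the extra AV equipment), funeral cost, Moore's-law price
# projection, and discounting.

#' Present value of a future amount
#'
#' @param amount Cost (USD) or QALYs.
#' @param t Years since the start of the model (vectorized).
#' @param rate Annual discount rate.
#' @return `amount / (1 + rate)^t`.
#' @export
discount <- function(amount, t, rate) {
  stopifnot(all(t >= 0))
  amount / (1 + rate)^t
}

#' Moore's-law cost projection
#'
#' The technology component of a price halves every `halving_period` years;
#' the non-technology component is carried unchanged.
#'
#' @param cost_now Current price, USD.
#' @param years Years into the future.
#' @param halving_period Halving period, years (default 2).
#' @param fixed_component USD of the price not subject to halving (e.g. the
#'   conventional-vehicle platform under the AV equipment).
#' @return Projected price, USD.
#' @export
moore_projection <- function(cost_now, years, halving_period = 2,
                             fixed_component = 0) {
  stopifnot(halving_period > 0, fixed_component >= 0,
            all(fixed_component <= cost_now))
  fixed_component + (cost_now - fixed_component) * 2^(-years / halving_period)
}

#' Annuitized parking cost
#'
#' Spreads the capital cost of the parking spots attributable to one vehicle
#' (spot cost times the spots-per-registered-car ratio; taxis use a single
#' spot) over an amortization horizon. At a zero real rate this is
#' straight-line division; at a positive rate it is the standard annuity.
#'
#' @param spot_cost Cost of one parking spot, USD.
#' @param ratio Parking spots per registered car.
#' @param amortization_years Amortization horizon, years.
#' @param rate Real interest rate for the annuity (default 0).
#' @return USD per year.
#' @export
amortize_parking <- function(spot_cost, ratio, amortization_years = 40,
                             rate = 0) {
  stopifnot(amortization_years > 0)
  principal <- spot_cost * ratio
  if (rate == 0) return(principal / amortization_years)
  principal * rate / (1 - (1 + rate)^(-amortization_years))
}

#' Per-category vehicle-damage shares implied by the published crash costs
#'
#' The AV crash-cost columns equal the HPV costs plus damage to the AV's
#' extra equipment, scaled by the vehicle price ratio. Inverting that
#' relationship on the published base values gives the implied share of each
#' HPV crash cost attributable to vehicle damage.
#'
#' @param params An `avcea_parameters` object.
#' @return Named vector of damage shares over PDO/MINOR/SEVERE/FATAL.
#' @export
default_damage_shares <- function(params = default_parameters()) {
  ratio <- param_value(params, "av_vehicle_cost") /
    param_value(params, "hpv_vehicle_cost")
  hpv <- param_value(params, paste0("crash_cost_",
                                    c("pdo", "minor", "severe", "fatal"),
                                    "_hpv"))
  av <- param_value(params, paste0("crash_cost_",
                                   c("pdo", "minor", "severe", "fatal"),
                                   "_av"))
  shares <- (av / hpv - 1) / (ratio - 1)
  names(shares) <- .severities
  shares
}

#' Scale an HPV crash cost to its AV counterpart
#'
#' `hpv_cost + damage_share * hpv_cost * (av_vehicle_cost / hpv_vehicle_cost
#' - 1)`: the vehicle-damage share of the crash cost grows in proportion to
#' the extra capital at risk in an AV. The simulation's critical path uses
#' the published AV crash costs directly; this function documents and
#' validates the scaling's structure.
#'
#' @param hpv_cost HPV crash cost, USD.
#' @param damage_share Fraction of `hpv_cost` attributable to vehicle
#'   damage, in `[0, 1]`.
#' @param hpv_vehicle_cost,av_vehicle_cost Vehicle prices, USD.
#' @return Scaled crash cost, USD (never below `hpv_cost`).
#' @export
scale_crash_cost <- function(hpv_cost, damage_share, hpv_vehicle_cost,
                             av_vehicle_cost) {
  stopifnot(all(hpv_cost > 0), all(damage_share >= 0), all(damage_share <= 1),
            hpv_vehicle_cost > 0, av_vehicle_cost > 0)
  if (av_vehicle_cost < hpv_vehicle_cost) {
    warning("AV vehicle cost below HPV vehicle cost; crash cost clamped at ",
            "the HPV cost")
  }
  pmax(hpv_cost,
       hpv_cost + damage_share * hpv_cost *
         (av_vehicle_cost / hpv_vehicle_cost - 1))
}

#' Build a strategy's cost schedule
#'
#' Assembles all dollar flows for one strategy:
#' \describe{
#'   \item{purchase}{vehicle price at t = 0 (HPV 33,666; AV 183,666; AV in
#'     5 years 56,539; human-piloted taxi 132,427; AV taxi 282,427 at
#'     default parameters).}
#'   \item{annual_recurring}{ownership (8,536/yr, plus a fixed annual
#'     premium for the upkeep of AV sensing/computing equipment), parking
#'     (non-taxi: one spot times the 3.4 spots-per-car ratio, annuitized;
#'     taxi: a single spot), productivity loss from piloting (HPV only;
#'     zero for AVs and for taxi passengers), and the driver's salary for
#'     the human-piloted taxi.}
#'   \item{crash_costs}{per-severity costs, AV column for AV strategies.}
#'   \item{funeral}{charged once at a death occurring during the analytic
#'     horizon.}
#' }
#'
#' @param strategy One of [strategies()].
#' @param params An `avcea_parameters` object.
#' @return A list of class `avcea_cost_schedule` with fields `strategy`,
#'   `purchase`, `annual_recurring`, `recurring_components`, `crash_costs`,
#'   `funeral`.
#' @examples
#' build_cost_schedule("HPV", default_parameters())
#' @export
build_cost_schedule <- function(strategy, params = default_parameters()) {
  strategy <- match.arg(strategy, .strategies)
  pv <- function(nm) param_value(params, nm)
  is_av <- strategy %in% c("AV", "AV_5YR", "AV_TAXI")
  is_taxi <- strategy %in% c("AV_TAXI", "HPT")

  purchase <- switch(strategy,
                     HPV = pv("hpv_vehicle_cost"),
                     AV = pv("av_vehicle_cost"),
                     AV_5YR = pv("av5_vehicle_cost"),
                     AV_TAXI = pv("av_taxi_vehicle_cost"),
                     HPT = pv("taxi_vehicle_cost"))
  ownership <- pv("annual_ownership_cost") +
    if (is_av) pv("av_ownership_premium") else 0
  parking <- if (is_taxi) {
    amortize_parking(pv("taxi_parking_spot_cost"), 1,
                     pv("parking_amortization_years"))
  } else {
    amortize_parking(pv("parking_spot_cost"), pv("parking_spot_ratio"),
                     pv("parking_amortization_years"))
  }
  # productivity loss only while piloting a vehicle yourself
  productivity <- if (strategy == "HPV") {
    pv("productivity_cost") * pv("productivity_fraction") / 0.3
  } else 0
  salary <- if (strategy == "HPT") pv("taxi_salary") else 0

  suffix <- if (is_av) "_av" else "_hpv"
  crash_costs <- pv(paste0("crash_cost_", c("pdo", "minor", "severe", "fatal"),
                           suffix))
  names(crash_costs) <- .severities

  components <- c(ownership = ownership, parking = parking,
                  productivity = productivity, salary = salary)
  structure(list(strategy = strategy, purchase = purchase,
                 annual_recurring = sum(components),
                 recurring_components = components,
                 crash_costs = crash_costs,
                 funeral = pv("funeral_cost")),
            class = "avcea_cost_schedule")
}

#' Dump cost schedules as CSV
#'
#' One row per strategy and component: `strategy, component, amount`.
#'
#' @param params An `avcea_parameters` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cost_schedules_csv <- function(params, path) {
  rows <- do.call(rbind, lapply(.strategies, function(s) {
    cs <- build_cost_schedule(s, params)
    data.frame(strategy = s,
               component = c("purchase", names(cs$recurring_components),
                             paste0("crash_", tolower(names(cs$crash_costs))),
                             "funeral"),
               amount = c(cs$purchase, unname(cs$recurring_components),
                          unname(cs$crash_costs), cs$funeral))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
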