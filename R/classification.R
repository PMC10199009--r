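#' Travel mode vocabulary
#'
#' The modes recognised in trip-leg records, grouped by how they enter the
#' duration-based classification: walking/cycling minutes, car minutes
#' (driver, passenger or taxi), public-transport use (bus, train, tram,
#' ferry; any use sets a flag, in-vehicle time never enters the duration
#' scheme), and "other" motorised modes (motorcycle, commercial vehicle)
#' which count towards having travelled but towards no duration total.
#'
#' @format A named list of character vectors.
#' @export
travel_modes <- list(
  walk_cycle = c("walk", "cycle"),
  car = c("car_driver", "car_passenger", "taxi"),
  public_transport = c("bus", "train", "tram", "ferry"),
  other = c("motorcycle", "commercial")
)

#' Duration-based travel category levels
#' @keywords internal
duration_levels <- c("NO_TRAVEL", "LOW_AT", "HIGH_AT", "MT", "ST")

#' Mode-based group levels ("OTHER" holds travellers using only
#' motorcycle/commercial modes; they belong to none of the three groups)
#' @keywords internal
mode_levels <- c("WALK_CYCLE_ONLY", "CAR_USER", "PT_USER", "NON_TRAVELLER",
                 "OTHER")

check_modes <- function(mode) {
  known <- unlist(travel_modes, use.names = FALSE)
  bad <- setdiff(unique(mode), known)
  if (length(bad) > 0L)
    stop("unknown travel mode(s): ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

#' Summarise one person-day of trip legs
#'
#' Totals a single participant's survey-day trip legs into the quantities the
#' duration- and mode-based classifications need: minutes of walking/cycling,
#' minutes of car use (driving, riding as a passenger, or taxi; motorcycles
#' and commercial vehicles are excluded), whether any public transport was
#' used, and whether the person travelled at all.
#'
#' @param legs data frame of trip legs for one person-day with columns
#'   `mode` (see [travel_modes]) and `duration_min` (non-negative minutes).
#'   Zero rows represent a day without travel.
#' @return One-row data frame with columns `walkcycle_min`, `car_min`,
#'   `pt_used`, `travelled`, `other_only`.
#' @examples
#' summarise_person_day(data.frame(mode = c("walk", "taxi"),
#'                                 duration_min = c(10, 25)))
#' @export
summarise_person_day <- function(legs) {
  if (nrow(legs) == 0L)
    return(data.frame(walkcycle_min = 0, car_min = 0, pt_used = FALSE,
                      travelled = FALSE, other_only = FALSE))
  check_modes(legs$mode)
  if (any(!is.finite(legs$duration_min)) || any(legs$duration_min < 0))
    stop("trip-leg durations must be finite and non-negative", call. = FALSE)
  wc <- sum(legs$duration_min[legs$mode %in% travel_modes$walk_cycle])
  car <- sum(legs$duration_min[legs$mode %in% travel_modes$car])
  pt <- any(legs$mode %in% travel_modes$public_transport)
  data.frame(walkcycle_min = wc, car_min = car, pt_used = pt,
             travelled = TRUE,
             other_only = !pt && wc == 0 && car == 0)
}

#' Assign the duration-based travel category
#'
#' Classifies person-day summaries by the duration of walking/cycling and car
#' use: `NO_TRAVEL` (neither), `LOW_AT` (under 30 min/d of walking/cycling,
#' no car), `HIGH_AT` (30+ min/d walking/cycling, no car), `MT` (both), `ST`
#' (any car use without walking/cycling). Public-transport use plays no role
#' here. The `PST` flag marks the `ST` sub-category with 60+ min/d of car
#' time. Participants who travelled only by motorcycle/commercial vehicle
#' have zero minutes in both duration totals and fall in `NO_TRAVEL`.
#'
#' @param summaries data frame with columns `walkcycle_min` and `car_min`
#'   (e.g. from [summarise_person_day()] or [classify_travel()]).
#' @return data frame with factor column `duration_category` and logical
#'   `pst_flag`.
#' @export
duration_category <- function(summaries) {
  wc <- summaries$walkcycle_min
  car <- summaries$car_min
  if (any(!is.finite(wc)) || any(!is.finite(car)) || any(wc < 0) ||
      any(car < 0))
    stop("walkcycle_min and car_min must be finite and non-negative",
         call. = FALSE)
  cat_ <- ifelse(wc == 0 & car == 0, "NO_TRAVEL",
          ifelse(wc > 0 & car == 0 & wc < 30, "LOW_AT",
          ifelse(wc >= 30 & car == 0, "HIGH_AT",
          ifelse(wc > 0 & car > 0, "MT", "ST"))))
  cat_ <- factor(cat_, levels = duration_levels)
  data.frame(duration_category = cat_,
             pst_flag = cat_ == "ST" & car >= 60)
}

#' Assign the mode-based travel group
#'
#' Groups travellers by the modes they used: `PT_USER` for any
#' public-transport use (including park-and-ride combinations with cars),
#' `CAR_USER` for car use without public transport (some walking/cycling
#' allowed), `WALK_CYCLE_ONLY` for walking/cycling without cars or public
#' transport, and `NON_TRAVELLER` for those who made no trips. Travellers
#' using only motorcycle/commercial modes fit none of the three groups and
#' are labelled `OTHER`.
#'
#' @param summaries data frame with columns `walkcycle_min`, `car_min`,
#'   `pt_used` and `travelled`.
#' @return factor of mode groups.
#' @export
mode_group <- function(summaries) {
  grp <- with(summaries,
    ifelse(!travelled, "NON_TRAVELLER",
    ifelse(pt_used, "PT_USER",
    ifelse(car_min > 0, "CAR_USER",
    ifelse(walkcycle_min > 0, "WALK_CYCLE_ONLY", "OTHER")))))
  factor(grp, levels = mode_levels)
}

#' Classify a travel survey
#'
#' Runs the full person-day classification over a trips table: summarises
#' each participant's legs, assigns the duration category, the prolonged
#' sedentary travel (PST) flag and the mode group, and joins person
#' attributes. Participants present in `persons` but absent from `trips`
#' are treated as days without travel.
#'
#' @param trips data frame of trip legs: `person_id`, `area_id`, `mode`,
#'   `duration_min`.
#' @param persons optional data frame of person attributes keyed by
#'   `person_id` (and carrying `area_id` when a person has no trips).
#' @return data frame with one row per participant: ids, duration totals,
#'   flags, `duration_category`, `pst_flag`, `mode_group`, plus any
#'   attribute columns from `persons`. The number of travellers classifiable
#'   only as `OTHER` is attached as attribute `n_other_mode` (and reported
#'   with a warning when positive).
#' @export
classify_travel <- function(trips, persons = NULL) {
  stopifnot(all(c("person_id", "area_id", "mode", "duration_min") %in%
                  names(trips)))
  check_modes(trips$mode)
  if (any(!is.finite(trips$duration_min)) || any(trips$duration_min < 0))
    stop("trip-leg durations must be finite and non-negative", call. = FALSE)

  ids <- unique(trips$person_id)
  if (!is.null(persons)) {
    stopifnot("person_id" %in% names(persons))
    if (anyDuplicated(persons$person_id))
      stop("duplicate person_id in persons table", call. = FALSE)
    ids <- union(persons$person_id, ids)
  }
  idx <- match(trips$person_id, ids)
  zero <- numeric(length(ids))
  wc <- car <- zero
  in_wc <- trips$mode %in% travel_modes$walk_cycle
  in_car <- trips$mode %in% travel_modes$car
  in_pt <- trips$mode %in% travel_modes$public_transport
  add <- function(sel) {
    out <- zero
    if (any(sel)) {
      s <- rowsum(trips$duration_min[sel], idx[sel])
      out[as.integer(rownames(s))] <- s[, 1L]
    }
    out
  }
  wc <- add(in_wc)
  car <- add(in_car)
  pt <- logical(length(ids))
  pt[unique(idx[in_pt])] <- TRUE
  travelled <- logical(length(ids))
  travelled[unique(idx)] <- TRUE

  area <- trips$area_id[match(ids, trips$person_id)]
  if (!is.null(persons) && "area_id" %in% names(persons)) {
    pa <- persons$area_id[match(ids, persons$person_id)]
    area <- ifelse(is.na(area), pa, area)
  }
  out <- data.frame(person_id = ids, area_id = area,
                    walkcycle_min = wc, car_min = car,
                    pt_used = pt, travelled = travelled)
  out <- cbind(out, duration_category(out))
  out$mode_group <- mode_group(out)
  if (!is.null(persons)) {
    extra <- persons[match(ids, persons$person_id),
                     setdiff(names(persons), c("person_id", "area_id")),
                     drop = FALSE]
    rownames(extra) <- NULL
    out <- cbind(out, extra)
  }
  n_other <- sum(out$mode_group == "OTHER")
  if (n_other > 0L)
    warning(n_other, " traveller(s) used only motorcycle/commercial modes; ",
            "placed in NO_TRAVEL for the duration scheme and excluded from ",
            "the three mode groups", call. = FALSE)
  attr(out, "n_other_mode") <- n_other
  rownames(out) <- NULL
  out
}
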