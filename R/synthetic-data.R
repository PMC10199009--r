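# Synthetic travel-survey generator: grid geographies, diary legs drawn from
# a category mixture with bound-respecting durations, and area outcomes from
# a Leroux CAR generative model with known ground truth.

#' Generate a grid geography of small areas
#'
#' Creates a rectangular grid of areas with rook contiguity (areas sharing a
#' grid edge are neighbours), as a controllable surrogate for irregular
#' small-area maps. Populations are drawn uniformly from `pop_range`.
#'
#' @param rows,cols grid dimensions (positive integers).
#' @param pop_range integer interval `c(lo, hi)` of persons per area.
#' @param seed optional integer seed.
#' @return object of class `area_geography`: list with `area_ids`, `edges`
#'   (data frame `area_a`, `area_b`), `populations` (named), `rows`, `cols`.
#' @export
generate_geography <- function(rows, cols, pop_range = c(5000, 25000),
                               seed = NULL) {
  if (rows < 1 || cols < 1)
    stop("grid dimensions must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rows <- as.integer(rows); cols <- as.integer(cols)
  n <- rows * cols
  ids <- sprintf("A%04d", seq_len(n))
  # area (r, c) has index (r - 1) * cols + c; rook neighbours right and down
  idx <- function(r, c) (r - 1L) * cols + c
  ea <- eb <- integer(0)
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    if (c < cols) { ea <- c(ea, idx(r, c)); eb <- c(eb, idx(r, c + 1L)) }
    if (r < rows) { ea <- c(ea, idx(r, c)); eb <- c(eb, idx(r + 1L, c)) }
  }
  pops <- if (pop_range[1L] == pop_range[2L]) rep(pop_range[1L], n) else
    sample(seq(pop_range[1L], pop_range[2L]), n, replace = TRUE)
  structure(list(area_ids = ids,
                 edges = data.frame(area_a = ids[ea], area_b = ids[eb]),
                 populations = setNames(as.integer(pops), ids),
                 rows = rows, cols = cols),
            class = "area_geography")
}

#' @export
print.area_geography <- function(x, ...) {
  cat("Area geography:", length(x$area_ids), "areas (",
      x$rows, "x", x$cols, "grid ),", nrow(x$edges), "contiguity edges\n")
  invisible(x)
}

#' Adjacency matrix of a geography
#' @param geography an `area_geography`.
#' @return 0/1 matrix via [adjacency_from_edges()].
#' @export
geography_adjacency <- function(geography) {
  adjacency_from_edges(geography$area_ids, geography$edges)
}

#' Behaviour profile for the diary generator
#'
#' Defines the mixture of duration-based travel categories, the
#' public-transport use probability within each category, duration
#' distributions (truncated log-normal, respecting each category's bounds)
#' and Bernoulli rates for person attributes. Defaults emulate the
#' area-level means observed in combined Australian metropolitan household
#' travel surveys: category shares no-travel 20.8%, low AT 2.6%, high AT
#' 5.5%, MT 11.9%, ST 59.2%, giving mode-group shares among travellers of
#' roughly 6% walking/cycling only, 85% car users and 9% public-transport
#' users.
#'
#' @param category_probs named probabilities over
#'   `c("no_travel","low_at","high_at","mt","st")`; must sum to 1 (tolerance
#'   `1e-6`).
#' @param pt_prob named per-category probability of using public transport
#'   on the survey day. Public-transport legs never alter the duration
#'   category: walking recorded for access is already part of the walk/cycle
#'   minutes drawn for AT/MT categories, and for ST/no-travel categories
#'   only in-vehicle legs are generated.
#' @param durations list of `c(meanlog, sdlog, lo, hi)` vectors for the
#'   walk/cycle and car duration draws per category.
#' @param attr_rates Bernoulli rates for `male`, `age_65plus`, `worker`,
#'   `hh_children`, `low_income`.
#' @return object of class `behaviour_profile`.
#' @export
behaviour_profile <- function(
    category_probs = c(no_travel = 0.208, low_at = 0.026, high_at = 0.055,
                       mt = 0.119, st = 0.592),
    pt_prob = c(no_travel = 0.04, low_at = 0.45, high_at = 0.40,
                mt = 0.04, st = 0.04),
    durations = list(
      low_at_walk = c(meanlog = log(12), sdlog = 0.6, lo = 1, hi = 29.99),
      high_at_walk = c(meanlog = log(55), sdlog = 0.5, lo = 30, hi = 240),
      mt_walk = c(meanlog = log(28), sdlog = 0.6, lo = 1, hi = 180),
      mt_car = c(meanlog = log(55), sdlog = 0.6, lo = 1, hi = 300),
      st_car = c(meanlog = log(60), sdlog = 0.7, lo = 1, hi = 300),
      pt = c(meanlog = log(35), sdlog = 0.5, lo = 5, hi = 120)),
    attr_rates = c(male = 0.47, age_65plus = 0.172, worker = 0.67,
                   hh_children = 0.47, low_income = 0.32)) {
  cats <- c("no_travel", "low_at", "high_at", "mt", "st")
  if (!setequal(names(category_probs), cats))
    stop("category_probs must be named over: ", paste(cats, collapse = ", "),
         call. = FALSE)
  category_probs <- category_probs[cats]
  if (any(category_probs < 0) ||
      abs(sum(category_probs) - 1) > 1e-6)
    stop("category probabilities must be non-negative and sum to 1",
         call. = FALSE)
  pt_prob <- pt_prob[cats]
  if (anyNA(pt_prob) || any(pt_prob < 0) || any(pt_prob > 1))
    stop("pt_prob must give a probability for every category", call. = FALSE)
  structure(list(category_probs = category_probs, pt_prob = pt_prob,
                 durations = durations, attr_rates = attr_rates),
            class = "behaviour_profile")
}

# inverse-CDF draw from a log-normal truncated to [lo, hi]
rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  u <- runif(n, plnorm(lo, meanlog, sdlog), plnorm(hi, meanlog, sdlog))
  pmin(pmax(qlnorm(u, meanlog, sdlog), lo), hi)
}

#' Generate synthetic travel-diary participants
#'
#' Draws participants for every area of a geography: each person gets a
#' duration-based category from the profile's mixture, bound-respecting
#' walk/cycle and car durations split into trip legs, optional
#' public-transport legs, and Bernoulli attributes. By construction,
#' re-classifying the generated legs with [classify_travel()] recovers each
#' person's generating category exactly.
#'
#' @param geography an `area_geography`.
#' @param n_per_area integer interval `c(lo, hi)`; each area's participant
#'   count is drawn uniformly from it.
#' @param profile a [behaviour_profile()].
#' @param seed optional integer seed.
#' @return object of class `travel_survey`: list with data frames `trips`
#'   (`person_id`, `area_id`, `mode`, `duration_min`) and `persons`
#'   (`person_id`, `area_id`, attributes, and the generating
#'   `true_category`).
#' @export
generate_participants <- function(geography, n_per_area = c(100, 200),
                                  profile = behaviour_profile(),
                                  seed = NULL) {
  stopifnot(inherits(geography, "area_geography"),
            inherits(profile, "behaviour_profile"))
  if (!is.null(seed)) set.seed(seed)
  n_area <- length(geography$area_ids)
  n_i <- if (n_per_area[1L] == n_per_area[2L])
    rep(n_per_area[1L], n_area) else
    sample(seq(n_per_area[1L], n_per_area[2L]), n_area, replace = TRUE)
  area <- rep(geography$area_ids, n_i)
  n <- length(area)
  pid <- sprintf("P%06d", seq_len(n))
  cats <- names(profile$category_probs)
  category <- sample(cats, n, replace = TRUE, prob = profile$category_probs)

  du <- profile$durations
  draw <- function(sel, par) {
    out <- numeric(sum(sel))
    if (length(out) > 0)
      out <- rlnorm_trunc(length(out), par["meanlog"], par["sdlog"],
                          par["lo"], par["hi"])
    out
  }
  walk_min <- car_min <- rep(NA_real_, n)
  walk_min[category == "low_at"] <- draw(category == "low_at", du$low_at_walk)
  walk_min[category == "high_at"] <- draw(category == "high_at",
                                          du$high_at_walk)
  walk_min[category == "mt"] <- draw(category == "mt", du$mt_walk)
  car_min[category == "mt"] <- draw(category == "mt", du$mt_car)
  car_min[category == "st"] <- draw(category == "st", du$st_car)
  use_pt <- runif(n) < profile$pt_prob[category]

  legs <- list()
  add_leg <- function(sel, mode, dur) {
    if (!any(sel)) return()
    legs[[length(legs) + 1L]] <<- data.frame(
      person_id = pid[sel], area_id = area[sel], mode = mode,
      duration_min = dur[sel])
  }
  has_walk <- !is.na(walk_min)
  # walking/cycling split: cycle with probability 0.2
  is_cycle <- runif(n) < 0.2
  add_leg(has_walk & !is_cycle, "walk", walk_min)
  add_leg(has_walk & is_cycle, "cycle", walk_min)
  has_car <- !is.na(car_min)
  car_mode <- sample(c("car_driver", "car_passenger", "taxi"), n,
                     replace = TRUE, prob = c(0.75, 0.22, 0.03))
  for (m in c("car_driver", "car_passenger", "taxi"))
    add_leg(has_car & car_mode == m, m, car_min)
  pt_mode <- sample(c("bus", "train", "tram", "ferry"), n, replace = TRUE,
                    prob = c(0.45, 0.40, 0.10, 0.05))
  pt_min <- rlnorm_trunc(n, du$pt["meanlog"], du$pt["sdlog"],
                         du$pt["lo"], du$pt["hi"])
  for (m in c("bus", "train", "tram", "ferry"))
    add_leg(use_pt & pt_mode == m, m, pt_min)

  trips <- do.call(rbind, legs)
  trips <- trips[order(trips$person_id), , drop = FALSE]
  rownames(trips) <- NULL
  ar <- profile$attr_rates
  persons <- data.frame(
    person_id = pid, area_id = area,
    male = runif(n) < ar["male"],
    age_65plus = runif(n) < ar["age_65plus"],
    worker = runif(n) < ar["worker"],
    hh_children = runif(n) < ar["hh_children"],
    low_income = runif(n) < ar["low_income"],
    true_category = category)
  structure(list(trips = trips, persons = persons, seed = seed),
            class = "travel_survey")
}

#' @export
print.travel_survey <- function(x, ...) {
  cat("Synthetic travel survey:", nrow(x$persons), "participants,",
      nrow(x$trips), "trip legs\n")
  invisible(x)
}

#' Ground-truth parameters for outcome generation
#'
#' The generative counterparts of the CAR regression parameters: outcome
#' intercept (%), regression coefficients per 1 percentage point of each
#' area metric, spatial dependence `rho`, spatial variance `tau2` and
#' observation noise variance `nu2` (both in %^2).
#'
#' @param intercept outcome level (%) when all metrics are zero.
#' @param beta named coefficients; names must match area-profile columns.
#' @param rho spatial dependence in \[0, 1\].
#' @param tau2,nu2 non-negative variances.
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(intercept = 62, beta = c(pct_high_at = -0.134),
                         rho = 0.5, tau2 = 2, nu2 = 1) {
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]", call. = FALSE)
  if (tau2 < 0 || nu2 < 0)
    stop("variances must be non-negative", call. = FALSE)
  if (length(beta) > 0 && is.null(names(beta)))
    stop("beta must be named by area-profile columns", call. = FALSE)
  structure(list(intercept = intercept, beta = beta, rho = rho,
                 tau2 = tau2, nu2 = nu2), class = "ground_truth")
}

# one draw of Leroux CAR spatial effects: phi ~ N(0, tau2 * Q(rho)^-1)
draw_car_effects <- function(W, rho, tau2, n = nrow(W)) {
  if (tau2 == 0) return(numeric(n))
  D <- diag(rowSums(W))
  Q <- rho * (D - W) + (1 - rho) * diag(n)
  U <- tryCatch(chol(Q), error = function(e)
    stop("CAR precision is singular (rho = 1 on a disconnected graph?)",
         call. = FALSE))
  sqrt(tau2) * backsolve(U, rnorm(n))
}

#' Generate area outcomes from known ground truth
#'
#' Draws outcome rates `y = intercept + X beta + phi + eps`, where `phi`
#' follows the Leroux CAR prior with precision
#' `(rho (D - W) + (1 - rho) I) / tau2` on the geography's contiguity graph
#' and `eps` is iid Gaussian noise with variance `nu2` — the same model
#' family the fitting routine assumes, so parameter-recovery experiments are
#' well posed.
#'
#' @param profiles area-profile data frame; must contain the columns named
#'   in `truth$beta` and align with `geography$area_ids`.
#' @param geography an `area_geography`.
#' @param truth a [ground_truth()].
#' @param seed optional integer seed.
#' @return named numeric outcome vector (%), with the spatial effects and
#'   the linear predictor attached as attributes `phi` and
#'   `linear_predictor`.
#' @export
generate_outcomes <- function(profiles, geography, truth, seed = NULL) {
  stopifnot(inherits(geography, "area_geography"),
            inherits(truth, "ground_truth"))
  ord <- match(geography$area_ids, profiles$area_id)
  if (anyNA(ord))
    stop("profiles must cover every area of the geography", call. = FALSE)
  profiles <- profiles[ord, , drop = FALSE]
  if (!all(names(truth$beta) %in% names(profiles)))
    stop("profiles lack beta column(s): ",
         paste(setdiff(names(truth$beta), names(profiles)), collapse = ", "),
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(profiles)
  X <- as.matrix(profiles[, names(truth$beta), drop = FALSE])
  linpred <- truth$intercept + drop(X %*% truth$beta)
  W <- geography_adjacency(geography)
  phi <- draw_car_effects(W, truth$rho, truth$tau2)
  eps <- if (truth$nu2 == 0) numeric(n) else rnorm(n, 0, sqrt(truth$nu2))
  y <- setNames(linpred + phi + eps, profiles$area_id)
  attr(y, "phi") <- phi
  attr(y, "linear_predictor") <- linpred
  y
}

#' Write a synthetic survey to delimited files
#'
#' Writes tab-delimited `trips.tsv`, `persons.tsv` and `edges.tsv` under
#' `dir`; the generation seed (when known) is recorded as a `# seed:`
#' comment line at the top of each file.
#'
#' @param survey a `travel_survey`.
#' @param geography the matching `area_geography`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_survey_files <- function(survey, geography, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("trips.tsv", "persons.tsv", "edges.tsv"))
  tabs <- list(survey$trips, survey$persons, geography$edges)
  for (i in seq_along(paths)) {
    con <- file(paths[i], "w")
    writeLines(paste0("# seed: ", if (is.null(survey$seed)) "NA" else
      survey$seed), con)
    write.table(tabs[[i]], con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    close(con)
  }
  invisible(paths)
}

#' Read survey files written by [write_survey_files()]
#' @param dir directory containing `trips.tsv` and `persons.tsv`.
#' @return list with `trips` and `persons` data frames.
#' @export
read_survey_files <- function(dir) {
  rd <- function(f) read.delim(file.path(dir, f), comment.char = "#")
  list(trips = rd("trips.tsv"), persons = rd("persons.tsv"))
}
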