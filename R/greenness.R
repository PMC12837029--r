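GREEN_CRITERIA <- c("toxicity", "flammability", "environmental_impact",
                    "volatility_exposure", "corrosiveness")

#' Solvent safety/greenness profile
#'
#' Scores a solvent on five Safety-Data-Sheet-derived criteria — toxicity,
#' flammability, environmental impact, volatility/exposure risk and
#' corrosiveness — each an integer from 1 (least favorable) to 10 (most
#' favorable).
#'
#' @param name solvent name.
#' @param toxicity,flammability,environmental_impact,volatility_exposure,corrosiveness
#'   integer scores in 1..10.
#' @return object of class `solvent_profile`.
#' @export
solvent_profile <- function(name, toxicity, flammability, environmental_impact,
                            volatility_exposure, corrosiveness) {
  scores <- c(toxicity = toxicity, flammability = flammability,
              environmental_impact = environmental_impact,
              volatility_exposure = volatility_exposure,
              corrosiveness = corrosiveness)
  if (any(scores < 1 | scores > 10 | scores != round(scores)))
    stop("all criterion scores must be integers in [1, 10]")
  structure(list(name = name, scores = scores), class = "solvent_profile")
}

#' Greenness index of a solvent profile
#'
#' Weighted mean of the five criterion scores divided by 10, giving an
#' index in (0, 1]; equal weights by default. An optional min-max rescale
#' maps the attainable range `[0.1, 1]` onto `[0, 1]`.
#'
#' @param profile a [solvent_profile()].
#' @param weights optional numeric weights (summing to 1).
#' @param rescale min-max rescale to `[0, 1]` (default `FALSE`).
#' @return a number in `[0, 1]`.
#' @export
greenness_index <- function(profile, weights = NULL, rescale = FALSE) {
  stopifnot(inherits(profile, "solvent_profile"))
  k <- length(profile$scores)
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (length(weights) != k || abs(sum(weights) - 1) > 1e-9)
    stop("weights must have one entry per criterion and sum to 1")
  idx <- sum(weights * profile$scores) / 10
  if (rescale) idx <- (idx - 0.1) / 0.9
  idx
}

#' Long-format radar-chart table of solvent profiles
#'
#' One row per (solvent, criterion); the representation round-trips
#' losslessly with the profile list and feeds spider/radar plotting.
#'
#' @param profiles list of [solvent_profile()] objects (unique names).
#' @return data.frame with columns `solvent`, `criterion`, `score`.
#' @export
radar_table <- function(profiles) {
  if (length(profiles) < 1L) stop("at least one profile required")
  nms <- vapply(profiles, function(p) p$name, "")
  if (anyDuplicated(nms)) stop("duplicate solvent names")
  do.call(rbind, lapply(profiles, function(p)
    data.frame(solvent = p$name, criterion = names(p$scores),
               score = unname(p$scores))))
}

#' Rebuild solvent profiles from a radar table
#'
#' @param table a data.frame as returned by [radar_table()].
#' @return list of [solvent_profile()] objects.
#' @export
profiles_from_radar_table <- function(table) {
  lapply(split(table, table$solvent)[unique(table$solvent)], function(df) {
    s <- stats::setNames(df$score, df$criterion)[GREEN_CRITERIA]
    do.call(solvent_profile, c(list(name = df$solvent[1]), as.list(s)))
  })
}

#' Illustrative bundled solvent score set
#'
#' Synthetic SDS-style scores for the solvents commonly compared in
#' aqueous UV-Vis method development (water, ethanol, methanol,
#' acetonitrile, phosphoric/formic/hydrochloric acid). These are
#' illustrative fixtures for demonstrations — not measured values.
#'
#' @return named list of [solvent_profile()] objects.
#' @export
example_solvent_profiles <- function() {
  mk <- solvent_profile
  list(
    water = mk("water", 10, 10, 10, 10, 10),
    ethanol = mk("ethanol", 7, 4, 8, 6, 8),
    methanol = mk("methanol", 4, 4, 7, 5, 7),
    acetonitrile = mk("acetonitrile", 3, 4, 4, 4, 6),
    phosphoric_acid = mk("phosphoric_acid", 5, 9, 6, 7, 3),
    formic_acid = mk("formic_acid", 5, 6, 6, 5, 3),
    hydrochloric_acid = mk("hydrochloric_acid", 3, 8, 5, 3, 2)
  )
}

#' Greenness report across solvents
#'
#' @param profiles list of [solvent_profile()]s.
#' @param external optional named list of externally obtained whole-method
#'   scores (e.g. `list(agree = 0.84, bagi = 85)`) recorded verbatim;
#'   those tools are not reimplemented here.
#' @return list with per-solvent indices, the radar table and the echoed
#'   external scores.
#' @export
greenness_report <- function(profiles, external = NULL) {
  idx <- vapply(profiles, greenness_index, numeric(1))
  names(idx) <- vapply(profiles, function(p) p$name, "")
  list(index = idx, radar = radar_table(profiles), external = external)
}
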