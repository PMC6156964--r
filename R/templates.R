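## Ready-made two-population divergence model templates (M1-M6) and the
## small reference histories used for comparison against analytic
## expectations (IM, IUA, single-population size change).

.twoPopSkeleton <- function(mu) {
  demographicModel(
    data.frame(name = c("S", "B"), size = c(1e4, 1e4), growth = c(0, 0)),
    referenceSize = 1e4, mutationRate = mu, recombinationRate = 0)
}

.defaultBounds <- list(
  size  = c(50, 2e6),
  time  = c(1e-3, 30),     # units of 4*N_A generations
  rate  = c(1e-11, 1e-6),  # per-site recombination rate
  mig   = c(1e-4, 50),     # 4*N_A*m
  alpha = c(-20, 20),      # growth, units of 1/(4*N_A) generations
  frac  = c(0, 0.999))

#' Two-population divergence model templates
#'
#' Returns a template model plus parameter map for a family of nested
#' two-population histories of populations S and B with ancestral population
#' size \eqn{N_A}:
#' \describe{
#'   \item{M1}{clean split at time T; all sizes equal \eqn{N_A}
#'     (free: N_A, r, T).}
#'   \item{M2}{M1 with distinct present-day sizes \eqn{N_S}, \eqn{N_B}.}
#'   \item{M3}{M2 with exponential growth/decline rates \eqn{\alpha_S},
#'     \eqn{\alpha_B} in each daughter population.}
#'   \item{M4}{M2 with continuous bidirectional migration
#'     (rates \eqn{4 N_A m} per direction) from the split to the present.}
#'   \item{M5}{M4 with migration ceasing at a time \eqn{T_2 < T}
#'     (isolation with initial migration).}
#'   \item{M6}{M2 with a bidirectional admixture pulse at \eqn{T_2 < T}
#'     (fractions \eqn{f_{S \to B}}, \eqn{f_{S \leftarrow B}}).}
#'   \item{onePop}{single panmictic population, one free size parameter
#'     (plus fixed mutation rate); used for one-dimensional recovery
#'     checks.}
#' }
#' Times are in units of \eqn{4 N_A} generations; sizes in individuals; the
#' per-site recombination rate r is a free parameter of M1-M6. Growth-rate
#' parameters are taken in units of \eqn{1/(4 N_A)} generations and are the
#' only parameters searched on a linear (signed) scale besides admixture
#' fractions.
#'
#' @param name template name.
#' @param mu fixed per-site per-generation mutation rate.
#' @param fixed named numeric vector of parameters to hold fixed (removed
#'   from the free-parameter map), e.g. \code{c(r = 2e-8)}.
#' @return List with elements \code{template} (a
#'   \code{\link{demographicModel}}), \code{map} (a
#'   \code{\link{parameterMap}}) and \code{name}.
#' @examples
#' tpl <- modelTemplate("M2")
#' tpl$map@names  # N_A, r, T, N_S, N_B
#' @export
modelTemplate <- function(name = c("M1", "M2", "M3", "M4", "M5", "M6",
                                   "onePop"),
                          mu = 2e-8, fixed = NULL) {
  name <- match.arg(name)
  bd <- .defaultBounds
  if (name == "onePop") {
    tpl <- demographicModel(data.frame(name = "P", size = 1e4, growth = 0),
                            referenceSize = 1e4, mutationRate = mu)
    map <- parameterMap(
      names = "N_e", lower = bd$size[1], upper = bd$size[2],
      bind = function(template, p) {
        demographicModel(data.frame(name = "P", size = p[["N_e"]], growth = 0),
                         referenceSize = p[["N_e"]], mutationRate = mu)
      })
    return(.applyFixed(list(template = tpl, map = map, name = name), fixed))
  }

  defs <- list(
    M1 = c("N_A", "r", "T"),
    M2 = c("N_A", "r", "T", "N_S", "N_B"),
    M3 = c("N_A", "r", "T", "N_S", "N_B", "alpha_S", "alpha_B"),
    M4 = c("N_A", "r", "T", "N_S", "N_B", "M_SB", "M_BS"),
    M5 = c("N_A", "r", "T", "N_S", "N_B", "M_SB", "M_BS", "T_2"),
    M6 = c("N_A", "r", "T", "N_S", "N_B", "T_2", "f_SB", "f_BS"))
  nm <- defs[[name]]
  boundOf <- function(p) {
    switch(sub("_.*", "", p),
           N = bd$size, r = bd$rate, T = bd$time, M = bd$mig,
           alpha = bd$alpha, f = bd$frac)
  }
  lower <- vapply(nm, function(p) boundOf(p)[1], 0)
  upper <- vapply(nm, function(p) boundOf(p)[2], 0)
  logScale <- !(grepl("^alpha", nm) | grepl("^f_", nm))

  constraints <- if (name %in% c("M5", "M6")) {
    function(p) if (p[["T_2"]] < p[["T"]]) TRUE else
      "the admixture/stopping time T_2 must precede the split time T"
  } else function(p) TRUE

  bind <- function(template, p) {
    NA_ <- p[["N_A"]]
    NS <- if ("N_S" %in% names(p)) p[["N_S"]] else NA_
    NB <- if ("N_B" %in% names(p)) p[["N_B"]] else NA_
    aS <- if ("alpha_S" %in% names(p)) p[["alpha_S"]] / (4 * NA_) else 0
    aB <- if ("alpha_B" %in% names(p)) p[["alpha_B"]] / (4 * NA_) else 0
    ev <- list()
    if (name %in% c("M4", "M5")) {
      t0 <- if (name == "M5") p[["T_2"]] else 0
      ev <- c(ev, list(
        demographicEvent("migration_change", t0, "S", "B",
                         value = p[["M_SB"]]),
        demographicEvent("migration_change", t0, "B", "S",
                         value = p[["M_BS"]])))
    }
    if (name == "M6") {
      ev <- c(ev, list(
        demographicEvent("admixture_pulse", p[["T_2"]], "S", "B",
                         value = p[["f_SB"]]),
        demographicEvent("admixture_pulse", p[["T_2"]], "B", "S",
                         value = p[["f_BS"]])))
    }
    ev <- c(ev, list(
      demographicEvent("split_join", p[["T"]], "B", "S"),
      demographicEvent("size_change", p[["T"]], "S", value = NA_)))
    demographicModel(
      data.frame(name = c("S", "B"), size = c(NS, NB), growth = c(aS, aB)),
      do.call(rbind, ev), referenceSize = NA_, mutationRate = mu,
      recombinationRate = p[["r"]])
  }

  out <- list(template = .twoPopSkeleton(mu),
              map = parameterMap(nm, lower, upper, logScale,
                                 constraints, bind),
              name = name)
  .applyFixed(out, fixed)
}

## remove fixed parameters from a template's free map by capturing them in
## the bind closure
.applyFixed <- function(tpl, fixed) {
  if (is.null(fixed) || !length(fixed)) return(tpl)
  map <- tpl$map
  if (!all(names(fixed) %in% map@names))
    stop("fixed parameters not in template: ",
         paste(setdiff(names(fixed), map@names), collapse = ", "))
  keep <- !(map@names %in% names(fixed))
  oldBind <- map@bind
  oldCons <- map@constraints
  fullNames <- map@names
  fx <- fixed
  tpl$map <- parameterMap(
    names = map@names[keep], lower = map@lower[keep],
    upper = map@upper[keep], logScale = map@logScale[keep],
    constraints = function(p) oldCons(.mergeFixed(p, fx, fullNames)),
    bind = function(template, p)
      oldBind(template, .mergeFixed(p, fx, fullNames)))
  tpl
}

.mergeFixed <- function(p, fixed, fullNames) {
  out <- c(p, fixed)[fullNames]
  names(out) <- fullNames
  out
}

#' Reference histories with known analytic blockwise spectra
#'
#' Small models used to validate the Monte Carlo machinery against exact
#' results. Input times are in units of \eqn{2 N_e} generations (the
#' convention of the analytic literature for these histories) and are
#' converted internally to the package's \eqn{4 N_{ref}} scaling.
#'
#' \code{imModel}: two populations A and B of equal size split at \code{T};
#' after the split, continuous unidirectional migration at rate
#' \code{M = 4*Ne*m} migrants per generation from A into B (forward in
#' time).
#'
#' \code{iuaModel}: three populations A, B, C; B and A split at \code{T1},
#' C and A at \code{T2}, and at \code{Tgf} a fraction \code{f} of B's
#' lineages trace back to A (unidirectional admixture A into B).
#'
#' \code{popSizeChangeModel}: one population whose size changes from
#' \code{sizeRatio * Ne} (ancestral) to \code{Ne} at time \code{T}.
#'
#' @param T,T1,T2,Tgf event times in units of \eqn{2 N_e} generations.
#' @param M scaled migration rate \eqn{4 N_e m}.
#' @param f admixture fraction.
#' @param sizeRatio ancestral size as a fraction of the present size.
#' @param referenceSize \eqn{N_e} in individuals.
#' @param mu,r per-site per-generation mutation/recombination rates.
#' @return A \code{\link{demographicModel}}.
#' @export
imModel <- function(T = 1.2, M = 0.5, referenceSize = 1e4, mu = 2e-8,
                    r = 0) {
  demographicModel(
    data.frame(name = c("A", "B"), size = referenceSize, growth = 0),
    rbind(demographicEvent("migration_change", 0, "A", "B", value = M),
          demographicEvent("split_join", T / 2, "B", "A"),
          demographicEvent("size_change", T / 2, "A",
                           value = referenceSize)),
    referenceSize = referenceSize, mutationRate = mu,
    recombinationRate = r)
}

#' @rdname imModel
#' @export
iuaModel <- function(f = 0.06, T2 = 0.6, T1 = 0.15, Tgf = 0.125,
                     referenceSize = 1e4, mu = 2e-8, r = 0) {
  stopifnot(Tgf < T1, T1 < T2)
  demographicModel(
    data.frame(name = c("A", "B", "C"), size = referenceSize, growth = 0),
    rbind(demographicEvent("admixture_pulse", Tgf / 2, "A", "B", value = f),
          demographicEvent("split_join", T1 / 2, "B", "A"),
          demographicEvent("split_join", T2 / 2, "C", "A"),
          demographicEvent("size_change", T2 / 2, "A",
                           value = referenceSize)),
    referenceSize = referenceSize, mutationRate = mu,
    recombinationRate = r)
}

#' @rdname imModel
#' @export
popSizeChangeModel <- function(T = 0.2, sizeRatio = 0.5,
                               referenceSize = 1e4, mu = 2e-8, r = 0) {
  demographicModel(
    data.frame(name = "P", size = referenceSize, growth = 0),
    demographicEvent("size_change", T / 2, "P",
                     value = sizeRatio * referenceSize),
    referenceSize = referenceSize, mutationRate = mu,
    recombinationRate = r)
}
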