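## Mapping flat parameter vectors into simulator-ready demographic histories.

#' Bind a free-parameter vector to a demographic model
#'
#' Validates the parameters against the map's box bounds and nonlinear
#' ordering constraints (for example, an admixture time that must precede
#' the population split) and, when feasible, builds the fully bound model.
#' Infeasible points return a rejection object rather than raising, so that
#' a global optimizer can treat them as infeasible and continue; use
#' \code{\link{isInfeasible}} to test for it.
#'
#' @param params numeric vector, one value per map parameter.
#' @param map a \code{\link{parameterMap}}.
#' @param template the template \code{\link{demographicModel}} the map binds
#'   into.
#' @return A \code{DemographicModel} with \code{freeParameters(model)} equal
#'   to \code{params}, or an object of class \code{"infeasiblePoint"}.
#' @examples
#' tpl <- modelTemplate("M1")
#' m <- buildModel(c(N_A = 10000, r = 1e-8, T = 1.0), tpl$map, tpl$template)
#' @export
buildModel <- function(params, map, template) {
  if (length(params) != length(map@names))
    stop("expected ", length(map@names), " parameters, got ", length(params))
  params <- as.numeric(params)
  names(params) <- map@names
  if (any(params < map@lower | params > map@upper)) {
    bad <- map@names[params < map@lower | params > map@upper]
    return(structure(list(message = paste("out of bounds:",
                                          paste(bad, collapse = ", "))),
                     class = "infeasiblePoint"))
  }
  ok <- map@constraints(params)
  if (!isTRUE(ok))
    return(structure(list(message = if (is.character(ok)) ok else
                            "nonlinear constraint violated"),
                     class = "infeasiblePoint"))
  model <- map@bind(template, params)
  model@parameters <- params
  validObject(model)
  model
}

#' @rdname buildModel
#' @param x object returned by \code{buildModel}.
#' @export
isInfeasible <- function(x) inherits(x, "infeasiblePoint")

#' Convert a model to simulator (scaled) units
#'
#' Produces the scaled quantities the ARG sampler consumes: population sizes
#' as ratios to the reference size, growth rates and event times in units of
#' \code{4 * referenceSize} generations, the backward-in-time event list, and
#' the block-scaled mutation and recombination rates
#' \eqn{\theta = 4 N_{ref} \mu E} (with \eqn{E} the effective block length)
#' and \eqn{\rho = 4 N_{ref} r (L - 1)} (with \eqn{L - 1} the number of
#' inter-site gaps in a block of length \eqn{L}).
#'
#' @param model a \code{\link{demographicModel}}.
#' @param blockLength block length in bp.
#' @param effectiveLength callable bases per block (defaults to
#'   \code{blockLength}).
#' @return List with \code{popNames}, \code{sizeRel}, \code{growthScaled},
#'   \code{events} (numeric matrix time/code/i/j/value, 0-based population
#'   indices, backward-time semantics), \code{thetaBlock}, \code{rhoBlock}.
#' @export
toScaledUnits <- function(model, blockLength,
                          effectiveLength = blockLength) {
  stopifnot(blockLength >= 1)
  Nref <- referenceSize(model)
  pops <- populations(model)
  idx <- function(nm) match(nm, pops$name) - 1L
  ev <- demographicEvents(model)
  em <- matrix(0, nrow(ev), 5,
               dimnames = list(NULL, c("time", "code", "i", "j", "value")))
  for (r in seq_len(nrow(ev))) {
    em[r, "time"] <- ev$time[r]
    switch(ev$kind[r],
      split_join = {
        em[r, "code"] <- 1
        em[r, "i"] <- idx(ev$pop1[r]); em[r, "j"] <- idx(ev$pop2[r])
      },
      size_change = {
        em[r, "code"] <- 2
        em[r, "i"] <- idx(ev$pop1[r]); em[r, "value"] <- ev$value[r] / Nref
      },
      growth_change = {
        em[r, "code"] <- 3
        em[r, "i"] <- idx(ev$pop1[r])
        em[r, "value"] <- ev$value[r] * 4 * Nref
      },
      migration_change = {
        ## forward donor pop1 -> recipient pop2: backward, lineages in the
        ## recipient jump to the donor at rate 4*Nref*m
        em[r, "code"] <- 4
        em[r, "i"] <- idx(ev$pop2[r]); em[r, "j"] <- idx(ev$pop1[r])
        em[r, "value"] <- ev$value[r]
      },
      admixture_pulse = {
        em[r, "code"] <- 5
        em[r, "i"] <- idx(ev$pop2[r]); em[r, "j"] <- idx(ev$pop1[r])
        em[r, "value"] <- ev$value[r]
      })
  }
  list(popNames = pops$name,
       sizeRel = pops$size / Nref,
       growthScaled = pops$growth * 4 * Nref,
       events = em,
       thetaBlock = 4 * Nref * mutationRate(model) * effectiveLength,
       rhoBlock = 4 * Nref * recombinationRate(model) *
         max(blockLength - 1, 0))
}

#' Convert between scaled times and years
#'
#' @param timeScaled time in units of \code{4 * referenceSize} generations.
#' @param model a \code{\link{demographicModel}}.
#' @param generationTime generation time in years.
#' @return Time in years (\code{scaledToYears}) or scaled units
#'   (\code{yearsToScaled}).
#' @export
scaledToYears <- function(timeScaled, model, generationTime = 20) {
  timeScaled * 4 * referenceSize(model) * generationTime
}

#' @rdname scaledToYears
#' @param years time in years.
#' @export
yearsToScaled <- function(years, model, generationTime = 20) {
  years / (4 * referenceSize(model) * generationTime)
}

## ---- ms-style command-line interoperability ----

#' Convert a demographic model to and from an ms-style command line
#'
#' \code{msCommand} renders the model as a Hudson \code{ms}-style argument
#' string (\code{-I/-n/-g/-ej/-en/-eg/-em/-es} flags; admixture pulses are
#' expressed as \code{-es} followed by \code{-ej} of the transient deme).
#' \code{parseMsCommand} parses that subset back into a
#' \code{\link{demographicModel}}; the two functions round-trip.
#'
#' @param model a \code{\link{demographicModel}}.
#' @param layout a \code{\link{sampleLayout}} (for sample sizes and block
#'   scaling).
#' @param nreps replicate count to put on the command line.
#' @return \code{msCommand}: a character string; \code{parseMsCommand}: a
#'   \code{DemographicModel}.
#' @export
msCommand <- function(model, layout, nreps = 1) {
  sc <- toScaledUnits(model, blockLength(layout), effectiveLength(layout))
  pops <- populations(model)
  X <- nrow(pops)
  b <- sampleSizes(layout)
  parts <- c("ms", sum(b), nreps,
             "-t", format(sc$thetaBlock, digits = 10))
  if (sc$rhoBlock > 0)
    parts <- c(parts, "-r", format(sc$rhoBlock, digits = 10),
               blockLength(layout))
  if (X > 1) parts <- c(parts, "-I", X, b)
  for (i in seq_len(X)) {
    if (sc$sizeRel[i] != 1)
      parts <- c(parts, "-n", i, format(sc$sizeRel[i], digits = 10))
    if (sc$growthScaled[i] != 0)
      parts <- c(parts, "-g", i, format(sc$growthScaled[i], digits = 10))
  }
  nextPop <- X
  ev <- sc$events
  for (r in seq_len(nrow(ev))) {
    tm <- format(ev[r, "time"], digits = 10)
    i <- ev[r, "i"] + 1; j <- ev[r, "j"] + 1
    parts <- c(parts, switch(as.character(ev[r, "code"]),
      "1" = c("-ej", tm, i, j),
      "2" = c("-en", tm, i, format(ev[r, "value"], digits = 10)),
      "3" = c("-eg", tm, i, format(ev[r, "value"], digits = 10)),
      ## ms -em t i j x: i = forward recipient, j = forward donor
      "4" = c("-em", tm, i, j, format(ev[r, "value"], digits = 10)),
      "5" = {
        nextPop <- nextPop + 1
        c("-es", tm, i, format(1 - ev[r, "value"], digits = 10),
          "-ej", tm, nextPop, j)
      }))
  }
  paste(unlist(parts), collapse = " ")
}

#' @rdname msCommand
#' @param command an ms-style command string produced by \code{msCommand}.
#' @param referenceSize,mutationRate values not recoverable from the ms
#'   scaling, needed to reconstruct an unscaled model.
#' @export
parseMsCommand <- function(command, referenceSize = 1e4,
                           mutationRate = 2e-8) {
  tok <- strsplit(trimws(command), "\\s+")[[1]]
  if (tok[1] == "ms") tok <- tok[-(1:3)]
  num <- function(i) as.numeric(tok[i])
  X <- 1L
  b <- NULL
  theta <- NA_real_; rho <- 0; L <- NA_real_
  sizes <- NULL; growth <- NULL
  evs <- list()
  esPop <- integer() # transient demes created by -es, by 1-based index
  esInfo <- list()   # time and source pop of each pending -es
  i <- 1
  while (i <= length(tok)) {
    flag <- tok[i]
    if (flag == "-t") { theta <- num(i + 1); i <- i + 2 }
    else if (flag == "-r") { rho <- num(i + 1); L <- num(i + 2); i <- i + 3 }
    else if (flag == "-I") {
      X <- as.integer(tok[i + 1])
      b <- as.integer(tok[i + 1 + seq_len(X)])
      i <- i + 2 + X
    } else if (flag == "-n") {
      sizes <- c(sizes, setNames(num(i + 2), tok[i + 1])); i <- i + 3
    } else if (flag == "-g") {
      growth <- c(growth, setNames(num(i + 2), tok[i + 1])); i <- i + 3
    } else if (flag == "-m") {
      evs[[length(evs) + 1]] <- c(0, 4, as.integer(tok[i + 1]),
                                  as.integer(tok[i + 2]), num(i + 3))
      i <- i + 4
    } else if (flag == "-em") {
      evs[[length(evs) + 1]] <- c(num(i + 1), 4, as.integer(tok[i + 2]),
                                  as.integer(tok[i + 3]), num(i + 4))
      i <- i + 5
    } else if (flag == "-en") {
      evs[[length(evs) + 1]] <- c(num(i + 1), 2, as.integer(tok[i + 2]), NA,
                                  num(i + 3))
      i <- i + 4
    } else if (flag == "-eg") {
      evs[[length(evs) + 1]] <- c(num(i + 1), 3, as.integer(tok[i + 2]), NA,
                                  num(i + 3))
      i <- i + 4
    } else if (flag == "-es") {
      newPop <- X + length(esPop) + 1L
      esPop <- c(esPop, newPop)
      esInfo[[as.character(newPop)]] <-
        list(time = num(i + 1), from = as.integer(tok[i + 2]),
             frac = 1 - num(i + 3))
      i <- i + 4
    } else if (flag == "-ej") {
      from <- as.integer(tok[i + 2]); to <- as.integer(tok[i + 3])
      info <- esInfo[[as.character(from)]]
      if (!is.null(info)) {
        ## -es/-ej pair encodes a pulse: recipient info$from, donor 'to'
        evs[[length(evs) + 1]] <- c(info$time, 5, info$from, to, info$frac)
      } else {
        evs[[length(evs) + 1]] <- c(num(i + 1), 1, from, to, NA)
      }
      i <- i + 4
    } else {
      stop("unsupported ms flag in command: ", flag)
    }
  }
  if (is.null(b)) b <- X
  popNames <- paste0("pop", seq_len(X))
  szRel <- rep(1, X); grw <- rep(0, X)
  if (!is.null(sizes)) szRel[as.integer(names(sizes))] <- sizes
  if (!is.null(growth)) grw[as.integer(names(growth))] <- growth
  rows <- lapply(evs, function(e) {
    kind <- c("split_join", "size_change", "growth_change",
              "migration_change", "admixture_pulse")[e[2]]
    switch(kind,
      split_join = demographicEvent(kind, e[1], popNames[e[3]],
                                    popNames[e[4]]),
      size_change = demographicEvent(kind, e[1], popNames[e[3]],
                                     value = e[5] * referenceSize),
      growth_change = demographicEvent(kind, e[1], popNames[e[3]],
                                       value = e[5] / (4 * referenceSize)),
      ## ms -em i j: i = forward recipient, j = forward donor
      migration_change = demographicEvent(kind, e[1], popNames[e[4]],
                                          popNames[e[3]], value = e[5]),
      admixture_pulse = demographicEvent(kind, e[1], popNames[e[4]],
                                         popNames[e[3]], value = e[5]))
  })
  events <- do.call(rbind, rows)
  demographicModel(
    data.frame(name = popNames, size = szRel * referenceSize,
               growth = grw / (4 * referenceSize)),
    events, referenceSize = referenceSize, mutationRate = mutationRate,
    recombinationRate = if (rho > 0 && !is.na(L))
      rho / (4 * referenceSize * (L - 1)) else 0)
}
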