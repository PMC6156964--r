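#' @useDynLib blockLik, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats optim rpois runif rnorm sd setNames
#' @importFrom utils head read.table write.table
NULL

#' Sample layout of a multi-population blockwise dataset
#'
#' Describes how many genomes were sampled per population, whether the data
#' are polarized (an outgroup assigns ancestral states, so joint-SFS classes
#' are unfolded) and the physical block geometry: the block length in bp and
#' the effective (callable) number of bases per block that enters the
#' block-scaled mutation rate.
#'
#' @slot sampleSizes integer vector, genomes sampled per population.
#' @slot polarized logical; if \code{FALSE} the joint SFS is folded.
#' @slot blockLength block length in bp.
#' @slot effectiveLength callable bases per block used for the mutation rate.
#' @export
setClass("SampleLayout",
  representation(sampleSizes = "integer", polarized = "logical",
                 blockLength = "numeric", effectiveLength = "numeric"))

setValidity("SampleLayout", function(object) {
  b <- object@sampleSizes
  if (length(b) < 1 || any(b < 1L)) return("each population needs >= 1 genome")
  if (sum(b) < 2L) return("at least two genomes must be sampled in total")
  if (object@blockLength < 1) return("blockLength must be >= 1")
  if (object@effectiveLength < 1 || object@effectiveLength > object@blockLength)
    return("effectiveLength must lie in [1, blockLength]")
  TRUE
})

#' Construct a sample layout
#'
#' @param sampleSizes integer vector of genomes sampled per population.
#' @param polarized logical; \code{TRUE} when an outgroup polarizes variants.
#' @param blockLength block length in bp.
#' @param effectiveLength callable bases per block (defaults to
#'   \code{blockLength}).
#' @return A \code{SampleLayout} object.
#' @examples
#' sampleLayout(c(2, 2), blockLength = 2000, effectiveLength = 1600)
#' @export
sampleLayout <- function(sampleSizes, polarized = FALSE, blockLength = 1000,
                         effectiveLength = blockLength) {
  new("SampleLayout", sampleSizes = as.integer(sampleSizes),
      polarized = as.logical(polarized), blockLength = as.numeric(blockLength),
      effectiveLength = as.numeric(effectiveLength))
}

.EVENT_KINDS <- c("split_join", "size_change", "growth_change",
                  "migration_change", "admixture_pulse")

#' Parameterized demographic model
#'
#' A demographic history over one or more populations: present-day effective
#' sizes and exponential growth rates, plus a time-ordered list of events
#' (population joins viewed backward in time, size or growth changes,
#' continuous-migration rate changes and admixture pulses), together with the
#' per-site per-generation mutation and recombination rates.
#'
#' Scaling conventions: event times are in units of \code{4 * referenceSize}
#' generations, backward from the present; population sizes are in
#' individuals; growth rates are per generation; continuous migration rates
#' are \code{4 * referenceSize * m} where \code{m} is the per-generation
#' migration fraction; migration and pulse directions are stated
#' forward in time as donor to recipient.
#'
#' @slot populations data.frame with columns \code{name}, \code{size}
#'   (individuals) and \code{growth} (per-generation exponential rate).
#' @slot events data.frame with columns \code{kind}, \code{time},
#'   \code{pop1}, \code{pop2}, \code{value}; see \code{\link{demographicEvent}}.
#' @slot referenceSize reference effective size used for all time scalings.
#' @slot mutationRate per-site per-generation mutation rate.
#' @slot recombinationRate per-site per-generation recombination rate.
#' @slot parameters free-parameter vector this model was built from (may be
#'   empty for hand-constructed models).
#' @export
setClass("DemographicModel",
  representation(populations = "data.frame", events = "data.frame",
                 referenceSize = "numeric", mutationRate = "numeric",
                 recombinationRate = "numeric", parameters = "numeric"))

setValidity("DemographicModel", function(object) {
  p <- object@populations
  e <- object@events
  if (!all(c("name", "size", "growth") %in% names(p)))
    return("populations needs columns name, size, growth")
  if (any(p$size <= 0)) return("population sizes must be positive")
  if (any(!is.finite(p$growth))) return("growth rates must be finite")
  if (anyDuplicated(p$name)) return("population names must be unique")
  if (nrow(e)) {
    if (!all(c("kind", "time", "pop1", "pop2", "value") %in% names(e)))
      return("events needs columns kind, time, pop1, pop2, value")
    if (!all(e$kind %in% .EVENT_KINDS))
      return(paste("unknown event kind; allowed:",
                   paste(.EVENT_KINDS, collapse = ", ")))
    if (any(e$time < 0)) return("event times must be >= 0")
    if (is.unsorted(e$time)) return("events must be sorted by time")
    lbl <- c(e$pop1, e$pop2)
    lbl <- lbl[!is.na(lbl)]
    if (!all(lbl %in% p$name))
      return("every event participant must be a declared population")
    pulses <- e$kind == "admixture_pulse"
    if (any(pulses & (e$value < 0 | e$value > 1)))
      return("admixture pulse fractions must lie in [0, 1]")
    mig <- e$kind == "migration_change"
    if (any(mig & e$value < 0)) return("migration rates must be >= 0")
    two <- e$kind %in% c("split_join", "migration_change", "admixture_pulse")
    if (any(two & (is.na(e$pop1) | is.na(e$pop2))))
      return("split_join, migration_change and admixture_pulse need two populations")
  }
  if (object@referenceSize <= 0) return("referenceSize must be positive")
  if (object@mutationRate < 0 || object@recombinationRate < 0)
    return("mutation and recombination rates must be >= 0")
  TRUE
})

#' Build a demographic event record
#'
#' @param kind one of \code{"split_join"}, \code{"size_change"},
#'   \code{"growth_change"}, \code{"migration_change"},
#'   \code{"admixture_pulse"}.
#' @param time scaled event time (units of \code{4 * referenceSize}
#'   generations, backward from the present).
#' @param pop1,pop2 population labels. For \code{split_join}, \code{pop1} is
#'   the derived population that merges (backward in time) into \code{pop2}.
#'   For \code{migration_change} and \code{admixture_pulse}, \code{pop1} is
#'   the forward-in-time donor and \code{pop2} the recipient.
#' @param value event-specific scalar: new size in individuals
#'   (\code{size_change}), new per-generation growth rate
#'   (\code{growth_change}), scaled rate \code{4*Nref*m}
#'   (\code{migration_change}) or pulse fraction in \code{[0, 1]}
#'   (\code{admixture_pulse}).
#' @return A one-row data.frame suitable for \code{\link{demographicModel}}.
#' @export
demographicEvent <- function(kind, time, pop1, pop2 = NA_character_,
                             value = NA_real_) {
  kind <- match.arg(kind, .EVENT_KINDS)
  data.frame(kind = kind, time = as.numeric(time),
             pop1 = as.character(pop1), pop2 = as.character(pop2),
             value = as.numeric(value), stringsAsFactors = FALSE)
}

#' Construct a demographic model
#'
#' @param populations data.frame with columns \code{name}, \code{size}
#'   (individuals), \code{growth} (per-generation rate); a missing
#'   \code{growth} column defaults to zero.
#' @param events data.frame of event rows (see
#'   \code{\link{demographicEvent}}); rows are sorted by time, preserving the
#'   given order among simultaneous events.
#' @param referenceSize reference size for time scaling.
#' @param mutationRate,recombinationRate per-site per-generation rates.
#' @param parameters optional free-parameter vector recorded for provenance.
#' @return A \code{DemographicModel} object.
#' @export
demographicModel <- function(populations, events = NULL,
                             referenceSize, mutationRate = 2e-8,
                             recombinationRate = 0, parameters = numeric()) {
  if (is.null(populations$growth)) populations$growth <- 0
  populations$name <- as.character(populations$name)
  if (is.null(events) || !nrow(events)) {
    events <- data.frame(kind = character(), time = numeric(),
                         pop1 = character(), pop2 = character(),
                         value = numeric(), stringsAsFactors = FALSE)
  } else {
    events <- events[order(events$time), , drop = FALSE]
    rownames(events) <- NULL
  }
  new("DemographicModel", populations = populations, events = events,
      referenceSize = as.numeric(referenceSize),
      mutationRate = as.numeric(mutationRate),
      recombinationRate = as.numeric(recombinationRate),
      parameters = as.numeric(parameters))
}

#' Free-parameter map for model fitting
#'
#' Binds a flat vector of free parameters to fields of a template
#' \code{\link{demographicModel}}, with per-parameter box bounds, the search
#' scale (log for positive quantities, linear for signed ones such as growth
#' rates) and optional nonlinear ordering constraints (for example an
#' admixture time that must precede the population split).
#'
#' @slot names ordered free-parameter labels.
#' @slot lower,upper per-parameter bounds (lower < upper).
#' @slot logScale logical per parameter; searched on log scale when TRUE.
#' @slot constraints function of the named parameter vector returning TRUE
#'   when feasible, or a character description of the violated constraint.
#' @slot bind function(template, params) building the bound model.
#' @export
setClass("ParameterMap",
  representation(names = "character", lower = "numeric", upper = "numeric",
                 logScale = "logical", constraints = "function",
                 bind = "function"))

setValidity("ParameterMap", function(object) {
  n <- length(object@names)
  if (length(object@lower) != n || length(object@upper) != n ||
      length(object@logScale) != n)
    return("names, lower, upper and logScale must have equal length")
  if (any(object@lower >= object@upper))
    return("every lower bound must be below its upper bound")
  if (anyDuplicated(object@names)) return("parameter names must be unique")
  TRUE
})

#' Construct a parameter map
#'
#' @param names,lower,upper,logScale per-parameter metadata.
#' @param constraints feasibility function (see \code{ParameterMap}).
#' @param bind binding function(template, named parameter vector).
#' @return A \code{ParameterMap}.
#' @export
parameterMap <- function(names, lower, upper, logScale = NULL,
                         constraints = function(p) TRUE, bind) {
  if (is.null(logScale)) logScale <- lower > 0
  new("ParameterMap", names = names, lower = as.numeric(lower),
      upper = as.numeric(upper), logScale = as.logical(logScale),
      constraints = constraints, bind = bind)
}

#' Blockwise SFS table
#'
#' The histogram of blockwise mutation configurations: each row of
#' \code{configs} is a vector of per-class mutation counts (entries of
#' \code{-1} encode the lumped \dQuote{more than k_max} marker) and
#' \code{counts} gives the number of blocks showing that configuration.
#'
#' @slot layout the \code{\link{sampleLayout}} the classes refer to.
#' @slot configs integer matrix, one row per configuration, one column per
#'   mutation class (class order as in \code{\link{mutationClasses}}).
#' @slot counts numeric vector of block counts per configuration.
#' @slot kmax per-class cap; \code{NA} when no lumping is in force.
#' @export
setClass("BsfsTable",
  representation(layout = "SampleLayout", configs = "matrix",
                 counts = "numeric", kmax = "integer"))

setValidity("BsfsTable", function(object) {
  if (nrow(object@configs) != length(object@counts))
    return("configs and counts must agree in length")
  if (ncol(object@configs) != nrow(mutationClasses(object@layout)))
    return("configuration width must equal the number of mutation classes")
  if (any(object@counts < 0)) return("block counts must be >= 0")
  k <- object@configs
  if (any(k < -1)) return("configuration entries must be >= 0 or the lumped marker")
  if (any(k == -1L) && is.na(object@kmax))
    return("lumped entries require a k_max")
  if (!is.na(object@kmax) && any(k > object@kmax))
    return("configuration entries exceed k_max")
  if (anyDuplicated(apply(k, 1, paste, collapse = ",")))
    return("duplicate configurations in table")
  TRUE
})

#' Construct a bSFS table
#'
#' @param layout a \code{\link{sampleLayout}}.
#' @param configs integer matrix of configurations (rows) by mutation class
#'   (columns); \code{-1} marks a lumped \code{> kmax} entry.
#' @param counts block count per configuration.
#' @param kmax optional per-class cap in force.
#' @return A \code{BsfsTable}.
#' @export
bsfsTable <- function(layout, configs, counts, kmax = NA) {
  configs <- matrix(as.integer(configs), nrow = NROW(configs),
                    ncol = NCOL(configs))
  new("BsfsTable", layout = layout, configs = configs,
      counts = as.numeric(counts), kmax = as.integer(kmax))
}

## ---- accessors ----

#' @describeIn sampleLayout genomes sampled per population
#' @param x,object a SampleLayout
#' @export
sampleSizes <- function(x) x@sampleSizes

#' @describeIn sampleLayout block length in bp
#' @export
blockLength <- function(x) x@blockLength

#' @describeIn sampleLayout callable bases per block
#' @export
effectiveLength <- function(x) x@effectiveLength

#' @describeIn sampleLayout whether variants are polarized
#' @export
isPolarized <- function(x) x@polarized

#' Accessors for bSFS tables
#'
#' @param x a \code{\link{bsfsTable}}.
#' @return \code{totalBlocks}: the number of blocks tallied;
#'   \code{configCounts}: named numeric vector of block counts;
#'   \code{configMatrix}: the configuration matrix; \code{tableLayout}: the
#'   \code{SampleLayout}; \code{kMax}: the lumping cap (NA if none).
#' @export
totalBlocks <- function(x) sum(x@counts)

#' @rdname totalBlocks
#' @export
configCounts <- function(x) setNames(x@counts, .configLabels(x@configs))

#' @rdname totalBlocks
#' @export
configMatrix <- function(x) x@configs

#' @rdname totalBlocks
#' @export
tableLayout <- function(x) x@layout

#' @rdname totalBlocks
#' @export
kMax <- function(x) x@kmax

#' Accessors for demographic models
#'
#' @param x a \code{\link{demographicModel}}.
#' @export
populations <- function(x) x@populations

#' @rdname populations
#' @export
demographicEvents <- function(x) x@events

#' @rdname populations
#' @export
referenceSize <- function(x) x@referenceSize

#' @rdname populations
#' @export
mutationRate <- function(x) x@mutationRate

#' @rdname populations
#' @export
recombinationRate <- function(x) x@recombinationRate

#' @rdname populations
#' @export
freeParameters <- function(x) x@parameters

.configLabels <- function(K) {
  apply(K, 1, function(r) paste(ifelse(r < 0, ">k", r), collapse = ","))
}

setMethod("show", "SampleLayout", function(object) {
  cat("SampleLayout:", paste(object@sampleSizes, collapse = "+"),
      "genomes from", length(object@sampleSizes), "population(s);",
      if (object@polarized) "polarized" else "folded", "\n")
  cat("  block:", object@blockLength, "bp,", object@effectiveLength,
      "callable\n")
})

setMethod("show", "DemographicModel", function(object) {
  cat("DemographicModel with", nrow(object@populations), "population(s),",
      nrow(object@events), "event(s)\n")
  cat("  N_ref =", object@referenceSize,
      " mu =", object@mutationRate, " r =", object@recombinationRate, "\n")
  if (nrow(object@events)) {
    ev <- object@events
    cat(paste0("  t=", signif(ev$time, 4), " ", ev$kind,
               ifelse(is.na(ev$pop2), paste0(" [", ev$pop1, "]"),
                      paste0(" [", ev$pop1, " -> ", ev$pop2, "]")),
               ifelse(is.na(ev$value), "", paste0(" = ", signif(ev$value, 4))),
               collapse = "\n"), "\n")
  }
})

setMethod("show", "BsfsTable", function(object) {
  cat("BsfsTable:", nrow(object@configs), "unique configuration(s) over",
      totalBlocks(object), "block(s)\n")
  show(object@layout)
  if (!is.na(object@kmax)) cat("  lumped at k_max =", object@kmax, "\n")
})

setMethod("show", "ParameterMap", function(object) {
  cat("ParameterMap:", length(object@names), "free parameter(s)\n")
  for (i in seq_along(object@names))
    cat(sprintf("  %-12s [%g, %g]%s\n", object@names[i], object@lower[i],
                object@upper[i], if (object@logScale[i]) " (log)" else ""))
})
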