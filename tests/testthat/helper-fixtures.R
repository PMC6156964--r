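# shared fixtures: small models and layouts built in code

# single panmictic population of size N (reference size N)
onePopModel <- function(N = 1e4, mu = 2e-8, r = 0) {
  demographicModel(data.frame(name = "P", size = N, growth = 0),
                   referenceSize = N, mutationRate = mu,
                   recombinationRate = r)
}

# layout whose block-scaled mutation rate is exactly theta for the model
layoutWithTheta <- function(model, theta, sampleSizes = 2,
                            polarized = FALSE) {
  E <- theta / (4 * referenceSize(model) * mutationRate(model))
  sampleLayout(sampleSizes, polarized = polarized, blockLength = E,
               effectiveLength = E)
}

# the two-population divergence truth used across recovery experiments
# (ancestral size, split time and daughter sizes of the 2-kb orangutan-like
# configuration; recombination fixed at the mutation rate)
m2Fixture <- function() {
  tpl <- modelTemplate("M2", fixed = c(r = 2e-8))
  truth <- c(N_A = 1380, T = 2.66, N_S = 22100, N_B = 8610)
  lay <- sampleLayout(c(2, 2), blockLength = 2000, effectiveLength = 1600)
  model <- buildModel(truth[tpl$map@names], tpl$map, tpl$template)
  list(tpl = tpl, truth = truth[tpl$map@names], lay = lay, model = model)
}

# geometric law for the pairwise-sample blockwise SFS:
# P(k) = theta^k / (1 + theta)^(k + 1)
geomBsfs <- function(k, theta) theta^k / (1 + theta)^(k + 1)

# quick folded (2,2) class labels
lab22 <- function() rownames(mutationClasses(sampleLayout(c(2, 2))))
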